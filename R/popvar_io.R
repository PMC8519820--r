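## popvar_io: multi-sample VCF ingestion, the genotype matrix container and
## the site-level noise filters applied before any haplotype analysis.

#' Construct a genotype matrix
#'
#' The central container for population genotypes against a draft assembly.
#' Calls are coded per accession as `0` (hom-ref), `1` (het), `2` (hom-alt),
#' `NA` (missing); the accession order of `panel` is frozen for the whole run,
#' because variation patterns are defined as the succession of genotype states
#' within a fixed order of individuals.
#'
#' @param panel character vector of unique accession names (order is frozen).
#' @param sites `data.frame`/`data.table` with columns `contig`, `pos`
#'   (1-based, VCF convention), `ref`, `alt` (comma-separated if
#'   multi-allelic), and optionally `is_snp`, `is_biallelic`, `total_depth`.
#'   Within a contig, `pos` must be strictly increasing.
#' @param calls integer matrix, `nrow(sites)` x `length(panel)`.
#' @param contig_lengths named numeric vector of contig lengths (bp); every
#'   site's contig must be present.
#' @param depths optional integer matrix of per-accession read depths,
#'   same shape as `calls`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(panel, sites, calls, contig_lengths, depths = NULL) {
  stopifnot(length(panel) >= 1L, !anyDuplicated(panel))
  sites <- as.data.table(sites)
  if (!nrow(sites)) {
    sites <- data.table(contig = character(), pos = integer(),
                        ref = character(), alt = character(),
                        is_snp = logical(), is_biallelic = logical(),
                        total_depth = integer())
  }
  for (col in c("is_snp", "is_biallelic")) {
    if (is.null(sites[[col]])) sites[, (col) := TRUE]
  }
  if (is.null(sites[["total_depth"]])) sites[, total_depth := NA_integer_]
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(sites) != nrow(calls) || ncol(calls) != length(panel))
    stop("calls must be nrow(sites) x length(panel)")
  bad <- setdiff(unique(sites$contig), names(contig_lengths))
  if (length(bad))
    stop("sites refer to contigs absent from contig_lengths: ",
         paste(head(bad, 5), collapse = ", "))
  if (nrow(sites)) {
    ord <- sites[, all(diff(pos) > 0), by = contig]
    if (!all(ord$V1)) stop("site positions must be strictly increasing per contig")
    if (any(sites$pos < 1L) ||
        any(sites$pos > contig_lengths[sites$contig]))
      stop("site positions outside contig bounds")
  }
  structure(list(panel = panel, sites = sites, calls = calls,
                 depths = depths, contig_lengths = contig_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites on %d contigs, %d accessions\n",
              nrow(x$sites), length(unique(x$sites$contig)), length(x$panel)))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param m a [genotype_matrix()].
#' @return integer site count.
#' @export
n_sites <- function(m) nrow(m$sites)

.gt_to_code <- function(gt) {
  ## GT strings ("0/1", "1|0", "./.", ".") -> integer codes; any allele > 1 is
  ## treated as carrying a non-reference allele (such records are flagged
  ## non-biallelic and removed by filter_sites anyway).
  a <- sub("^([^/|]*)[/|]?.*$", "\\1", gt)
  b <- sub("^[^/|]*[/|]([^/|]*)$", "\\1", gt)
  b[!grepl("[/|]", gt)] <- a[!grepl("[/|]", gt)]  # haploid calls
  miss <- a == "." | b == "." | gt == "." | is.na(gt)
  ai <- suppressWarnings(as.integer(a))
  bi <- suppressWarnings(as.integer(b))
  ai[miss | is.na(ai)] <- 0L
  bi[miss | is.na(bi)] <- 0L
  code <- integer(length(gt))
  nz <- (ai > 0L) + (bi > 0L)
  code[nz == 0L] <- .REF_HOM
  code[nz == 1L] <- .HET
  code[nz == 2L] <- .ALT_HOM
  code[miss] <- NA_integer_
  code
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Genotypes are mapped as `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`,
#' `./. -> NA`. Multi-allelic and non-SNP records are retained but flagged
#' (`is_biallelic`, `is_snp`) so that the filter stage can attribute their
#' removal. Contig lengths are taken from the VCF `##contig` headers.
#' Per-sample depths (`FORMAT/DP`) and the site total depth (`INFO/DP`, or the
#' sum of per-sample depths) are kept when present so that the depth filters
#' can be applied.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param panel_subset optional character vector of accession names; the
#'   returned panel uses this order. An absent name is an error.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, panel_subset = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  gmat <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(gmat)) stop("VCF has no GT genotype field: ", path)
  gt <- gmat$GT
  panel <- colnames(gt)
  if (!is.null(panel_subset)) {
    missing_acc <- setdiff(panel_subset, panel)
    if (length(missing_acc))
      stop("requested accession(s) absent from VCF: ",
           paste(missing_acc, collapse = ", "))
    gt <- gt[, panel_subset, drop = FALSE]
    panel <- panel_subset
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- vapply(as(alt_list, "CharacterList"), function(x)
    paste(as.character(x), collapse = ","), character(1))
  ref_chr <- as.character(VariantAnnotation::ref(vcf))
  n_alt <- lengths(alt_list)
  is_biallelic <- n_alt == 1L
  is_snp <- nchar(ref_chr) == 1L &
    !grepl("[^ACGTacgt,]", alt_chr) &
    vapply(strsplit(alt_chr, ",", fixed = TRUE),
           function(x) all(nchar(x) == 1L), logical(1))

  calls <- matrix(.gt_to_code(as.vector(gt)), nrow = nrow(gt),
                  ncol = ncol(gt))
  colnames(calls) <- panel

  depths <- NULL
  if ("DP" %in% names(gmat)) {
    depths <- gmat$DP
    if (!is.null(panel_subset)) depths <- depths[, panel_subset, drop = FALSE]
    storage.mode(depths) <- "integer"
    if (all(is.na(depths))) depths <- NULL  # declared but never filled
  }
  info <- VariantAnnotation::info(vcf)
  total_depth <- if ("DP" %in% colnames(info)) as.integer(info$DP)
                 else if (!is.null(depths)) as.integer(rowSums(depths, na.rm = TRUE))
                 else rep(NA_integer_, nrow(calls))

  sl <- GenomeInfoDb::seqinfo(vcf)
  contig_lengths <- stats::setNames(as.numeric(GenomeInfoDb::seqlengths(sl)),
                                    GenomeInfoDb::seqnames(sl))
  if (anyNA(contig_lengths)) {
    ## headers without lengths: fall back to max observed position per contig
    obs <- tapply(GenomicRanges::start(rr), as.character(GenomicRanges::seqnames(rr)), max)
    nas <- names(contig_lengths)[is.na(contig_lengths)]
    contig_lengths[nas] <- obs[nas]
    contig_lengths <- contig_lengths[!is.na(contig_lengths)]
  }

  sites <- data.table(contig = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      ref = ref_chr, alt = alt_chr,
                      is_snp = is_snp, is_biallelic = is_biallelic,
                      total_depth = total_depth)
  ord <- order(sites$contig, sites$pos)
  genotype_matrix(panel, sites[ord], calls[ord, , drop = FALSE],
                  contig_lengths,
                  depths = if (!is.null(depths)) depths[ord, , drop = FALSE])
}

#' Site filter configuration
#'
#' Defaults follow the pipeline defaults: a position is kept when at least
#' half of the accessions cover it with at least one read, when at most 300
#' reads in total cover it, when at least two accessions carry the reference
#' and at least two the alternative allele, when it is a biallelic SNP, and
#' when the minor allele frequency is at least 0.05. All "at least/at most"
#' bounds are inclusive. `max_missing_fraction` is an optional stricter
#' missingness override (set to 0.10 to reproduce the quinoa run).
#'
#' @param min_called_fraction minimum fraction of accessions with a covered,
#'   non-missing genotype (default 0.5).
#' @param min_ref_genotypes minimum accessions whose call carries the
#'   reference allele, i.e. hom-ref or het (default 2).
#' @param min_alt_genotypes minimum accessions whose call carries the
#'   alternative allele, i.e. hom-alt or het (default 2).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_total_depth maximum total read depth across accessions
#'   (default 300); skipped when the VCF carries no depth information.
#' @param min_depth_per_called_accession minimum per-accession depth for a
#'   call to count as covered (default 1); applied only when per-sample
#'   depths are available.
#' @param biallelic_snp_only drop non-SNP and multi-allelic records
#'   (default TRUE).
#' @param max_missing_fraction optional maximum fraction of missing genotypes
#'   (default NA = only `min_called_fraction` applies).
#' @return a `site_filter_config` list.
#' @export
site_filter_config <- function(min_called_fraction = 0.5,
                               min_ref_genotypes = 2L,
                               min_alt_genotypes = 2L,
                               maf_min = 0.05,
                               max_total_depth = 300,
                               min_depth_per_called_accession = 1L,
                               biallelic_snp_only = TRUE,
                               max_missing_fraction = NA_real_) {
  stopifnot(min_called_fraction >= 0, min_called_fraction <= 1,
            maf_min >= 0, maf_min <= 1,
            min_ref_genotypes >= 0, min_alt_genotypes >= 0,
            is.na(max_missing_fraction) ||
              (max_missing_fraction >= 0 && max_missing_fraction <= 1))
  structure(list(min_called_fraction = min_called_fraction,
                 min_ref_genotypes = as.integer(min_ref_genotypes),
                 min_alt_genotypes = as.integer(min_alt_genotypes),
                 maf_min = maf_min,
                 max_total_depth = max_total_depth,
                 min_depth_per_called_accession =
                   as.integer(min_depth_per_called_accession),
                 biallelic_snp_only = biallelic_snp_only,
                 max_missing_fraction = max_missing_fraction),
            class = "site_filter_config")
}

#' Minor allele frequency of one site
#'
#' Alternative allele count is `2 * hom_alt + het` over `2 * called`;
#' the minor allele frequency is `min(f, 1 - f)`. Undefined (NA) when no
#' accession is called; such sites are treated as filtered.
#'
#' @param calls integer genotype code vector for one site.
#' @return MAF in `[0, 0.5]`, or `NA` if nothing is called.
#' @export
minor_allele_frequency <- function(calls) {
  called <- sum(!is.na(calls))
  if (called == 0L) return(NA_real_)
  f <- sum(calls, na.rm = TRUE) / (2 * called)
  min(f, 1 - f)
}

## vectorized per-site statistics used by filter_sites
.site_stats <- function(m, cfg) {
  calls <- m$calls
  called <- !is.na(calls)
  covered <- called
  if (!is.null(m$depths)) {
    dp <- m$depths
    dp[is.na(dp)] <- 0L
    covered <- called & dp >= cfg$min_depth_per_called_accession
  }
  n <- length(m$panel)
  n_called <- rowSums(called)
  alt_cnt <- rowSums(calls, na.rm = TRUE)          # alt allele count
  f <- ifelse(n_called > 0, alt_cnt / (2 * n_called), NA_real_)
  list(n = n,
       called_frac = rowSums(covered) / n,
       missing_frac = 1 - n_called / n,
       n_ref_geno = rowSums(calls <= 1L, na.rm = TRUE),  # carries ref allele
       n_alt_geno = rowSums(calls >= 1L, na.rm = TRUE),  # carries alt allele
       maf = pmin(f, 1 - f))
}

#' Apply site-level noise filters
#'
#' Retains sites satisfying all rules of `cfg`; the report partitions
#' removals by the first failing rule in a fixed order:
#' `not_snp`, `not_biallelic`, `missingness`, `depth`, `genotype_counts`,
#' `maf`. Depth rules are skipped (and reported as `depth_rule_skipped`)
#' when the matrix carries no depth information. Filtering never reorders
#' sites or accessions and is idempotent.
#'
#' @param m a [genotype_matrix()].
#' @param cfg a [site_filter_config()].
#' @return list with `matrix` (filtered [genotype_matrix()]) and `report`
#'   (named integer vector of removal counts plus `retained`).
#' @export
filter_sites <- function(m, cfg = site_filter_config()) {
  stopifnot(inherits(m, "genotype_matrix"), inherits(cfg, "site_filter_config"))
  ns <- nrow(m$sites)
  report <- c(not_snp = 0L, not_biallelic = 0L, missingness = 0L,
              depth = 0L, genotype_counts = 0L, maf = 0L, retained = 0L)
  if (!ns) {
    return(list(matrix = m, report = report))
  }
  st <- .site_stats(m, cfg)
  depth_known <- !all(is.na(m$sites$total_depth))

  fail <- rep(NA_character_, ns)
  mark <- function(fail, cond, rule) {
    idx <- is.na(fail) & cond & !is.na(cond)
    fail[idx] <- rule
    fail
  }
  if (cfg$biallelic_snp_only) {
    fail <- mark(fail, !m$sites$is_snp, "not_snp")
    fail <- mark(fail, !m$sites$is_biallelic, "not_biallelic")
  }
  miss_bad <- st$called_frac < cfg$min_called_fraction
  if (!is.na(cfg$max_missing_fraction))
    miss_bad <- miss_bad | st$missing_frac > cfg$max_missing_fraction
  fail <- mark(fail, miss_bad, "missingness")
  if (depth_known)
    fail <- mark(fail, m$sites$total_depth > cfg$max_total_depth, "depth")
  fail <- mark(fail, st$n_ref_geno < cfg$min_ref_genotypes |
                 st$n_alt_geno < cfg$min_alt_genotypes, "genotype_counts")
  fail <- mark(fail, is.na(st$maf) | st$maf < cfg$maf_min, "maf")

  keep <- is.na(fail)
  tab <- table(factor(fail, levels = c("not_snp", "not_biallelic",
                                       "missingness", "depth",
                                       "genotype_counts", "maf")))
  report[names(tab)] <- as.integer(tab)
  report["retained"] <- sum(keep)
  out <- genotype_matrix(m$panel, m$sites[keep],
                         m$calls[keep, , drop = FALSE], m$contig_lengths,
                         depths = if (!is.null(m$depths))
                           m$depths[keep, , drop = FALSE])
  if (!depth_known) attr(report, "depth_rule_skipped") <- TRUE
  list(matrix = out, report = report)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file with `##contig` headers, `GT` (and `DP` when depths
#' are present). The written file round-trips through [read_vcf()].
#'
#' @param m a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ldscaffold",
               sprintf("##contig=<ID=%s,length=%d>", names(m$contig_lengths),
                       as.integer(m$contig_lengths)),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               if (!is.null(m$depths))
                 "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", m$panel), collapse = "\t")), con)
  if (!nrow(m$sites)) return(invisible(path))
  gt <- matrix(c("0/0", "0/1", "1/1")[m$calls + 1L], nrow = nrow(m$calls))
  gt[is.na(m$calls)] <- "./."
  has_dp <- !is.null(m$depths)
  if (has_dp) {
    dp <- m$depths
    dp[is.na(dp)] <- 0L
    gt <- matrix(paste0(gt, ":", dp), nrow = nrow(gt))
  }
  info <- ifelse(is.na(m$sites$total_depth), ".",
                 paste0("DP=", m$sites$total_depth))
  lines <- paste(m$sites$contig, m$sites$pos, ".", m$sites$ref, m$sites$alt,
                 ".", "PASS", info, if (has_dp) "GT:DP" else "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write filtered sites as a TSV
#'
#' One row per site: contig, position, ref, alt and one genotype label per
#' accession (`REF_HOM`/`HET`/`ALT_HOM`/`MISSING`).
#'
#' @param m a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(m, path) {
  lab <- matrix(genotype_code_labels(m$calls), nrow = nrow(m$calls))
  colnames(lab) <- m$panel
  out <- cbind(m$sites[, .(contig, pos, ref, alt)], as.data.table(lab))
  fwrite(out, path, sep = "\t")
  invisible(path)
}
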