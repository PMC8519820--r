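## simpop: founder-mosaic population simulator, assembly fragmentation with
## known truth, simulated physical evidence, recovery metrics, and the
## closed-form utilities (k-mer genome size, LD r^2 decay).

#' Simulation configuration
#'
#' Defaults describe the package's reference benchmark: a selfing population
#' of 50 accessions derived from 8 founder haplotypes on 2 chromosomes of
#' 10 Mbp, with 3.5 variant sites per kbp, and a reference fragmented into
#' ~40 contigs. Founder allele sharing follows a neutral site-frequency
#' spectrum (P(k carrier founders) proportional to 1/k). Heterozygosity is
#' modelled as residual heterozygous blocks (a second founder mosaic active
#' inside blocks), with the block genome fraction calibrated so that the
#' expected share of heterozygous calls among variant calls equals
#' `het_fraction`.
#'
#' @param n_chromosomes number of chromosomes (default 2).
#' @param chromosome_length chromosome length in bp (default 1e7).
#' @param n_founders number of founder haplotypes F (default 8; F = 1 gives
#'   a population without segregating variation after filtering).
#' @param n_accessions panel size N (default 50).
#' @param variant_density expected variant sites per kbp (default 3.5).
#' @param recombination_rate expected crossovers per chromosome per accession
#'   lineage, accumulated over the population history (default 10; gives
#'   per-lineage haplotype blocks of ~1 Mbp and pattern sharing over a few
#'   hundred kbp, i.e. LD maintained over hundreds of kbp as expected for a
#'   selfer).
#' @param het_fraction target fraction of heterozygous calls among variant
#'   calls (default 0.40).
#' @param het_block_bp mean residual-heterozygosity block length (default
#'   5e5 bp).
#' @param missing_rate per-call missingness probability (default 0.05).
#' @param genotype_error_rate per-call probability of replacing the genotype
#'   with a random different code (default 0.005).
#' @param contig_length list with `mean`, `sd`, `min` of the contig length
#'   distribution in bp (default mean 5e5, sd 1.5e5, min 5e4: ~40 contigs on
#'   the default genome).
#' @param seed mandatory RNG seed; the same seed and config give
#'   byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2L, chromosome_length = 1e7,
                       n_founders = 8L, n_accessions = 50L,
                       variant_density = 3.5, recombination_rate = 10,
                       het_fraction = 0.40, het_block_bp = 5e5,
                       missing_rate = 0.05, genotype_error_rate = 0.005,
                       contig_length = list(mean = 5e5, sd = 1.5e5,
                                            min = 5e4),
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(n_founders >= 1L, n_accessions >= 1L, variant_density >= 0,
            het_fraction >= 0, het_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            contig_length$min >= 1)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.numeric(chromosome_length),
                 n_founders = as.integer(n_founders),
                 n_accessions = as.integer(n_accessions),
                 variant_density = variant_density,
                 recombination_rate = recombination_rate,
                 het_fraction = het_fraction, het_block_bp = het_block_bp,
                 missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 contig_length = contig_length, seed = as.integer(seed)),
            class = "sim_config")
}

## genome fraction q of residual-het blocks so that the expected het share of
## variant calls equals cfg$het_fraction, given the founder SFS (p = k/F with
## weight 1/k): het share = qA / (qC + (1-q)B) with A = E[2p(1-p)], B = E[p],
## C = E[1-(1-p)^2]
.het_block_fraction <- function(cfg) {
  f <- cfg$n_founders
  r <- cfg$het_fraction
  if (f < 2L || r <= 0) return(0)
  k <- seq_len(f - 1L)
  w <- (1 / k) / sum(1 / k)
  p <- k / f
  B <- sum(w * p)
  Ep2 <- sum(w * p^2)
  A <- 2 * (B - Ep2)
  C <- 2 * B - Ep2
  q <- r * B / (A - r * (C - B))
  min(max(q, 0), 1)
}

## one founder-mosaic assignment along a chromosome: founder id per site
.mosaic <- function(pos, chrom_len, n_founders, rate) {
  nbp <- rpois(1L, rate)
  bp <- sort(runif(nbp, 0, chrom_len))
  founders <- sample.int(n_founders, nbp + 1L, replace = TRUE)
  founders[findInterval(pos, bp) + 1L]
}

#' Simulate a re-sequenced selfing population
#'
#' Founder haplotypes are drawn per chromosome; each accession is a mosaic
#' of founder blocks with Poisson-distributed crossover points. Inside
#' residual-heterozygosity blocks a second, independent mosaic is active and
#' the genotype is the allele sum of the two haplotypes; outside, calls are
#' homozygous for the primary haplotype. Missingness and genotype errors are
#' applied per call. Deterministic for a given seed.
#'
#' @param cfg a [sim_config()].
#' @return object of class `population_sim`: `cfg`, `panel`, `sites`
#'   (`data.table`: chrom, pos, ref, alt, k_founders), `calls`
#'   (sites x accessions integer matrix), `founder_alleles` (list of logical
#'   site x founder matrices per chromosome), and `matrix` (the
#'   chromosome-level [genotype_matrix()]).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  panel <- sprintf("acc%03d", seq_len(cfg$n_accessions))
  q_het <- .het_block_fraction(cfg)
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  nucl <- c("A", "C", "G", "T")
  site_list <- list()
  call_list <- list()
  fa_list <- list()
  for (ci in seq_along(chroms)) {
    L <- cfg$chromosome_length
    ns <- rbinom(1L, as.integer(L), min(1, cfg$variant_density / 1000))
    pos <- sort(sample.int(as.integer(L), ns))
    f <- cfg$n_founders
    if (f >= 2L) {
      kk <- sample.int(f - 1L, ns, replace = TRUE,
                       prob = 1 / seq_len(f - 1L))
    } else {
      kk <- rep(1L, ns)  # single founder: every "variant" is fixed
    }
    FA <- matrix(FALSE, ns, f)
    for (i in seq_len(ns))
      FA[i, sample.int(f, min(kk[i], f))] <- TRUE
    calls <- matrix(NA_integer_, ns, cfg$n_accessions)
    for (a in seq_len(cfg$n_accessions)) {
      f1 <- .mosaic(pos, L, f, cfg$recombination_rate)
      a1 <- FA[cbind(seq_len(ns), f1)]
      a2 <- a1
      if (q_het > 0 && f >= 2L) {
        nb <- rpois(1L, L / cfg$het_block_bp)
        bnd <- sort(runif(nb, 0, L))
        seg_het <- runif(nb + 1L) < q_het
        in_het <- seg_het[findInterval(pos, bnd) + 1L]
        if (any(in_het)) {
          f2 <- .mosaic(pos, L, f, cfg$recombination_rate)
          a2[in_het] <- FA[cbind(seq_len(ns), f2)][in_het]
        }
      }
      g <- as.integer(a1) + as.integer(a2)
      if (cfg$genotype_error_rate > 0) {
        err <- runif(ns) < cfg$genotype_error_rate
        if (any(err))
          g[err] <- (g[err] + sample.int(2L, sum(err), replace = TRUE)) %% 3L
      }
      if (cfg$missing_rate > 0)
        g[runif(ns) < cfg$missing_rate] <- NA_integer_
      calls[, a] <- g
    }
    ref <- sample(nucl, ns, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nucl, r), 1L), character(1))
    site_list[[ci]] <- data.table(chrom = chroms[ci], pos = pos,
                                  ref = ref, alt = unname(alt),
                                  k_founders = kk)
    call_list[[ci]] <- calls
    fa_list[[ci]] <- FA
  }
  sites <- rbindlist(site_list)
  calls <- do.call(rbind, call_list)
  colnames(calls) <- panel
  chrom_lengths <- stats::setNames(rep(cfg$chromosome_length,
                                       length(chroms)), chroms)
  m <- genotype_matrix(panel,
                       sites[, .(contig = chrom, pos, ref, alt)],
                       calls, chrom_lengths)
  structure(list(cfg = cfg, panel = panel, sites = sites, calls = calls,
                 founder_alleles = fa_list, matrix = m),
            class = "population_sim")
}

#' @export
print.population_sim <- function(x, ...) {
  cat(sprintf("population_sim: %d accessions, %d founders, %d sites on %d chromosome(s)\n",
              x$cfg$n_accessions, x$cfg$n_founders, nrow(x$sites),
              x$cfg$n_chromosomes))
  invisible(x)
}

#' Fragment the simulated reference into contigs with known truth
#'
#' Chromosomes are cut at random positions following the configured contig
#' length distribution; contigs get shuffled names and random orientations
#' (a `-` contig is the reverse complement of its genomic interval). The
#' truth map records interval, orientation and genomic order of every
#' contig. Optionally neighboring contigs share `overlap_bp` of sequence
#' (the left contig extends into its right neighbor), for overlap-merge
#' tests.
#'
#' @param sim a [simulate_population()] result.
#' @param overlap_bp simulated overlap between genomic neighbors
#'   (default 0).
#' @param with_sequence also generate random chromosome/contig sequences
#'   (default FALSE; required for overlap and FASTA tests).
#' @return object of class `fragmented_assembly`: `truth` (`data.table`:
#'   contig, chrom, start, end, orientation, ordinal, ext — tail extension
#'   bp), `contig_lengths`, `matrix` (contig-level [genotype_matrix()]),
#'   `adjacencies` (`data.table` of true neighbor pairs), `chrom_seqs`,
#'   `contig_seqs` (`DNAStringSet` or `NULL`).
#' @export
fragment_reference <- function(sim, overlap_bp = 0L, with_sequence = FALSE) {
  cfg <- sim$cfg
  cl <- cfg$contig_length
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  truth <- list()
  for (ci in seq_along(chroms)) {
    L <- cfg$chromosome_length
    ends <- numeric(0)
    cursor <- 0
    while (cursor < L) {
      len <- max(cl$min, round(rnorm(1L, cl$mean, cl$sd)))
      cursor <- min(cursor + len, L)
      ends <- c(ends, cursor)
    }
    starts <- c(1, head(ends, -1L) + 1)
    if (length(ends) > 1L && (ends[length(ends)] - starts[length(ends)] + 1) < cl$min) {
      ## merge an undersized final remainder into its neighbor
      starts <- head(starts, -1L)
      ends <- ends[-(length(ends) - 1L)]
    }
    truth[[ci]] <- data.table(chrom = chroms[ci], start = starts, end = ends,
                              ordinal = seq_along(starts))
  }
  truth <- rbindlist(truth)
  truth[, orientation := sample(c("+", "-"), .N, replace = TRUE)]
  truth[, contig := sprintf("tig%05d", sample.int(.N))]
  ## optional overlap: every non-terminal contig extends into its right
  ## neighbor by `ext` bp of shared sequence
  truth[, ext := 0]
  if (overlap_bp > 0) {
    truth[, ext := ifelse(ordinal < max(ordinal),
                          pmin(overlap_bp, cfg$chromosome_length - end), 0),
          by = chrom]
  }
  truth[, len := end - start + 1 + ext]
  contig_lengths <- stats::setNames(truth$len, truth$contig)

  ## map chromosome-level sites onto contig coordinates (core intervals)
  sites <- copy(sim$sites)
  mapped <- list()
  for (ci in seq_along(chroms)) {
    tr <- truth[chrom == chroms[ci]][order(start)]
    ss <- sites[chrom == chroms[ci]]
    idx <- findInterval(ss$pos, tr$start)
    ss[, `:=`(contig = tr$contig[idx],
              ctg_or = tr$orientation[idx],
              ctg_len = tr$len[idx],
              ctg_start = tr$start[idx])]
    ss[, cpos := ifelse(ctg_or == "+", pos - ctg_start + 1,
                        ctg_len - (pos - ctg_start))]
    mapped[[ci]] <- ss
  }
  mapped <- rbindlist(mapped)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- mapped$ctg_or == "-"
  mapped[flip, `:=`(ref = comp[ref], alt = comp[alt])]
  ord <- order(mapped$contig, mapped$cpos)
  mapped <- mapped[ord]
  calls <- sim$calls[ord, , drop = FALSE]
  m <- genotype_matrix(sim$panel,
                       mapped[, .(contig, pos = cpos, ref, alt)],
                       calls, contig_lengths)

  adj <- truth[order(chrom, ordinal),
               .(contig_left = head(contig, -1L),
                 contig_right = tail(contig, -1L)), by = chrom]

  chrom_seqs <- contig_seqs <- NULL
  if (with_sequence) {
    chrom_seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
      paste(sample(c("A", "C", "G", "T"), cfg$chromosome_length,
                   replace = TRUE), collapse = ""), character(1)))
    names(chrom_seqs) <- chroms
    pieces <- vapply(seq_len(nrow(truth)), function(i) {
      s <- Biostrings::subseq(chrom_seqs[[truth$chrom[i]]], truth$start[i],
                              truth$end[i] + truth$ext[i])
      if (truth$orientation[i] == "-")
        s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    contig_seqs <- Biostrings::DNAStringSet(pieces)
    names(contig_seqs) <- truth$contig
  }
  structure(list(truth = truth[], contig_lengths = contig_lengths,
                 matrix = m, adjacencies = adj, chrom_seqs = chrom_seqs,
                 contig_seqs = contig_seqs, cfg = cfg),
            class = "fragmented_assembly")
}

#' Simulate mate-pair links from the truth map
#'
#' Fragments of length ~ `Normal(span, sd)` are placed uniformly on the true
#' genome; the two fragment-terminal positions are mapped onto contig
#' coordinates/strands and reported as a link table consumable by
#' [decide_joins()]. The declared library span (`span`) is recorded with
#' every link; the drawn fragment length is the noisy truth.
#'
#' @param fr a [fragment_reference()] result.
#' @param span declared library span (bp, default 5000).
#' @param sd fragment length standard deviation (default `0.1 * span`).
#' @param n_pairs total pairs to draw genome-wide (default 2e5).
#' @param library library label (default `"mp"`).
#' @return `data.table`: read, contig_a, pos_a, strand_a, contig_b, pos_b,
#'   strand_b, span, library (only pairs with both ends on the genome).
#' @export
simulate_mate_pairs <- function(fr, span = 5000, sd = span * 0.1,
                                n_pairs = 2e5, library = "mp") {
  cfg <- fr$cfg
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  out <- list()
  for (ci in seq_along(chroms)) {
    L <- cfg$chromosome_length
    n <- round(n_pairs / length(chroms))
    s <- runif(n, 1, L)
    true_span <- pmax(100, round(rnorm(n, span, sd)))
    e <- s + true_span - 1
    keep <- e <= L
    s <- floor(s[keep]); e <- floor(e[keep])
    tr <- fr$truth[chrom == chroms[ci]][order(start)]
    ia <- findInterval(s, tr$start)
    ib <- findInterval(e, tr$start)
    map_end <- function(g, idx, genome_strand) {
      or <- tr$orientation[idx]
      pos <- ifelse(or == "+", g - tr$start[idx] + 1,
                    tr$len[idx] - (g - tr$start[idx]))
      strand <- ifelse(or == "+", genome_strand,
                       ifelse(genome_strand == "+", "-", "+"))
      list(contig = tr$contig[idx], pos = pos, strand = strand)
    }
    ea <- map_end(s, ia, "+")
    eb <- map_end(e, ib, "-")
    out[[ci]] <- data.table(read = sprintf("%s_%s_%06d", library,
                                           chroms[ci], seq_along(s)),
                            contig_a = ea$contig, pos_a = ea$pos,
                            strand_a = ea$strand,
                            contig_b = eb$contig, pos_b = eb$pos,
                            strand_b = eb$strand,
                            span = span, library = library)
  }
  rbindlist(out)
}

#' Simulate junction-spanning long reads as PAF alignments
#'
#' Reads of length ~ `Normal(mean_len, sd_len)` are placed uniformly on the
#' true genome and split into per-contig alignments (PAF mandatory columns;
#' query coordinates on the forward read, target strand reflecting the
#' contig orientation). Alignments shorter than `min_aln` are dropped, so
#' only reads meaningfully anchored on both sides of a junction link
#' contigs.
#'
#' @param fr a [fragment_reference()] result.
#' @param n_reads number of reads (default 2000).
#' @param mean_len,sd_len read length distribution (default 10,000 / 2,000).
#' @param min_aln minimum alignment length kept (default 500).
#' @return PAF `data.table` (see [read_paf()]).
#' @export
simulate_long_reads <- function(fr, n_reads = 2000L, mean_len = 10000,
                                sd_len = 2000, min_aln = 500L) {
  cfg <- fr$cfg
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  out <- list()
  rid <- 0L
  for (ci in seq_along(chroms)) {
    L <- cfg$chromosome_length
    n <- round(n_reads / length(chroms))
    s <- floor(runif(n, 1, L))
    len <- pmax(1000, round(rnorm(n, mean_len, sd_len)))
    e <- pmin(s + len - 1, L)
    tr <- fr$truth[chrom == chroms[ci]][order(start)]
    for (r in seq_len(n)) {
      rid <- rid + 1L
      idx <- which(tr$start <= e[r] & tr$end >= s[r])
      rows <- list()
      for (i in idx) {
        g1 <- max(s[r], tr$start[i])
        g2 <- min(e[r], tr$end[i])
        if (g2 - g1 + 1 < min_aln) next
        or <- tr$orientation[i]
        if (or == "+") {
          tstart <- g1 - tr$start[i]; tend <- g2 - tr$start[i] + 1
        } else {
          tstart <- tr$len[i] - (g2 - tr$start[i]) - 1
          tend <- tr$len[i] - (g1 - tr$start[i])
        }
        rows[[length(rows) + 1L]] <- data.table(
          qname = sprintf("lr%06d", rid), qlen = e[r] - s[r] + 1L,
          qstart = g1 - s[r], qend = g2 - s[r] + 1L,
          strand = if (or == "+") "+" else "-",
          tname = tr$contig[i], tlen = tr$len[i],
          tstart = as.integer(tstart), tend = as.integer(tend),
          nmatch = g2 - g1 + 1L, alnlen = g2 - g1 + 1L, mapq = 60L)
      }
      if (length(rows)) out[[length(out) + 1L]] <- rbindlist(rows)
    }
  }
  if (!length(out)) return(read_paf(tempfile()))  # empty table
  rbindlist(out)
}

#' Write simulation outputs to standard files
#'
#' Emits a VCF of the contig-level genotype matrix, the truth table (TSV),
#' and, when present/supplied, the contig FASTA, mate-pair link TSVs and a
#' PAF of long-read alignments.
#'
#' @param fr a [fragment_reference()] result.
#' @param dir output directory (created if needed).
#' @param mate_links optional [simulate_mate_pairs()] table (or a named list
#'   of them, one file per library).
#' @param paf optional [simulate_long_reads()] table.
#' @return named character vector of written paths, invisibly.
#' @export
write_sim_outputs <- function(fr, dir, mate_links = NULL, paf = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "pop.vcf"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(fr$matrix, paths[["vcf"]])
  fwrite(fr$truth, paths[["truth"]], sep = "\t")
  if (!is.null(fr$contig_seqs)) {
    paths[["fasta"]] <- file.path(dir, "contigs.fa")
    Biostrings::writeXStringSet(fr$contig_seqs, paths[["fasta"]])
  }
  if (!is.null(mate_links)) {
    if (!is.list(mate_links) || is.data.frame(mate_links))
      mate_links <- list(mp = mate_links)
    for (nm in names(mate_links)) {
      p <- file.path(dir, sprintf("links_%s.tsv", nm))
      fwrite(mate_links[[nm]], p, sep = "\t")
      paths[[paste0("links_", nm)]] <- p
    }
  }
  if (!is.null(paf)) {
    paths[["paf"]] <- file.path(dir, "reads.paf")
    fwrite(paf, paths[["paf"]], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}

## genomic interval of a segment, via the truth map
.segments_to_genome <- function(segments, truth) {
  segs <- as.data.table(segments)
  tr <- as.data.table(truth)
  missing_ct <- setdiff(unique(segs$contig), tr$contig)
  if (length(missing_ct))
    stop("segments on contig(s) missing from truth: ",
         paste(head(missing_ct, 5), collapse = ", "))
  x <- tr[segs, on = "contig"]
  x[, `:=`(gstart = ifelse(orientation == "+", start + i.start,
                           start + (len - i.end)),
           gend = ifelse(orientation == "+", start + i.end - 1,
                         start + (len - i.start) - 1))]
  x[, .(segment_id, contig, chrom, gstart, gend)]
}

#' Evaluate relation recovery against the simulation truth
#'
#' A valid relation is *adjacent* when its two segments lie on the same true
#' chromosome with at most `segment_size` bp between their genomic
#' intervals (consecutive segments, possibly spanning a contig junction);
#' *remote* when the segments lie on different chromosomes or more than
#' `remote_dist` (1 Mbp) apart. Precision is adjacent / (adjacent + remote);
#' recall is the fraction of true contig junctions recovered by at least one
#' valid junction-spanning relation. Rates are normalized per Mbp of
#' assembly.
#'
#' @param relations relation table ([all_vs_all()]).
#' @param truth truth map (`fr$truth` from [fragment_reference()]).
#' @param segments segment table ([segment_assembly()]); segments on contigs
#'   absent from the truth are an error.
#' @param segment_size segment size used for the fingerprints (default 1e5).
#' @param remote_dist distance beyond which a same-chromosome relation is
#'   remote (default 1e6).
#' @return list of metrics: `n_valid`, `n_adjacent`, `n_remote`,
#'   `adjacent_per_mbp`, `remote_per_mbp`, `precision`, `recall`,
#'   `n_junctions`, `n_recovered`.
#' @export
evaluate_recovery <- function(relations, truth, segments,
                              segment_size = 1e5, remote_dist = 1e6) {
  truth <- as.data.table(truth)
  seg_g <- .segments_to_genome(segments, truth)
  rel <- as.data.table(relations)[valid == TRUE]
  assembly_mbp <- sum(truth$len) / 1e6
  junctions <- truth[order(chrom, ordinal),
                     .(a = head(contig, -1L), b = tail(contig, -1L)),
                     by = chrom]
  n_j <- nrow(junctions)
  if (!nrow(rel)) {
    return(list(n_valid = 0L, n_adjacent = 0L, n_remote = 0L,
                adjacent_per_mbp = 0, remote_per_mbp = 0,
                precision = NaN, recall = 0, n_junctions = n_j,
                n_recovered = 0L))
  }
  ga <- seg_g[rel, on = c(segment_id = "seg_a")]
  gb <- seg_g[rel, on = c(segment_id = "seg_b")]
  same_chrom <- ga$chrom == gb$chrom
  gap <- pmax(0, pmax(ga$gstart, gb$gstart) - pmin(ga$gend, gb$gend) - 1)
  adjacent <- same_chrom & gap <= segment_size
  remote <- !same_chrom | (same_chrom & gap > remote_dist)
  jkey <- paste(pmin(ga$contig, gb$contig), pmax(ga$contig, gb$contig))
  rec_keys <- unique(jkey[adjacent & ga$contig != gb$contig])
  jall <- paste(pmin(junctions$a, junctions$b),
                pmax(junctions$a, junctions$b))
  n_rec <- sum(jall %in% rec_keys)
  n_adj <- sum(adjacent); n_rem <- sum(remote)
  list(n_valid = nrow(rel), n_adjacent = n_adj, n_remote = n_rem,
       adjacent_per_mbp = n_adj / assembly_mbp,
       remote_per_mbp = n_rem / assembly_mbp,
       precision = if (n_adj + n_rem > 0) n_adj / (n_adj + n_rem) else NaN,
       recall = if (n_j > 0) n_rec / n_j else NaN,
       n_junctions = n_j, n_recovered = n_rec)
}

#' Closed-form k-mer genome size estimate
#'
#' `seqDepth = kmerCovPeak * readLength / (readLength - kmerSize + 1)` and
#' `genomeSize = totalBases / seqDepth`, evaluated exactly. When
#' `assumed_genome_size` is given, the plain coverage
#' `totalBases / assumed_genome_size` is also reported.
#'
#' @param kmer_cov_peak peak of the k-mer coverage distribution.
#' @param read_length (post-trimming) read length in nt.
#' @param kmer_size k; must satisfy `read_length > kmer_size >= 1`.
#' @param total_bases total sequenced bases.
#' @param assumed_genome_size optional genome size for plain coverage.
#' @return list: `seq_depth`, `genome_size`, `coverage` (NA without an
#'   assumed size).
#' @export
estimate_genome_size <- function(kmer_cov_peak, read_length, kmer_size,
                                 total_bases, assumed_genome_size = NULL) {
  if (kmer_cov_peak <= 0 || total_bases <= 0 || kmer_size < 1 ||
      read_length <= kmer_size)
    stop("require positive inputs with read_length > kmer_size >= 1")
  seq_depth <- kmer_cov_peak * read_length / (read_length - kmer_size + 1)
  list(seq_depth = seq_depth,
       genome_size = total_bases / seq_depth,
       coverage = if (is.null(assumed_genome_size)) NA_real_
                  else total_bases / assumed_genome_size)
}

#' Linkage disequilibrium decay (r-squared vs distance)
#'
#' Sites are thinned to at least `thin_bp` spacing; for every pair within
#' `max_dist` on the same contig, r-squared is the squared Pearson
#' correlation of allele dosages (0/1/2, missing excluded pairwise);
#' monomorphic pairs are skipped. Means are reported per distance bin.
#'
#' @param m a (filtered) [genotype_matrix()] of biallelic sites.
#' @param thin_bp minimum spacing after thinning (default 1000).
#' @param max_dist maximum pair distance (default 1e6).
#' @param bin_bp distance bin width (default 1e4).
#' @return `data.table`: `bin_start`, `bin_mid`, `mean_r2`, `n_pairs`.
#' @export
ld_r2_decay <- function(m, thin_bp = 1000, max_dist = 1e6, bin_bp = 1e4) {
  res <- list()
  for (ct in unique(m$sites$contig)) {
    rows <- which(m$sites$contig == ct)
    pos <- m$sites$pos[rows]
    keep <- logical(length(pos))
    last <- -Inf
    for (i in seq_along(pos)) {
      if (pos[i] - last >= thin_bp) {
        keep[i] <- TRUE
        last <- pos[i]
      }
    }
    rows <- rows[keep]; pos <- pos[keep]
    if (length(rows) < 2L) next
    dos <- t(m$calls[rows, , drop = FALSE])   # accessions x sites
    for (i in seq_len(length(rows) - 1L)) {
      j <- which(pos > pos[i] & pos - pos[i] <= max_dist)
      j <- j[j > i]
      if (!length(j)) next
      r <- suppressWarnings(
        cor(dos[, i], dos[, j, drop = FALSE],
            use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      ok <- !is.na(r2)
      if (!any(ok)) next
      res[[length(res) + 1L]] <- data.table(
        dist = pos[j][ok] - pos[i], r2 = r2[ok])
    }
  }
  if (!length(res))
    return(data.table(bin_start = numeric(), bin_mid = numeric(),
                      mean_r2 = numeric(), n_pairs = integer()))
  dd <- rbindlist(res)
  dd[, bin_start := (dist - 1) %/% bin_bp * bin_bp]
  out <- dd[, .(mean_r2 = mean(r2), n_pairs = .N), by = bin_start]
  out[, bin_mid := bin_start + bin_bp / 2]
  setorder(out, bin_start)
  out[, .(bin_start, bin_mid, mean_r2, n_pairs)]
}
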