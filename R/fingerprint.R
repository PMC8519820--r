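## fingerprint: segmentation of the assembly, variation-pattern similarity,
## and the greedy clustering/compression that turns the sites of one segment
## into its variation fingerprint.

#' Similarity / fingerprint configuration
#'
#' @param het_tol maximum fraction of accessions allowed to differ between two
#'   patterns through heterozygous or missing calls (default 0.10; with 50
#'   accessions at most `floor(0.10 * 50) = 5` genotypes may differ).
#' @param rare_fraction if the starting pattern carries fewer than
#'   `rare_fraction * n` alternative (or reference) genotypes, no mismatch at
#'   all is allowed at those accessions (default 0.20; with 50 accessions the
#'   zero-mismatch rule engages strictly below 10 carriers).
#' @param min_occurrence minimum number of member positions for a compressed
#'   pattern to stay in the fingerprint (default 3).
#' @param segment_size segment length in bp (default 100,000).
#' @return a `similarity_config` list.
#' @export
similarity_config <- function(het_tol = 0.10, rare_fraction = 0.20,
                              min_occurrence = 3L, segment_size = 100000L) {
  stopifnot(het_tol > 0, het_tol <= 1, rare_fraction > 0, rare_fraction <= 1,
            min_occurrence >= 1L, segment_size >= 1)
  structure(list(het_tol = het_tol, rare_fraction = rare_fraction,
                 min_occurrence = as.integer(min_occurrence),
                 segment_size = as.numeric(segment_size)),
            class = "similarity_config")
}

#' Tile contigs into analysis segments
#'
#' Contigs shorter than `segment_size` become a single segment; longer contigs
#' are cut into consecutive `segment_size` tiles with the final remainder
#' (shorter than `segment_size`) as its own segment. Coordinates are 0-based
#' half-open; ordering is deterministic (contig name, then start).
#'
#' @param contig_lengths named numeric vector of contig lengths (bp).
#' @param segment_size tile size in bp.
#' @return `data.table` with columns `contig`, `start`, `end`, `index`
#'   (1-based ordinal within contig) and `segment_id`.
#' @export
segment_assembly <- function(contig_lengths, segment_size = 100000L) {
  if (any(contig_lengths <= 0)) stop("zero-length contig")
  contigs <- sort(names(contig_lengths))
  out <- lapply(contigs, function(ct) {
    len <- as.numeric(contig_lengths[[ct]])
    if (len < segment_size) {
      starts <- 0
    } else {
      starts <- seq(0, len - 1, by = segment_size)
    }
    ends <- pmin(starts + segment_size, len)
    data.table(contig = ct, start = starts, end = ends,
               index = seq_along(starts))
  })
  segs <- rbindlist(out)
  segs[, segment_id := sprintf("%s:%d", contig, index)]
  segs[]
}

## Vectorized core on column layout: are the column patterns of Ct (taken as
## *starting* patterns) similar to the single pattern b?  Implements, in
## order: (i) no opposing homozygous calls; (ii) at most floor(het_tol * n)
## het/missing mismatches; (iii) the zero-mismatch rule at rare alternative
## (or reference) carriers of the starting pattern. b recycles down columns.
.similar_cols <- function(Ct, b, cfg) {
  k <- ncol(Ct)
  if (!k) return(logical(0))
  n <- nrow(Ct)
  naA <- is.na(Ct)
  nb <- is.na(b)
  opp <- (Ct == 0L & b == 2L) | (Ct == 2L & b == 0L)
  opp[naA | nb] <- FALSE
  d <- (naA != nb) | (Ct != b)
  d[naA & nb] <- FALSE
  d[is.na(d)] <- FALSE
  ok <- colSums(opp) == 0L & colSums(d) <= floor(cfg$het_tol * n)
  altc <- Ct >= 1L; altc[naA] <- FALSE
  refc <- Ct <= 1L; refc[naA] <- FALSE
  thr <- cfg$rare_fraction * n
  ok & !(colSums(altc) < thr & colSums(d & altc) > 0L) &
    !(colSums(refc) < thr & colSums(d & refc) > 0L)
}

.similar_rows <- function(A, b, cfg) .similar_cols(t(A), b, cfg)

## pack the TRUE positions of logical vector/matrix columns into 31-bit words
.mask_words <- function(n) max(1L, as.integer(ceiling(n / 31)))

.pack_logical <- function(x, words) {
  ## x: logical vector length n -> integer vector length words
  n <- length(x)
  out <- integer(words)
  idx <- which(x)
  if (length(idx)) {
    w <- (idx - 1L) %/% 31L + 1L
    bit <- (idx - 1L) %% 31L
    for (u in unique(w)) out[u] <- sum(2^bit[w == u])
  }
  as.integer(out)
}

#' Are two variation patterns similar?
#'
#' Two patterns are similar iff (i) no accession has opposing homozygous
#' calls, (ii) at most `floor(het_tol * n)` accessions differ through
#' heterozygous or missing calls, and (iii) when the starting pattern `a` has
#' fewer than `rare_fraction * n` alternative-carrying genotypes, no mismatch
#' of any kind is allowed at those accessions (and symmetrically for rare
#' reference-carrying genotypes). The rule set is asymmetric: `a` plays the
#' role of the starting (consensus) pattern.
#'
#' @param a,b integer genotype-code vectors of equal length (or objects with a
#'   `$consensus` field).
#' @param cfg a [similarity_config()].
#' @param n_accessions panel size (defaults to `length(a)`).
#' @return logical scalar.
#' @export
patterns_similar <- function(a, b, cfg = similarity_config(),
                             n_accessions = NULL) {
  if (is.list(a)) a <- a$consensus
  if (is.list(b)) b <- b$consensus
  if (length(a) != length(b)) stop("pattern length mismatch")
  n <- if (is.null(n_accessions)) length(a) else n_accessions
  ## thresholds are defined on the panel size n; rescale so that the
  ## vectorized core (which uses ncol) applies them unchanged
  eff <- list(het_tol = cfg$het_tol * n / length(a),
              rare_fraction = cfg$rare_fraction * n / length(a))
  unname(.similar_rows(matrix(as.integer(a), 1L), as.integer(b), eff))
}

## Greedy single-pass clustering of site patterns (rows of calls_mat, in
## genomic order). Each site joins the first similar cluster in creation
## order; the cluster consensus is updated at missing entries (any called
## state wins) and heterozygous entries (a homozygous member call wins).
.cluster_patterns <- function(calls_mat, cfg) {
  ns <- nrow(calls_mat)
  n <- ncol(calls_mat)
  consT <- matrix(NA_integer_, n, ns)     # clusters as columns
  occ <- integer(ns)
  members <- vector("list", ns)
  words <- .mask_words(n)
  ## per-cluster packed hom-alt / hom-ref masks for a cheap opposing-hom
  ## prefilter (exactly similarity condition (i); full check follows)
  mAH <- matrix(0L, words, ns)
  mRH <- matrix(0L, words, ns)
  k <- 0L
  for (i in seq_len(ns)) {
    b <- calls_mat[i, ]
    bAH <- .pack_logical(!is.na(b) & b == 2L, words)
    bRH <- .pack_logical(!is.na(b) & b == 0L, words)
    j <- NA_integer_
    if (k > 0L) {
      kk <- seq_len(k)
      ok <- rep(TRUE, k)
      for (w in seq_len(words)) {
        ok <- ok & bitwAnd(mAH[w, kk], bRH[w]) == 0L &
          bitwAnd(mRH[w, kk], bAH[w]) == 0L
      }
      cand <- which(ok)
      if (length(cand)) {
        s <- .similar_cols(consT[, cand, drop = FALSE], b, cfg)
        hits <- cand[s]
        if (length(hits)) j <- hits[1L]
      }
    }
    if (!is.na(j)) {
      cur <- consT[, j]
      upd <- (is.na(cur) & !is.na(b)) |
        (!is.na(cur) & cur == 1L & !is.na(b) & b != 1L)
      if (any(upd)) {
        cur[upd] <- b[upd]
        consT[, j] <- cur
        mAH[, j] <- .pack_logical(!is.na(cur) & cur == 2L, words)
        mRH[, j] <- .pack_logical(!is.na(cur) & cur == 0L, words)
      }
      occ[j] <- occ[j] + 1L
      members[[j]] <- c(members[[j]], i)
    } else {
      k <- k + 1L
      consT[, k] <- b
      mAH[, k] <- bAH
      mRH[, k] <- bRH
      occ[k] <- 1L
      members[[k]] <- i
    }
  }
  list(cons = t(consT[, seq_len(k), drop = FALSE]), occ = occ[seq_len(k)],
       members = members[seq_len(k)])
}

#' Build the variation fingerprint of one segment
#'
#' Sites are clustered by a greedy single pass in genomic order: each site's
#' pattern is compared to existing cluster consensuses in cluster-creation
#' order and absorbed by the first similar one (updating the consensus), or
#' opens a new cluster. Clusters supported by fewer than
#' `cfg$min_occurrence` positions are then dropped.
#'
#' @param calls integer genotype matrix (sites x accessions) of the segment's
#'   sites, in genomic order.
#' @param positions site positions (bp, same order as rows of `calls`).
#' @param segment one-row `data.table`/list with `contig`, `start`, `end`,
#'   `segment_id` (see [segment_assembly()]).
#' @param cfg a [similarity_config()].
#' @return object of class `fingerprint`: fields `segment_id`, `contig`,
#'   `start`, `end`, `cons` (pattern consensus matrix), `occ` (occurrence
#'   counts), `members` (list of member positions), `n_sites` (sites before
#'   pruning).
#' @export
build_fingerprint <- function(calls, positions, segment,
                              cfg = similarity_config()) {
  calls <- matrix(as.integer(calls), nrow = NROW(calls))
  stopifnot(nrow(calls) == length(positions))
  cl <- .cluster_patterns(calls, cfg)
  keep <- cl$occ >= cfg$min_occurrence
  structure(list(segment_id = segment$segment_id, contig = segment$contig,
                 start = segment$start, end = segment$end,
                 cons = cl$cons[keep, , drop = FALSE], occ = cl$occ[keep],
                 members = lapply(cl$members[keep], function(ix) positions[ix]),
                 n_sites = nrow(calls),
                 clusters_total = length(cl$occ)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint %s: %d patterns (occurrences %s) from %d sites\n",
              x$segment_id, length(x$occ),
              paste(x$occ, collapse = ","), x$n_sites))
  invisible(x)
}

#' Number of retained patterns in a fingerprint
#' @param fp a [build_fingerprint()] result.
#' @return integer.
#' @export
n_patterns <- function(fp) length(fp$occ)

#' Build fingerprints for every segment of an assembly
#'
#' Applies [segment_assembly()] to the matrix's contig lengths, assigns every
#' site to its segment and runs [build_fingerprint()] per segment. Segments
#' without variation get no fingerprint (they cannot relate to anything).
#'
#' @param m a filtered [genotype_matrix()].
#' @param cfg a [similarity_config()].
#' @return list with `segments` (the full segment table) and `fingerprints`
#'   (named list of `fingerprint` objects, by `segment_id`).
#' @export
build_fingerprints <- function(m, cfg = similarity_config()) {
  segs <- segment_assembly(m$contig_lengths, cfg$segment_size)
  if (!nrow(m$sites))
    return(list(segments = segs, fingerprints = list()))
  idx <- (m$sites$pos - 1) %/% cfg$segment_size + 1L
  sid <- sprintf("%s:%d", m$sites$contig, idx)
  seg_lookup <- split(seq_len(nrow(m$sites)), sid)
  seg_tab <- segs[segment_id %in% names(seg_lookup)]
  fps <- vector("list", nrow(seg_tab))
  names(fps) <- seg_tab$segment_id
  for (r in seq_len(nrow(seg_tab))) {
    sidr <- seg_tab$segment_id[r]
    rows <- seg_lookup[[sidr]]
    fps[[r]] <- build_fingerprint(m$calls[rows, , drop = FALSE],
                                  m$sites$pos[rows], seg_tab[r], cfg)
  }
  fps <- fps[vapply(fps, n_patterns, integer(1)) > 0L]
  list(segments = segs, fingerprints = fps)
}

#' Serialize fingerprints to TSV
#'
#' One row per retained pattern: segment id, pattern index, occurrence and
#' the consensus as a string over accession codes (`0`,`1`,`2`,`.`).
#'
#' @param fps named list of fingerprints (see [build_fingerprints()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fingerprints_tsv <- function(fps, path) {
  rows <- lapply(fps, function(fp) {
    if (!n_patterns(fp)) return(NULL)
    cons_str <- apply(fp$cons, 1L, function(v) {
      v2 <- as.character(v); v2[is.na(v)] <- "."
      paste(v2, collapse = "")
    })
    data.table(segment_id = fp$segment_id, pattern = seq_along(fp$occ),
               occurrence = fp$occ, consensus = cons_str)
  })
  fwrite(rbindlist(rows), path, sep = "\t")
  invisible(path)
}
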