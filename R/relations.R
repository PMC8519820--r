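## relations: all-vs-all fingerprint comparison, pruning of widespread
## ("yin-yang"-like) patterns, and the occurrence-normalized Jaccard score.

#' Relation configuration
#'
#' @param validity_threshold minimum similarity score for a relation to be
#'   considered valid (default 0.1: fingerprints must share at least 10% of
#'   their variant patterns).
#' @param max_pattern_fingerprints patterns whose similarity group appears in
#'   more than this many fingerprints are pruned everywhere (default 50,
#'   i.e. more than 5 Mbp at 100-kbp segments).
#' @return a `relation_config` list.
#' @export
relation_config <- function(validity_threshold = 0.1,
                            max_pattern_fingerprints = 50L) {
  stopifnot(validity_threshold > 0, validity_threshold <= 1,
            max_pattern_fingerprints >= 1L)
  structure(list(validity_threshold = validity_threshold,
                 max_pattern_fingerprints = as.integer(max_pattern_fingerprints)),
            class = "relation_config")
}

## ---- internal pattern index over a fingerprint collection ----------------

.pattern_key <- function(consmat) {
  if (!nrow(consmat)) return(character(0))
  apply(consmat, 1L, function(v) {
    v2 <- as.character(v); v2[is.na(v)] <- "."
    paste(v2, collapse = "")
  })
}

## deduplicate patterns across fingerprints; returns the unique consensus
## matrix U and, per fingerprint, the uid of each of its patterns
.pattern_index <- function(fps) {
  keys <- lapply(fps, function(fp) .pattern_key(fp$cons))
  all_keys <- unlist(keys, use.names = FALSE)
  ukeys <- unique(all_keys)
  if (!length(ukeys))
    return(list(U = matrix(integer(), 0, 0), uids = lapply(keys, function(x) integer(0))))
  first_fp <- which(vapply(fps, n_patterns, integer(1)) > 0L)[1L]
  n <- ncol(fps[[first_fp]]$cons)
  U <- matrix(NA_integer_, length(ukeys), n)
  km <- match(ukeys, all_keys)
  offs <- rep(seq_along(fps), vapply(keys, length, integer(1)))
  within <- unlist(lapply(keys, seq_along), use.names = FALSE)
  for (r in seq_along(ukeys))
    U[r, ] <- fps[[offs[km[r]]]]$cons[within[km[r]], ]
  list(U = U, uids = lapply(keys, function(kk) match(kk, ukeys)))
}

## pack homozygous calls into 31-bit integer words for a fast
## opposing-homozygote prefilter
.pack_masks <- function(M) {
  n <- ncol(M)
  words <- max(1L, ceiling(n / 31))
  out <- matrix(0L, nrow(M), words)
  for (w in seq_len(words)) {
    idx <- ((w - 1L) * 31L + 1L):min(w * 31L, n)
    pw <- 2^(seq_along(idx) - 1)
    out[, w] <- as.integer(M[, idx, drop = FALSE] %*% pw)
  }
  out
}

#' Pairwise similarity matrix over unique patterns
#'
#' `sim[i, j]` is `TRUE` iff pattern `i`, taken as starting pattern, is
#' similar to pattern `j` under [patterns_similar()] semantics. A bitmask
#' prefilter on opposing homozygous calls keeps the all-vs-all comparison
#' fast; it implements exactly the first similarity condition, so results are
#' identical to calling [patterns_similar()] pairwise.
#'
#' @param U integer matrix of unique patterns (patterns x accessions).
#' @param cfg a [similarity_config()].
#' @return logical k x k matrix.
#' @export
pattern_similarity_matrix <- function(U, cfg = similarity_config()) {
  k <- nrow(U)
  sim <- matrix(FALSE, k, k)
  if (!k) return(sim)
  AH <- U == 2L; AH[is.na(U)] <- FALSE
  RH <- U == 0L; RH[is.na(U)] <- FALSE
  ah <- .pack_masks(AH)
  rh <- .pack_masks(RH)
  words <- ncol(ah)
  tU <- t(U)
  for (j in seq_len(k)) {
    ok <- rep(TRUE, k)
    for (w in seq_len(words)) {
      ok <- ok & bitwAnd(ah[, w], rh[j, w]) == 0L &
        bitwAnd(rh[, w], ah[j, w]) == 0L
    }
    idx <- which(ok)
    if (length(idx))
      sim[idx, j] <- .similar_cols(tU[, idx, drop = FALSE], U[j, ], cfg)
  }
  sim
}

#' Prune widespread variation patterns
#'
#' Patterns are grouped across fingerprints by single-linkage over pairwise
#' similarity; every pattern whose group touches more than
#' `cfg$max_pattern_fingerprints` distinct fingerprints is removed from all
#' fingerprints (strictly more: a pattern in exactly 50 fingerprints is
#' kept at the default). This removes recurrent common haplotypes (e.g.
#' genome-wide "yin-yang" pairs) that would create spurious connections.
#'
#' @param fps named list of fingerprints.
#' @param cfg a [relation_config()].
#' @param sim_cfg the [similarity_config()] the fingerprints were built with.
#' @return list with `fingerprints` (pruned; empties dropped) and
#'   `prevalence` (`data.table`: segment_id, pattern, group, n_fingerprints,
#'   pruned).
#' @export
prune_widespread <- function(fps, cfg = relation_config(),
                             sim_cfg = similarity_config()) {
  if (!length(fps))
    return(list(fingerprints = fps,
                prevalence = data.table(segment_id = character(),
                                        pattern = integer(), group = integer(),
                                        n_fingerprints = integer(),
                                        pruned = logical())))
  px <- .pattern_index(fps)
  k <- nrow(px$U)
  sim <- pattern_similarity_matrix(px$U, sim_cfg)
  simU <- sim | t(sim)
  g <- igraph::graph_from_adjacency_matrix(simU, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  tab <- data.table(
    segment_id = rep(names(fps), vapply(px$uids, length, integer(1))),
    pattern = unlist(lapply(px$uids, seq_along), use.names = FALSE),
    uid = unlist(px$uids, use.names = FALSE))
  tab[, group := comp[uid]]
  prev <- tab[, .(n_fingerprints = uniqueN(segment_id)), by = group]
  tab <- prev[tab, on = "group"]
  tab[, pruned := n_fingerprints > cfg$max_pattern_fingerprints]
  out <- fps
  for (s in unique(tab[pruned == TRUE]$segment_id)) {
    drop <- tab[segment_id == s & pruned == TRUE]$pattern
    fp <- out[[s]]
    keep <- setdiff(seq_along(fp$occ), drop)
    fp$cons <- fp$cons[keep, , drop = FALSE]
    fp$occ <- fp$occ[keep]
    fp$members <- fp$members[keep]
    out[[s]] <- fp
  }
  out <- out[vapply(out, n_patterns, integer(1)) > 0L]
  list(fingerprints = out,
       prevalence = tab[, .(segment_id, pattern, group, n_fingerprints, pruned)])
}

#' Match the patterns of two fingerprints
#'
#' Greedy one-to-one matching: for each pattern of `fA` in
#' occurrence-descending order (ties by pattern index), the first similar,
#' not-yet-matched pattern of `fB` (same ordering) is taken. `fA`'s patterns
#' play the starting-pattern role in [patterns_similar()].
#'
#' @param fA,fB fingerprints.
#' @param cfg a [similarity_config()].
#' @return `data.table` with columns `idx_a`, `idx_b`, `occ_a`, `occ_b`
#'   (zero rows if nothing matches).
#' @export
match_patterns <- function(fA, fB, cfg = similarity_config()) {
  ka <- n_patterns(fA); kb <- n_patterns(fB)
  empty <- data.table(idx_a = integer(), idx_b = integer(),
                      occ_a = integer(), occ_b = integer())
  if (!ka || !kb) return(empty)
  ordA <- order(-fA$occ, seq_len(ka))
  ordB <- order(-fB$occ, seq_len(kb))
  usedB <- logical(kb)
  ia_out <- ib_out <- integer(0)
  for (ia in ordA) {
    for (ib in ordB) {
      if (usedB[ib]) next
      if (patterns_similar(fA$cons[ia, ], fB$cons[ib, ], cfg)) {
        usedB[ib] <- TRUE
        ia_out <- c(ia_out, ia)
        ib_out <- c(ib_out, ib)
        break
      }
    }
  }
  if (!length(ia_out)) return(empty)
  data.table(idx_a = ia_out, idx_b = ib_out,
             occ_a = fA$occ[ia_out], occ_b = fB$occ[ib_out])
}

#' Directed occurrence-normalized Jaccard score
#'
#' With `T_A` the total occurrences in `fA`, `I` the summed `fA` occurrences
#' over matched patterns, and `U_B` the summed occurrences of unmatched `fB`
#' patterns, the score is `I / (T_A + U_B)`. Matched `fB` occurrences are
#' rescaled to their `fA` counterpart (the pattern-wise coefficient
#' `c = o_A / o_B`), so on a single-match case this reduces to the
#' intersection-over-union formula with the printed coefficient (e.g.
#' `c = 10/9` for occurrences 10 vs 9, score `10 / ((10+5) + 9*10/9 - 10) =
#' 0.667`).
#'
#' @param fA,fB fingerprints.
#' @param matches result of `match_patterns(fA, fB, cfg)`.
#' @return score in `[0, 1]` (0 for empty fingerprints).
#' @export
directed_score <- function(fA, fB, matches) {
  t_a <- sum(fA$occ)
  if (t_a == 0) return(0)
  i_a <- sum(matches$occ_a)
  u_b <- sum(fB$occ) - sum(matches$occ_b)
  i_a / (t_a + u_b)
}

#' Score the relation between two segments
#'
#' The emitted score is the maximum of the two directed scores (a haplotype
#' fully contained in one fingerprint suffices to document the relation);
#' `valid` flags scores at or above `cfg$validity_threshold`. Pairs without
#' any shared pattern yield `NULL` (no relation is emitted).
#'
#' @param fA,fB fingerprints.
#' @param sim_cfg a [similarity_config()].
#' @param cfg a [relation_config()].
#' @return one-row `data.table` (`seg_a`, `seg_b`, `contig_a`, `contig_b`,
#'   `n_shared`, `score_ab`, `score_ba`, `score`, `valid`, `intra_contig`)
#'   or `NULL`.
#' @export
relation_score <- function(fA, fB, sim_cfg = similarity_config(),
                           cfg = relation_config()) {
  m_ab <- match_patterns(fA, fB, sim_cfg)
  m_ba <- match_patterns(fB, fA, sim_cfg)
  if (!nrow(m_ab) && !nrow(m_ba)) return(NULL)
  s_ab <- directed_score(fA, fB, m_ab)
  s_ba <- directed_score(fB, fA, m_ba)
  sc <- max(s_ab, s_ba)
  data.table(seg_a = fA$segment_id, seg_b = fB$segment_id,
             contig_a = fA$contig, contig_b = fB$contig,
             n_shared = max(nrow(m_ab), nrow(m_ba)),
             score_ab = s_ab, score_ba = s_ba, score = sc,
             valid = sc >= cfg$validity_threshold,
             intra_contig = fA$contig == fB$contig)
}

## fast greedy matcher on precomputed uid similarity
.match_uid <- function(uidA, occA, uidB, occB, sim) {
  ordA <- order(-occA, seq_along(occA))
  ordB <- order(-occB, seq_along(occB))
  usedB <- logical(length(occB))
  ia_out <- ib_out <- integer(0)
  for (ia in ordA) {
    srow <- sim[uidA[ia], uidB]
    for (ib in ordB) {
      if (usedB[ib] || !srow[ib]) next
      usedB[ib] <- TRUE
      ia_out <- c(ia_out, ia)
      ib_out <- c(ib_out, ib)
      break
    }
  }
  list(ia = ia_out, ib = ib_out)
}

#' All-against-all comparison of fingerprints
#'
#' Emits every unordered segment pair sharing at least one variation pattern,
#' including intra-contig pairs (flagged). A precomputed unique-pattern
#' similarity matrix plus an inverted fingerprint index keeps the comparison
#' near-linear in the number of actually related pairs; results are identical
#' to the naive double loop over [relation_score()]. Output order is
#' deterministic (by segment ids).
#'
#' @param fps named list of (pruned) fingerprints.
#' @param sim_cfg a [similarity_config()].
#' @param cfg a [relation_config()].
#' @return `data.table` of relations (see [relation_score()]).
#' @export
all_vs_all <- function(fps, sim_cfg = similarity_config(),
                       cfg = relation_config()) {
  empty <- data.table(seg_a = character(), seg_b = character(),
                      contig_a = character(), contig_b = character(),
                      n_shared = integer(), score_ab = numeric(),
                      score_ba = numeric(), score = numeric(),
                      valid = logical(), intra_contig = logical())
  if (length(fps) < 2L) return(empty)
  px <- .pattern_index(fps)
  k <- nrow(px$U)
  if (!k) return(empty)
  sim <- pattern_similarity_matrix(px$U, sim_cfg)
  simU <- sim | t(sim)
  inv <- vector("list", k)           # uid -> fingerprint indices
  for (f in seq_along(fps)) for (u in px$uids[[f]])
    inv[[u]] <- c(inv[[u]], f)
  ## candidate fingerprint pairs from similar uid pairs
  simpairs <- which(simU & upper.tri(simU, diag = TRUE), arr.ind = TRUE)
  cand <- vector("list", nrow(simpairs))
  for (r in seq_len(nrow(simpairs))) {
    fi <- inv[[simpairs[r, 1L]]]
    fj <- inv[[simpairs[r, 2L]]]
    if (is.null(fi) || is.null(fj)) next
    cand[[r]] <- CJ(a = fi, b = fj)
  }
  cand <- rbindlist(cand)
  if (!nrow(cand)) return(empty)
  cand <- cand[a != b]
  if (!nrow(cand)) return(empty)
  cand <- unique(data.table(a = pmin(cand$a, cand$b),
                            b = pmax(cand$a, cand$b)))
  out <- vector("list", nrow(cand))
  thr <- cfg$validity_threshold
  for (r in seq_len(nrow(cand))) {
    fA <- fps[[cand$a[r]]]; fB <- fps[[cand$b[r]]]
    uidA <- px$uids[[cand$a[r]]]; uidB <- px$uids[[cand$b[r]]]
    m_ab <- .match_uid(uidA, fA$occ, uidB, fB$occ, sim)
    m_ba <- .match_uid(uidB, fB$occ, uidA, fA$occ, sim)
    if (!length(m_ab$ia) && !length(m_ba$ia)) next
    s_ab <- directed_score(fA, fB, data.table(occ_a = fA$occ[m_ab$ia],
                                              occ_b = fB$occ[m_ab$ib]))
    s_ba <- directed_score(fB, fA, data.table(occ_a = fB$occ[m_ba$ia],
                                              occ_b = fA$occ[m_ba$ib]))
    sc <- max(s_ab, s_ba)
    out[[r]] <- data.table(seg_a = fA$segment_id, seg_b = fB$segment_id,
                           contig_a = fA$contig, contig_b = fB$contig,
                           n_shared = max(length(m_ab$ia), length(m_ba$ia)),
                           score_ab = s_ab, score_ba = s_ba, score = sc,
                           valid = sc >= thr,
                           intra_contig = fA$contig == fB$contig)
  }
  res <- rbindlist(out)
  if (!nrow(res)) return(empty)
  setorder(res, seg_a, seg_b)
  res[]
}

#' Write relations to TSV
#' @param relations relation table from [all_vs_all()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_relations_tsv <- function(relations, path) {
  fwrite(relations, path, sep = "\t")
  invisible(path)
}
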