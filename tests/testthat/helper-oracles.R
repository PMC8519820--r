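## Independent brute-force oracles. These deliberately re-derive the rules
## with straightforward scalar code (no shared helpers with the package
## internals beyond the public API where the oracle targets a different
## operation).

## -- site filter oracle: re-check each site directly ----------------------
oracle_filter_keep <- function(m, cfg) {
  n <- length(m$panel)
  depth_known <- !all(is.na(m$sites$total_depth))
  vapply(seq_len(nrow(m$sites)), function(i) {
    calls <- m$calls[i, ]
    if (cfg$biallelic_snp_only &&
        (!m$sites$is_snp[i] || !m$sites$is_biallelic[i])) return(FALSE)
    covered <- !is.na(calls)
    if (!is.null(m$depths)) {
      dp <- m$depths[i, ]; dp[is.na(dp)] <- 0
      covered <- covered & dp >= cfg$min_depth_per_called_accession
    }
    if (sum(covered) / n < cfg$min_called_fraction) return(FALSE)
    if (!is.na(cfg$max_missing_fraction) &&
        mean(is.na(calls)) > cfg$max_missing_fraction) return(FALSE)
    if (depth_known && !is.na(m$sites$total_depth[i]) &&
        m$sites$total_depth[i] > cfg$max_total_depth) return(FALSE)
    if (sum(calls %in% c(0, 1)) < cfg$min_ref_genotypes) return(FALSE)
    if (sum(calls %in% c(1, 2)) < cfg$min_alt_genotypes) return(FALSE)
    called <- sum(!is.na(calls))
    if (called == 0) return(FALSE)
    f <- sum(calls, na.rm = TRUE) / (2 * called)
    if (min(f, 1 - f) < cfg$maf_min) return(FALSE)
    TRUE
  }, logical(1))
}

## -- pattern similarity oracle: scalar re-derivation of the three rules ---
oracle_similar <- function(a, b, het_tol = 0.10, rare_fraction = 0.20) {
  n <- length(a)
  for (i in seq_len(n)) {
    if (!is.na(a[i]) && !is.na(b[i]) &&
        ((a[i] == 0 && b[i] == 2) || (a[i] == 2 && b[i] == 0))) return(FALSE)
  }
  differ <- vapply(seq_len(n), function(i) {
    if (is.na(a[i]) && is.na(b[i])) return(FALSE)
    if (is.na(a[i]) || is.na(b[i])) return(TRUE)
    a[i] != b[i]
  }, logical(1))
  if (sum(differ) > floor(het_tol * n)) return(FALSE)
  alt_acc <- which(!is.na(a) & a >= 1)
  if (length(alt_acc) < rare_fraction * n && any(differ[alt_acc])) return(FALSE)
  ref_acc <- which(!is.na(a) & a <= 1)
  if (length(ref_acc) < rare_fraction * n && any(differ[ref_acc])) return(FALSE)
  TRUE
}

## -- greedy clustering oracle (independent loop implementation) -----------
oracle_cluster <- function(calls, het_tol = 0.10, rare_fraction = 0.20) {
  clusters <- list()
  for (i in seq_len(nrow(calls))) {
    b <- calls[i, ]
    placed <- FALSE
    for (k in seq_along(clusters)) {
      if (oracle_similar(clusters[[k]]$cons, b, het_tol, rare_fraction)) {
        cons <- clusters[[k]]$cons
        for (p in seq_along(cons)) {
          if (is.na(cons[p]) && !is.na(b[p])) cons[p] <- b[p]
          else if (!is.na(cons[p]) && cons[p] == 1 && !is.na(b[p]) &&
                   b[p] != 1) cons[p] <- b[p]
        }
        clusters[[k]]$cons <- cons
        clusters[[k]]$members <- c(clusters[[k]]$members, i)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <- list(cons = b, members = i)
  }
  clusters
}

## -- exhaustive maximum bipartite matching (for <= 4x4 instances) ---------
oracle_max_matching <- function(simmat) {
  ka <- nrow(simmat); kb <- ncol(simmat)
  best <- 0L
  rec <- function(ia, used, count) {
    if (ia > ka) {
      best <<- max(best, count)
      return()
    }
    rec(ia + 1L, used, count)
    for (ib in seq_len(kb)) {
      if (!used[ib] && simmat[ia, ib]) {
        used[ib] <- TRUE
        rec(ia + 1L, used, count + 1L)
        used[ib] <- FALSE
      }
    }
  }
  rec(1L, logical(kb), 0L)
  best
}

## -- union-find connected components --------------------------------------
oracle_components <- function(nodes, edges_a, edges_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  stats::setNames(vapply(nodes, find, character(1)), nodes)
}

## -- exhaustive simple-path search on small graphs ------------------------
## returns all Hamiltonian paths (as vectors) whose consecutive pairs are
## edges
oracle_hamiltonian_paths <- function(nodes, edge_key) {
  has_edge <- function(u, v) paste(pmin(u, v), pmax(u, v)) %in% edge_key
  out <- list()
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) res[[length(res) + 1L]] <- c(v[i], p)
    res
  }
  for (p in perms(nodes)) {
    ok <- all(vapply(seq_len(length(p) - 1L),
                     function(i) has_edge(p[i], p[i + 1L]), logical(1)))
    if (ok) out[[length(out) + 1L]] <- p
  }
  out
}

## -- dynamic-programming suffix/prefix overlap aligner --------------------
## global-ish alignment with free leading gaps in A and free trailing gaps
## in B; returns best overlap length on A and identity
oracle_overlap <- function(a, b, match = 1, mismatch = -2, gap = -2) {
  a <- strsplit(as.character(a), "")[[1]]
  b <- strsplit(as.character(b), "")[[1]]
  na <- length(a); nb <- length(b)
  ## score[i+1, j+1]: best score aligning a[..i] suffix start free, b[1..j]
  S <- matrix(0, na + 1, nb + 1)
  S[1, ] <- c(0, cumsum(rep(gap, nb)))  # b must start at 1: leading b gaps penalized
  S[, 1] <- 0                            # suffix of a: free start
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sc <- if (a[i] == b[j]) match else mismatch
      S[i + 1, j + 1] <- max(S[i, j] + sc, S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  ## a must end at na (suffix anchored right): look at last row only
  j_best <- which.max(S[na + 1, ])
  list(score = S[na + 1, j_best], b_end = j_best - 1L)
}

## -- recovery metric oracle ------------------------------------------------
oracle_recovery <- function(relations, truth, segments, segment_size = 1e5,
                            remote_dist = 1e6) {
  truth <- as.data.frame(truth)
  segments <- as.data.frame(segments)
  rel <- as.data.frame(relations)
  rel <- rel[rel$valid, , drop = FALSE]
  glookup <- function(sid) {
    s <- segments[segments$segment_id == sid, ]
    tr <- truth[truth$contig == s$contig, ]
    if (tr$orientation == "+") {
      c(tr$chrom, tr$start + s$start, tr$start + s$end - 1)
    } else {
      c(tr$chrom, tr$start + (tr$len - s$end), tr$start + (tr$len - s$start) - 1)
    }
  }
  n_adj <- 0L; n_rem <- 0L
  rec <- character(0)
  for (r in seq_len(nrow(rel))) {
    ga <- glookup(rel$seg_a[r]); gb <- glookup(rel$seg_b[r])
    if (ga[1] != gb[1]) {
      n_rem <- n_rem + 1L
      next
    }
    gap <- max(0, max(as.numeric(ga[2]), as.numeric(gb[2])) -
                 min(as.numeric(ga[3]), as.numeric(gb[3])) - 1)
    if (gap <= segment_size) {
      n_adj <- n_adj + 1L
      if (rel$contig_a[r] != rel$contig_b[r])
        rec <- c(rec, paste(sort(c(rel$contig_a[r], rel$contig_b[r])),
                            collapse = " "))
    } else if (gap > remote_dist) n_rem <- n_rem + 1L
  }
  truth <- truth[order(truth$chrom, truth$ordinal), ]
  jn <- character(0)
  for (ch in unique(truth$chrom)) {
    ctg <- truth$contig[truth$chrom == ch]
    if (length(ctg) > 1)
      for (i in seq_len(length(ctg) - 1))
        jn <- c(jn, paste(sort(c(ctg[i], ctg[i + 1])), collapse = " "))
  }
  list(n_adjacent = n_adj, n_remote = n_rem,
       precision = if (n_adj + n_rem) n_adj / (n_adj + n_rem) else NaN,
       recall = if (length(jn)) mean(jn %in% unique(rec)) else NaN)
}
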