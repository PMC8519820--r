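## minimal relation rows for graph tests
rel_row <- function(ca, cb, score, valid = TRUE, seg_a = NULL, seg_b = NULL) {
  data.table::data.table(
    seg_a = if (is.null(seg_a)) paste0(ca, ":1") else seg_a,
    seg_b = if (is.null(seg_b)) paste0(cb, ":1") else seg_b,
    contig_a = ca, contig_b = cb, n_shared = 1L,
    score_ab = score, score_ba = score, score = score, valid = valid,
    intra_contig = ca == cb)
}

test_that("build_contig_graph aggregates segment relations per contig pair", {
  rel <- rbind(rel_row("A", "B", 0.3, seg_a = "A:1", seg_b = "B:1"),
               rel_row("A", "B", 0.8, seg_a = "A:2", seg_b = "B:1"),
               rel_row("B", "A", 0.5, seg_a = "B:2", seg_b = "A:3"),
               rel_row("A", "A", 0.9, seg_a = "A:1", seg_b = "A:4"),
               rel_row("C", "D", 0.05, valid = FALSE))
  g <- build_contig_graph(rel)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$score, 0.8)          # max over the three
  expect_equal(g$edges$n_segment_pairs, 3L)
  expect_equal(nrow(g$intra), 1L)           # kept separately
  ## only intra-contig relations -> empty edge set
  g2 <- build_contig_graph(rel_row("A", "A", 0.9))
  expect_equal(nrow(g2$edges), 0L)
})

test_that("contig graph aggregation equals a brute-force double loop", {
  s <- small_sim(seed = 23, n_acc = 25, chrom_len = 2e6)
  res <- haplotype_relations(s$fr$matrix)
  g <- build_contig_graph(res$relations)
  rel <- res$relations[valid == TRUE & intra_contig == FALSE]
  pairs <- unique(data.frame(a = pmin(rel$contig_a, rel$contig_b),
                             b = pmax(rel$contig_a, rel$contig_b)))
  expect_equal(nrow(g$edges), nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    sel <- (pmin(rel$contig_a, rel$contig_b) == pairs$a[r]) &
      (pmax(rel$contig_a, rel$contig_b) == pairs$b[r])
    got <- g$edges[contig_a == pairs$a[r] & contig_b == pairs$b[r]]
    expect_equal(got$score, max(rel$score[sel]))
    expect_equal(got$n_segment_pairs, sum(sel))
  }
})

test_that("form_groups returns connected components excluding singletons", {
  rel <- rbind(rel_row("A", "B", 0.5), rel_row("B", "C", 0.5),
               rel_row("D", "D", 0.5),                      # intra only
               rel_row("E", "F", 0.2))
  g <- build_contig_graph(rel)
  groups <- form_groups(g)
  expect_length(groups, 2L)
  expect_equal(groups[[1]]$members, c("A", "B", "C"))
  expect_equal(groups[[2]]$members, c("E", "F"))
  ## empty graph
  expect_length(form_groups(build_contig_graph(rel_row("A", "A", 1))), 0L)
})

test_that("components match a union-find oracle on random graphs", {
  set.seed(31)
  for (rep in 1:10) {
    nodes <- sprintf("n%02d", 1:12)
    ne <- sample(3:16, 1)
    ea <- sample(nodes, ne, replace = TRUE)
    eb <- sample(nodes, ne, replace = TRUE)
    keep <- ea != eb
    ea <- ea[keep]; eb <- eb[keep]
    if (!length(ea)) next
    rel <- data.table::rbindlist(lapply(seq_along(ea), function(i)
      rel_row(ea[i], eb[i], 0.5,
              seg_a = paste0(ea[i], ":1"), seg_b = paste0(eb[i], ":1"))))
    groups <- form_groups(build_contig_graph(rel))
    roots <- oracle_components(nodes, ea, eb)
    expected <- table(roots)[table(roots) >= 2]
    expect_length(groups, length(expected))
    for (grp in groups) {
      expect_equal(length(unique(roots[grp$members])), 1L)
      expect_equal(sum(roots == roots[[grp$members[1]]]),
                   length(grp$members))
    }
  }
})

test_that("linearize_group resolves paths and rejects stars", {
  ## chain of 4
  rel <- rbind(rel_row("A", "B", 0.5), rel_row("B", "C", 0.5),
               rel_row("C", "D", 0.5))
  g <- build_contig_graph(rel)
  grp <- form_groups(g)[[1]]
  res <- linearize_group(grp, g)
  expect_equal(res$resolution, "linear")
  expect_equal(res$order, c("A", "B", "C", "D"))
  ## star with 3 leaves
  rel <- rbind(rel_row("X", "A", 0.5), rel_row("X", "B", 0.5),
               rel_row("X", "C", 0.5))
  g <- build_contig_graph(rel)
  res <- linearize_group(form_groups(g)[[1]], g)
  expect_equal(res$resolution, "complex")
  ## triangle with one weak transitive edge reduces to a path
  rel <- rbind(rel_row("A", "B", 0.8), rel_row("B", "C", 0.7),
               rel_row("A", "C", 0.2))
  g <- build_contig_graph(rel)
  res <- linearize_group(form_groups(g)[[1]], g)
  expect_equal(res$resolution, "linear")
  expect_equal(res$order, c("A", "B", "C"))
  expect_equal(nrow(res$removed_edges), 1L)
})

test_that("linearization agrees with exhaustive path enumeration on small graphs", {
  set.seed(41)
  for (rep in 1:20) {
    nodes <- sprintf("n%d", 1:sample(3:6, 1))
    ## random connected-ish graph
    ne <- sample(length(nodes):(length(nodes) + 2), 1)
    ea <- sample(nodes, ne, replace = TRUE)
    eb <- sample(nodes, ne, replace = TRUE)
    keep <- ea != eb
    if (!any(keep)) next
    dt <- unique(data.table::data.table(a = pmin(ea, eb)[keep],
                                        b = pmax(ea, eb)[keep]))
    rel <- data.table::rbindlist(lapply(seq_len(nrow(dt)), function(i)
      rel_row(dt$a[i], dt$b[i], 0.5,
              seg_a = paste0(dt$a[i], ":1"), seg_b = paste0(dt$b[i], ":1"))))
    g <- build_contig_graph(rel)
    groups <- form_groups(g)
    for (grp in groups) {
      res <- linearize_group(grp, g)
      sub_edges <- g$edges[contig_a %in% grp$members &
                             contig_b %in% grp$members]
      ## equal scores: no transitive reduction possible; linear iff the
      ## subgraph is a simple path, i.e. a unique Hamiltonian path traversing
      ## every edge (n-1 edges)
      paths <- oracle_hamiltonian_paths(grp$members,
                                        paste(sub_edges$contig_a,
                                              sub_edges$contig_b))
      is_path <- length(paths) == 2 &&
        nrow(sub_edges) == length(grp$members) - 1
      expect_equal(res$resolution == "linear", is_path,
                   info = paste("rep", rep))
      if (is_path) {
        expect_true(identical(res$order, paths[[1]]) ||
                      identical(res$order, paths[[2]]))
        ## consecutive pairs are all edges
        cons <- paste(pmin(head(res$order, -1), tail(res$order, -1)),
                      pmax(head(res$order, -1), tail(res$order, -1)))
        expect_true(all(cons %in% paste(sub_edges$contig_a,
                                        sub_edges$contig_b)))
      }
    }
  }
})

test_that("marker_consistency labels groups and reports conflicts", {
  groups <- list(structure(list(id = 1L, members = c("t1", "t2"),
                                total_bp = NA_real_), class = "contig_group"),
                 structure(list(id = 2L, members = c("t3", "t4"),
                                total_bp = NA_real_), class = "contig_group"),
                 structure(list(id = 3L, members = c("t5", "t6"),
                                total_bp = NA_real_), class = "contig_group"))
  pl <- data.table::data.table(
    marker = c("m1", "m2", "m3", "m4", "m5"),
    contig = c("t1", "t2", "t3", "t4", "t9"),
    pos = c(100L, 200L, 10L, 20L, 5L),
    lg = c("LG1", "LG6", "LG2", "LG2", "LG3"))
  expect_warning(rep <- marker_consistency(groups, pl), "t9")
  expect_equal(rep$status, c("conflicting", "consistent", "unanchored"))
  expect_equal(rep$lgs[1], "LG1,LG6")
  detail <- rep$detail[[1]]
  expect_setequal(detail$contig, c("t1", "t2"))
})

test_that("export_dot round-trips nodes and edges", {
  rel <- rbind(rel_row("A", "B", 0.5), rel_row("B", "C", 0.25))
  g <- build_contig_graph(rel)
  dot <- export_dot(g, contig_lengths = c(A = 100, B = 200, C = 300))
  expect_match(dot[1], "^graph ")
  parsed <- parse_dot(dot)
  expect_equal(parsed$nodes, c("A", "B", "C"))
  expect_equal(parsed$edges, c("A B", "B C"))
  ## single edge graph -> 2 nodes, 1 edge
  p1 <- parse_dot(export_dot(build_contig_graph(rel_row("X", "Y", 1))))
  expect_equal(length(p1$nodes), 2L)
  expect_equal(length(p1$edges), 1L)
  ## empty graph -> no nodes/edges but valid DOT
  p0 <- parse_dot(export_dot(build_contig_graph(rel_row("A", "A", 1))))
  expect_length(p0$nodes, 0L)
  expect_length(p0$edges, 0L)
  ## file writing
  f <- tempfile(fileext = ".dot")
  export_dot(g, contig_lengths = c(A = 100, B = 200, C = 300), path = f)
  expect_equal(readLines(f), unname(dot))
})
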