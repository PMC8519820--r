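## grouping: lift segment relations to a contig graph, form groups, resolve
## unambiguous linear orders, check marker consistency, export DOT.

#' Lift segment relations to a contig graph
#'
#' One edge per contig pair, aggregating all its valid segment-level
#' relations: the edge score is the maximum segment-pair score (a single
#' strong shared haplotype is the evidence unit), with the number of
#' supporting segment pairs and total shared-pattern count kept. Intra-contig
#' relations are stored separately as self-consistency evidence and are not
#' used for grouping.
#'
#' @param relations relation table ([all_vs_all()]); only rows with
#'   `valid == TRUE` contribute edges.
#' @return object of class `contig_graph`: `edges` (`data.table`: contig_a,
#'   contig_b, score, n_segment_pairs, n_shared), `intra` (intra-contig
#'   relations), `graph` (an igraph object with `score` edge attribute).
#' @export
build_contig_graph <- function(relations) {
  rel <- as.data.table(relations)[valid == TRUE]
  intra <- rel[intra_contig == TRUE]
  inter <- rel[intra_contig == FALSE]
  if (nrow(inter)) {
    inter <- inter[, .(contig_a = pmin(contig_a, contig_b),
                       contig_b = pmax(contig_a, contig_b),
                       score, n_shared)]
    edges <- inter[, .(score = max(score), n_segment_pairs = .N,
                       n_shared = sum(n_shared)),
                   by = .(contig_a, contig_b)]
    setorder(edges, contig_a, contig_b)
  } else {
    edges <- data.table(contig_a = character(), contig_b = character(),
                        score = numeric(), n_segment_pairs = integer(),
                        n_shared = integer())
  }
  g <- igraph::graph_from_data_frame(
    edges[, .(from = contig_a, to = contig_b, score)], directed = FALSE)
  structure(list(edges = edges, intra = intra, graph = g),
            class = "contig_graph")
}

#' @export
print.contig_graph <- function(x, ...) {
  cat(sprintf("contig_graph: %d contigs, %d edges (+%d intra-contig relations)\n",
              igraph::vcount(x$graph), nrow(x$edges), nrow(x$intra)))
  invisible(x)
}

#' Form contig groups
#'
#' Groups are the connected components of the valid-edge contig graph;
#' singleton contigs are excluded (a group needs at least one relation).
#'
#' @param g a [build_contig_graph()] result.
#' @param contig_lengths optional named lengths to annotate total bp.
#' @return list of `contig_group` objects: `members`, `total_bp` (NA when
#'   lengths are not supplied).
#' @export
form_groups <- function(g, contig_lengths = NULL) {
  if (!igraph::vcount(g$graph)) return(list())
  comp <- igraph::components(g$graph)
  groups <- split(names(comp$membership), comp$membership)
  groups <- Filter(function(x) length(x) >= 2L, groups)
  groups <- groups[order(vapply(groups, min, character(1)))]
  unname(lapply(seq_along(groups), function(i) {
    members <- sort(groups[[i]])
    structure(list(id = i, members = members,
                   total_bp = if (is.null(contig_lengths)) NA_real_
                              else sum(contig_lengths[members])),
              class = "contig_group")
  }))
}

## is this subgraph a simple path? If yes, return the ordered node list
.path_order <- function(sub) {
  nv <- igraph::vcount(sub)
  deg <- igraph::degree(sub)
  if (nv == 1L) return(igraph::V(sub)$name)
  if (igraph::ecount(sub) != nv - 1L) return(NULL)       # has a cycle
  if (sum(deg == 1L) != 2L || any(deg > 2L)) return(NULL)
  if (!igraph::is_connected(sub)) return(NULL)
  ends <- sort(names(deg)[deg == 1L])
  ord <- igraph::dfs(sub, root = ends[1L])$order
  igraph::V(sub)$name[as.integer(ord)]
}

#' Resolve a contig group into a linear order
#'
#' A group is `linear` when its subgraph is a simple path (two degree-1
#' nodes, the rest degree-2, acyclic); the direction starts from the
#' lexicographically smaller endpoint. Otherwise a transitive-reduction
#' fallback removes, in ascending score order, any edge `(u, w)` bypassed by
#' a two-hop path `u-v-w` whose both edges score strictly higher, and
#' re-tests. Groups that still are not paths — or that exceed `max_nodes` —
#' are reported `complex`. Orientation is never asserted from haplotype
#' information alone; it comes from the scaffold module.
#'
#' @param group a `contig_group` (see [form_groups()]).
#' @param g the [build_contig_graph()] result.
#' @param max_nodes transitive-reduction bound (default 30); larger ambiguous
#'   groups are reported complex.
#' @return list with `resolution` (`"linear"` or `"complex"`), `order`
#'   (character vector or `NULL`) and `removed_edges` (`data.table`).
#' @export
linearize_group <- function(group, g, max_nodes = 30L) {
  sub <- igraph::induced_subgraph(g$graph, group$members)
  removed <- data.table(contig_a = character(), contig_b = character(),
                        score = numeric())
  ord <- .path_order(sub)
  if (!is.null(ord))
    return(list(resolution = "linear", order = ord, removed_edges = removed))
  if (igraph::vcount(sub) > max_nodes)
    return(list(resolution = "complex", order = NULL, removed_edges = removed))
  ## transitive reduction: drop weak edges explained by a stronger 2-hop path
  repeat {
    el <- igraph::as_data_frame(sub, what = "edges")
    if (!nrow(el)) break
    el <- el[order(el$score), , drop = FALSE]
    dropped <- FALSE
    for (r in seq_len(nrow(el))) {
      u <- el$from[r]; w <- el$to[r]; sc <- el$score[r]
      nu <- setdiff(intersect(names(igraph::neighbors(sub, u)),
                              names(igraph::neighbors(sub, w))), c(u, w))
      if (!length(nu)) next
      better <- vapply(nu, function(v) {
        s1 <- igraph::E(sub)[igraph::get_edge_ids(sub, c(u, v))]$score
        s2 <- igraph::E(sub)[igraph::get_edge_ids(sub, c(v, w))]$score
        min(s1, s2) > sc
      }, logical(1))
      if (any(better)) {
        sub <- igraph::delete_edges(sub, igraph::get_edge_ids(sub, c(u, w)))
        removed <- rbind(removed,
                         data.table(contig_a = min(u, w),
                                    contig_b = max(u, w), score = sc))
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
    ord <- .path_order(sub)
    if (!is.null(ord))
      return(list(resolution = "linear", order = ord,
                  removed_edges = removed))
  }
  list(resolution = "complex", order = NULL, removed_edges = removed)
}

#' Check marker/linkage-group consistency of contig groups
#'
#' Each group is labeled `consistent` (all markers map to one linkage group),
#' `conflicting` (markers from two or more linkage groups; the offending
#' contigs and marker positions are listed so a coverage-drop check can
#' localize a misassembly), or `unanchored` (no markers).
#'
#' @param groups list of contig groups ([form_groups()]).
#' @param placements `data.table` with columns `marker`, `contig`, `pos`,
#'   `lg` (linkage group) and optionally `tier`. Placements on contigs
#'   unknown to every group raise a warning and are skipped.
#' @param known_contigs optional character vector of all assembly contigs
#'   (for the unknown-placement warning; defaults to the grouped contigs).
#' @return `data.table`: group id, status, linkage groups seen, and a
#'   `detail` list column with the conflicting placements.
#' @export
marker_consistency <- function(groups, placements, known_contigs = NULL) {
  placements <- as.data.table(placements)
  if (is.null(known_contigs))
    known_contigs <- unique(unlist(lapply(groups, `[[`, "members")))
  unknown <- setdiff(unique(placements$contig), known_contigs)
  if (length(unknown)) {
    warning("marker placements on unknown contig(s) skipped: ",
            paste(head(unknown, 5), collapse = ", "))
    placements <- placements[!contig %in% unknown]
  }
  rows <- lapply(groups, function(grp) {
    pl <- placements[contig %in% grp$members]
    if (!nrow(pl))
      return(data.table(group = grp$id, status = "unanchored",
                        lgs = "", detail = list(pl)))
    lgs <- sort(unique(pl$lg))
    data.table(group = grp$id,
               status = if (length(lgs) == 1L) "consistent" else "conflicting",
               lgs = paste(lgs, collapse = ","),
               detail = list(pl[order(contig, pos)]))
  })
  rbindlist(rows)
}

.dot_quote <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")

#' Export a contig graph (or one group) in DOT format
#'
#' Nodes are contigs (annotated with their size when lengths are given),
#' edges carry the relation score as weight/label. The output parses with
#' standard renderers (dot, circo).
#'
#' @param g a [build_contig_graph()] result.
#' @param group optional `contig_group`: restrict output to its members.
#' @param contig_lengths optional named lengths for node size labels.
#' @param path optional file to write to.
#' @return the DOT text (character vector of lines), invisibly when `path`
#'   is given.
#' @export
export_dot <- function(g, group = NULL, contig_lengths = NULL, path = NULL) {
  edges <- g$edges
  nodes <- sort(unique(c(edges$contig_a, edges$contig_b)))
  if (!is.null(group)) {
    nodes <- sort(group$members)
    edges <- edges[contig_a %in% nodes & contig_b %in% nodes]
  }
  node_lines <- vapply(nodes, function(nd) {
    lab <- if (!is.null(contig_lengths) && nd %in% names(contig_lengths))
      sprintf(" [label=%s]",
              .dot_quote(sprintf("%s\\n%d bp", nd,
                                 as.integer(contig_lengths[[nd]]))))
    else ""
    sprintf("  %s%s;", .dot_quote(nd), lab)
  }, character(1), USE.NAMES = FALSE)
  edge_lines <- if (nrow(edges))
    sprintf("  %s -- %s [weight=%.4f, label=\"%.3f\"];",
            .dot_quote(edges$contig_a), .dot_quote(edges$contig_b),
            edges$score, edges$score)
  else character(0)
  out <- c("graph contig_relations {", node_lines, edge_lines, "}")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Write groups and their resolutions to TSV
#'
#' @param groups list of contig groups.
#' @param resolutions list of [linearize_group()] results (same order).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(groups, resolutions, path) {
  rows <- lapply(seq_along(groups), function(i) {
    grp <- groups[[i]]; res <- resolutions[[i]]
    data.table(group = grp$id, resolution = res$resolution,
               n_contigs = length(grp$members), total_bp = grp$total_bp,
               members = paste(if (res$resolution == "linear") res$order
                               else grp$members, collapse = ","))
  })
  fwrite(rbindlist(rows), path, sep = "\t")
  invisible(path)
}
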