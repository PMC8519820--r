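## pipeline: convenience wrapper running the haplotype-relation stages in
## order (filter -> segment/fingerprint -> prune -> all-vs-all).

#' Run the haplotype-relation pipeline on a genotype matrix
#'
#' Applies the site filters, builds per-segment fingerprints, prunes
#' widespread patterns and performs the all-against-all fingerprint
#' comparison.
#'
#' @param m a [genotype_matrix()].
#' @param filter_cfg a [site_filter_config()] (set `NULL` to skip filtering,
#'   e.g. for an already-filtered matrix).
#' @param sim_cfg a [similarity_config()].
#' @param rel_cfg a [relation_config()].
#' @return list: `matrix` (filtered), `filter_report`, `segments`,
#'   `fingerprints` (pruned), `prevalence`, `relations`.
#' @export
haplotype_relations <- function(m, filter_cfg = site_filter_config(),
                                sim_cfg = similarity_config(),
                                rel_cfg = relation_config()) {
  report <- NULL
  if (!is.null(filter_cfg)) {
    fl <- filter_sites(m, filter_cfg)
    m <- fl$matrix
    report <- fl$report
  }
  fb <- build_fingerprints(m, sim_cfg)
  pr <- prune_widespread(fb$fingerprints, rel_cfg, sim_cfg)
  rel <- all_vs_all(pr$fingerprints, sim_cfg, rel_cfg)
  list(matrix = m, filter_report = report, segments = fb$segments,
       fingerprints = pr$fingerprints, prevalence = pr$prevalence,
       relations = rel)
}

#' Group and linearize contigs from a relation table
#'
#' Builds the contig graph, forms groups and attempts a linear resolution
#' for each.
#'
#' @param relations relation table ([all_vs_all()]).
#' @param contig_lengths optional named contig lengths (bp annotation).
#' @param max_nodes linearization bound (see [linearize_group()]).
#' @return list: `graph`, `groups`, `resolutions` (one per group).
#' @export
group_contigs <- function(relations, contig_lengths = NULL, max_nodes = 30L) {
  g <- build_contig_graph(relations)
  groups <- form_groups(g, contig_lengths)
  res <- lapply(groups, linearize_group, g = g, max_nodes = max_nodes)
  list(graph = g, groups = groups, resolutions = res)
}
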