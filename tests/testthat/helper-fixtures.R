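## Small fixtures built in code.

## a random genotype matrix with plausible structure, for property tests
random_genotype_matrix <- function(n_sites = 200, n_acc = 12, n_contigs = 3,
                                   contig_len = 50000, seed = 1,
                                   with_depth = FALSE) {
  set.seed(seed)
  panel <- sprintf("s%02d", seq_len(n_acc))
  contigs <- sprintf("ctg%d", seq_len(n_contigs))
  lens <- stats::setNames(rep(contig_len, n_contigs), contigs)
  ct <- sort(sample(contigs, n_sites, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_sites), ct), function(ix)
    sort(sample.int(contig_len, length(ix)))), use.names = FALSE)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), n_sites * n_acc, replace = TRUE,
                         prob = c(.45, .2, .25, .1)), n_sites, n_acc)
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  is_snp <- runif(n_sites) > 0.05
  alt[!is_snp] <- paste0(alt[!is_snp], "T")      # make some indels
  is_biallelic <- runif(n_sites) > 0.05
  alt[!is_biallelic & is_snp] <-
    paste0(alt[!is_biallelic & is_snp], ",",
           vapply(ref[!is_biallelic & is_snp], function(r)
             sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1)))
  depth <- if (with_depth)
    matrix(rpois(n_sites * n_acc, 6), n_sites, n_acc) else NULL
  sites <- data.table::data.table(
    contig = ct, pos = pos, ref = ref, alt = unname(alt),
    is_snp = nchar(ref) == 1 & !grepl(",", alt) & nchar(gsub(",.*", "", alt)) == 1,
    is_biallelic = !grepl(",", alt),
    total_depth = if (with_depth) as.integer(rowSums(depth))
                  else sample(c(NA_integer_, 100L, 350L), n_sites,
                              replace = TRUE, prob = c(.2, .7, .1)))
  genotype_matrix(panel, sites, calls, lens, depths = depth)
}

## build a fingerprint object directly from a consensus matrix + occurrences
make_fp <- function(id, cons, occ, contig = "tigA", start = 0, end = 1e5) {
  structure(list(segment_id = id, contig = contig, start = start, end = end,
                 cons = cons, occ = as.integer(occ),
                 members = lapply(seq_along(occ), function(i) integer(0)),
                 n_sites = sum(occ), clusters_total = length(occ)),
            class = "fingerprint")
}

## distinct, mutually dissimilar base patterns (strong opposing-hom blocks)
dissimilar_patterns <- function(k, n = 20) {
  stopifnot(k <= n %/% 2)
  t(vapply(seq_len(k), function(i) {
    v <- rep(0L, n)
    v[((i - 1) * 2 + 1):(i * 2)] <- 2L
    v[n] <- 2L                      # shared alt so patterns are not rare-ref
    v
  }, integer(n)))
}

## tiny benchmark simulation reused by several module tests (kept small)
small_sim <- function(seed = 7, n_acc = 30, chrom_len = 2e6, n_chrom = 1) {
  cfg <- sim_config(n_chromosomes = n_chrom, chromosome_length = chrom_len,
                    n_accessions = n_acc,
                    contig_length = list(mean = 4e5, sd = 1e5, min = 5e4),
                    seed = seed)
  sim <- simulate_population(cfg)
  fr <- fragment_reference(sim)
  list(cfg = cfg, sim = sim, fr = fr)
}

## parse DOT text back into node/edge multisets (round-trip oracle)
parse_dot <- function(lines) {
  body <- lines[-c(1, length(lines))]
  edge_lines <- grep(" -- ", body, value = TRUE)
  node_lines <- setdiff(body, edge_lines)
  nodes <- gsub("^\\s*\"([^\"]+)\".*$", "\\1", node_lines)
  from <- gsub("^\\s*\"([^\"]+)\" -- .*$", "\\1", edge_lines)
  to <- gsub("^\\s*\"[^\"]+\" -- \"([^\"]+)\".*$", "\\1", edge_lines)
  list(nodes = sort(nodes),
       edges = sort(paste(pmin(from, to), pmax(from, to))))
}
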