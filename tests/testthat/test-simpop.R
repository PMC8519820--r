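test_that("sim_config validates and requires a seed", {
  expect_error(sim_config(), "seed")
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_founders, 8L)
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 2e5,
                    n_accessions = 8, seed = 5)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$calls, s2$calls)
  f1 <- fragment_reference(s1)
  f2 <- fragment_reference(s2)
  expect_identical(f1$truth, f2$truth)
})

test_that("degenerate simulator inputs behave as documented", {
  cfg0 <- sim_config(n_chromosomes = 1, chromosome_length = 1e5,
                     variant_density = 0, n_accessions = 5, seed = 2)
  expect_equal(nrow(simulate_population(cfg0)$sites), 0L)
  ## F = 1: all variation fixed, nothing segregates after filtering
  cfg1 <- sim_config(n_chromosomes = 1, chromosome_length = 2e5,
                     n_founders = 1, n_accessions = 10,
                     genotype_error_rate = 0, seed = 2)
  m <- filter_sites(simulate_population(cfg1)$matrix)$matrix
  expect_equal(nrow(m$sites), 0L)
})

test_that("site counts follow the density (99% binomial band over seeds)", {
  L <- 2e5
  d <- 3.5 / 1000
  lo <- qbinom(0.005, L, d)
  hi <- qbinom(0.995, L, d)
  counts <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_chromosomes = 1, chromosome_length = L,
                      n_accessions = 4, seed = seed)
    nrow(simulate_population(cfg)$sites)
  }, numeric(1))
  expect_gte(sum(counts >= lo & counts <= hi), 19)
})

test_that("the call composition approximates the configured het share", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 1e6, seed = 9)
  sim <- simulate_population(cfg)
  variant <- sim$calls > 0
  het_share <- sum(sim$calls == 1L, na.rm = TRUE) /
    sum(variant, na.rm = TRUE)
  expect_gt(het_share, 0.30)
  expect_lt(het_share, 0.50)
})

test_that("fragment_reference tiles chromosomes and round-trips sequence", {
  s <- small_sim(seed = 13, n_acc = 6, chrom_len = 5e5)
  fr <- fragment_reference(s$sim, with_sequence = TRUE)
  tr <- fr$truth[order(chrom, ordinal)]
  ## contigs tile without overlap
  expect_equal(tr$start, c(1, head(tr$end, -1) + 1))
  expect_equal(max(tr$end), 5e5)
  ## reassembling oriented contigs reproduces the chromosome byte-identically
  pieces <- vapply(seq_len(nrow(tr)), function(i) {
    sq <- fr$contig_seqs[[tr$contig[i]]]
    if (tr$orientation[i] == "-") sq <- Biostrings::reverseComplement(sq)
    as.character(sq)
  }, character(1))
  expect_equal(paste(pieces, collapse = ""),
               as.character(fr$chrom_seqs[[1]]))
  ## site calls are preserved, only re-indexed
  expect_equal(sort(fr$matrix$sites$ref), sort(s$sim$sites$ref))
  expect_equal(nrow(fr$matrix$sites), nrow(s$sim$sites))
})

test_that("a contig distribution wider than the chromosome gives one contig", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 1e5,
                    n_accessions = 4,
                    contig_length = list(mean = 1e6, sd = 1, min = 5e4),
                    seed = 3)
  fr <- fragment_reference(simulate_population(cfg))
  expect_equal(nrow(fr$truth), 2L)
  expect_equal(nrow(fr$adjacencies), 0L)
})

test_that("write_sim_outputs writes standard files incl. header-only VCF", {
  s <- small_sim(seed = 17, n_acc = 5, chrom_len = 2e5)
  fr <- fragment_reference(s$sim, with_sequence = TRUE)
  set.seed(18)
  links <- simulate_mate_pairs(fr, span = 3000, n_pairs = 500)
  paf <- simulate_long_reads(fr, n_reads = 50)
  dir <- tempfile()
  paths <- write_sim_outputs(fr, dir, mate_links = links, paf = paf)
  expect_true(all(file.exists(paths)))
  m2 <- read_vcf(paths[["vcf"]])
  expect_equal(unname(m2$calls), unname(fr$matrix$calls))
  paf2 <- read_paf(paths[["paf"]])
  expect_equal(nrow(paf2), nrow(paf))
  ## empty matrix -> header-only VCF, still readable
  empty <- genotype_matrix(c("a", "b"),
                           data.table::data.table(contig = character(),
                                                  pos = integer(),
                                                  ref = character(),
                                                  alt = character()),
                           matrix(integer(), 0, 2), c(c1 = 100))
  p <- tempfile(fileext = ".vcf")
  write_vcf(empty, p)
  expect_equal(nrow(read_vcf(p)$sites), 0L)
})

test_that("simulated mate-pair spans are distributed around the library span", {
  s <- small_sim(seed = 21, n_acc = 4, chrom_len = 5e5)
  fr <- fragment_reference(s$sim)
  set.seed(22)
  links <- simulate_mate_pairs(fr, span = 4000, sd = 300, n_pairs = 3000)
  ## same-contig forward pairs: observed distance reflects the fragment
  tr <- fr$truth
  fwd <- links[links$contig_a == links$contig_b &
                 links$contig_a %in% tr$contig[tr$orientation == "+"], ]
  obs <- abs(fwd$pos_b - fwd$pos_a) + 1
  expect_gt(nrow(fwd), 100)
  expect_lt(abs(mean(obs) - 4000), 3 * 300 / sqrt(nrow(fwd)) + 50)
})

test_that("evaluate_recovery handles the trivial cases", {
  truth <- data.table::data.table(
    contig = c("A", "B", "C"), chrom = "chr01",
    start = c(1, 1001, 2001), end = c(1000, 2000, 3000),
    ordinal = 1:3, orientation = "+", ext = 0, len = 1000)
  segments <- data.table::data.table(
    contig = c("A", "B", "C"), start = 0, end = 1000, index = 1,
    segment_id = c("A:1", "B:1", "C:1"))
  rel <- data.table::data.table(
    seg_a = c("A:1", "B:1"), seg_b = c("B:1", "C:1"),
    contig_a = c("A", "B"), contig_b = c("B", "C"),
    n_shared = 1L, score_ab = 1, score_ba = 1, score = 1,
    valid = TRUE, intra_contig = FALSE)
  ev <- evaluate_recovery(rel, truth, segments, segment_size = 1000)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  ## empty relations
  ev0 <- evaluate_recovery(rel[0], truth, segments)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$adjacent_per_mbp, 0)
  ## unknown contig in segments errors
  seg_bad <- data.table::copy(segments)[1, contig := "Z"]
  seg_bad[1, segment_id := "Z:1"]
  expect_error(evaluate_recovery(rel, truth, seg_bad), "missing from truth")
})

test_that("evaluate_recovery equals an independent recomputation on a sim", {
  s <- small_sim(seed = 23, n_acc = 25, chrom_len = 2e6)
  res <- haplotype_relations(s$fr$matrix)
  ev <- evaluate_recovery(res$relations, s$fr$truth, res$segments)
  ora <- oracle_recovery(res$relations, s$fr$truth, res$segments)
  expect_equal(ev$n_adjacent, ora$n_adjacent)
  expect_equal(ev$n_remote, ora$n_remote)
  expect_equal(ev$precision, ora$precision)
  expect_equal(ev$recall, ora$recall)
})

test_that("estimate_genome_size evaluates the closed forms exactly", {
  ## formula collapses at k = 1
  expect_equal(estimate_genome_size(100, 100, 1, 1e9)$seq_depth, 100)
  ## the published inputs: exact formula value (the source rounds to 99.3)
  est <- estimate_genome_size(81.4, 89, 17, 121826911748,
                              assumed_genome_size = 1.45e9)
  expect_equal(est$seq_depth, 81.4 * 89 / 73)
  expect_equal(round(est$seq_depth, 2), 99.24)
  expect_equal(round(est$genome_size / 1e9, 2), 1.23)
  expect_equal(round(est$coverage), 84)
  expect_error(estimate_genome_size(81.4, 17, 89, 1), "read_length")
  expect_error(estimate_genome_size(-1, 89, 17, 1))
})

test_that("ld_r2_decay: duplicates give r2 = 1, independence the 1/(N-1) floor", {
  set.seed(31)
  n_acc <- 40
  panel <- sprintf("a%02d", 1:n_acc)
  dosage <- sample(0:2, n_acc, replace = TRUE)
  calls <- rbind(dosage, dosage)
  m <- genotype_matrix(panel,
                       data.table::data.table(contig = "c", pos = c(100L, 300L),
                                              ref = "A", alt = "G"),
                       calls, c(c = 1000))
  out <- ld_r2_decay(m, thin_bp = 1, bin_bp = 1000)
  expect_equal(out$mean_r2, 1)
  ## independent loci: mean r2 near 1/(N-1)
  ns <- 60
  calls <- matrix(sample(0:2, ns * n_acc, replace = TRUE), ns, n_acc)
  m2 <- genotype_matrix(panel,
                        data.table::data.table(contig = "c",
                                               pos = seq(1L, by = 50L,
                                                         length.out = ns),
                                               ref = "A", alt = "G"),
                        calls, c(c = 10000))
  out2 <- ld_r2_decay(m2, thin_bp = 1, max_dist = 1e4, bin_bp = 1e4)
  floor_r2 <- 1 / (n_acc - 1)
  expect_lt(abs(sum(out2$mean_r2 * out2$n_pairs) / sum(out2$n_pairs) -
                  floor_r2), floor_r2)
})

test_that("lower recombination slows the r2 decay", {
  decay_at <- function(rate) {
    cfg <- sim_config(n_chromosomes = 1, chromosome_length = 1e6,
                      n_accessions = 25, recombination_rate = rate,
                      seed = 33)
    m <- filter_sites(simulate_population(cfg)$matrix)$matrix
    out <- ld_r2_decay(m, thin_bp = 2000, max_dist = 1e5, bin_bp = 2e4)
    sum(out$mean_r2 * out$n_pairs) / sum(out$n_pairs)
  }
  expect_gt(decay_at(2), decay_at(30))
})

test_that("recovery degrades monotonically with genotype error (fixed seed)", {
  metrics <- lapply(c(0, 0.05, 0.15), function(err) {
    cfg <- sim_config(n_chromosomes = 1, chromosome_length = 2e6,
                      n_accessions = 25, genotype_error_rate = err,
                      contig_length = list(mean = 4e5, sd = 1e5, min = 5e4),
                      seed = 35)
    sim <- simulate_population(cfg)
    fr <- fragment_reference(sim)
    res <- haplotype_relations(fr$matrix)
    evaluate_recovery(res$relations, fr$truth, res$segments)
  })
  rec <- vapply(metrics, `[[`, numeric(1), "recall")
  adj <- vapply(metrics, `[[`, numeric(1), "adjacent_per_mbp")
  expect_true(all(diff(rec) <= 0) || all(diff(adj) < 0))
})
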