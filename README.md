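# ldscaffold

Haplotype-guided genome assembly scaffolding from population variation.

## The problem

Draft genome assemblies of repeat-rich plant genomes fragment into
thousands of contigs, and the long-range information needed to order and
orient them (Hi-C, optical maps, linked reads) demands high-molecular-weight
DNA that plant samples often cannot provide. But most genome projects
re-sequence a panel of accessions anyway, producing a multi-sample variant
catalog — and that catalog contains long-range information for free.
Because chromosomes are inherited in blocks, the *variation pattern* at a
site (the succession of hom-ref / het / hom-alt / missing calls across the
fixed accession panel) persists over distances set by the local extent of
linkage disequilibrium. Patterns that continue across an assembly gap tie
the flanking contigs together.

`ldscaffold` is for assembly teams holding a draft assembly plus a
population VCF (tens of accessions, a few-fold coverage each — a selfing
crop panel is the ideal case). It detects shared haplotype "fingerprints"
between assembly segments, scores contig relations, groups and orders
contigs, and scaffolds them where mate-pairs, long reads or contig-end
overlaps confirm the junction. A founder-mosaic population simulator with
known truth makes the whole pipeline testable offline.

## The statistic at its core

Each 100-kbp segment's sites are clustered into a *fingerprint*: the set of
distinct variation patterns with occurrence counts, keeping patterns seen
at ≥ 3 positions. Two patterns are similar iff no accession opposes
homozygously, at most `floor(0.10 n)` accessions differ via het/missing
calls, and rare patterns (< 20% carriers) admit no mismatch at their
carriers. For fingerprints *A*, *B* with total occurrences `T_A`, matched
occurrences `I` (greedy one-to-one matching, occurrence-descending) and
unmatched *B*-mass `U_B`, the directed score is

```
s(A -> B) = I / (T_A + U_B)
```

an occurrence-normalized Jaccard index in which each matched *B* pattern is
rescaled to its *A* counterpart (coefficient `c = o_A / o_B`); for
fingerprints {5, 10} vs {9} with one cross-match this is
`10 / ((10+5) + 9*(10/9) - 10) = 0.667`. A relation is *valid* when
`max(s(A->B), s(B->A)) >= 0.1`. Valid relations lift to a contig graph;
connected components become contig groups; simple chains (after a
transitive reduction of weak bypass edges) become linear orders; physical
evidence decides orientation (majority vote) and gap sizes
(`median(span - d_A - d_B)`), with overlap merges trimmed and joined by
10 Ns.

## Worked example

A 4-Mbp single-chromosome population of 50 accessions, fragmented into 8
contigs, related and scaffolded end to end:

```r
library(ldscaffold)
cfg <- sim_config(n_chromosomes = 1, chromosome_length = 4e6,
                  n_accessions = 50, seed = 42)
sim <- simulate_population(cfg)
fr  <- fragment_reference(sim, with_sequence = TRUE)

res <- haplotype_relations(fr$matrix,
                           site_filter_config(max_missing_fraction = 0.10))
gc  <- group_contigs(res$relations, fr$contig_lengths)

set.seed(43)
links <- simulate_mate_pairs(fr, span = 5000, n_pairs = 6e4)
plan  <- decide_joins(gc$resolutions[[1]]$order, fr$contig_lengths,
                      mate_links = links, group_id = 1)
out   <- emit_scaffolds(fr$contig_seqs, plan)
evaluate_recovery(res$relations, fr$truth, res$segments)
```

This prints (numbers produced by the code above):

```
genotype_matrix: 13885 sites on 8 contigs, 50 accessions
filter report: missingness 529, maf 82, retained 13274
43 fingerprints, 50 relations (26 valid)
2 group(s); linear orders:
  tig00002 - tig00004 - tig00008 - tig00003 - tig00006 | tig00005 - tig00007
scaffolds: scaffold_1_1 (2825367 bp)
N50: 533769 -> 2825367
adjacent 6.5 /Mbp, remote 0.0 /Mbp, precision 1.00, recall 0.71
```

Reading: 13,274 informative biallelic SNPs survive the noise filters; 26
segment pairs share enough of their fingerprints to be valid relations; the
contigs fall into two chains whose order matches the simulation truth; the
five-contig chain is confirmed by mate-pairs and merges into a 2.8-Mbp
scaffold, quintupling N50. Every valid relation links truly adjacent
segments (precision 1.00); 71% of true contig junctions are recovered on
this small genome (97% on the full 20-Mbp benchmark).

The closed-form genome-size utility evaluates the k-mer depth formula
`seqDepth = peak * readLength / (readLength - kmerSize + 1)` exactly:

```r
estimate_genome_size(81.4, 89, 17, 121826911748, assumed_genome_size = 1.45e9)
#> k-mer depth 99.24, genome size 1.23 Gbp, coverage 84x
```

## Command line

An `exec/ldscaffold` script exposes the pipeline:

```sh
ldscaffold simulate --seed 42 --out sim/
ldscaffold relate   --vcf sim/pop.vcf --out relations.tsv --max-missing 0.10
ldscaffold group    --relations relations.tsv --out groups/
ldscaffold scaffold --fasta sim/contigs.fa --groups groups/groups.tsv \
                    --links sim/links_mp.tsv --out scaffolds/
ldscaffold evaluate --relations relations.tsv --truth sim/truth.tsv
```

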