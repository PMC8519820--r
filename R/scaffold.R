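## scaffold: physical-evidence confirmation of haplotype-derived contig
## orders — mate-pair gap estimation, long-read end links, contig-end
## overlaps — and emission of scaffold FASTA/AGP.

#' N50 of a set of sequence lengths
#' @param lengths numeric vector of sequence lengths (bp).
#' @return the length such that 50% of the summed bases reside in sequences
#'   at least that long.
#' @export
n50 <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  if (!length(lengths)) return(0)
  lengths[which(cumsum(lengths) >= sum(lengths) / 2)[1L]]
}

#' Estimate the gap between two contigs from mate-pair links
#'
#' Per supporting pair, `gap_i = span - (d_a + d_b)` where `d_a`, `d_b` are
#' the distances from the read positions to the facing contig ends and `span`
#' is the expected peak span size of the library; the estimate is the median
#' over pairs (robust to chimeric pairs). Negative values signal a probable
#' overlap.
#'
#' @param links `data.frame`/`data.table` with numeric columns `span`, `d_a`,
#'   `d_b` (one row per read pair).
#' @return signed bp estimate; an error if no pairs are given (the join must
#'   be rejected).
#' @export
estimate_gap <- function(links) {
  links <- as.data.table(links)
  if (!nrow(links)) stop("no supporting pairs: gap undefined, join rejected")
  stats::median(links$span - (links$d_a + links$d_b))
}

#' Read a PAF file of long-read alignments
#'
#' Only the 12 mandatory columns are kept. Lines with fewer than 12 fields
#' are skipped with a warning.
#'
#' @param path PAF file path.
#' @return `data.table` with columns qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, nmatch, alnlen, mapq.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- nf < 12L
  if (any(bad)) {
    warning(sum(bad), " malformed PAF line(s) skipped")
    lines <- lines[!bad]
  }
  if (!length(lines))
    return(data.table(qname = character(), qlen = integer(),
                      qstart = integer(), qend = integer(),
                      strand = character(), tname = character(),
                      tlen = integer(), tstart = integer(), tend = integer(),
                      nmatch = integer(), alnlen = integer(), mapq = integer()))
  dt <- fread(text = lines, header = FALSE, sep = "\t", fill = TRUE,
              select = 1:12)
  setnames(dt, c("qname", "qlen", "qstart", "qend", "strand", "tname",
                 "tlen", "tstart", "tend", "nmatch", "alnlen", "mapq"))
  dt
}

#' Derive contig links from end-proximal long-read alignments
#'
#' A read (including split-read siblings, recognized by a `/<n>` name
#' suffix) links two contigs only when both alignments fall within
#' `end_fraction` of a contig head or tail. For each linked pair the
#' read-space distance between the two alignments is kept as a gap estimate,
#' and the alignment strands give the relative orientation (equal strands =
#' same orientation).
#'
#' @param paf alignment table from [read_paf()].
#' @param end_fraction fraction of the contig length counting as
#'   end-proximal (default 0.10).
#' @return `data.table`: read, contig_a, strand_a, end_a, contig_b,
#'   strand_b, end_b, gap.
#' @export
longread_links <- function(paf, end_fraction = 0.10) {
  paf <- as.data.table(paf)
  empty <- data.table(read = character(), contig_a = character(),
                      strand_a = character(), end_a = character(),
                      contig_b = character(), strand_b = character(),
                      end_b = character(), gap = numeric())
  if (!nrow(paf)) return(empty)
  paf[, read := sub("/[0-9]+$", "", qname)]
  head_prox <- paf$tstart <= end_fraction * paf$tlen
  tail_prox <- paf$tend >= (1 - end_fraction) * paf$tlen
  keep <- head_prox | tail_prox
  if (!any(keep)) return(empty)
  hp <- head_prox[keep]; tp <- tail_prox[keep]
  paf <- paf[keep]
  paf[, end_hit := ifelse(tp & !hp, "tail", ifelse(hp & !tp, "head", "both"))]
  setorder(paf, read, qstart)
  out <- paf[, {
    if (.N >= 2L && uniqueN(tname) >= 2L) {
      i <- seq_len(.N - 1L)
      keep <- tname[i] != tname[i + 1L]
      list(contig_a = tname[i][keep], strand_a = strand[i][keep],
           end_a = end_hit[i][keep],
           contig_b = tname[i + 1L][keep], strand_b = strand[i + 1L][keep],
           end_b = end_hit[i + 1L][keep],
           gap = as.numeric(qstart[i + 1L][keep] - qend[i][keep]))
    } else NULL
  }, by = read]
  if (!nrow(out)) return(empty)
  out[]
}

#' Find a suffix/prefix overlap between two oriented contig ends
#'
#' Best ends-free alignment of the tail of `seq_a` against the head of
#' `seq_b` (both already in scaffold orientation); reported only when it
#' actually reaches `seq_a`'s end and `seq_b`'s start, is at least `min_len`
#' long and at least `min_identity` identical.
#'
#' @param seq_a,seq_b `Biostrings::DNAString` (or character) sequences.
#' @param min_len minimum overlap length in bp (default 100).
#' @param min_identity minimum fractional identity (default 0.95).
#' @param window how much of each end to consider (default 10,000 bp).
#' @return list (`length`, `identity`, `trim_b`: bases to trim from the head
#'   of `seq_b`) or `NULL` when no acceptable overlap exists.
#' @export
find_overlap <- function(seq_a, seq_b, min_len = 100L, min_identity = 0.95,
                         window = 10000L) {
  seq_a <- Biostrings::DNAString(as.character(seq_a))
  seq_b <- Biostrings::DNAString(as.character(seq_b))
  la <- length(seq_a); lb <- length(seq_b)
  tail_a <- Biostrings::subseq(seq_a, max(1L, la - window + 1L), la)
  head_b <- Biostrings::subseq(seq_b, 1L, min(window, lb))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(tail_a, head_b, type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 2)
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  if (Biostrings::score(aln) <= 0) return(NULL)
  ## must anchor at A's end and B's start to be a true suffix/prefix overlap
  if (IRanges::end(pr@range) != length(tail_a) ||
      IRanges::start(sr@range) != 1L) return(NULL)
  ov_len <- IRanges::width(pr@range)
  ident <- Biostrings::pid(aln) / 100
  if (ov_len < min_len || ident < min_identity) return(NULL)
  list(length = ov_len, identity = ident,
       trim_b = IRanges::end(sr@range))
}

## orientation/gap bookkeeping for one adjacent pair, from normalized links
## (contig_a = left contig X, contig_b = right contig Y of the junction)
.pair_votes <- function(links, or_x, len_x, len_y, type = c("mate", "long")) {
  type <- match.arg(type)
  ## relative orientation: mate pairs face each other (strands differ when
  ## orientations agree); a long read crosses the junction on one strand
  ## (strands agree when orientations agree)
  rel_flip <- if (type == "mate") links$strand_a == links$strand_b
              else links$strand_a != links$strand_b
  votes <- table(rel_flip)
  n_same <- sum(!rel_flip); n_flip <- sum(rel_flip)
  if (n_same == n_flip) return(NULL)      # exact tie: reject join
  flip <- n_flip > n_same
  or_y <- if (flip) setdiff(c("+", "-"), or_x) else or_x
  use <- links[rel_flip == flip]
  d_a <- ifelse(or_x == "+", len_x - use$pos_a + 1, use$pos_a)
  d_b <- ifelse(or_y == "+", use$pos_b, len_y - use$pos_b + 1)
  list(or_y = or_y, n_links = nrow(use),
       links = data.table(span = use$span, d_a = d_a, d_b = d_b))
}

#' Decide scaffold joins for a linear contig group
#'
#' Adjacent contigs of the haplotype-derived order are joined only when at
#' least one type of physical evidence supports the junction; mate-pair and
#' long-read evidence is used preferentially over overlaps. The orientation
#' of each pair is decided by majority vote over the supporting links (an
#' exact tie rejects the join); the first contig of each output sequence is
#' oriented `+`. Junctions without physical evidence split the output into
#' separate sequences that still carry the group identity.
#'
#' @param order character vector of contigs (linear group order).
#' @param contig_lengths named lengths of the contigs.
#' @param mate_links `data.table` of mate-pair links with columns `contig_a`,
#'   `pos_a`, `strand_a`, `contig_b`, `pos_b`, `strand_b`, `span` (declared
#'   library span; `pos` is the outermost, fragment-terminal aligned base).
#' @param lr_links optional [longread_links()] table.
#' @param overlaps optional `data.table` of overlap candidates: `contig_a`,
#'   `contig_b`, `length`, `identity`.
#' @param group_id identifier recorded in the plan (default 1).
#' @param min_links minimum supporting links per junction (default 1).
#' @param min_gap minimum N-gap length (default 10).
#' @return object of class `scaffold_plan`: list `sequences`, each with
#'   `members` (`data.table`: contig, orientation) and `joins`
#'   (`data.table`: type, gap, evidence, n_links — one row per internal
#'   junction).
#' @export
decide_joins <- function(order, contig_lengths, mate_links = NULL,
                         lr_links = NULL, overlaps = NULL, group_id = 1L,
                         min_links = 1L, min_gap = 10L) {
  mate_links <- if (is.null(mate_links)) data.table() else as.data.table(mate_links)
  lr_links <- if (is.null(lr_links)) data.table() else as.data.table(lr_links)
  overlaps <- if (is.null(overlaps)) data.table() else as.data.table(overlaps)

  norm_pair <- function(links, x, y, swap_cols) {
    if (!nrow(links)) return(links[0])
    fwd <- links[links$contig_a == x & links$contig_b == y, ]
    rev <- links[links$contig_a == y & links$contig_b == x, ]
    if (nrow(rev)) {
      setnames(rev, swap_cols, swap_cols[c(2, 1, 4, 3, 6, 5)[seq_along(swap_cols)]])
      fwd <- rbind(fwd, rev, use.names = TRUE, fill = TRUE)
    }
    fwd
  }

  sequences <- list()
  cur_members <- data.table(contig = order[1L], orientation = "+")
  cur_joins <- data.table(type = character(), gap = numeric(),
                          evidence = character(), n_links = integer())
  flush <- function() {
    sequences[[length(sequences) + 1L]] <<-
      list(members = cur_members, joins = cur_joins)
  }
  for (i in seq_len(length(order) - 1L)) {
    x <- order[i]; y <- order[i + 1L]
    or_x <- cur_members$orientation[nrow(cur_members)]
    mp <- norm_pair(mate_links, x, y,
                    c("contig_a", "contig_b", "pos_a", "pos_b",
                      "strand_a", "strand_b"))
    lr <- norm_pair(lr_links, x, y,
                    c("contig_a", "contig_b", "strand_a", "strand_b",
                      "end_a", "end_b"))
    ov <- if (nrow(overlaps)) {
      rbind(overlaps[overlaps$contig_a == x & overlaps$contig_b == y, ],
            overlaps[overlaps$contig_a == y & overlaps$contig_b == x,
                     .(contig_a = contig_b, contig_b = contig_a,
                       length, identity)],
            fill = TRUE)
    } else overlaps
    decided <- NULL
    if (nrow(mp) >= min_links) {
      pv <- .pair_votes(mp, or_x, contig_lengths[[x]], contig_lengths[[y]],
                        "mate")
      if (!is.null(pv)) {
        gap <- estimate_gap(pv$links)
        decided <- list(or_y = pv$or_y, gap = gap, evidence = "mate_pair",
                        n_links = pv$n_links)
      }
    }
    if (is.null(decided) && nrow(lr) >= min_links) {
      rel_flip <- lr$strand_a != lr$strand_b
      n_flip <- sum(rel_flip); n_same <- sum(!rel_flip)
      if (n_flip != n_same) {
        flip <- n_flip > n_same
        or_y <- if (flip) setdiff(c("+", "-"), or_x) else or_x
        decided <- list(or_y = or_y,
                        gap = stats::median(lr$gap[rel_flip == flip]),
                        evidence = "long_read",
                        n_links = max(n_flip, n_same))
      }
    }
    if (!is.null(decided) && decided$gap < 0 && nrow(ov)) {
      ## negative gap estimate: prefer the overlap merge
      decided <- list(or_y = decided$or_y, gap = -ov$length[1L],
                      evidence = paste0(decided$evidence, "+overlap"),
                      n_links = decided$n_links, overlap = ov$length[1L])
    }
    if (is.null(decided) && nrow(ov)) {
      decided <- list(or_y = or_x, gap = -ov$length[1L], evidence = "overlap",
                      n_links = nrow(ov), overlap = ov$length[1L])
    }
    if (is.null(decided)) {
      flush()
      cur_members <- data.table(contig = y, orientation = "+")
      cur_joins <- cur_joins[0]
    } else {
      cur_members <- rbind(cur_members,
                           data.table(contig = y, orientation = decided$or_y))
      cur_joins <- rbind(cur_joins, data.table(
        type = if (!is.null(decided$overlap)) "overlap" else "gap",
        gap = if (!is.null(decided$overlap)) -decided$overlap
              else max(decided$gap, min_gap),
        evidence = decided$evidence, n_links = decided$n_links))
    }
  }
  flush()
  structure(list(group_id = group_id, sequences = sequences),
            class = "scaffold_plan")
}

#' @export
print.scaffold_plan <- function(x, ...) {
  nj <- sum(vapply(x$sequences, function(s) nrow(s$joins), integer(1)))
  cat(sprintf("scaffold_plan (group %s): %d sequence(s), %d join(s)\n",
              x$group_id, length(x$sequences), nj))
  invisible(x)
}

#' Emit scaffold sequences and an AGP from a plan
#'
#' Gap joins insert `max(estimated gap, min_gap)` Ns; overlap joins trim the
#' overlap from the head of the incoming contig and insert exactly `min_gap`
#' (10) Ns. Output sequences are named `<prefix><group>_<n>` to reflect group
#' and order. The AGP (v2.1) describes every component and gap; together with
#' the input FASTA it reconstructs the output exactly.
#'
#' @param seqs `Biostrings::DNAStringSet` of input contigs (named).
#' @param plan a [decide_joins()] result.
#' @param min_gap minimum/overlap-join gap size (default 10).
#' @param prefix output sequence name prefix (default `"scaffold_"`).
#' @return list with `scaffolds` (`DNAStringSet`) and `agp` (`data.table`
#'   with the nine AGP columns).
#' @export
emit_scaffolds <- function(seqs, plan, min_gap = 10L, prefix = "scaffold_") {
  out_seqs <- list()
  agp <- list()
  for (si in seq_along(plan$sequences)) {
    sq <- plan$sequences[[si]]
    name <- sprintf("%s%s_%d", prefix, plan$group_id, si)
    parts <- character(0)
    rows <- list()
    cursor <- 0L
    part_no <- 0L
    for (mi in seq_len(nrow(sq$members))) {
      ct <- sq$members$contig[mi]
      or <- sq$members$orientation[mi]
      if (!ct %in% names(seqs)) stop("sequence missing for contig ", ct)
      s <- seqs[[ct]]
      clen <- length(s)
      trim <- 0L
      if (mi > 1L) {
        jn <- sq$joins[mi - 1L]
        if (jn$type == "overlap") {
          trim <- as.integer(-jn$gap)
          if (trim >= clen)
            stop("overlap trim (", trim, ") not shorter than contig ", ct)
          gap_len <- as.integer(min_gap)
        } else {
          gap_len <- as.integer(max(jn$gap, min_gap))
        }
        part_no <- part_no + 1L
        rows[[length(rows) + 1L]] <- data.table(
          object = name, object_beg = cursor + 1L,
          object_end = cursor + gap_len, part_number = part_no,
          component_type = "N", component_id = as.character(gap_len),
          component_beg = "scaffold", component_end = "yes",
          orientation = "paired-ends")
        parts <- c(parts, strrep("N", gap_len))
        cursor <- cursor + gap_len
      }
      ## component interval in original contig coordinates
      if (or == "+") {
        beg <- trim + 1L; endc <- clen
        piece <- Biostrings::subseq(s, beg, endc)
      } else {
        beg <- 1L; endc <- clen - trim
        piece <- Biostrings::reverseComplement(Biostrings::subseq(s, beg, endc))
      }
      part_no <- part_no + 1L
      rows[[length(rows) + 1L]] <- data.table(
        object = name, object_beg = cursor + 1L,
        object_end = cursor + length(piece), part_number = part_no,
        component_type = "W", component_id = ct,
        component_beg = as.character(beg), component_end = as.character(endc),
        orientation = or)
      parts <- c(parts, as.character(piece))
      cursor <- cursor + length(piece)
    }
    out_seqs[[name]] <- paste(parts, collapse = "")
    agp[[length(agp) + 1L]] <- rbindlist(rows)
  }
  scaffolds <- Biostrings::DNAStringSet(unlist(out_seqs))
  list(scaffolds = scaffolds, agp = rbindlist(agp))
}

#' Write an AGP table
#' @param agp AGP `data.table` from [emit_scaffolds()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  writeLines("##agp-version\t2.1", path)
  fwrite(agp, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Detect coverage drops indicating possible misassemblies
#'
#' Windows whose mean coverage falls below `drop_ratio` times the contig
#' median are reported (adjacent windows merged). Used to split contigs
#' carrying conflicting linkage-group assignments at the drop position.
#'
#' @param coverage numeric per-base coverage along the contig.
#' @param window window size in bp (default 1000).
#' @param drop_ratio fraction of the contig median below which a window is a
#'   candidate (default 0.25); 0 never triggers.
#' @return `data.table` with 1-based `start`, `end` of candidate regions
#'   (zero rows if none).
#' @export
detect_coverage_drop <- function(coverage, window = 1000L, drop_ratio = 0.25) {
  empty <- data.table(start = integer(), end = integer())
  n <- length(coverage)
  if (!n || drop_ratio <= 0) return(empty)
  med <- stats::median(coverage, na.rm = TRUE)
  bins <- (seq_len(n) - 1L) %/% window
  means <- tapply(coverage, bins, mean, na.rm = TRUE)
  hit <- which(means < drop_ratio * med)
  if (!length(hit)) return(empty)
  runs <- split(hit, cumsum(c(1L, diff(hit) != 1L)))
  rbindlist(lapply(runs, function(r) {
    b <- as.integer(names(means)[r])
    data.table(start = min(b) * window + 1L,
               end = min(n, (max(b) + 1L) * window))
  }))
}
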