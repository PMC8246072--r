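# SV evidence features, extracted identically from actual and simulated
# alignments: realigned allele counts, insert-probability-weighted spanning
# pairs, soft-clip counts, and depth fold-changes.

#' Realignment scoring configuration
#'
#' Log10-unit scoring for pair realignment: match `log10(1 - e)`, mismatch
#' `log10(e / 3)` (error rate `e` from the profile), affine gap open -6 and
#' extend -1 per base, and a pair assigned to an allele only when its log10
#' score difference exceeds `assign_threshold`.
#'
#' @param gap_open,gap_extend Positive gap costs (log10 units).
#' @param assign_threshold Minimum log10 score difference for a unique
#'   allele assignment.
#' @param min_clip Minimum soft-clip length (bp) counted as clip evidence.
#' @param depth_flank Flank length (bp) for the flank-normalized depth
#'   fold-change.
#' @return A list of scoring constants.
#' @export
realign_config <- function(gap_open = 6, gap_extend = 1,
                           assign_threshold = 1, min_clip = 4L,
                           depth_flank = 1000L) {
  list(gap_open = gap_open, gap_extend = gap_extend,
       assign_threshold = assign_threshold, min_clip = as.integer(min_clip),
       depth_flank = as.integer(depth_flank))
}

#' Names of the model features
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c("ref_count", "alt_count", "alt_fraction", "span_ref", "span_alt",
    "clip_count", "dhfc", "dhbfc", "dhffc")
}

# 0-based half-open event interval on the reference: the changed bases after
# the padding base (empty for a pure insertion).
event_interval <- function(v) {
  c(start = v$pos, end = v$pos - 1L + nchar(v$ref))
}

# Pairs (read1/read2 rows joined on qname) among mapped reads.
pair_table <- function(reads) {
  if (is.null(reads[["span"]])) reads$span <- cigar_ref_span(reads$cigar)
  r1 <- reads %>% filter(.data$mate == 1L)
  r2 <- reads %>% filter(.data$mate == 2L)
  dplyr::inner_join(
    r1 %>% select("qname", pos1 = "pos", cigar1 = "cigar", seq1 = "seq",
                  mapped1 = "mapped", span1 = "span"),
    r2 %>% select("qname", pos2 = "pos", cigar2 = "cigar", seq2 = "seq",
                  mapped2 = "mapped", span2 = "span"),
    by = "qname")
}

# Reads overlapping [start0 - pad, end0 + pad) on the contig.
region_reads <- function(reads, contig, start0, end0, pad = 0L) {
  if (nrow(reads) == 0) return(reads)
  span <- reads[["span"]] %||% cigar_ref_span(reads$cigar)
  keep <- reads$mapped & reads$contig == contig &
    (reads$pos - 1L) < end0 + pad & (reads$pos - 1L + span) > start0 - pad
  reads[keep, ]
}

#' Realign read pairs to both allele contexts and assign alleles
#'
#' Per allele, each read of the pair is scored with a glocal affine-gap
#' alignment in log10 probability units and the pair score adds the log10
#' insert-size probability of the fragment length implied by the two
#' alignments on that allele. The pair supports the allele with the higher
#' score when the log10 difference exceeds the assignment threshold;
#' otherwise it is ambiguous.
#'
#' @param pairs Tibble with `seq1`, `seq2` (reference-oriented read
#'   sequences), one row per pair.
#' @param contexts An `allele_pair` from [allele_contexts()].
#' @param p `sample_profile`.
#' @param config [realign_config()].
#' @return `pairs` with `score_ref`, `score_alt` and `allele` in
#'   `{"REF", "ALT", "AMBIGUOUS"}`.
#' @export
realign_pairs <- function(pairs, contexts, p, config = realign_config()) {
  if (nrow(pairs) == 0) {
    return(mutate(pairs, score_ref = numeric(0), score_alt = numeric(0),
                  allele = character(0)))
  }
  e <- max(p$base_error_rate, 1e-4)   # floor so mismatch cost is finite
  match_s <- log10(1 - e)
  mismatch_s <- log10(e / 3)
  score_allele <- function(ctx) {
    s1 <- score_reads_cpp(pairs$seq1, ctx, match_s, mismatch_s,
                          config$gap_open, config$gap_extend)
    s2 <- score_reads_cpp(pairs$seq2, ctx, match_s, mismatch_s,
                          config$gap_open, config$gap_extend)
    frag <- pmax(s1[, "end"], s2[, "end"]) - pmin(s1[, "start"], s2[, "start"])
    s1[, "score"] + s2[, "score"] + log10(insert_probability(p, frag))
  }
  score_ref <- score_allele(contexts$ref_context)
  score_alt <- score_allele(contexts$alt_context)
  d <- score_alt - score_ref
  pairs %>% mutate(
    score_ref = score_ref, score_alt = score_alt,
    allele = dplyr::case_when(
      d > config$assign_threshold ~ "ALT",
      d < -config$assign_threshold ~ "REF",
      TRUE ~ "AMBIGUOUS"
    ))
}

#' Allele support counts from local realignment
#'
#' Realigns read pairs originally mapped within the flanking distance
#' (default the 99th percentile of the insert size) of the breakpoints and
#' counts pairs uniquely assigned to each allele; ambiguous pairs are counted
#' in neither.
#'
#' @param alignments Alignment tibble.
#' @param v One-row `sv_tbl`.
#' @param contexts [allele_contexts()] result.
#' @param p `sample_profile`.
#' @param flank_dist Realignment recruitment distance (bp).
#' @param config [realign_config()].
#' @return Tibble with `ref_count`, `alt_count`, `alt_fraction`,
#'   `ambiguous_count`.
#' @export
count_alleles <- function(alignments, v, contexts, p,
                          flank_dist = insert_q99(p),
                          config = realign_config()) {
  ev <- event_interval(v)
  near <- region_reads(alignments, v$contig, ev["start"], ev["end"],
                       pad = flank_dist)
  pairs <- pair_table(alignments[alignments$qname %in% near$qname, ])
  pairs <- pairs[pairs$mapped1 | pairs$mapped2, ]
  if (nrow(pairs) == 0) {
    return(tibble(ref_count = 0, alt_count = 0, alt_fraction = 0,
                  ambiguous_count = 0))
  }
  res <- realign_pairs(pairs, contexts, p, config)
  rc <- sum(res$allele == "REF"); ac <- sum(res$allele == "ALT")
  tibble(ref_count = rc, alt_count = ac,
         alt_fraction = if (rc + ac == 0) 0 else ac / (rc + ac),
         ambiguous_count = sum(res$allele == "AMBIGUOUS"))
}

#' Insert-probability-weighted spanning-pair counts
#'
#' For each pair whose mates flank the event, the observed reference-frame
#' fragment length `L` is weighted by its insert-size probability under each
#' allele: `P(L)` for the reference and `P(L + svlen)` for the alternate
#' (a fragment spanning a deletion shrinks, one spanning an insertion grows,
#' when mapped back to the allele frame). Each pair contributes its two
#' weights normalized to sum to one.
#'
#' @inheritParams count_alleles
#' @return Tibble with `span_ref`, `span_alt`.
#' @export
spanning_counts <- function(alignments, v, p) {
  ev <- event_interval(v)
  near <- region_reads(alignments, v$contig, ev["start"], ev["end"],
                       pad = 2L * insert_q99(p) + abs(v$svlen))
  pairs <- pair_table(alignments[alignments$qname %in% near$qname, ])
  if (nrow(pairs) > 0) {
    pairs <- pairs[pairs$mapped1 & pairs$mapped2, ]
  }
  if (nrow(pairs) == 0) return(tibble(span_ref = 0, span_alt = 0))
  end1 <- pairs$pos1 - 1L + pairs$span1
  end2 <- pairs$pos2 - 1L + pairs$span2
  left_end <- pmin(end1, end2)
  right_start <- pmax(pairs$pos1, pairs$pos2) - 1L
  frag_lo <- pmin(pairs$pos1, pairs$pos2) - 1L
  frag_hi <- pmax(end1, end2)
  spanning <- left_end <= ev["start"] & right_start >= ev["end"]
  if (!any(spanning)) return(tibble(span_ref = 0, span_alt = 0))
  L <- (frag_hi - frag_lo)[spanning]
  w_ref <- insert_probability(p, L)
  w_alt <- insert_probability(p, pmax(0, L + v$svlen))
  tot <- w_ref + w_alt
  tibble(span_ref = sum(w_ref / tot), span_alt = sum(w_alt / tot))
}

#' Soft-clip evidence near the breakpoints
#'
#' Counts primary alignments carrying a soft clip of at least `min_clip`
#' bases whose clip boundary lies within `clip_window` of either breakpoint.
#'
#' @inheritParams count_alleles
#' @param min_clip Minimum clip length (bp).
#' @param clip_window Window around each breakpoint (bp); default twice the
#'   read length.
#' @return Tibble with `clip_count`.
#' @export
clipped_counts <- function(alignments, v, p, min_clip = 4L,
                           clip_window = 2L * p$read_length) {
  ev <- event_interval(v)
  reads <- region_reads(alignments, v$contig, ev["start"], ev["end"],
                        pad = clip_window + 2L * p$read_length)
  reads <- reads[reads$mapped & grepl("S", reads$cigar), ]
  if (nrow(reads) == 0) return(tibble(clip_count = 0L))
  n <- 0L
  ops <- cigar_ops(reads$cigar)
  spans <- cigar_ref_span(reads$cigar)
  bps <- c(ev["start"], ev["end"])   # 0-based breakpoint coordinates
  for (i in seq_len(nrow(reads))) {
    o <- ops[[i]]
    k <- length(o$op)
    hit <- FALSE
    if (o$op[1] == "S" && o$len[1] >= min_clip) {
      hit <- hit || any(abs((reads$pos[i] - 1L) - bps) <= clip_window)
    }
    if (o$op[k] == "S" && o$len[k] >= min_clip) {
      hit <- hit || any(abs((reads$pos[i] - 1L + spans[i]) - bps) <= clip_window)
    }
    if (hit) n <- n + 1L
  }
  tibble(clip_count = n)
}

#' Depth fold-change features
#'
#' Mean per-base depth of the event region divided by the contig mean
#' coverage (DHFC), by the mean coverage of equal-GC bins (DHBFC), and by the
#' mean depth of the flanking regions (DHFFC). For deletions the event region
#' is the deleted span; insertions have no reference width, so the event
#' region is the breakpoint +/- one read length. Zero denominators yield NA
#' (excluded from standardization and imputed at prediction).
#'
#' @inheritParams count_alleles
#' @param genome Genome (for the event GC fraction).
#' @param flank_len Flank length (bp) for DHFFC.
#' @return Tibble with `dhfc`, `dhbfc`, `dhffc` and diagnostic
#'   `event_depth`.
#' @export
depth_features <- function(alignments, v, p, genome, flank_len = 1000L) {
  ev <- event_interval(v)
  if (v$svtype == "INS") {
    ev <- c(start = max(0L, ev[["start"]] - p$read_length),
            end = ev[["start"]] + p$read_length)
  }
  clen <- contig_length(genome, v$contig)
  ev["end"] <- min(ev[["end"]], clen)
  reads <- region_reads(alignments, v$contig, ev["start"] - flank_len,
                        ev["end"] + flank_len)
  depth_of <- function(s0, e0) {
    s0 <- max(0L, s0); e0 <- min(clen, e0)
    if (e0 <= s0) return(NA_real_)
    mean(interval_depth(reads, s0, e0))
  }
  event_depth <- depth_of(ev[["start"]], ev[["end"]])
  flank_depth <- mean(c(interval_depth(reads, ev[["start"]] - flank_len,
                                       ev[["start"]]),
                        interval_depth(reads, ev[["end"]],
                                       ev[["end"]] + flank_len)))
  chrom <- chrom_coverage(p, v$contig)
  gc <- gc_fraction(genome_substr(genome, v$contig, ev[["start"]],
                                  ev[["end"]]))
  gcc <- gc_coverage(p, gc)
  tibble(
    dhfc = if (is.na(chrom) || chrom <= 0) NA_real_ else event_depth / chrom,
    dhbfc = if (is.na(gcc) || gcc <= 0) NA_real_ else event_depth / gcc,
    dhffc = if (is.na(flank_depth) || flank_depth <= 0) NA_real_
            else event_depth / flank_depth,
    event_depth = event_depth
  )
}

# Per-base depth over [s0, e0) from aligned segments (clamped to >= 0).
# Coverage is computed in window coordinates so the cost scales with the
# window, not the contig.
interval_depth <- function(reads, s0, e0) {
  s0 <- max(0L, s0)
  w <- e0 - s0
  if (w <= 0) return(numeric(0))
  if (nrow(reads) == 0) return(rep(0, w))
  segs <- read_ref_segments(reads)
  start <- pmax(segs$start - s0, 1L)
  end <- pmin(segs$end - s0, w)
  keep <- start <= end & segs$end > s0 & segs$start <= e0
  if (!any(keep)) return(rep(0, w))
  cov <- IRanges::coverage(IRanges::IRanges(start[keep], end[keep]),
                           width = w)
  as.numeric(cov)
}

#' Extract the full feature vector for one variant
#'
#' Aggregates realigned allele counts, spanning-pair weights, clip counts,
#' and depth fold-changes. The identical code path serves actual and
#' simulated alignments, which is what makes the simulated training data
#' comparable with the observed evidence.
#'
#' @inheritParams count_alleles
#' @param genome Genome.
#' @param label Optional zygosity label (for simulated replicates).
#' @return One-row feature tibble.
#' @export
extract_features <- function(alignments, v, contexts, p, genome,
                             config = realign_config(), label = NA_character_) {
  dplyr::bind_cols(
    tibble(variant_id = v$variant_id, label = label),
    count_alleles(alignments, v, contexts, p, config = config),
    spanning_counts(alignments, v, p),
    clipped_counts(alignments, v, p, min_clip = config$min_clip),
    depth_features(alignments, v, p, genome, flank_len = config$depth_flank)
  )
}
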