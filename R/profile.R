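# Sample sequencing profile: the statistics that parameterize replicate
# simulation and depth-feature normalization.

#' Construct a sample profile
#'
#' @param read_length Modal read length in bp.
#' @param base_error_rate Per-base substitution error probability.
#' @param mean_coverage Genome-wide mean fold coverage.
#' @param insert_pmf Tibble with columns `len` (fragment length, bp) and
#'   `prob`, summing to 1.
#' @param per_chrom_coverage Named numeric vector, contig -> fold coverage.
#'   Defaults to `mean_coverage` for every contig queried.
#' @param per_gc_coverage Named numeric vector, GC-bin left edge (width 0.05)
#'   -> fold coverage. Defaults flat at `mean_coverage`.
#' @return A `sample_profile` object (list) with derived `insert_mean` and
#'   `insert_sd`.
#' @export
sample_profile <- function(read_length, base_error_rate, mean_coverage,
                           insert_pmf, per_chrom_coverage = NULL,
                           per_gc_coverage = NULL) {
  insert_pmf <- as_tibble(insert_pmf)
  stopifnot(all(c("len", "prob") %in% names(insert_pmf)),
            all(insert_pmf$prob >= 0))
  insert_pmf$prob <- insert_pmf$prob / sum(insert_pmf$prob)
  m <- sum(insert_pmf$len * insert_pmf$prob)
  s <- sqrt(sum((insert_pmf$len - m)^2 * insert_pmf$prob))
  structure(list(
    read_length = as.integer(read_length),
    base_error_rate = base_error_rate,
    mean_coverage = mean_coverage,
    per_chrom_coverage = per_chrom_coverage,
    per_gc_coverage = per_gc_coverage,
    insert_pmf = insert_pmf,
    insert_mean = m,
    insert_sd = s
  ), class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("<sample_profile>\n",
      " read length: ", x$read_length, " bp, error rate: ",
      signif(x$base_error_rate, 3), "\n",
      " mean coverage: ", signif(x$mean_coverage, 4), "x\n",
      " insert size: ", round(x$insert_mean, 1), " +/- ",
      round(x$insert_sd, 1), " bp (support ", min(x$insert_pmf$len), "-",
      max(x$insert_pmf$len), ")\n", sep = "")
  invisible(x)
}

#' @rdname sample_profile
#' @param x A `sample_profile`.
#' @param ... Unused.
#' @export
tidy.sample_profile <- function(x, ...) {
  x$insert_pmf
}

#' @rdname sample_profile
#' @export
glance.sample_profile <- function(x, ...) {
  tibble(read_length = x$read_length, base_error_rate = x$base_error_rate,
         mean_coverage = x$mean_coverage, insert_mean = x$insert_mean,
         insert_sd = x$insert_sd)
}

chrom_coverage <- function(p, contig) {
  if (!is.null(p$per_chrom_coverage) && contig %in% names(p$per_chrom_coverage)) {
    unname(p$per_chrom_coverage[[contig]])
  } else {
    p$mean_coverage
  }
}

gc_coverage <- function(p, frac) {
  if (is.na(frac)) return(p$mean_coverage)
  b <- as.character(gc_bin(frac))
  if (!is.null(p$per_gc_coverage) && b %in% names(p$per_gc_coverage)) {
    unname(p$per_gc_coverage[[b]])
  } else {
    p$mean_coverage
  }
}

# 99th percentile of the insert-size distribution: the default flanking
# distance within which reads are realigned.
insert_q99 <- function(p) {
  cdf <- cumsum(p$insert_pmf$prob)
  p$insert_pmf$len[which(cdf >= 0.99)[1]]
}

#' Smoothed insert-size probability
#'
#' Probability of a fragment length under the sample's insert-size
#' distribution with additive smoothing: `(count + eps) / (total + eps * K)`
#' over the truncated support of `K` distinct lengths, so lengths outside the
#' support return a small positive floor rather than zero.
#'
#' @param p A `sample_profile`.
#' @param fragment_length Integer vector of fragment lengths (bp, >= 0).
#' @param eps Smoothing constant.
#' @return Numeric vector of probabilities.
#' @export
insert_probability <- function(p, fragment_length, eps = 1e-6) {
  pmf <- p$insert_pmf
  K <- nrow(pmf)
  i <- match(round(fragment_length), pmf$len)
  pr <- ifelse(is.na(i), 0, pmf$prob[ifelse(is.na(i), 1L, i)])
  (pr + eps) / (1 + eps * K)
}

#' Estimate a sample profile from aligned reads
#'
#' Computes read length (modal), mean / per-contig / per-GC-bin coverage, and
#' the insert-size distribution from proper-pair template lengths. Template
#' lengths are truncated at the 0.05th and 99.95th percentiles before the PMF
#' is built. Per-GC coverage is measured over non-overlapping 100 bp windows
#' binned by GC fraction (bin width 0.05).
#'
#' @param alignments Alignment tibble (see [read_alignments()]) or a BAM path.
#' @param genome Named DNAStringSet or named character vector.
#' @param sample_fraction Fraction of windows/pairs to use (1 = all; smaller
#'   values subsample deterministically for speed).
#' @param base_error_rate Assumed per-base error rate (not estimable without
#'   a reference pileup; recorded as given).
#' @param window Window size in bp for GC-stratified coverage.
#' @return A `sample_profile`.
#' @export
estimate_profile <- function(alignments, genome, sample_fraction = 1,
                             base_error_rate = 0.001, window = 100L) {
  reads <- as_read_tbl(alignments)
  reads <- reads[reads$mapped, ]
  if (nrow(reads) == 0) stop("no mapped reads")
  read_length <- as.integer(names(sort(table(nchar(reads$seq)),
                                       decreasing = TRUE))[1])
  # Insert sizes from proper pairs: first mate with positive template length.
  tl <- reads$tlen[reads$mate == 1L & !is.na(reads$tlen) & reads$tlen > 0]
  if (length(tl) == 0) stop("no proper pairs with positive template length; ",
                            "paired-end data required")
  if (sample_fraction < 1) {
    tl <- tl[seq(1, length(tl), by = max(1L, round(1 / sample_fraction)))]
  }
  q <- quantile(tl, c(0.0005, 0.9995), type = 1)
  tl <- tl[tl >= q[1] & tl <= q[2]]
  pmf <- as_tibble(as.data.frame(table(len = tl), stringsAsFactors = FALSE))
  pmf$len <- as.integer(pmf$len)
  pmf$prob <- pmf$Freq / sum(pmf$Freq)
  pmf$Freq <- NULL
  g <- as_dnastringset(genome)
  lens <- setNames(Biostrings::width(g), names(g))
  # Per-base coverage per contig from aligned reference spans.
  spans <- reads %>%
    mutate(span = cigar_ref_span(.data$cigar)) %>%
    group_by(.data$contig) %>%
    summarise(bases = sum(.data$span), .groups = "drop")
  per_chrom <- setNames(rep(0, length(lens)), names(lens))
  per_chrom[spans$contig] <- spans$bases / lens[spans$contig]
  mean_cov <- sum(spans$bases) / sum(lens)
  # GC-stratified coverage over fixed windows.
  gc_tbl <- purrr::map_dfr(names(lens), function(ct) {
    starts <- seq(0L, lens[[ct]] - window, by = window)
    if (sample_fraction < 1) {
      starts <- starts[seq(1, length(starts),
                           by = max(1L, round(1 / sample_fraction)))]
    }
    seqs <- substring(as.character(g[[ct]]), starts + 1, starts + window)
    gcf <- (nchar(gsub("[^GCgc]", "", seqs))) /
      pmax(1L, nchar(gsub("[Nn]", "", seqs)))
    cov <- window_depth(reads[reads$contig == ct, ], starts, window)
    tibble(bin = gc_bin(gcf), cov = cov)
  })
  per_gc <- gc_tbl %>%
    group_by(.data$bin) %>%
    summarise(cov = mean(.data$cov), .groups = "drop")
  sample_profile(
    read_length = read_length, base_error_rate = base_error_rate,
    mean_coverage = mean_cov, insert_pmf = pmf,
    per_chrom_coverage = per_chrom,
    per_gc_coverage = setNames(per_gc$cov, as.character(per_gc$bin))
  )
}

# Mean per-base depth of fixed-width windows starting at `starts` (0-based).
window_depth <- function(reads, starts, window) {
  if (nrow(reads) == 0) return(rep(0, length(starts)))
  segs <- read_ref_segments(reads)
  cov <- IRanges::coverage(IRanges::IRanges(segs$start, segs$end))
  v <- as.numeric(cov)
  total <- numeric(length(v) + 1)
  csum <- c(0, cumsum(v))
  vapply(starts, function(s) {
    lo <- min(s + 1, length(csum))
    hi <- min(s + window + 1, length(csum))
    (csum[hi] - csum[lo]) / window
  }, numeric(1))
}

#' Load a sample profile from a key=value metrics file
#'
#' Reads plain-text `KEY=VALUE` lines with keys `READ_LENGTH`, `INSERT_MEAN`,
#' `INSERT_SD`, `MEAN_COVERAGE`, and optional `ERROR_RATE`. The insert-size
#' PMF is a discretized normal truncated at mean +/- 5 SD and renormalized
#' (a point mass when SD = 0).
#'
#' @param path Metrics file path.
#' @return A `sample_profile`.
#' @export
load_profile <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- toupper(trimws(vapply(kv, `[`, "", 1)))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  get <- function(key, required = TRUE, default = NA) {
    i <- match(key, keys)
    if (is.na(i)) {
      if (required) stop("metrics file missing mandatory key: ", key)
      return(default)
    }
    vals[i]
  }
  m <- get("INSERT_MEAN"); s <- get("INSERT_SD")
  pmf <- discretized_normal_pmf(m, s)
  sample_profile(
    read_length = get("READ_LENGTH"),
    base_error_rate = get("ERROR_RATE", required = FALSE, default = 0.001),
    mean_coverage = get("MEAN_COVERAGE"),
    insert_pmf = pmf
  )
}

discretized_normal_pmf <- function(mean, sd) {
  if (sd <= 0) return(tibble(len = as.integer(round(mean)), prob = 1))
  lens <- seq(max(0L, floor(mean - 5 * sd)), ceiling(mean + 5 * sd))
  pr <- dnorm(lens, mean, sd)
  tibble(len = as.integer(lens), prob = pr / sum(pr))
}
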