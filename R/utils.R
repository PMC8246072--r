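# Internal helpers shared across modules.

# Deterministic per-task seed derivation. Mixes a global seed with small
# integer coordinates (variant index, zygosity code, replicate index) into a
# 31-bit seed so independent tasks get independent, reproducible streams.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    # multiplier kept small so h * 69069 stays exactly representable in a
    # double (< 2^53); larger multipliers silently drop the low-order terms
    h <- (h * 69069 + as.numeric(p) + 12345) %% 2147483647
  }
  as.integer(h)
}

zygosity_levels <- function() c("HOM_REF", "HET", "HOM_ALT")

gt_levels <- function() c("0/0", "0/1", "1/1", "./.")

zygosity_to_gt <- function(z) {
  unname(c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1")[z])
}

gt_to_zygosity <- function(gt) {
  unname(c(`0/0` = "HOM_REF", `0/1` = "HET", `1/0` = "HET",
           `1/1` = "HOM_ALT")[gt])
}

#' Phred-scaled genotype quality from class probabilities
#'
#' GQ = min(99, floor(-10 log10(max(1 - max(p), 1e-10)))), the Phred-scaled
#' probability that the most likely genotype is wrong, floored to an integer
#' and capped at 99 for VCF compatibility.
#'
#' @param probs Numeric vector (or matrix with one row per call) of class
#'   probabilities summing to 1.
#' @return Integer GQ in 0..99.
#' @export
phred_gq <- function(probs) {
  if (is.matrix(probs)) pmax <- apply(probs, 1, max) else pmax <- max(probs)
  err <- pmax(1 - pmax, 1e-10)
  as.integer(pmin(99, floor(-10 * log10(err))))
}

# Reverse complement of a character vector of DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

gc_fraction <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- sum(v != "N")
  if (n == 0) return(NA_real_)
  sum(v %in% c("G", "C")) / n
}

gc_bin <- function(frac, width = 0.05) {
  # 20 bins of width 0.05 over [0, 1]; bin label is the left edge.
  b <- pmin(floor(frac / width), 1 / width - 1) * width
  round(b, 10)
}

# Empty alignment tibble with the canonical column set (one row per read).
empty_reads <- function() {
  tibble(
    qname = character(), mate = integer(), contig = character(),
    pos = integer(), strand = character(), cigar = character(),
    seq = character(), mapq = integer(), mpos = integer(), tlen = integer(),
    hap = integer(), hap_pos = integer(), mapped = logical()
  )
}

# Parse CIGAR strings into per-read operation tables (lengths + ops).
cigar_ops <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  Map(function(l, o) list(len = as.integer(l), op = o), lens, ops)
}

# Reference span consumed by a CIGAR (M/D/N/=/X ops). Vectorized fast path
# for the dominant single-M case.
cigar_ref_span <- function(cigar) {
  out <- integer(length(cigar))
  cigar[is.na(cigar)] <- "0M"
  simple <- grepl("^[0-9]+M$", cigar)
  out[simple] <- as.integer(sub("M", "", cigar[simple], fixed = TRUE))
  rest <- which(!simple)
  if (length(rest) > 0) {
    out[rest] <- vapply(cigar_ops(cigar[rest]), function(x) {
      sum(x$len[x$op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
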