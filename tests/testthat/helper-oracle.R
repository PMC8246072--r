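# Independent oracle for pair realignment scoring: Biostrings
# pairwiseAlignment with the same scoring constants (read-global /
# context-local, gap of length k costs open + k * extend).
oracle_score <- function(read, ctx, e, gap_open = 6, gap_extend = 1) {
  m <- Biostrings::nucleotideSubstitutionMatrix(
    match = log10(1 - e), mismatch = log10(e / 3), baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(ctx),
    type = "global-local", substitutionMatrix = m,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(score = Biostrings::score(aln),
       start = Biostrings::start(Biostrings::subject(aln)) - 1L,
       end = Biostrings::end(Biostrings::subject(aln)))
}

oracle_assign <- function(pairs, ctx, p, threshold = 1) {
  e <- max(p$base_error_rate, 1e-4)
  score_pair <- function(s1, s2, context) {
    a1 <- oracle_score(s1, context, e)
    a2 <- oracle_score(s2, context, e)
    frag <- max(a1$end, a2$end) - min(a1$start, a2$start)
    a1$score + a2$score + log10(insert_probability(p, frag))
  }
  vapply(seq_len(nrow(pairs)), function(i) {
    d <- score_pair(pairs$seq1[i], pairs$seq2[i], ctx$alt_context) -
      score_pair(pairs$seq1[i], pairs$seq2[i], ctx$ref_context)
    if (d > threshold) "ALT" else if (d < -threshold) "REF" else "AMBIGUOUS"
  }, "")
}

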