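test_that("degenerate identical contexts leave every pair ambiguous", {
  p <- toy_profile()
  ctxseq <- rand_seq(800, 71)
  ctx <- list(ref_context = ctxseq, alt_context = ctxseq)
  pairs <- tibble::tibble(
    seq1 = substring(ctxseq, c(1, 101, 301), c(100, 200, 400)),
    seq2 = substring(ctxseq, c(301, 401, 601), c(400, 500, 700)))
  out <- realign_pairs(pairs, ctx, p)
  expect_true(all(out$allele == "AMBIGUOUS"))
  expect_equal(out$score_ref, out$score_alt)
})

test_that("breakpoint-straddling pairs are assigned to the alt allele", {
  spec <- tiny_spec("DEL", 300L, "HOM_ALT", seed = 73)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  ctx <- allele_contexts(v, smp$genome, 600L)
  # error-free pair drawn from the alt context, read1 straddling the
  # breakpoint (alt-context coordinate 600 is the padding base)
  pairs <- tibble::tibble(
    seq1 = substr(ctx$alt_context, 551, 650),
    seq2 = substr(ctx$alt_context, 801, 900))
  out <- realign_pairs(pairs, ctx, toy_profile())
  expect_equal(out$allele, "ALT")
  # and the mirrored ref-only pair supports the reference
  pairs_ref <- tibble::tibble(
    seq1 = substr(ctx$ref_context, 551, 650),
    seq2 = substr(ctx$ref_context, 801, 900))
  out_ref <- realign_pairs(pairs_ref, ctx, toy_profile())
  expect_equal(out_ref$allele, "REF")
})

test_that("realignment agrees with the dynamic-programming oracle", {
  set.seed(75)
  p <- toy_profile()
  n_ok <- 0; n <- 60
  spec <- tiny_spec("DEL", 150L, "HET", seed = 77)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  ctx <- allele_contexts(v, smp$genome, 400L)
  hap <- list(ctx$ref_context, ctx$alt_context)
  pairs <- purrr::map_dfr(1:n, function(i) {
    h <- hap[[1 + i %% 2]]
    flen <- min(sample(p$insert_pmf$len, 1, prob = p$insert_pmf$prob),
                nchar(h))
    s <- sample.int(nchar(h) - flen + 1, 1) - 1
    tibble::tibble(seq1 = substr(h, s + 1, s + 100),
                   seq2 = substr(h, s + flen - 99, s + flen))
  })
  got <- realign_pairs(pairs, ctx, p)$allele
  want <- oracle_assign(pairs, ctx, p)
  expect_gte(mean(got == want), 0.99)
})

test_that("count_alleles handles empty input and hom-ref data", {
  spec <- tiny_spec("DEL", 500L, "HOM_REF", seed = 79)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  p <- smp$profile
  ctx <- allele_contexts(v, smp$genome, svgenotyper:::compute_flank(p))
  out0 <- count_alleles(svgenotyper:::empty_reads(), v, ctx, p)
  expect_equal(unlist(out0),
               c(ref_count = 0, alt_count = 0, alt_fraction = 0,
                 ambiguous_count = 0))
  out <- count_alleles(smp$reads, v, ctx, p)
  expect_gt(out$ref_count, 0)
  expect_lt(out$alt_fraction, 0.05)
})

test_that("spanning counts weight pairs by insert probability", {
  # 100 bp deletion: a flanking pair with reference-frame fragment length
  # at the insert mean supports the reference; one whose implied alt-frame
  # length hits the mean (L = mean + 100) supports the deletion
  p <- sample_profile(100, 0.001, 30,
                      svgenotyper:::discretized_normal_pmf(350, 10))
  g <- Biostrings::DNAStringSet(c(chr1 = rand_seq(3000, 81)))
  ref <- svgenotyper:::genome_substr(g, "chr1", 999, 1100)
  v <- sv_tibble("d", "chr1", 1000, ref, substr(ref, 1, 1))
  mk_pair <- function(start1, flen) {
    dplyr::bind_rows(
      tibble::tibble(qname = "q1", mate = 1L, contig = "chr1",
                     pos = start1, strand = "+", cigar = "100M",
                     seq = "A", mapq = 60L, mpos = start1 + flen - 100L,
                     tlen = flen, hap = NA_integer_,
                     hap_pos = NA_integer_, mapped = TRUE),
      tibble::tibble(qname = "q1", mate = 2L, contig = "chr1",
                     pos = start1 + flen - 100L, strand = "-",
                     cigar = "100M", seq = "A", mapq = 60L, mpos = start1,
                     tlen = -flen, hap = NA_integer_,
                     hap_pos = NA_integer_, mapped = TRUE))
  }
  # mates flank the deleted span; L = 350 is the insert mode
  out <- spanning_counts(mk_pair(898L, 350L), v, p)
  expect_gt(out$span_ref, 0.9)
  expect_lt(out$span_alt, 0.1)
  # fragment length consistent with the deletion (L = 350 + 100)
  out_alt <- spanning_counts(mk_pair(898L, 450L), v, p)
  expect_gt(out_alt$span_alt, 0.9)
  # no flanking pairs
  out0 <- spanning_counts(svgenotyper:::empty_reads(), v, p)
  expect_equal(unlist(out0), c(span_ref = 0, span_alt = 0))
})

test_that("clip counting reacts to clip-mode alignments and thresholds", {
  spec <- tiny_spec("DEL", 500L, "HOM_ALT", seed = 83)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  p0 <- sample_profile(100, 0, 30, smp$profile$insert_pmf)
  haps <- genotype_haplotypes(v, smp$genome, "HOM_ALT", 900L)
  rep <- simulate_pairs(haps, p0, seed = 3)
  gapped <- align_replicate(rep)
  clipped <- align_replicate(rep, clip_mode = TRUE)
  expect_equal(clipped_counts(gapped, v, p0)$clip_count, 0L)
  expect_gt(clipped_counts(clipped, v, p0)$clip_count, 0L)
  expect_equal(clipped_counts(clipped, v, p0, min_clip = 150L)$clip_count, 0L)
  # error-free hom-ref replicate has no clipped reads at all
  hr <- align_replicate(simulate_pairs(
    genotype_haplotypes(v, smp$genome, "HOM_REF", 900L), p0, seed = 4))
  expect_equal(clipped_counts(hr, v, p0)$clip_count, 0L)
})

test_that("depth fold-changes follow their definitions", {
  g <- Biostrings::DNAStringSet(c(chr1 = rand_seq(6000, 85)))
  p <- toy_profile()
  ref <- svgenotyper:::genome_substr(g, "chr1", 2999, 3300)
  v <- sv_tibble("d", "chr1", 3000, ref, substr(ref, 1, 1))
  mk_cover <- function(s0, e0, depth, prefix) {
    n_reads <- round(depth * (e0 - s0) / 100)
    if (n_reads <= 0) return(NULL)
    starts <- as.integer(seq(s0, e0 - 100L, length.out = n_reads))
    tibble::tibble(qname = paste0(prefix, seq_len(n_reads)), mate = 1L,
                   contig = "chr1", pos = starts + 1L, strand = "+",
                   cigar = "100M", seq = "A", mapq = 60L,
                   mpos = NA_integer_, tlen = NA_integer_,
                   hap = NA_integer_, hap_pos = NA_integer_, mapped = TRUE)
  }
  # event depth ~15, flank depth ~30
  reads <- dplyr::bind_rows(mk_cover(2000L, 3000L, 30, "l"),
                            mk_cover(3000L, 3300L, 15, "e"),
                            mk_cover(3300L, 4300L, 30, "r"))
  out <- depth_features(reads, v, p, g)
  expect_equal(out$dhffc, 0.5, tolerance = 0.1)
  expect_equal(out$dhfc, 15 / 30, tolerance = 0.1)
  # empty event region under a hom-alt deletion gives dhffc ~ 0
  reads2 <- dplyr::bind_rows(mk_cover(2000L, 3000L, 30, "l"),
                             mk_cover(3300L, 4300L, 30, "r"))
  out2 <- depth_features(reads2, v, p, g)
  expect_lt(out2$dhffc, 0.05)
  # no reads at all: fold-changes against profile coverage are 0, the
  # flank-normalized one is undefined
  out3 <- depth_features(svgenotyper:::empty_reads(), v, p, g)
  expect_equal(out3$dhfc, 0)
  expect_true(is.na(out3$dhffc))
})

test_that("uniform-coverage data yield fold-changes near one", {
  # single-site depth ratios at 30x fluctuate by ~10%, so average over
  # five hom-ref sites before applying the 0.15 band
  spec <- fixture_spec(
    contigs = c(chrA = 80000L),
    variants = tibble::tibble(svtype = "DEL", size = rep(400L, 5),
                              zygosity = "HOM_REF", context = "unique",
                              shift = 0L),
    seed = 87)
  smp <- cached_sample(spec)
  pe <- estimate_profile(smp$reads, smp$genome)
  out <- purrr::map_dfr(seq_len(5), function(i) {
    depth_features(smp$reads, smp$truth[i, ], pe, smp$genome)
  })
  expect_true(all(abs(colMeans(out[, c("dhfc", "dhbfc", "dhffc")]) - 1)
                  < 0.15))
})

test_that("extract_features is order-invariant and labels rows", {
  spec <- tiny_spec("INS", 150L, "HET", seed = 89)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  p <- smp$profile
  ctx <- allele_contexts(v, smp$genome, svgenotyper:::compute_flank(p))
  fv1 <- extract_features(smp$reads, v, ctx, p, smp$genome)
  set.seed(1)
  shuffled <- smp$reads[sample.int(nrow(smp$reads)), ]
  fv2 <- extract_features(shuffled, v, ctx, p, smp$genome)
  expect_equal(fv1, fv2)
  expect_true(is.na(fv1$label))
  fv3 <- extract_features(smp$reads, v, ctx, p, smp$genome, label = "HET")
  expect_equal(fv3$label, "HET")
  expect_true(all(feature_names() %in% names(fv1)))
})

test_that("class-conditional feature means are ordered across zygosities", {
  spec <- tiny_spec("DEL", 400L, "HET", seed = 91)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  p <- smp$profile
  flank <- svgenotyper:::compute_flank(p)
  rows <- training_features(v, smp$reads, smp$genome, p, 5L, flank,
                            seed = 5, hom_ref_sim = TRUE)
  m <- rows %>% dplyr::group_by(label) %>%
    dplyr::summarise(af = mean(alt_fraction), dh = mean(dhffc))
  af <- setNames(m$af, m$label); dh <- setNames(m$dh, m$label)
  expect_true(af[["HOM_REF"]] < af[["HET"]] && af[["HET"]] < af[["HOM_ALT"]])
  expect_true(dh[["HOM_REF"]] > dh[["HET"]] && dh[["HET"]] > dh[["HOM_ALT"]])
})
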