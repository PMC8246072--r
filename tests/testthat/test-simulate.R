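test_that("genotype_haplotypes encodes zygosity correctly", {
  spec <- tiny_spec("DEL", 100L, "HET", seed = 51)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  hr <- genotype_haplotypes(v, smp$genome, "HOM_REF", 300L)
  expect_identical(hr[[1]]$seq, hr[[2]]$seq)
  expect_identical(hr[[1]]$seq,
                   svgenotyper:::genome_substr(smp$genome, v$contig,
                                               v$pos - 1L - 300L,
                                               v$end + 300L))
  het <- genotype_haplotypes(v, smp$genome, "HET", 300L)
  expect_equal(nchar(het[[1]]$seq) - nchar(het[[2]]$seq), 100L)
  # HOM_ALT insertion carries the insert exactly once at the breakpoint
  spec_i <- tiny_spec("INS", 80L, "HOM_ALT", seed = 53)
  smp_i <- cached_sample(spec_i)
  vi <- smp_i$truth[1, ]
  ha <- genotype_haplotypes(vi, smp_i$genome, "HOM_ALT", 300L)
  ins <- substr(vi$alt, 2, nchar(vi$alt))
  for (h in 1:2) {
    hits <- gregexpr(ins, ha[[h]]$seq, fixed = TRUE)[[1]]
    expect_equal(length(hits), 1L)
    expect_equal(as.integer(hits), 302L)
  }
})

test_that("error-free simulated reads are exact haplotype substrings", {
  spec <- tiny_spec("DEL", 200L, "HOM_ALT", seed = 55)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  p0 <- sample_profile(100, 0, 30, smp$profile$insert_pmf)
  haps <- genotype_haplotypes(v, smp$genome, "HOM_ALT", 800L)
  rep <- simulate_pairs(haps, p0, seed = 9)
  ok <- vapply(seq_len(nrow(rep)), function(i) {
    substr(haps[[rep$hap[i]]]$seq, rep$hap_pos[i] + 1,
           rep$hap_pos[i] + 100) == rep$seq[i]
  }, logical(1))
  expect_true(all(ok))
})

test_that("pair counts follow the coverage model within Poisson noise", {
  p <- toy_profile()
  hap <- list(seq = rand_seq(2000, 57), map = tibble::tibble(
    hap_start = 0L, len = 2000L, ref_start = 0L), contig = "chr1")
  n_pairs <- vapply(1:20, function(s) {
    rep <- simulate_pairs(list(hap), p, seed = s, coverage = 30)
    nrow(rep) / 2
  }, numeric(1))
  expected <- 30 * (2000 - p$insert_mean) / (2 * 100)
  expect_lt(abs(mean(n_pairs) - expected), 3 * sqrt(expected))
})

test_that("simulation is byte-identical under a fixed seed", {
  spec <- tiny_spec("INS", 120L, "HET", seed = 59)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  r1 <- simulate_replicate(v, smp$genome, "HET", smp$profile, 700L, seed = 77)
  r2 <- simulate_replicate(v, smp$genome, "HET", smp$profile, 700L, seed = 77)
  expect_identical(r1, r2)
  r3 <- simulate_replicate(v, smp$genome, "HET", smp$profile, 700L, seed = 78)
  expect_false(identical(r1, r3))
})

test_that("the built-in aligner maps flank and breakpoint reads correctly", {
  spec <- tiny_spec("DEL", 100L, "HOM_ALT", seed = 61)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  p0 <- sample_profile(100, 0, 40, smp$profile$insert_pmf)
  haps <- genotype_haplotypes(v, smp$genome, "HOM_ALT", 800L)
  rep <- simulate_pairs(haps, p0, seed = 13)
  aligned <- align_replicate(rep)
  ctx_start0 <- v$pos - 1L - 800L
  # reads fully in the left flank: ungapped match at the correct offset
  left <- aligned[aligned$hap_pos + 100L <= 800L, ]
  expect_gt(nrow(left), 0)
  expect_true(all(left$cigar == "100M"))
  expect_equal(left$pos, ctx_start0 + left$hap_pos + 1L)
  # reads spanning the deletion breakpoint carry a 100 bp deletion element
  span <- aligned[aligned$hap_pos + 100L > 810L & aligned$hap_pos < 791L, ]
  expect_gt(nrow(span), 0)
  expect_true(all(grepl("100D", span$cigar)))
  # error-free aligned bases map back to the reference bases (truth-tag
  # oracle): ungapped reads equal the reference substring
  flankish <- aligned[aligned$cigar == "100M", ]
  idx <- head(seq_len(nrow(flankish)), 50)
  ok <- vapply(idx, function(i) {
    svgenotyper:::genome_substr(smp$genome, v$contig,
                                flankish$pos[i] - 1L,
                                flankish$pos[i] + 99L) == flankish$seq[i]
  }, logical(1))
  expect_true(all(ok))
})

test_that("reads inside a long insertion are unmapped or soft-clipped", {
  spec <- tiny_spec("INS", 300L, "HOM_ALT", seed = 63)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  p0 <- sample_profile(100, 0, 40, smp$profile$insert_pmf)
  haps <- genotype_haplotypes(v, smp$genome, "HOM_ALT", 800L)
  rep <- simulate_pairs(haps, p0, seed = 15)
  aligned <- align_replicate(rep)
  # novel insert occupies haplotype [801, 1101); fully-interior reads have
  # no reference position
  interior <- aligned[aligned$hap_pos >= 801L & aligned$hap_pos + 100L <= 1101L, ]
  expect_gt(nrow(interior), 0)
  expect_true(all(!interior$mapped))
  # reads overlapping the insert edge are soft-clipped or gapped
  edge <- aligned[aligned$mapped & aligned$hap_pos < 801L &
                    aligned$hap_pos + 100L > 801L, ]
  expect_gt(nrow(edge), 0)
  expect_true(all(grepl("[SI]", edge$cigar)))
})

test_that("null variants are size-matched and respect the partition", {
  spec <- fixture_spec(contigs = c(chrA = 30000L, chrB = 30000L,
                                   chrX = 30000L),
                       variants = tibble::tibble(
                         svtype = "DEL", size = 150L, zygosity = "HET",
                         context = "unique", shift = 0L), seed = 65)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  set.seed(1)
  nv <- sample_null_variant(v, smp$genome,
                            contig_partition = c("chrA", "chrB"))
  expect_equal(nv$svtype, v$svtype)
  expect_equal(abs(nv$svlen), abs(v$svlen))
  expect_true(nv$contig %in% c("chrA", "chrB"))
  # sampling is ~uniform over two equal contigs
  set.seed(2)
  draws <- vapply(1:600, function(i) {
    sample_null_variant(v, smp$genome,
                        contig_partition = c("chrA", "chrB"))$contig
  }, "")
  frac <- mean(draws == "chrA")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 600) + 0.01)
})

test_that("training replicate generation is deterministic and structured", {
  cfg <- classifier_config()
  expect_equal(cfg$replicates_variant, 100L)
  expect_equal(cfg$replicates_single, 1L)
  spec <- tiny_spec("DEL", 150L, "HET", seed = 67)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  reps <- generate_training_replicates(v, smp$genome, smp$profile,
                                       n_per_zygosity = 2L, flank = 700L,
                                       seed = 3)
  expect_named(reps, c("HET", "HOM_ALT"))
  expect_length(reps$HET, 2L)
  flank <- svgenotyper:::compute_flank(smp$profile)
  t1 <- training_features(v, smp$reads, smp$genome, smp$profile, 2L, flank,
                          seed = 3)
  t2 <- training_features(v, smp$reads, smp$genome, smp$profile, 2L, flank,
                          seed = 3)
  expect_identical(t1, t2)
  expect_equal(unname(c(sum(t1$label == "HOM_REF"), sum(t1$label == "HET"),
                        sum(t1$label == "HOM_ALT"))), c(2L, 2L, 2L))
})
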