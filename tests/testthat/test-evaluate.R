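# Build small call/truth sets on a shared fake genome coordinate frame.
mk_set <- function(pos, sizes, gt = NULL, svtype = "DEL", contig = "chr1",
                   seed = 201, prefix = "v") {
  seqs <- vapply(seq_along(pos), function(i) {
    if (svtype[[min(i, length(svtype))]] == "DEL") {
      paste0("T", rand_seq(sizes[i], seed + i))
    } else "T"
  }, "")
  alts <- vapply(seq_along(pos), function(i) {
    if (svtype[[min(i, length(svtype))]] == "DEL") "T"
    else paste0("T", rand_seq(sizes[i], seed + i))
  }, "")
  out <- sv_tibble(paste0(prefix, seq_along(pos)), contig, pos, seqs, alts)
  if (!is.null(gt)) out$gt <- gt
  out
}

test_that("identical variants match with zero offset", {
  truth <- mk_set(c(1000, 8000), c(100, 200), gt = c("0/1", "1/1"))
  calls <- mk_set(c(1000, 8000), c(100, 200), gt = c("0/1", "1/1"),
                  prefix = "c")
  m <- match_variants(calls, truth)
  expect_equal(nrow(m$pairs), 2L)
  expect_true(all(m$pairs$max_offset == 0))
  expect_equal(nrow(m$unmatched_calls), 0L)
})

test_that("size similarity is thresholded exactly", {
  truth <- mk_set(1000, 100, seed = 211)
  for (case in list(c(69, FALSE), c(70, TRUE), c(71, TRUE))) {
    calls <- mk_set(1000, case[1], seed = 211, prefix = "c")
    # identical deleted prefix so sequence similarity stays high
    calls$ref <- substr(truth$ref, 1, case[1] + 1)
    calls$end <- calls$pos + nchar(calls$ref) - 1L
    calls$svlen <- -as.integer(case[1])
    m <- match_variants(calls, truth, size_sim = 0.70)
    expect_equal(nrow(m$pairs) == 1L, as.logical(case[2]),
                 label = paste("size", case[1]))
  }
  # sizes 100 vs 60: similarity 0.6 < 0.7, unmatched
  calls60 <- mk_set(1000, 60, seed = 211, prefix = "c")
  calls60$ref <- substr(truth$ref, 1, 61)
  calls60$end <- calls60$pos + 60L
  calls60$svlen <- -60L
  expect_equal(nrow(match_variants(calls60, truth)$pairs), 0L)
})

test_that("relaxing the size threshold is monotone in matches", {
  truth <- mk_set(c(1000, 8000, 16000), c(100, 150, 200), seed = 221)
  calls <- mk_set(c(1020, 8010, 16005), c(40, 148, 90), seed = 231,
                  prefix = "c")
  # give call 2 the same deleted sequence prefix as its truth partner
  calls$ref[2] <- substr(truth$ref[2], 1, 149)
  calls$end[2] <- calls$pos[2] + 148L
  n_strict <- nrow(match_variants(calls, truth, size_sim = 0.7,
                                  seq_sim = 0.3)$pairs)
  n_relaxed <- nrow(match_variants(calls, truth, size_sim = 0.3,
                                   seq_sim = 0.3)$pairs)
  expect_gt(n_relaxed, n_strict)
})

test_that("matching respects contig, svtype and window", {
  truth <- mk_set(1000, 100)
  far <- mk_set(4000, 100, prefix = "c")      # outside 2 kb window
  far$ref <- truth$ref; far$end <- far$pos + 100L
  expect_equal(nrow(match_variants(far, truth)$pairs), 0L)
  near <- mk_set(2500, 100, prefix = "c")
  near$ref <- truth$ref; near$end <- near$pos + 100L
  expect_equal(nrow(match_variants(near, truth)$pairs), 1L)
  ins <- mk_set(1000, 100, svtype = "INS", prefix = "c")
  expect_equal(nrow(match_variants(ins, truth)$pairs), 0L)
})

test_that("concordance metrics match hand computation", {
  truth <- mk_set(seq(1000, by = 6000, length.out = 6), rep(100, 6),
                  gt = c("0/0", "0/1", "0/1", "1/1", "1/1", "0/1"))
  calls <- mk_set(seq(1000, by = 6000, length.out = 6), rep(100, 6),
                  gt = c("0/0", "0/1", "1/1", "1/1", "0/0", "./."),
                  prefix = "c")
  for (i in 1:6) calls$ref[i] <- truth$ref[i]
  m <- match_variants(calls, truth)
  expect_equal(nrow(m$pairs), 6L)
  rep <- concordance(m)
  # exact matches: v1 (0/0), v2 (0/1), v4 (1/1) -> 3/6
  expect_equal(rep$genotype_concordance, 3 / 6)
  # non-ref collapse adds v3 (0/1 vs 1/1) -> 4/6
  expect_equal(rep$nonref_concordance, 4 / 6)
  # binarized: TP = v2,v3,v4; FP = 0; FN = v5 (called 0/0), v6 (./.)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 3 / 5)
  expect_equal(rep$f1, 2 * 1 * 0.6 / 1.6)
  expect_equal(sum(rep$confusion), 6)
  expect_equal(unname(rep$confusion["0/1", "1/1"]), 1)
  # excluding no-calls shrinks the denominator
  rep2 <- concordance(m, exclude_nocall = TRUE)
  expect_equal(rep2$genotype_concordance, 3 / 5)
})

test_that("concordance equals a brute-force confusion computation", {
  set.seed(241)
  for (rep_i in 1:5) {
    n <- 12
    tg <- sample(c("0/0", "0/1", "1/1"), n, replace = TRUE)
    cg <- sample(c("0/0", "0/1", "1/1", "./."), n, replace = TRUE)
    truth <- mk_set(seq(1000, by = 5000, length.out = n), rep(80, n),
                    gt = tg, seed = 250 + rep_i)
    calls <- truth
    calls$variant_id <- paste0("c", seq_len(n))
    calls$gt <- cg
    m <- match_variants(calls, truth)
    rep <- concordance(m)
    expect_equal(rep$genotype_concordance, mean(cg == tg))
    collapse <- function(g) ifelse(g %in% c("0/1", "1/1"), "N", g)
    expect_equal(rep$nonref_concordance, mean(collapse(cg) == collapse(tg)))
  }
})

test_that("Mendelian-error flags match the exhaustive transmission oracle", {
  gts <- c("0/0", "0/1", "1/1")
  combos <- expand.grid(child = gts, mother = gts, father = gts,
                        stringsAsFactors = FALSE)
  # oracle: enumerate transmitted allele pairs
  oracle <- vapply(seq_len(nrow(combos)), function(i) {
    al <- strsplit(unlist(combos[i, ]), "/")
    child_sorted <- sort(al$child)
    ok <- FALSE
    for (a in al$mother) for (b in al$father) {
      if (identical(sort(c(a, b)), child_sorted)) ok <- TRUE
    }
    !ok
  }, logical(1))
  rep <- mendelian(tibble::as_tibble(combos))
  expect_identical(rep$sites$me, oracle)
  expect_equal(rep$n_sites, 27L)
  expect_equal(rep$mer, sum(oracle) / 27)
  # stated category examples
  one <- mendelian(tibble::tibble(child = "0/1", mother = "0/0",
                                  father = "0/0"))
  expect_equal(one$het_denovo, 1L)
  other <- mendelian(tibble::tibble(child = "1/1", mother = "0/0",
                                    father = "0/1"))
  expect_equal(other$other, 1L)
  expect_equal(other$het_denovo + other$hom_denovo, 0L)
})

test_that("Mendelian analysis respects missing genotypes and GQ filters", {
  trio <- tibble::tibble(
    child = c("0/1", "0/1", "./."),
    mother = c("0/0", "0/0", "0/0"),
    father = c("0/0", "0/0", "0/0"),
    child_gq = c(50, 3, 60), mother_gq = c(40, 99, 60),
    father_gq = c(40, 99, 60))
  rep <- mendelian(trio)
  expect_equal(rep$n_sites, 2L)       # ./. site excluded
  expect_equal(rep$n_errors, 2L)
  rep10 <- mendelian(trio, min_gq = 10)
  expect_equal(rep10$n_sites, 1L)     # low-GQ site filtered
  expect_equal(rep10$n_errors, 1L)
})

test_that("offset-stratified concordance bins pairs correctly", {
  truth <- mk_set(c(1000, 8000, 16000), rep(100, 3),
                  gt = c("0/1", "0/1", "0/1"))
  calls <- mk_set(c(1000, 8005, 16060), rep(100, 3),
                  gt = c("0/1", "0/1", "1/1"), prefix = "c")
  for (i in 1:3) calls$ref[i] <- truth$ref[i]
  m <- match_variants(calls, truth)
  expect_equal(sort(m$pairs$max_offset), c(0, 5, 60))
  out <- offset_stratified_concordance(m, bins = c(0, 10))
  expect_equal(nrow(out), 2L)
  expect_equal(out$n_pairs, c(2L, 1L))
  expect_equal(out$genotype_concordance, c(1, 0))
  # degenerate: all offsets zero reproduces the plain concordance
  m0 <- match_variants(truth, truth)
  out0 <- offset_stratified_concordance(m0, bins = c(0, 10))
  expect_equal(nrow(out0), 1L)
  expect_equal(out0$genotype_concordance,
               concordance(m0)$genotype_concordance)
})
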