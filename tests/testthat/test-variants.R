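test_that("sv_tibble enforces allele and length invariants", {
  v <- sv_tibble("a", "chr1", 100, "TACGT", "T")
  expect_equal(v$svtype, "DEL")
  expect_equal(v$svlen, -4L)
  expect_equal(v$end, 104L)
  vi <- sv_tibble("b", "chr1", 100, "T", "TAAAA")
  expect_equal(vi$svtype, "INS")
  expect_equal(vi$svlen, 4L)
  expect_error(sv_tibble("c", "chr1", 100, "A", "G"),
               "non-zero|padding")
  expect_error(sv_tibble("d", "chr1", 100, "ACGT", "GCGT"), "padding")
  expect_error(sv_tibble("e", "chr1", 100, "", "A"), "non-empty")
})

test_that("parse_sv_vcf applies the size window", {
  seq30 <- rand_seq(30, 1); seq100 <- rand_seq(100, 2)
  lines <- c(
    paste("chr1", 100, "small", paste0("T", seq30), "T", ".", "PASS",
          "SVTYPE=DEL", "GT", "0/1", sep = "\t"),
    paste("chr1", 5000, "ok", paste0("G", seq100), "G", ".", "PASS",
          "SVTYPE=DEL", "GT", "0/1", sep = "\t"),
    paste("chr1", 9000, "huge", "A",
          paste0("A", rand_seq(50, 3)), ".", "PASS", "SVTYPE=INS", "GT",
          "1/1", sep = "\t"))
  # make the third record exceed the maximum by shrinking size_max instead
  # of materializing a 20 Mb allele
  out <- suppressWarnings(parse_sv_vcf(write_test_vcf(lines),
                                       size_min = 50, size_max = 45))
  expect_equal(nrow(out), 0L)
  out <- suppressWarnings(parse_sv_vcf(write_test_vcf(lines)))
  expect_equal(out$variant_id, c("ok", "huge"))
  expect_equal(out$gt, c("0/1", "1/1"))
})

test_that("parse_sv_vcf keeps only sequence-resolved biallelic DEL/INS", {
  del1 <- paste0("T", rand_seq(80, 4)); del2 <- paste0("C", rand_seq(60, 5))
  ins <- paste0("A", rand_seq(70, 6))
  lines <- c(
    paste("chr1", 1000, "d1", del1, "T", ".", "PASS", ".", "GT", "0/1",
          sep = "\t"),
    paste("chr1", 3000, "d2", del2, "C", ".", "PASS", ".", "GT", "1/1",
          sep = "\t"),
    paste("chr1", 5000, "i1", "A", ins, ".", "PASS", ".", "GT", "0/1",
          sep = "\t"),
    paste("chr1", 7000, "snv", "A", "G", ".", "PASS", ".", "GT", "0/1",
          sep = "\t"),
    paste("chr1", 9000, "sym", "A", "<INS>", ".", "PASS", "SVTYPE=INS",
          "GT", "0/1", sep = "\t"))
  expect_warning(out <- parse_sv_vcf(write_test_vcf(lines)), "skipped")
  expect_equal(nrow(out), 3L)
  expect_equal(out$variant_id, c("d1", "d2", "i1"))
  expect_equal(out$svtype, c("DEL", "DEL", "INS"))
})

test_that("empty VCF body yields an empty variant set", {
  out <- parse_sv_vcf(write_test_vcf(character(0)))
  expect_equal(nrow(out), 0L)
  expect_true(all(c("variant_id", "svlen", "svtype") %in% names(out)))
})

test_that("pass_only filtering respects keep_filters", {
  del <- paste0("T", rand_seq(80, 7))
  lines <- c(
    paste("chr1", 1000, "f1", del, "T", ".", "lowQual", ".", "GT", "0/1",
          sep = "\t"),
    paste("chr1", 3000, "f2", del, "T", ".", "LongReadHomRef", ".", "GT",
          "0/0", sep = "\t"),
    paste("chr1", 5000, "f3", del, "T", ".", "PASS", ".", "GT", "1/1",
          sep = "\t"))
  out <- suppressWarnings(parse_sv_vcf(write_test_vcf(lines),
                                       pass_only = TRUE))
  expect_equal(out$variant_id, c("f2", "f3"))
})

test_that("allele_contexts obeys the length arithmetic and identity cases", {
  spec <- tiny_spec("DEL", 100L, "HOM_ALT", seed = 31)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  ctx <- allele_contexts(v, smp$genome, 200L)
  expect_equal(nchar(ctx$ref_context), 2L * 200L + nchar(v$ref))
  expect_equal(nchar(ctx$alt_context), nchar(ctx$ref_context) + v$svlen)
  # the ref context is exactly the reference substring
  expect_equal(ctx$ref_context,
               svgenotyper:::genome_substr(smp$genome, v$contig,
                                           v$pos - 1L - 200L,
                                           v$end + 200L))
  expect_error(allele_contexts(v, smp$genome, v$pos + 10L), "flank")
})

test_that("planted insertion appears exactly once in the alt context", {
  spec <- tiny_spec("INS", 60L, "HOM_ALT", seed = 33)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  ctx <- allele_contexts(v, smp$genome, 250L)
  ins <- substr(v$alt, 2, nchar(v$alt))
  hits <- gregexpr(ins, ctx$alt_context, fixed = TRUE)[[1]]
  expect_equal(length(hits), 1L)
  expect_equal(as.integer(hits), 250L + 2L)
})

test_that("write/parse round-trips coordinates, alleles, genotypes", {
  spec <- tiny_spec("DEL", 120L, "HET", seed = 35)
  smp <- cached_sample(spec)
  calls <- tibble::tibble(variant_id = smp$truth$variant_id, gt = "0/1",
                          gq = 17.3, mode_used = "single")
  path <- tempfile(fileext = ".vcf")
  write_genotyped_vcf(smp$truth, calls, path)
  back <- parse_sv_vcf(path)
  expect_equal(back$pos, smp$truth$pos)
  expect_equal(back$ref, smp$truth$ref)
  expect_equal(back$alt, smp$truth$alt)
  expect_equal(back$gt, "0/1")
  # GQ serialized as floor integer
  body_line <- tail(readLines(path), 1)
  gq_field <- sub(".*:", "", tail(strsplit(body_line, "\t")[[1]], 1))
  expect_equal(gq_field, "17")
  # fixed point: writing the parsed copy is byte-identical
  path2 <- tempfile(fileext = ".vcf")
  back$variant_id <- smp$truth$variant_id
  write_genotyped_vcf(back, calls, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(write_genotyped_vcf(smp$truth, calls[0, ], path), "one row")
})

test_that("parsed REF alleles match the reference genome", {
  spec <- tiny_spec("DEL", 200L, "HET", seed = 37)
  smp <- cached_sample(spec)
  v <- smp$truth[1, ]
  got <- svgenotyper:::genome_substr(smp$genome, v$contig, v$pos - 1L, v$end)
  expect_identical(got, v$ref)
})
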