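# Shared in-code fixtures for the test suite. Everything is generated at
# test time from seeds; nothing is read from disk.

# Small single-contig genome with one planted variant, reused across tests.
tiny_spec <- function(svtype = "DEL", size = 300L, zygosity = "HET",
                      seed = 11L, contig_len = 60000L, shift = 0L, ...) {
  fixture_spec(
    contigs = c(chrA = contig_len),
    variants = tibble::tibble(svtype = svtype, size = size,
                              zygosity = zygosity, context = "unique",
                              shift = shift),
    seed = seed, ...)
}

# Cache plant_sample results per call signature within a test run (the
# genome-wide simulation is the slow part).
.fixture_cache <- new.env(parent = emptyenv())

cached_sample <- function(spec) {
  key <- paste(deparse(spec[setdiff(names(spec), "tr_tracts")]),
               deparse(spec$tr_tracts), collapse = "")
  key <- digestish(key)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- plant_sample(spec)
  }
  .fixture_cache[[key]]
}

digestish <- function(s) {
  v <- utf8ToInt(s)
  paste0("k", sum(v * seq_along(v)) %% 1e9, "_", length(v))
}

# Deterministic random uppercase DNA string.
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A minimal profile with a discretized-normal insert PMF.
toy_profile <- function(read_length = 100L, error = 0.001, coverage = 30,
                        insert_mean = 350, insert_sd = 75) {
  sample_profile(read_length, error, coverage,
                 svgenotyper:::discretized_normal_pmf(insert_mean, insert_sd))
}

# Write a small VCF file for parser tests.
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"))
  writeLines(c(header, lines), path)
  path
}

# Synthetic labeled feature rows with well-separated classes.
fake_rows <- function(n_per_class = 20, sep = 6, seed = 1, jitter = 1) {
  set.seed(seed)
  centers <- list(HOM_REF = c(af = 0, dh = 1), HET = c(af = 0.5, dh = 0.5),
                  HOM_ALT = c(af = 1, dh = 0))
  purrr::map_dfr(names(centers), function(z) {
    tibble::tibble(
      variant_id = paste0("v", seq_len(n_per_class)), label = z,
      ref_count = rnorm(n_per_class, 10 * (1 - centers[[z]]["af"]) * sep,
                        jitter),
      alt_count = rnorm(n_per_class, 10 * centers[[z]]["af"] * sep, jitter),
      alt_fraction = pmin(1, pmax(0, rnorm(n_per_class,
                                           centers[[z]]["af"], 0.05))),
      span_ref = rnorm(n_per_class, 5 * (1 - centers[[z]]["af"]), jitter),
      span_alt = rnorm(n_per_class, 5 * centers[[z]]["af"], jitter),
      clip_count = rnorm(n_per_class, 3 * centers[[z]]["af"], 0.3),
      dhfc = rnorm(n_per_class, centers[[z]]["dh"], 0.05),
      dhbfc = rnorm(n_per_class, centers[[z]]["dh"], 0.05),
      dhffc = rnorm(n_per_class, centers[[z]]["dh"], 0.05))
  })
}

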