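# Fully synthetic fixtures: reference genomes with optional tandem-repeat
# tracts, diploid samples with planted SVs of known zygosity, and trios with
# known Mendelian-error structure. Everything is deterministic under the
# spec seed, so every other module is testable without external data.

#' Fixture specification
#'
#' @param contigs Named integer vector of contig lengths (bp).
#' @param gc_target Genome-wide GC fraction.
#' @param tr_tracts Optional tibble (`contig`, `pos` 1-based start, `unit`,
#'   `copies`, optional `divergence`) of tandem-repeat tracts to embed;
#'   `divergence` is the per-base substitution rate between copies
#'   (default 0.03, emulating imperfect real repeats).
#' @param variants Optional tibble (`svtype`, `size`, `zygosity`, `context`
#'   in `{"unique", "TR"}`, `shift`) describing SVs to plant; `shift` offsets
#'   the *observed* description from the truth.
#' @param coverage,read_length,error_rate Sequencing parameters.
#' @param insert_mean,insert_sd Fragment-length distribution (bp).
#' @param margin Minimum distance of planted variants from contig edges (bp).
#' @param spacing Minimum separation between planted variants (bp).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(contigs = c(chrA = 250000L, chrB = 250000L),
                         gc_target = 0.5, tr_tracts = NULL, variants = NULL,
                         coverage = 30, read_length = 100L,
                         error_rate = 0.001, insert_mean = 350,
                         insert_sd = 75, margin = 3000L, spacing = 5000L,
                         seed = 42L) {
  structure(list(contigs = contigs, gc_target = gc_target,
                 tr_tracts = tr_tracts, variants = variants,
                 coverage = coverage, read_length = as.integer(read_length),
                 error_rate = error_rate, insert_mean = insert_mean,
                 insert_sd = insert_sd, margin = as.integer(margin),
                 spacing = as.integer(spacing), seed = as.integer(seed)),
            class = "fixture_spec")
}

#' The sequencing profile a fixture is simulated under
#'
#' @param spec A `fixture_spec`.
#' @return A `sample_profile` with a discretized-normal insert PMF.
#' @export
fixture_profile <- function(spec) {
  sample_profile(spec$read_length, spec$error_rate, spec$coverage,
                 discretized_normal_pmf(spec$insert_mean, spec$insert_sd))
}

#' Generate the fixture reference genome
#'
#' Seeded random sequence at the target GC with any tandem-repeat tracts
#' embedded at their recorded coordinates.
#'
#' @param spec A `fixture_spec`.
#' @return List with `genome` (DNAStringSet) and `tr_bed` (tibble `contig`,
#'   `start` 0-based, `end`, `unit`, `copies`).
#' @export
make_reference <- function(spec) {
  set.seed(spec$seed)
  seqs <- lapply(spec$contigs, function(L) random_dna(L, spec$gc_target))
  tr_bed <- tibble(contig = character(), start = integer(), end = integer(),
                   unit = character(), copies = integer())
  if (!is.null(spec$tr_tracts) && nrow(spec$tr_tracts) > 0) {
    for (i in seq_len(nrow(spec$tr_tracts))) {
      t <- spec$tr_tracts[i, ]
      tract <- strrep(t$unit, t$copies)
      # real tandem repeats are imperfect; without divergence between
      # copies, unit-shifted deletion placements would be exactly
      # equivalent and breakpoint refinement undecidable
      div <- if ("divergence" %in% names(t)) t$divergence else 0.03
      if (div > 0) {
        b <- strsplit(tract, "")[[1]]
        mut <- which(runif(length(b)) < div)
        for (k in mut) b[k] <- sample(setdiff(c("A", "C", "G", "T"), b[k]), 1)
        tract <- paste(b, collapse = "")
      }
      s0 <- t$pos - 1L
      seqs[[t$contig]] <- paste0(
        substr(seqs[[t$contig]], 1, s0), tract,
        substr(seqs[[t$contig]], s0 + nchar(tract) + 1,
               nchar(seqs[[t$contig]])))
      tr_bed <- bind_rows(tr_bed,
                          tibble(contig = t$contig, start = s0,
                                 end = s0 + nchar(tract), unit = t$unit,
                                 copies = as.integer(t$copies)))
    }
  }
  list(genome = Biostrings::DNAStringSet(unlist(seqs)), tr_bed = tr_bed)
}

# Place the spec's variants on the genome: evenly spaced within each contig
# (round-robin), honoring margin and spacing; TR-context variants are placed
# at the start of their assigned tract, deleting/inserting whole units.
place_variants <- function(spec, ref) {
  vs <- spec$variants
  if (is.null(vs) || nrow(vs) == 0) {
    return(list(variants = sv_tibble(character(), character(), integer(),
                                     character(), character()),
                zygosity = character(), shift = integer()))
  }
  genome <- ref$genome
  contigs <- names(spec$contigs)
  vs$contig <- contigs[(seq_len(nrow(vs)) - 1) %% length(contigs) + 1]
  rows <- vector("list", nrow(vs))
  tr_used <- 0L
  cursor <- setNames(rep(spec$margin, length(contigs)), contigs)
  per_contig <- table(vs$contig)
  step <- setNames(
    as.integer(floor((spec$contigs[contigs] - 2 * spec$margin) /
                       pmax(1, per_contig[contigs]))), contigs)
  for (i in seq_len(nrow(vs))) {
    v <- vs[i, ]
    size <- as.integer(v$size)
    if (identical(v$context, "TR")) {
      tr_used <- tr_used + 1L
      if (tr_used > nrow(ref$tr_bed)) stop("not enough TR tracts in spec")
      t <- ref$tr_bed[tr_used, ]
      unit <- nchar(t$unit)
      if (v$svtype == "DEL" && size %% unit != 0) {
        stop("TR deletion size must be a multiple of the unit length")
      }
      pos <- t$start + unit      # after one full unit, 1-based padding base
      ct <- t$contig
    } else {
      ct <- v$contig
      pos <- cursor[[ct]] + 1L   # 1-based padding base
      if (pos + size > spec$contigs[[ct]] - spec$margin) {
        stop("contig ", ct, " too short for the requested variants")
      }
      cursor[[ct]] <- cursor[[ct]] + max(step[[ct]], size + spec$spacing)
    }
    if (v$svtype == "DEL") {
      # padding base plus `size` deleted bases, so |svlen| == size
      refa <- genome_substr(genome, ct, pos - 1L, pos + size)
      alta <- substr(refa, 1, 1)
    } else {
      refa <- genome_substr(genome, ct, pos - 1L, pos)
      ins <- if (identical(v$context, "TR")) {
        t <- ref$tr_bed[tr_used, ]
        strrep(t$unit, size / nchar(t$unit))
      } else {
        random_dna(size, spec$gc_target)
      }
      alta <- paste0(refa, ins)
    }
    rows[[i]] <- sv_tibble(sprintf("sv%03d", i), ct, pos, refa, alta)
  }
  out <- bind_rows(rows)
  class(out) <- c("sv_tbl", setdiff(class(out), "sv_tbl"))
  list(variants = out, zygosity = vs$zygosity,
       shift = as.integer(vs$shift %||% rep(0L, nrow(vs))))
}

#' Plant a diploid sample: truth variants, haplotypes, and aligned reads
#'
#' Builds diploid haplotypes carrying the spec's variants at their
#' zygosities (heterozygous variants go on haplotype 2), simulates
#' paired-end reads genome-wide from both haplotypes, and aligns them with
#' the built-in truth-aware aligner. When a variant has a non-zero `shift`,
#' an additional "observed" description offset from the truth is recorded
#' for offset/proposal experiments.
#'
#' @param spec A `fixture_spec`.
#' @param ref Optional result of [make_reference()] (built if missing).
#' @return List with `genome`, `tr_bed`, `truth` (`sv_tbl` with `gt`),
#'   `observed` (`sv_tbl`, shifted descriptions), `reads` (alignment
#'   tibble), and `profile`.
#' @export
plant_sample <- function(spec, ref = make_reference(spec)) {
  set.seed(spec$seed)
  placed <- place_variants(spec, ref)
  truth <- placed$variants
  genome <- ref$genome
  p <- fixture_profile(spec)
  reads <- purrr::map_dfr(names(spec$contigs), function(ct) {
    L <- spec$contigs[[ct]]
    on_ct <- truth$contig == ct
    hap_vars <- function(h) {
      z <- placed$zygosity[on_ct]
      sel <- z == "HOM_ALT" | (z == "HET" & h == 2)
      truth[on_ct, ][sel, ]
    }
    haps <- lapply(1:2, function(h) {
      build_haplotype(hap_vars(h), genome, ct, 0L, L)
    })
    rep <- simulate_pairs(haps, p, seed = derive_seed(spec$seed,
                                                      match(ct, names(spec$contigs))))
    out <- align_replicate(rep)
    out$qname <- paste0(ct, "_", out$qname)
    out
  })
  truth$gt <- zygosity_to_gt(placed$zygosity)
  observed <- truth
  if (any(placed$shift != 0L)) {
    for (i in which(placed$shift != 0L)) {
      pos <- truth$pos[i] + placed$shift[i]
      refa <- genome_substr(genome, truth$contig[i], pos - 1L,
                            pos - 1L + nchar(truth$ref[i]))
      alta <- if (truth$svtype[i] == "DEL") substr(refa, 1, 1) else {
        paste0(substr(refa, 1, 1), substr(truth$alt[i], 2,
                                          nchar(truth$alt[i])))
      }
      observed[i, c("pos", "end", "ref", "alt")] <-
        list(pos, as.integer(pos + nchar(refa) - 1L), refa, alta)
    }
  }
  list(genome = genome, tr_bed = ref$tr_bed, truth = truth,
       observed = observed, reads = reads, profile = p)
}

#' Simulate a trio of genotypes with known Mendelian-error structure
#'
#' Parental genotypes are drawn independently per site from `gt_probs`;
#' child genotypes follow random Mendelian transmission except at the listed
#' de novo sites, where the stated error is planted (parents forced
#' homozygous reference for the de novo categories).
#'
#' @param n_sites Number of sites.
#' @param de_novo Optional tibble (`site`, `category` in
#'   `{"het_denovo", "hom_denovo", "other"}`).
#' @param gt_probs Probabilities of 0/0, 0/1, 1/1 for each parent.
#' @param seed Integer seed.
#' @return Tibble `site`, `child`, `mother`, `father`, `planted_me`,
#'   `planted_category`.
#' @export
make_trio <- function(n_sites, de_novo = NULL,
                      gt_probs = c(0.4, 0.4, 0.2), seed = 1L) {
  set.seed(seed)
  gts <- c("0/0", "0/1", "1/1")
  mother <- sample(gts, n_sites, replace = TRUE, prob = gt_probs)
  father <- sample(gts, n_sites, replace = TRUE, prob = gt_probs)
  transmit <- function(g) {
    al <- strsplit(g, "/", fixed = TRUE)
    vapply(al, function(a) sample(a, 1), "")
  }
  ma <- transmit(mother)
  fa <- transmit(father)
  child <- paste(pmin(ma, fa), pmax(ma, fa), sep = "/")
  out <- tibble(site = seq_len(n_sites), child = child, mother = mother,
                father = father, planted_me = FALSE,
                planted_category = NA_character_)
  if (!is.null(de_novo) && nrow(de_novo) > 0) {
    for (i in seq_len(nrow(de_novo))) {
      s <- de_novo$site[i]; cat <- de_novo$category[i]
      if (cat == "het_denovo") {
        out[s, c("child", "mother", "father")] <- list("0/1", "0/0", "0/0")
      } else if (cat == "hom_denovo") {
        out[s, c("child", "mother", "father")] <- list("1/1", "0/0", "0/0")
      } else {
        out[s, c("child", "mother", "father")] <- list("1/1", "0/0", "0/1")
      }
      out$planted_me[s] <- TRUE
      out$planted_category[s] <- cat
    }
  }
  out
}

#' Benchmark fixture: 60 unique-context SVs at typical WGS settings
#'
#' The standard end-to-end evaluation sample for this package: 30 deletions
#' and 30 insertions of 60-2,000 bp, 20 per zygosity, planted on two 250 kb
#' contigs and sequenced at 30x with 100 bp reads and a 0.1% error rate.
#'
#' @param seed Integer seed.
#' @return A `fixture_spec`.
#' @export
benchmark_spec <- function(seed = 42L) {
  sizes <- as.integer(round(seq(60, 2000, length.out = 30)))
  fixture_spec(
    contigs = c(chrA = 250000L, chrB = 250000L),
    variants = tibble::tibble(
      svtype = rep(c("DEL", "INS"), each = 30),
      size = c(sizes, sizes),
      zygosity = rep(c("HOM_REF", "HET", "HOM_ALT"), 20),
      context = "unique", shift = 0L),
    coverage = 30, read_length = 100L, error_rate = 0.001,
    insert_mean = 350, insert_sd = 75, seed = seed)
}

#' Write a fixture to disk (FASTA, SAM, truth/observed VCFs, BED)
#'
#' @param sample Result of [plant_sample()].
#' @param dir Output directory (created).
#' @param sample_name Sample name used in the SAM/VCFs.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sample, dir, sample_name = "FIXTURE") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sample$genome, file.path(dir, "genome.fa"))
  write_sam(sample$reads, sample$genome, file.path(dir, "sample.sam"),
            sample_name)
  calls <- tibble(variant_id = sample$truth$variant_id, gt = sample$truth$gt,
                  gq = 99)
  write_genotyped_vcf(sample$truth, calls, file.path(dir, "truth.vcf"),
                      sample_name)
  obs_calls <- calls %>% mutate(gt = "./.", gq = 0)
  write_genotyped_vcf(sample$observed, obs_calls,
                      file.path(dir, "observed.vcf"), sample_name)
  if (nrow(sample$tr_bed) > 0) {
    utils::write.table(sample$tr_bed[, c("contig", "start", "end")],
                       file.path(dir, "tr_tracts.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
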