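# Replicate simulation: per-variant, per-zygosity synthetic paired-end read
# sets matched to the sample profile, plus size-matched null-variant sampling
# for homozygous-reference training data.

#' Diploid haplotype pair for a variant at a given zygosity
#'
#' Builds the two haplotype sequences (with their haplotype-to-reference
#' coordinate maps) over the context region `[pos - flank, end + flank]`:
#' HOM_REF gives (ref, ref), HET (ref, alt), HOM_ALT (alt, alt).
#'
#' @param v One-row `sv_tbl`.
#' @param genome Genome.
#' @param zygosity One of `"HOM_REF"`, `"HET"`, `"HOM_ALT"`.
#' @param flank Flank length (bp).
#' @return List of two haplotype builds, each with `seq`, `map`, `contig`.
#' @export
genotype_haplotypes <- function(v, genome, zygosity, flank) {
  zygosity <- match.arg(zygosity, zygosity_levels())
  pos0 <- v$pos - 1L
  r0 <- pos0 - flank
  r1 <- pos0 + nchar(v$ref) + flank
  ref_hap <- build_haplotype(NULL, genome, v$contig, r0, r1)
  alt_hap <- build_haplotype(v, genome, v$contig, r0, r1)
  switch(zygosity,
         HOM_REF = list(ref_hap, ref_hap),
         HET = list(ref_hap, alt_hap),
         HOM_ALT = list(alt_hap, alt_hap))
}

#' Simulate paired-end reads from haplotypes
#'
#' Fragments are placed uniformly along each haplotype (coverage split
#' equally between the haplotypes), with fragment lengths drawn from the
#' profile's insert-size PMF, a read of `read_length` taken from each end
#' (mate 2 reverse-complemented on the sequencer but stored
#' reference-oriented), and per-base substitution errors applied at the
#' profile's error rate. When the profile carries per-GC coverage, fragments
#' are accepted with probability proportional to the coverage of their GC
#' bin. Deterministic for a fixed seed.
#'
#' @param haplotypes List of haplotype builds (from [genotype_haplotypes()]).
#' @param p `sample_profile`.
#' @param seed Integer seed.
#' @param coverage Total fold coverage to simulate (default: the profile's
#'   coverage for the haplotypes' contig).
#' @return Unaligned replicate: tibble with `qname`, `mate`, `strand`,
#'   `hap`, `hap_pos` (0-based), `seq`; haplotypes attached as an attribute.
#' @export
simulate_pairs <- function(haplotypes, p, seed,
                           coverage = chrom_coverage(p, haplotypes[[1]]$contig)) {
  set.seed(seed)
  rl <- p$read_length
  out <- purrr::map_dfr(seq_along(haplotypes), function(h) {
    hap <- haplotypes[[h]]
    L <- nchar(hap$seq)
    # fragments must fit inside the haplotype, so the effective placement
    # length is L - E[insert]; sizing n to it gives the target coverage in
    # the interior (negligible correction when L >> insert)
    L_eff <- max(L - p$insert_mean, rl)
    lambda <- (coverage / length(haplotypes)) * L_eff / (2 * rl)
    n <- rpois(1, lambda)
    if (n == 0) return(NULL)
    flen <- pmax(rl, sample(p$insert_pmf$len, n, replace = TRUE,
                            prob = p$insert_pmf$prob))
    flen <- pmin(flen, L)
    start <- floor(runif(n, 0, L - flen + 1))   # 0-based fragment start
    if (!is.null(p$per_gc_coverage) && p$mean_coverage > 0) {
      frag_gc <- substr_gc(hap$seq, start, flen)
      ratio <- vapply(frag_gc, function(f) gc_coverage(p, f), numeric(1)) /
        p$mean_coverage
      keep <- runif(n) < pmin(1, ratio)
      start <- start[keep]; flen <- flen[keep]; n <- length(start)
      if (n == 0) return(NULL)
    }
    s1 <- substring(hap$seq, start + 1, start + rl)
    s2 <- substring(hap$seq, start + flen - rl + 1, start + flen)
    tibble(
      qname = rep(sprintf("sim_h%d_%d", h, seq_len(n)), 2),
      mate = rep(c(1L, 2L), each = n),
      strand = rep(c("+", "-"), each = n),
      hap = h,
      hap_pos = as.integer(c(start, start + flen - rl)),
      seq = apply_errors(c(s1, s2), p$base_error_rate)
    )
  })
  if (is.null(out) || nrow(out) == 0) out <- empty_reads()[, c("qname", "mate", "strand", "hap", "hap_pos", "seq")]
  attr(out, "haplotypes") <- haplotypes
  attr(out, "seed") <- seed
  out
}

substr_gc <- function(seq, start0, len) {
  s <- substring(seq, start0 + 1, start0 + len)
  nchar(gsub("[^GC]", "", s)) / pmax(1L, nchar(gsub("N", "", s)))
}

# Uniform per-base substitution errors at rate e, random alternative base.
apply_errors <- function(seqs, e) {
  if (e <= 0 || length(seqs) == 0) return(seqs)
  nerr <- rbinom(length(seqs), nchar(seqs), e)
  idx <- which(nerr > 0)
  for (i in idx) {
    v <- strsplit(seqs[i], "")[[1]]
    ps <- sample.int(length(v), nerr[i])
    for (j in ps) {
      v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
    }
    seqs[i] <- paste(v, collapse = "")
  }
  seqs
}

#' Align a simulated replicate to the reference
#'
#' The default built-in aligner is truth-aware: each read is placed via the
#' haplotype-to-reference coordinate map implied by the variant. Flank bases
#' map directly; deletions introduce D CIGAR elements in spanning reads;
#' novel inserted bases become I elements (soft clips when the insertion
#' consumes a read end); reads wholly within novel sequence are unmapped.
#' Mate position and template length are set consistently.
#'
#' @param replicate Output of [simulate_pairs()].
#' @param aligner Optional plugin: a function `(replicate) -> alignment
#'   tibble` (e.g. wrapping an external aligner); default uses the built-in
#'   coordinate-map aligner.
#' @param clip_mode If TRUE, spanning deletion CIGARs are converted to soft
#'   clips at the breakpoint (mimics aligners that clip rather than gap).
#' @return Alignment tibble in reference coordinates.
#' @export
align_replicate <- function(replicate, aligner = NULL, clip_mode = FALSE) {
  if (!is.null(aligner)) {
    out <- tryCatch(aligner(replicate),
                    error = function(e) stop("plugin aligner failed: ",
                                             conditionMessage(e)))
    return(as_read_tbl(out))
  }
  haps <- attr(replicate, "haplotypes")
  if (nrow(replicate) == 0) return(empty_reads())
  parts <- lapply(unique(replicate$hap), function(h) {
    r <- replicate[replicate$hap == h, ]
    m <- map_reads_to_ref(r$hap_pos, nchar(r$seq), haps[[h]]$map)
    tibble(
      qname = r$qname, mate = r$mate, contig = haps[[h]]$contig,
      pos = m$pos, strand = r$strand, cigar = m$cigar, seq = r$seq,
      mapq = ifelse(m$mapped, 60L, 0L), mpos = NA_integer_,
      tlen = NA_integer_, hap = r$hap, hap_pos = r$hap_pos,
      mapped = m$mapped
    )
  })
  out <- bind_rows(parts) %>% set_mate_fields()
  if (clip_mode) out$cigar <- clip_deletions(out$cigar)
  out %>% arrange(.data$pos)
}

# Convert D-containing CIGARs to a soft-clipped prefix alignment (the read is
# clipped at the first deletion breakpoint).
clip_deletions <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || !grepl("D", cg)) return(cg)
    o <- cigar_ops(cg)[[1]]
    d <- which(o$op == "D")[1]
    after <- seq_along(o$op) > d
    clip <- sum(o$len[after & o$op %in% c("M", "I", "S")])
    paste0(paste0(o$len[seq_len(d - 1)], o$op[seq_len(d - 1)],
                  collapse = ""),
           if (clip > 0) paste0(clip, "S") else "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate and align one replicate for a variant and zygosity
#'
#' @inheritParams genotype_haplotypes
#' @inheritParams simulate_pairs
#' @param aligner,clip_mode Passed to [align_replicate()].
#' @return Alignment tibble in reference coordinates.
#' @export
simulate_replicate <- function(v, genome, zygosity, p, flank, seed,
                               aligner = NULL, clip_mode = FALSE) {
  haps <- genotype_haplotypes(v, genome, zygosity, flank)
  rep <- simulate_pairs(haps, p, seed)
  align_replicate(rep, aligner = aligner, clip_mode = clip_mode)
}

#' Sample a size-matched null variant
#'
#' Draws a variant of the same type and size at a uniform random eligible
#' location, used to harvest homozygous-reference training features from the
#' actual alignments. Locations overlapping the input variant or whose
#' reference allele exceeds 10% N are rejected. The contig is drawn from
#' `contig_partition` (e.g. autosomes for autosomal SVs) with probability
#' proportional to eligible length.
#'
#' @param v One-row `sv_tbl`.
#' @param genome Genome.
#' @param contig_partition Character vector of eligible contigs (default: all
#'   contigs in the genome).
#' @param flank Margin kept clear of contig edges (bp).
#' @param max_tries Rejection-sampling attempts before erroring.
#' @param exclude `sv_tbl` of regions the null window must not overlap
#'   (default: the input variant; pass the whole call set so null windows
#'   never sit on another putative SV).
#' @return A one-row `sv_tbl` for the null variant.
#' @export
sample_null_variant <- function(v, genome, contig_partition = NULL,
                                flank = 1000L, max_tries = 200L,
                                exclude = v) {
  g <- as_dnastringset(genome)
  contigs <- contig_partition %||% names(g)
  lens <- setNames(Biostrings::width(g), names(g))[contigs]
  ref_len <- nchar(v$ref)
  elig <- pmax(lens - 2 * flank - ref_len, 0)  # pmax keeps 1st arg's names
  if (sum(elig) <= 0) stop("no eligible window for null-variant sampling")
  for (i in seq_len(max_tries)) {
    ct <- sample(contigs, 1, prob = elig)
    pos <- sample.int(elig[[ct]], 1) + flank   # 1-based padding base
    hit <- exclude$contig == ct & pos < exclude$end + flank &
      pos + ref_len > exclude$pos - flank
    if (any(hit)) next
    ref <- genome_substr(genome, ct, pos - 1L, pos - 1L + ref_len)
    if (mean(strsplit(ref, "")[[1]] == "N") > 0.1) next
    if (grepl("[^ACGTN]", ref)) next
    alt <- if (v$svtype == "DEL") {
      substr(ref, 1, 1)
    } else {
      paste0(substr(ref, 1, 1), substr(v$alt, 2, nchar(v$alt)))
    }
    if (substr(ref, 1, 1) == "N") next
    nv <- sv_tibble(paste0(v$variant_id, "_null", i), ct, pos, ref, alt)
    return(nv)
  }
  stop("no eligible window found after ", max_tries, " tries")
}

#' Generate training replicates for one variant
#'
#' Simulates `n_per_zygosity` aligned replicates for HET and HOM_ALT (and for
#' HOM_REF when `hom_ref_sim = TRUE`). By default HOM_REF training data come
#' from null-variant sampling against the actual alignments (handled by the
#' genotyping pipeline), since pure hom-ref simulation can exhibit
#' unrealistically low variance. Replicate seeds are derived deterministically
#' from (seed, variant id, zygosity, replicate index).
#'
#' @inheritParams simulate_replicate
#' @param n_per_zygosity Replicates per zygosity (variant model default 100,
#'   single model default 1).
#' @param hom_ref_sim Also simulate HOM_REF replicates.
#' @return Named list of lists of alignment tibbles, one element per
#'   simulated zygosity.
#' @export
generate_training_replicates <- function(v, genome, p, n_per_zygosity, flank,
                                         seed, hom_ref_sim = FALSE,
                                         aligner = NULL) {
  stopifnot(n_per_zygosity >= 1)
  zygs <- if (hom_ref_sim) zygosity_levels() else c("HET", "HOM_ALT")
  vhash <- sum(utf8ToInt(v$variant_id))
  setNames(lapply(zygs, function(z) {
    zi <- match(z, zygosity_levels())
    lapply(seq_len(n_per_zygosity), function(k) {
      simulate_replicate(v, genome, z, p, flank,
                         seed = derive_seed(seed, vhash, zi, k),
                         aligner = aligner)
    })
  }), zygs)
}

#' Write a simulated replicate as paired FASTQ files
#'
#' Mate 1 is written as sequenced; mate 2 is reverse-complemented back to
#' sequencing orientation. Intended for feeding an external plugin aligner.
#'
#' @param replicate Output of [simulate_pairs()].
#' @param prefix Output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq <- function(replicate, prefix) {
  paths <- paste0(prefix, "_", 1:2, ".fastq")
  for (m in 1:2) {
    r <- replicate[replicate$mate == m, ]
    seqs <- if (m == 2) revcomp(r$seq) else r$seq
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    writeLines(as.vector(rbind(paste0("@", r$qname, "/", m), seqs,
                               "+", qual)), paths[m])
  }
  invisible(paths)
}
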