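# Parsing, validation, and serialization of sequence-resolved structural
# variants. Coordinates are VCF 1-based inclusive at the interface; internal
# computations use 0-based half-open intervals.

#' Construct a structural-variant tibble
#'
#' One row per biallelic, sequence-resolved deletion or insertion. `pos` is
#' the 1-based position of the padding base shared by both alleles; `svlen`
#' is `nchar(alt) - nchar(ref)` (negative for deletions); `end` is the
#' 1-based inclusive end of the reference allele.
#'
#' @param variant_id Character IDs (unique).
#' @param contig Contig names.
#' @param pos 1-based padding-base positions.
#' @param ref,alt Uppercase allele strings (shared first base).
#' @return A tibble with class `sv_tbl`, columns `variant_id`, `contig`,
#'   `pos`, `end`, `ref`, `alt`, `svtype`, `svlen`.
#' @export
sv_tibble <- function(variant_id, contig, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  bad <- grepl("[^ACGTN]", ref) | grepl("[^ACGTN]", alt) |
    nchar(ref) == 0 | nchar(alt) == 0
  if (any(bad)) stop("alleles must be non-empty strings over {A,C,G,T,N}")
  if (any(substr(ref, 1, 1) != substr(alt, 1, 1))) {
    stop("REF and ALT must share a padding base (first character)")
  }
  svlen <- nchar(alt) - nchar(ref)
  if (any(svlen == 0)) stop("svlen must be non-zero (DEL or INS only)")
  out <- tibble(
    variant_id = as.character(variant_id),
    contig = as.character(contig),
    pos = as.integer(pos),
    end = as.integer(pos + nchar(ref) - 1L),
    ref = ref, alt = alt,
    svtype = ifelse(svlen < 0, "DEL", "INS"),
    svlen = as.integer(svlen)
  )
  class(out) <- c("sv_tbl", class(out))
  out
}

#' Parse sequence-resolved DEL/INS structural variants from a VCF
#'
#' Retains biallelic records with explicit REF/ALT sequences whose absolute
#' length change lies in `[size_min, size_max]`. Symbolic alleles (e.g.
#' `<DEL>`), multi-allelic records, SNVs/short indels, and (optionally)
#' records failing FILTER are skipped with a warning; record order is
#' preserved.
#'
#' @param path VCF file (plain text or bgzip).
#' @param size_min,size_max Inclusive window on `abs(svlen)` in bp.
#' @param pass_only Drop records whose FILTER is neither PASS nor missing.
#' @param keep_filters FILTER values additionally treated as passing when
#'   `pass_only` (e.g. `"LongReadHomRef"`).
#' @param max_n_fraction Skip variants whose REF allele exceeds this fraction
#'   of N bases (simulation over assembly gaps is meaningless).
#' @return An `sv_tbl` tibble (see [sv_tibble()]) with an additional
#'   `gt` column when the VCF has a sample column (character, `NA` if absent).
#' @export
parse_sv_vcf <- function(path, size_min = 50, size_max = 15e6,
                         pass_only = FALSE, keep_filters = "LongReadHomRef",
                         max_n_fraction = 0.1) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- sv_tibble(character(), character(), integer(), character(),
                     character())
    out$gt <- character()
    return(out)
  }
  gt <- rep(NA_character_, nrow(fix))
  if (ncol(v@gt) >= 2) {
    fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
    smp <- strsplit(v@gt[, 2], ":", fixed = TRUE)
    gt <- mapply(function(f, s) {
      i <- match("GT", f)
      if (is.na(i) || i > length(s)) NA_character_ else gsub("|", "/", s[i], fixed = TRUE)
    }, fmt, smp)
  }
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  n <- nrow(fix)
  keep <- rep(TRUE, n)
  why <- rep(NA_character_, n)
  drop <- function(cond, reason) {
    why[keep & cond] <<- reason
    keep <<- keep & !cond
  }
  drop(is.na(alt) | grepl(",", alt, fixed = TRUE), "multi-allelic or missing ALT")
  drop(grepl("[<>\\[\\]]", alt), "symbolic or breakend ALT")
  drop(grepl("[^ACGTN]", ref) | grepl("[^ACGTN]", alt), "non-ACGTN allele")
  drop(substr(ref, 1, 1) != substr(alt, 1, 1), "missing padding base")
  svlen <- nchar(alt) - nchar(ref)
  drop(abs(svlen) < size_min | abs(svlen) > size_max, "size outside window")
  if (pass_only) {
    filt <- fix$FILTER
    ok <- is.na(filt) | filt %in% c("PASS", ".", "", keep_filters)
    drop(!ok, "non-PASS FILTER")
  }
  nfrac <- vapply(ref, function(r) {
    if (nchar(r) == 0) return(0)
    sum(strsplit(r, "")[[1]] == "N") / nchar(r)
  }, numeric(1), USE.NAMES = FALSE)
  drop(nfrac > max_n_fraction, "REF allele >10% N")
  skipped <- table(why[!keep & !is.na(why)])
  if (length(skipped) > 0) {
    warning("skipped ", sum(skipped), " record(s): ",
            paste(names(skipped), skipped, sep = " x", collapse = "; "),
            call. = FALSE)
  }
  idx <- which(keep)
  ids <- fix$ID[idx]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[idx][noid], "_", fix$POS[idx][noid])
  out <- sv_tibble(ids, fix$CHROM[idx], as.integer(fix$POS[idx]),
                   ref[idx], alt[idx])
  out$gt <- unname(gt[idx])
  out
}

#' Reference and alternate haplotype contexts around a variant
#'
#' Extracts the reference sequence from `flank` bases upstream of the padding
#' base to `flank` bases downstream of the reference allele, and the same
#' region with ALT substituted for REF. These are the sequences read pairs are
#' realigned against and that replicate simulation samples from.
#'
#' @param v One-row `sv_tbl`.
#' @param genome Named DNAStringSet or named character vector.
#' @param flank Flank length in bp (should be at least the read length;
#'   typically the 99th percentile of the insert size).
#' @return A list with `ref_context`, `alt_context`, `flank`, `ctx_start0`
#'   (0-based start of the context on the contig), and the originating
#'   variant row `origin`.
#' @export
allele_contexts <- function(v, genome, flank) {
  stopifnot(nrow(v) == 1)
  pos0 <- v$pos - 1L           # 0-based padding base
  ref_end0 <- pos0 + nchar(v$ref)
  clen <- contig_length(genome, v$contig)
  if (pos0 - flank < 0 || ref_end0 + flank > clen) {
    stop("variant within ", flank, " bp of contig edge; clamp the flank ",
         "to at most ", min(pos0, clen - ref_end0), " bp")
  }
  ref_context <- genome_substr(genome, v$contig, pos0 - flank,
                               ref_end0 + flank)
  obs_ref <- substr(ref_context, flank + 1, flank + nchar(v$ref))
  if (obs_ref != v$ref) {
    stop("REF allele does not match the reference genome at ",
         v$contig, ":", v$pos)
  }
  alt_context <- paste0(substr(ref_context, 1, flank), v$alt,
                        substr(ref_context, flank + nchar(v$ref) + 1,
                               nchar(ref_context)))
  structure(list(ref_context = ref_context, alt_context = alt_context,
                 flank = as.integer(flank),
                 ctx_start0 = as.integer(pos0 - flank), origin = v),
            class = "allele_pair")
}

#' Write a genotyped copy of a variant set
#'
#' Serializes variants with predicted genotypes as a minimal VCF 4.2 file.
#' The header is fixed text (no timestamps or versions), so identical inputs
#' produce byte-identical files. GQ is floored to an integer.
#'
#' @param variants `sv_tbl` tibble.
#' @param calls Tibble with `variant_id`, `gt`, `gq` (and optionally
#'   `mode_used`), one row per variant; `gt` in `0/0`, `0/1`, `1/1`, `./.`.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_genotyped_vcf <- function(variants, calls, path, sample_name = "SAMPLE") {
  if (!setequal(variants$variant_id, calls$variant_id) ||
      nrow(calls) != nrow(variants)) {
    stop("calls must contain exactly one row per variant")
  }
  calls <- calls[match(variants$variant_id, calls$variant_id), ]
  stopifnot(all(calls$gt %in% gt_levels()))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svgenotyper",
    paste0("##contig=<ID=", unique(variants$contig), ">"),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length difference of alternate and reference alleles\">",
    "##INFO=<ID=MODEL,Number=1,Type=String,Description=\"Classifier model used (single or variant)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Phred-scaled genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  info <- paste0("SVTYPE=", variants$svtype, ";SVLEN=", variants$svlen)
  if (!is.null(calls[["mode_used"]])) {
    info <- paste0(info, ";MODEL=", calls[["mode_used"]])
  }
  gq <- ifelse(calls$gt == "./.", ".", as.character(as.integer(floor(calls$gq))))
  body <- paste(variants$contig, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", info, "GT:GQ",
                paste0(calls$gt, ":", gq), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
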