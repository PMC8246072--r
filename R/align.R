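# In-memory alignment container, haplotype->reference coordinate maps, and
# the built-in truth-aware aligner used for simulated replicates.
#
# The canonical alignment container is a tibble with one row per read:
#   qname, mate (1/2), contig, pos (1-based leftmost), strand (+/-), cigar,
#   seq (reference-oriented), mapq, mpos, tlen, hap, hap_pos, mapped.
# hap/hap_pos are truth tags recording the originating haplotype (1/2) and
# 0-based position on it; they are NA for reads loaded from real data.

as_read_tbl <- function(x) {
  if (is.character(x) && length(x) == 1) return(read_alignments(x))
  stopifnot(is.data.frame(x))
  as_tibble(x)
}

#' Read alignments from a BAM or SAM file into a tibble
#'
#' Primary alignments only. SAM input is converted via Rsamtools.
#'
#' @param path BAM or SAM path.
#' @return Alignment tibble (one row per read).
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read BAM/SAM files")
  }
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    path <- bam
  }
  res <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq",
               "mapq", "mpos", "isize"),
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
    ))[[1]]
  tibble(
    qname = res$qname,
    mate = ifelse(bitwAnd(res$flag, 64L) > 0, 1L, 2L),
    contig = as.character(res$rname),
    pos = res$pos,
    strand = as.character(res$strand),
    cigar = res$cigar,
    seq = as.character(res$seq),
    mapq = res$mapq,
    mpos = res$mpos,
    tlen = res$isize,
    hap = NA_integer_, hap_pos = NA_integer_,
    mapped = bitwAnd(res$flag, 4L) == 0 & !is.na(res$pos),
    span = cigar_ref_span(res$cigar)
  )
}

#' Write an alignment tibble as a SAM file
#'
#' @param reads Alignment tibble.
#' @param genome Genome (for header contig lengths).
#' @param path Output path (`.sam`).
#' @param sample_name Read-group sample name.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path, sample_name = "SAMPLE") {
  g <- as_dnastringset(genome)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(g), "\tLN:", Biostrings::width(g)),
           paste0("@RG\tID:rg1\tSM:", sample_name))
  reads <- reads %>% arrange(.data$contig, .data$pos)
  flag <- 1L + 2L +                       # paired, proper
    ifelse(reads$mapped, 0L, 4L) +
    ifelse(reads$strand == "-", 16L, 32L) +
    ifelse(reads$mate == 1L, 64L, 128L)
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  body <- paste(reads$qname, flag, reads$contig, reads$pos, reads$mapq,
                ifelse(is.na(reads$cigar), "*", reads$cigar), "=",
                ifelse(is.na(reads$mpos), 0L, reads$mpos),
                ifelse(is.na(reads$tlen), 0L, reads$tlen),
                reads$seq, qual, "RG:Z:rg1", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- haplotype -> reference coordinate maps -------------------------------

# A haplotype map is a tibble of segments in haplotype order:
#   hap_start (0-based), len, ref_start (0-based on the contig, NA for novel
#   inserted bases). Consecutive mapped segments with a reference gap imply a
#   deletion. build_haplotype() applies a set of variants (rows of an sv_tbl,
#   assumed sorted and non-overlapping) to the region [region_start0,
#   region_end0) of a contig and returns the haplotype sequence plus its map.
build_haplotype <- function(variants, genome, contig, region_start0,
                            region_end0) {
  seqs <- character(0)
  segs <- list()
  cur_ref <- region_start0
  cur_hap <- 0L
  add_match <- function(from, to) {
    if (to > from) {
      seqs[[length(seqs) + 1]] <<- genome_substr(genome, contig, from, to)
      segs[[length(segs) + 1]] <<- tibble(hap_start = cur_hap,
                                          len = to - from, ref_start = from)
      cur_hap <<- cur_hap + (to - from)
    }
  }
  if (!is.null(variants) && nrow(variants) > 0) {
    variants <- variants[order(variants$pos), ]
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      pos0 <- v$pos - 1L
      # shared padding base is part of the preceding match segment
      add_match(cur_ref, pos0 + 1L)
      ins <- substr(v$alt, 2, nchar(v$alt))
      if (nchar(ins) > 0) {            # novel inserted bases
        seqs[[length(seqs) + 1]] <- ins
        segs[[length(segs) + 1]] <- tibble(hap_start = cur_hap,
                                           len = nchar(ins),
                                           ref_start = NA_integer_)
        cur_hap <- cur_hap + nchar(ins)
      }
      cur_ref <- pos0 + nchar(v$ref)   # skip deleted reference bases
    }
  }
  add_match(cur_ref, region_end0)
  map <- bind_rows(segs)
  list(seq = paste(seqs, collapse = ""), map = map, contig = contig)
}

# Map reads sampled from a haplotype (0-based hap_pos, read length from seq)
# to reference coordinates using the haplotype map. Returns pos (1-based),
# cigar, mapped for each read. Vectorized fast path for reads falling inside
# a single mapped segment; boundary reads take the op-walk.
map_reads_to_ref <- function(hap_pos, read_len, map) {
  n <- length(hap_pos)
  pos <- integer(n); cigar <- character(n); mapped <- logical(n)
  seg_starts <- map$hap_start
  seg_idx_l <- findInterval(hap_pos, seg_starts)
  seg_idx_r <- findInterval(hap_pos + read_len - 1L, seg_starts)
  simple <- seg_idx_l == seg_idx_r & !is.na(map$ref_start[seg_idx_l])
  pos[simple] <- map$ref_start[seg_idx_l[simple]] +
    (hap_pos[simple] - map$hap_start[seg_idx_l[simple]]) + 1L
  cigar[simple] <- paste0(read_len[simple], "M")
  mapped[simple] <- TRUE
  for (i in which(!simple)) {
    r <- map_one_read(hap_pos[i], read_len[i], map)
    pos[i] <- r$pos; cigar[i] <- r$cigar; mapped[i] <- r$mapped
  }
  tibble(pos = pos, cigar = cigar, mapped = mapped)
}

# Op-walk for a read crossing segment boundaries. Novel bases become I in the
# read interior and soft clips at read ends; reference gaps between mapped
# segments become D (only between two aligned blocks).
map_one_read <- function(h0, rl, map) {
  h1 <- h0 + rl
  ops <- character(0); lens <- integer(0)
  first_ref <- NA_integer_
  prev_ref_end <- NA_integer_
  for (j in seq_len(nrow(map))) {
    s <- map$hap_start[j]; e <- s + map$len[j]
    if (e <= h0 || s >= h1) next
    ov0 <- max(s, h0); ov1 <- min(e, h1)
    olen <- ov1 - ov0
    if (is.na(map$ref_start[j])) {
      ops <- c(ops, "I"); lens <- c(lens, olen)
    } else {
      rstart <- map$ref_start[j] + (ov0 - s)
      if (!is.na(prev_ref_end) && rstart > prev_ref_end &&
          any(ops == "M")) {
        ops <- c(ops, "D"); lens <- c(lens, rstart - prev_ref_end)
      }
      if (is.na(first_ref) ) first_ref <- rstart
      ops <- c(ops, "M"); lens <- c(lens, olen)
      prev_ref_end <- rstart + olen
    }
  }
  if (!any(ops == "M")) {
    return(list(pos = NA_integer_, cigar = NA_character_, mapped = FALSE))
  }
  # leading/trailing insertions become soft clips; drop leading/trailing D
  while (length(ops) > 0 && ops[1] != "M") {
    if (ops[1] == "I") ops[1] <- "S" else { ops <- ops[-1]; lens <- lens[-1] }
    if (length(ops) > 0 && ops[1] == "S") break
  }
  while (length(ops) > 0 && ops[length(ops)] != "M") {
    k <- length(ops)
    if (ops[k] == "I") ops[k] <- "S" else { ops <- ops[-k]; lens <- lens[-k] }
    if (length(ops) > 0 && ops[length(ops)] == "S") break
  }
  # first M determines pos; recompute first_ref in case leading M was dropped
  keep <- paste0(lens, ops)
  list(pos = first_ref + 1L, cigar = paste(keep, collapse = ""),
       mapped = TRUE)
}

# Reference-consuming (M/=/X) segments of each mapped read, 1-based
# inclusive, for IRanges::coverage. Vectorized fast path for ungapped
# (single-M) CIGARs; gapped/clipped reads take a per-read walk.
read_ref_segments <- function(reads) {
  reads <- reads[reads$mapped & !is.na(reads$cigar), ]
  if (nrow(reads) == 0) return(tibble(start = integer(), end = integer()))
  simple <- grepl("^[0-9]+M$", reads$cigar)
  out_s <- list()
  if (any(simple)) {
    len <- as.integer(sub("M", "", reads$cigar[simple], fixed = TRUE))
    out_s[[1]] <- tibble(start = reads$pos[simple],
                         end = reads$pos[simple] + len - 1L)
  }
  if (any(!simple)) {
    idx <- which(!simple)
    ops <- cigar_ops(reads$cigar[idx])
    starts <- vector("list", length(idx)); ends <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      o <- ops[[k]]
      cur <- reads$pos[idx[k]]
      ss <- integer(0); ee <- integer(0)
      for (j in seq_along(o$op)) {
        if (o$op[j] %in% c("M", "=", "X")) {
          ss <- c(ss, cur); ee <- c(ee, cur + o$len[j] - 1L)
          cur <- cur + o$len[j]
        } else if (o$op[j] %in% c("D", "N")) {
          cur <- cur + o$len[j]
        }
      }
      starts[[k]] <- ss; ends[[k]] <- ee
    }
    out_s[[length(out_s) + 1]] <- tibble(start = unlist(starts),
                                         end = unlist(ends))
  }
  bind_rows(out_s)
}

# Set mate fields (mpos, tlen) and cache the reference span for paired reads
# sharing a qname. Vectorized via hashed mate lookup.
set_mate_fields <- function(reads) {
  span <- cigar_ref_span(reads$cigar)
  mi <- match(paste0(reads$qname, "\r", 3L - reads$mate),
              paste0(reads$qname, "\r", reads$mate))
  ok <- !is.na(mi) & reads$mapped & reads$mapped[ifelse(is.na(mi), 1L, mi)]
  end_self <- reads$pos + span - 1L
  end_mate <- reads$pos[mi] + span[mi] - 1L
  lo <- pmin(reads$pos, reads$pos[mi])
  hi <- pmax(end_self, end_mate)
  s <- hi - lo + 1L
  leftmost <- reads$pos < reads$pos[mi] |
    (reads$pos == reads$pos[mi] & reads$mate == 1L)
  reads$span <- span
  reads$mpos <- ifelse(ok, reads$pos[mi], NA_integer_)
  reads$tlen <- ifelse(ok, ifelse(leftmost, s, -s), NA_integer_)
  reads
}
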