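# Reference genome access. The canonical container is a named
# Biostrings::DNAStringSet; plain named character vectors are accepted
# everywhere for convenience in tests and fixtures.

#' Read a reference genome
#'
#' @param path Path to a (possibly bgzipped) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  # FASTA descriptions may carry comments after the contig name.
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome to FASTA with a .fai index
#'
#' @param genome Named DNAStringSet or named character vector.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  g <- as_dnastringset(genome)
  Biostrings::writeXStringSet(g, path, width = 70L)
  # Plain-text .fai: name, length, offset, linebases, linewidth.
  lens <- Biostrings::width(g)
  offs <- cumsum(c(0, head(nchar(names(g)) + 2 + lens + ceiling(lens / 70), -1)))
  fai <- data.frame(names(g), lens, offs + nchar(names(g)) + 2, 70L, 71L)
  utils::write.table(fai, paste0(path, ".fai"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_dnastringset <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  Biostrings::DNAStringSet(unlist(genome))
}

contig_length <- function(genome, contig) {
  g <- as_dnastringset(genome)
  if (!contig %in% names(g)) stop("contig not in genome: ", contig)
  Biostrings::width(g)[match(contig, names(g))]
}

# 0-based half-open substring of a contig, returned as uppercase character.
genome_substr <- function(genome, contig, start0, end0) {
  g <- as_dnastringset(genome)
  len <- contig_length(g, contig)
  if (start0 < 0 || end0 > len || start0 > end0) {
    stop(sprintf("region [%d,%d) outside contig %s (length %d)",
                 start0, end0, contig, len))
  }
  toupper(as.character(Biostrings::subseq(g[[contig]], start0 + 1, end0)))
}
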