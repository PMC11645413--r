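#' Read a genome FASTA into a named character vector
#'
#' Sequences are held in memory as upper-case character strings, which is
#' adequate for the simulated and peak-scale genomes this package targets.
#'
#' @param path FASTA file.
#' @return Named character vector of class `genome`, one element per
#'   sequence.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(ss))
  class(g) <- "genome"
  g
}

#' Write a genome to FASTA
#' @param genome Named character vector (class `genome` or plain).
#' @param path Output FASTA path.
#' @param header_note Optional string appended to each header (used to
#'   record simulation seeds).
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path, header_note = NULL) {
  nm <- names(genome)
  if (!is.null(header_note)) nm <- paste(nm, header_note)
  ss <- Biostrings::DNAStringSet(unclass(genome))
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

# Extract [start, end) (0-based half-open) from one chromosome, clipping at
# the chromosome boundaries. Returns the clipped sequence and its genomic
# start.
.get_window <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop(sprintf("chromosome '%s' absent from genome", chrom))
  len <- nchar(genome[[chrom]])
  s <- max(0, start); e <- min(len, end)
  if (s >= e) return(list(seq = "", start = s))
  list(seq = substr(genome[[chrom]], s + 1, e), start = s)
}

# DNA complement / reverse complement on plain strings.
.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, NULL)[[1]]), collapse = ""), ""))
}

# Map a DNA string to integer codes A=1 C=2 G=3 T=4, NA otherwise.
.seq_to_int <- function(s) {
  code <- match(strsplit(toupper(s), NULL)[[1]], c("A", "C", "G", "T"))
  code
}
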