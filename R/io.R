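#' FASTA/FASTQ input and output
#'
#' Thin wrappers around Biostrings readers/writers that move sequences in and
#' out of the plain data.frame read representation used across the package
#' (`read_id`, `sequence`, `quality`).
#'
#' @name io
NULL

#' Read a FASTQ file into the package's read data.frame
#' @param path FASTQ file (optionally gzipped)
#' @return data.frame with columns `read_id`, `sequence`, `quality`
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  data.frame(read_id = names(x), sequence = as.character(x),
             quality = q, stringsAsFactors = FALSE)
}

#' Write the package's read data.frame to FASTQ (Phred+33)
#' @param reads data.frame with `read_id`, `sequence`, `quality`
#' @param path output file
#' @export
write_fastq <- function(reads, path) {
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence/quality length mismatch")
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$quality)
  xq <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
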