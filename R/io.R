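# Thin wrappers around Biostrings readers/writers so the pipeline's external
# interfaces (FASTQ in, per-sample FASTA out, TSV sheets) stay one-liners.

#' Write reads to a FASTQ file (Sanger Phred+33)
#'
#' @param reads `data.frame` with columns `read_id`, `seq` and optionally
#'   `qual` (Phred+33 strings; missing quals are written as Q30).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  qual <- if ("qual" %in% names(reads) && !anyNA(reads$qual)) {
    reads$qual
  } else {
    vapply(nchar(reads$seq), function(n) strrep("?", n), character(1))
  }
  q <- Biostrings::BStringSet(qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into the pipeline's read table
#'
#' @param path FASTQ file (Phred+33).
#' @return `data.frame` with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own metadata columns here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(
    read_id = names(x),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE
  )
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, or `data.frame` with `read_id`/`seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$read_id)
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}
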