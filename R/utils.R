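#' @importFrom stats aov lm coef rnorm runif setNames complete.cases
#' @importFrom utils head data
NULL

# IUPAC nucleotide ambiguity codes -> character classes for regex matching
IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

#' Convert an IUPAC-degenerate primer to a regular expression
#'
#' Spaces are stripped (primers are often written in blocks of three).
#'
#' @param primer Primer sequence, 5'->3', possibly containing IUPAC
#'   degeneracy codes.
#' @return A character scalar holding the equivalent regular expression.
#' @export
iupac_regex <- function(primer) {
  primer <- gsub("[[:space:]]", "", toupper(primer))
  chars <- strsplit(primer, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0) {
    stop("primer contains non-IUPAC characters: ", paste(bad, collapse = ", "))
  }
  paste(IUPAC_MAP[chars], collapse = "")
}

#' Reverse complement of nucleotide sequences
#'
#' @param x Character vector of nucleotide sequences (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate nucleotide sequences in a given frame
#'
#' Frames follow the BLAST convention: +1/+2/+3 start at base 1/2/3 of the
#' forward strand; -1/-2/-3 start at base 1/2/3 of the reverse complement.
#' Trailing partial codons are dropped; stop codons appear as `*`.
#'
#' @param x Character vector of nucleotide sequences (ACGT).
#' @param frame Integer in `c(1, 2, 3, -1, -2, -3)`.
#' @return Character vector of amino-acid sequences.
#' @export
translate_frame <- function(x, frame) {
  stopifnot(frame %in% c(1, 2, 3, -1, -2, -3))
  if (frame < 0) x <- revcomp(x)
  off <- abs(frame) - 1
  sub <- substring(x, off + 1)
  len <- nchar(sub) - nchar(sub) %% 3
  sub <- substring(sub, 1, len)
  out <- character(length(sub))
  ok <- len >= 3
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(sub[ok]),
      no.init.codon = TRUE
    ))
  }
  out
}

# Phred+33 string -> integer vector of quality scores
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; filter-accounting percentages use
#' the commercial convention (half away from zero).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# standard genetic code indexed by codon string
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc
}

# draw a deterministic child seed (< 2^31) from a base seed and a tag
derive_seed <- function(seed, tag) {
  (as.integer(seed) %% 1000003L) * 1009L + (sum(utf8ToInt(tag)) %% 997L)
}
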