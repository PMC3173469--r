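# Demultiplexing and read screening: quality / barcode / primer / length
# filters plus the running ledger used for the filter-accounting table.

#' Start a filter ledger
#'
#' The ledger records the number of reads surviving each screening stage so
#' the final accounting (counts and percentages of the raw total) can be
#' produced by [summarize_filtering()].
#'
#' @param raw_count Number of raw reads entering the pipeline.
#' @return `data.frame` with columns `stage`, `count`.
#' @export
filter_ledger <- function(raw_count) {
  data.frame(stage = "raw", count = as.numeric(raw_count),
             stringsAsFactors = FALSE)
}

#' Append a stage to a filter ledger
#'
#' @param ledger Ledger from [filter_ledger()].
#' @param stage Stage label.
#' @param count Reads surviving the stage (must not exceed the previous
#'   stage).
#' @return Updated ledger.
#' @export
ledger_add <- function(ledger, stage, count) {
  if (count > ledger$count[nrow(ledger)]) {
    stop("ledger counts must be non-increasing (stage '", stage, "')")
  }
  rbind(ledger, data.frame(stage = stage, count = as.numeric(count),
                           stringsAsFactors = FALSE))
}

#' Initial quality screen
#'
#' Removes reads shorter than `min_len`, reads containing an ambiguous base
#' `N`, and (when qualities are present) reads whose arithmetic mean Phred
#' score over the raw read is below `min_qual`. Order-preserving. Reads
#' without qualities skip the mean-quality criterion; this is recorded in the
#' returned summary.
#'
#' @param reads Read table (`read_id`, `seq`, optional `qual`).
#' @param min_len Minimum raw read length (default 50).
#' @param min_qual Minimum mean Phred score (default 20).
#' @return List with `reads` (kept), `removed` (dropped rows) and
#'   `qualities_used` (logical).
#' @export
quality_screen <- function(reads, min_len = 50, min_qual = 20) {
  has_qual <- "qual" %in% names(reads) && !anyNA(reads$qual)
  too_short <- nchar(reads$seq) < min_len
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  low_q <- if (has_qual) {
    vapply(reads$qual, function(q) mean(utf8ToInt(q) - 33) < min_qual,
           logical(1), USE.NAMES = FALSE)
  } else {
    rep(FALSE, nrow(reads))
  }
  drop <- too_short | has_n | low_q
  list(reads = reads[!drop, , drop = FALSE],
       removed = reads[drop, , drop = FALSE],
       qualities_used = has_qual)
}

#' Assign reads to samples by exact barcode prefix match
#'
#' A read is assigned iff its first `nchar(barcode)` bases exactly equal one
#' of the sheet's barcodes (no mismatches tolerated); the barcode is then
#' trimmed and the read labelled with the sheet's sample and gene. Everything
#' else lands in the unassigned pile.
#'
#' @param reads Read table.
#' @param barcode_sheet `data.frame` with columns `sample`, `gene`,
#'   `barcode` (all barcodes the same length and unique).
#' @return List with `assigned` (read table plus `sample`, `gene` columns)
#'   and `unassigned`.
#' @export
demultiplex <- function(reads, barcode_sheet) {
  if (anyDuplicated(barcode_sheet$barcode)) {
    stop("duplicate barcodes in sheet")
  }
  blen <- unique(nchar(barcode_sheet$barcode))
  if (length(blen) != 1) stop("barcodes must all have the same length")
  prefix <- substr(reads$seq, 1, blen)
  idx <- match(prefix, barcode_sheet$barcode)
  hit <- !is.na(idx) & nchar(reads$seq) > blen
  assigned <- reads[hit, , drop = FALSE]
  assigned$seq <- substring(assigned$seq, blen + 1)
  if ("qual" %in% names(assigned)) {
    assigned$qual <- substring(assigned$qual, blen + 1)
  }
  assigned$sample <- barcode_sheet$sample[idx[hit]]
  assigned$gene <- barcode_sheet$gene[idx[hit]]
  list(assigned = assigned, unassigned = reads[!hit, , drop = FALSE])
}

#' Primer screen, orientation and length filter
#'
#' A read whose 5' end matches a realization of the (IUPAC-degenerate)
#' forward primer is kept as-is; one matching the reverse primer is
#' reverse-complemented so all survivors are forward-oriented. The matched
#' primer is trimmed, and reads shorter than `min_len` after trimming are
#' removed. Reads already flagged as trimmed pass through untouched, so the
#' screen is idempotent.
#'
#' @param reads Read table (barcode already removed).
#' @param fwd_primer,rev_primer Primers, 5'->3', IUPAC codes allowed.
#' @param min_len Minimum post-trim length (default 350, inclusive).
#' @return List with `reads` (kept, all forward-oriented, `trimmed = TRUE`)
#'   and `removed`.
#' @export
primer_screen_and_orient <- function(reads, fwd_primer, rev_primer,
                                     min_len = 350) {
  if ("trimmed" %in% names(reads) && all(reads$trimmed)) {
    return(list(reads = reads, removed = reads[0, , drop = FALSE]))
  }
  fwd_re <- paste0("^", iupac_regex(fwd_primer))
  rev_re <- paste0("^", iupac_regex(rev_primer))
  flen <- nchar(gsub("[[:space:]]", "", fwd_primer))
  rlen <- nchar(gsub("[[:space:]]", "", rev_primer))
  is_fwd <- grepl(fwd_re, reads$seq)
  is_rev <- !is_fwd & grepl(rev_re, reads$seq)
  out <- reads[is_fwd | is_rev, , drop = FALSE]
  fwd_sel <- is_fwd[is_fwd | is_rev]
  plen <- ifelse(fwd_sel, flen, rlen)
  out$seq <- substring(out$seq, plen + 1)
  has_qual <- "qual" %in% names(out)
  if (has_qual) out$qual <- substring(out$qual, plen + 1)
  if (any(!fwd_sel)) {
    out$seq[!fwd_sel] <- revcomp(out$seq[!fwd_sel])
    if (has_qual) {
      out$qual[!fwd_sel] <- vapply(
        out$qual[!fwd_sel],
        function(q) intToUtf8(rev(utf8ToInt(q))),
        character(1), USE.NAMES = FALSE
      )
    }
  }
  out$oriented_forward <- TRUE
  keep <- nchar(out$seq) >= min_len
  out <- out[keep, , drop = FALSE]
  out$trimmed <- TRUE
  removed <- rbind(
    reads[!(is_fwd | is_rev), , drop = FALSE],
    reads[is_fwd | is_rev, , drop = FALSE][!keep, , drop = FALSE]
  )
  list(reads = out, removed = removed)
}

#' Filter-accounting summary
#'
#' Reports each ledger stage as a count and a percentage of the raw total,
#' rounded half away from zero to one decimal.
#'
#' @param ledger Ledger from [filter_ledger()] / [ledger_add()].
#' @return `data.frame` with columns `stage`, `count`, `percent`.
#' @export
summarize_filtering <- function(ledger) {
  raw <- ledger$count[ledger$stage == "raw"][1]
  if (is.na(raw) || raw == 0) stop("empty input: raw count is zero")
  data.frame(
    stage = ledger$stage,
    count = ledger$count,
    percent = round_half_up(100 * ledger$count / raw, 1),
    stringsAsFactors = FALSE
  )
}

#' Percentage difference between two pipeline variants
#'
#' Expresses `a` relative to reference `b` as `100 * (b - a) / b`, rounded
#' half away from zero to one decimal (e.g. 26,431 valid reads vs 30,101 is
#' a 12.2% reduction).
#'
#' @param a,b Counts; `b` is the reference.
#' @return Percentage reduction, one decimal.
#' @export
percent_fewer <- function(a, b) {
  if (b == 0) stop("reference count is zero")
  round_half_up(100 * (b - a) / b, 1)
}
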