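# Translated (protein-space) screening of amplicon reads. Each read is
# aligned in all six frames against the reference protein set; the hit
# geometry then drives the two artefact rules:
#   frameshift - one reference matched in different frames over largely
#                disjoint regions of the read;
#   chimera    - two or more distinct reference origins matched over largely
#                disjoint regions.

# gapped BLOSUM62 (open 11 / extend 1) Karlin-Altschul constants
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Per-column scores of one aligned pair (gap run: -(open+ext) for the first
# column, -ext for the rest), used for hit-end trimming.
alignment_column_scores <- function(pat, sub, gap_open = 11, gap_ext = 1) {
  a <- strsplit(pat, "")[[1]]
  b <- strsplit(sub, "")[[1]]
  gap <- a == "-" | b == "-"
  s <- numeric(length(a))
  if (any(!gap)) {
    s[!gap] <- blosum62()[cbind(a[!gap], b[!gap])]
  }
  if (any(gap)) {
    first <- gap & !c(FALSE, gap[-length(gap)])
    s[gap] <- -gap_ext
    s[first] <- -(gap_open + gap_ext)
  }
  s
}

# Extract the hit's core: the maximum-scoring alignment segment after
# charging every column a small rent `delta`. A Smith-Waterman optimum can
# drag in weakly positive random flanks (expected column score just above
# 0), which blur the hit's region boundaries; under the rent such flanks
# are strongly negative while genuine homology (>= +3 per column at the
# divergences this pipeline targets) survives. Returns NULL when nothing
# survives.
trim_hit <- function(pat, sub, delta = 2) {
  s <- alignment_column_scores(pat, sub) - delta
  n <- length(s)
  # Kadane: best segment [i*, j*] of the rented scores
  best <- 0; best_i <- 0L; best_j <- -1L
  cur <- 0; cur_i <- 1L
  for (t in seq_len(n)) {
    if (cur <= 0) { cur <- s[t]; cur_i <- t } else cur <- cur + s[t]
    if (cur > best) { best <- cur; best_i <- cur_i; best_j <- t }
  }
  if (best_j < best_i) return(NULL)
  a <- strsplit(pat, "")[[1]]
  keep <- seq.int(best_i, best_j)
  list(
    score = sum(s[keep]) + delta * length(keep),
    # pattern residues removed from each end (gaps in pattern don't count)
    res_left = if (best_i > 1) sum(a[seq_len(best_i - 1L)] != "-") else 0L,
    res_right = if (best_j < n) {
      sum(a[seq.int(best_j + 1L, n)] != "-")
    } else 0L
  )
}

#' Six-frame translated search against a reference protein set
#'
#' Every read is translated in frames +1/+2/+3/-1/-2/-3 and locally aligned
#' (Smith-Waterman, BLOSUM62, gap open 11 / extend 1) against every
#' reference. Per (reference, frame) the best local alignment is retained as
#' one hit; hits are filtered by a Karlin-Altschul E-value
#' `E = K * m * n * exp(-lambda * S)` (m = translated query length, n =
#' total reference residues) and the top `k` per read are kept, ordered by
#' descending score with ties broken by subject id then query start.
#'
#' @param reads Read table (`read_id`, `seq`; forward-oriented,
#'   primer-trimmed) or named character vector of sequences.
#' @param refs Reference set (`data.frame` with `id`, `aa_seq`), e.g. from
#'   [make_reference_set()].
#' @param k Maximum hits per read (default 10).
#' @param evalue_cutoff E-value cutoff (default 0.001).
#' @param lambda,K Karlin-Altschul constants for gapped BLOSUM62-11-1.
#' @param core_delta Per-column rent used to extract each hit's core
#'   segment (see Details); removes weakly positive random flanks that
#'   would otherwise blur region boundaries. Set to 0 to disable.
#' @return `data.frame` of hits: `read_id`, `subject_id`, `frame`,
#'   `q_start`, `q_end` (1-based nt coordinates on the forward read),
#'   `score`, `evalue`.
#' @export
translated_search <- function(reads, refs, k = 10, evalue_cutoff = 0.001,
                              lambda = KA_LAMBDA, K = KA_K, core_delta = 2) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = names(reads), seq = unname(reads),
                        stringsAsFactors = FALSE)
  }
  if (nrow(refs) == 0) stop("empty reference set")
  n_res <- sum(nchar(refs$aa_seq))
  L <- nchar(reads$seq)
  hits <- list()
  for (frame in c(1, 2, 3, -1, -2, -3)) {
    aa <- translate_frame(reads$seq, frame)
    m_aa <- nchar(aa)
    ok <- m_aa >= 5
    if (!any(ok)) next
    pat <- Biostrings::AAStringSet(aa[ok])
    for (ri in seq_len(nrow(refs))) {
      # fast score-only pass; full alignments only for E-value survivors
      sc0 <- Biostrings::pairwiseAlignment(
        pat, Biostrings::AAString(refs$aa_seq[ri]),
        type = "local", substitutionMatrix = blosum62(),
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
      )
      ev0 <- K * m_aa[ok] * n_res * exp(-lambda * sc0)
      keep <- sc0 > 0 & ev0 <= evalue_cutoff
      if (!any(keep)) next
      al <- Biostrings::pairwiseAlignment(
        pat[keep], Biostrings::AAString(refs$aa_seq[ri]),
        type = "local", substitutionMatrix = blosum62(),
        gapOpening = 11, gapExtension = 1
      )
      sc <- Biostrings::score(al)
      ev <- ev0[keep]
      s_aa <- Biostrings::start(Biostrings::pattern(al))
      e_aa <- Biostrings::end(Biostrings::pattern(al))
      mq <- m_aa[ok][keep]
      if (core_delta > 0) {
        pa <- as.character(Biostrings::pattern(al))
        sa <- as.character(Biostrings::subject(al))
        ok2 <- logical(length(pa))
        for (hh in seq_along(pa)) {
          tr <- trim_hit(pa[hh], sa[hh], core_delta)
          if (is.null(tr)) next
          s_aa[hh] <- s_aa[hh] + tr$res_left
          e_aa[hh] <- e_aa[hh] - tr$res_right
          sc[hh] <- tr$score
          ok2[hh] <- TRUE
        }
        ev2 <- K * mq * n_res * exp(-lambda * sc)
        keep2 <- ok2 & sc > 0 & ev2 <= evalue_cutoff
        if (!any(keep2)) next
        s_aa <- s_aa[keep2]; e_aa <- e_aa[keep2]
        sc <- sc[keep2]
        ev <- ev2[keep2]
        keep[keep] <- keep2
      }
      li <- L[ok][keep]
      off <- abs(frame) - 1
      if (frame > 0) {
        qs <- off + 3 * (s_aa - 1) + 1
        qe <- off + 3 * e_aa
      } else {
        rs <- off + 3 * (s_aa - 1) + 1
        re <- off + 3 * e_aa
        qs <- li - re + 1
        qe <- li - rs + 1
      }
      hits[[length(hits) + 1]] <- data.frame(
        read_id = reads$read_id[ok][keep],
        subject_id = refs$id[ri],
        frame = as.integer(frame),
        q_start = qs, q_end = qe,
        score = sc, evalue = ev,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0) {
    return(data.frame(read_id = character(), subject_id = character(),
                      frame = integer(), q_start = integer(),
                      q_end = integer(), score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$read_id, -out$score, out$subject_id, out$q_start), ]
  out <- do.call(rbind, lapply(split(out, out$read_id), head, n = k))
  rownames(out) <- NULL
  out
}

# fraction of the shorter interval covered by the overlap
interval_overlap_frac <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
  ov / min(e1 - s1 + 1, e2 - s2 + 1)
}

classify_one <- function(h, max_region_overlap) {
  if (nrow(h) == 0) {
    return(list(verdict = "no_hit", best_subject = NA_character_,
                best_frame = NA_integer_))
  }
  best <- h[which.max(h$score), ]
  # frameshift: same subject, different frames, largely disjoint regions
  for (subj in unique(h$subject_id)) {
    hs <- h[h$subject_id == subj, , drop = FALSE]
    if (nrow(hs) < 2) next
    for (i in seq_len(nrow(hs) - 1)) {
      for (j in seq((i + 1), nrow(hs))) {
        if (hs$frame[i] != hs$frame[j] &&
            interval_overlap_frac(hs$q_start[i], hs$q_end[i],
                                  hs$q_start[j], hs$q_end[j]) <
              max_region_overlap) {
          return(list(verdict = "frameshift", best_subject = subj,
                      best_frame = best$frame))
        }
      }
    }
  }
  # chimera: best hits of distinct subjects occupy largely disjoint regions
  subs <- unique(h$subject_id)
  if (length(subs) >= 2) {
    bests <- do.call(rbind, lapply(subs, function(s) {
      hs <- h[h$subject_id == s, , drop = FALSE]
      hs[which.max(hs$score), , drop = FALSE]
    }))
    for (i in seq_len(nrow(bests) - 1)) {
      for (j in seq((i + 1), nrow(bests))) {
        if (interval_overlap_frac(bests$q_start[i], bests$q_end[i],
                                  bests$q_start[j], bests$q_end[j]) <
              max_region_overlap) {
          return(list(verdict = "chimera", best_subject = best$subject_id,
                      best_frame = best$frame))
        }
      }
    }
  }
  list(verdict = "valid", best_subject = best$subject_id,
       best_frame = best$frame)
}

#' Classify reads as valid / frameshift / chimera / no_hit
#'
#' Applies the frame-consistency frameshift rule and the multi-origin
#' chimera rule to the hit geometry from [translated_search()]. Two query
#' intervals count as "different regions" when their overlap is below
#' `max_region_overlap` of the shorter interval. The frameshift rule takes
#' precedence; two references hitting the *same* region (homologs) is not a
#' chimera.
#'
#' @param hits Hit table from [translated_search()].
#' @param read_ids All read ids that were searched (reads without hits
#'   become `no_hit`).
#' @param max_region_overlap Maximum mutual overlap fraction for two hits to
#'   count as different regions (default 0.2).
#' @return `data.frame` with one row per read: `read_id`, `verdict`,
#'   `best_subject`, `best_frame`.
#' @export
classify_reads <- function(hits, read_ids, max_region_overlap = 0.2) {
  by_read <- split(hits, factor(hits$read_id, levels = read_ids))
  res <- lapply(read_ids, function(id) {
    h <- by_read[[id]]
    if (is.null(h)) h <- hits[0, , drop = FALSE]
    classify_one(h, max_region_overlap)
  })
  data.frame(
    read_id = read_ids,
    verdict = vapply(res, `[[`, character(1), "verdict"),
    best_subject = vapply(res, `[[`, character(1), "best_subject"),
    best_frame = vapply(res, `[[`, integer(1), "best_frame"),
    stringsAsFactors = FALSE
  )
}

#' Translate a valid read in its best hit's frame
#'
#' Translates the hit's query interval in the hit's frame. An internal stop
#' codon truncates the product and sets the `truncated` flag.
#'
#' @param seq Nucleotide sequence of the read (forward orientation).
#' @param frame Frame of the best hit (+1..+3 / -1..-3).
#' @param q_start,q_end 1-based nt interval of the hit on the forward read.
#' @return List with `aa` (amino-acid string) and `truncated` (logical).
#' @export
translate_valid <- function(seq, frame, q_start = 1,
                            q_end = nchar(seq)) {
  L <- nchar(seq)
  if (q_start < 1 || q_end > L || q_start > q_end) {
    stop("hit interval inconsistent with read length")
  }
  if (frame > 0) {
    s <- seq; rs <- q_start; re <- q_end
  } else {
    s <- revcomp(seq)
    rs <- L - q_end + 1
    re <- L - q_start + 1
  }
  off <- abs(frame) - 1
  # snap the interval start onto the frame's codon grid
  shift <- (rs - (off + 1)) %% 3
  if (shift != 0) rs <- rs + (3 - shift)
  ncod <- (re - rs + 1) %/% 3
  if (ncod < 1) stop("hit interval inconsistent with frame")
  aa <- translate_frame(substr(s, rs, rs + 3 * ncod - 1), 1)
  truncated <- grepl("*", aa, fixed = TRUE)
  if (truncated) aa <- sub("\\*.*$", "", aa)
  list(aa = aa, truncated = truncated)
}

#' Full translated screen of a read set
#'
#' Convenience wrapper: search, classify, translate the valid reads.
#'
#' @inheritParams translated_search
#' @inheritParams classify_reads
#' @return List with `verdicts`, `hits`, and `aa` (`data.frame` of
#'   translated valid reads: `read_id`, `aa`, `truncated`).
#' @export
screen_reads <- function(reads, refs, k = 10, evalue_cutoff = 0.001,
                         max_region_overlap = 0.2) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = names(reads), seq = unname(reads),
                        stringsAsFactors = FALSE)
  }
  hits <- translated_search(reads, refs, k = k,
                            evalue_cutoff = evalue_cutoff)
  verdicts <- classify_reads(hits, reads$read_id, max_region_overlap)
  valid <- verdicts$read_id[verdicts$verdict == "valid"]
  aa <- do.call(rbind, lapply(valid, function(id) {
    h <- hits[hits$read_id == id, , drop = FALSE]
    b <- h[which.max(h$score), ]
    tr <- translate_valid(reads$seq[reads$read_id == id],
                          b$frame, b$q_start, b$q_end)
    data.frame(read_id = id, aa = tr$aa, truncated = tr$truncated,
               stringsAsFactors = FALSE)
  }))
  if (is.null(aa)) {
    aa <- data.frame(read_id = character(), aa = character(),
                     truncated = logical(), stringsAsFactors = FALSE)
  }
  list(verdicts = verdicts, hits = hits, aa = aa)
}
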