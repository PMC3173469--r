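# Monotonic-trend detection: which phylotypes continuously increased,
# decreased, appeared or disappeared across baseline -> year 1 -> year 2
# within each crop treatment.

#' Call the trend class of one abundance series
#'
#' Classes over the three ordered timepoints (c0 = baseline, c1, c2), on
#' depth-normalised counts:
#' * `appear` (++): c0 == 0, c1 > 0 and c2 > 0 (keyed on detection, so a
#'   flat 0,7,7 series is still `appear`);
#' * `disappear` (--): c0 > 0, c1 == 0 and c2 == 0;
#' * `increase` (+): strict c0 < c1 < c2;
#' * `decrease` (-): strict c0 > c1 > c2;
#' * `none` otherwise (a flat step breaks "continuously" changing).
#'
#' @param counts Numeric vector of exactly 3 non-negative counts.
#' @return One of `"appear"`, `"disappear"`, `"increase"`, `"decrease"`,
#'   `"none"`.
#' @export
call_trend <- function(counts) {
  if (length(counts) != 3) stop("exactly 3 timepoints are required")
  if (any(counts < 0)) stop("counts must be non-negative")
  c0 <- counts[1]; c1 <- counts[2]; c2 <- counts[3]
  if (c0 == 0 && c1 > 0 && c2 > 0) return("appear")
  if (c0 > 0 && c1 == 0 && c2 == 0) return("disappear")
  if (c0 < c1 && c1 < c2) return("increase")
  if (c0 > c1 && c1 > c2) return("decrease")
  "none"
}

#' Call trends for every (taxon, crop) series in an abundance table
#'
#' @param counts Taxon x sample count matrix; sample columns are mapped to
#'   (crop, timepoint) via `metadata`.
#' @param metadata `data.frame` with columns `sample`, `crop`, `timepoint`;
#'   `timepoint` must be an ordered factor or sortable labels with exactly 3
#'   levels per crop.
#' @return `data.frame` with one row per (taxon, crop): `taxon`, `crop`,
#'   `class`, `c0`, `c1`, `c2`.
#' @export
call_trends <- function(counts, metadata) {
  stopifnot(all(c("sample", "crop", "timepoint") %in% names(metadata)))
  crops <- unique(metadata$crop)
  out <- list()
  for (crop in crops) {
    md <- metadata[metadata$crop == crop, , drop = FALSE]
    md <- md[order(md$timepoint), , drop = FALSE]
    if (nrow(md) != 3) stop("crop ", crop, " must have exactly 3 timepoints")
    sub <- counts[, md$sample, drop = FALSE]
    cls <- apply(sub, 1, call_trend)
    out[[crop]] <- data.frame(
      taxon = rownames(counts), crop = crop, class = cls,
      c0 = sub[, 1], c1 = sub[, 2], c2 = sub[, 3],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Summarise changed phylotypes per gene
#'
#' Counts, per crop, the taxa with a non-`none` trend call, and per gene the
#' *unique* taxa changed in at least one crop. The changed percentage uses
#' the gene's pre-resampling OTU richness as denominator and is reported
#' both exactly and rounded half away from zero to one decimal (85 changed
#' of 309 OTUs -> 27.5%).
#'
#' @param calls Trend calls from [call_trends()]; an optional `gene` column
#'   splits the summary by gene.
#' @param totals Named numeric vector of total OTU richness per gene (or a
#'   scalar when `calls` has no `gene` column).
#' @return `data.frame` with one row per gene: per-crop changed counts,
#'   `unique_changed`, `total`, `percent_exact`, `percent`.
#' @export
summarize_changed <- function(calls, totals) {
  if (!"gene" %in% names(calls)) {
    calls$gene <- "gene"
    if (is.null(names(totals))) names(totals) <- "gene"
  }
  if (any(totals <= 0)) stop("empty input: zero total richness")
  genes <- unique(calls$gene)
  crops <- unique(calls$crop)
  rows <- lapply(genes, function(g) {
    cg <- calls[calls$gene == g, , drop = FALSE]
    changed <- cg[cg$class != "none", , drop = FALSE]
    per_crop <- vapply(crops, function(cr) {
      length(unique(changed$taxon[changed$crop == cr]))
    }, numeric(1))
    uniq <- length(unique(changed$taxon))
    tot <- totals[[g]]
    c(setNames(as.list(per_crop), crops),
      list(unique_changed = uniq, total = tot,
           percent_exact = 100 * uniq / tot,
           percent = round_half_up(100 * uniq / tot, 1)))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out <- cbind(data.frame(gene = genes, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Changed-fraction arithmetic from printed counts
#'
#' Direct helper for reproducing published changed-phylotype fractions from
#' a unique-changed count and a total richness.
#'
#' @param unique_changed Number of distinct changed taxa.
#' @param total Total OTU/genus richness.
#' @return Percentage, one decimal, half away from zero.
#' @export
changed_percent <- function(unique_changed, total) {
  if (total <= 0) stop("empty input: zero total richness")
  round_half_up(100 * unique_changed / total, 1)
}
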