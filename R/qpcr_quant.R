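# Absolute qPCR quantification: standard curves from dilution series,
# amplification efficiency E = 10^(-1/slope), sample-derived standards
# converted from mass concentration to copy number, copies per gram of dry
# soil, group comparison (ANOVA + Tukey), and rate-vs-log-abundance
# regression.

AVOGADRO <- 6.022e23

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of mean Cq on log10(input); replicate Cq values at
#' the same input are averaged first. Efficiency is `E = 10^(-1/slope)`.
#'
#' @param dilution_table `data.frame` with columns `log10_input` (or
#'   `dilution`, from which log10 is taken) and `cq`.
#' @return A `standard_curve`: `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `cq_range`, `n_points`.
#' @export
fit_standard_curve <- function(dilution_table) {
  if (!"log10_input" %in% names(dilution_table)) {
    if (!"dilution" %in% names(dilution_table)) {
      stop("need a log10_input or dilution column")
    }
    dilution_table$log10_input <- log10(dilution_table$dilution)
  }
  mean_cq <- tapply(dilution_table$cq, dilution_table$log10_input, mean)
  x <- as.numeric(names(mean_cq))
  y <- as.numeric(mean_cq)
  if (length(x) < 3) stop("need at least 3 dilution points")
  if (any(!is.finite(y))) stop("Cq values must be finite")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= -1e-12) {
    stop("degenerate curve: slope must be negative")
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = r2, efficiency = 10^(-1 / slope),
         cq_range = range(y), n_points = length(x)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: slope %.4f, intercept %.3f, R2 %.4f, E = %.3f\n",
    x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}

#' Copy number of a sample-derived standard
#'
#' Converts a dsDNA mass concentration to copies per microlitre using the
#' mean amplicon length: `mw = mean_len_bp * bp_mw` g/mol, `copies/uL =
#' conc * 1e-9 / mw * 6.022e23`.
#'
#' @param conc_ng_per_ul DNA concentration (ng/uL), > 0.
#' @param mean_len_bp Mean amplicon length in bp (e.g. estimated from the
#'   valid pyrosequencing reads plus primers), > 0.
#' @param bp_mw Mean molecular weight per double-stranded base pair
#'   (default 660 g/mol).
#' @return Copies per microlitre.
#' @export
standard_copies <- function(conc_ng_per_ul, mean_len_bp, bp_mw = 660) {
  if (conc_ng_per_ul <= 0 || mean_len_bp <= 0 || bp_mw <= 0) {
    stop("inputs must be positive")
  }
  conc_ng_per_ul * 1e-9 / (mean_len_bp * bp_mw) * AVOGADRO
}

#' Quantify a sample from its replicate Cq values
#'
#' Inverts the standard curve at the mean Cq to copies per ng of template
#' DNA, then scales to copies per gram of dry soil:
#' `copies_per_g = copies_per_ng * dna_ng_per_g / extraction_eff`.
#'
#' @param curve A [fit_standard_curve()] result calibrated in log10(copies
#'   per ng DNA).
#' @param cqs Replicate Cq values (typically a triplicate).
#' @param dna_ng_per_g Extracted DNA yield per gram of dry soil (default
#'   6230 ng/g, i.e. 6.23 ug/g).
#' @param extraction_eff Assumed DNA extraction efficiency (default 0.30).
#' @param detection_limit Copies below which the result is flagged censored
#'   (default 10, the assay's copies/uL detection limit).
#' @return List: `copies_per_ng`, `copies_per_g`, `mean_cq`,
#'   `below_detection`, `extrapolated`.
#' @export
quantify_sample <- function(curve, cqs, dna_ng_per_g = 6230,
                            extraction_eff = 0.30, detection_limit = 10) {
  stopifnot(inherits(curve, "standard_curve"))
  mean_cq <- mean(cqs)
  extrapolated <- mean_cq < curve$cq_range[1] || mean_cq > curve$cq_range[2]
  if (extrapolated) {
    warning("mean Cq outside the calibrated range; extrapolating")
  }
  log10_copies <- (mean_cq - curve$intercept) / curve$slope
  copies_per_ng <- 10^log10_copies
  list(
    copies_per_ng = copies_per_ng,
    copies_per_g = copies_per_ng * dna_ng_per_g / extraction_eff,
    mean_cq = mean_cq,
    below_detection = copies_per_ng < detection_limit,
    extrapolated = extrapolated
  )
}

# greedy compact-letter display from a logical "significantly different"
# matrix (insert-and-absorb is overkill at n = 4 groups)
tukey_letters <- function(sig) {
  g <- rownames(sig)
  sets <- list()
  for (gi in g) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (!any(sig[gi, sets[[k]]])) {
        sets[[k]] <- c(sets[[k]], gi)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- gi
  }
  letters_out <- setNames(rep("", length(g)), g)
  for (k in seq_along(sets)) {
    letters_out[sets[[k]]] <- paste0(letters_out[sets[[k]]], letters[k])
  }
  letters_out
}

#' Compare gene abundances between groups
#'
#' One-way ANOVA on log10 copies per gram followed by Tukey HSD pairwise
#' comparisons with a compact letter display (groups sharing a letter are
#' not separated at `alpha`).
#'
#' @param copies_per_g Positive abundances (copies per gram).
#' @param groups Grouping factor (>= 2 groups, each >= 2 replicates).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List: `anova` (`data.frame` with F and p), `tukey` (pairwise
#'   table), `letters`.
#' @export
compare_groups <- function(copies_per_g, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 replicates")
  y <- log10(copies_per_g)
  lv <- levels(groups)
  if (stats::var(y) < 1e-20) {
    # all observations identical: F is 0/0; report no separation
    return(list(
      anova = data.frame(F = NA_real_, p = NA_real_),
      tukey = data.frame(),
      letters = setNames(rep("a", length(lv)), lv)
    ))
  }
  fit <- aov(y ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  sig <- matrix(FALSE, nlevels(groups), nlevels(groups),
                dimnames = list(lv, lv))
  pr <- setNames(tk[, "p adj"], rownames(tk))
  for (nm in rownames(tk)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    s <- is.finite(pr[nm]) && pr[nm] < alpha
    sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- s
  }
  list(
    anova = data.frame(F = tab$`F value`[1], p = tab$`Pr(>F)`[1]),
    tukey = as.data.frame(tk),
    letters = tukey_letters(sig)
  )
}

#' Regress a process rate on log gene abundance
#'
#' OLS of `rate` on log10(copies per gram), reporting R-squared, the
#' two-sided p-value of the slope, and n (e.g. nitrification rate vs
#' archaeal amoA abundance).
#'
#' @param rates Numeric response (one per sample).
#' @param copies_per_g Positive abundances, paired with `rates`.
#' @return List: `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
regress_rate_on_logcopies <- function(rates, copies_per_g) {
  ok <- is.finite(rates) & is.finite(copies_per_g)
  rates <- rates[ok]; copies_per_g <- copies_per_g[ok]
  if (length(rates) < 3) stop("need at least 3 paired observations")
  x <- log10(copies_per_g)
  if (stats::sd(x) == 0) stop("degenerate predictor: zero variance")
  fit <- lm(rates ~ x)
  sm <- suppressWarnings(summary(fit))  # warns on perfect fits
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p = sm$coefficients[2, 4],
    n = length(rates)
  )
}
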