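# T-RFLP community analysis: in-silico terminal restriction digests,
# peak-table filtering and normalisation, Bray-Curtis dissimilarity, ANOSIM,
# and correspondence analysis.

# recognition site and cut offset (bases 5' of the cut, within the site)
RESTRICTION_ENZYMES <- list(
  AluI = list(site = "AGCT", cut = 2L),  # AG^CT
  HhaI = list(site = "GCGC", cut = 3L)   # GCG^C
)

#' In-silico terminal restriction fragment lengths
#'
#' The terminal restriction fragment (TRF) is the distance from the labelled
#' 5' end of the amplicon to the first cut position on the labelled strand;
#' an amplicon with no recognition site yields its full length.
#'
#' @param amplicon_nt Character vector of amplicons, 5'->3' on the labelled
#'   strand.
#' @param enzymes Enzyme names among `"AluI"` (AG^CT) and `"HhaI"` (GCG^C).
#' @return Numeric matrix, amplicons x enzymes, of TRF lengths in bp.
#' @export
insilico_digest <- function(amplicon_nt, enzymes = c("AluI", "HhaI")) {
  unknown <- setdiff(enzymes, names(RESTRICTION_ENZYMES))
  if (length(unknown) > 0) {
    stop("unknown enzyme(s): ", paste(unknown, collapse = ", "))
  }
  out <- sapply(enzymes, function(e) {
    enz <- RESTRICTION_ENZYMES[[e]]
    pos <- regexpr(enz$site, amplicon_nt, fixed = TRUE)
    ifelse(pos == -1L, nchar(amplicon_nt), as.integer(pos) - 1L + enz$cut)
  })
  out <- matrix(out, nrow = length(amplicon_nt),
                dimnames = list(names(amplicon_nt), enzymes))
  out
}

#' Filter and normalise one T-RFLP profile
#'
#' Keeps fragments with sizes between 50 bp and the amplicon length
#' (inclusive) and peak area strictly greater than `min_area`, then divides
#' each surviving area by their total. If everything is filtered the sample
#' is flagged empty (attribute `empty`).
#'
#' @param profile `data.frame` with columns `size`, `area`.
#' @param amplicon_len Length of the PCR product in bp.
#' @param min_size Minimum fragment size (default 50 bp).
#' @param min_area Peak-area threshold; strictly greater-than (default
#'   500).
#' @return `data.frame` with columns `size`, `rel_abundance`; attribute
#'   `empty` is `TRUE` when no peak survived.
#' @export
filter_normalize <- function(profile, amplicon_len, min_size = 50,
                             min_area = 500) {
  keep <- profile$size >= min_size & profile$size <= amplicon_len &
    profile$area > min_area
  kept <- profile[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    out <- data.frame(size = numeric(0), rel_abundance = numeric(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- data.frame(size = kept$size,
                    rel_abundance = kept$area / sum(kept$area))
  out <- out[order(out$size), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "empty") <- FALSE
  out
}

#' Build a community matrix from a T-RFLP peak table
#'
#' Applies [filter_normalize()] per sample and aligns fragments across
#' samples by integer-rounded size (a +/- 1 bp binning tolerance is
#' standard for matching empirical sizes to predicted ones).
#'
#' @param peaks `data.frame` with columns `sample`, `size`, `area`.
#' @param amplicon_len Length of the PCR product in bp.
#' @param min_size,min_area Passed to [filter_normalize()].
#' @return Samples x fragment-size matrix of relative abundances (rows sum
#'   to 1, or 0 for empty samples).
#' @export
trflp_community_matrix <- function(peaks, amplicon_len, min_size = 50,
                                   min_area = 500) {
  samples <- sort(unique(peaks$sample))
  profs <- lapply(samples, function(s) {
    p <- filter_normalize(peaks[peaks$sample == s, , drop = FALSE],
                          amplicon_len, min_size, min_area)
    p$size <- round(p$size)
    stats::aggregate(rel_abundance ~ size, p, sum)
  })
  sizes <- sort(unique(unlist(lapply(profs, `[[`, "size"))))
  m <- matrix(0, length(samples), length(sizes),
              dimnames = list(samples, as.character(sizes)))
  for (i in seq_along(profs)) {
    m[i, as.character(profs[[i]]$size)] <- profs[[i]]$rel_abundance
  }
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x_ik - x_jk| / sum (x_ik + x_jk)`, in \[0, 1\]. A pair of
#' all-zero rows has distance 0 (with a warning).
#'
#' @param mat Samples x features matrix of non-negative abundances.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
bray_curtis <- function(mat) {
  if (any(mat < 0)) stop("abundances must be non-negative")
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(mat[i, ] + mat[j, ])
      if (denom == 0) {
        if (!warned) {
          warning("all-zero sample pair; Bray-Curtis set to 0")
          warned <- TRUE
        }
        d[i, j] <- d[j, i] <- 0
      } else {
        d[i, j] <- d[j, i] <- sum(abs(mat[i, ] - mat[j, ])) / denom
      }
    }
  }
  d
}

anosim_r <- function(rk, within, n) {
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based test of between- versus within-group community distances:
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`.
#' The one-sided permutation p-value is `(#{R_perm >= R_obs} + 1) /
#' (n_perm + 1)`.
#'
#' @param dm Symmetric distance matrix.
#' @param groups Grouping factor (>= 2 groups, each >= 2 members).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed (the permutation stream is deterministic).
#' @return List: `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(dm, groups, n_perm = 999, seed = 1) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("singleton group not allowed")
  n <- nrow(dm)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  rk <- rank(dm[upper.tri(dm)])
  within_of <- function(g) g[pairs[, 1]] == g[pairs[, 2]]
  r_obs <- anosim_r(rk, within_of(groups), n)
  with_seed(seed, {
    r_perm <- vapply(seq_len(n_perm), function(i) {
      anosim_r(rk, within_of(sample(groups)), n)
    }, numeric(1))
    list(R = r_obs,
         p = (sum(r_perm >= r_obs) + 1) / (n_perm + 1),
         n_perm = n_perm)
  })
}

#' Correspondence analysis of a community table
#'
#' Singular value decomposition of the chi-square standardised residual
#' matrix `S = (P - r c') / sqrt(r c')` where `P` is the table divided by
#' its grand total. Axis k explains `100 * d_k^2 / sum(d^2)` percent of the
#' total inertia, and the total inertia equals the chi-square statistic of
#' the table divided by its grand total. Zero rows/columns are dropped with
#' a warning. Scores are reproducible up to axis sign.
#'
#' @param mat Non-negative samples x features matrix with positive total.
#' @return List: `sample_scores`, `feature_scores` (principal coordinates),
#'   `inertia_percent`, `total_inertia`.
#' @export
correspondence_analysis <- function(mat) {
  if (any(mat < 0)) stop("matrix must be non-negative")
  if (sum(mat) <= 0) stop("grand total must be positive")
  zr <- rowSums(mat) == 0
  zc <- colSums(mat) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s)")
    mat <- mat[!zr, !zc, drop = FALSE]
  }
  P <- mat / sum(mat)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  keep <- sv$d > 1e-12
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  inertia <- d^2
  sample_scores <- sweep(u, 1, sqrt(r), "/") %*% diag(d, length(d))
  feature_scores <- sweep(v, 1, sqrt(cc), "/") %*% diag(d, length(d))
  rownames(sample_scores) <- rownames(mat)
  rownames(feature_scores) <- colnames(mat)
  colnames(sample_scores) <- colnames(feature_scores) <-
    sprintf("CA%d", seq_along(d))
  list(
    sample_scores = sample_scores,
    feature_scores = feature_scores,
    inertia_percent = 100 * inertia / sum(inertia),
    total_inertia = sum(inertia)
  )
}
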