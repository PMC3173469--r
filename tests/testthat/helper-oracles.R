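# Independent oracles used to cross-check the package implementation.
# Everything here is written from first principles and must not call the
# package functions it is checking.

# --- pairwise identity by direct position count (equal-length sequences) ---
hamming_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  sum(va == vb) / length(va)
}

mean_pairwise_identity <- function(seqs) {
  n <- length(seqs)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + hamming_identity(seqs[i], seqs[j])
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

# --- ends-free (overlap) Needleman-Wunsch with affine gaps, plus the
# DOTUR-style distance, as an independent dynamic program ---------------
# scoring must mirror the implementation: match +1, mismatch -1,
# gap = -(open + ext * len) with open 2, ext 1
nw_overlap_align <- function(a, b, match = 1, mismatch = -1,
                             open = 2, ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in y (x consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in x (y consumed)
  M[1, ] <- 0; M[, 1] <- 0        # free terminal gaps
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  # best end on last row or column, any state
  best <- NEG; bi <- n + 1; bj <- m + 1; bs <- "M"
  for (j in 2:(m + 1)) {
    for (st in c("M", "X", "Y")) {
      v <- switch(st, M = M[n + 1, j], X = X[n + 1, j], Y = Y[n + 1, j])
      if (v > best) { best <- v; bi <- n + 1; bj <- j; bs <- st }
    }
  }
  for (i in 2:(n + 1)) {
    for (st in c("M", "X", "Y")) {
      v <- switch(st, M = M[i, m + 1], X = X[i, m + 1], Y = Y[i, m + 1])
      if (v > best) { best <- v; bi <- i; bj <- m + 1; bs <- st }
    }
  }
  # traceback through the overlap region only
  ap <- character(0); as_ <- character(0)
  i <- bi; j <- bj; st <- bs
  while (i > 1 && j > 1) {
    if (st == "M") {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      prev <- c(M = M[i - 1, j - 1], X = X[i - 1, j - 1],
                Y = Y[i - 1, j - 1])
      st_new <- names(prev)[which.max(prev)]
      ap <- c(x[i - 1], ap); as_ <- c(y[j - 1], as_)
      i <- i - 1; j <- j - 1
      if (i == 1 || j == 1) break
      st <- st_new
    } else if (st == "X") {
      from_m <- M[i - 1, j] - open - ext
      ap <- c(x[i - 1], ap); as_ <- c("-", as_)
      st <- if (X[i, j] == from_m) "M" else "X"
      i <- i - 1
    } else {
      from_m <- M[i, j - 1] - open - ext
      ap <- c("-", ap); as_ <- c(y[j - 1], as_)
      st <- if (Y[i, j] == from_m) "M" else "Y"
      j <- j - 1
    }
  }
  list(score = best, pattern = paste(ap, collapse = ""),
       subject = paste(as_, collapse = ""))
}

# distance on the overlap alignment: 1 - matches / (paired columns +
# internal gap runs); recoded here independently of the package
nw_distance <- function(a, b) {
  al <- nw_overlap_align(a, b)
  p <- strsplit(al$pattern, "")[[1]]
  s <- strsplit(al$subject, "")[[1]]
  gap <- p == "-" | s == "-"
  runs <- rle(gap)
  n_runs <- sum(runs$values)
  paired <- sum(!gap)
  matches <- sum(p[!gap] == s[!gap])
  1 - matches / (paired + n_runs)
}

# --- naive furthest-neighbour agglomeration (recomputes every linkage from
# the raw matrix at every step; no Lance-Williams update) ----------------
naive_complete_linkage <- function(dm, cutoff) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- Inf; pick <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        link <- max(dm[clusters[[i]], clusters[[j]]])
        a1 <- min(clusters[[i]]); a2 <- min(clusters[[j]])
        key <- c(min(a1, a2), max(a1, a2))
        if (link < best ||
            (link == best && (key[1] < pick$key[1] ||
              (key[1] == pick$key[1] && key[2] < pick$key[2])))) {
          best <- link
          pick <- list(i = i, j = j, key = key)
        }
      }
    }
    if (best > cutoff) break
    clusters[[pick$i]] <- c(clusters[[pick$i]], clusters[[pick$j]])
    clusters[[pick$j]] <- NULL
  }
  # canonical membership vector
  memb <- integer(n)
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  memb
}

# partitions as label-independent canonical strings
canonical_partition <- function(memb) {
  paste(vapply(split(seq_along(memb), memb), paste, "", collapse = ","),
        collapse = ";")
}

# --- exhaustive ANOSIM for two groups of 3 (all 20 relabelings) ---------
anosim_exhaustive_p <- function(dm, groups) {
  n <- nrow(dm)
  rk <- matrix(0, n, n)
  rk[upper.tri(rk)] <- rank(dm[upper.tri(dm)])
  rk <- rk + t(rk)
  stat <- function(g) {
    w <- c(); b <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (g[i] == g[j]) w <- c(w, rk[i, j]) else b <- c(b, rk[i, j])
    }
    (mean(b) - mean(w)) / (n * (n - 1) / 4)
  }
  obs <- stat(groups)
  combos <- utils::combn(n, sum(groups == groups[1]))
  rs <- apply(combos, 2, function(idx) {
    g <- rep("B", n); g[idx] <- "A"
    stat(g)
  })
  mean(rs >= obs - 1e-12)
}

# --- chi-square statistic of a contingency table, by hand ---------------
chisq_stat <- function(m) {
  N <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / N
  sum((m - e)^2 / e)
}

# --- closed-form two-group one-way ANOVA F ------------------------------
two_group_f <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  gm <- mean(c(x1, x2))
  ssb <- n1 * (mean(x1) - gm)^2 + n2 * (mean(x2) - gm)^2
  ssw <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  (ssb / 1) / (ssw / (n1 + n2 - 2))
}
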