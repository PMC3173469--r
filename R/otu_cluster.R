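# Dereplication, alignment-based pairwise distances, furthest-neighbour OTU
# clustering, analytic rarefaction, and re-sampling to common depth.

#' Dereplicate sequences
#'
#' Exact duplicates and exact-prefix duplicates collapse to one record whose
#' representative is the longest member (ties broken by lexicographically
#' smallest id). Per-sample multiplicities are preserved.
#'
#' @param seqs Character vector of sequences.
#' @param ids Sequence ids (defaults to `names(seqs)` or `seq1..seqN`).
#' @param samples Sample label per sequence (defaults to one sample
#'   `"all"`).
#' @return List with `unique` (`data.frame`: `rep_id`, `seq`), `map`
#'   (`data.frame`: `id`, `rep_id`) and `counts` (unique x sample
#'   multiplicity matrix).
#' @export
dereplicate <- function(seqs, ids = NULL,
                        samples = rep("all", length(seqs))) {
  if (is.null(ids)) {
    ids <- if (!is.null(names(seqs))) names(seqs) else
      sprintf("seq%d", seq_along(seqs))
  }
  stopifnot(length(ids) == length(seqs), length(samples) == length(seqs))
  ord <- order(-nchar(seqs), ids)
  rep_seq <- character(0)
  rep_id <- character(0)
  assign_to <- integer(length(seqs))
  for (i in ord) {
    hit <- which(startsWith(rep_seq, seqs[i]))
    if (length(hit) > 0) {
      assign_to[i] <- hit[1]
    } else {
      rep_seq <- c(rep_seq, seqs[i])
      rep_id <- c(rep_id, ids[i])
      assign_to[i] <- length(rep_seq)
    }
  }
  smp <- sort(unique(samples))
  counts <- matrix(0L, nrow = length(rep_seq), ncol = length(smp),
                   dimnames = list(rep_id, smp))
  for (i in seq_along(seqs)) {
    counts[assign_to[i], samples[i]] <- counts[assign_to[i], samples[i]] + 1L
  }
  list(
    unique = data.frame(rep_id = rep_id, seq = rep_seq,
                        stringsAsFactors = FALSE),
    map = data.frame(id = ids, rep_id = rep_id[assign_to],
                     stringsAsFactors = FALSE),
    counts = counts
  )
}

# identity-scoring substitution matrix over an alphabet
identity_submat <- function(alphabet, match = 1, mismatch = -1) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

# distance from one pairwise alignment: 1 - matches / (aligned columns with
# both residues + internal gap runs); terminal gaps are excluded by the
# ends-free alignment itself
aligned_distance <- function(p, s) {
  a <- strsplit(p, "")[[1]]
  b <- strsplit(s, "")[[1]]
  gap <- a == "-" | b == "-"
  both <- !gap
  matches <- sum(a[both] == b[both])
  r <- rle(gap)
  gap_runs <- sum(r$values)
  denom <- sum(both) + gap_runs
  if (denom == 0) return(1)
  1 - matches / denom
}

#' Pairwise alignment distances
#'
#' Global (ends-free) pairwise alignment of every sequence pair; distance is
#' `1 - identity` where identity = matches / aligned positions, terminal
#' gaps are excluded, and each internal gap run counts as a single
#' difference (the DOTUR/mothur convention).
#'
#' @param seqs Named character vector (>= 2 sequences).
#' @param space `"amino_acid"` or `"nucleotide"` (controls the alignment
#'   alphabet only; the scoring is identity-based in both).
#' @return Symmetric distance matrix with zero diagonal, values in \[0, 1\].
#' @export
pairwise_distances <- function(seqs, space = c("amino_acid", "nucleotide")) {
  space <- match.arg(space)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (any(nchar(seqs) == 0)) stop("empty sequence")
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  n <- length(seqs)
  alph <- if (space == "amino_acid") {
    strsplit("ARNDCQEGHILKMFPSTWYVBZJUOX*", "")[[1]]
  } else {
    c("A", "C", "G", "T", "N")
  }
  sm <- identity_submat(alph)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  strset <- if (space == "amino_acid") Biostrings::AAStringSet else
    Biostrings::DNAStringSet
  xs <- strset(unname(seqs))
  for (i in seq_len(n - 1)) {
    al <- Biostrings::pairwiseAlignment(
      xs[(i + 1):n], xs[[i]],
      type = "overlap", substitutionMatrix = sm,
      gapOpening = 2, gapExtension = 1
    )
    pa <- as.character(Biostrings::alignedPattern(al))
    sa <- as.character(Biostrings::alignedSubject(al))
    for (jj in seq_along(pa)) {
      j <- i + jj
      d[i, j] <- d[j, i] <- aligned_distance(pa[jj], sa[jj])
    }
  }
  d
}

#' Cluster sequences into OTUs by agglomeration
#'
#' Furthest-neighbour (complete-linkage) agglomeration by default: clusters
#' are merged in order of increasing linkage distance while the linkage is
#' at most `cutoff`, so every OTU's maximum intra-cluster distance is
#' `<= cutoff`. Merge ties are broken by the smallest (row, column) label
#' pair.
#'
#' @param dm Symmetric distance matrix (labels in dimnames).
#' @param cutoff Distance threshold in \[0, 1\] (0.10 reproduces a 90%
#'   amino-acid similarity cutoff; 0.03 a 97% nucleotide cutoff).
#' @param counts Optional unique x sample multiplicity matrix (rows in
#'   `rownames(dm)` order) to aggregate into the OTU table.
#' @param method `"furthest"` (default), `"nearest"` or `"average"`.
#' @return An `otu_table`: list with `counts` (OTU x sample), `members`
#'   (list of member labels), `representative`, `cutoff`, `method`.
#' @export
cluster_otus <- function(dm, cutoff, counts = NULL,
                         method = c("furthest", "nearest", "average")) {
  method <- match.arg(method)
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  labels <- rownames(dm)
  n <- nrow(dm)
  if (is.null(counts)) {
    counts <- matrix(1L, n, 1, dimnames = list(labels, "all"))
  }
  # active cluster bookkeeping; linkage matrix updated by Lance-Williams
  D <- dm
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  anchor <- seq_len(n)  # smallest original index in each cluster
  while (sum(active) > 1) {
    ai <- which(active)
    sub <- D[ai, ai, drop = FALSE]
    diag(sub) <- Inf
    mn <- min(sub)
    if (mn > cutoff) break
    # tie-break: smallest (anchor_i, anchor_j) pair
    cand <- which(sub == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pa <- anchor[ai[cand[, 1]]]
    pb <- anchor[ai[cand[, 2]]]
    lo <- pmin(pa, pb); hi <- pmax(pa, pb)
    pick <- order(lo, hi)[1]
    i <- ai[cand[pick, 1]]; j <- ai[cand[pick, 2]]
    if (anchor[j] < anchor[i]) { tmp <- i; i <- j; j <- tmp }
    upd <- setdiff(ai, c(i, j))
    D[i, upd] <- D[upd, i] <- switch(method,
      furthest = pmax(D[i, upd], D[j, upd]),
      nearest  = pmin(D[i, upd], D[j, upd]),
      average  = (sizes[i] * D[i, upd] + sizes[j] * D[j, upd]) /
                   (sizes[i] + sizes[j])
    )
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    anchor[i] <- min(anchor[i], anchor[j])
    active[j] <- FALSE
  }
  keep <- which(active)
  keep <- keep[order(anchor[keep])]
  member_labels <- lapply(members[keep], function(m) labels[sort(m)])
  otu_counts <- t(vapply(members[keep], function(m) {
    colSums(counts[m, , drop = FALSE])
  }, numeric(ncol(counts))))
  if (ncol(counts) == 1) otu_counts <- matrix(otu_counts, ncol = 1,
                                              dimnames = list(NULL,
                                                colnames(counts)))
  rep_ids <- vapply(member_labels, `[`, character(1), 1)
  rownames(otu_counts) <- sprintf("OTU%04d", seq_along(keep))
  structure(
    list(counts = otu_counts, members = member_labels,
         representative = rep_ids, cutoff = cutoff, method = method),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "OTUs x", ncol(x$counts),
      "samples (cutoff", x$cutoff, ",", x$method, "linkage)\n")
  invisible(x)
}

#' Analytic rarefaction curve
#'
#' Expected OTU richness in a without-replacement subsample of size `m`:
#' `E[S_m] = S - sum_i C(N - N_i, m) / C(N, m)` (hypergeometric
#' expectation), evaluated on one sample of an OTU table.
#'
#' @param otu_table An `otu_table` (or bare OTU x sample count matrix).
#' @param sample Sample (column) name or index.
#' @param grid Subsample sizes (each <= the sample's depth).
#' @return `data.frame` with columns `m`, `expected_otus`.
#' @export
rarefaction_curve <- function(otu_table, sample = 1, grid = NULL) {
  counts <- if (inherits(otu_table, "otu_table")) otu_table$counts else
    otu_table
  ni <- counts[, sample]
  ni <- ni[ni > 0]
  N <- sum(ni)
  if (is.null(grid)) grid <- unique(round(seq(1, N, length.out = 20)))
  if (any(grid > N)) stop("grid value exceeds sample depth (", N, ")")
  S <- length(ni)
  es <- vapply(grid, function(m) {
    S - sum(exp(lchoose(N - ni, m) - lchoose(N, m)))
  }, numeric(1))
  data.frame(m = grid, expected_otus = es)
}

#' Re-sample an OTU table to a common depth
#'
#' Per-sample multivariate hypergeometric draw (without replacement), e.g.
#' to 697 reads/sample for the N-cycling genes or 1789 for 16S, so richness
#' comparisons are made at equal sequencing effort.
#'
#' @param otu_table An `otu_table`.
#' @param depth Target depth (<= every sample's total).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A new `otu_table` whose column sums all equal `depth`.
#' @export
resample_to_depth <- function(otu_table, depth, seed) {
  counts <- otu_table$counts
  tot <- colSums(counts)
  bad <- tot < depth
  if (any(bad)) {
    stop("depth ", depth, " exceeds total of sample(s): ",
         paste(colnames(counts)[bad], collapse = ", "))
  }
  with_seed(seed, {
    new_counts <- counts
    for (j in seq_len(ncol(counts))) {
      pool <- rep(seq_len(nrow(counts)), counts[, j])
      take <- pool[sample.int(length(pool), depth)]
      new_counts[, j] <- tabulate(take, nbins = nrow(counts))
    }
    out <- otu_table
    out$counts <- new_counts
    out
  })
}
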