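test_that("dereplicate collapses duplicates and exact prefixes", {
  out <- dereplicate(c("MAKV", "MAKV", "MAK"),
                     ids = c("a", "b", "c"))
  expect_equal(nrow(out$unique), 1)
  expect_equal(out$unique$seq, "MAKV")
  expect_equal(sum(out$counts), 3)
  # representative is the longest member, ties by smallest id
  expect_equal(out$unique$rep_id, "a")

  # all distinct: identity mapping
  out2 <- dereplicate(c("AAA", "CCC", "GGG"), ids = c("x", "y", "z"))
  expect_equal(nrow(out2$unique), 3)
  expect_identical(out2$map$rep_id, out2$map$id)

  # 1000 planted duplicates vs a hash-count oracle
  set.seed(19)
  base <- vapply(1:40, function(i) {
    paste(sample(LETTERS[1:20], 30, TRUE), collapse = "")
  }, character(1))
  idx <- sample(40, 1000, TRUE)
  seqs <- base[idx]
  samples <- sample(c("s1", "s2"), 1000, TRUE)
  out3 <- dereplicate(seqs, ids = sprintf("q%04d", 1:1000),
                      samples = samples)
  oracle <- table(factor(seqs, levels = base))
  got <- rowSums(out3$counts)[match(base, out3$unique$seq)]
  expect_equal(unname(got), as.numeric(oracle))
  expect_equal(sum(out3$counts), 1000)
})

test_that("pairwise_distances matches hand values and an independent DP", {
  expect_equal(
    pairwise_distances(c(a = "AAAA", b = "AAAA"), "nucleotide")["a", "b"],
    0
  )
  expect_equal(
    pairwise_distances(c(a = "AAAA", b = "AATA"), "nucleotide")["a", "b"],
    0.25
  )
  # 10 synthetic amino-acid sequences vs the Needleman-Wunsch oracle
  set.seed(57)
  anc <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 60, TRUE)
  seqs <- vapply(1:10, function(i) {
    s <- anc
    mut <- runif(60) < 0.25
    s[mut] <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                     sum(mut), TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%02d", 1:10)
  d <- pairwise_distances(seqs, "amino_acid")
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(d[i, j], nw_distance(seqs[i], seqs[j]),
                   tolerance = 1e-12)
    }
  }
  expect_error(pairwise_distances(c(a = "", b = "AA")), "empty")
})

test_that("cluster_otus: worked example, zero cutoff, linkage property", {
  dm <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dm["A", "B"] <- dm["B", "A"] <- 0.05
  dm["A", "C"] <- dm["C", "A"] <- 0.5
  dm["B", "C"] <- dm["C", "B"] <- 0.5
  ot <- cluster_otus(dm, 0.10)
  expect_equal(length(ot$members), 2)
  expect_setequal(ot$members[[1]], c("A", "B"))
  expect_equal(ot$members[[2]], "C")

  # cutoff 0: every unique its own OTU
  ot0 <- cluster_otus(dm, 0)
  expect_equal(length(ot0$members), 3)

  # planted clusters: 30 sequences in 4 groups
  set.seed(61)
  n_per <- c(8, 8, 7, 7)
  dm2 <- matrix(0.4 + runif(30 * 30, -0.02, 0.02), 30, 30)
  dm2 <- (dm2 + t(dm2)) / 2
  start <- cumsum(c(1, n_per))[1:4]
  memb_true <- rep(1:4, n_per)
  for (g in 1:4) {
    i <- which(memb_true == g)
    dm2[i, i] <- 0.05
  }
  diag(dm2) <- 0
  dimnames(dm2) <- list(sprintf("u%02d", 1:30), sprintf("u%02d", 1:30))
  ot2 <- cluster_otus(dm2, 0.10)
  expect_equal(length(ot2$members), 4)
  got_memb <- integer(30)
  for (k in seq_along(ot2$members)) {
    got_memb[match(ot2$members[[k]], rownames(dm2))] <- k
  }
  expect_equal(canonical_partition(got_memb),
               canonical_partition(memb_true))

  # complete-linkage property: max intra-OTU distance <= cutoff
  for (k in seq_along(ot2$members)) {
    i <- match(ot2$members[[k]], rownames(dm2))
    expect_lte(max(dm2[i, i]), 0.10)
  }
})

test_that("cluster_otus agrees with a naive re-computing agglomerator", {
  set.seed(71)
  for (trial in 1:10) {
    n <- sample(5:12, 1)
    dm <- matrix(runif(n * n, 0, 0.6), n, n)
    dm <- (dm + t(dm)) / 2
    diag(dm) <- 0
    dimnames(dm) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
    cutoff <- runif(1, 0.1, 0.4)
    ot <- cluster_otus(dm, cutoff)
    memb <- integer(n)
    for (k in seq_along(ot$members)) {
      memb[match(ot$members[[k]], rownames(dm))] <- k
    }
    oracle <- naive_complete_linkage(dm, cutoff)
    expect_equal(canonical_partition(memb), canonical_partition(oracle))
  }
})

test_that("OTU count is non-increasing in the cutoff (lumping)", {
  set.seed(77)
  n <- 15
  dm <- matrix(runif(n * n), n, n); dm <- (dm + t(dm)) / 2; diag(dm) <- 0
  dimnames(dm) <- list(sprintf("y%02d", 1:n), sprintf("y%02d", 1:n))
  sizes <- vapply(seq(0, 1, 0.1), function(co) {
    length(cluster_otus(dm, co)$members)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("rarefaction: exact endpoints and Monte-Carlo agreement", {
  counts <- matrix(c(40, 25, 20, 10, 5), ncol = 1,
                   dimnames = list(sprintf("o%d", 1:5), "s1"))
  ot <- structure(list(counts = counts), class = "otu_table")
  N <- sum(counts)
  rc <- rarefaction_curve(ot, "s1", grid = c(1, 50, N))
  expect_equal(rc$expected_otus[1], 1)
  expect_equal(rc$expected_otus[3], 5)
  expect_true(all(diff(rc$expected_otus) >= 0))
  # Monte-Carlo oracle at m = 50
  set.seed(83)
  pool <- rep(1:5, counts)
  n_mc <- 4000
  draws <- vapply(seq_len(n_mc), function(i) {
    length(unique(pool[sample.int(N, 50)]))
  }, numeric(1))
  se <- stats::sd(draws) / sqrt(n_mc)
  expect_lt(abs(rc$expected_otus[2] - mean(draws)), 3 * se)
  expect_error(rarefaction_curve(ot, "s1", grid = N + 1), "exceeds")
})

test_that("resample_to_depth: determinism, edge cases, mean behaviour", {
  counts <- matrix(c(60, 30, 10, 80, 15, 5), ncol = 2,
                   dimnames = list(c("o1", "o2", "o3"), c("s1", "s2")))
  ot <- structure(list(counts = counts), class = "otu_table")
  # depth = total: unchanged
  same <- resample_to_depth(ot, 100, seed = 1)
  expect_equal(same$counts, counts)
  # deterministic given seed
  a <- resample_to_depth(ot, 40, seed = 5)
  b <- resample_to_depth(ot, 40, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_true(all(colSums(a$counts) == 40))
  # single-OTU sample
  one <- structure(list(counts = matrix(c(50, 0), ncol = 1,
                        dimnames = list(c("o1", "o2"), "s"))),
                   class = "otu_table")
  expect_equal(resample_to_depth(one, 20, seed = 2)$counts["o1", "s"], 20)
  # error names the offending sample
  expect_error(resample_to_depth(ot, 150, seed = 1), "s1")
  # hypergeometric mean: mean count ~ depth * proportion
  reps <- vapply(1:400, function(s) {
    resample_to_depth(ot, 50, seed = s)$counts["o1", "s1"]
  }, numeric(1))
  mu <- 50 * 60 / 100
  # variance of the multivariate hypergeometric component
  v <- 50 * 0.6 * 0.4 * (100 - 50) / (100 - 1)
  expect_lt(abs(mean(reps) - mu), 3 * sqrt(v / 400))
})
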