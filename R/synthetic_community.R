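# Synthetic community generator: produces every input the pipeline consumes
# (references, barcoded reads, qPCR plates, T-RFLP peak tables) with full
# ground truth, emulating a 4-crop x (baseline + 2 years) field design.

GENE_FAMILIES <- c("nifH", "amoA_archaea", "amoA_bacteria", "nosZ")

# Approximate amplicon lengths (nt) of the commonly used primer sets for each
# marker gene, rounded to whole codons. Configurable everywhere; these are
# conventional values, not measured quantities.
AMPLICON_NT <- c(
  nifH = 360L, amoA_archaea = 633L, amoA_bacteria = 489L, nosZ = 453L
)

TREND_CLASSES <- c("increase", "decrease", "appear", "disappear", "stable")

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Robinson & Robinson (1991) background amino-acid frequencies; using a
# realistic composition keeps the expected BLOSUM62 score of unrelated
# sequence pairs negative, as alignment statistics assume
AA_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
  Y = 0.032, V = 0.066
)

# amino acid -> coding codons (stops excluded)
aa_codons <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      gc <- Biostrings::GENETIC_CODE
      tbl <<- split(names(gc), unname(gc))
      tbl[["*"]] <<- NULL
    }
    tbl
  }
})

#' Generate a synthetic reference protein set for a gene family
#'
#' All references descend from one random ancestor by independent per-site
#' amino-acid substitution, so the expected pairwise identity decreases with
#' `divergence`. Coding nucleotide sequences are produced by uniform
#' synonymous back-translation and therefore contain no internal stop codons.
#'
#' @param family One of `"nifH"`, `"amoA_archaea"`, `"amoA_bacteria"`,
#'   `"nosZ"`.
#' @param n_refs Number of reference proteins (>= 1).
#' @param mean_aa_len Protein length in residues (>= 50).
#' @param divergence Per-site substitution probability from the ancestor,
#'   in (0, 0.5).
#' @param seed Integer seed; output is byte-identical for identical seeds.
#' @return A `data.frame` with columns `id`, `family`, `aa_seq`, `nt_seq`.
#' @export
make_reference_set <- function(family, n_refs, mean_aa_len, divergence, seed) {
  family <- match.arg(family, GENE_FAMILIES)
  if (n_refs < 1) stop("n_refs must be >= 1")
  if (!(divergence > 0 && divergence < 0.5)) {
    stop("divergence must lie in (0, 0.5)")
  }
  if (mean_aa_len < 50) stop("mean_aa_len must be >= 50")
  aas <- names(AA_BACKGROUND)
  with_seed(seed, {
    anc <- sample(aas, mean_aa_len, replace = TRUE, prob = AA_BACKGROUND)
    refs <- lapply(seq_len(n_refs), function(i) {
      aa <- anc
      hit <- runif(mean_aa_len) < divergence
      if (any(hit)) {
        aa[hit] <- vapply(
          aa[hit],
          function(a) {
            keep <- aas != a
            sample(aas[keep], 1, prob = AA_BACKGROUND[keep])
          },
          character(1)
        )
      }
      nt <- vapply(aa, function(a) {
        cods <- aa_codons()[[a]]
        cods[sample.int(length(cods), 1)]
      }, character(1))
      list(aa = paste(aa, collapse = ""), nt = paste(nt, collapse = ""))
    })
    data.frame(
      id = sprintf("%s_ref%02d", family, seq_len(n_refs)),
      family = family,
      aa_seq = vapply(refs, `[[`, character(1), "aa"),
      nt_seq = vapply(refs, `[[`, character(1), "nt"),
      stringsAsFactors = FALSE
    )
  })
}

#' Describe a synthetic community experiment
#'
#' Encodes the field design: crop treatments, ordered timepoints (baseline +
#' two growing seasons), one trend class per (taxon, crop), and the read-level
#' artefact rates. Per-(crop, timepoint) relative abundances are derived from
#' the baseline abundance and the trend class (2-fold change per step for
#' increase/decrease; exact zeros for the absent phases of appear/disappear)
#' and renormalised to sum to one.
#'
#' @param taxa `data.frame` with columns `taxon` (must match reference ids)
#'   and `baseline` (relative abundance before renormalisation).
#' @param trends Character matrix, rows = taxa, columns = crops, entries in
#'   `c("increase","decrease","appear","disappear","stable")`. A single class
#'   is recycled to all (taxon, crop) pairs.
#' @param crops Treatment labels.
#' @param timepoints Ordered timepoint labels (exactly 3: baseline, year 1,
#'   year 2).
#' @param read_depth Reads per (crop, timepoint) sample.
#' @param chimera_rate,frameshift_rate Per-read artefact probabilities in
#'   \[0, 1\].
#' @param reverse_frac Fraction of reads emitted in reverse orientation.
#' @param low_quality_frac Fraction of reads with degraded (mean Phred 15)
#'   qualities.
#' @param seed Integer seed driving all randomness downstream.
#' @return An object of class `community_design`.
#' @export
community_design <- function(taxa, trends = "stable",
                             crops = c("MG", "PV", "NP", "ZM"),
                             timepoints = c("t0", "t1", "t2"),
                             read_depth = 2000,
                             chimera_rate = 0, frameshift_rate = 0,
                             reverse_frac = 0, low_quality_frac = 0,
                             seed = 1) {
  stopifnot(is.data.frame(taxa), all(c("taxon", "baseline") %in% names(taxa)))
  if (length(timepoints) != 3) stop("exactly 3 timepoints are required")
  n <- nrow(taxa)
  if (is.character(trends) && length(trends) == 1) {
    trends <- matrix(trends, n, length(crops))
  }
  trends <- as.matrix(trends)
  dimnames(trends) <- list(taxa$taxon, crops)
  if (!all(trends %in% TREND_CLASSES)) {
    stop("unknown trend class; allowed: ", paste(TREND_CLASSES, collapse = ", "))
  }
  for (r in c(chimera_rate, frameshift_rate, reverse_frac, low_quality_frac)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  # abundance array: taxon x crop x timepoint
  ab <- array(0, dim = c(n, length(crops), 3),
              dimnames = list(taxa$taxon, crops, timepoints))
  prof <- function(class, b) {
    switch(class,
      stable    = c(b, b, b),
      increase  = c(b, 2 * b, 4 * b),
      decrease  = c(b, b / 2, b / 4),
      appear    = c(0, b, b),
      disappear = c(b, 0, 0)
    )
  }
  for (i in seq_len(n)) {
    for (j in seq_along(crops)) {
      ab[i, j, ] <- prof(trends[i, j], taxa$baseline[i])
    }
  }
  for (j in seq_along(crops)) {
    for (k in 1:3) {
      s <- sum(ab[, j, k])
      if (s <= 0) stop("all-zero abundance at (", crops[j], ", ",
                       timepoints[k], ")")
      ab[, j, k] <- ab[, j, k] / s
    }
  }
  structure(
    list(taxa = taxa, trends = trends, crops = crops,
         timepoints = timepoints, abundance = ab,
         read_depth = read_depth, chimera_rate = chimera_rate,
         frameshift_rate = frameshift_rate, reverse_frac = reverse_frac,
         low_quality_frac = low_quality_frac, seed = seed),
    class = "community_design"
  )
}

#' @export
print.community_design <- function(x, ...) {
  cat("community_design:", nrow(x$taxa), "taxa,",
      length(x$crops), "crops x", length(x$timepoints), "timepoints,",
      x$read_depth, "reads/sample\n")
  cat("  chimera rate", x$chimera_rate,
      "| frameshift rate", x$frameshift_rate, "| seed", x$seed, "\n")
  invisible(x)
}

# one concrete realization of an IUPAC-degenerate primer
realize_primer <- function(primer) {
  primer <- gsub("[[:space:]]", "", toupper(primer))
  chars <- strsplit(primer, "")[[1]]
  opts <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  paste(vapply(chars, function(ch) {
    o <- opts[[ch]]
    o[sample.int(length(o), 1)]
  }, character(1)), collapse = "")
}

draw_quals <- function(len, mean_q) {
  q <- round(rnorm(len, mean_q, 5))
  pmin(pmax(q, 2), 40)
}

#' Simulate barcoded amplicon reads with ground truth
#'
#' Each read is `barcode + primer realization + amplicon` (the amplicon and
#' primer reverse-complemented / swapped for reverse-oriented reads). Reads
#' per (sample, taxon) are multinomial draws of the design abundances.
#' Chimeric reads splice two distinct parent amplicons at one breakpoint in
#' the middle 50% of the amplicon; frameshifted reads carry a single 1-bp
#' insertion or deletion at least 60 bp from either end. Per-base Phred
#' qualities are Normal(30, 5) truncated to \[2, 40\] (mean 15 for the
#' designated low-quality fraction).
#'
#' @param design A [community_design()].
#' @param refs Reference set from [make_reference_set()]; `design$taxa$taxon`
#'   must match `refs$id`.
#' @param barcodes `data.frame` with columns `sample`, `gene`, `barcode`
#'   (all barcodes same length, unique). Samples must be named
#'   `<crop>_<timepoint>`.
#' @param primers List with elements `fwd` and `rev` (IUPAC allowed, 5'->3').
#' @return A list with `reads` (`data.frame`: `read_id`, `seq`, `qual`) and
#'   `truth` (`data.frame`: per-read sample, taxon, artefact flags and
#'   construction parameters).
#' @export
simulate_reads <- function(design, refs, barcodes, primers) {
  stopifnot(inherits(design, "community_design"))
  if (anyDuplicated(barcodes$barcode)) stop("barcode collision in sheet")
  if (length(unique(nchar(barcodes$barcode))) != 1) {
    stop("all barcodes must have the same length")
  }
  miss <- setdiff(design$taxa$taxon, refs$id)
  if (length(miss) > 0) stop("taxa missing from refs: ",
                             paste(miss, collapse = ", "))
  amp <- setNames(refs$nt_seq, refs$id)
  samples <- as.vector(outer(design$crops, design$timepoints, paste, sep = "_"))
  bc <- setNames(barcodes$barcode, barcodes$sample)
  if (!all(samples %in% names(bc))) stop("barcode sheet missing samples")

  with_seed(design$seed, {
    rows <- vector("list", length(samples))
    for (si in seq_along(samples)) {
      smp <- samples[si]
      parts <- strsplit(smp, "_")[[1]]
      crop <- parts[1]; tp <- parts[2]
      p <- design$abundance[, crop, tp]
      counts <- as.vector(stats::rmultinom(1, design$read_depth, p))
      taxon <- rep(design$taxa$taxon, counts)
      n <- length(taxon)
      is_chim <- runif(n) < design$chimera_rate
      is_fs <- !is_chim & runif(n) < design$frameshift_rate
      reversed <- runif(n) < design$reverse_frac
      lowq <- runif(n) < design$low_quality_frac
      parent2 <- rep(NA_character_, n)
      breakpoint <- rep(NA_integer_, n)
      indel_pos <- rep(NA_integer_, n)
      indel_type <- rep(NA_character_, n)
      seqs <- character(n)
      for (i in seq_len(n)) {
        body <- amp[[taxon[i]]]
        L <- nchar(body)
        if (is_chim[i]) {
          others <- setdiff(names(amp), taxon[i])
          p2 <- others[sample.int(length(others), 1)]
          b <- sample(seq.int(floor(0.25 * L), ceiling(0.75 * L)), 1)
          L2 <- nchar(amp[[p2]])
          body <- paste0(substr(body, 1, b),
                         substr(amp[[p2]], min(b + 1, L2), L2))
          parent2[i] <- p2
          breakpoint[i] <- b
        } else if (is_fs[i]) {
          pos <- sample(seq.int(60L, L - 60L), 1)
          if (runif(1) < 0.5) {
            base <- sample(c("A", "C", "G", "T"), 1)
            body <- paste0(substr(body, 1, pos), base,
                           substr(body, pos + 1, L))
            indel_type[i] <- "insertion"
          } else {
            body <- paste0(substr(body, 1, pos - 1),
                           substr(body, pos + 1, L))
            indel_type[i] <- "deletion"
          }
          indel_pos[i] <- pos
        }
        if (reversed[i]) {
          seqs[i] <- paste0(bc[[smp]], realize_primer(primers$rev),
                            revcomp(body))
        } else {
          seqs[i] <- paste0(bc[[smp]], realize_primer(primers$fwd), body)
        }
      }
      quals <- vapply(seq_len(n), function(i) {
        int_to_phred(list(draw_quals(nchar(seqs[i]),
                                     if (lowq[i]) 15 else 30)))
      }, character(1))
      rows[[si]] <- data.frame(
        read_id = sprintf("%s_r%05d", smp, seq_len(n)),
        seq = seqs, qual = quals, sample = smp, taxon = taxon,
        is_chimera = is_chim, parent2 = parent2, breakpoint = breakpoint,
        is_frameshift = is_fs, indel_pos = indel_pos,
        indel_type = indel_type, reversed = reversed,
        low_quality = lowq, stringsAsFactors = FALSE
      )
    }
    all <- do.call(rbind, rows)
    rownames(all) <- NULL
    list(
      reads = all[, c("read_id", "seq", "qual")],
      truth = all[, setdiff(names(all), c("seq", "qual"))]
    )
  })
}

#' Simulate a qPCR dilution series
#'
#' Inverts the standard-curve model: `Cq = intercept - log10(input) /
#' log10(E) + Normal(0, noise_sd)`, so that fitting Cq on log10(input)
#' recovers slope `-1/log10(E)` and efficiency `E = 10^(-1/slope)`.
#'
#' @param true_efficiency Amplification efficiency E in (1, 2.2].
#' @param intercept Cq at relative input 1.
#' @param dilution_factors Positive, descending relative inputs (e.g.
#'   `2^-(0:5)` for a two-fold series).
#' @param noise_sd Standard deviation of Cq noise (cycles).
#' @param seed Integer seed.
#' @param replicates Technical replicates per dilution.
#' @return `data.frame` with columns `dilution`, `log10_input`, `replicate`,
#'   `cq`.
#' @export
simulate_qpcr <- function(true_efficiency, intercept, dilution_factors,
                          noise_sd = 0, seed = 1, replicates = 1) {
  if (!(true_efficiency > 1 && true_efficiency <= 2.2)) {
    stop("true_efficiency must lie in (1, 2.2]")
  }
  if (any(dilution_factors <= 0)) stop("dilution factors must be positive")
  if (is.unsorted(rev(dilution_factors))) {
    stop("dilution factors must be descending")
  }
  with_seed(seed, {
    d <- rep(dilution_factors, each = replicates)
    cq <- intercept - log10(d) / log10(true_efficiency) +
      rnorm(length(d), 0, noise_sd)
    data.frame(
      dilution = d,
      log10_input = log10(d),
      replicate = rep(seq_len(replicates), times = length(dilution_factors)),
      cq = cq
    )
  })
}

#' Simulate T-RFLP peak tables
#'
#' Adds multiplicative noise to true peak areas and plants sub-threshold
#' (area <= 500) and out-of-range (size < 50 bp or > amplicon length) junk
#' peaks so downstream size/area filters are exercised.
#'
#' @param profiles_truth `data.frame` with columns `sample`, `size`, `area`
#'   (true peaks, sizes in bp).
#' @param peak_noise Coefficient of variation of the area noise (0 = exact).
#' @param seed Integer seed.
#' @param n_junk Junk peaks added per sample.
#' @param amplicon_len Amplicon length used to place oversize junk peaks.
#' @return `data.frame` with columns `sample`, `size`, `area`.
#' @export
simulate_trflp <- function(profiles_truth, peak_noise = 0, seed = 1,
                           n_junk = 0, amplicon_len = 500) {
  if (any(profiles_truth$size <= 0)) stop("fragment sizes must be positive")
  with_seed(seed, {
    out <- profiles_truth
    if (peak_noise > 0) {
      out$area <- out$area *
        pmax(1 + rnorm(nrow(out), 0, peak_noise), 0.01)
    }
    if (n_junk > 0) {
      junk <- do.call(rbind, lapply(unique(out$sample), function(s) {
        small <- data.frame(
          sample = s,
          size = runif(n_junk, 60, amplicon_len - 10),
          area = runif(n_junk, 10, 500)
        )
        oob <- data.frame(
          sample = s,
          size = c(runif(ceiling(n_junk / 2), 5, 49),
                   runif(floor(n_junk / 2), amplicon_len + 1,
                         amplicon_len + 200)),
          area = runif(n_junk, 600, 5000)
        )
        rbind(small, oob)
      }))
      out <- rbind(out, junk)
    }
    rownames(out) <- NULL
    out
  })
}
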