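# Shared fixtures, built in code at test time.

# the study's nifH qPCR primers (IUPAC-degenerate)
POLF <- "TGC GAY CCS AAR GCB GAC TC"
POLR <- "ATS GCC ATC ATY TCR CCG GA"

# reference panel of mutually unrelated lineages (independent ancestors),
# so planted chimeras join sequence of genuinely different origin
lineage_refs <- function(n = 6, aa_len = 120, seed0 = 100) {
  refs <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- make_reference_set("nifH", 1, aa_len, 0.2, seed0 + i)
    r$id <- sprintf("nifH_tax%02d", i)
    r
  }))
  refs
}

fixture_barcodes <- function(samples, gene = "nifH") {
  pool <- c("ACGTACGTAC", "TGCATGCATG", "GATCGATCGA", "CCGGAATTCC",
            "TTGGCCAATT", "AGAGTCTCGA", "GTGTCACAGT", "CACAGTGTGA",
            "TCTCAGAGCT", "AATTCCGGTT", "GGTTAACCGG", "CGATCGATTA")
  stopifnot(length(samples) <= length(pool))
  data.frame(sample = samples, gene = gene,
             barcode = pool[seq_along(samples)],
             stringsAsFactors = FALSE)
}

fixture_primers <- list(fwd = POLF, rev = POLR)

# small simulated experiment reused across test files
fixture_simulation <- function(read_depth = 200, chimera_rate = 0,
                               frameshift_rate = 0, reverse_frac = 0,
                               low_quality_frac = 0, crops = "MG",
                               n_taxa = 4, seed = 7) {
  refs <- lineage_refs(n_taxa)
  taxa <- data.frame(taxon = refs$id, baseline = rep(1 / n_taxa, n_taxa))
  des <- community_design(
    taxa, crops = crops, read_depth = read_depth,
    chimera_rate = chimera_rate, frameshift_rate = frameshift_rate,
    reverse_frac = reverse_frac, low_quality_frac = low_quality_frac,
    seed = seed
  )
  samples <- as.vector(outer(crops, c("t0", "t1", "t2"), paste, sep = "_"))
  bc <- fixture_barcodes(samples)
  sim <- simulate_reads(des, refs, bc, fixture_primers)
  list(refs = refs, design = des, barcodes = bc, sim = sim)
}
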