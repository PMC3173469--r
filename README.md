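# ncycamp

Functional-gene amplicon analysis of soil nitrogen-cycling communities.

`ncycamp` is a desk-scale R pipeline for surveys that track the nitrogen
cycle's marker genes — *nifH* (nitrogen fixation), archaeal and bacterial
*amoA* (ammonia oxidation), *nosZ* (complete denitrification) and 16S
rRNA — across crop treatments and years. It covers the full workflow of a
barcoded pyrosequencing + qPCR + T-RFLP field study:

* **Synthetic community generator** — emits barcoded reads (FASTQ), qPCR
  plates and T-RFLP peak tables with complete ground truth: sample of
  origin, source taxon, planted two-parent chimeras, planted 1-bp
  frameshifts, planted monotonic abundance trends. Everything downstream
  is testable without a sequencer.
* **Demultiplexing & QC** — mean-Phred/length/`N` screening, exact-prefix
  barcode assignment, IUPAC-degenerate primer matching and orientation,
  and a filter ledger that reports each stage as a percentage of raw reads.
* **Translated screening** — six-frame Smith–Waterman search (BLOSUM62,
  gap 11/1, Karlin–Altschul E-values) against a reference protein set;
  reads are called `frameshift` when one reference is hit in different
  frames over disjoint read regions, `chimera` when two distinct origins
  are hit over disjoint regions.
* **OTU clustering** — dereplication (longest representative),
  DOTUR-convention alignment distances, furthest-neighbour clustering
  (0.10 amino acid ≈ 90% similarity; 0.03 nucleotide ≈ 97%), analytic
  rarefaction `E[S_m] = S − Σ C(N−N_i, m)/C(N, m)`, and seeded
  re-sampling to common depth.
* **Trend analysis** — per (taxon, crop) classification over baseline →
  year 1 → year 2 into increase (+), decrease (−), appear (++),
  disappear (−−) with strict monotonicity, and changed-fraction summaries.
* **qPCR quantification** — standard curves with efficiency
  `E = 10^(−1/slope)`, sample-derived standards
  (`copies/µL = c·10⁻⁹/(L·660)·6.022×10²³`), copies per gram of dry soil
  with extraction-efficiency correction, ANOVA + Tukey letters, and
  rate-vs-log-abundance regression.
* **T-RFLP** — in-silico AluI/HhaI terminal-fragment prediction, peak
  filtering (50 bp ≤ size ≤ amplicon length, area > 500) and
  normalisation, Bray–Curtis, seeded ANOSIM, correspondence analysis.

See `vignettes/ncycamp-methods.Rmd` for the models, assumptions and design
choices.

## Worked example

Simulate one maize (ZM) time series with planted trends and artefacts,
run the screen, call trends, and fit a qPCR curve:

```r
library(ncycamp)

refs <- do.call(rbind, lapply(1:4, function(i) {
  r <- make_reference_set("nifH", 1, 120, 0.2, 200 + i)
  r$id <- sprintf("nifH_tax%02d", i); r
}))
taxa   <- data.frame(taxon = refs$id, baseline = 0.25)
trends <- matrix(c("increase", "decrease", "appear", "stable"), 4, 1)
des <- community_design(taxa, trends, crops = "ZM", read_depth = 800,
                        chimera_rate = 0.03, frameshift_rate = 0.03,
                        seed = 42)
barcodes <- data.frame(sample = paste0("ZM_", c("t0", "t1", "t2")),
                       gene = "nifH",
                       barcode = c("ACGTACGTAC", "TGCATGCATG", "GATCGATCGA"))
primers <- list(fwd = "TGC GAY CCS AAR GCB GAC TC",
                rev = "ATS GCC ATC ATY TCR CCG GA")
sim <- simulate_reads(des, refs, barcodes, primers)

qc  <- quality_screen(sim$reads)
dmx <- demultiplex(qc$reads, barcodes)
scr <- primer_screen_and_orient(dmx$assigned, primers$fwd, primers$rev)
res <- screen_reads(scr$reads, refs)
table(res$verdicts$verdict)
#>    chimera frameshift      valid
#>         77         79       2244
```

The planted 3% chimera / 3% frameshift rates are recovered (77 and 79 of
2400 reads) and the remaining reads are valid. Trend calls on the valid
reads' per-sample taxon counts:

```r
#>           taxon    class  c0  c1  c2
#> ZM.1 nifH_tax01 increase 233 335 469
#> ZM.2 nifH_tax02 decrease 265  88  34
#> ZM.3 nifH_tax03   appear   0 162 112
#> ZM.4 nifH_tax04 decrease 246 171 129
```

Three of the four planted classes are recovered exactly. The nominally
"stable" taxon is called `decrease` — correctly so: relative abundances
are compositional, and a taxon holding a constant share of a community in
which others appear and double genuinely loses share at fixed sequencing
depth.

```r
curve <- fit_standard_curve(
  simulate_qpcr(1.90, 22, 2^-(0:6), noise_sd = 0.05, seed = 1,
                replicates = 3))
curve
#> standard_curve: slope -3.6010, intercept 21.999, R2 0.9999, E = 1.895
quantify_sample(curve, cqs = c(24.1, 24.3, 24.2))$copies_per_g
#> [1] 5075.247
```

A two-fold dilution series generated at efficiency 1.90 with realistic Cq
noise is fitted back to E = 1.895 (R² > 0.999); the triplicate sample Cq
is inverted through the curve and scaled by the default 6230 ng DNA/g and
30% extraction efficiency to copies per gram of dry soil.

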