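---
title: "ncycamp: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ncycamp: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncycamp)
```

## What this package computes

`ncycamp` reimplements, as a tested and reusable pipeline, the analysis
workflow of a two-year field survey of soil nitrogen-cycling microbial
communities under bioenergy crops (maize, switchgrass, *Miscanthus*,
restored prairie). The survey's measurements are barcoded 454 amplicon
libraries of the marker genes *nifH* (nitrogen fixation), archaeal and
bacterial *amoA* (ammonia oxidation), *nosZ* (complete denitrification) and
16S rRNA, together with qPCR abundance assays and T-RFLP community
fingerprints. Real soil DNA is not required: a synthetic-community module
generates every input with known ground truth, and all claims the test
suite makes are claims about recovery of that ground truth or about
arithmetic the source publications print.

## The screening model

Reads pass a staged screen:

1. **Quality**: drop reads shorter than 50 bp, containing `N`, or with
   arithmetic mean Phred below 20 (computed on the raw read, before any
   trimming).
2. **Demultiplexing**: exact prefix match of the 10-bp barcode, which is
   then trimmed. No error correction — a one-mismatch barcode is
   unassigned, mirroring the "fully matched" policy of the original
   pipeline.
3. **Primer/orientation**: a read starting with a realization of the
   IUPAC-degenerate forward primer is kept; one starting with the reverse
   primer is reverse-complemented so all survivors are forward-oriented.
   The primer is trimmed and reads shorter than 350 bp after trimming are
   removed. The 350-bp threshold is applied *after* barcode and primer
   removal and as `>= 350`; both points are ambiguous in the original
   description and both are configurable. Screens mark their output
   `trimmed`, so re-running them is a no-op rather than a second deletion.
4. **Translated screen**: six-frame local alignment (Smith–Waterman,
   BLOSUM62, gap open 11 / extend 1) of each read against a reference
   protein set, with a Karlin–Altschul E-value
   \(E = K m n e^{-\lambda S}\) (gapped BLOSUM62 constants
   \(\lambda = 0.267\), \(K = 0.041\); \(m\) = translated query length,
   \(n\) = total reference residues), cutoff \(10^{-3}\), top 10 hits per
   read.

### Frameshift and chimera rules

The verdicts are driven purely by hit geometry:

* **frameshift** — one reference matched by two hits in *different frames*
  whose query intervals overlap by less than 20% of the shorter interval;
* **chimera** — two *distinct references* whose best hits occupy query
  intervals overlapping by less than 20% of the shorter interval;
* otherwise **valid** (any hit) or **no_hit**.

Two references hitting the *same* region are homologs, not a chimera;
without this reading every read in a homolog-rich reference set would be
discarded. The 20% overlap quantifier is configurable
(`max_region_overlap`).

**Hit cores.** A raw Smith–Waterman optimum may include weakly positive
random flanks — 10–25 residues whose net score is barely above zero happen
regularly at these read lengths, and they extend hits across indels and
chimera breakpoints, destroying the disjoint-region geometry. Each hit is
therefore reduced to its *core*: the maximum-scoring alignment segment
after charging every column a rent of `core_delta = 2`. Random flanks
(expected column score near 0) become strongly negative under the rent;
genuine homology at the divergences this pipeline targets (column score
+3 or more) is untouched. Set `core_delta = 0` to recover raw
Smith–Waterman intervals.

**A structural blind spot.** The disjoint-region chimera rule cannot fire
when the two parents are moderate homologs: a local alignment extends
across the breakpoint whenever the expected BLOSUM62 column score is
positive, which holds down to roughly 10% amino-acid identity. Chimeras of
close relatives therefore evade any screen of this family — including the
original BLASTX-based one. The synthetic tests plant chimeras between
references from independent lineages (near-random mutual identity), where
the rule's sensitivity is measured at 1.0 with zero false positives on
clean reads.

## OTU clustering and diversity

Valid reads are translated in their best hit's frame (internal stop codons
truncate the product and set a flag), dereplicated (exact and exact-prefix
duplicates collapse; the representative is the longest member, ties broken
by smallest id), and clustered.

* **Distances**: pairwise ends-free global alignment; distance
  \(= 1 - \text{matches} / (\text{paired columns} + \text{internal gap
  runs})\), terminal gaps excluded — the DOTUR/mothur convention. Pairwise
  alignment replaces the original MSA-then-distance route to avoid heavy
  external dependencies while preserving the clustering contract.
* **Clustering**: furthest-neighbour (complete-linkage) agglomeration, the
  DOTUR default; merges proceed in order of increasing linkage while the
  linkage is at most the cutoff, so every OTU's maximum intra-cluster
  distance is \(\le\) cutoff. Merge ties break on the smallest label pair.
  Cutoff 0.10 on amino acids reproduces the 90% similarity convention for
  N-cycling genes; 0.03 on nucleotides the 97% convention for 16S.
* **Rarefaction**: the analytic hypergeometric expectation
  \(E[S_m] = S - \sum_i \binom{N - N_i}{m} / \binom{N}{m}\), validated
  against Monte-Carlo subsampling in the tests.
* **Re-sampling**: multivariate hypergeometric draw to a common depth
  (the published analyses used 697 reads/sample for the N-genes and 1789
  for 16S), seed-deterministic.

## Trend calling

For each (taxon, crop), counts at the three ordered timepoints
\((c_0, c_1, c_2)\) — baseline, year 1, year 2 — on depth-normalised
libraries:

| class | rule |
|---|---|
| appear (++) | \(c_0 = 0,\; c_1 > 0,\; c_2 > 0\) |
| disappear (−−) | \(c_0 > 0,\; c_1 = 0,\; c_2 = 0\) |
| increase (+) | \(c_0 < c_1 < c_2\) strictly |
| decrease (−) | \(c_0 > c_1 > c_2\) strictly |
| none | otherwise |

Strict inequalities implement "continuously" changing — a flat step is not
a trend. Appearance is keyed on detection, not growth, so a (0, 7, 7)
series is `appear`. Percentages of changed phylotypes use the
pre-resampling OTU richness as denominator and are reported both exactly
and rounded half away from zero to one decimal; the implementation does not
assert any particular rounding mode for published values that sit on a
truncation boundary.

## qPCR quantification

The standard-curve chain is: ordinary least squares of mean Cq on
\(\log_{10}\)(input), efficiency \(E = 10^{-1/\text{slope}}\),
sample-derived standard copy number
\(\text{copies}/\mu L = c \cdot 10^{-9} / (L \cdot 660) \cdot 6.022
\times 10^{23}\) (c in ng/µL, L the mean amplicon length in bp, 660 g/mol
per double-stranded base pair — the constant is configurable because the
source states only "average molecular weight"), and
\(\text{copies/g soil} = \text{copies/ng} \times \text{ng DNA/g} /
\text{extraction efficiency}\) with defaults 6230 ng/g and 0.30. The DNA
yield is interpreted as the extracted (pre-correction) amount, following
the order of operations in the source's caption. Quantities below the
10 copies/µL detection limit are flagged censored, not zeroed. Group
comparisons use one-way ANOVA on \(\log_{10}\) copies with Tukey HSD
letters (the published Tukey-B differs negligibly at n = 4 and is rarely
implemented); identical observations in all groups yield F = NA and no
separations rather than a floating-point artifact.

## T-RFLP

In-silico digestion models AluI (AG^CT) and HhaI (GCG^C) as separate
digests; the terminal restriction fragment is the distance from the
labelled 5' end to the first cut on the labelled strand, full length if no
site. Peak tables keep fragments between 50 bp and the amplicon length
with area strictly greater than 500, then normalise to relative abundance.
Community statistics: Bray–Curtis dissimilarity
\(d_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})\), ANOSIM
(rank-based \(R\), one-sided permutation p with
\((\#\{R^* \ge R\} + 1)/(n_{perm} + 1)\), 999 permutations, seeded), and
correspondence analysis by SVD of the chi-square standardised residuals,
whose total inertia equals \(\chi^2 / N\) — an identity the tests assert to
\(10^{-9}\). Constrained ordination (CCA) is out of scope; it would require
an environmental matrix the synthetic module would have to invent.

## The synthetic world

The generator emulates the study design: 4 crops × (baseline + 2 years),
with one composite library per (crop, year). Reads are
`barcode + primer realization + amplicon` (reverse-oriented for a
configurable fraction); counts per sample are multinomial in the design
abundances; qualities are Normal(30, 5) truncated to [2, 40], with a
configurable low-quality fraction at mean 15 to exercise the mean-quality
filter. Chimeras splice exactly two parents at one breakpoint uniform in
the middle 50% of the amplicon (detectable by the disjoint-region rule in
the minimal two-origin case); frameshifts are a single 1-bp indel at least
60 bp from either end (guaranteeing alignable flanks in two frames). The
two artefact flags are mutually exclusive per read. Amplicon lengths
default to the conventional sizes of the published primer sets (~360 nt
*nifH*, ~633 nt archaeal *amoA*, ~489 nt bacterial *amoA*, ~453 nt *nosZ*,
rounded to whole codons) and are configurable — the source does not state
them as inputs.

Reference proteins descend from one random ancestor by per-site
substitution; residues are drawn from Robinson–Robinson background
frequencies because uniform composition overweights rare high-scoring
residues (W, C) and makes the expected BLOSUM62 score of *unrelated* pairs
positive, which would break alignment statistics in a way real proteins do
not. Mutually unrelated taxa are obtained by generating one-lineage sets
under different seeds.

What the generator does **not** model: 454 homopolymer error spectra,
flowgram-level noise, chimera breakpoint preference for conserved regions,
barcode sequencing errors, and abundance distributions with realistic
long tails. A green test therefore establishes that the *rules* are
implemented correctly and recover a stated world — not that the pipeline's
operating characteristics on real 454 data equal those measured here.

## Numerical choices

* Percentages are rounded half away from zero (commercial rounding), one
  decimal, as the published tables do.
* Hit ordering is deterministic: descending score, then subject id, then
  query start; equal-seed runs are byte-identical everywhere.
* The distance alignment scores match +1 / mismatch −1 with affine gaps
  (open 2, extend 1); the scoring only tie-breaks among near-optimal
  alignments since the distance itself is identity-based.
* Monte-Carlo test bounds use the empirical SE with a Bonferroni
  adjustment across simultaneous comparisons and a rule-of-three floor
  where rare-miss events make the empirical SE collapse.
* No shell CLI is shipped: in the R tier of this domain the package's
  exported functions are the interface, and `scripts/acceptance.R` is the
  reproducible entry point.

## Known limitations

* Chimeras between moderate homologs (roughly 10–80% amino-acid identity)
  are structurally undetectable by the published rule; see above.
* The 16S lane-mask distance convention is not implemented; OTU totals for
  16S would shift slightly relative to masked distances.
* Tukey-B is approximated by Tukey HSD.
* ANOSIM p-values are one-sided on R (the ecology convention); a flag
  exposes nothing else because the exhaustive null is available in the
  tests for the sizes used here.
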