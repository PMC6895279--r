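---
title: "Methods: modelling and detecting RNase R resistance"
author: "rnaserseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and detecting RNase R resistance}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rnaserseq)
```

# The biological problem

RNase R is a highly processive 3'→5' exoribonuclease widely used to enrich
circular RNAs: linear RNAs are degraded while covalently closed circles
survive. The enzyme, however, is not a clean filter for circularity. It
needs a single-stranded 3' overhang of roughly seven nucleotides to engage a
substrate (ten or more for optimal activity), so RNAs with structured 3'
termini — snRNAs, histone mRNAs and similar species — resist digestion
unless an overhang is first added by in vitro A-tailing (E-PAP). The enzyme
also stalls at internal G-quadruplex (G4) structures, leaving behind
3'-truncated fragments of otherwise ordinary polyadenylated mRNAs. G4s are
stabilized by K⁺ in the reaction buffer; substituting Li⁺ (or Na⁺), which
does not readily stabilize quadruplexes, lets the enzyme read through.

`rnaserseq` turns this biochemistry into a testable computational pipeline:
it classifies genes as RNase R resistant from paired control/treated RNA-seq
libraries, locates stalling sites as change points in coverage, scores
quadruplex-forming sequence (QGRS) potential around those sites against
shuffled nulls, and quantifies circular RNA enrichment from junction-read
tables. A mechanistic simulator generates fully labelled synthetic libraries
so every stage can be validated against ground truth without any external
data.

# The digestion model

Each transcript is a `transcript_model`: exons (0-based half-open genomic
intervals), topology (`linear`, `circular_exonic`, `circular_intronic`), a
3'-end structure (`free` or `structured`), a 3' overhang length, optional G4
elements with cation-specific stalling probabilities, and an abundance in
arbitrary molecules-per-cell units.

`simulate_digestion()` applies, in order:

1. **Circularity.** Circular transcripts have no ends and are returned
   intact at full weight.
2. **Engagement.** The effective overhang is the annotated overhang plus,
   if the reaction was A-tailed, a geometric tail of mean `tail_mean`
   (default 50 nt — any mean far above the optimum threshold behaves the
   same; the geometric shape means a small minority of tails still fall
   below the 7 nt minimum, which is why structured-end depletion is tested
   as a high fraction rather than an exact rule). Overhangs below
   `overhang_min = 7` nt are never engaged; overhangs between 7 and
   `overhang_opt = 10` nt are engaged at half rate.
3. **Kinetics.** The engaged fraction after `t` minutes is
   `1 - exp(-k(cation) * t * r)` with defaults `k_K = 0.2`/min and
   `k_Na = k_Li = 0.05`/min. The single-exponential form is the simplest
   model that reproduces partial digestion at a short (15 min) and near
   complete digestion at a long (90 min) incubation; digestion is less
   efficient in Na⁺/Li⁺ buffer.
4. **Stalling.** Engaged molecules meet G4 elements 3'→5'; each element
   stalls the enzyme with its cation-specific probability (defaults 0.9 in
   K⁺, 0.1 in Na⁺, 0.05 in Li⁺ — free parameters of the simulator, not
   estimates; no quantitative per-G4 stall probabilities exist). A stalled
   molecule leaves a fragment ending at the element's 3' edge plus a 5 nt
   enzyme footprint plus Gaussian jitter (sd 10 nt), clipped to the
   transcript. Molecules that pass every element are removed entirely,
   emulating library size selection of full digestion products.

Surviving weight is therefore conserved (never exceeds the input abundance,
with equality exactly for circles, unengaged structured ends, or zero
rate×time), monotone non-increasing in incubation time and initiation rate,
and higher under K⁺ than Li⁺ for G4-containing transcripts. These are the
package's acceptance invariants.

# What the simulator emulates — and what it does not

`build_transcriptome()` draws genes from five classes: plain mRNAs, G4
mRNAs (with a planted telomeric-repeat-like QGRS motif in the last exon),
structured-end RNAs, circRNA hosts (linear mRNA plus an exonic circle from
the middle exon at half the host abundance) and ciRNA hosts (plus an
intronic circle). The default mix (0.40/0.35/0.10/0.10/0.05) is weighted
toward the classes under study so that each downstream statistic has
adequate per-class counts at the default scale. Abundances are log-normal
(sdlog 1); both strands are used; ERCC-like spike-ins are rendered
identically in all libraries.

`render_libraries()` simulates coverage at base resolution directly:
per-base expected coverage is `depth ×` surviving fragment weight, sampled
as independent Poisson counts per replicate. Junction reads (backsplice for
circles, spliced for linear multi-exon transcripts) are Poisson with a
configurable junction factor. Read placement, fragment-length effects,
mappability, positional bias and isoform complexity are intentionally *not*
modelled; passing tests therefore demonstrate correctness of the inference
machinery under idealized sampling, not robustness to alignment artefacts
in real libraries. A `noise = "none"` mode renders the exact expectations
for exact-recovery tests.

The truth table records, per gene, the expected RNase R/Control RPKM ratio
computed from the noise-free expectations with the *same* exon-union
counting and library normalization the analysis uses, the implied
resistance label, and the planted/realized stall coordinates.

# Quantification conventions

* RPKM is `count × 10⁹ / (length × mapped)`; gene counts are summed
  per-base coverage over the exon union of all the gene's transcripts
  (circles included), and library sizes are total gene counts plus spike-in
  counts. Spike-ins are QC-only (pairwise r² of log10 RPKM); they are never
  used for normalization.
* "Highly expressed" means at or above the 0.75 type-7 quantile of
  control-sample RPKM in *every* replicate (intersection across replicates
  — the conservative reading consistent with the both-replicates rule used
  for ratios; ties at the threshold are included, which matters at test
  scale).
* A gene is resistant iff it is highly expressed and its treated/control
  RPKM ratio is ≥ 1 (inclusive) in all replicates. Ratios are undefined
  where control RPKM is zero; such genes are skipped with a warning.

Because RPKM is per million mapped reads and the treated libraries lose
most of their material, surviving RNAs gain a library renormalization boost
of several fold — this is what pushes partially surviving G4 mRNAs above a
ratio of 1 and produces the several-fold apparent enrichment of circRNA
junction reads.

# Stalling-site detection

The per-base statistic is `y(i) = log2((treated + ψ) / (control + ψ))`
(pseudocount ψ = 1), oriented 5'→3' over the gene's annotated last exon
(for multiple linear isoforms, the longest last exon), with replicates
pooled by summation. `fit_changepoint()` fits a single breakpoint by
exhaustive search over piecewise-constant two-segment fits with a minimum
segment of 25 nt (avoiding degenerate edge fits), and computes
`F = (SSE₁ − SSE₂) / (SSE₂ / (L − 2))` against F(1, L−2).

Because the breakpoint is *selected* as the best of ~L candidate splits,
the raw F tail probability is strongly anti-conservative under the null
(its null distribution is that of a maximum, not a single draw; in
simulation, null p-values concentrate near 10⁻³). The reported `p_value`
is therefore Bonferroni-adjusted over the number of candidate splits — a
valid, if conservative, bound on the selection. Power is unaffected in
practice: a genuine stall at 100× depth yields F statistics in the
thousands. Benjamini–Hochberg FDR is then applied across tested genes and
sites are kept at FDR ≤ 0.05 with a positive drop (`a > b`).

Manual inspection is operationalized by `auto_inspect()`: the drop-off
position is the 5'-most index where 21-nt median-smoothed treated coverage
falls below 0.2 × the median coverage 5' of the breakpoint and stays below
for ≥ 50 nt (or through the end of the region); a site passes when it lies
within 200 nt of that drop-off. All three constants are conservative and
config-exposed. No offset correction is applied for the known tendency of
regression-based estimates to sit slightly 5' of the true drop — the
discrepancy is reported (as the median coordinate error against the
simulator truth), not corrected.

A 400 nt window centered on each inspected site is extracted in genomic
coordinates and returned 5'→3' in transcript orientation
(reverse-complemented on the minus strand); sites too close to a
chromosome end to be centered are dropped with a warning.

# QGRS scoring and enrichment statistics

A QGRS motif is `G_x N_y1 G_x N_y2 G_x N_y3 G_x` with equal G runs of
x ≥ 2, loops ≥ 1 nt (loops may contain G), and total length ≤ 30 nt.
`find_qgrs()` enumerates every motif exhaustively (overlaps included) and
scores each as

`S = 20·(x − 2) + (30 − length) − (|y1−y2| + |y1−y3| + |y2−y3|)`

— a surrogate for the published QGRS mapper score, whose exact formula is
not reproduced here; it preserves the mapper's stated principles (more
tetrads score higher; shorter and more even loops score higher) and is
checked exhaustively for those monotonicity properties. Per window only
the highest value is retained (ties: leftmost start, then shortest motif);
windows without any motif are scored `NA` and excluded from score
comparisons, with counts reported.

The shuffle null places sites per-base uniformly over the concatenated
eligible space — last exons of highly expressed genes — keeping the full
window inside a single region; 100 shuffles by default. A deliberate
difference from interval-shuffling tools that weight by region: per-base
uniformity is declared, seeded and tested by goodness of fit. For the
Fisher test of G4 proximity, all shuffles are pooled into a single null row
of the 2×2 table (pooling vs averaging is unspecified in the protocol this
follows; pooling keeps the test exact). The Fisher p-value is computed by
direct hypergeometric enumeration. Distances from sites to annotated G4s
are signed in transcript orientation (positive = G4 downstream), measured
edge-to-site; proximity means |distance| ≤ 200 nt. Mann–Whitney tests are
exact for pooled samples of ≤ 12 untied observations and use the normal
approximation with tie correction otherwise.

By default only the first shuffle's windows are also QGRS-scored for the
score-distribution comparison (the protocol's own score control used a
single shuffle); `qgrs_shuffles` raises this.

# Circular RNA enrichment

A circle is detected in a condition when ≥ 2 backsplice junction reads
appear in at least one library of that condition; replicate-consistent
detection requires every replicate. Fold enrichment is the treated/control
ratio of backsplice reads per million mapped reads, averaged over
replicates (genes with zero control RPM are excluded with a message); the
pooled total-RPM fold is also reported since the protocol does not specify
gene-level vs pool-level averaging. The junction ratio is
`backsplice / (backsplice + linear spliced)` per replicate, averaged, and
the two conditions are compared by Mann–Whitney with empirical CDFs for
plotting.

# Problem sizes and numerical choices

The default study (`run_config()` defaults) simulates 1,200 genes with two
replicates per condition at 100× depth and a 90 min K⁺ digestion — chosen
so the default run yields on the order of 100 inspected stalling sites and
~140 resistant genes, a desk-scale analogue of the published analysis'
result structure, while completing in about a minute on one CPU. Tests use
smaller transcriptomes (20–500 genes) per stage. Acceptance checks run the
default pipeline twice (K⁺ and Li⁺) and assert the qualitative structure:
central G-enrichment at sites, G4 proximity far beyond the shuffled null,
a junction-ratio shift after treatment, and near-total loss of stalling
sites in Li⁺.

Other numerical details: all coordinates 0-based half-open internally with
conversion only at the GTF boundary; seeded RNG everywhere, with stage
seeds derived from a single root seed and restored after use so helpers do
not perturb outer streams; `sse_two = 0` fits get p = 0; all-zero coverage
yields a "no signal" result rather than an error; BH via `p.adjust`;
quantiles type 7.

# Known limitations

* Coverage is Poisson at base resolution; no read-level simulation,
  alignment error, or isoform deconvolution.
* One change point per gene: multi-breakpoint segmentation (several G4s
  stalling in one last exon) is out of scope, and only the 3'-most planted
  element is recovered as "the" site.
* The digestion kinetics are a one-parameter-per-cation caricature adequate
  for ordering conditions, not for fitting time courses.
* 2'–3' cyclic phosphate ends and other exotic 3' chemistry are only
  represented through the free/structured dichotomy.
* The QGRS score is a surrogate; absolute score values are not comparable
  to the published mapper, only their ordering behaviour is.
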