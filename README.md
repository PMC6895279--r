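# rnaserseq

Which RNAs survive RNase R, and why?

RNase R is the processive 3'→5' exoribonuclease used to enrich circular
RNAs from total RNA: linear molecules are eaten, covalently closed circles
are not. But the enzyme is an imperfect filter. It cannot engage RNAs that
lack a single-stranded 3' overhang of ~7 nt (snRNAs, histone mRNAs), and it
stalls inside ordinary polyadenylated mRNAs at G-quadruplex (G4) structures
— a K⁺-dependent effect that disappears when the buffer cation is Li⁺.
`rnaserseq` is an R package for analysing paired control / RNase R-treated
RNA-seq libraries with exactly these failure modes in mind, plus a
mechanistic simulator of the digestion so that every analysis stage is
validated against ground truth.

## What it computes

Given gene annotation (GTF), per-base coverage (bedGraph), a
backsplice/linear junction-count table (TSV) and genome sequence (FASTA):

* **Resistance calls** — gene-level RPKM
  (`count × 10⁹ / (length × mapped)`), the top-25% expression filter per
  replicate, and the call *resistant ⟺ highly expressed and RNase R/Control
  RPKM ratio ≥ 1 in every replicate*; ERCC-style spike-in QC (pairwise r²
  of log RPKM).
* **Stalling sites** — per resistant gene, a single change point in the
  last-exon log2 treated/control coverage ratio
  (`y(i) = log2((T+ψ)/(C+ψ))`, exhaustive two-segment least squares, F
  statistic with selection-adjusted p-value), Benjamini–Hochberg FDR ≤
  0.05, an automated "signal clearly dropped off within 200 nt" inspection
  rule, and 400 nt site-centered windows.
* **G4 association** — exhaustive enumeration of quadruplex-forming G-rich
  sequences `G_x N_y1 G_x N_y2 G_x N_y3 G_x` (x ≥ 2, loops ≥ 1, length ≤
  30) scored by `S = 20(x−2) + (30−ℓ) − Σ|loop differences|` with max
  retention per window; per-position nucleotide profiles; sites shuffled
  100× over last exons of highly expressed genes as the null; signed
  distances to annotated G4 intervals; Fisher exact (hypergeometric
  enumeration) and Mann–Whitney statistics.
* **Circular RNA enrichment** — the ≥2-junction-read detection rule,
  treated/control backsplice reads-per-million fold enrichment, and the
  backsplice/(backsplice+linear) junction ratio compared across conditions.

The simulator (`build_transcriptome()`, `simulate_digestion()`,
`render_libraries()`, `write_tracks()`) generates transcriptomes with plain
mRNAs, G4-containing mRNAs, structured-end RNAs, circRNA/ciRNA host genes
and spike-ins, digests them under configurable cation / A-tailing /
incubation-time conditions, and emits bedGraph/GTF/FASTA/TSV files plus a
truth table.

## Worked example

A complete synthetic study — simulate, write the run directory, and analyse
— in one call:

```r
library(rnaserseq)
run <- run_pipeline(run_config(mode = "full", n_genes = 200, seed = 1,
                               outdir = "readme_run"))
#> [simulate] building transcriptome of 200 genes
#> [quantify] 33 / 200 genes called resistant
#> [stallfind] 26 sites at FDR <= 0.05; 26 pass inspection
#> [g4score] Fisher p = 1.711356e-10
#> [circquant] 29 circle genes; median fold 3.191839

head(run$sites[, c("gene_id", "chrom", "pos", "strand", "drop", "fdr")], 3)
#>   gene_id chrom   pos strand     drop fdr
#> 1   G0003  chrS  7502      + 9.837342   0
#> 2   G0008  chrS 20803      - 8.522226   0
#> 3   G0013  chrS 33633      - 9.190845   0

run$g4_stats$fisher_table
#>          g4_near no_g4
#> observed      26     0
#> shuffled    1087  1513
```

Reading the output: 33 of 200 genes keep an RPKM ratio ≥ 1 in both
replicates after digestion (circles, structured ends and stalled G4 mRNAs —
most linear mRNAs are depleted, which is also why the per-million
normalization makes circRNA junction reads ~3.2-fold more abundant after
treatment). All 26 coverage change points that pass FDR control and
inspection fall within 200 nt of a planted G-quadruplex, against 42% of
shuffled positions (Fisher p = 1.7×10⁻¹⁰); `drop` is the height of the
log2-ratio step at the site. Re-running with
`run_config(cation = "Li", ...)` removes the stalling sites entirely while
leaving circle enrichment intact.

Each stage is also available as plain functions (`quantify_libraries()`,
`fit_changepoint()`, `detect_stalling_sites()`, `find_qgrs()`,
`shuffle_sites()`, `g4_enrichment()`, `detect_circles()`, ...) for use on
your own tables; `inst/scripts/run_pipeline.R` is a shell wrapper around
the same configuration object.

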