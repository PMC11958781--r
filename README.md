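# succer

Differential histone-mark enrichment analysis and multi-omics integration
for CUT&Tag data.

## The problem

CUT&Tag profiles of a histone modification (for example H3K23 succinylation
or H3K27 acetylation) in two conditions with replicates yield peak regions
and fragment-level signal. The scientific questions downstream are: which
regions gain or lose the mark between conditions, which genes those regions
plausibly regulate, whether the enrichment changes track expression changes
measured by RNA-seq, which transcription-factor motifs concentrate at the
changing regions, and which pathways the affected genes populate. `succer`
implements this integration pipeline for analysts who already have peaks,
fragments, gene models, an expression table, gene sets (GMT) and a PWM
library — alignment and peak calling are upstream concerns.

## The method

**DER calling.** Per-sample region signal is normalized as

    RPKM = count × 10⁹ / (region length in bp × library size)

over union-merged consensus regions. With group means m̄_ctrl, m̄_case of
replicate RPKMs and pseudocount ε = 0.5:

    GAIN  ⇔  (m̄_case + ε) / (m̄_ctrl + ε) > τ        (τ = 2)
    LOSS  ⇔  (m̄_ctrl + ε) / (m̄_case + ε) > τ

**Integration.** Each DER is assigned to the nearest gene TSS within
100 kb; DER-linked genes are intersected with DEGs; Pearson r (with
Student-t P) relates DER and gene log₂ fold changes; paired expression
shifts per DER class are tested by the Wilcoxon signed-rank test (exact
null for n ≤ 25).

**Motifs.** PWM log-odds scanning (s = Σᵢ log₂ pᵢ(xᵢ)/b(xᵢ), both strands,
hit at ≥ 80% of the maximum score) over ±200 bp summit windows; enrichment
by the one-sided binomial tail against non-DER background windows
(P < 0.01); DETFs are enriched TFs whose own expression changes
concordantly; motif occurrence is profiled in 10-bp bins over ±500 bp
around summits; TF targets are DEGs with a hit within 2 kb of the TSS.

**Pathways.** Hypergeometric upper-tail over-representation (computed in
log space) of DER-linked DEGs with |log₂FC| > 1, P < 0.05.

A fully deterministic synthetic-study generator (negative-binomial region
counts with planted GAIN/LOSS effects, expression correlated with planted
effects at a target ρ, motifs planted in GAIN summit windows, one planted
gene set) provides ground truth for recovery testing; see the methods
vignette (`vignettes/methods.Rmd`) for the model and its assumptions.

## Worked example

```r
library(succer)
res <- run_pipeline(demo_config(seed = 1), "demo_out", quiet = TRUE)

res$ders[1:3, c("region_id", "class", "mean_ctrl", "mean_case",
                "log2fc", "feature", "dist_tss")]
#>      region_id class mean_ctrl mean_case   log2fc      feature dist_tss
#> 1 region_00014  GAIN  413.1151  5394.173 3.705175 promoter-TSS      588
#> 2 region_00317  GAIN 1726.4832 19277.974 3.480665 promoter-TSS      424
#> 3 region_00085  GAIN 1695.8502 17381.498 3.357088 promoter-TSS      585

res$correlation
#> Pearson r = 0.710 (n = 83, two-sided P = 5.78e-14)

head(res$motif_gain[, c("motif", "k", "n", "k_bg", "n_bg", "p")], 3)
#>           motif  k  n k_bg n_bg            p
#> 1 planted_motif 19 44   12  307 9.712326e-16
#> 2     decoy_001  0 44    1  307 1.000000e+00
#> 3     decoy_002  0 44    0  307 1.000000e+00

head(res$enrichment_gain[, c("set", "k", "K", "n", "N", "p")], 3)
#>            set  k  K  n   N            p
#> 1  planted_set 12 20 14 111 2.487495e-09
#> 2 decoy_set_03  4 20 14 111 2.250117e-01
#> 3 decoy_set_06  3 20 14 111 4.816425e-01
```

The demo simulates a 2 × 150 kb study (400 regions, 200 genes, 2 + 2
replicates) and runs every stage. The three top GAIN DERs are
promoter-proximal with ~10-fold RPKM increases; the DER–gene fold-change
correlation (r = 0.71 over 83 linked genes) recovers the generator's
target ρ = 0.7; the planted motif is the only one enriched in GAIN summit
windows (19/44 windows vs 12/307 background); and the planted gene set
ranks first in the pathway stage. Every stage's tables are also written
under `demo_out/`, together with `report.txt` and an md5 `manifest.tsv`
(re-running the same config reproduces identical checksums).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/succer.R run --seed 1 --out demo_out
Rscript inst/cli/succer.R report --out demo_out
```

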