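---
title: "Methods: differential histone-mark enrichment and multi-omics integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential histone-mark enrichment and multi-omics integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`succer` implements a desk-scale pipeline for linking differential
histone-modification enrichment, measured by CUT&Tag in two conditions with
replicates, to differential gene expression, transcription-factor (TF)
regulation and pathway membership. The pipeline starts from peak regions and
fragment intervals (alignment and peak calling are upstream concerns) and
proceeds:

1. **Consensus regions** — union-merge of all samples' peaks.
2. **Quantification** — per-sample RPKM over consensus regions.
3. **DER calling** — GAIN/LOSS classification by a fold-change rule on
   group-mean RPKM.
4. **Annotation** — genomic feature, TSS distance, chromosome distribution,
   meta-profiles.
5. **Integration** — nearest-gene assignment within 100 kb, DEG
   intersection, fold-change correlation, paired signed-rank comparisons,
   cross-mark concordance.
6. **Motifs** — PWM scanning of summit windows, enrichment against a
   background, DETF identification, occurrence profiling, promoter-proximal
   target assignment.
7. **Pathways** — hypergeometric over-representation of DER-linked DEG
   sets.

A synthetic-data generator with complete ground truth accompanies the
pipeline so that every stage can be validated by parameter recovery.

# Coordinate and data conventions

All coordinates are 0-based half-open (BED-native) everywhere inside the
package; the readers convert on load and the writers round-trip canonical
BED byte-identically. The TSS of a minus-strand gene is `tx_end - 1` so the
TSS is always a valid coordinate; the TES is the opposite end. Book-ended
intervals merge at `gap = 0`, matching the dominant merge semantics of
genomic toolkits. Interval algebra (merging, overlap counting) is delegated
to `IRanges`; sequence handling to `Biostrings`.

# DER calling

Per sample, region signal is quantified as
\[
\mathrm{RPKM} = \frac{\text{fragment count} \times 10^9}
                     {\text{region length (bp)} \times \text{library size}},
\]
where the library size is the sample's total fragment count. Group means
are arithmetic means of replicate RPKMs. A region is **GAIN** when
\((\bar m_{case} + \varepsilon)/(\bar m_{ctrl} + \varepsilon) > \tau\) and
**LOSS** when the inverse ratio exceeds \(\tau\), with \(\tau = 2\) (the
study rule "more than 2-fold") and pseudocount \(\varepsilon = 0.5\) RPKM.

Choices worth noting:

* **Pseudocount** (\(\varepsilon\), RPKM units, default 0.5). The fold rule
  is undefined for zero-signal regions; without \(\varepsilon\) any region
  with a zero group mean becomes an infinite-fold call. 0.5 RPKM is far
  below real signal (hundreds to thousands of RPKM at usual depths) so it
  only stabilizes near-empty regions. Configurable.
* **Consensus set**. Whether group RPKM should be computed over a shared
  consensus or per-group peak sets is genuinely open; we default to the
  union consensus, which maximizes recall and keeps a single region
  universe for every downstream stage. Per-region contributing samples are
  recorded so stricter filters can be applied later.
* **No variance model.** The fold rule is deliberately the study's rule: a
  threshold on group-mean ratios, not a dispersion-modelled test with FDR
  control. The synthetic recovery results below quantify its operating
  characteristics under the generator's noise model; they are not a
  substitute for a statistical differential-binding test on real data.

Annotation uses the region midpoint with precedence
promoter-TSS > TES > exon > intron > intergenic. The promoter window is
\([TSS - 1000, TSS + 100)\) strand-oriented — the category's bounds are not
part of the study rule, so we adopt the convention of the annotation tool
family the field uses; it is configurable. TES proximity means within
100 bp. TSS distances are signed and strand-oriented (negative = upstream).

# Expression integration

Each DER is assigned to the gene minimizing |midpoint − TSS|, kept only
within 100 kb (strand-agnostic, per the study rule), ties broken by
lexicographically smallest gene id. "Nearest genes" is implemented as a
single nearest gene per DER; when several DERs share a gene, the per-gene
representative for the correlation scatter is the DER with the largest
|log2 fold change|, mirroring one-dot-per-gene presentations
(`per_gene = FALSE` gives all pairs). Genes absent from the expression
table are excluded, never imputed, and counted.

The Pearson correlation between DER and gene log2 fold changes is computed
by the product-moment formula with a two-sided Student-t P value
(`stats::cor.test`). The paired Wilcoxon signed-rank test drops zero
differences, assigns average ranks to ties, and uses an exact
dynamic-programming null for \(n_{\mathrm{eff}} \le 25\) (the DP runs on
doubled ranks so tied half-integer ranks stay on an integer grid); beyond
that, a normal approximation with tie-corrected variance and continuity
correction. The switch point is far below where the approximation error
matters; the exact path is itself validated against full \(2^n\)
enumeration in the tests.

# Motif layer

Summit windows are \(\pm 200\) bp around DER summits (midpoints when no
summit is recorded), clipped at chromosome ends. PWMs are column-normalized
counts with pseudocount \(\alpha = 0.01\); sites score
\(s = \sum_i \log_2 (p_i(x_i) / b(x_i))\) against a uniform background,
both strands, with N bases contributing the background odds (0) so masked
sequence degrades gracefully rather than failing. A hit requires
\(s \ge 0.8 \, s_{max}\); the study names no score cutoff, so the threshold
is a parameter. Overlapping same-strand hits collapse to the best-scoring
one. The scanner is vectorized by concatenating windows with an unscoreable
spacer; tests verify it against a naive per-position oracle.

Enrichment of a motif in target windows uses the one-sided binomial upper
tail \(P(X \ge k \mid n, p_0)\) with \(p_0\) the background hit fraction
floored at \(1/(2 n_{bg})\) — the behaviour of the cumulative-binomial
known-motif tools the field uses — with a hypergeometric alternative for
small fixed backgrounds. The study's gate is raw \(P < 0.01\);
Benjamini–Hochberg q-values are reported alongside but do not drive the
gate. The default background is summit windows of non-DER consensus
regions; the study does not state its background, and this choice keeps
background sequence composition matched to targets.

DETFs are TFs whose motif is enriched in GAIN regions and whose own gene is
significantly upregulated (mirror for LOSS/down). Occurrence profiles bin
hit midpoints in 10-bp bins over \(\pm 500\) bp around summits, as hit
density per bp per window, so that density × bin width × window count
reproduces the total hit count exactly. Target DEGs of a TF are genes with
a hit midpoint inside \([TSS - 2000, TSS + 2000)\) (strand-agnostic gate on
genomic coordinates; a promoter window is scanned with motif-length padding
so border sites are scored, then gated on the midpoint), sorted by
decreasing |log2FC|.

# Pathway over-representation

The hypergeometric upper tail
\(p = \sum_{i=k}^{\min(K,n)} \binom{K}{i} \binom{N-K}{n-i} / \binom{N}{n}\)
is accumulated in log space (`lchoose` + log-sum-exp) for numerical
stability. The query is the GAIN- (or LOSS-) linked DEGs filtered to
|log2FC| > 1, per the study's downstream rule; the gate is raw
\(P < 0.05\). The enrichment universe is not stated in the study; we
default to all genes present in both the expression table and the gene-set
collection — the least-assuming reproducible choice — and it is
configurable.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with full ground truth:

* **Genome and genes** — i.i.d. bases at configurable GC; non-overlapping
  genes (400–900 bp) on alternating strands with 2–5 exons, tiled with
  200–500 bp gaps.
* **Regions and signal** — regions tiled one per stride cell (so they never
  overlap), width 200–400 bp, summit at the midpoint. Fragment counts per
  region, sample and condition are negative binomial,
  \(X \sim \mathrm{NB}(\mu = d \, u_r \, 2^{\beta_r [case]}, \phi)\), with
  shared dispersion \(\phi\) (Gamma–Poisson, the standard overdispersion
  model for enrichment sequencing; Poisson recovered as \(\phi \to
  \infty\)) and region baselines \(u_r \sim \mathrm{LogNormal}(0, 0.5)\).
  Planted GAIN/LOSS regions receive \(|\beta| \in [\log_2 3, 3]\), above
  the 2-fold call threshold with margin, and are placed so each planted
  region's nearest gene is unique, guaranteeing recoverable linkage.
* **Library background** — a fraction of each library falls in consensus
  regions (`frip`, default 0.3, typical of a broadly distributed histone
  mark); the remainder is condition-independent background placed in
  inter-region gaps. This matters: real RPKM normalizes by *total* mapped
  reads, which are dominated by genome-wide background. A library composed
  only of in-peak fragments would make the normalization
  composition-sensitive — planted GAIN signal would inflate the case
  library and shift every null region toward LOSS. At desk scale regions
  cover a large fraction of the toy genome (unlike a few percent of a real
  genome), so background is kept out of regions entirely to stand in for
  "background overwhelmingly outside peaks".
* **Expression** — linked genes get \(\log_2 FC = a \beta_r + e\),
  \(e \sim N(0, \sigma_e)\) with \(\sigma_e = 1\) (moderate biological
  noise in log2 units) and \(a\) set from the planted-\(\beta\) spread so
  the population correlation equals `rho_target`; unlinked genes get pure
  noise. `significant` applies the downstream DEG filter |log2FC| > 1 —
  the DEG derivation itself is an upstream product consumed as a table, so
  the generator exercises the filter rather than simulating a full DE
  test.
* **Motifs** — with probability `p_fg` (GAIN summit windows) or `p_bg`
  (background windows) one site sampled from the PWM's raw base
  frequencies is written into the genome at a Normal(0, 50 bp) offset from
  the summit, clipped to the window. Sampling uses raw frequencies, not
  pseudocounted probabilities, so a consensus motif always plants its
  consensus.
* **Gene sets** — decoy sets are uniform draws; the planted set draws 60%
  of its members from GAIN-linked upregulated DEGs.

Determinism: one master seed; each stage derives a fixed child stream
(`stage_seed`), so stages are re-runnable in isolation and identical
configurations reproduce byte-identical output files (the pipeline manifest
records md5 checksums of every output; the timestamped log is excluded).

What the generator does **not** emulate: read-level errors, fragment-size
distributions, spike-ins, chromatin-state autocorrelation along the genome,
distance-dependent enhancer–gene linkage, correlated replicates, or the
composition of a real PWM library. Passing recovery tests therefore
demonstrates the pipeline's correctness under its own statistical
assumptions, not performance on real data.

# Validation scales and expected behaviour

The recovery checks run at the study conditions the package adopts
throughout its tests: a 1 Mb genome (2 × 500 kb), 700 genes, 2,000 regions
with 10% GAIN + 10% LOSS planted at \(|\beta| \ge \log_2 3\), depth 200,
\(\phi = 10\), 2 + 2 replicates; the correlation check plants 600 linked
pairs at \(\rho = 0.7\); the motif check plants at
\(p_{fg} = 0.6 / p_{bg} = 0.05\) over 200 foreground and 2,000 background
windows against 100 random decoy motifs. The bundled demonstration
configuration (`demo_config()`) is a 2 × 150 kb genome with 400 regions
and 200 genes, sized so the full pipeline completes in seconds while every
stage retains recoverable signal. The correlation check evaluates the
measured region log2FC of all planted linked pairs against gene log2FC:
measurement noise attenuates the planted \(\rho\) only slightly (the
planted effect spread dominates the NB noise at depth 200), so the
recovered r is expected a little below the target.

# Known limitations

* The fold rule provides no error-rate control; its type-I behaviour
  depends on depth, dispersion and the pseudocount.
* Single-nearest-gene assignment ignores multi-gene regulatory domains and
  distance weighting.
* The binomial enrichment test treats windows as exchangeable; sequence
  composition differences between targets and background are only
  addressed through the choice of background windows.
* The study's own headline region/gene/TF counts derive from deposited
  sequencing data and upstream alignment and peak-calling choices, and are
  out of reach at desk scale by design; validation is property- and
  recovery-based instead.
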