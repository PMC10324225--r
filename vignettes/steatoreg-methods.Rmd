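---
title: "Methods: integrative regulatory and methylation analysis of hepatocyte epigenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative regulatory and methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoreg)
```

# Overview

`steatoreg` implements an integrative analysis for a two-condition hepatocyte
study design — a steatosis-inducing high-fat/alcohol diet (LDC) against a
control diet (Co) — combining three data layers:

1. **Open chromatin**: differential DNase-accessibility peaks, scored for
   transcription-factor (TF) binding affinity and aggregated into per-gene,
   per-condition TF scores.
2. **Transcriptome**: filtered differential-expression (DE) calls partitioned
   into k = 4 functional gene clusters.
3. **DNA methylation**: chromatogram-based methylation indices and bisulfite
   read-count tables, filtered to differential CpGs and classified for
   aging-versus-diet concordance.

The unifying question: which TFs explain the direction of differential
expression, and in which gene cluster is each TF's accessibility gain
concentrated? Because the original sequencing data are not required, a
first-class synthetic module generates all inputs with the assumed
statistical structure, and the test suite's plant–recover and null
calibration checks are run against it.

# TF binding affinity (TRAP model)

Each motif is a position frequency matrix regularized with a pseudo-count of
1 per cell (preventing infinite log-odds) and column-normalized. A candidate
site `s` of width `W` receives a binding probability

$$p(s) = \frac{K}{1+K}, \qquad K = R_0\, e^{-E(s)/\lambda},$$

where the mismatch energy `E(s)` is the consensus log-odds sum minus the
site's log-odds sum against a uniform 25% background, so the consensus site
has `E = 0` and probability `R0/(1+R0)`. Parameters follow the TRAP
biophysical calibration used by open-chromatin TF scoring pipelines:
`lambda = 0.7` and `ln R0 = 0.584 W − 5.66`; both are exposed via
`trap_params()`. `N` bases contribute the background frequency (zero
log-odds). Both strands are scored as separate sites — no per-position
strand maximum — and a region's affinity is the plain sum of site
probabilities over every position on both strands. Regions shorter than the
motif score 0 with a warning: no site fits, and treating this as an error
would make mixed-width motif panels unusable.

## TF–gene scores and the affinity quotient

For gene *g* and TF *t*, the score $A_{t,g}$ sums full (unprorated) region
affinities over all peaks of one condition-specific peak set that overlap
the window `[TSS − w, TSS + w)` with `w = 50000` bp by default — the same
window used to tie chromatin domains to genes. Design choices here, made
where the underlying method description is silent:

- **Any-overlap, full contribution.** A peak overlapping two genes' windows
  counts fully for both. No exponential distance decay is applied, matching
  the plain "sum over peaks in a window" formulation; the decay variant is a
  deliberate non-goal.
- **TSS anchoring.** The window is anchored at the TSS (the convention of
  the open-chromatin scoring tool this emulates); `anchor = "gene_body"`
  extends from both gene ends instead for sensitivity analysis.
- **Condition-specific peak sets.** Peaks are split by the sign of their
  accessibility log fold change (LDC over Co): positive-logFC peaks form the
  LDC set, negative the Co set. Zero-logFC peaks are excluded and counted.
- **Expressed-TF filter.** TFs whose gene has baseMean < 10 in the DE
  results are dropped before scoring.

The downstream feature is the pseudo-counted log2 quotient
$q_{t,g} = \log_2\!\big((A^{LDC}_{t,g}+\varepsilon)/(A^{Co}_{t,g}+\varepsilon)\big)$
with $\varepsilon = 10^{-6}$. The pseudocount makes the quotient exactly 0
when both affinities vanish and antisymmetric under swapping conditions.

# Expression filters and clustering

Genes are retained when **more than** 0.1 FPM is observed in at least 4
samples (the FPM comparison is strict, the sample count inclusive). DE calls
use adjusted p ≤ 0.05 — the threshold is read as an attained upper bound, so
a gene at exactly 0.05 passes; boundary cases are logged. Direction is the
sign of log2FC; significant genes with log2FC exactly 0 are flagged and
excluded from direction labels.

The original analysis clustered DE genes on a protein-interaction network,
which is out of scope here; `cluster_genes()` runs Euclidean k-means
(k-means++ seeding, 10 restarts, 300 Lloyd iterations) on any caller-supplied
feature matrix, and the cluster-assignment file format is the contract, so
externally derived clusters can be injected unchanged. Rows are sorted by
gene id before seeding, making the partition invariant to input order under
a fixed seed.

# Regulator inference

`fit_dynamite()` regresses the per-gene DE direction (up/down) on the
standardized quotients $q_{\cdot,g}$ with elastic-net logistic regression at
mixing parameter `alpha = 0.01` (mostly ridge — the features are strongly
correlated because peak presence moves all TF scores together). The penalty
strength is selected by 6-fold inner cross-validation over a 50-point log
grid ($10^{-4}$–$10^2$); 10-fold outer cross-validation, stratified by
label, reports held-out accuracy; final coefficients come from a fit on all
data at the inner-selected penalty, then are normalized by the maximum
absolute coefficient. Normalization on the final fit (rather than averaging
across outer folds) is a documented choice where the upstream tool is
silent. TFs are ranked by normalized |coefficient|, ties broken by name, and
selected at ≥ 0.125; when a "top-n" convention and the threshold disagree,
the threshold rule wins.

# Cluster-wise TF effect score

With $Q_{t,i}$ the median of $q_{t,g}$ over the DE genes of cluster *i*
(only DE genes ever enter), the effect score is

$$E_{t,i} = Q_{t,i} - \frac{1}{K-1}\sum_{j \neq i} Q_{t,j},$$

i.e. the cluster's median quotient minus the mean of the other clusters'
medians. The `K − 1` divisor follows the verbal definition ("mean of the
others"); the printed formula's divisor is ambiguous, so a `divisor = "all"`
flag provides the `1/K` variant for sensitivity analysis. Consequences used
as tests: each TF's row of `E` sums to zero (to 1e-9), `E` is invariant
under per-TF location shifts of `Q`, and swapping condition labels negates
it. A positive $E_{t,i}$ means TF *t*'s binding gain under LDC is stronger
for cluster *i*'s genes than for the rest.

# Peak annotation

Differential peaks are partitioned by logFC sign, then labelled
promoter / gene body / intergenic with precedence promoter > gene body —
the precedence makes the three percentages an exact partition (summing to
100 per sign class), which double counting would not. The promoter is the
strand-oriented window `[TSS − 1000, TSS + 500)`; the original work never
defines "promoter", so this common convention is a config default exposed
as flags. `domains_to_genes()` assigns each chromatin domain its single
closest gene by interval distance (overlap = 0), reported only within 50 kb,
ties broken by TSS distance then gene id.

# Methylation arm

- **Chromatogram index**: `h(M) / (h(M) + h(UM))` from methylated and
  unmethylated peak heights; scale-invariant; undefined (error) when both
  heights are zero. Panel values are min–max normalized to [0, 100] for
  cross-technology display.
- **Differential CpGs**: a site passes iff coverage ≥ 5 reads in every
  sample (a per-group-mean mode is flag-selectable), |Δβ| ≥ 0.05, unbiased
  per-group variance of β < 0.05 in *both* groups, and BH-FDR-adjusted
  p < 0.05. The per-site p-value is a two-sided Welch t-test on
  arcsine-square-root transformed β — a declared stand-in for the original
  moderated linear-model test; at group sizes of 2–4 the moderation prior
  would dominate and is deliberately omitted, while the filter thresholds,
  which drive the result, are implemented exactly. Variance is computed on
  β (not M-values). The BH procedure is implemented internally and checked
  against a brute-force step-up oracle.
- **Aging loci**: |Δβ| strictly > 0.30 and FDR strictly < 0.1.
- **Coverage mask**: a site is excluded from reporting when any sample
  covers it with fewer than 3 reads (3 itself is retained).
- **Concordance**: per locus, the aging contrast (aged − young) and the diet
  contrast (LDC − Co) each yield a direction and a significance call
  (unpaired two-sided t, the shared engine for all technologies); classes
  are concordant / discordant / age_only / diet_only / neither.

# The synthetic world

The generator emulates the study design at toy scale, and its defaults are
fixed once:

| parameter | default | rationale |
|---|---|---|
| genome_length / n_genes | 40 Mb / 450 | ~90 kb gene spacing, so 50 kb TSS windows rarely capture neighbors, as in a mammalian genome |
| n_tfs / n_active_tfs | 20 / 2 | the plant–recover acceptance design |
| n_de_genes / n_clusters | 400 / 4 | DE genes partitioned into 4 clusters |
| effect_size | 1.5 | log2 accessibility gain of planted peaks in LDC |
| accessibility noise | NB, dispersion 0.1 | count overdispersion typical of DNase data |
| n_samples_per_group | 4 | the aging/validation cohort size; the diet epigenome arm of the emulated design used n = 2, too few for the unpaired t-tests the concordance comparison prescribes |
| aging_delta / diet_delta | 0.4 / +0.3 | aging hypomethylation beyond the strict 30% selection rule; diet shift opposite in sign |
| depth | 100 | typical targeted-bisulfite coverage; binomial SE ≈ 0.05 |
| SNuPE noise | log-normal, σ = 0.1 | multiplicative chromatographic height error |

Active TFs get informative motifs (85% consensus base per column) planted —
written into the genome sequence — at one peak within 2 kb of the TSS of
every DE gene of their target cluster; those peaks' negative-binomial mean
is multiplied by $2^{\text{effect\_size}}$ in LDC. The DE table is a planted
stand-in for an external count-model test: designated DE genes receive
padj < 1e-3 and direction labels that follow the planted accessibility
change in targeted clusters (coin flips elsewhere); non-DE genes get
padj ≥ 0.5. With `effect_size = 0` all planting is disabled and adjusted
p-values are uniform, so downstream DE fractions are nominal by
construction.

**What a green test does and does not establish.** The synthetic world has
i.i.d. background sequence, uniform base composition, independent peaks,
exactly consensus motif plants, and label noise only through sampling — no
GC bias, no correlated peaks, no motif degeneracy in the plants, no
batch structure, and the DE table's p-values are planted rather than fit
from counts. Recovery here demonstrates that the scoring, regression and
effect-score machinery propagate a known signal correctly; it does not
demonstrate power or error control on real sequencing data.

# Numerical choices and degenerate inputs

- All randomness flows from one root seed through named substreams
  (a string-hashed child seed per generator), so adding a generator never
  perturbs another's output; every generator is byte-deterministic.
- k-means ties and restarts: best of 10 k-means++ restarts by within-cluster
  sum of squares.
- Ranking ties: lexicographic TF name, making output files deterministic.
- `affinity_quotient` on all-zero matrices returns exactly 0 (ε/ε).
- Constant vectors in `normalize_index` map to 0 with a warning; a fold with
  a single class in `fit_dynamite` is prevented by stratified folding, and
  an unsplittable class is an error.
- Degenerate chromatogram calls (both heights 0) and malformed intervals
  (start ≥ end) are errors naming the offending record; parsers never
  silently drop lines.

# Known limitations

- The per-CpG test is unmoderated; at n = 2 per group (the emulated diet
  arm's real size) it is underpowered, which is why the synthetic default
  uses the validation cohort size of 4.
- No read-level simulation: signal is modeled at peak/site count level, so
  alignment and peak-calling artifacts are out of reach.
- The regression's feature transform fixes the quotient convention; other
  feature choices (per-condition scores, ratios without pseudocount) are not
  explored.
- Real cluster assignments (e.g. from a protein-network clustering) must be
  supplied through the cluster-file contract; the built-in k-means on
  expression features is a stand-in and will not reproduce network-derived
  clusters.
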