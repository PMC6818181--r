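---
title: "Distinguishing Warburg effects by pH logic: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing Warburg effects by pH logic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warburgph)
```

## The scientific question

Cancer tissues and normal proliferating cells (NPCs) both run the Warburg
effect — glycolytic ATP production with lactate secretion despite available
oxygen — but plausibly for different reasons. The package's working model:
cancer cells face continuous hydroxide production from cytosolic Fenton
chemistry and respond with a coordinated acidification program (acid-loading
transporters induced, acid extruders repressed, glycolytic ATP as a net
proton source), whereas NPCs first bank respiration-made ATP to *raise*
intracellular pH for division and then switch to glycolysis because a
consumed glycolytic ATP is pH neutral overall. Everything here operates on
case/control expression matrices; no metabolite is measured, so every
chemical quantity enters through a transcript proxy.

This vignette documents the models, the tunable parameters, the simulation
conditions the validation suite uses, and the numerical decisions taken
where the design was genuinely open.

## Expressed-gene thresholding

Pooled log2 expression over all genes and samples of a dataset is treated
as a two-mode mixture: a low mode of non-expressed genes and a high mode of
expressed ones. `find_expression_threshold()` estimates the density by
Gaussian KDE with Silverman's rule-of-thumb bandwidth on a 512-point grid,
takes the two highest local maxima as the modes, and places the threshold
at the density minimum strictly between them. Two guards matter in
practice:

- a candidate mode must reach at least 5% of the global density maximum
  (`min_peak_frac`); without this, tail ripples of a unimodal density get
  read as a second mode and the "valley" lands in the far tail;
- unimodal data signal a `NoValleyError` rather than returning a guess;
  `run_pipeline()` then falls back to a user-supplied manual threshold.

The threshold is computed once per dataset on cases and controls pooled. A
per-group computation would allow the "expressed" universe to differ
between groups being compared, which the downstream exclusion rule (only
genes expressed in neither group are dropped) does not want; `mark_expressed()`
still reports per-group flags, using the group median against the
threshold. For an equal-weight N(0,1) + N(6,1) mixture the analytic density
minimum is exactly 3.0 by symmetry, which anchors the recovery test.

## Differential expression

Tests are Wilcoxon: rank-sum for independent groups, signed-rank only when
the design declares matched pairs — a signed-rank test is simply undefined
for unpaired unequal groups, so the unpaired test is the default even
though matched designs are common in tissue studies. P-values are exact
when the implementation's exact small-sample path applies (no ties) and
tie-corrected normal otherwise; the suite pins the exact path to a full
permutation enumeration for totals up to 12. FDR is Benjamini–Hochberg
across the tested genes of one dataset.

Fold change defaults to the difference of log2 group means (a ratio of
geometric means on the linear scale), which is the natural statistic for
log-stored data; `fc_method = "linear_means"` provides the
arithmetic-ratio alternative for sensitivity analysis. Two calling tiers
coexist deliberately: the differential call (FC > 1.3 with q < 0.01) feeds
gene lists, while the coarser |log2FC| > 0.6 tier feeds the categorical
transporter heat map, where a significance gate would leave mostly blanks
in small datasets.

## The transporter panel and the acidification score

The panel is shipped as data (`inst/extdata/transporter_panel.tsv`), not
code: membership is a curation decision users may amend. Included are the
plasma-membrane transporters with an unambiguous acid-loading or
acid-extruding direction; each excluded family member carries its reason
(multi-compartment localization, Golgi/endosome residence, no expression,
single-tissue expression, non-bicarbonate function). ATP6V0B and ATP6V0C
are one plasma-membrane V-ATPase signal carried under two symbols; the
synthetic presets plant them identically.

The acidification score is an integer tally,
`(#loaders up + #extruders down) − (#loaders down + #extruders up)` over
the heat-map calls, giving a maximum of +13 for the full cancer-like
pattern (6 loaders + 7 extruders). It is a transparent, antisymmetric
surrogate for a qualitative expression-pattern argument — nothing more. The
lactate exporters SLC16A1/A3 never enter it: they are driven by the proton
gradient, so their induction says nothing about which way the cell is
pushing its pH.

## The Warburg classifier

Criterion (i) requires more-than-two-fold induction of lactate production
(LDHA or LDHB) *and* of lactate export (SLC16A1 or SLC16A3). Criterion
(ii) requires the PDHB/PKM expression ratio — the proxy for the fraction
of glycolytic flux leaving pyruvate kinase for the TCA cycle via pyruvate
dehydrogenase — to decrease in cases. Both are computed on the linear
scale: a ratio of log values is not a flux proxy, and linear computation
makes the verdict invariant to a common positive rescaling of all samples.

"Decreases" is operationalized as a strict decrease of the median
per-sample ratio. The per-sample form was chosen over the ratio of group
means because it is robust to a few extreme PKM values and admits an
optional rank-sum significance gate (`significance_gate = TRUE`, off by
default since the criterion is descriptive); the group-mean form remains
available as `ratio_mode = "group_means"`. Samples with zero linear PKM
would make the ratio undefined and are excluded with a logged count.

## Gene-set correlation machinery

Three procedures, used where each is defined:

**PC regression.** For a single gene against a set, PCA on the set's
samples-by-genes submatrix; if PC1+PC2 explain at least 75% of the
variance, fit `e_g = β1·PC1 + β2·PC2 + β0` by least squares and report R²
with the overall F-test p. The 75% gate is a fixed parameter
(`variance_gate`); when the second PC is numerically degenerate
(collinear sets) the regression simply drops to PC1 with β2 = 0.

**Hypergeometric overlap.** When the gate fails, significance comes from
selection: Pearson-correlate the gene against all other genes (background
N), select the n genes significant under BH at α = 0.01, count the overlap
m with the M-gene set, and report the upper hypergeometric tail
`P = 1 − Σ_{i=0}^{m−1} C(M,i)C(N−M,n−i)/C(N,n)`, evaluated as an explicit
log-binomial sum. The overlap count is the *intersection* of the selection
with the set — the tail is only defined for m ≤ min(n, M), so a union
reading of m would be ill-formed. The same statistic drives
`enrich_genesets()` against user-supplied GMT libraries; no pathway
database is bundled.

**Principal curves.** For set-vs-set correlation, each set's sample cloud
is summarized by a one-dimensional principal curve; samples project to
arc-length positions (DP1, DP2) whose Pearson correlation (with its
two-sided p) is the set-to-set statistic. The fitter is Hastie–Stuetzle
projection–smoothing: positions initialized from PC1, coordinates smoothed
against positions by smoothing splines (df = 5) evaluated on at most 50
grid vertices, samples re-projected onto the polyline. Iteration stops on
the standard criterion for this algorithm — relative change in total
squared projection distance below 1e-4 — or when the mean displacement of
projected points falls below 1e-6, whichever comes first (cap 30
iterations). On diffuse clouds the displacement criterion alone never
fires: the iteration keeps relocating points at the 1e-3 level
indefinitely, which is why the distance criterion is the operative one.
Curve orientation is gauge-fixed so that positions correlate positively
with the set's per-sample mean expression, making the sign of the reported
correlation meaningful; exactly-antithetic data then give PCC = −1, which
the suite asserts.

## The Fenton criterion

The iron-catalyzed Haber–Weiss reaction `O2·− + H2O2 → ·OH + OH− + O2`
cannot be observed in expression data; the criterion asks instead whether
transcript proxies of its two sides co-vary across samples. The product
side is proxied by proteasome subunits (protein damage from ·OH); the
substrate side by H2O2-response genes (TXN, TXN2, GCLC, GCLM) and iron
uptake (TFRC, TFR2). Superoxide has no default proxy — it is produced
largely by innate immune cells outside the sampled transcriptome — so it is
a required-if-used configuration entry, validated for disjointness.

Each side is aggregated to a per-sample score by the first principal
component of the z-scored gene submatrix, sign-fixed to correlate
positively with the side's mean standardized expression. PC1 after
standardization is the minimal aggregation consistent with "a weighted
summary of the marker genes"; standardization makes the verdict invariant
to per-gene rescaling, which the suite asserts. The reaction is called
present when the two scores correlate positively with two-sided Pearson
p < 0.01. Under the null simulation this criterion's type-I error is
checked against the 0.02 band at 200 replicates; power is checked at a
planted latent correlation of 0.8.

## Proton energetics

The stoichiometric ledger is fixed by the three reactions: respiratory ATP
synthesis consumes one proton (hydroxide is released), glycolytic
synthesis is pH neutral with one lactate per ATP, hydrolysis releases one
proton. Consequences: a consumed glycolytic ATP nets +1 H⁺, a consumed
respiratory ATP nets 0, and accumulating N respiratory ATPs removes N
protons.

The closed-form proton count for a pH shift is
`(10^−pH_start − 10^−pH_end) × V × 10⁻¹⁵ × β × N_A` with V in μm³
(10⁻¹⁵ L/μm³) and β the dimensionless buffering coefficient converting the
free-proton change to total protons moved against the cytosolic buffer in
this pH range. The constants are fixed at the conventional values used for
this calculation — V = 100 μm³, β = 2×10⁵, N_A = 6.02×10²³ (not CODATA, so
printed three-digit values reproduce exactly) — giving 1.4289×10⁹ protons
for 6.8 → 7.4, equal to the respiratory-ATP count, and 4.76% of the
3×10¹⁰-ATP cost of synthesizing a 6×10⁹-nucleotide genome at 5 ATP per
nucleotide.

## Time courses

An activation time course (19 points at 20-minute intervals in the
emulated design) is reduced to 18 usable points by dropping time zero — it
precedes activation; `drop_first = FALSE` trims the end instead — and
averaged within six consecutive 3-point segments. Trends are classified
from segment means: Spearman ρ ≥ 0.8 against segment index is `rising`,
≤ −0.8 `falling`, an interior maximum with monotone flanks
`peak_then_decline`, anything else `flat`. The ρ threshold is a
package-defined operationalization of verbal trend descriptions; reversing
a series provably swaps rising and falling.

## The synthetic-data generator

`simulate_dataset()` is the ground-truth instrument for the whole suite.
Its model: per-gene baselines from a two-component Gaussian mixture on the
log2 scale (non-expressed N(0,1) with probability 0.3, expressed N(6,1));
independent per-sample Gaussian noise of sd 1; planted fold changes as
additive log2 shifts on case samples; latent links realized by a shared
per-sample factor z with loadings √ρ on both member sets (sign of ρ
carried by the second set), giving expected cross-set gene-gene
correlation ρ without specifying a full covariance. These defaults are the
fixed study conditions of the validation suite — 50/50 samples (100/100
where the tests say so), 2000 genes for distribution-level checks, smaller
panels where only named genes matter.

What it deliberately does *not* model: read counts and library-size
effects, probe-level microarray noise, tumor purity, batch structure, and
correlated noise beyond the planted links. Passing tests therefore
demonstrate that the statistics recover *planted* structure under clean
sampling assumptions — they say nothing about robustness to the
compositional and technical artifacts of real TCGA/GEO data, which is the
usual caveat for simulation-validated pipelines.

Time courses are generated per trend shape: linear ramps for
rising/falling and a half-sine bump for peak-then-decline, so noiseless
segment means are strictly monotone on each flank, plus Gaussian noise
(sd 0.25 by default).

## Validation suite sizes and runtimes

The simulation studies run at fixed sizes chosen to make their binomial
error bands meaningful while keeping the whole suite around a minute and a
half on one CPU: classifier power and size at 100 replicates of
n = 100/100; Fenton size at 200 null replicates and power at 100; valley
recovery at 50 replicates of 5000 pooled values; principal-curve null
calibration at 100 replicates of n = 200. The acceptance script re-runs
the same studies with seeds derived from its `--seed` argument.

## Known limitations

- The Fenton criterion is correlational; a strong shared confounder across
  proxy sets (e.g., proliferation rate) would satisfy it without any
  chemistry. The proxy lists are editable precisely so users can probe
  this.
- The proteasome default list covers the 26S subunits (PSMA1–7, PSMB1–7,
  PSMC1–6, PSMD1–14); immunoproteasome variants are not included by
  default.
- The Pearson p-value attached to principal-curve projections treats the
  projections as ordinary observations; with flexible curves it runs
  slightly anti-conservative near the nominal 5% level (measured ~0.05–0.06
  under the null conditions above).
- The plasma-membrane fraction of V-ATPase expression is not deconvolved;
  observed ATP6V0B/0C expression is used directly.
- `classify_warburg()` presumes the six marker genes are present and
  expressed; datasets lacking them fail fast rather than degrade.
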