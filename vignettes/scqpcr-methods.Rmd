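---
title: "Methods: pooled single-cell qPCR analysis with scqpcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled single-cell qPCR analysis with scqpcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scqpcr)
```

## The measurement model

`scqpcr` analyzes microfluidic qPCR experiments in which the unit of
measurement is a pool of ~10 laser-captured single cells of one type
(neuron, microglia, or astrocyte), with several pools per animal, animals
nested in treatments (Placebo, Morphine, Naltrexone, Withdrawal), and a
parallel qPCR panel of gut bacterial taxa measured in cecal specimens. A
raw measurement is a cycle-threshold value Ct: the PCR cycle at which
fluorescence crosses threshold. Ct is a log2-scale quantity — one cycle is
one doubling — and *lower* Ct means *more* template. A reaction that never
crosses threshold is a **non-detect**; `scqpcr` treats non-detects as
missing values throughout. Substituting a ceiling value (say Ct = 40)
would translate into a fake, finite expression value after normalization,
so non-detects propagate as `NA` with pairwise-complete handling in every
downstream computation, and nothing is imputed.

## Quality control

Three QC layers, each with exact bookkeeping in a `qc_report`:

* **Batch-wise assay exclusion** (`exclude_failed_assays`). An assay that
  fails within any single batch — from poor signal quality or assay
  contamination — is removed from the *entire* dataset, not just the
  offending batch, so every retained gene is analyzable across the whole
  design. "Fails" is operationalized as a within-batch non-detect
  fraction at or above `failure_rule`; the default 1.0 demands complete
  failure. The threshold is configuration, not inference: the rule itself
  is qualitative in origin and a study may reasonably tighten it.
* **Sample-level filters** (`sample_qc`). Samples are dropped when their
  overall non-detect fraction exceeds `max_missing_frac` (default 0.3) or
  when any housekeeping Ct leaves `hk_ct_range` (default 5–35 cycles),
  both signs of failed capture, lysis, or loading. Detected Ct outside a
  plausible 0–40-cycle range warns but does not drop by default.
* **Marker validation** (`validate_celltype_markers`). Collection purity
  is confirmed per cell type by requiring the median expression of the
  type's own marker (NeuN, Maf, Gfap) to strictly exceed the within-type
  median of every other type's marker.

## Two-step −ΔΔCt normalization

**Step 1 — reference correction.** Within each sample,
−ΔCt(s, g) = ref(s) − Ct(s, g), where ref(s) is the arithmetic mean of
the selected reference genes' Ct values. Because Ct is log-scale, the
arithmetic mean of Ct is exactly the log of the geometric mean of the
linear-scale reference quantities — the geometric mean that multi-gene
reference normalization calls for. (Averaging on the linear scale instead
is a common implementation mistake; the package deliberately never forms
linear-scale quantities.) The subtraction cancels any per-sample additive
Ct offset, which is the shift-invariance property the test suite checks to
10⁻¹². Samples in which a reference gene is a non-detect cannot be
normalized and are dropped with a log message.

**Step 2 — median centering.** Each gene's −ΔCt values are centered on
their median across the centering scope, producing −ΔΔCt: unitless,
log2-scale relative expression with higher = more expressed. The default
scope is global (all samples of the dataset being normalized); per-group
centering (e.g. per cell type) is exposed because cell-type panels are
typically run as separate arrays, and whether batches should be centered
jointly is genuinely ambiguous — we default to joint centering and leave
the scope as explicit configuration.

**Reference-gene selection.** Candidate housekeeping genes are ranked by
two stability measures computed on raw Ct: per-assay variance, and the
geNorm M value — for candidates j, k the pairwise variation
V(j,k) = sd over samples of (Ct_j − Ct_k), and M_j = mean of V(j,k) over
k ≠ j, with iterative exclusion of the highest-M candidate recorded round
by round. The combined rank is the unweighted mean of the two measure
ranks (no weighting is justified by anything stronger than symmetry), ties
resolved toward lower variance, then lexicographically, so selection is
deterministic. `select_reference_genes` takes the top `n_refs` (default 2,
the Ldha/Actb situation in brain panels; pan-bacterial controls play the
same role for gut panels). A designated independent control (Gapdh) is
normalized like any gene but is excluded from candidacy and from
downstream testing.

## Differential expression: nested ANOVA

Replicate pools from one animal are not independent: the animal (n = 4
per treatment) is the biological replicate. Treating pools as independent
replicates inflates the type-I error badly — with an animal-level SD equal
to the residual SD and 8 pools per animal, naive pooled one-way ANOVA
rejects a true null far above its nominal 5% (the suite demonstrates
>10% empirically, typically ~35%), while the nested test holds its size.
The nested F statistic is MS(treatment) / MS(animal within treatment).
Two routes are implemented and are provably identical on balanced data:
a closed-form expected-mean-square decomposition (`method = "balanced"`),
and the default collapse of pools to unweighted animal means followed by
one-way ANOVA across animal means, which remains valid under unbalanced
pool counts. Degenerate inputs are pinned down rather than left to
floating-point accident: zero between-group signal reports F = 0, p = 1;
a zero denominator mean square reports p = NaN with a warning, and NaN p
values are excluded from multiple-testing adjustment with a logged count.

Microbial differential abundance uses a treatment × taxon two-way linear
model on animal-level data, with per-taxon treatment F tests and the two
reported contrasts (Withdrawal vs Morphine, Withdrawal vs Placebo)
extracted via estimated marginal means; a per-taxon one-way variant is a
configuration switch, since the exact factorization behind a published
"two-way ANOVA" on such panels is ambiguous. Benjamini–Hochberg
adjustment (`bh_adjust`, delegating to `stats::p.adjust`) supplies q
values; BH is the standard step-up procedure producing "q < threshold"
edge and significance criteria.

## Treatment separation: PCA composite weights and LDA centroids

PCA is run on the samples × genes −ΔΔCt matrix with genes standardized by
default (consistent with z-scored heat-map displays; covariance PCA is a
switch). In this design the first component tends to carry overall
expression magnitude while treatment structure concentrates on components
2 and 3, so each gene's contribution to treatment clustering is the
composite weight √(PC2² + PC3²) of its loadings — invariant to the
arbitrary sign of either component.

Treatment separation is quantified in Fisher discriminant space. The
convention matters for the numbers and is therefore fixed and documented:
pooled within-class covariance S_W with denominator N − C; between-class
covariance S_B weighted by class size; generalized eigenproblem solved by
symmetric whitening of S_W; discriminants scaled to unit pooled
within-class variance (a′ S_W a = 1) and sign-fixed by making the
largest-magnitude loading positive. A ridge of 10⁻⁶ × mean(diag(S_W)) is
added for numerical stability; it perturbs distances at the ~10⁻⁶
relative level. Class centroids are class means in the full (C − 1)-
dimensional space and separation is their pairwise Euclidean distance.
Under this convention centroid distances are invariant to any invertible
linear transformation of the gene space (a property test), and they agree
with `MASS::lda`'s scaling to ~10⁻³ relative difference, so published
distances computed under that common convention are directly comparable.

## Correlation networks

Within each treatment × cell type condition, all gene pairs get a Pearson
correlation on pairwise-complete observations (pairs with fewer than
`min_pairs = 5` shared observations are untested and logged; zero-variance
genes are excluded). Two-sided p values come from the t distribution on
n − 2 df; BH adjustment runs within each condition's full set of tested
pairs — per-condition rather than pooled, matching networks that are
rendered per panel. Edges are pairs with q < 0.001, carrying r, |r| as
weight, and sign; node attributes carry each gene's median −ΔΔCt. The
handshake lemma, threshold monotonicity, and empirical FDR control under
the null are all asserted by the suite. Export goes to edge-list TSV and
`igraph` for downstream graph tooling.

## Bimodal subphenotypes

Some genes split one condition's samples into high/low-expressing
subgroups. No standard test is implied by a density plot, so the package
uses a transparent model comparison: one- versus two-component Gaussian
mixtures (unequal variances, deterministic model-based initialization via
`mclust`, so repeated runs are identical), calling bimodality when the
two-component BIC improves on the one-component BIC by at least
`criterion_threshold = 6` — a conventional strong-evidence margin — and
both mixture weights clear `min_group / n` and both realized subgroups
hold at least `min_group = 3` samples. The split point is the
equal-posterior boundary between the component means (root of the
weighted-density difference, found inside the interval between means;
midpoint fallback for heavily overlapped fits). The threshold is
deliberately conservative: on unimodal Gaussian nulls the false-positive
rate stays under 5%, and a planted mixture with components at −2 and +2
(σ = 0.5, n = 60) is detected in ≥95% of replicates. Detection power
drops steeply for component separations below ~6σ at this margin; an
explicit user-supplied split point can override the model-based cut, which
mirrors reading a density plot by eye. `split_and_profile` partitions the
condition at the anchor gene's split and reports per-gene subgroup
medians, optionally relative to mean Placebo expression.

## The Firmicutes:Bacteroides ratio

Gut panels are normalized by the identical two-step machinery with
pan-bacterial control assays as the reference. The dysbiosis summary uses
the phylum-level Firmicutes (F) and Bacteroides (B) assays — the dedicated
phylum assays, not aggregates over member taxa. Because −ΔΔCt values are
relative, the ratio is anchored by a normalization factor NF = 1 − F
recomputed per treatment, displayed as (F + NF) : (B + NF) = 1 : r with
r = B + NF. Two consequences are tested: F + NF = 1 identically, and r is
invariant to adding a common constant to both medians *only because* NF is
recomputed — NF is not a fixed constant. The NF construction is a
reconstruction from a published summary table (consistent across all four
of its columns) rather than a formula stated in prose, so `fb_ratio`
accepts an explicit NF override; the anchoring of F at exactly 1 has no
stated derivation. Display rounds half-even at 2 decimals and a computed
right-hand side of 0.425 prints as 0.42 under that convention, a
sensitivity worth knowing when comparing against printed tables.
A non-positive B + NF has no meaningful ratio and is flagged undefined
rather than clipped.

## The synthetic-data generator

`generate_sc_qpcr` produces Ct-level data with the full structure the
analysis assumes, with every planted quantity recorded in a ground-truth
object so each pipeline stage has a recoverable target. Effects are
planted on the −ΔΔCt (log2) scale and mapped to Ct by sign inversion.
Defaults mirror the motivating design: 4 treatments × 4 animals × 8
ten-cell pools per animal per cell type (~96 pools per cell type, near
the ~93 of the motivating study), 46 measured genes plus housekeeping
candidates of graded noise SD (0.15–0.8 Ct; Gapdh as never-selectable
control), residual SD 0.5 Ct, animal random-effect SD 0.3 Ct, a
withdrawal-dominated effect map (Tnf +1.5, cFos +1.2, Nos3 +1.0,
Ptges3 −1.8, Mapk1 −1.0 −ΔΔCt units in Withdrawal; Morphine ≈ Placebo)
with astrocytes most responsive (gain 1.3), marker elevation +4, one
bimodal condition (Mapk1 in Withdrawal astrocytes, gap 4, weight 0.5),
and logistic dropout in true Ct (midpoint 36 cycles, slope 1.5). The seed
is mandatory and generation is bit-identical given it.

What the generator does *not* emulate: amplification-efficiency
differences between assays, melt-curve artifacts, contamination
structure, non-Gaussian expression beyond the single planted mixture, and
correlation structure beyond what treatment/animal effects induce. A
passing suite therefore shows the pipeline recovers what it assumes — it
does not validate those assumptions on real chemistry.

The microbial generator (`generate_microbiome`) plants per-treatment
taxon shifts whose phylum-level pattern follows the motivating study's
published per-treatment medians, with subgroup taxa shifting in the same
direction as their phylum. One arithmetic caveat, relevant to exactness:
with equal group sizes, global median centering forces the all-sample
median of each taxon to 0, so planted constant shifts cannot reproduce an
arbitrary set of published group medians *exactly* — group medians of
centered data are only shift-equivariant, not freely assignable. The
worked-example path (`fb_ratio_from_medians`) therefore takes published
medians directly, and generator-based checks assert approximate recovery.

## Problem sizes and numerical choices

Simulation-backed assertions use sizes chosen to make their Monte-Carlo
error small relative to the asserted margins: 1000 null replicates for
ANOVA size calibration (binomial SE ≈ 0.7 percentage points at α = 0.05),
500 replicates for network FDR and planted-edge power, 200 replicates for
mixture detection and reference-pair recovery, and 200 random instances
for exact oracle equivalence of geNorm M. Exact identities (median-zero
centering, shift invariance, QC bookkeeping) are asserted to 10⁻¹² or
exactly. Ties are broken deterministically everywhere (documented in the
relevant functions); all randomness flows from explicit seeds.

## Known limitations

* No amplification-efficiency (standard-curve or Pfaffl-style)
  correction; −ΔΔCt assumes ~100% efficiency for all assays.
* The nested ANOVA is a fixed-effects-by-collapse approximation, not a
  REML mixed model; with severely unbalanced pool counts the unweighted
  animal-mean collapse loses some efficiency (the animal remains the
  replicate either way).
* LDA centroid distances are convention-dependent; comparisons against
  distances computed elsewhere are only meaningful under the documented
  whitening convention (ratios of distances are much more portable, being
  invariant to a global scale).
* Mixture-based bimodality detection with a BIC margin of 6 is
  conservative by design; weak separations (< ~6σ between components at
  n = 60) will often go uncalled.
* The NF = 1 − F anchoring is reconstructed arithmetic, not a derived
  quantity; interpret the ratio's absolute scale accordingly.
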