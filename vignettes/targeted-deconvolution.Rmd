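---
title: "Methods: targeted methylation-based cell-type deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted methylation-based cell-type deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetDeconv)
```

## Overview

targetDeconv estimates the cell-type composition of bulk samples from a
small panel of cell-type-specific CpG methylation markers assayed by
targeted bisulfite amplicon sequencing. The workflow has three stages:
select markers from a methylome-wide screen of sorted cells, build a
reference panel by assaying those markers in sorted cells, and estimate
proportions in bulk samples that were assayed for the same markers. This
vignette explains the statistical choices behind each stage, the knobs that
matter, and what the synthetic-data generator does and does not emulate.

## Marker selection: the priority score

The screen provides, for each CpG, a fragment-coverage value per sorted
sample (in enrichment-based methylome assays, coverage tracks methylation).
For a candidate CpG and a target cell type, the priority score counts the
conforming samples: target-type samples with coverage strictly above a
threshold (default 0.3) plus all other samples strictly below it. With 9
individuals sorted into 4 cell types the maximum score is 36, attained only
by CpGs that behave cell-type-specifically in every individual.

Two readings of the bound "individuals × cell types" are possible; we count
every conforming sample (9 above + 27 below = 36) rather than summing four
per-type sub-scores. Samples exactly at the threshold conform to neither
condition ("higher than"/"lower than" are taken literally as strict
inequalities). `rank_markers()` keeps CpGs whose best score reaches
`min_score` — the strict default intent is the total sample count, i.e.
specificity in *every* individual — groups them by best target type (ties
between types broken in lexicographic order), sorts by score then genomic
position, and optionally caps markers per type.

## Methylation calling and quality control

The methylation level (beta) of a CpG is the number of reads carrying a
methylated cytosine at the site divided by the total reads there; zero-depth
sites are missing, never 0/0 artifacts.

Targeted runs include no-DNA blanks. Their per-amplicon read level defines
the background; an amplicon in a real sample is kept only if its read level
**strictly exceeds** `factor` (default 5) times the mean blank level for
that amplicon — ties are excluded. We interpret an amplicon's "read level"
as its mean per-CpG total depth, which is directly comparable with the same
summary on the blanks; because both sides use the same summary, the
decision is unchanged if amplicon read sums are used instead. Amplicons
lacking blank coverage get background 0 (so any read retains them) and are
logged. Filtering happens per replicate, before merging: a replicate that
fails the background bar should not contaminate a passing one. The filter is
idempotent and always removes whole amplicons (all their CpGs) per
sample-replicate.

Duplicate assays are merged per CpG by the unweighted mean of the available
replicate betas (default), or by pooling raw counts
(`(meth1+meth2)/(tot1+tot2)`, the `"weighted"` policy). At equal depths the
two coincide exactly; at unequal depths the weighted policy favours the
deeper replicate.

## The reference panel

For each marker CpG and cell type the panel stores the mean methylation
across the sorted-cell reference individuals (`R^c`) and the cross-subject
dispersion. By default the dispersion is diagonal — one variance per cell
type per CpG — which is defined for any design. When the same individuals
were sorted into every cell type (a matched design), a full per-CpG
cell-type covariance can be estimated (`covariance = "full"`); with only a
handful of matched individuals this estimate is noisy, which is why the
diagonal remains the default. Missing betas (background-filtered) are
dropped complete-case per CpG per type; CpGs observed in fewer than two
individuals for some type are removed with a warning, since their mean or
variance would be undefined. Reference duplicates are merged before panel
construction.

## Estimating proportions

Per subject *i*, bulk methylation is modelled as
`Y_i = Σ_c p_i^c R^c + E_i` with no intercept (a mixture of fractions needs
none), and a separate regression is run for each subject on the
intersection of the subject's observed CpGs and the panel.

**OLS.** Unconstrained least squares; negative coefficients are truncated
to zero and the vector renormalized to sum to 1. The raw coefficients and
residuals are retained so users can inspect the unconstrained fit.

**Weighted NNLS.** The default estimator imposes non-negativity inside the
solver (Lawson–Hanson NNLS via `pracma::lsqnonneg`) and iterates a
variance-based weighting: with current normalized proportions `p`, CpG *g*
receives weight

\[ w_g = \frac{1}{\nu + p^\top S_g p} \]

where `S_g` is the cross-subject dispersion at *g* — with the diagonal
default, `p' S_g p = Σ_c p_c² var_c(g)`. The NNLS is refitted on rows
scaled by `√w_g` until the maximum change in normalized proportions drops
below `tol` (default 1e-6; `max_iter` 100, non-convergence is flagged and
warned, not hidden). No library-size factor enters the weight because betas
are already proportions. `ν` (default 1e-4) is a variance floor that keeps
weights finite for CpGs with zero estimated cross-subject variance; as
`ν → ∞` all weights equalize and the estimator reduces to plain NNLS.

The sum-to-one constraint is imposed by post-hoc normalization rather than
inside the solver, mirroring relative-abundance normalization in weighted
deconvolution practice; the raw (unnormalized) coefficients are reported
alongside. Tree-guided recursive zooming over cell-type hierarchies is
deliberately not implemented: the target problem is a flat four-type panel.

**Missing and critical markers.** Each subject is estimated on whatever
markers survived QC, provided at least as many markers as cell types remain
and the reduced design is full rank (collinear reference profiles raise an
error naming the cell types involved). Some amplicons, however, carry
information that cannot be compensated; `deconvolve_cohort()` accepts a set
of critical amplicons (e.g. `c("P14", "P17")`) and sets a subject's
proportions to missing — flagged, not silently estimated — when any of them
is entirely absent for that subject. The leave-one-out analysis below is the
tool for identifying such amplicons.

## Evaluation

Against samples of known composition, `evaluate_estimates()` reports per
cell type the Pearson correlation between estimated and true proportions
across samples (undefined — flagged `NA` — with fewer than 3 pairs or a
constant vector), the mean and sample SD (n−1) of the estimates next to the
truth's, and the RMSE with 1/n inside the mean (the standard definition, a
function of both bias and precision). Overall summaries are unweighted
means over cell types.

The bias test pools all sample × cell-type differences (estimate − truth)
into one paired two-sided t-test; per-type tests are also returned. One
structural caveat: when both estimates and truth lie exactly on the
simplex, the pooled differences sum to zero within each sample, so the
pooled mean difference is zero by construction and the pooled p-value is
close to 1 whenever per-type biases cancel; the per-type p-values are the
informative ones in that regime. Degenerate difference vectors are handled
explicitly: identically zero differences give p = 1 with a note, a constant
non-zero offset gives p = 0 with a note.

`leave_one_out()` drops each amplicon in turn, re-estimates all subjects and
re-evaluates, emitting one row per amplicon plus a baseline row computed on
the full panel (the baseline is byte-identical to a direct full-panel
evaluation). Markers whose exclusion collapses a cell type's correlation
are candidates for the critical set.

## The synthetic-data generator

`simulation_config()` defines a complete synthetic study; every downstream
stage is exercised by generated data, and a fixed seed reproduces all
tables bit-for-bit. The defaults describe the blood system the package was
built around:

* **Panel layout** — 4 cell types with 4/7/3/3 amplicons (17 total), 2 CpGs
  per amplicon (34 CpGs). Marker CpGs are methylated at `high_level` (0.9)
  in their target type and `low_level` (0.1) elsewhere: the bimodal,
  nearly-binary profile that priority-score selection produces.
* **Subject variation** — each individual's profile is the truth plus
  Gaussian noise truncated to [0,1], SD `subject_sd` (0.03) for a typical
  CpG. A fraction of CpGs (`var_cpg_fraction`, 0.25) is "variable", with
  `var_cpg_factor` (5) times that SD. Cross-subject consistency differs
  between CpGs in real panels, and this heterogeneity is precisely what
  variance-based weighting exploits; with homogeneous noise the weighted
  and unweighted estimators would be indistinguishable. Which CpGs are
  variable is part of the seeded ground truth and applies to reference
  individuals and bulk donors alike.
* **Read sampling** — per CpG, total reads are Poisson around `depth`
  (default 3000, a round figure of the same order as the per-target
  coverage such targeted runs achieve) and methylated reads are binomial.
  Duplicate assays are independent draws from the same expected beta.
* **Mixtures** — 10 bulk samples in duplicate, recycled from a fixed
  5-mixture design with per-type means (0.26, 0.12, 0.54, 0.08): a dominant
  granulocyte fraction, mid-sized T-cell and monocyte fractions and a rare
  B-cell fraction, with large spreads for CD3/CD15 and small ones for
  CD14/CD19. (A published expected-mean column of (0.28, 0.13, 0.58, 0.08)
  sums to 1.07 and therefore cannot be realized exactly by simplex rows;
  the design above is the closest simplex-valid analogue.) Each bulk sample
  draws its own donor profiles (truth + subject noise), so the reference
  panel never matches the bulk donors perfectly — the model's residual term
  is real, not decorative. A Dirichlet mode is available for cohort-style
  spreads.
* **Blanks** — two no-DNA libraries with Poisson(`blank_rate`, default 10)
  background reads per CpG site. No distribution for blank reads is
  established in the field; Poisson is an assumption of this simulator, and
  `blank_rate` is defined per site so that the amplicon-level background
  (mean per-site depth) equals it.
* **Coverage screen** — `simulate_coverage()` emulates the marker-discovery
  matrix (9 individuals by default): coverage centred on the methylation
  level with Gaussian measurement noise, floored at 0.

What the generator does **not** emulate: bisulfite-conversion failure,
alignment and mapping artifacts, primer/amplification efficiency
differences between amplicons, batch effects, and correlated errors between
CpGs of one amplicon (amplicon-level exclusion is modelled, amplicon-level
noise coupling is not). Passing recovery tests on synthetic data therefore
demonstrates correctness of the estimation machinery under the stated
statistical model, not robustness to every artifact of real amplicon
sequencing.

## Numerical choices and degenerate inputs

* NNLS: Lawson–Hanson active-set (`pracma::lsqnonneg`); the iteration,
  weighting and normalization are implemented here.
* Weight floor `ν = 1e-4`, convergence `tol = 1e-6` on proportions,
  `max_iter = 100`; non-convergence returns the last iterate with
  `converged = FALSE` and a warning.
* All-zero truncated OLS coefficients (a bulk profile anti-correlated with
  every reference) raise an error rather than returning an arbitrary
  simplex point.
* Score ties in marker ranking break by genomic position; type ties for a
  CpG's best target break lexicographically — both make output order
  deterministic.
* Background-filter ties ("exactly 5×") are excluded; threshold ties in the
  priority score conform to neither condition.
* Proportions are reported to machine precision on the simplex (sum within
  1e-9); evaluation excludes missing estimates pairwise.

## Problem sizes used by the test suite

The suite exercises the default study (10 mixtures × 2 replicates, 34 CpGs,
depth 3000), a 50-sample Dirichlet cohort for parameter-recovery checks, a
20-replicate depth-contrast experiment (depth 150 vs 3000) for the
precision-vs-depth property, and 100 random two-type panels for the
grid-search oracle of the OLS solution — sizes chosen so the whole suite
runs in a few minutes on one CPU while leaving the stochastic assertions
comfortable margins.

## Known limitations

* Flat estimation over the configured cell types; no hierarchical zooming.
* The diagonal dispersion default ignores cross-cell-type covariance of
  subject effects unless a matched design is declared.
* The pooled bias test is uninformative when estimates are
  simplex-normalized (see above); rely on the per-type tests there.
* Reference and bulk assays are assumed to share the marker universe;
  probe-level batch harmonisation is out of scope.
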