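---
title: "Poly-omic risk scores: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poly-omic risk scores: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
statistical model, the assumptions behind each stage, the tunable
parameters and their defaults, what the synthetic cohort generator does
and does not emulate, and the numerical choices that were genuinely open.

## The modelling framework

The package predicts a binary diagnosis (IBD vs non-IBD) from longitudinal
multi-omic stool profiles. The central idea is borrowed from polygenic
risk scores: instead of testing features one at a time, each omic layer
contributes a single *score* — a sparse weighted sum of its features —
and the scores, not the features, are compared and combined.

Three models do the work.

**Selection** (per layer, training samples only): an L1-penalized
mixed-effects logistic regression

$$y = \mu + \sum_{i=1}^{n} \beta_i\,\mathrm{feature}_i + \beta_{n+1}\,
\mathrm{age} + \beta_{n+2}\,\mathrm{sex} + \beta_{n+3}\,\mathrm{race} +
\beta_{n+4}\,\mathrm{abx} + (1\mid \mathrm{site}) +
(1\mid \mathrm{participant})$$

with the penalty applied only to the feature block. Random intercepts for
study site and participant absorb site effects and the repeated sampling
of individuals; demographic covariates are never penalized, so features
are selected *conditionally* on them. The additive error in the printed
form of such logistic models is read here as binomial observation error,
not an estimable residual.

**Refit**: the selected features are refitted without penalty in the same
mixed-model structure (`lme4::glmer`), giving unshrunken weights
$\beta_1 \dots \beta_n$ estimated in the presence of the confounders.

**Scoring and evaluation**: each sample's raw score is
$\sum_j \beta_j x_{ij}$ — covariates deliberately excluded, so the score
carries only omic information. Raw scores are standardized against the
training scores (mean 0, SD 1, sample SD with $n-1$) and averaged over
each validation participant's longitudinal samples. Because validation
data collapse to one row per participant, evaluation models are ordinary
logistic regressions: `diagnosis ~ score + age + sex` for the
covariate-adjusted odds ratio per SD (Wald 95% CI), AUC from the
Mann–Whitney statistic with a DeLong CI (`pROC`), and Nagelkerke's
pseudo-$R^2$ against the intercept-only null. The combined model
`diagnosis ~ MGN + MTS + VRM + MBL + age + sex` is fitted on validation
participants averaged over samples where *all* layers are present, with
an age+sex reduction for $\Delta R^2$ and a leave-one-omic-out
decomposition.

## Preprocessing

Layer-specific recipes, in the order normalize → presence → collinearity
→ SD:

| layer | transform | presence rule (on raw) | collinearity | SD cutoff |
|-------|-----------|------------------------|--------------|-----------|
| MGN   | CLR       | —                      | —            | 1.0       |
| MTS   | CLR       | —                      | \|r\| > 0.95 | 1.0       |
| VRM   | CLR       | keep ≥ 5% of samples   | —            | 0.1       |
| MBL   | log10     | keep > 99% of samples  | \|r\| > 0.95 | 0.1       |

Decisions a reader should know about:

* **Pseudocounts.** CLR needs strictly positive values; the default adds
  0.5 to counts (half-count replacement) and 1 to intensities before
  log10. A pseudocount of 0 is allowed when the data contain no zeros;
  only negative pseudocounts are rejected.
* **Presence is computed on raw values.** After CLR with a pseudocount no
  zeros remain, so presence fractions are always taken on the raw table —
  the only self-consistent reading of a post-hoc sparsity filter.
* **Boundary conventions differ by design**: the sparse-layer rule removes
  features in *fewer than* 5% of samples (so exactly 5% survives), while
  the metabolite rule keeps compounds in *more than* 99% (so exactly 99%
  is removed).
* **Collinearity removal is random but seeded.** Whichever member of a
  collinear pair is dropped is chosen by a seeded RNG; the surviving
  *count* is invariant to the seed for clique-structured collinearity,
  the identities need not be.
* **Filters are fitted on training samples only** (`filter_scope =
  "train"`), then the frozen feature list is applied to validation
  samples, preventing information leakage through filter statistics. The
  pooled alternative is available via `filter_scope = "all"`.
* SD uses the $n-1$ denominator throughout.

## The penalized mixed-effects solver

No off-the-shelf penalized GLMM fitter is assumed; the solver is part of
the package. It alternates:

1. **Fixed effects** — a weighted least-squares lasso on the working
   response of the current IRLS linearization, solved by coordinate
   descent with soft-thresholding (compiled, with an active-set strategy:
   cycle the active columns to convergence, then one full sweep as a KKT
   check). Covariates and intercept are never thresholded. Features are
   standardized internally and weights back-transformed on output.
2. **Random effects** — closed-form group-wise ridge updates of the
   intercepts $u_g$ given the working weights, followed by an EM-style
   variance update $\sigma^2 \leftarrow (\sum_g u_g^2 + \sum_g v_g)/G$
   using the Laplace posterior variances $v_g$.

This is a penalized quasi-likelihood (PQL/Laplace) scheme: standard,
fast, and exact in the limits that matter for testing — with no grouping
and $\lambda = 0$ it reduces to IRLS logistic regression and matches
`glm` to ~1e-8; with no random effects it matches `glmnet` at matched
penalty; on orthogonal designs the kernel equals closed-form
soft-thresholding.

Numerical choices:

* **Convergence** is declared when the relative change of the penalized
  objective falls below `tol` (1e-8 by default, 1e-7 inside the pipeline)
  *or* when the joint parameter vector stalls (relative change < 1e-6).
  The second criterion matters because the alternating variance updates
  keep the objective wiggling at a small level that the objective
  criterion alone may never reach.
* **Monotonicity** of the penalized objective holds exactly for the
  fixed-effect phase and is asserted in tests in the no-random-effect
  regime; across variance-component updates small non-monotone wobble is
  expected and tolerated.
* **IRLS weights** are floored at 1e-6; coefficients larger than 30 on
  the standardized scale trigger a separation warning.
* $\lambda_{\max}$ is the largest absolute score-equation component of
  the penalized block at the **mixed** null model (intercept, covariates
  and random intercepts, no features), inflated by 0.5% so that the top
  of the grid reliably selects nothing despite the approximate
  convergence of the null fit. The grid is log-spaced down to
  `lambda_min_ratio` (pipeline default 0.05) with warm starts along the
  path.
* **Elbow rule**: among interior grid points (ordered by decreasing
  $\lambda$) pick the one maximizing the downward curvature
  $2c_k - c_{k-1} - c_{k+1}$ of the selected-count curve — the point
  where the count has just jumped and then flattens — with ties broken
  toward larger $\lambda$ (the sparser model). If no point has positive
  curvature (flat or linear curves, as in null data), the point whose
  count is closest to half the maximum is used, with a warning. The
  pipeline also truncates the path once a model exceeds `max_selected`
  (default 60) features: denser models are beyond the interpretable scale
  this framework targets, the elbow lies well below, and the dense tail
  dominates runtime.
* **Refit engine**: `lme4::glmer` with `nAGQ = 0` (PIRLS) by default —
  feature weights differ negligibly from the full Laplace fit at a
  fraction of the cost; `nAGQ = 1` is available. Failure falls back down
  the chain (other `nAGQ`, then `glm` without random effects), recording
  the engine used.

## Train/validation split

The split is at participant level: the `n_validation` (default 30)
participants with the most samples carrying *all* layers — ties broken by
the fewest incomplete samples, then participant ID — form the validation
set, because only complete samples can enter the combined model. Every
sample of a participant shares its assignment, so no validation
information can reach any training-stage computation; the run manifest
records the split and per-stage content hashes so this can be audited.
Score standardization constants likewise come from training scores only
(`standardize_scope = "train"`), with a pooled option.

## What the synthetic cohort emulates

`hmp2_like_design()` packages the study conditions the framework is
aimed at: 130 participants (103 IBD cases — CD:UC at 65:38 — and 27
controls) across 5 sites with realistic site weights, ages from
Normal(28, 17) truncated to 6–76 years, antibiotic use in ~18% of cases
and no controls, and one stool sample every 4 weeks over a year (13
visits). Layers carry 578/421/239/596 features (MGN/MTS/VRM/MBL) before
filtering.

Generation is case-control conditional: diagnosis is assigned first, and
each layer's per-participant latent log-abundance profile is baseline +
causal shift (cases only) + participant random intercept + site random
intercept, with i.i.d. per-sample noise. Count layers exponentiate,
normalize and draw multinomial counts at the layer's library size;
intensities are exponentiated directly. Random intercepts are drawn per
(participant, feature) and per (site, feature): a scalar per-participant
shift would cancel under compositional normalization, whereas per-feature
intercepts create the within-participant correlation the `(1|participant)`
term is there to absorb. Each RNG stream is derived per layer from the
master seed, so adding a layer never perturbs another's data.

Sparsity is emulated with per-feature dropout probabilities drawn from a
Beta distribution whose mean and concentration are layer parameters,
applied as a mask *after* the multinomial draw so presence fractions are
directly controlled. The VRM spectrum (mean 0.93, concentration 0.4)
makes ~90% of viruses too rare to pass the 5% presence rule, mirroring
the published bookkeeping of that cohort (239 → 9 features); the MBL
spectrum (mean 0.02, concentration 25) lets roughly half the compounds
fail the >99% rule (596 → 269). Causal effects are planted among
abundant, low-dropout features — in real cohorts the discriminative
features are the prevalent ones — with random signs. Effect sizes default
to strong metabolomic/viromic signals (0.5, 0.9 on the latent log scale),
a moderate metatranscriptomic signal (0.6, largely eroded by that layer's
35% missingness) and a weak metagenomic one (0.3), reproducing the
qualitative regime the framework is designed to expose (MBL/VRM highly
predictive, MGN near chance); these were set once against the reported
AUC regime of the motivating cohort and are not tuned further.

What the generator deliberately does **not** model: phylogenetic or
functional correlation among taxa, within-participant temporal
autocorrelation beyond the participant intercept (samples are i.i.d.
around the participant mean), batch effects, and the heavy-tailed
intensity distributions of real mass spectrometry. Passing tests
therefore demonstrate that the pipeline recovers planted additive
log-scale effects under compositional observation — not that it is robust
to those unmodelled structures.

## Problem sizes used in the test suite

Chosen as the package's own balance of statistical resolution and test
granularity: support recovery uses 130 participants (100 training after
the 30-participant split), 50 features with 5 causal at shift 2.0 and
participant-intercept SD 0.5, over 10 seeds; null calibration uses 20
seeds of a 60-participant, 30-feature cohort with all effects at zero;
the layer-ordering check runs the full pipeline on 10 seeds of a
50-participant, three-layer design with strong viromic/metabolomic and
weak metagenomic effects. The full four-layer emulation above is
exercised once in the acceptance script.

## Known limitations

* PQL/Laplace approximations bias variance components downward for
  binary data with small cluster sizes; the package uses them for
  selection (where only the support matters) and delegates the refit to
  `glmer`.
* The elbow is a heuristic; on signal-free data it falls back to
  half-maximum count and will happily select noise features (their refit
  weights are then small, and validation AUC sits at chance — the null
  calibration tests check exactly this).
* CLR is not subcompositionally consistent and is sensitive to the
  pseudocount for very sparse features; alternative log-ratio transforms
  are out of scope.
* With 30 validation participants and strong signals, evaluation models
  can separate completely; ORs are then flagged and their CIs reported as
  unbounded rather than trusted.
* KO-set origin classification is direction-agnostic presence/absence
  logic over user-supplied flat files; it does not reason about reaction
  directionality or pathway gaps.
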