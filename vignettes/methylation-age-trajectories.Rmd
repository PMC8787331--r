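---
title: "Methods: DNAm age, cell-type adjustment, and trajectory mixtures in serial CSF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNAm age, cell-type adjustment, and trajectory mixtures in serial CSF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnamtraj)
```

# The scientific setting

After aneurysmal subarachnoid hemorrhage (aSAH), cerebrospinal fluid is
drained through an external ventricular drain for up to 14 days, yielding
serial samples of a tissue that directly bathes the injured brain. Two
features make its DNA methylation hard to interpret. First, epigenetic
clocks were trained on other tissues, so their CSF behavior needs
characterization rather than assumption. Second, the rupture floods the
subarachnoid space with blood that clears gradually, so the cell mixture
contributing DNA changes over the very window being studied. `dnamtraj`
packages the full chain — clocks, reference-free cell-type deconvolution,
residual age acceleration, and group-based trajectory modeling with
posterior QC — with a synthetic cohort generator that plants known truth
under every stage.

# Epigenetic clocks

A clock is a linear predictor over a fixed probe set,
$\mathrm{DNAmAge} = m_0 + \sum_i m_i \beta_i$, with beta values
$\beta_i \in [0,1]$. `clock_definition()` carries three conventions that
differ between published clocks:

* **Output transform.** The Horvath clock predicts on a transformed age
  scale, logarithmic below an anchor (adult) age $a^\ast$ and linear above
  it. `horvath_inverse()` maps a raw score $x$ back to years:
  $(a^\ast{+}1)e^{x} - 1$ for $x \le 0$, else $(a^\ast{+}1)x + a^\ast$;
  `horvath_forward()` is its exact inverse. $a^\ast = 20$ years is the
  canonical constant, exposed as an argument so the round-trip identity can
  be tested at other anchors. The transform is continuous and strictly
  increasing, so sample rank order in raw scores is preserved in years.
* **Per-sample standardization.** The Zhang clock applies its coefficients
  to betas centered and scaled *within each sample* over the probe set;
  the preset sets this flag, the other clocks leave it off. A side effect,
  tested as an invariant, is shift-invariance of the score under a
  constant offset to a sample's betas.
* **Missing probes.** Array QC removes a handful of clock probes
  (published analyses proceeded with 1–11 missing per clock). The default
  policy drops missing probes and logs counts per sample
  (`n_probes_used` + `n_probes_missing` always equals the clock size);
  `intersect_tissues` restricts to probes present in every supplied tissue
  matrix so CSF and blood ages are computed on the same probe support, and
  `strict` turns any missing probe into an error. No imputation is
  offered: for desk-scale probe losses it would add a modeling assumption
  with no way to validate it here.

Coefficient tables load from CSV (`probe_id`, `coefficient`, one
`"(Intercept)"` sentinel row — the dialect of published coefficient
files). Because the real coefficient files are distributed as journal
supplements rather than package data, `synthetic_clock_table()` generates
structural stand-ins with the published probe counts (353/71/513/514) and
conventions but simulated IDs and coefficients; they exercise the loading,
intersection, and policy machinery, and are explicitly not biologically
meaningful.

# The synthetic cohort and the planted clock

`simulate_cohort()` reproduces the study conditions as defaults: 273
participants; age Normal(52.9, 11.1²) truncated at 18; 68.5 % female,
87.2 % White; Fisher grades 2/3/4 at 29.7/49.5/20.9 % (renormalized —
the printed percentages sum to 100.1); BMI Normal(28.1, 7.2²); 66.3 %
with any smoking history, split current/social/past in the printed
proportions so the yes-vs-never recode used in group tests is exercisable;
a 72-participant blood subset sampled only on days 0–2. CSF draws target
days 1, 4, 7, 10, 13, each jittered uniformly by −1/0/+1 day and clipped
to [0, 14], and are retained independently with probability 850/1365
(≈ 0.62), reproducing the ~850 retained observations from 273×5 slots. A
participant who would lose all five slots keeps one at random, because the
cohort is defined as participants *with* serial CSF data; this perturbs
the expected count by well under 1 %. The real distribution of
observations per participant is not published; independent per-slot
retention is the simplest assumption consistent with the totals.

Every participant is assigned a latent trajectory group. The default
groups are four flat trajectories at −8, −2, 1, 5 years with residual SD
2 and proportions 0.05/0.40/0.40/0.15 — the magnitude and shape of the
well-separated structure the trajectory model is expected to find, with
adjacent-group gaps between 1.5σ and 3σ.

`simulate_cell_mixtures()` encodes the clearing contamination: the two
highest-baseline cell types at day 0 are "blood-like" and their
unnormalized expected weight decays as $e^{-\lambda d}$ with day $d$
(default $\lambda = 0.15$/day, i.e. roughly an 86 % reduction over the
14-day window — chosen as a visible but incomplete clearance; no
quantitative clearance rate is published). Sample weights are Dirichlet
draws centered on the day's expected composition; blood samples stay at
the day-0 composition. This encodes "blood clears over recovery" without
claiming real CSF cytology.

`simulate_beta()` assembles probes × samples betas: clock probes carry
$b_p + (\mathrm{age} + \mathrm{accel})/s$ with baselines
$b_p \in [0.1, 0.3]$ and scale $s = 200$ (keeping betas inside [0, 1] for
ages up to ~130); filler probes carry `profiles × weights`; Gaussian
noise is added and values are clipped to [0, 1] — mixture + signal +
noise, then clip, the simplest order that preserves the beta contract.
With zero noise no clipping is active and the planted clock returns
`age + acceleration` to 1e−9 years, which is the generator-inversion
oracle used throughout the tests. All draws descend from one seed through
a labeled stream-splitting scheme (`derive_seed`), so identical seeds give
byte-identical outputs.

# Reference-free cell-type proportions

No reference panel exists for post-aSAH CSF, so proportions are estimated
directly from the betas: $B \approx MW$ with profiles $M \in [0,1]^{P
\times K}$ and each sample's weights on the K-simplex. The fitting
alternates two exact convex subproblems:

* profiles: per-probe box-constrained least squares, solved by cyclic
  coordinate minimization with clipping, run to tolerance;
* weights: per-sample simplex-constrained least squares, solved exactly by
  enumerating active sets of the non-negativity constraints (2^K − 1
  candidate supports, batched across samples through shared KKT
  factorizations; this caps K at 12, far above the K = 5 default).

Both steps decrease the squared-error objective monotonically — an
invariant the tests check — and the algorithm restarts from several random
simplex initializations (default 5), keeping the best objective.
Deconvolution runs on the most variable probes (default 1000), standard
practice that stabilizes the factorization and bounds runtime. As with
any reference-free method the components are putative and identified only
up to label permutation; recovery-against-truth tests therefore match
labels by best permutation, and use mixtures containing pure samples,
since without anchor points the exact factorization is not unique. The
published analysis this design follows reports only the output contract
(five simplex proportions per sample); the exact algorithm variant behind
it is not stated, so this package fixes one reproducible algorithm with
the same contract.

For regression adjustment the K proportions are collinear (they sum to
one), so `select_dropped_cell()` removes the cell with the lowest
across-sample variance — the least informative adjuster — with ties broken
to the lowest index.

# Residual age acceleration

Age acceleration is the residual of DNAm age on chronological age,
computed by OLS *within each (clock, tissue, time-bin) stratum* — never
pooled, because the cross-sectional design makes each bin its own
regression population. The CTH-adjusted flavor adds the K−1 retained
proportions as covariates; samples with missing proportions drop out of
the adjusted flavor only. Residuals are mean-zero and orthogonal to every
regressor within stratum by construction (tested at 1e−8 against a
hat-matrix oracle). Rank-deficient designs error naming the collinear
columns, except that exactly-constant covariates are silently dropped
(they carry no adjustment information, and dropping them makes the
adjusted flavor collapse onto the unadjusted one — the documented
zero-variance limit). Strata smaller than p + 2 observations are skipped
with a warning rather than fitted.

Outlier flags use Tukey fences at 3×IQR on DNAm age within the stratum,
with type-7 (linear interpolation) quartiles — the most common convention,
fixed for reproducibility. The source phrase for this rule is ambiguous
about sidedness; both readings are implemented, two-sided is the default,
and flags are informational: flagged observations are retained, matching
the practice of reporting outlier-unadjusted metrics after confirming
concordance.

# Group-based trajectory mixtures

The panel is per-participant acceleration indexed by time bin (missing
bins allowed). Group $g$ has polynomial mean $x(t)^\top\beta_g$ over the
centered bin index $t - 3$ (so intercepts are mid-window means), with
order 0/1/2 per the candidate shape. Participant $i$'s group-$g$
likelihood is the product over observed bins of (censored-)normal
densities with shared residual SD σ; the mixture weights π live directly
on the simplex. Fitting is EM:

* E-step: posterior memberships via log-sum-exp;
* M-step: π from posterior means; each β_g by weighted least squares with
  participant posteriors expanded to observations; σ² from the pooled
  weighted residual sum of squares.

With the default infinite censoring bounds this is exact EM and the
log-likelihood ascends monotonically (tested on every fit, and against a
brute-force enumeration oracle on ≤5-participant instances at 1e−10).
Finite bounds switch the M-step to numerical maximization of the expected
complete-data log-likelihood, accepted only when it improves — a
generalized EM that retains ascent. The default is no censoring: the
trajectory macro this follows is a censored-normal model, but its bounds
in the motivating analysis are unstated, so bounds are configuration
rather than a silent guess. σ is shared across groups (the macro's
default); per-group σ is available behind `shared_sigma = FALSE`.

Initialization splits participants into G groups by quantiles of their
mean acceleration; restarts jitter the means before splitting (default 5
starts, best log-likelihood kept). Convergence is relative log-likelihood
change below 1e−8 or 500 iterations, with non-convergence reported on the
fit rather than raised. Groups are reported in ascending intercept order,
making labels canonical; the mixture likelihood itself is permutation
invariant (tested).

Model selection uses `BIC = logL − ½·k·log(N)` on the larger-is-better
scale, with k counting trajectory coefficients, G−1 mixture weights and
the variance(s). Both the participant-count and observation-count
penalties are reported (`bic`, `bic_obs`) because trajectory software
prints both and analyses differ in which they quote; `model_search()`
selects by the participant-count version. The search grid applies the
same polynomial order to all groups per candidate (G = 1–6, order 0–2 by
default); per-group orders are supported by `fit_gbta()` directly.

Posterior QC applies the standard adequacy diagnostics: per-group average
posterior probability among modally assigned members (APP ≥ 0.7), odds of
correct classification
$\mathrm{OCC}_g = \frac{\mathrm{APP}_g/(1-\mathrm{APP}_g)}{\pi_g/(1-\pi_g)} > 5$,
and estimated-vs-observed group shares. "Approximately equal" shares have
no published operationalization; the default is an absolute tolerance of
0.1, configurable. A group with no modal members fails QC with an
explicit reason. On well-separated synthetic data the QC passes; when
group means sit ~1σ apart the OCC criterion fails — the same failure mode
that disqualifies weakly separated published models.

# Cohort statistics

Pearson correlations use pairwise-complete pairs with t-distribution
p-values; one-way ANOVA is the classical between/within F (constant input
returns F = 0, p = 1 rather than a 0/0); contingency tables use
chi-square without continuity correction unless any expected count is
below 5, in which case Fisher's exact test is selected (attempted for
larger tables, falling back to chi-square with a warning if infeasible) —
the selection rule is a pure function of expected counts and is tested on
a grid. Bivariate regressions are simple OLS with intercept reporting
unstandardized estimate, SE, t-based 95 % CI and p per non-reference
level; categorical covariates code against explicit references (sex:
male, race: White, smoking: no). A perfectly fitting covariate yields
zero residual SE and the p-value is reported as 0 with a warning rather
than NaN. p-values are unadjusted for multiplicity, matching the
bivariate-table convention being reproduced; excluded-record counts are
echoed by every test.

# The pipeline

`run_pipeline()` chains simulate (or load) → clocks → CTH → acceleration
→ trajectory search → group statistics from a nested list or YAML config,
validating the config (exactly one of `simulate`/`inputs`; referenced
files must exist) before any stage runs, deriving a labeled seed per
stochastic stage, writing every intermediate table as TSV/JSON, and
ending with a manifest of MD5 digests — two runs under the same config and
seed are digest-identical, which the tests assert. Stage failures abort
with the stage name; earlier outputs are retained.

# What the synthetic tests do and do not show

The generator emulates sampling structure, demographics, decaying
mixtures, and a linear clock signal with Gaussian beta noise. It does not
emulate probe-level chemistry (Type I/II designs), batch or chip effects,
genome-wide probe counts, non-Gaussian beta distributions near the
boundaries, or real CSF cytology. Passing tests therefore demonstrate
that the *computational* chain is correct and that the trajectory
diagnostics behave as designed under known truth — not that any specific
clock is valid in CSF, which is an empirical question about real arrays.

Problem sizes in the tests are chosen at desk scale: the full simulated
cohort (273 participants, ~850 observations) for trajectory-model checks,
smaller cohorts (20–120 participants, hundreds of probes) for stage-level
checks, and 20-replicate sweeps for the model-recovery properties. The
acceptance script at the repository root reruns the headline 4-group QC
computation from scratch under a caller-supplied seed.

# Known limitations

* The censored-normal M-step under finite bounds is numerical and only
  ascent-guaranteed, not closed form; the default (no censoring) is exact.
* Standard errors and confidence bands for trajectory parameters are not
  implemented; bootstrap refitting is the intended route.
* Reference-free components carry no biological identity; nothing in the
  package should be read as naming CSF cell types.
* Covariates are profiled after group assignment, never included in the
  mixture itself — a deliberate match to the data-driven design being
  reproduced, not a modeling recommendation.
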