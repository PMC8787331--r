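# dnamtraj

Trajectories of DNA-methylation age acceleration in serial cerebrospinal
fluid (CSF) after aneurysmal subarachnoid hemorrhage (aSAH).

After an aneurysm ruptures, CSF is drained for up to two weeks as part of
clinical care, giving a rare serial window on the central nervous system
during acute recovery. `dnamtraj` implements the analysis chain needed to
ask whether the *epigenetic age* of that tissue is stable over recovery:

1. **Epigenetic clocks** — DNAm age per sample as a linear predictor over
   clock-specific CpG probes,
   `DNAmAge = m0 + m1·β1 + m2·β2 + … + mn·βn`,
   where βi ∈ [0, 1] are methylation beta values. Clock conventions are
   handled explicitly: the Horvath clock's piecewise log/linear age
   transform (and its exact inverse), Zhang-style per-sample beta
   standardization, and drop-and-log handling of clock probes lost to
   array QC (Horvath/Hannum/Levine/Zhang use 353/71/513/514 CpGs).
2. **Reference-free cell-type heterogeneity (CTH)** — post-aSAH CSF is
   heavily contaminated with blood that clears over days; no reference
   deconvolution panel exists for it. Proportions of K putative cell types
   are estimated by a constrained factorization `betas ≈ profiles × weights`
   (profiles in [0, 1], weights on the K-simplex) fitted by alternating
   exact convex subproblems.
3. **Age acceleration** — the residual of DNAm age regressed on
   chronological age *within each cross-sectional time bin* (days 0–2,
   3–5, 6–8, 9–11, 12–14 post-aSAH), optionally adjusting for K−1 cell
   proportions (the lowest-variance cell dropped), with 3×IQR Tukey-fence
   outlier flags.
4. **Group-based trajectory analysis (GBTA)** — a finite mixture of
   polynomial trajectories (censored-normal observation model, EM
   fitting): participants fall into latent groups, each with its own
   intercept-only/linear/quadratic acceleration trajectory over the five
   time bins. Model selection maximizes `BIC = logL − ½·k·log(N)` (larger
   is better) over group numbers and shapes; fitted models are vetted by
   posterior QC — per-group average posterior probability (APP ≥ 0.7),
   odds of correct classification (OCC > 5), and agreement of estimated
   group probabilities with observed assignment shares.
5. **Cohort statistics** — Pearson correlations, one-way ANOVA,
   chi-square/Fisher tests and bivariate regressions used to profile
   trajectory groups against participant characteristics.

Because no cohort of this kind is publicly deposited, the package includes
a first-class **synthetic cohort generator**: demographically realistic
participants (age 52.9 ± 11.1 y, 68.5 % female, …), serial CSF sampling
at targeted days 1/4/7/10/13 (±1) with ~62 % retention, latent trajectory
groups, decaying blood-like cell mixtures, and a *planted clock* whose
probes carry `age + acceleration` exactly — so every stage is testable
against known truth.

It is aimed at epigenomics researchers working with longitudinal
methylation arrays in complex tissues, and at anyone who wants a tested,
reference implementation of trajectory-model QC diagnostics in R.

## Worked example

```r
library(dnamtraj)

sim <- simulate_cohort(cohort_config(n_participants = 120, blood_subset_n = 30, seed = 2024))
mix <- simulate_cell_mixtures(sim$sheet, K = 5, seed = 2024)
clk <- planted_clock(seed = 2024)
sb  <- simulate_beta(sim$sheet, sim$truth, mix, clk, noise_sd = 0.01, seed = 2024)

ages  <- compute_dnam_age(clk$clock, sb$betas)
cth   <- estimate_proportions(sb$betas, K = 5, seed = 2024)
accel <- compute_acceleration(ages, sim$sheet, cth = cth)

panel <- accel |>
  dplyr::filter(tissue == "CSF", flavor == "unadjusted") |>
  dplyr::transmute(participant_id, time_bin, value = residual)

search <- model_search(panel, G_range = 1:5, orders = 0, n_starts = 3, seed = 2024)
search$table
#>       G order loglik     k    bic bic_obs converged
#>       1     0 -1071.     2 -1076.  -1077. TRUE
#>       2     0 -1022.     4 -1031.  -1034. TRUE
#>       3     0  -973.     6  -988.   -991. TRUE
#>       4     0  -944.     8  -963.   -968. TRUE
#>       5     0  -943.    10  -967.   -973. TRUE

search$best_fit
#> <gbta_fit> 4 groups, orders (0,0,0,0), 120 participants / 392 observations
#>   loglik -943.708 | k 8 | BIC(N) -962.858 | BIC(obs) -967.593 | sigma 2.047
#>   group      pi intercept linear quadratic n_assigned
#> 1 group1 0.0352     -8.91      0         0          4
#> 2 group2 0.390      -2.12      0         0         48
#> 3 group3 0.448       1.17      0         0         52
#> 4 group4 0.126       5.52      0         0         16

posterior_qc(search$best_fit)
#> <gbta_qc> overall: PASS
#>   group n_assigned share_observed     pi   app   occ ...
#> 1     1          4         0.0333 0.0352 1.000  6.8e10
#> 2     2         48         0.4    0.390  0.897  13.6
#> 3     3         52         0.433  0.448  0.913  13.0
#> 4     4         16         0.133  0.126  0.902  63.7
```

BIC peaks at `G = 4` — the planted number of flat groups — and the
recovered intercepts (−8.9, −2.1, 1.2, 5.5 years) sit near the planted
means (−8, −2, 1, 5). Every group clears the APP ≥ 0.7 and OCC > 5
diagnostics, so group assignments can be trusted. DNAm age also tracks
chronological age as it should on realistic noise:

```r
chron <- sim$sheet$age[match(ages$sample_id, sim$sheet$sample_id)]
pearson(ages$dnam_age, chron)
#>       r         p     n n_excluded
#>   0.945 3.02e-205   422          0
```

`autoplot(search$best_fit)` draws the trajectory groups;
`tidy()`/`glance()` give broom-style summaries; `run_pipeline(config,
outdir)` runs all stages from a YAML/list config and writes every
intermediate table plus a digest manifest.

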