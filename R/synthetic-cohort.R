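#' Configuration for the synthetic aSAH cohort generator
#'
#' Defaults reproduce the published cohort's characteristics: 273
#' participants, age 52.9 (SD 11.1) years truncated at 18, 68.5% female,
#' 87.2% White, Fisher grades 2/3/4 in proportions 29.7/49.5/20.9
#' (renormalized), BMI 28.1 (SD 7.2) kg/m^2, 66.3% with any smoking history,
#' a 72-participant blood subset sampled only on days 0-2, and per-slot CSF
#' retention tuned so that 273 participants x 5 targeted days yield about
#' 850 retained observations (850/1365 ~ 0.62).
#'
#' @param n_participants Number of participants.
#' @param age_mean,age_sd,age_min Age distribution (years), normal truncated
#'   at `age_min`.
#' @param frac_female,frac_white Proportions of female sex and White race.
#' @param fisher_probs Length-3 probabilities of Fisher grades 2, 3, 4
#'   (renormalized to sum to 1).
#' @param smoking_prob Probability of any smoking history (current, social,
#'   or past); never-smokers have probability `1 - smoking_prob`.
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2).
#' @param blood_subset_n Participants with a blood sample at time 1.
#' @param retention_prob Per-slot probability that a targeted CSF draw is
#'   retained after QC.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 273L,
                          age_mean = 52.9, age_sd = 11.1, age_min = 18,
                          frac_female = 0.685, frac_white = 0.872,
                          fisher_probs = c(0.297, 0.495, 0.209),
                          smoking_prob = 0.663,
                          bmi_mean = 28.1, bmi_sd = 7.2,
                          blood_subset_n = 72L,
                          retention_prob = 850 / 1365,
                          seed = 1L) {
  probs <- c(frac_female = frac_female, frac_white = frac_white,
             smoking_prob = smoking_prob, retention_prob = retention_prob)
  bad <- probs[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad)) {
    stop_dnamtraj(paste0("probabilities must lie in [0, 1]: ",
                         paste(names(bad), collapse = ", ")),
                  class = "dnamtraj_config_error")
  }
  if (length(fisher_probs) != 3 || any(fisher_probs < 0) ||
      sum(fisher_probs) <= 0) {
    stop_dnamtraj("`fisher_probs` must be 3 nonnegative values with positive sum.",
                  class = "dnamtraj_config_error")
  }
  if (n_participants < 0 || age_sd < 0) {
    stop_dnamtraj("`n_participants` and `age_sd` must be nonnegative.",
                  class = "dnamtraj_config_error")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    frac_female = frac_female, frac_white = frac_white,
    fisher_probs = fisher_probs / sum(fisher_probs),
    smoking_prob = smoking_prob,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    blood_subset_n = as.integer(min(blood_subset_n, n_participants)),
    retention_prob = retention_prob,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Latent trajectory-group truth for the simulator
#'
#' Defines the groups whose acceleration trajectories are planted in the
#' synthetic data. The defaults are four flat (intercept-only) groups with
#' means -8, -2, 1 and 5 years, proportions 0.05/0.40/0.40/0.15 and residual
#' SD 2 years — the shape of the well-separated trajectory structure the
#' trajectory model is expected to recover.
#'
#' @param group_means Per-group intercepts (years) on the acceleration scale.
#' @param group_probs Group membership probabilities (simplex).
#' @param sigma Residual SD (years) of observation noise around the group
#'   trajectory.
#' @param group_slopes,group_quads Optional per-group linear and quadratic
#'   coefficients over the centered time-bin index (bin - 3); default 0
#'   (flat trajectories).
#' @return A `trajectory_groups` list with a `coeffs` matrix (G x 3).
#' @export
trajectory_groups <- function(group_means = c(-8, -2, 1, 5),
                              group_probs = c(0.05, 0.40, 0.40, 0.15),
                              sigma = 2,
                              group_slopes = rep(0, length(group_means)),
                              group_quads = rep(0, length(group_means))) {
  G <- length(group_means)
  stopifnot(length(group_probs) == G, length(group_slopes) == G,
            length(group_quads) == G)
  if (any(group_probs < 0) || abs(sum(group_probs) - 1) > 1e-9) {
    stop_dnamtraj("`group_probs` must be a probability simplex.",
                  class = "dnamtraj_config_error")
  }
  if (sigma < 0) stop_dnamtraj("`sigma` must be nonnegative.")
  structure(list(
    coeffs = cbind(intercept = group_means, linear = group_slopes,
                   quadratic = group_quads),
    group_probs = group_probs,
    sigma = sigma
  ), class = "trajectory_groups")
}

# Internal: polynomial group mean at time bin (centered at bin 3).
group_mean_at_bin <- function(coeffs, group, bin) {
  ct <- bin - 3
  coeffs[group, 1] + coeffs[group, 2] * ct + coeffs[group, 3] * ct^2
}

#' Simulate the longitudinal cohort sample sheet
#'
#' Generates one row per retained sample. CSF draws target post-injury days
#' 1, 4, 7, 10 and 13, each jittered by -1/0/+1 day (uniform) and clipped to
#' \[0, 14\], and are retained independently with probability
#' `retention_prob`. Blood rows exist only for the blood subset and only on
#' days 0-2. Each participant is assigned to a latent trajectory group;
#' the assignment is returned as truth alongside the sheet.
#'
#' @param config A [cohort_config()].
#' @param groups A [trajectory_groups()] definition.
#' @return A list: `sheet` (tibble: sample_id, participant_id, tissue, day,
#'   time_bin, age, sex, race, smoking, bmi, fisher) and `truth` (list:
#'   group_of named by participant, group_probs, coeffs, sigma).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            groups = trajectory_groups()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(groups, "trajectory_groups"))
  n <- config$n_participants
  empty_sheet <- tibble::tibble(
    sample_id = character(), participant_id = character(),
    tissue = character(), day = integer(), time_bin = integer(),
    age = numeric(), sex = character(), race = character(),
    smoking = character(), bmi = numeric(), fisher = integer()
  )
  if (n == 0) {
    return(list(sheet = empty_sheet,
                truth = list(group_of = stats::setNames(integer(), character()),
                             group_probs = groups$group_probs,
                             coeffs = groups$coeffs, sigma = groups$sigma)))
  }
  with_seed(config$seed, {
    pid <- sprintf("P%04d", seq_len(n))
    # truncated-normal ages: redraw below the floor
    age <- stats::rnorm(n, config$age_mean, config$age_sd)
    while (any(age < config$age_min)) {
      idx <- which(age < config$age_min)
      age[idx] <- stats::rnorm(length(idx), config$age_mean, config$age_sd)
    }
    sex <- ifelse(stats::runif(n) < config$frac_female, "female", "male")
    race <- ifelse(stats::runif(n) < config$frac_white, "White", "Other")
    smoker <- stats::runif(n) < config$smoking_prob
    smoking_type <- sample(c("current", "social", "quit"), n, replace = TRUE,
                           prob = c(0.538, 0.011, 0.114))
    smoking <- ifelse(smoker, smoking_type, "never")
    bmi <- pmax(stats::rnorm(n, config$bmi_mean, config$bmi_sd), 14)
    fisher <- sample(2:4, n, replace = TRUE, prob = config$fisher_probs)
    group_of <- stats::setNames(
      sample(seq_along(groups$group_probs), n, replace = TRUE,
             prob = groups$group_probs),
      pid
    )

    participants <- tibble::tibble(
      participant_id = pid, age = age, sex = sex, race = race,
      smoking = smoking, bmi = bmi, fisher = fisher
    )

    targeted <- c(1L, 4L, 7L, 10L, 13L)
    slots <- tidyr::expand_grid(participant_id = pid, target_day = targeted)
    jitter <- sample(c(-1L, 0L, 1L), nrow(slots), replace = TRUE)
    slots$day <- pmin(pmax(slots$target_day + jitter, 0L), 14L)
    kept <- stats::runif(nrow(slots)) < config$retention_prob
    # the cohort is defined by having serial CSF data: a participant who
    # would lose all five slots keeps one at random
    for (p in setdiff(pid, slots$participant_id[kept])) {
      kept[sample(which(slots$participant_id == p), 1)] <- TRUE
    }
    slots <- slots[kept, ]
    csf <- dplyr::mutate(
      dplyr::inner_join(slots, participants, by = "participant_id"),
      tissue = "CSF"
    )

    blood_pid <- sample(pid, config$blood_subset_n)
    blood <- dplyr::mutate(
      dplyr::inner_join(tibble::tibble(participant_id = blood_pid),
                        participants, by = "participant_id"),
      tissue = "blood",
      day = sample(0:2, length(blood_pid), replace = TRUE)
    )

    sheet <- dplyr::bind_rows(csf, blood)
    sheet <- dplyr::mutate(
      sheet,
      time_bin = assign_time_bin(.data$day),
      sample_id = sprintf("%s_d%02d_%s", .data$participant_id, .data$day,
                          .data$tissue)
    )
    sheet <- dplyr::arrange(
      dplyr::select(sheet, dplyr::all_of(names(empty_sheet))),
      .data$tissue == "blood", .data$participant_id, .data$day
    )
  })
  list(sheet = sheet,
       truth = list(group_of = group_of, group_probs = groups$group_probs,
                    coeffs = groups$coeffs, sigma = groups$sigma))
}

#' Simulate cell-type mixing weights with decaying blood contamination
#'
#' Emulates cell-type heterogeneity in post-hemorrhage CSF: blood floods the
#' subarachnoid space at rupture and gradually clears, so the expected share
#' of the blood-like cell types decays exponentially with day post-injury
#' while the remaining (resident) components grow by renormalization. Each
#' sample's weight vector is drawn from a Dirichlet centered on the expected
#' composition for its day; blood-tissue samples stay at the day-0 (fully
#' contaminated) composition.
#'
#' @param sheet Sample sheet (needs `sample_id`, `tissue`, `day`).
#' @param K Number of cell types (>= 1).
#' @param decay_rate Per-day exponential decay of the blood-like components'
#'   unnormalized expected weight.
#' @param n_probes Number of filler probes carrying the mixture signal.
#' @param concentration Dirichlet concentration (larger = less
#'   sample-to-sample noise).
#' @param seed Integer seed.
#' @return A list: `profiles` (K x n_probes matrix of cell-type baseline
#'   betas in \[0, 1\]), `weights` (K x n_samples, columns on the simplex),
#'   `blood_like` (indices of the decaying components), `decay_rate`.
#' @export
simulate_cell_mixtures <- function(sheet, K = 5L, decay_rate = 0.15,
                                   n_probes = 300L, concentration = 60,
                                   seed = 1L) {
  if (K < 1) stop_dnamtraj("`K` must be >= 1.")
  n_s <- nrow(sheet)
  with_seed(derive_seed(seed, "cellmix"), {
    # well-separated cell profiles: each cell type has its own beta regime
    centers <- stats::runif(K, 0.15, 0.85)
    profiles <- matrix(NA_real_, K, n_probes,
                       dimnames = list(paste0("cell", seq_len(K)),
                                       sprintf("fillcg%06d", seq_len(n_probes))))
    for (k in seq_len(K)) {
      profiles[k, ] <- pmin(pmax(stats::rnorm(n_probes, centers[k], 0.12), 0), 1)
    }
    base <- stats::runif(K, 0.5, 1.5)
    base <- base / sum(base)
    blood_like <- order(base, decreasing = TRUE)[seq_len(min(2L, K))]
    weights <- matrix(NA_real_, K, n_s,
                      dimnames = list(rownames(profiles), sheet$sample_id))
    day_eff <- ifelse(sheet$tissue == "blood", 0, sheet$day)
    for (s in seq_len(n_s)) {
      w <- base
      w[blood_like] <- w[blood_like] * exp(-decay_rate * day_eff[s])
      w <- w / sum(w)
      if (K == 1) {
        weights[, s] <- 1
      } else {
        g <- stats::rgamma(K, shape = concentration * w, rate = 1)
        if (sum(g) == 0) g <- w
        weights[, s] <- g / sum(g)
      }
    }
  })
  list(profiles = profiles, weights = weights, blood_like = blood_like,
       decay_rate = decay_rate)
}

#' Expected cell-mixture composition at a given day
#'
#' The noise-free generative mean used by [simulate_cell_mixtures()];
#' exposed so tests can check the decay analytically.
#'
#' @param mix A result of [simulate_cell_mixtures()] (uses `blood_like` and
#'   `decay_rate`).
#' @param base Baseline (day-0) unnormalized weights, K-vector.
#' @param day Day post-injury.
#' @return K-vector on the simplex.
#' @export
expected_mixture <- function(mix, base, day) {
  w <- base
  w[mix$blood_like] <- w[mix$blood_like] * exp(-mix$decay_rate * day)
  w / sum(w)
}

#' Construct a planted, exactly invertible epigenetic clock
#'
#' Builds a synthetic clock whose probes carry a pure age signal:
#' `beta_p = b_p + y / scale` with baselines `b_p` in \[0.1, 0.3\] and
#' `y = age + acceleration`. The coefficients are positive, sum to `scale`,
#' and the intercept cancels the baselines, so on noise-free data the clock
#' returns `y` exactly (round-trip error < 1e-9 years for ages up to ~130).
#' This is the test oracle for the DNAm-age computation.
#'
#' @param n_probes Number of clock probes.
#' @param scale Divisor mapping years into beta space (keeps betas < 1).
#' @param seed Integer seed.
#' @return A list of class `planted_clock`: `clock` (a [clock_definition()]),
#'   `baselines` (named vector), `scale`.
#' @export
planted_clock <- function(n_probes = 50L, scale = 200, seed = 1L) {
  with_seed(derive_seed(seed, "planted_clock"), {
    probes <- sprintf("clkcg%06d", seq_len(n_probes))
    b <- stats::setNames(stats::runif(n_probes, 0.1, 0.3), probes)
    m <- stats::runif(n_probes, 0.5, 1.5)
    m <- stats::setNames(m / sum(m) * scale, probes)
  })
  clock <- clock_definition(
    name = "planted", intercept = -sum(m * b), coefficients = m,
    transform = "identity"
  )
  # invertibility check on a grid of target ages
  y <- c(0, 25, 52.9, 90, 130)
  betas <- outer(b, y / scale, "+")
  colnames(betas) <- paste0("chk", seq_along(y))
  err <- max(abs(linear_predictor(clock, betas) - y))
  if (err >= 1e-9) {
    stop_dnamtraj("planted clock failed its round-trip invariant.")
  }
  structure(list(clock = clock, baselines = b, scale = scale),
            class = "planted_clock")
}

#' Planted per-observation acceleration values
#'
#' Draws each retained observation's acceleration as its participant's group
#' trajectory mean at the observation's time bin plus Gaussian noise
#' (`truth$sigma`). Deterministic given the seed; [simulate_beta()] uses the
#' same stream, so the values returned here are exactly the signal planted
#' in the betas.
#'
#' @param sheet Sample sheet from [simulate_cohort()].
#' @param truth Truth list from [simulate_cohort()].
#' @param seed Integer seed.
#' @return Tibble: sample_id, participant_id, tissue, time_bin, group,
#'   accel, dnam_age_target (= age + accel).
#' @export
planted_acceleration <- function(sheet, truth, seed = 1L) {
  if (nrow(sheet) == 0) {
    return(tibble::tibble(sample_id = character(),
                          participant_id = character(), tissue = character(),
                          time_bin = integer(), group = integer(),
                          accel = numeric(), dnam_age_target = numeric()))
  }
  grp <- truth$group_of[sheet$participant_id]
  mu <- group_mean_at_bin(truth$coeffs, grp, sheet$time_bin)
  noise <- with_seed(derive_seed(seed, "planted_accel"),
                     stats::rnorm(nrow(sheet), 0, truth$sigma))
  tibble::tibble(
    sample_id = sheet$sample_id,
    participant_id = sheet$participant_id,
    tissue = sheet$tissue,
    time_bin = sheet$time_bin,
    group = unname(grp),
    accel = mu + noise,
    dnam_age_target = sheet$age + mu + noise
  )
}

#' Simulate a beta matrix with planted clock signal and cell mixtures
#'
#' Clock probes carry `b_p + (age + accel) / scale`; filler probes carry the
#' cell-type mixture `profiles' x weights`. Gaussian measurement noise is
#' added to every entry and values are clipped to \[0, 1\] (mixture + signal
#' + noise, then clip). With `noise_sd = 0` no clipping is active and
#' [compute_dnam_age()] applied to the planted clock recovers
#' `age + acceleration` exactly.
#'
#' @param sheet,truth Output of [simulate_cohort()].
#' @param mix Output of [simulate_cell_mixtures()] for the same sheet.
#' @param clock A [planted_clock()].
#' @param noise_sd Beta-scale measurement noise SD (>= 0).
#' @param seed Integer seed.
#' @return A list: `betas` (probes x samples matrix in \[0, 1\]) and
#'   `planted` (the [planted_acceleration()] tibble used).
#' @export
simulate_beta <- function(sheet, truth, mix, clock, noise_sd = 0.01,
                          seed = 1L) {
  if (noise_sd < 0) stop_dnamtraj("`noise_sd` must be nonnegative.")
  stopifnot(inherits(clock, "planted_clock"))
  if (!identical(colnames(mix$weights), sheet$sample_id)) {
    stop_dnamtraj("`mix` was not generated from this sheet (sample IDs differ).")
  }
  planted <- planted_acceleration(sheet, truth, seed = seed)
  y <- planted$dnam_age_target
  clock_block <- outer(clock$baselines, y / clock$scale, "+")
  filler_block <- t(mix$profiles) %*% mix$weights
  betas <- rbind(clock_block, filler_block)
  colnames(betas) <- sheet$sample_id
  if (noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, "beta_noise"),
                       stats::rnorm(length(betas), 0, noise_sd))
    betas <- betas + noise
  }
  betas <- pmin(pmax(betas, 0), 1)
  list(betas = betas, planted = planted)
}
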