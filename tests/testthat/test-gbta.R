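test_that("G = 1 intercept-only collapses to the grand mean and MLE SD", {
  panel <- make_flat_panel(20, means = 0, sigma = 3, seed = 1)
  fit <- fit_gbta(panel, G = 1, order = 0, n_starts = 1, seed = 1)
  expect_equal(unname(fit$coefficients[1, 1]), mean(panel$value),
               tolerance = 1e-8)
  expect_equal(fit$sigma,
               sqrt(mean((panel$value - mean(panel$value))^2)),
               tolerance = 1e-6)
  expect_equal(unname(fit$pi), 1)
  expect_true(all(fit$posteriors == 1))
  expect_equal(fit$k, 1 + 0 + 1)
})

test_that("EM log-likelihood is non-decreasing on every fit", {
  for (s in 1:10) {
    panel <- make_flat_panel(25, means = rnorm(3, 0, 4), sigma = 2, seed = s)
    fit <- fit_gbta(panel, G = 3, order = sample(0:2, 1), n_starts = 2,
                    seed = s)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9),
                info = sprintf("seed %d", s))
  }
})

test_that("reported log-likelihood equals the enumeration oracle", {
  for (s in 1:5) {
    panel <- make_flat_panel(4, means = c(-3, 3), sigma = 1.5, seed = 100 + s)
    fit <- fit_gbta(panel, G = 2, order = 0, n_starts = 3, seed = s)
    expect_equal(fit$loglik,
                 loglik_oracle(panel, fit$pi, fit$coefficients, fit$sigma),
                 tolerance = 1e-10)
  }
  # also for a linear-trajectory fit
  panel <- make_flat_panel(5, means = c(-4, 4), sigma = 1, seed = 200)
  fit <- fit_gbta(panel, G = 2, order = 1, n_starts = 2, seed = 2)
  expect_equal(fit$loglik,
               loglik_oracle(panel, fit$pi, fit$coefficients, fit$sigma),
               tolerance = 1e-10)
})

test_that("two well-separated flat groups are recovered", {
  panel <- make_flat_panel(100, means = c(-5, 5), probs = c(0.5, 0.5),
                           sigma = 1, seed = 17)
  fit <- fit_gbta(panel, G = 2, order = 0, n_starts = 4, seed = 17)
  expect_lt(abs(fit$coefficients[1, 1] - (-5)), 0.3)
  expect_lt(abs(fit$coefficients[2, 1] - 5), 0.3)
  # assignment matches planted membership (canonical order = means order)
  truth <- attr(panel, "true_group")
  expect_lt(max(abs(fit$pi - as.vector(table(truth)) / 100)), 0.05)
  expect_gt(mean(fit$assignment == truth), 0.97)
})

test_that("posteriors are a proper soft assignment and labels are canonical", {
  panel <- make_flat_panel(60, means = c(-4, 0, 4), sigma = 1.5, seed = 23)
  fit <- fit_gbta(panel, G = 3, order = 0, n_starts = 3, seed = 23)
  expect_equal(unname(rowSums(fit$posteriors)), rep(1, fit$n_participants),
               tolerance = 1e-8)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
  expect_equal(unname(fit$assignment),
               unname(max.col(fit$posteriors, ties.method = "first")))
  expect_true(all(diff(fit$coefficients[, 1]) > 0))
})

test_that("preconditions and argument validation", {
  panel <- make_flat_panel(5, means = 0, sigma = 1, seed = 1)
  expect_error(fit_gbta(panel, G = 6))
  expect_error(fit_gbta(panel, G = 0))
  expect_error(fit_gbta(panel, G = 2, order = 3))
  expect_error(fit_gbta(panel, G = 2, censor_low = 1, censor_high = -1))
  bad <- panel; bad$time_bin[1] <- 7
  expect_error(fit_gbta(bad, G = 1))
})

test_that("BIC arithmetic, penalty direction, and n validation", {
  expect_equal(gbta_bic(-100, 4, 273), -100 - 2 * log(273), tolerance = 1e-12)
  expect_equal(gbta_bic(-100, 4, 273), -111.2187, tolerance = 1e-4)
  expect_error(gbta_bic(-100, 4, 0))

  # a useless quadratic term on flat truth lowers BIC
  panel <- make_flat_panel(80, means = c(-4, 4), sigma = 1, seed = 29)
  flat <- fit_gbta(panel, G = 2, order = 0, n_starts = 3, seed = 29)
  quad <- fit_gbta(panel, G = 2, order = 2, n_starts = 3, seed = 29)
  expect_lt(quad$bic, flat$bic)
})

test_that("model search fits the whole grid and picks the planted G", {
  panel <- make_flat_panel(80, means = c(-5, 5), sigma = 1, seed = 37)
  ms <- model_search(panel, G_range = 1:4, orders = 0, n_starts = 2,
                     seed = 37)
  expect_equal(nrow(ms$table), 4)
  expect_equal(length(ms$best_fit$pi), 2)

  single <- model_search(panel, G_range = 2, orders = 0, n_starts = 2,
                         seed = 37)
  expect_equal(nrow(single$table), 1)
  expect_equal(length(single$best_fit$pi), 2)
  expect_error(model_search(panel, G_range = integer(0), orders = 0))

  grid <- model_search(panel, G_range = 1:2, orders = 0:2, n_starts = 1,
                       seed = 1)
  expect_equal(nrow(grid$table), 6)
})

test_that("OCC follows the odds-ratio formula exactly", {
  expect_equal(occ(0.5, 0.5), 1)
  expect_equal(occ(0.9, 0.5), 9)
  expect_equal(occ(1, 0.3), Inf)
  expect_error(occ(0.8, 0))
  expect_error(occ(0.8, 1))
  set.seed(41)
  for (i in 1:20) {
    app <- runif(1, 0.01, 0.99); pi <- runif(1, 0.01, 0.99)
    expect_equal(occ(app, pi), (app / (1 - app)) / (pi / (1 - pi)),
                 tolerance = 1e-12)
  }
  # chance-level classification: app equal to pi gives odds ratio 1
  p <- runif(1, 0.05, 0.95)
  expect_equal(occ(p, p), 1, tolerance = 1e-12)
})

test_that("posterior QC passes perfect separation and flags weak groups", {
  panel <- make_flat_panel(80, means = c(-10, 10), sigma = 0.5, seed = 43)
  fit <- fit_gbta(panel, G = 2, order = 0, n_starts = 3, seed = 43)
  qc <- posterior_qc(fit)
  expect_true(qc$pass)
  expect_true(all(qc$groups$app > 0.99))

  # fabricated fit with one weak group
  weak <- fit
  n <- fit$n_participants
  post <- cbind(c(rep(0.6, n / 2), rep(0.4, n / 2)),
                c(rep(0.4, n / 2), rep(0.6, n / 2)))
  rownames(post) <- rownames(fit$posteriors)
  weak$posteriors <- post
  weak$assignment <- stats::setNames(max.col(post), rownames(post))
  weak$pi <- c(group1 = 0.5, group2 = 0.5)
  qc2 <- posterior_qc(weak)
  expect_false(qc2$pass)
  expect_true(all(!qc2$groups$pass_app))

  # weak separation (means ~1 SD apart) fails OCC even when fit converges
  close_panel <- make_flat_panel(120, means = c(0, 2), sigma = 2, seed = 47)
  close_fit <- fit_gbta(close_panel, G = 2, order = 0, n_starts = 4, seed = 47)
  close_qc <- posterior_qc(close_fit)
  expect_false(all(close_qc$groups$pass_occ))
})

test_that("empty groups fail QC with an explicit reason", {
  panel <- make_flat_panel(30, means = c(-5, 5), sigma = 1, seed = 53)
  fit <- fit_gbta(panel, G = 2, order = 0, n_starts = 3, seed = 53)
  starved <- fit
  starved$assignment[] <- 1L
  qc <- posterior_qc(starved)
  expect_false(qc$pass)
  expect_equal(qc$groups$reason[2], "no modally assigned members")
})

test_that("group labels permute freely without changing fit quality", {
  panel <- make_flat_panel(50, means = c(-4, 4), sigma = 1, seed = 59)
  fit <- fit_gbta(panel, G = 2, order = 0, n_starts = 3, seed = 59)
  perm <- c(2, 1)
  expect_equal(
    loglik_oracle(panel, fit$pi[perm], fit$coefficients[perm, , drop = FALSE],
                  fit$sigma),
    fit$loglik, tolerance = 1e-10)
})

test_that("group profiling summarizes covariates and finds planted imbalance", {
  panel <- make_flat_panel(120, means = c(-5, 5), probs = c(0.5, 0.5),
                           sigma = 1, seed = 61)
  fit <- fit_gbta(panel, G = 2, order = 0, n_starts = 3, seed = 61)
  truth <- attr(panel, "true_group")
  set.seed(61)
  covars <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:120),
    age = rnorm(120, 53, 11),
    sex = ifelse(runif(120) < ifelse(truth == 1, 0.9, 0.2),
                 "female", "male"),
    bmi = rnorm(120, 28, 7),
    smoking = sample(c("never", "current", "quit"), 120, replace = TRUE)
  )
  prof <- profile_groups(fit, covars)
  expect_s3_class(prof$summary, "tbl_df")
  counts <- tapply(prof$summary$n[prof$summary$variable == "sex"],
                   prof$summary$group[prof$summary$variable == "sex"], sum)
  expect_equal(sum(counts), 120)  # groups partition the panel
  sex_p <- prof$tests$p[prof$tests$variable == "sex"]
  expect_lt(sex_p, 0.01)

  # single group: no tests
  fit1 <- fit_gbta(panel, G = 1, order = 0, n_starts = 1, seed = 61)
  prof1 <- profile_groups(fit1, covars)
  expect_equal(nrow(prof1$tests), 0)
})

test_that("tidy, glance and autoplot expose the fit in standard shapes", {
  panel <- make_flat_panel(40, means = c(-3, 3), sigma = 1, seed = 67)
  fit <- fit_gbta(panel, G = 2, order = 1, n_starts = 2, seed = 67)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 4)  # 2 groups x (intercept, linear)
  expect_setequal(unique(td$term), c("intercept", "linear"))
  gl <- generics::glance(fit)
  expect_equal(gl$n_groups, 2)
  expect_equal(gl$logLik, fit$loglik)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
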