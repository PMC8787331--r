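#' Fit a group-based trajectory model to acceleration over time bins
#'
#' Group-based trajectory analysis assumes the cohort is a finite mixture of
#' G latent groups, each following its own polynomial trajectory of age
#' acceleration over the five cross-sectional time bins. Participant i with
#' observations \eqn{y_{ij}} at bins \eqn{t_{ij}} contributes, under group
#' g, the product over j of (censored-)normal densities centered at the
#' group's polynomial mean; the marginal likelihood mixes these with the
#' group probabilities \eqn{\pi_g}. The model is maximized by EM: the
#' E-step computes posterior group memberships, the M-step reweights the
#' group probabilities and refits each group's polynomial by weighted least
#' squares with a shared residual SD. The time regressor is the bin index
#' centered at 3 (so intercepts are mid-window means); groups are reported
#' in ascending order of intercept.
#'
#' With the default infinite censoring bounds the observation model is plain
#' normal and the M-step is closed form; finite bounds switch to a
#' censored-normal likelihood with a numerically maximized M-step
#' (generalized EM — the update is accepted only if it improves the expected
#' complete-data log-likelihood, preserving monotone ascent).
#'
#' @param panel Tibble with columns `participant_id`, `time_bin` (1-5) and
#'   `value` (acceleration, years); missing bins per participant are fine.
#' @param G Number of trajectory groups (>= 1, <= participants).
#' @param order Polynomial order, one of 0 (intercept-only), 1 (linear),
#'   2 (quadratic); either a scalar (same shape for all groups) or a
#'   length-G vector.
#' @param censor_low,censor_high Censoring bounds of the observation model;
#'   default `-Inf`/`Inf` (no censoring).
#' @param n_starts Number of EM starts (quantile-split initialization plus
#'   jittered restarts); the best final log-likelihood is kept.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param shared_sigma Share the residual SD across groups (default; the
#'   per-group alternative is available behind this flag).
#' @param seed Integer seed controlling the restarts.
#' @return An object of class `gbta_fit`: `pi` (group probabilities),
#'   `coefficients` (G x 3 matrix over centered time: intercept, linear,
#'   quadratic; unused terms 0), `orders`, `sigma`, `loglik`, `k` (free
#'   parameters), `n_participants`, `n_obs`, `bic` (participant-count
#'   penalty), `bic_obs` (observation-count penalty), `posteriors`
#'   (participants x G), `assignment` (modal group, named), `converged`,
#'   `loglik_trace`, `panel`.
#' @export
fit_gbta <- function(panel, G, order = 0L,
                     censor_low = -Inf, censor_high = Inf,
                     n_starts = 5L, max_iter = 500L, tol = 1e-8,
                     shared_sigma = TRUE, seed = 1L) {
  panel <- check_panel(panel)
  ids <- unique(panel$participant_id)
  N <- length(ids)
  if (G < 1) stop_dnamtraj("`G` must be >= 1.")
  if (G > N) {
    stop_dnamtraj(sprintf("G = %d exceeds the number of participants (%d).",
                          G, N))
  }
  orders <- if (length(order) == 1) rep(as.integer(order), G) else as.integer(order)
  if (length(orders) != G || any(!orders %in% 0:2)) {
    stop_dnamtraj("`order` must be 0, 1 or 2, scalar or length G.")
  }
  if (censor_low >= censor_high) {
    stop_dnamtraj("`censor_low` must be < `censor_high`.")
  }

  pidx <- match(panel$participant_id, ids)
  ct <- panel$time_bin - 3
  X <- cbind(1, ct, ct^2)
  y <- panel$value

  best <- NULL
  for (s in seq_len(n_starts)) {
    w0 <- with_seed(derive_seed(seed, paste0("gbta_start", s)),
                    init_assignment(panel, pidx, ids, G, jitter = s > 1))
    fit <- tryCatch(
      em_gbta(y, X, pidx, N, G, orders, censor_low, censor_high,
              w0, max_iter, tol, shared_sigma),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop_dnamtraj("all EM starts failed.")

  # canonical order: ascending intercept
  ord <- order(best$beta[, 1])
  beta <- best$beta[ord, , drop = FALSE]
  pi_g <- best$pi[ord]
  post <- best$post[, ord, drop = FALSE]
  orders <- orders[ord]
  sigma <- if (shared_sigma) best$sigma else best$sigma[ord]
  dimnames(beta) <- list(paste0("group", seq_len(G)),
                         c("intercept", "linear", "quadratic"))
  dimnames(post) <- list(ids, paste0("group", seq_len(G)))

  k <- sum(orders + 1) + (G - 1) + if (shared_sigma) 1L else G
  n_obs <- nrow(panel)
  structure(list(
    pi = stats::setNames(pi_g, rownames(beta)),
    coefficients = beta,
    orders = orders,
    sigma = sigma,
    loglik = best$loglik,
    k = k,
    n_participants = N,
    n_obs = n_obs,
    bic = gbta_bic(best$loglik, k, N),
    bic_obs = gbta_bic(best$loglik, k, n_obs),
    posteriors = post,
    assignment = stats::setNames(max.col(post, ties.method = "first"), ids),
    converged = best$converged,
    loglik_trace = best$trace,
    censor = c(low = censor_low, high = censor_high),
    shared_sigma = shared_sigma,
    panel = panel
  ), class = "gbta_fit")
}

check_panel <- function(panel) {
  need <- c("participant_id", "time_bin", "value")
  if (!all(need %in% names(panel))) {
    stop_dnamtraj("panel needs columns participant_id, time_bin, value.")
  }
  panel <- tibble::as_tibble(panel[need])
  if (any(!panel$time_bin %in% 1:5)) {
    stop_dnamtraj("time bins must be in 1..5.")
  }
  if (anyNA(panel$value)) stop_dnamtraj("panel values must be non-missing.")
  panel
}

# Initial hard assignment: quantile split of per-participant mean value
# (jittered on restarts), converted to a hard posterior matrix.
init_assignment <- function(panel, pidx, ids, G, jitter) {
  pm <- tapply(panel$value, pidx, mean)
  if (jitter) pm <- pm + stats::rnorm(length(pm), 0, stats::sd(pm) + 1e-8)
  grp <- if (G == 1) {
    rep(1L, length(pm))
  } else {
    as.integer(cut(rank(pm, ties.method = "first"), breaks = G,
                   labels = FALSE))
  }
  w <- matrix(1e-6, length(ids), G)
  w[cbind(seq_along(ids), grp)] <- 1
  w / rowSums(w)
}

# log observation density per obs x group under (possibly censored) normal
obs_logdens <- function(y, mu, sigma, lo, hi) {
  ld <- stats::dnorm(y, mu, sigma, log = TRUE)
  if (is.finite(lo)) {
    at_lo <- y <= lo
    ld[at_lo] <- stats::pnorm(lo, mu[at_lo], sigma, log.p = TRUE)
  }
  if (is.finite(hi)) {
    at_hi <- y >= hi
    ld[at_hi] <- stats::pnorm(hi, mu[at_hi], sigma, log.p = TRUE,
                              lower.tail = FALSE)
  }
  ld
}

em_gbta <- function(y, X, pidx, N, G, orders, lo, hi, w, max_iter, tol,
                    shared_sigma) {
  n_obs <- length(y)
  censored <- is.finite(lo) || is.finite(hi)
  beta <- matrix(0, G, 3)
  sigma <- if (shared_sigma) stats::sd(y) else rep(stats::sd(y), G)
  if (any(sigma == 0) || anyNA(sigma)) sigma <- pmax(sigma, 1e-3, na.rm = TRUE)
  pi_g <- colMeans(w)

  mstep_wls <- function(w) {
    # closed-form weighted LS update (uncensored case)
    sse <- 0
    sse_g <- numeric(G)
    for (g in seq_len(G)) {
      cols <- seq_len(orders[g] + 1)
      wo <- w[pidx, g]
      Xg <- X[, cols, drop = FALSE]
      XtW <- t(Xg * wo)
      bg <- solve(XtW %*% Xg, XtW %*% y)
      beta[g, ] <<- 0
      beta[g, cols] <<- bg
      r <- y - Xg %*% bg
      sse_g[g] <- sum(wo * r^2)
      sse <- sse + sse_g[g]
    }
    if (shared_sigma) {
      sigma <<- sqrt(sse / n_obs)
    } else {
      wobs <- vapply(seq_len(G), function(g) sum(w[pidx, g]), numeric(1))
      sigma <<- sqrt(sse_g / pmax(wobs, 1e-12))
    }
    sigma <<- pmax(sigma, 1e-6)
  }

  expected_q <- function(par) {
    # expected complete-data loglik (censored case), par = c(betas, log sigma)
    b <- matrix(0, G, 3)
    idx <- 0
    for (g in seq_len(G)) {
      cols <- seq_len(orders[g] + 1)
      b[g, cols] <- par[idx + cols]
      idx <- idx + length(cols)
    }
    sg <- exp(par[(idx + 1):length(par)])
    if (shared_sigma) sg <- rep(sg[1], G)
    q <- 0
    for (g in seq_len(G)) {
      mu <- drop(X %*% b[g, ])
      q <- q + sum(w[pidx, g] * obs_logdens(y, mu, sg[g], lo, hi))
    }
    -q
  }

  mstep_censored <- function(w) {
    par0 <- c(unlist(lapply(seq_len(G), function(g)
      beta[g, seq_len(orders[g] + 1)])),
      log(if (shared_sigma) sigma[1] else sigma))
    opt <- stats::optim(par0, expected_q, method = "BFGS",
                        control = list(maxit = 50))
    if (opt$value <= expected_q(par0)) {  # generalized EM: accept improvements
      idx <- 0
      for (g in seq_len(G)) {
        cols <- seq_len(orders[g] + 1)
        beta[g, ] <<- 0
        beta[g, cols] <<- opt$par[idx + cols]
        idx <- idx + length(cols)
      }
      sg <- exp(opt$par[(idx + 1):length(opt$par)])
      sigma <<- if (shared_sigma) sg[1] else sg
    }
  }

  estep <- function() {
    # per-participant log group likelihoods
    lg <- matrix(0, N, G)
    for (g in seq_len(G)) {
      mu <- drop(X %*% beta[g, ])
      sg <- if (shared_sigma) sigma[1] else sigma[g]
      ld <- obs_logdens(y, mu, sg, lo, hi)
      lg[, g] <- rowsum(ld, pidx)[, 1]
    }
    la <- sweep(lg, 2, log(pmax(pi_g, 1e-300)), "+")
    mx <- apply(la, 1, max)
    lse <- mx + log(rowSums(exp(la - mx)))
    list(w = exp(la - lse), loglik = sum(lse))
  }

  # initial M-step from the hard assignment
  if (censored) {
    mstep_wls(w)       # decent starting parameters
    mstep_censored(w)
  } else {
    mstep_wls(w)
  }
  pi_g <- colMeans(w)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    es <- estep()
    w <- es$w
    trace <- c(trace, es$loglik)
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- es$loglik
    pi_g <- colMeans(w)
    if (censored) mstep_censored(w) else mstep_wls(w)
  }
  es <- estep()
  list(pi = pi_g, beta = beta, sigma = sigma, post = es$w,
       loglik = es$loglik, trace = c(trace, es$loglik), converged = converged)
}

#' BIC on the "larger is better" scale
#'
#' `loglik - 0.5 * k * log(N)`; the convention in trajectory-model software,
#' where the model with the larger (less negative) BIC fits better. `k`
#' counts free trajectory coefficients, G - 1 mixture weights and the
#' residual variance(s). Both the participant-count and observation-count
#' penalties are meaningful; [fit_gbta()] reports both (`bic`, `bic_obs`).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Penalty sample size (> 0).
#' @return Scalar BIC.
#' @export
gbta_bic <- function(loglik, k, n) {
  if (n <= 0) stop_dnamtraj("`n` must be positive.")
  loglik - 0.5 * k * log(n)
}

#' Search over group numbers and trajectory shapes
#'
#' Fits every combination of `G` in `G_range` and polynomial order in
#' `orders` (the same shape for all groups within a candidate), collecting
#' log-likelihood, parameter count and BIC per candidate, and returns the
#' fit with the largest BIC. Failures in individual candidates are recorded
#' in the table without aborting the search.
#'
#' @param panel As in [fit_gbta()].
#' @param G_range Candidate group counts.
#' @param orders Candidate polynomial orders (subset of 0:2).
#' @param ... Passed to [fit_gbta()].
#' @param seed Integer seed.
#' @return An object of class `gbta_search`: `table` (tibble: G, order,
#'   loglik, k, bic, bic_obs, converged, error) and `best_fit`.
#' @export
model_search <- function(panel, G_range = 1:6, orders = 0:2, ...,
                         seed = 1L) {
  if (length(G_range) == 0 || length(orders) == 0) {
    stop_dnamtraj("`G_range` and `orders` must be nonempty.")
  }
  grid <- tidyr::expand_grid(G = as.integer(G_range),
                             order = as.integer(orders))
  fits <- vector("list", nrow(grid))
  rows <- purrr::pmap(grid, function(G, order) {
    fit <- tryCatch(
      fit_gbta(panel, G = G, order = order, seed = seed, ...),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      tibble::tibble(G = G, order = order, loglik = NA_real_, k = NA_integer_,
                     bic = NA_real_, bic_obs = NA_real_, converged = NA,
                     error = conditionMessage(fit))
    } else {
      fits[[which(grid$G == G & grid$order == order)]] <<- fit
      tibble::tibble(G = G, order = order, loglik = fit$loglik, k = fit$k,
                     bic = fit$bic, bic_obs = fit$bic_obs,
                     converged = fit$converged, error = NA_character_)
    }
  })
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$bic))) stop_dnamtraj("every candidate model failed.")
  best <- which.max(tab$bic)
  structure(list(table = tab, best_fit = fits[[best]]),
            class = "gbta_search")
}

#' Odds of correct classification for one group
#'
#' `OCC_g = (APP_g / (1 - APP_g)) / (pi_g / (1 - pi_g))`: the posterior odds
#' that modally assigned members truly belong to the group, relative to the
#' prior odds from the estimated group probability. Values above 5 indicate
#' the model assigns this group much better than chance; APP = 1 yields
#' `Inf`.
#'
#' @param app Average posterior probability among assigned members, in
#'   \[0, 1\].
#' @param pi Estimated group probability, in (0, 1).
#' @return Scalar odds ratio (possibly `Inf`).
#' @export
occ <- function(app, pi) {
  if (any(pi <= 0 | pi >= 1)) {
    stop_dnamtraj("`pi` must lie strictly inside (0, 1).")
  }
  if (any(app < 0 | app > 1)) stop_dnamtraj("`app` must lie in [0, 1].")
  ifelse(app == 1, Inf, (app / (1 - app)) / (pi / (1 - pi)))
}

#' Posterior classification quality control
#'
#' Applies the three standard adequacy checks to a fitted trajectory model:
#' (1) each group's average posterior probability of assignment (APP, the
#' mean posterior among its modally assigned members) is at least `app_min`
#' (0.7); (2) each group's odds of correct classification exceeds `occ_min`
#' (5); (3) the estimated group probabilities approximately equal the
#' observed assignment shares (within `prop_tol`, an absolute tolerance
#' operationalizing "approximately equal"). A group with no modal members
#' fails with an explicit reason.
#'
#' @param fit A `gbta_fit`.
#' @param app_min,occ_min,prop_tol QC thresholds.
#' @return An object of class `gbta_qc`: `groups` (tibble: group, n_assigned,
#'   share_observed, pi, app, occ, pass_app, pass_occ, pass_prop, reason)
#'   and `pass` (overall logical).
#' @export
posterior_qc <- function(fit, app_min = 0.7, occ_min = 5, prop_tol = 0.1) {
  stopifnot(inherits(fit, "gbta_fit"))
  G <- length(fit$pi)
  rows <- purrr::map(seq_len(G), function(g) {
    members <- fit$assignment == g
    n_g <- sum(members)
    share <- n_g / length(fit$assignment)
    if (n_g == 0) {
      return(tibble::tibble(
        group = g, n_assigned = 0L, share_observed = 0,
        pi = unname(fit$pi[g]), app = NA_real_, occ = NA_real_,
        pass_app = FALSE, pass_occ = FALSE,
        pass_prop = abs(fit$pi[g] - 0) <= prop_tol,
        reason = "no modally assigned members"
      ))
    }
    app_g <- mean(fit$posteriors[members, g])
    occ_g <- if (fit$pi[g] <= 0 || fit$pi[g] >= 1) {
      Inf
    } else {
      occ(app_g, unname(fit$pi[g]))
    }
    tibble::tibble(
      group = g, n_assigned = n_g, share_observed = share,
      pi = unname(fit$pi[g]), app = app_g, occ = occ_g,
      pass_app = app_g >= app_min, pass_occ = occ_g > occ_min,
      pass_prop = abs(fit$pi[g] - share) <= prop_tol,
      reason = NA_character_
    )
  })
  groups <- dplyr::bind_rows(rows)
  structure(list(
    groups = groups,
    pass = all(groups$pass_app & groups$pass_occ & groups$pass_prop),
    thresholds = c(app_min = app_min, occ_min = occ_min, prop_tol = prop_tol)
  ), class = "gbta_qc")
}

#' @export
print.gbta_qc <- function(x, ...) {
  cat(sprintf("<gbta_qc> overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  print(x$groups)
  invisible(x)
}

#' Profile trajectory groups against participant characteristics
#'
#' Summarizes covariates per modal trajectory group (mean (SD) for
#' continuous variables, n (%) for categorical) and tests group differences
#' with one-way ANOVA (continuous) or chi-square/Fisher (categorical) via
#' the cohort-statistics layer. Smoking is described on its raw levels but
#' tested as any-history (current/social/past) vs never, with unknowns
#' excluded from the test. No tests are run for a single-group fit.
#'
#' @param fit A `gbta_fit`.
#' @param covariates Participant-level tibble including `participant_id`.
#' @return A list of class `gbta_profile`: `summary` (long tibble: variable,
#'   level, group, n, mean, sd, pct), `tests` (tibble: variable, method,
#'   statistic, p), `n_unjoined` participants without covariates.
#' @export
profile_groups <- function(fit, covariates) {
  stopifnot(inherits(fit, "gbta_fit"), "participant_id" %in% names(covariates))
  assign_tbl <- tibble::tibble(
    participant_id = names(fit$assignment),
    group = unname(fit$assignment)
  )
  dat <- dplyr::left_join(assign_tbl, covariates, by = "participant_id")
  unjoined <- sum(!stats::complete.cases(dat["group"])) +
    sum(!assign_tbl$participant_id %in% covariates$participant_id)
  if (unjoined > 0) {
    rlang::warn(sprintf("%d participant(s) lack covariate rows.", unjoined))
  }
  vars <- setdiff(names(covariates), "participant_id")
  G <- length(fit$pi)

  summaries <- purrr::map(vars, function(v) {
    x <- dat[[v]]
    if (is.numeric(x)) {
      dplyr::summarise(
        dplyr::group_by(tibble::tibble(group = dat$group, x = x), .data$group),
        n = sum(!is.na(.data$x)), mean = mean(.data$x, na.rm = TRUE),
        sd = stats::sd(.data$x, na.rm = TRUE), .groups = "drop"
      ) |>
        dplyr::mutate(variable = v, level = NA_character_, pct = NA_real_)
    } else {
      tab <- dplyr::count(
        tibble::tibble(group = dat$group, level = as.character(x)),
        .data$group, .data$level
      )
      tab <- dplyr::mutate(
        dplyr::group_by(tab, .data$group),
        pct = 100 * .data$n / sum(.data$n)
      ) |>
        dplyr::ungroup() |>
        dplyr::mutate(variable = v, mean = NA_real_, sd = NA_real_)
      tab
    }
  })
  summary_tbl <- dplyr::select(
    dplyr::bind_rows(summaries),
    dplyr::all_of(c("variable", "level", "group", "n", "mean", "sd", "pct"))
  )

  tests <- if (G < 2) {
    tibble::tibble(variable = character(), method = character(),
                   statistic = numeric(), p = numeric())
  } else {
    dplyr::bind_rows(purrr::map(vars, function(v) {
      x <- dat[[v]]
      ok <- !is.na(x)
      if (is.numeric(x)) {
        res <- tryCatch(oneway_anova(x[ok], dat$group[ok]),
                        error = function(e) NULL)
        if (is.null(res)) return(NULL)
        tibble::tibble(variable = v, method = "one-way ANOVA",
                       statistic = res$f, p = res$p)
      } else {
        xv <- as.character(x)
        if (v == "smoking") {
          xv <- dplyr::case_when(
            xv %in% c("current", "social", "quit", "yes", "past") ~ "yes",
            xv == "never" | xv == "no" ~ "no",
            TRUE ~ NA_character_
          )
        }
        ok2 <- !is.na(xv)
        tab <- table(xv[ok2], dat$group[ok2])
        if (any(dim(tab) < 2)) return(NULL)
        res <- tryCatch(contingency_test(tab), error = function(e) NULL)
        if (is.null(res)) return(NULL)
        tibble::tibble(variable = v, method = res$method,
                       statistic = res$statistic, p = res$p)
      }
    }))
  }
  structure(list(summary = summary_tbl, tests = tests,
                 n_unjoined = unjoined),
            class = "gbta_profile")
}
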