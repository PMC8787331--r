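#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
print.gbta_fit <- function(x, ...) {
  cat(sprintf(
    "<gbta_fit> %d groups, orders (%s), %d participants / %d observations\n",
    length(x$pi), paste(x$orders, collapse = ","), x$n_participants, x$n_obs))
  cat(sprintf("  loglik %.3f | k %d | BIC(N) %.3f | BIC(obs) %.3f | sigma %s%s\n",
              x$loglik, x$k, x$bic, x$bic_obs,
              paste(sprintf("%.3f", x$sigma), collapse = "/"),
              if (x$converged) "" else " [not converged]"))
  tbl <- tibble::tibble(
    group = names(x$pi), pi = unname(x$pi),
    intercept = x$coefficients[, "intercept"],
    linear = x$coefficients[, "linear"],
    quadratic = x$coefficients[, "quadratic"],
    n_assigned = as.integer(table(factor(x$assignment,
                                         levels = seq_along(x$pi))))
  )
  print(tbl)
  invisible(x)
}

#' Tidy a fitted trajectory model
#'
#' One row per group x polynomial term (terms beyond the group's order are
#' omitted), with the group probability repeated per group.
#'
#' @param x A `gbta_fit`.
#' @param ... Unused.
#' @return Tibble: `group`, `term`, `estimate`, `pi`, `n_assigned`.
#' @method tidy gbta_fit
#' @export
tidy.gbta_fit <- function(x, ...) {
  terms <- c("intercept", "linear", "quadratic")
  counts <- table(factor(x$assignment, levels = seq_along(x$pi)))
  dplyr::bind_rows(purrr::map(seq_along(x$pi), function(g) {
    tibble::tibble(
      group = names(x$pi)[g],
      term = terms[seq_len(x$orders[g] + 1)],
      estimate = unname(x$coefficients[g, seq_len(x$orders[g] + 1)]),
      pi = unname(x$pi[g]),
      n_assigned = as.integer(counts[g])
    )
  }))
}

#' Model-level summary of a fitted trajectory model
#'
#' @param x A `gbta_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_groups`, `logLik`, `k`, `bic`, `bic_obs`,
#'   `sigma`, `n_participants`, `n_obs`, `converged`.
#' @method glance gbta_fit
#' @export
glance.gbta_fit <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$pi), logLik = x$loglik, k = x$k,
    bic = x$bic, bic_obs = x$bic_obs,
    sigma = if (x$shared_sigma) x$sigma[1] else mean(x$sigma),
    n_participants = x$n_participants, n_obs = x$n_obs,
    converged = x$converged
  )
}

#' Plot fitted trajectory groups over time bins
#'
#' Group mean trajectories (lines) over the five time bins with the
#' observed per-participant values colored by modal group assignment.
#'
#' @param object A `gbta_fit`.
#' @param show_observed Overlay observed values.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gbta_fit
#' @export
autoplot.gbta_fit <- function(object, show_observed = TRUE, ...) {
  bins <- 1:5
  pred <- dplyr::bind_rows(purrr::map(seq_along(object$pi), function(g) {
    tibble::tibble(
      group = names(object$pi)[g], time_bin = bins,
      value = group_mean_at_bin(object$coefficients, g, bins)
    )
  }))
  p <- ggplot2::ggplot(pred,
                       ggplot2::aes(x = .data$time_bin, y = .data$value,
                                    color = .data$group))
  if (show_observed) {
    obs <- dplyr::mutate(
      object$panel,
      group = names(object$pi)[object$assignment[.data$participant_id]]
    )
    p <- p + ggplot2::geom_jitter(data = obs, width = 0.12, height = 0,
                                  alpha = 0.25, size = 0.8)
  }
  p +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Cross-sectional time bin",
                  y = "Age acceleration (years)",
                  color = "Trajectory group") +
    ggplot2::theme_minimal()
}

#' Plot a BIC model-search table
#'
#' @param object A `gbta_search`.
#' @param ... Unused.
#' @return A ggplot of BIC against the number of groups, one line per
#'   polynomial order.
#' @method autoplot gbta_search
#' @export
autoplot.gbta_search <- function(object, ...) {
  tab <- dplyr::filter(object$table, !is.na(.data$bic))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$G, y = .data$bic,
                                    color = factor(.data$order))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of groups", y = "BIC (larger is better)",
                  color = "Polynomial order") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of age acceleration by time bin
#'
#' Boxplots of residual acceleration per time bin, faceted by clock and
#' adjustment flavor.
#'
#' @param accel Acceleration table from [compute_acceleration()].
#' @param tissue Tissue to plot (default CSF).
#' @return A ggplot.
#' @export
plot_acceleration <- function(accel, tissue = "CSF") {
  dat <- dplyr::filter(accel, .data$tissue == !!tissue)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$time_bin),
                                    y = .data$residual)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$clock),
                        cols = ggplot2::vars(.data$flavor)) +
    ggplot2::labs(x = "Cross-sectional time bin",
                  y = "Age acceleration (years)") +
    ggplot2::theme_minimal()
}
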