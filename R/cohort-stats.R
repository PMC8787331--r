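#' Pearson correlation with test
#'
#' Product-moment correlation with the usual t-distribution two-sided
#' p-value. Pairs with a missing value in either vector are dropped
#' (pairwise-complete); the number of excluded pairs is recorded.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Tibble: `r`, `p`, `n` (pairs used), `n_excluded`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  xs <- x[ok]; ys <- y[ok]
  if (length(xs) < 3) stop_dnamtraj("need at least 3 complete pairs.")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop_dnamtraj("zero variance: correlation undefined.")
  }
  ct <- stats::cor.test(xs, ys, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n = length(xs), n_excluded = sum(!ok))
}

#' One-way analysis of variance
#'
#' Classical between/within F test with df (G - 1, N - G).
#'
#' @param value Numeric response.
#' @param group Group labels (>= 2 nonempty groups, N > G).
#' @return Tibble: `f`, `df1`, `df2`, `p`, `n`.
#' @export
oneway_anova <- function(value, group) {
  stopifnot(length(value) == length(group))
  ok <- stats::complete.cases(value, group)
  value <- value[ok]; group <- factor(group[ok])
  if (nlevels(group) < 2) stop_dnamtraj("need at least 2 nonempty groups.")
  if (length(value) <= nlevels(group)) {
    stop_dnamtraj("need more observations than groups.")
  }
  if (stats::var(value) == 0) {
    # identical values everywhere: no between-group signal
    return(tibble::tibble(f = 0, df1 = nlevels(group) - 1L,
                          df2 = length(value) - nlevels(group), p = 1,
                          n = length(value)))
  }
  a <- stats::anova(stats::lm(value ~ group))
  tibble::tibble(f = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                 p = a$`Pr(>F)`[1], n = length(value))
}

#' Chi-square or Fisher's exact test of a contingency table
#'
#' Uses the chi-square test without continuity correction unless any
#' expected count falls below 5, in which case Fisher's exact test is used
#' (always for 2x2; for larger tables the exact test is attempted and falls
#' back to chi-square with a warning if infeasible).
#'
#' @param tab Matrix/table of nonnegative integer counts, at least 2x2.
#' @return Tibble: `method` (`"chi-square"` or `"fisher"`), `statistic`
#'   (chi-square statistic; `NA` for Fisher), `p`, `n`,
#'   `min_expected`.
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_dnamtraj("counts must be nonnegative integers.")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stop_dnamtraj("table must be >= 2x2.")
  if (sum(tab) == 0) stop_dnamtraj("all-zero table.")
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  min_exp <- min(chi$expected)
  if (min_exp < 5) {
    ft <- tryCatch(stats::fisher.test(tab), error = function(e) NULL)
    if (!is.null(ft)) {
      return(tibble::tibble(method = "fisher", statistic = NA_real_,
                            p = ft$p.value, n = sum(tab),
                            min_expected = min_exp))
    }
    rlang::warn("Fisher's exact test infeasible; falling back to chi-square.")
  }
  tibble::tibble(method = "chi-square",
                 statistic = unname(chi$statistic), p = chi$p.value,
                 n = sum(tab), min_expected = min_exp)
}

#' Bivariate regression of acceleration on one participant characteristic
#'
#' Simple OLS with intercept, the shape of a bivariate-association table:
#' unstandardized estimate, SE, 95% CI (t quantile) and p per non-intercept
#' term. Categorical covariates are coded against `reference` (e.g., sex
#' against male, race against White, smoking against no). Listwise deletion
#' within the regression; a perfectly fitting covariate yields a zero
#' residual SE and the p-value is reported as 0 with a warning.
#'
#' @param accel Numeric response (age acceleration, years).
#' @param covariate Numeric vector or factor/character covariate.
#' @param reference Reference level for categorical covariates.
#' @return Tibble: `term`, `estimate`, `se`, `conf_low`, `conf_high`, `p`,
#'   `n`, `n_excluded`.
#' @export
bivariate_regression <- function(accel, covariate, reference = NULL) {
  stopifnot(length(accel) == length(covariate))
  ok <- stats::complete.cases(accel, covariate)
  y <- accel[ok]; x <- covariate[ok]
  if (length(y) < 3) stop_dnamtraj("need at least 3 complete pairs.")
  if (is.character(x) || is.factor(x)) {
    x <- factor(x)
    if (!is.null(reference)) x <- stats::relevel(x, ref = reference)
    if (nlevels(x) < 2) {
      stop_dnamtraj("constant covariate: nothing to regress on.")
    }
  } else if (stats::sd(x) == 0) {
    stop_dnamtraj("constant covariate: nothing to regress on.")
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns separately on zero-residual fits; we detect and report
  # that case ourselves
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  perfect <- sfit$sigma < 1e-10
  if (perfect) {
    rlang::warn("perfect fit (zero residual SE); p reported as 0.")
  }
  rows <- rownames(sm)[-1]
  tibble::tibble(
    term = sub("^x", "", rows),
    estimate = sm[-1, 1],
    se = sm[-1, 2],
    conf_low = sm[-1, 1] - stats::qt(0.975, fit$df.residual) * sm[-1, 2],
    conf_high = sm[-1, 1] + stats::qt(0.975, fit$df.residual) * sm[-1, 2],
    p = if (perfect) 0 else sm[-1, 4],
    n = length(y),
    n_excluded = sum(!ok)
  )
}
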