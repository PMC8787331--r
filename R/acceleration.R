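#' Assign post-injury days to cross-sectional time bins
#'
#' Serial samples are collapsed into five 3-day windows: time 1 = days 0-2,
#' time 2 = days 3-5, time 3 = days 6-8, time 4 = days 9-11, time 5 =
#' days 12-14. Days outside 0-14 are unassigned (`NA`).
#'
#' @param day Integer day(s) post-injury.
#' @return Integer time-bin index 1-5, or `NA` for out-of-window days.
#' @export
assign_time_bin <- function(day) {
  day <- as.integer(round(day))
  bin <- day %/% 3L + 1L
  bin[day < 0L | day > 14L] <- NA_integer_
  bin
}

#' Restrict blood samples to the first time bin
#'
#' Blood was drawn around presentation, so blood samples falling outside
#' time 1 (days 0-2) are excluded from analysis; CSF rows are untouched.
#'
#' @param sheet Sample sheet with `tissue` and `day` columns.
#' @return The filtered sheet; attribute `n_removed` records the count.
#' @export
filter_blood_to_time1 <- function(sheet) {
  keep <- sheet$tissue != "blood" |
    (!is.na(assign_time_bin(sheet$day)) & assign_time_bin(sheet$day) == 1L)
  out <- sheet[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Residual-based age acceleration within one stratum
#'
#' Age acceleration is the residual of DNAm age regressed (OLS, with
#' intercept) on chronological age — optionally plus cell-type proportion
#' covariates — within a single cross-sectional stratum. Residuals are
#' mean-zero and uncorrelated with every regressor by construction; a
#' positive residual marks a methylome "older" than expected for the
#' person's age within that stratum.
#'
#' @param age Chronological ages (years).
#' @param dnam_age DNAm ages (years), same length.
#' @param covariates Optional numeric matrix/data frame of extra regressors
#'   (e.g., K - 1 cell-type proportions with the lowest-variance cell
#'   already dropped).
#' @return Numeric residual vector.
#' @export
residual_acceleration <- function(age, dnam_age, covariates = NULL) {
  n <- length(age)
  stopifnot(length(dnam_age) == n)
  X <- cbind(`(Intercept)` = 1, age = age)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    stopifnot(nrow(cv) == n)
    X <- cbind(X, cv)
  }
  if (anyNA(X) || anyNA(dnam_age)) {
    stop_dnamtraj("missing values within stratum; filter before fitting.")
  }
  p <- ncol(X) - 1L
  if (n < p + 2L) {
    stop_dnamtraj(sprintf("stratum too small: %d observations for %d regressors.",
                          n, p),
                  class = "dnamtraj_small_stratum")
  }
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    bad <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop_dnamtraj(paste0("rank-deficient design; collinear column(s): ",
                         paste(bad, collapse = ", ")),
                  class = "dnamtraj_rank_error")
  }
  unname(qr.resid(qr_X, dnam_age))
}

#' Tukey-fence outlier flags for DNAm age within a stratum
#'
#' Flags DNAm ages outside `[Q1 - k * IQR, Q3 + k * IQR]` (multiplier
#' `k = 3`, extreme-outlier fences) using linear-interpolation (type-7)
#' quartiles. Flags are informational: flagged observations are retained by
#' default, matching the practice of reporting metrics unadjusted for
#' outliers after confirming results are concordant either way. A one-sided
#' (upper-fence only) reading is available via `side = "upper"`.
#'
#' @param x Numeric DNAm ages (>= 4 observations).
#' @param k Fence multiplier.
#' @param side `"both"` (default) or `"upper"`.
#' @return Logical flags, `TRUE` = outlier.
#' @export
flag_outliers <- function(x, k = 3, side = c("both", "upper")) {
  side <- match.arg(side)
  if (length(x) < 4) {
    stop_dnamtraj("need at least 4 observations to place quartile fences.")
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  upper <- x > q[2] + k * iqr
  if (side == "upper") return(upper)
  upper | x < q[1] - k * iqr
}

#' Acceleration table across clocks, tissues, time bins and flavors
#'
#' Joins DNAm ages to the sample sheet and computes residual age
#' acceleration separately within every (clock, tissue, time bin) stratum —
#' "within each cross-sectional time point", never pooled — in two flavors:
#' `unadjusted` (DNAm age ~ age) and, when `cth` is supplied,
#' `cth_adjusted` (DNAm age ~ age + K-1 cell proportions, the
#' lowest-variance cell dropped). Blood rows outside time 1 are removed
#' first. Samples with missing cell-proportion values are excluded from the
#' adjusted flavor only. Strata too small for the regression are skipped
#' with a warning. Outlier flags use [flag_outliers()] on DNAm age within
#' the stratum (no flags when the stratum has fewer than 4 samples).
#'
#' @param dnam_ages Tibble from [compute_dnam_age()] (possibly several
#'   clocks row-bound).
#' @param sheet Sample sheet with sample_id, participant_id, tissue, day,
#'   time_bin, age.
#' @param cth Optional [estimate_proportions()] result (or its
#'   `proportions` tibble).
#' @param outlier_k,outlier_side Passed to [flag_outliers()].
#' @return Tibble: sample_id, participant_id, clock, tissue, time_bin,
#'   flavor, residual, outlier_flag.
#' @export
compute_acceleration <- function(dnam_ages, sheet, cth = NULL,
                                 outlier_k = 3, outlier_side = "both") {
  sheet <- filter_blood_to_time1(sheet)
  dat <- dplyr::inner_join(
    dnam_ages,
    dplyr::select(sheet, dplyr::all_of(c("sample_id", "participant_id",
                                         "tissue", "time_bin", "age"))),
    by = "sample_id"
  )
  props <- NULL
  if (!is.null(cth)) {
    pt <- if (inherits(cth, "cth_estimate")) cth$proportions else cth
    cell_cols <- grep("^cell_\\d+$", names(pt), value = TRUE)
    drop_col <- if (inherits(cth, "cth_estimate")) {
      paste0("cell_", cth$dropped_index)
    } else {
      cell_cols[select_dropped_cell(pt[cell_cols])]
    }
    props <- pt[c("sample_id", setdiff(cell_cols, drop_col))]
  }

  strata <- dplyr::group_split(
    dplyr::group_by(dat, .data$clock, .data$tissue, .data$time_bin)
  )
  out <- purrr::map(strata, function(st) {
    flags <- if (nrow(st) >= 4) {
      flag_outliers(st$dnam_age, k = outlier_k, side = outlier_side)
    } else {
      rep(FALSE, nrow(st))
    }
    base <- tibble::tibble(
      sample_id = st$sample_id, participant_id = st$participant_id,
      clock = st$clock, tissue = st$tissue, time_bin = st$time_bin,
      outlier_flag = flags
    )
    res <- list()
    unadj <- tryCatch(
      residual_acceleration(st$age, st$dnam_age),
      dnamtraj_small_stratum = function(e) {
        rlang::warn(sprintf(
          "skipping unadjusted stratum %s/%s/bin %d: %s",
          st$clock[1], st$tissue[1], st$time_bin[1], conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(unadj)) {
      res$unadj <- dplyr::mutate(base, flavor = "unadjusted", residual = unadj)
    }
    if (!is.null(props)) {
      stc <- dplyr::inner_join(st, props, by = "sample_id")
      stc <- stc[stats::complete.cases(stc), , drop = FALSE]
      cv <- as.matrix(stc[setdiff(names(props), "sample_id")])
      # zero-variance proportions carry no adjustment information and are
      # collinear with the intercept: drop them
      cv <- cv[, apply(cv, 2, stats::var) > 0, drop = FALSE]
      if (ncol(cv) == 0) cv <- NULL
      adj <- tryCatch(
        residual_acceleration(stc$age, stc$dnam_age, covariates = cv),
        dnamtraj_small_stratum = function(e) {
          rlang::warn(sprintf(
            "skipping CTH-adjusted stratum %s/%s/bin %d: %s",
            st$clock[1], st$tissue[1], st$time_bin[1], conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(adj)) {
        res$adj <- dplyr::mutate(
          base[match(stc$sample_id, base$sample_id), ],
          flavor = "cth_adjusted", residual = adj
        )
      }
    }
    dplyr::bind_rows(res)
  })
  dplyr::relocate(dplyr::bind_rows(out), "flavor", .after = "time_bin")
}
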