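#' Construct an epigenetic clock definition
#'
#' An epigenetic clock is a linear predictor of age from methylation beta
#' values at a fixed probe set: `DNAmAge = m0 + sum_i m_i * beta_i`, followed
#' by an optional output transform. The Horvath clock reports the linear
#' score on a transformed age scale and needs [horvath_inverse()] to map back
#' to years; the Hannum, Levine and Zhang clocks report years directly. The
#' Zhang clock additionally standardizes each sample's beta values over the
#' clock probe set before applying the coefficients.
#'
#' @param name Clock name (identifier).
#' @param intercept Model intercept `m0`, in clock units.
#' @param coefficients Named numeric vector, probe ID -> coefficient.
#' @param transform Output transform: `"identity"` or `"horvath_inverse"`.
#' @param standardize_per_sample Center/scale each sample's betas over the
#'   probe set before applying coefficients (Zhang convention).
#' @param adult_age Anchor age (years) of the Horvath transform.
#' @return An object of class `clock_definition`.
#' @export
clock_definition <- function(name, intercept, coefficients,
                             transform = c("identity", "horvath_inverse"),
                             standardize_per_sample = FALSE,
                             adult_age = 20) {
  transform <- match.arg(transform)
  if (length(coefficients) == 0) {
    stop_dnamtraj("a clock needs at least one probe coefficient.",
                  class = "dnamtraj_format_error")
  }
  probes <- names(coefficients)
  if (is.null(probes) || any(!nzchar(probes))) {
    stop_dnamtraj("`coefficients` must be named by probe ID.")
  }
  if (anyDuplicated(probes)) {
    stop_dnamtraj(
      paste0("duplicate probe IDs in clock table: ",
             paste(unique(probes[duplicated(probes)]), collapse = ", ")),
      class = "dnamtraj_format_error"
    )
  }
  structure(
    list(
      name = as.character(name),
      intercept = as.numeric(intercept),
      coefficients = coefficients,
      transform = transform,
      standardize_per_sample = isTRUE(standardize_per_sample),
      adult_age = adult_age
    ),
    class = "clock_definition"
  )
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf(
    "<clock_definition> %s: %d probes, intercept %.4g, transform %s%s\n",
    x$name, length(x$coefficients), x$intercept, x$transform,
    if (x$standardize_per_sample) ", per-sample standardized betas" else ""
  ))
  invisible(x)
}

#' Load a clock coefficient table from CSV
#'
#' Reads a coefficient table with columns `probe_id` and `coefficient` and
#' exactly one intercept row (probe ID `"(Intercept)"` by default, the
#' dialect used by published coefficient tables).
#'
#' @param path CSV file path.
#' @param name Clock name.
#' @inheritParams clock_definition
#' @param intercept_sentinel Probe ID marking the intercept row.
#' @return A [clock_definition()].
#' @export
load_clock_table <- function(path, name = "clock",
                             transform = c("identity", "horvath_inverse"),
                             standardize_per_sample = FALSE,
                             intercept_sentinel = "(Intercept)",
                             adult_age = 20) {
  transform <- match.arg(transform)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    coefficient = readr::col_double()
  ))
  if (!all(c("probe_id", "coefficient") %in% names(tbl))) {
    stop_dnamtraj("clock table must have columns probe_id and coefficient.",
                  class = "dnamtraj_format_error")
  }
  is_int <- tbl$probe_id == intercept_sentinel
  if (sum(is_int) != 1) {
    stop_dnamtraj(
      sprintf("clock table must contain exactly one '%s' row (found %d).",
              intercept_sentinel, sum(is_int)),
      class = "dnamtraj_format_error"
    )
  }
  probes <- tbl[!is_int, ]
  if (nrow(probes) == 0) {
    stop_dnamtraj("clock table has an intercept but no probe rows.",
                  class = "dnamtraj_format_error")
  }
  coefs <- stats::setNames(probes$coefficient, probes$probe_id)
  clock_definition(
    name = name, intercept = tbl$coefficient[is_int][1], coefficients = coefs,
    transform = transform, standardize_per_sample = standardize_per_sample,
    adult_age = adult_age
  )
}

#' Intersect clock probes with the probes measured in each tissue
#'
#' For cross-tissue comparability only clock probes measured in *every*
#' supplied matrix are used, mirroring the practice of restricting a clock to
#' probes available in both CSF and blood after array QC. An empty
#' intersection is allowed and simply reported.
#'
#' @param clock A [clock_definition()].
#' @param ... One beta matrix per tissue (probes x samples), optionally named.
#' @return A list with `probes` (character vector retained), and `report`
#'   (tibble: clock, n_clock_probes, n_retained, n_missing, missing_probes).
#' @export
intersect_probes <- function(clock, ...) {
  mats <- list(...)
  if (length(mats) == 0) {
    stop_dnamtraj("supply at least one beta matrix.")
  }
  clock_probes <- names(clock$coefficients)
  keep <- clock_probes
  for (m in mats) keep <- keep[keep %in% rownames(m)]
  missing <- setdiff(clock_probes, keep)
  list(
    probes = keep,
    report = tibble::tibble(
      clock = clock$name,
      n_clock_probes = length(clock_probes),
      n_retained = length(keep),
      n_missing = length(missing),
      missing_probes = list(missing)
    )
  )
}

#' Raw clock score (linear predictor) per sample
#'
#' Computes `m0 + sum_i m_i beta_i` over `probe_set` for each sample. With
#' per-sample standardization, each sample's betas over the probe set are
#' centered and scaled (sd) first.
#'
#' @param clock A [clock_definition()].
#' @param betas Beta matrix, probes x samples, in \[0, 1\].
#' @param probe_set Probes to use; defaults to all clock probes.
#' @return Named numeric vector of raw scores, one per sample.
#' @export
linear_predictor <- function(clock, betas, probe_set = names(clock$coefficients)) {
  check_beta_matrix(betas)
  if (length(probe_set) == 0) {
    stop_dnamtraj("empty probe set: no clock probes available in the data.")
  }
  missing <- setdiff(probe_set, rownames(betas))
  if (length(missing)) {
    stop_dnamtraj(
      paste0("probe_set contains probes absent from the beta matrix: ",
             paste(head(missing, 5), collapse = ", "),
             if (length(missing) > 5) ", ..." else "")
    )
  }
  b <- betas[probe_set, , drop = FALSE]
  if (clock$standardize_per_sample) {
    mu <- colMeans(b)
    sds <- apply(b, 2, stats::sd)
    sds[sds == 0] <- 1  # constant sample: centering alone
    b <- sweep(sweep(b, 2, mu, "-"), 2, sds, "/")
  }
  m <- clock$coefficients[probe_set]
  score <- drop(clock$intercept + crossprod(b, m))
  stats::setNames(as.numeric(score), colnames(betas))
}

#' Horvath age transform and its inverse
#'
#' The Horvath clock is trained on a transformed age scale that is
#' logarithmic below an anchor ("adult") age and linear above it. The
#' forward transform is `F(a) = log(a + 1) - log(adult_age + 1)` for
#' `a <= adult_age` and `(a - adult_age) / (adult_age + 1)` above; the
#' inverse maps a raw clock score back to years:
#' `(adult_age + 1) * exp(x) - 1` for `x <= 0`, else
#' `(adult_age + 1) * x + adult_age`. Both are continuous and strictly
#' increasing.
#'
#' @param x Raw clock score(s) (transformed-age scale).
#' @param age Chronological age(s) in years (forward direction).
#' @param adult_age Anchor age in years (canonical value 20).
#' @return Years (`horvath_inverse`) or transformed age (`horvath_forward`).
#' @export
horvath_inverse <- function(x, adult_age = 20) {
  if (any(!is.finite(x))) {
    stop_dnamtraj("raw clock score must be finite.")
  }
  ifelse(x <= 0, (adult_age + 1) * exp(x) - 1, (adult_age + 1) * x + adult_age)
}

#' @rdname horvath_inverse
#' @export
horvath_forward <- function(age, adult_age = 20) {
  if (any(!is.finite(age))) {
    stop_dnamtraj("age must be finite.")
  }
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' Compute DNAm age for every sample under a clock
#'
#' Applies the clock's linear predictor and output transform, with an
#' explicit policy for clock probes absent from the data:
#' \describe{
#'   \item{`drop_missing`}{drop absent probes and proceed, logging counts
#'     (the default; published analyses proceeded with a handful of probes
#'     missing after QC rather than imputing).}
#'   \item{`intersect_tissues`}{restrict to probes present in every matrix in
#'     `other_tissues` as well as `betas`, then proceed as `drop_missing`.}
#'   \item{`strict`}{error if any clock probe is absent.}
#' }
#'
#' @param clock A [clock_definition()].
#' @param betas Beta matrix, probes x samples.
#' @param probe_policy Missing-probe policy (see Details).
#' @param other_tissues List of additional beta matrices (for
#'   `intersect_tissues`).
#' @return A tibble with one row per sample: `sample_id`, `clock`,
#'   `dnam_age`, `n_probes_used`, `n_probes_missing`.
#' @export
compute_dnam_age <- function(clock, betas,
                             probe_policy = c("drop_missing",
                                              "intersect_tissues", "strict"),
                             other_tissues = list()) {
  probe_policy <- match.arg(probe_policy)
  check_beta_matrix(betas)
  clock_probes <- names(clock$coefficients)
  if (probe_policy == "intersect_tissues") {
    probe_set <- do.call(
      intersect_probes, c(list(clock, betas), other_tissues)
    )$probes
  } else {
    probe_set <- intersect(clock_probes, rownames(betas))
    if (probe_policy == "strict" && length(probe_set) < length(clock_probes)) {
      stop_dnamtraj(
        sprintf("strict probe policy: %d clock probe(s) missing from the data.",
                length(clock_probes) - length(probe_set)),
        class = "dnamtraj_missing_probe_error"
      )
    }
  }
  score <- linear_predictor(clock, betas, probe_set)
  age <- switch(clock$transform,
    identity = score,
    horvath_inverse = horvath_inverse(score, adult_age = clock$adult_age)
  )
  tibble::tibble(
    sample_id = colnames(betas),
    clock = clock$name,
    dnam_age = unname(age),
    n_probes_used = length(probe_set),
    n_probes_missing = length(clock_probes) - length(probe_set)
  )
}

#' Synthetic clock coefficient table with the published structure
#'
#' Generates a *synthetic* stand-in for a clock coefficient table: the probe
#' count, intercept row and per-sample-standardization convention match the
#' published clock (Horvath 353 CpGs with the transformed-age output scale,
#' Hannum 71, Levine 513, Zhang 514 with standardized betas), but probe IDs
#' and coefficient values are simulated. Useful for structural tests and
#' pipeline runs when the real coefficient files are not at hand; DNAm ages
#' from these tables are not biologically meaningful.
#'
#' @param preset One of `"horvath"`, `"hannum"`, `"levine"`, `"zhang"`.
#' @param seed Integer seed controlling the simulated IDs/coefficients.
#' @return A tibble with columns `probe_id`, `coefficient` (intercept row
#'   first, sentinel `"(Intercept)"`), plus attributes `transform` and
#'   `standardize_per_sample` recording the preset's conventions.
#' @export
synthetic_clock_table <- function(preset = c("horvath", "hannum", "levine", "zhang"),
                                  seed = 1L) {
  preset <- match.arg(preset)
  n_probes <- c(horvath = 353L, hannum = 71L, levine = 513L, zhang = 514L)[[preset]]
  with_seed(derive_seed(seed, paste0("clock_", preset)), {
    ids <- sprintf("cg%08d", sample.int(99999999L, n_probes))
    coefs <- stats::rnorm(n_probes, 0, 2)
    tbl <- tibble::tibble(
      probe_id = c("(Intercept)", ids),
      coefficient = c(stats::rnorm(1, 40, 5), coefs)
    )
  })
  attr(tbl, "transform") <-
    if (preset == "horvath") "horvath_inverse" else "identity"
  attr(tbl, "standardize_per_sample") <- preset == "zhang"
  tbl
}
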