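#' Run the full analysis pipeline from a config
#'
#' Orchestrates simulate (or load) -> clock -> cell-type heterogeneity ->
#' acceleration -> trajectory modeling -> group statistics, writing every
#' intermediate table as TSV/JSON plus a run manifest with file digests so
#' two runs under the same config and seed are digest-identical.
#'
#' The config is a nested list (or a YAML/JSON file path) with exactly one
#' of:
#' \describe{
#'   \item{`simulate`}{arguments for the synthetic cohort: any
#'     [cohort_config()] fields, an optional `groups` block (`means`,
#'     `probs`, `sigma`), plus `noise_sd`, `clock_probes`, and a `mix`
#'     block (`K`, `decay_rate`, `n_probes`).}
#'   \item{`inputs`}{paths: `betas` (TSV), `sample_sheet` (CSV/TSV), and a
#'     `clocks` list of coefficient-table entries (`path`, `name`,
#'     `transform`, `standardize_per_sample`). Files must exist before any
#'     stage runs.}
#' }
#' plus optional `cth` (`enabled`, `K`, `n_probes`), `gbta` (`G_range`,
#' `orders`, `n_starts`, `flavor`, `clock`, `qc` thresholds), `stats`
#' (`enabled`) blocks and a `seed`. Every stochastic stage receives a seed
#' derived from the global seed; the derivation is recorded in the
#' manifest.
#'
#' @param config Nested list, or path to a YAML/JSON config file.
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @param stages Stages to run, a subset of
#'   `c("simulate", "clock", "cth", "accel", "gbta", "stats")` (stage
#'   `simulate` loads inputs instead when `inputs` is configured).
#' @return The manifest (list), invisibly; all outputs are files under
#'   `outdir`.
#' @export
run_pipeline <- function(config, outdir,
                         seed = NULL,
                         stages = c("simulate", "clock", "cth", "accel",
                                    "gbta", "stats")) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop_dnamtraj(sprintf("config file not found: %s", config),
                    class = "dnamtraj_config_error")
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stages <- match.arg(stages, several.ok = TRUE)
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    stop_dnamtraj("config must contain exactly one of `simulate` or `inputs`.",
                  class = "dnamtraj_config_error")
  }
  if (has_inp) {
    paths <- c(config$inputs$betas, config$inputs$sample_sheet,
               vapply(config$inputs$clocks, `[[`, character(1), "path"))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop_dnamtraj(paste0("input file(s) not found: ",
                           paste(missing, collapse = ", ")),
                    class = "dnamtraj_config_error")
    }
  }
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = logfile, append = TRUE)
  }
  run_stage <- function(name, code) {
    log_line("stage %s: start", name)
    out <- tryCatch(force(code), error = function(e) {
      log_line("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop_dnamtraj(sprintf("stage '%s' failed: %s", name,
                            conditionMessage(e)),
                    class = "dnamtraj_stage_error")
    })
    log_line("stage %s: done", name)
    out
  }
  outputs <- character(0)
  emit <- function(obj, file, writer = readr::write_tsv) {
    path <- file.path(outdir, file)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  emit_json <- function(obj, file) {
    path <- file.path(outdir, file)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs <<- c(outputs, path)
    path
  }

  sheet <- NULL; truth <- NULL; betas <- NULL; clocks <- NULL
  dnam <- NULL; cth <- NULL; accel <- NULL; search <- NULL; fit <- NULL

  if ("simulate" %in% stages) {
    if (has_sim) {
      sim_cfg <- config$simulate
      run_stage("simulate", {
        cc_args <- sim_cfg[intersect(names(sim_cfg),
                                     names(formals(cohort_config)))]
        cc_args$seed <- derive_seed(seed, "cohort")
        cfg <- do.call(cohort_config, cc_args)
        grp <- if (!is.null(sim_cfg$groups)) {
          trajectory_groups(group_means = sim_cfg$groups$means,
                            group_probs = sim_cfg$groups$probs,
                            sigma = sim_cfg$groups$sigma %||% 2)
        } else {
          trajectory_groups()
        }
        sim <- simulate_cohort(cfg, grp)
        sheet <- sim$sheet; truth <- sim$truth
        mix <- simulate_cell_mixtures(
          sheet, K = sim_cfg$mix$K %||% 5L,
          decay_rate = sim_cfg$mix$decay_rate %||% 0.15,
          n_probes = sim_cfg$mix$n_probes %||% 300L,
          seed = derive_seed(seed, "mix"))
        pc <- planted_clock(n_probes = sim_cfg$clock_probes %||% 50L,
                            seed = derive_seed(seed, "clock"))
        sim_b <- simulate_beta(sheet, truth, mix, pc,
                               noise_sd = sim_cfg$noise_sd %||% 0.01,
                               seed = derive_seed(seed, "beta"))
        betas <- sim_b$betas
        clocks <- list(pc$clock)
        emit(sheet, "sample_sheet.tsv")
        emit_json(list(
          group_of = as.list(truth$group_of),
          group_probs = truth$group_probs,
          coefficients = apply(truth$coeffs, 1, as.list),
          sigma = truth$sigma
        ), "truth.json")
        emit(betas, "beta_matrix.tsv", writer = write_beta_matrix)
      })
    } else {
      run_stage("load", {
        sheet <- read_sample_sheet(config$inputs$sample_sheet)
        betas <- read_beta_matrix(config$inputs$betas)
        clocks <- purrr::map(config$inputs$clocks, function(cl) {
          load_clock_table(
            cl$path, name = cl$name %||% "clock",
            transform = cl$transform %||% "identity",
            standardize_per_sample = isTRUE(cl$standardize_per_sample))
        })
        emit(sheet, "sample_sheet.tsv")
      })
    }
  }

  if ("clock" %in% stages) {
    dnam <- run_stage("clock", {
      tab <- dplyr::bind_rows(purrr::map(clocks, compute_dnam_age,
                                         betas = betas))
      emit(tab, "dnam_age.tsv")
      tab
    })
  }

  cth_on <- isTRUE(config$cth$enabled %||% TRUE)
  if ("cth" %in% stages && cth_on) {
    cth <- run_stage("cth", {
      est <- estimate_proportions(
        betas, K = config$cth$K %||% 5L,
        n_probes = config$cth$n_probes %||% 1000L,
        seed = derive_seed(seed, "cth"))
      emit(est$proportions, "cth_proportions.tsv")
      est
    })
  }

  if ("accel" %in% stages) {
    accel <- run_stage("accel", {
      at <- compute_acceleration(dnam, sheet, cth = cth)
      emit(at, "acceleration.tsv")
      at
    })
  }

  if ("gbta" %in% stages) {
    run_stage("gbta", {
      gcfg <- config$gbta %||% list()
      clock_name <- gcfg$clock %||% accel$clock[1]
      flavor <- gcfg$flavor %||% "unadjusted"
      panel <- dplyr::transmute(
        dplyr::filter(accel, .data$clock == clock_name,
                      .data$tissue == "CSF", .data$flavor == !!flavor),
        participant_id = .data$participant_id, time_bin = .data$time_bin,
        value = .data$residual)
      search <- model_search(
        panel, G_range = gcfg$G_range %||% 1:4,
        orders = gcfg$orders %||% 0L,
        n_starts = gcfg$n_starts %||% 3L,
        seed = derive_seed(seed, "gbta"))
      fit <- search$best_fit
      emit(search$table, "gbta_search.tsv")
      emit_json(list(
        pi = unname(fit$pi),
        coefficients = apply(fit$coefficients, 1, as.list),
        orders = fit$orders, sigma = fit$sigma, loglik = fit$loglik,
        k = fit$k, bic = fit$bic, bic_obs = fit$bic_obs,
        converged = fit$converged
      ), "gbta_fit.json")
      emit(tibble::as_tibble(fit$posteriors, rownames = "participant_id"),
           "gbta_posteriors.tsv")
      qc <- posterior_qc(fit,
                         app_min = gcfg$qc$app_min %||% 0.7,
                         occ_min = gcfg$qc$occ_min %||% 5,
                         prop_tol = gcfg$qc$prop_tol %||% 0.1)
      emit_json(list(pass = qc$pass, thresholds = as.list(qc$thresholds),
                     groups = qc$groups), "gbta_qc.json")
    })
  }

  if ("stats" %in% stages && isTRUE(config$stats$enabled %||% TRUE)) {
    run_stage("stats", {
      covars <- dplyr::distinct(
        dplyr::select(sheet, dplyr::all_of(c("participant_id", "age", "sex",
                                             "race", "smoking", "bmi",
                                             "fisher"))))
      if (!is.null(fit)) {
        prof <- profile_groups(fit, covars)
        emit(prof$summary, "group_profile_summary.tsv")
        emit(prof$tests, "group_profile_tests.tsv")
      }
      # bivariate associations of participant-mean acceleration
      pm <- dplyr::summarise(
        dplyr::group_by(
          dplyr::filter(accel, .data$tissue == "CSF"),
          .data$clock, .data$flavor, .data$participant_id),
        accel = mean(.data$residual), .groups = "drop")
      pm <- dplyr::inner_join(pm, covars, by = "participant_id")
      pm$smoking_any <- ifelse(pm$smoking == "never", "no", "yes")
      biv <- dplyr::bind_rows(purrr::map(
        dplyr::group_split(dplyr::group_by(pm, .data$clock, .data$flavor)),
        function(d) {
          specs <- list(
            sex = list(x = d$sex, ref = "male"),
            race = list(x = d$race, ref = "White"),
            smoking = list(x = d$smoking_any, ref = "no"),
            bmi = list(x = d$bmi, ref = NULL))
          dplyr::bind_rows(purrr::imap(specs, function(sp, nm) {
            row <- tryCatch(
              bivariate_regression(d$accel, sp$x, reference = sp$ref),
              error = function(e) NULL)
            if (is.null(row)) return(NULL)
            dplyr::mutate(row, clock = d$clock[1], flavor = d$flavor[1],
                          covariate = nm, .before = 1)
          }))
        }))
      emit(biv, "bivariate.tsv")
    })
  }

  manifest <- list(
    package = "dnamtraj",
    version = as.character(utils::packageVersion("dnamtraj")),
    seed = seed,
    stages = stages,
    derived_seeds = list(
      cohort = derive_seed(seed, "cohort"), mix = derive_seed(seed, "mix"),
      clock = derive_seed(seed, "clock"), beta = derive_seed(seed, "beta"),
      cth = derive_seed(seed, "cth"), gbta = derive_seed(seed, "gbta")),
    files = as.list(stats::setNames(
      unname(tools::md5sum(sort(unique(outputs)))),
      basename(sort(unique(outputs)))))
  )
  emit_json_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, emit_json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_line("pipeline complete: %d files", length(outputs) + 1L)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
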