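#' @importFrom rlang .data abort warn
#' @importFrom stats lm coef resid quantile var sd rnorm runif rbinom dnorm pnorm
#' @importFrom utils head
NULL

# Internal: consistent error helper with a class so tests can be specific.
stop_dnamtraj <- function(msg, class = "dnamtraj_error") {
  rlang::abort(msg, class = class)
}

# Internal: validate a beta matrix (probes x samples, values in [0,1]).
check_beta_matrix <- function(betas, allow_na = FALSE) {
  if (!is.matrix(betas) || !is.numeric(betas)) {
    stop_dnamtraj("`betas` must be a numeric matrix (probes x samples).")
  }
  if (is.null(rownames(betas)) || is.null(colnames(betas))) {
    stop_dnamtraj("`betas` must have probe IDs as rownames and sample IDs as colnames.")
  }
  vals <- betas[!is.na(betas)]
  if (!allow_na && anyNA(betas)) {
    stop_dnamtraj("`betas` contains missing values.")
  }
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    stop_dnamtraj("beta values must lie in [0, 1].", class = "dnamtraj_validation_error")
  }
  invisible(betas)
}

# Internal: derive a reproducible child seed from a parent seed and a stream
# label. Keeps results < 2^31 so they remain valid R integer seeds.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629L)
}

# Internal: run code under a locally-set RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483629))
  force(code)
}
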