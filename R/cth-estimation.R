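#' Reference-free cell-type proportion estimation
#'
#' Estimates K putative cell-type proportions per sample directly from the
#' beta matrix, without a reference panel — the situation in post-hemorrhage
#' CSF, where no reference deconvolution panel exists. The model is a
#' constrained low-rank factorization `betas ~ profiles %*% weights` with
#' cell-type profiles in \[0, 1\] (they are methylation fractions) and each
#' sample's weight vector on the K-simplex (they are proportions). Fitting
#' alternates two exact convex subproblems: box-constrained least squares
#' for the profiles (cyclic coordinate minimization with clipping, run to
#' tolerance) and simplex-constrained least squares for the weights
#' (active-set enumeration over support sets, batched across samples). Both
#' steps monotonically decrease the squared-error objective. As with any
#' reference-free method the recovered components are putative: they are
#' identified only up to label permutation and carry no cell-type names.
#'
#' @param betas Beta matrix, probes x samples, values in \[0, 1\].
#' @param K Number of cell types (1 <= K <= number of samples; K <= 12).
#' @param n_probes Use the `n_probes` most variable probes (all if fewer);
#'   restricting to variable probes is standard and keeps runtime modest.
#' @param n_restarts Random restarts; the best objective is kept.
#' @param max_iter Maximum alternating iterations per restart.
#' @param tol Convergence: relative objective change below `tol`.
#' @param seed Integer seed (initial weights are random).
#' @return An object of class `cth_estimate`: `proportions` (tibble:
#'   sample_id, cell_1..cell_K, dropped logical column flagging the
#'   lowest-variance cell), `profiles` (probes x K matrix), `variances`
#'   (per-cell across-sample variance), `dropped_index`, `objective`
#'   (per-iteration trace of the best restart), `converged`.
#' @export
estimate_proportions <- function(betas, K = 5L, n_probes = 1000L,
                                 n_restarts = 5L, max_iter = 100L,
                                 tol = 1e-8, seed = 1L) {
  check_beta_matrix(betas)
  n_s <- ncol(betas)
  if (K < 1) stop_dnamtraj("`K` must be >= 1.")
  if (K > n_s) {
    stop_dnamtraj(sprintf("K = %d exceeds the number of samples (%d).", K, n_s))
  }
  if (K > 12) stop_dnamtraj("K > 12 is not supported (exact simplex solver).")
  if (nrow(betas) < K) {
    stop_dnamtraj("need at least K probes for a rank-K factorization.")
  }
  # most variable probes
  v <- apply(betas, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_probes, nrow(betas)))]
  B <- betas[sort(keep), , drop = FALSE]

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(seed, paste0("cth_restart", r)),
                     als_factorize(B, K, max_iter, tol))
    if (is.null(best) || fit$objective[length(fit$objective)] <
        best$objective[length(best$objective)]) {
      best <- fit
    }
  }
  W <- best$W
  rownames(W) <- paste0("cell_", seq_len(K))
  colnames(W) <- colnames(B)
  variances <- apply(W, 1, stats::var)
  dropped <- select_dropped_cell(t(W))
  props <- tibble::as_tibble(t(W))
  props <- dplyr::mutate(props,
                         sample_id = colnames(B), .before = 1)
  props$dropped_cell <- paste0("cell_", dropped)
  structure(list(
    proportions = props,
    profiles = best$M,
    variances = variances,
    dropped_index = dropped,
    objective = best$objective,
    converged = best$converged
  ), class = "cth_estimate")
}

#' @export
print.cth_estimate <- function(x, ...) {
  cat(sprintf(
    "<cth_estimate> %d samples x %d cells; dropped (lowest variance): cell_%d; final SSE %.6g%s\n",
    nrow(x$proportions), length(x$variances), x$dropped_index,
    x$objective[length(x$objective)],
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Cell type to exclude from regression adjustment
#'
#' Because the K proportions sum to one, only K - 1 can enter a regression;
#' the cell with the lowest across-sample variance is excluded (it carries
#' the least adjustment information). Ties break to the lowest index.
#'
#' @param props Matrix or data frame of proportions, samples x cells.
#' @return Integer index of the cell to drop.
#' @export
select_dropped_cell <- function(props) {
  m <- as.matrix(props[, vapply(as.data.frame(props), is.numeric, logical(1)),
                       drop = FALSE])
  if (ncol(m) == 0) stop_dnamtraj("no cell-type columns supplied.")
  v <- apply(m, 2, stats::var)
  unname(which.min(v))  # which.min breaks ties by lowest index
}

# ---- internal solvers -----------------------------------------------------

# Alternating least squares: B (P x S) ~ M (P x K) %*% W (K x S),
# M in [0,1], W columns on the simplex.
als_factorize <- function(B, K, max_iter, tol) {
  P <- nrow(B); S <- ncol(B)
  # random simplex init for W
  W <- matrix(stats::rgamma(K * S, 1, 1), K, S)
  W <- sweep(W, 2, colSums(W), "/")
  M <- matrix(stats::runif(P * K), P, K)
  obj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M <- update_profiles(B, M, W)
    W <- simplex_ls(M, B)
    o <- sum((B - M %*% W)^2)
    obj <- c(obj, o)
    if (it > 1 && abs(obj[it - 1] - o) <= tol * (abs(obj[it - 1]) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  rownames(M) <- rownames(B)
  colnames(M) <- paste0("cell_", seq_len(K))
  list(M = M, W = W, objective = obj, converged = converged)
}

# Box-constrained LS for profiles: per probe p minimize ||b_p - m_p W||^2
# over m_p in [0,1]^K. Exact cyclic coordinate minimization (clipped),
# vectorized across probes; monotone in the objective.
update_profiles <- function(B, M, W, sweeps = 30L, tol = 1e-12) {
  G <- W %*% t(W)          # K x K
  H <- B %*% t(W)          # P x K
  K <- ncol(M)
  for (s in seq_len(sweeps)) {
    delta <- 0
    for (k in seq_len(K)) {
      if (G[k, k] <= 0) next
      rest <- H[, k] - M[, -k, drop = FALSE] %*% G[-k, k]
      mk <- pmin(pmax(rest / G[k, k], 0), 1)
      delta <- max(delta, max(abs(mk - M[, k])))
      M[, k] <- mk
    }
    if (delta < tol) break
  }
  M
}

# Simplex-constrained LS for weights: per sample minimize ||b - M w||^2 over
# w >= 0, sum(w) = 1. Exact: enumerate support sets, solving the
# equality-constrained KKT system batched across samples; keep the feasible
# solution with the smallest objective.
simplex_ls <- function(M, B) {
  K <- ncol(M); S <- ncol(B)
  if (K == 1) return(matrix(1, 1, S))
  AtA <- crossprod(M)
  AtB <- crossprod(M, B)              # K x S
  W <- matrix(0, K, S)
  best <- rep(Inf, S)
  for (mask in seq_len(2^K - 1)) {
    kk <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    m <- length(kk)
    Kmat <- rbind(cbind(AtA[kk, kk, drop = FALSE], 1),
                  c(rep(1, m), 0))
    sol <- tryCatch(solve(Kmat, rbind(AtB[kk, , drop = FALSE], rep(1, S))),
                    error = function(e) NULL)
    if (is.null(sol)) next
    Wsub <- sol[seq_len(m), , drop = FALSE]
    feas <- colSums(Wsub < -1e-10) == 0
    if (!any(feas)) next
    # objective up to a constant: w'AtA w - 2 w'Atb
    o <- colSums(Wsub * (AtA[kk, kk, drop = FALSE] %*% Wsub)) -
      2 * colSums(Wsub * AtB[kk, , drop = FALSE])
    upd <- feas & (o < best - 1e-15)
    if (any(upd)) {
      W[, upd] <- 0
      W[kk, upd] <- pmax(Wsub[, upd, drop = FALSE], 0)
      best[upd] <- o[upd]
    }
  }
  # renormalize away any active-set epsilon
  sweep(W, 2, colSums(W), "/")
}
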