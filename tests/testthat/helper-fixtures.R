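# Shared fixture builders. Everything is generated in code under explicit
# seeds; no fixture files.

# Flat-group trajectory panel with known membership, built independently of
# the package's own simulator so it can serve as ground truth for GBTA.
make_flat_panel <- function(n, means, probs = rep(1 / length(means), length(means)),
                            sigma = 2, retention = 0.62, seed = 1) {
  set.seed(seed)
  g <- sample(seq_along(means), n, replace = TRUE, prob = probs)
  rows <- lapply(seq_len(n), function(i) {
    bins <- which(stats::runif(5) < retention)
    if (length(bins) == 0) bins <- sample(1:5, 1)
    data.frame(
      participant_id = sprintf("P%03d", i),
      time_bin = bins,
      value = stats::rnorm(length(bins), means[g[i]], sigma)
    )
  })
  panel <- do.call(rbind, rows)
  attr(panel, "true_group") <- g
  panel
}

# Brute-force mixture log-likelihood: explicit per-participant sum over
# groups of prior-weighted products of normal densities.
loglik_oracle <- function(panel, pi, coeffs, sigma) {
  ids <- unique(panel$participant_id)
  sum(vapply(ids, function(id) {
    d <- panel[panel$participant_id == id, ]
    ct <- d$time_bin - 3
    comp <- vapply(seq_along(pi), function(g) {
      mu <- coeffs[g, 1] + coeffs[g, 2] * ct + coeffs[g, 3] * ct^2
      pi[g] * prod(stats::dnorm(d$value, mu, sigma))
    }, numeric(1))
    log(sum(comp))
  }, numeric(1)))
}

# A small end-to-end synthetic dataset reused by several files.
small_sim <- function(n = 40, seed = 3, noise_sd = 0, K = 3) {
  sim <- simulate_cohort(cohort_config(n_participants = n, blood_subset_n = 10,
                                       seed = seed))
  mix <- simulate_cell_mixtures(sim$sheet, K = K, n_probes = 120, seed = seed)
  pc <- planted_clock(n_probes = 20, seed = seed)
  sb <- simulate_beta(sim$sheet, sim$truth, mix, pc, noise_sd = noise_sd,
                      seed = seed)
  list(sim = sim, mix = mix, pc = pc, betas = sb$betas, planted = sb$planted)
}

# Map recovered cell-mixture weights onto truth by best label permutation
# (small K only) and return the max absolute weight error.
best_permutation_error <- function(est, truth) {
  K <- nrow(truth)
  errs <- vapply(combinat_perms(K),
                 function(p) max(abs(est[p, , drop = FALSE] - truth)),
                 numeric(1))
  min(errs)
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(n - 1L)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}
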