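# Shared fixtures, built once per test run.

# A reference simulated session: moderate sensory noise, informative
# confidence, realistic RT parameters.
ref_params <- function(sigma_s = 5, sigma_c = 0.5, ...) {
  observer_params(sigma_s = sigma_s, sigma_c = sigma_c,
                  rt_alpha = 520, rt_beta = -100, rt_gamma = 50,
                  rt_noise_sd = 150, ...)
}

ref_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_session(ref_params(), seed = 42)
    cache
  }
})

# Binomial counts drawn directly from the psychometric model.
simulate_counts <- function(mu, sigma, lambda = 0, n_per_level = 60,
                            deltas = seq(-9, 9, by = 3), seed = 1) {
  p <- lambda / 2 + (1 - lambda) * pnorm((deltas - mu) / sigma)
  k <- metaconf:::with_rng_seed(seed, rbinom(length(deltas), n_per_level, p))
  tibble::tibble(delta = deltas, n = n_per_level, k = k)
}

# Penalized objective evaluated on a dense parameter grid: the independent
# search oracle for the psychometric fit (same objective, exhaustive search).
grid_oracle_psy <- function(counts, mu_grid, sigma_grid, lambda_grid) {
  best <- list(obj = Inf)
  for (lam in lambda_grid) {
    for (sg in sigma_grid) {
      p <- outer(counts$delta, mu_grid,
                 function(d, m) lam / 2 + (1 - lam) * pnorm((d - m) / sg))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      nll <- -colSums(counts$k * log(p) + (counts$n - counts$k) * log1p(-p)) -
        dbeta(max(lam, 1e-9), 1.5, 20, log = TRUE)
      i <- which.min(nll)
      if (nll[i] < best$obj) {
        best <- list(obj = nll[i], mu = mu_grid[i], sigma = sg, lambda = lam)
      }
    }
  }
  best
}
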