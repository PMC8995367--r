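#' Aggregate decisions into per-level response counts
#'
#' Counts, for each distinct signed contrast difference, how many decisions
#' reported the test patch as higher in contrast.
#'
#' @param decisions A decision-level tibble (needs columns `delta` and
#'   `decision` with labels `"higher"`/`"lower"`).
#' @return A tibble with columns `delta`, `n` (decisions at that delta) and
#'   `k` (decisions reporting "higher"), sorted by delta.
#' @export
aggregate_proportions <- function(decisions) {
  stopifnot(nrow(decisions) >= 1)
  decisions |>
    dplyr::summarise(n = dplyr::n(),
                     k = sum(.data$decision == "higher"),
                     .by = "delta") |>
    dplyr::arrange(.data$delta)
}

# Psychometric model: p(delta) = lambda/2 + (1 - lambda) * Phi((delta - mu)/sigma).
# Equal guess and lapse asymptotes (lambda/2 each), appropriate for a
# two-alternative judgement recoded as "test higher".
psy_prob <- function(delta, mu, sigma, lambda) {
  lambda / 2 + (1 - lambda) * stats::pnorm((delta - mu) / sigma)
}

# Penalized negative log-likelihood. The beta(1.5, 20) penalty on the lapse
# rate regularizes lambda without fixing it, mirroring common practice for
# psychometric lapse priors.
psy_nll <- function(par, delta, n, k, lambda_max) {
  mu <- par[1]; sigma <- exp(par[2]); lambda <- par[3]
  p <- psy_prob(delta, mu, sigma, lambda)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log1p(-p)) -
    stats::dbeta(pmax(lambda, 1e-9), 1.5, 20, log = TRUE)
}

#' Fit a cumulative Gaussian psychometric function
#'
#' Maximum-likelihood fit of
#' \deqn{p(\Delta) = \lambda/2 + (1-\lambda)\,\Phi((\Delta-\mu)/\sigma)}
#' to binomial response counts, with a beta(1.5, 20) penalty on the lapse
#' rate \eqn{\lambda} (bounded to `[0, lambda_max]`) and box bounds on
#' \eqn{\sigma}. \eqn{\mu} is the point of subjective equality (PSE) and
#' \eqn{1/\sigma} the contrast sensitivity. Optimization is deterministic:
#' multi-start `nlminb` from a fixed grid of starting values derived from
#' the data range.
#'
#' Degenerate data are reported rather than hidden: responses carrying no
#' slope information drive \eqn{\sigma} to its upper bound, perfectly
#' separated responses drive it to the lower bound; both raise a warning and
#' set the `degenerate` flag.
#'
#' @param counts Tibble from [aggregate_proportions()] (`delta`, `n`, `k`).
#' @param lambda_max Upper bound of the lapse rate (default 0.1).
#' @param sigma_bounds Lower/upper bounds of sigma in % contrast
#'   (default `c(0.1, 100)`).
#' @return An object of class `psychometric_fit` with elements `mu`, `sigma`,
#'   `sensitivity` (= 1/sigma), `lambda`, `deviance`, `n_total`, `loglik`,
#'   `degenerate`.
#' @examples
#' d <- decisions_long(simulate_session(observer_params(sigma_s = 5), seed = 2))
#' fit_cumulative_gaussian(aggregate_proportions(d))
#' @export
fit_cumulative_gaussian <- function(counts, lambda_max = 0.1,
                                    sigma_bounds = c(0.1, 100)) {
  counts <- counts[counts$n > 0, , drop = FALSE]
  if (nrow(counts) < 3) {
    stop("need at least 3 levels with observations to fit (got ",
         nrow(counts), ")")
  }
  delta <- counts$delta; n <- counts$n; k <- counts$k
  stopifnot(all(k >= 0), all(k <= n), !anyDuplicated(delta))

  span <- max(diff(range(delta)), 1)
  mu_starts <- stats::quantile(range(delta), c(0.25, 0.5, 0.75), names = FALSE)
  sigma_starts <- span * c(0.1, 0.3, 0.8)
  lambda_starts <- c(0.01, 0.05)
  starts <- expand.grid(mu = mu_starts, ls = log(sigma_starts),
                        lam = lambda_starts)

  lower <- c(min(delta) - 2 * span, log(sigma_bounds[1]), 1e-6)
  upper <- c(max(delta) + 2 * span, log(sigma_bounds[2]), lambda_max)

  # screen the start grid by objective value, optimize from the best few
  obj0 <- apply(starts, 1, psy_nll, delta = delta, n = n, k = k,
                lambda_max = lambda_max)
  top <- order(obj0)[seq_len(min(4, nrow(starts)))]
  best <- NULL
  for (i in top) {
    res <- tryCatch(
      stats::nlminb(as.numeric(starts[i, ]), psy_nll,
                    delta = delta, n = n, k = k, lambda_max = lambda_max,
                    lower = lower, upper = upper,
                    control = list(iter.max = 300)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective)) {
      best <- res
    }
  }
  if (is.null(best)) stop("psychometric fit failed from every start")

  mu <- best$par[1]; sigma <- exp(best$par[2]); lambda <- best$par[3]
  degenerate <- FALSE
  if (sigma >= sigma_bounds[2] * 0.999) {
    degenerate <- TRUE
    warning("sigma at upper bound: responses carry no usable slope information")
  } else if (sigma <= sigma_bounds[1] * 1.001) {
    degenerate <- TRUE
    warning("sigma at lower bound: responses are (near-)perfectly separated")
  }

  p_hat <- psy_prob(delta, mu, sigma, lambda)
  ll <- sum(k * log(pmax(p_hat, 1e-12)) + (n - k) * log(pmax(1 - p_hat, 1e-12)))
  fit <- structure(
    list(mu = mu, sigma = sigma, sensitivity = 1 / sigma, lambda = lambda,
         deviance = NA_real_, n_total = sum(n), loglik = ll,
         degenerate = degenerate, counts = counts),
    class = "psychometric_fit")
  fit$deviance <- psychometric_deviance(fit, counts)
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Cumulative Gaussian fit: PSE = %.3f, sigma = %.3f (sensitivity %.4f), lambda = %.4f\n",
    x$mu, x$sigma, x$sensitivity, x$lambda))
  cat(sprintf("deviance D = %.3f on %d decisions%s\n", x$deviance, x$n_total,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
as.data.frame.psychometric_fit <- function(x, ...) {
  data.frame(mu = x$mu, sigma = x$sigma, sensitivity = x$sensitivity,
             lambda = x$lambda, deviance = x$deviance, n_total = x$n_total)
}

#' Deviance goodness of fit of a psychometric function
#'
#' Twice the log-likelihood ratio of the saturated binomial model against the
#' fitted model:
#' \deqn{D = 2\sum_j \left[k_j \ln\frac{k_j}{n_j \hat p_j} +
#'   (n_j-k_j) \ln\frac{n_j-k_j}{n_j(1-\hat p_j)}\right]}
#' with the convention \eqn{0\ln 0 = 0}. If a fitted probability is exactly
#' 0 or 1 while the observed count disagrees, the fit is degenerate and
#' `Inf` is returned.
#'
#' @param fit A `psychometric_fit` (or any list with `mu`, `sigma`, `lambda`).
#' @param counts The level counts the fit was produced from.
#' @return Non-negative deviance (possibly `Inf`).
#' @export
psychometric_deviance <- function(fit, counts) {
  p_hat <- psy_prob(counts$delta, fit$mu, fit$sigma, fit$lambda)
  deviance_from_probs(counts$n, counts$k, p_hat)
}

deviance_from_probs <- function(n, k, p_hat) {
  stopifnot(length(n) == length(k), length(n) == length(p_hat))
  if (any((p_hat == 0 & k > 0) | (p_hat == 1 & k < n))) return(Inf)
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(x / y))
  2 * sum(xlogy(k, n * p_hat) + xlogy(n - k, n * (1 - p_hat)))
}
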