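#' Generative signal-detection confidence observer
#'
#' Parameters of the generative model used to simulate sessions. On each
#' perceptual decision the observer draws internal evidence
#' \eqn{e \sim N((\Delta - bias)/\sigma_s, 1)} and reports "test higher" iff
#' \eqn{e > 0} (with probability `lapse` the report is replaced by a fair
#' coin). Confidence evidence is the distance from criterion corrupted by
#' confidence noise, \eqn{c = |e| + N(0, \sigma_c)}; the decision with the
#' larger confidence evidence is selected in the confidence task.
#' \eqn{\sigma_c = 0} is the ideal confidence observer; as
#' \eqn{\sigma_c \to \infty} confidence decouples from the evidence.
#' Response times follow the exponential RT model
#' \eqn{RT = \alpha - \beta e^{-S^2/2} - \gamma C} with
#' \eqn{S = (\Delta - bias)/\sigma_s}, C the realized confidence code,
#' plus Gaussian noise truncated below at 100 ms. A negative `rt_beta`
#' (the default) makes responses slow down towards the point of subjective
#' equality, i.e. with increasing difficulty; positive `rt_gamma` speeds up
#' decisions selected as confident.
#'
#' @param sigma_s Sensory noise in % contrast (> 0).
#' @param bias PSE offset in % contrast.
#' @param sigma_c Confidence noise in evidence units (>= 0).
#' @param lapse Probability of a random perceptual response, in `[0, 0.1]`.
#' @param rt_alpha,rt_beta,rt_gamma RT model parameters in ms.
#' @param rt_noise_sd SD of additive RT noise in ms.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(sigma_s, bias = 0, sigma_c = 0, lapse = 0,
                            rt_alpha = 500, rt_beta = -100, rt_gamma = 50,
                            rt_noise_sd = 0) {
  stopifnot(sigma_s > 0, sigma_c >= 0, lapse >= 0, lapse <= 0.1,
            rt_noise_sd >= 0)
  p <- structure(as.list(environment()), class = "observer_params")
  # worst case over the design range: exp(-S^2/2) in [0, 1], C in {0, 1}
  rt_min <- p$rt_alpha - max(p$rt_beta, 0) - max(p$rt_gamma, 0)
  if (rt_min <= 0) {
    stop("RT parameters give non-positive RTs (minimum ", rt_min, " ms)")
  }
  p
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "SDT observer: sigma_s = %.2f, bias = %.2f, sigma_c = %.2f, lapse = %.3f\n",
    x$sigma_s, x$bias, x$sigma_c, x$lapse))
  cat(sprintf("RT: alpha = %.0f, beta = %.0f, gamma = %.0f, noise SD = %.0f ms\n",
              x$rt_alpha, x$rt_beta, x$rt_gamma, x$rt_noise_sd))
  invisible(x)
}

#' Simulate one confidence forced-choice session
#'
#' Generates a randomized design via [generate_design()] and fills in the
#' observer's perceptual decisions, confidence choice and response times
#' according to the generative model described in [observer_params()].
#' Confidence ties are broken by a fair coin.
#'
#' @param params An [observer_params()].
#' @param spec A [design_spec()].
#' @param seed Integer seed; the session is reproducible given the seed.
#' @param participant_id Identifier copied into every row.
#' @return A complete session tibble.
#' @examples
#' s <- simulate_session(observer_params(sigma_s = 5, sigma_c = 0.5), seed = 1)
#' mean(s$conf_choice == 1)
#' @export
simulate_session <- function(params, spec = design_spec(), seed = 1L,
                             participant_id = "sim") {
  stopifnot(inherits(params, "observer_params"))
  seeds <- derive_seeds(seed, 2)
  trials <- generate_design(spec, seed = seeds[1],
                            participant_id = participant_id)
  n <- nrow(trials)
  with_rng_seed(seeds[2], {
    sim_task <- function(delta) {
      mu <- (delta - params$bias) / params$sigma_s
      e <- stats::rnorm(n, mean = mu, sd = 1)
      report_higher <- e > 0
      if (params$lapse > 0) {
        lapsed <- stats::runif(n) < params$lapse
        report_higher[lapsed] <- stats::runif(sum(lapsed)) < 0.5
      }
      conf_ev <- abs(e) + stats::rnorm(n, 0, params$sigma_c)
      list(decision = ifelse(report_higher, "higher", "lower"),
           conf_ev = conf_ev, s = mu)
    }
    t1 <- sim_task(trials$task1_delta)
    t2 <- sim_task(trials$task2_delta)
    conf_choice <- ifelse(t1$conf_ev > t2$conf_ev, 1L,
                          ifelse(t1$conf_ev < t2$conf_ev, 2L,
                                 sample(1:2, n, replace = TRUE)))
    rt_of <- function(s, chosen) {
      rt <- params$rt_alpha - params$rt_beta * exp(-s^2 / 2) -
        params$rt_gamma * as.numeric(chosen) +
        stats::rnorm(n, 0, params$rt_noise_sd)
      pmax(rt, 100)
    }
    trials$decision1 <- t1$decision
    trials$decision2 <- t2$decision
    trials$conf_choice <- conf_choice
    trials$rt1_ms <- rt_of(t1$s, conf_choice == 1L)
    trials$rt2_ms <- rt_of(t2$s, conf_choice == 2L)
  })
  trials
}

# P(evidence in half-plane s) for one task: s is +1 ("higher") or -1.
half_prob <- function(mu, s) if (s > 0) stats::pnorm(mu) else stats::pnorm(-mu)

# Integral over e1 in half s1, e2 in half s2 of
#   phi(e1 - mu1) phi(e2 - mu2) P(|e1| + n1 > |e2| + n2)
# with n_i ~ N(0, sigma_c) independent. For sigma_c = 0 the inner integral
# over e2 is a normal-CDF difference and a single 1D quadrature remains;
# for sigma_c > 0 the integrand is smooth on the half-plane and 2D adaptive
# quadrature is used.
half_plane_integral <- function(mu1, mu2, s1, s2, sigma_c, tol = 1e-6) {
  U <- 8 + max(abs(mu1), abs(mu2))
  lim1 <- if (s1 > 0) c(0, U) else c(-U, 0)
  lim2 <- if (s2 > 0) c(0, U) else c(-U, 0)
  if (sigma_c == 0) {
    inner <- function(a) { # P(e2 in half s2, |e2| < a), a >= 0
      if (s2 > 0) stats::pnorm(a - mu2) - stats::pnorm(-mu2)
      else stats::pnorm(-mu2) - stats::pnorm(-a - mu2)
    }
    f <- function(e1) stats::dnorm(e1 - mu1) * inner(abs(e1))
    stats::integrate(f, lim1[1], lim1[2], rel.tol = tol,
                     abs.tol = tol)$value
  } else {
    sd_d <- sqrt(2) * sigma_c
    f <- function(e1, e2) {
      stats::dnorm(e1 - mu1) * stats::dnorm(e2 - mu2) *
        stats::pnorm((abs(e1) - abs(e2)) / sd_d)
    }
    pracma::integral2(f, lim1[1], lim1[2], lim2[1], lim2[2],
                      reltol = tol)$Q
  }
}

#' Expected confidence-choice probability map of an observer
#'
#' Computes, by numeric integration over the bivariate evidence distribution
#' (no sampling), the probability that the observer selects the first
#' perceptual decision as more confident, for every pair of first/second-task
#' contrast differences — optionally conditional on one of the four
#' decision combinations. This is the idealized-observer counterpart of the
#' empirical [choice_probability_map()].
#'
#' @param params An [observer_params()] (finite `sigma_c`).
#' @param spec A [design_spec()].
#' @param condition `"aggregate"` (default) or one of `"lower-lower"`,
#'   `"lower-higher"`, `"higher-lower"`, `"higher-higher"` (first-decision
#'   label first).
#' @param tol Absolute quadrature tolerance.
#' @return A `confidence_map` tibble: `delta1`, `delta2`, `condition`, `p`,
#'   `n` (`n = NA`, probabilities are exact expectations).
#' @export
expected_choice_map <- function(params, spec = design_spec(),
                                condition = "aggregate", tol = 1e-6) {
  stopifnot(inherits(params, "observer_params"), is.finite(params$sigma_c))
  if (!condition %in% map_conditions) {
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(map_conditions, collapse = ", "))
  }
  deltas <- sort(spec$levels - spec$standard)
  lapse <- params$lapse
  # weight of a sign half-plane given the observed decision label
  wgt <- function(s, lab) {
    if (lab == "any") 1
    else (1 - lapse) * as.numeric((s > 0) == (lab == "higher")) + lapse / 2
  }
  labs <- if (condition == "aggregate") c("any", "any") else
    strsplit(condition, "-", fixed = TRUE)[[1]]
  cell_p <- function(d1, d2) {
    mu1 <- (d1 - params$bias) / params$sigma_s
    mu2 <- (d2 - params$bias) / params$sigma_s
    num <- 0
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
      w <- wgt(s1, labs[1]) * wgt(s2, labs[2])
      if (w > 0) {
        num <- num + w * half_plane_integral(mu1, mu2, s1, s2,
                                             params$sigma_c, tol)
      }
    }
    den <- if (condition == "aggregate") 1 else {
      p1 <- (1 - lapse) * half_prob(mu1, if (labs[1] == "higher") 1 else -1) +
        lapse / 2
      p2 <- (1 - lapse) * half_prob(mu2, if (labs[2] == "higher") 1 else -1) +
        lapse / 2
      p1 * p2
    }
    num / den
  }
  grid <- tidyr::expand_grid(delta1 = deltas, delta2 = deltas)
  grid$condition <- condition
  grid$p <- mapply(cell_p, grid$delta1, grid$delta2)
  grid$n <- NA_integer_
  class(grid) <- c("confidence_map", class(grid))
  grid
}
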