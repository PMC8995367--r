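# Cohort simulation: two age groups with group-specific sensory noise,
# confidence noise, RT parameters, and a cognitive battery whose
# executive-function composite is linked to latent confidence efficiency.

# Cognitive battery marginals (oriented scale: completion times negated so
# that larger = better) per age group: mean and SD for each measure.
default_battery <- function() {
  list(
    older = list(dsst = c(60.2, 11.3), tmtb = c(-77.4, 23.0),
                 vstc = c(-69.1, 42.2), lps3 = c(16.9, 3.4),
                 digit_span = c(4.4, 0.9), age = c(68.8, 4.7),
                 age_range = c(60, 78)),
    younger = list(dsst = c(82.3, 11.8), tmtb = c(-43.5, 13.2),
                   vstc = c(-25.5, 5.4), lps3 = c(22.1, 3.5),
                   digit_span = c(5.0, 1.0), age = c(24.6, 4.4),
                   age_range = c(19, 38))
  )
}

#' Specify a simulated two-group cohort
#'
#' Defines the distributions from which per-participant observer parameters
#' and cognitive scores are drawn. Sensory noise `sigma_s` is normal per
#' group (truncated positive), confidence noise `sigma_c` log-normal per
#' group, RT parameters normal per group. Cognitive battery scores are
#' Gaussian with group-specific means/SDs (defaults emulate a typical
#' older/younger contrast-discrimination cohort); the executive-function
#' composite is coupled to the latent confidence-efficiency trait
#' (standardized `-sigma_c`) by a Gaussian-factor construction with target
#' pooled correlation `ef_link`, while backward digit span is generated
#' independently of efficiency.
#'
#' The default parameter values define the package's reference cohort: group
#' differences in sensory noise (older noisier), confidence noise (older
#' less efficient), generic RT (older slower), and Table-style battery
#' marginals.
#'
#' @param n_older,n_younger Participants per group.
#' @param design A [design_spec()].
#' @param sigma_s Named list per group: `c(mean, sd)` of sensory noise
#'   (% contrast).
#' @param sigma_c Named list per group: `c(meanlog, sdlog)` of the
#'   log-normal confidence noise.
#' @param lapse Lapse probability applied to every observer.
#' @param rt_alpha,rt_beta,rt_gamma Named lists per group: `c(mean, sd)` in
#'   ms. `rt_beta` means are negative: in the minus convention of the RT
#'   model, slowing towards the PSE corresponds to `beta < 0`, which also
#'   places the generic RT `alpha` below the overall median RT as observed
#'   empirically.
#' @param rt_noise_sd Trial-level RT noise SD in ms.
#' @param ef_link Target pooled correlation between confidence efficiency
#'   and the EF composite as recovered by the analysis pipeline
#'   (estimated CMIs against EF scores), in (-1, 1). Because estimated CMIs
#'   carry estimation noise, the latent copula strength applied to the
#'   efficiency trait is `ef_link / ef_attenuation`.
#' @param ef_attenuation Calibrated attenuation factor: the expected
#'   correlation between pipeline-estimated CMIs and the latent efficiency
#'   trait under the default cohort, determined once by a calibration study
#'   at the package's reference parameters. Set to 1 to make `ef_link` act
#'   directly on the latent trait.
#' @param ef_loading Loading of each battery measure on the shared EF factor.
#' @param seed Master seed; the cohort is bitwise reproducible given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_older = 30, n_younger = 30,
                        design = design_spec(),
                        sigma_s = list(older = c(7.0, 1.3),
                                       younger = c(4.6, 0.8)),
                        sigma_c = list(older = c(log(1.0), 0.45),
                                       younger = c(log(0.66), 0.40)),
                        lapse = 0.02,
                        rt_alpha = list(older = c(524, 120),
                                        younger = c(438, 100)),
                        rt_beta = list(older = c(-100, 35),
                                       younger = c(-90, 30)),
                        rt_gamma = list(older = c(50, 22),
                                        younger = c(55, 22)),
                        rt_noise_sd = 150,
                        ef_link = 0.4,
                        ef_attenuation = 0.5,
                        ef_loading = 0.7,
                        seed = 1L) {
  stopifnot(n_older >= 2, n_younger >= 2,
            abs(ef_link) < 1, ef_attenuation > 0, ef_attenuation <= 1,
            ef_loading > 0, ef_loading <= 1)
  spec <- structure(as.list(environment()), class = "cohort_spec")
  # fail early on infeasible correlation structure
  invisible(ef_structure(spec))
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort: %d older + %d younger participants, ef_link = %.2f, seed = %d\n",
              x$n_older, x$n_younger, x$ef_link, as.integer(x$seed)))
  invisible(x)
}

# Moment computation for the EF-link construction. The latent efficiency
# trait is the population-standardized -sigma_c. Battery scores are
#   oriented_score_j = m_{j,g} + s_{j,g} * (loading * f + sqrt(1-loading^2) eta_j)
# with a shared factor f = rho_w * u + sqrt(1-rho_w^2) eps, where u is the
# within-group standardized efficiency. rho_w is solved so that the pooled
# correlation between the efficiency trait and the EF composite (mean of
# pooled z-scores) equals ef_link; infeasible targets error out.
ef_structure <- function(spec) {
  w <- c(older = spec$n_older, younger = spec$n_younger)
  w <- w / sum(w)
  # population moments of -sigma_c (log-normal) per group
  ln_mean <- function(p) exp(p[1] + p[2]^2 / 2)
  ln_var <- function(p) (exp(p[2]^2) - 1) * exp(2 * p[1] + p[2]^2)
  mu_g <- -vapply(spec$sigma_c, ln_mean, numeric(1))
  tau_g <- sqrt(vapply(spec$sigma_c, ln_var, numeric(1)))
  mu_bar <- sum(w * mu_g)
  v_pool <- sum(w * tau_g^2) + sum(w * (mu_g - mu_bar)^2)
  m_g <- (mu_g - mu_bar) / sqrt(v_pool)   # group mean of the trait
  s_g <- tau_g / sqrt(v_pool)             # within-group SD of the trait

  battery <- default_battery()
  measures <- c("dsst", "tmtb", "vstc", "lps3")
  M <- sapply(measures, function(j)
    vapply(battery, function(g) g[[j]][1], numeric(1)))  # groups x measures
  S <- sapply(measures, function(j)
    vapply(battery, function(g) g[[j]][2], numeric(1)))
  P <- colSums(w * M)
  Q <- sqrt(colSums(w * S^2) + colSums(w * (M - rep(P, each = 2))^2))
  a <- (M - rep(P, each = 2)) / rep(Q, each = 2)  # pooled-z offsets
  b <- S / rep(Q, each = 2)                       # pooled-z scalings
  A_g <- rowMeans(a)
  bbar_g <- rowMeans(b)
  b2_g <- rowSums(b^2)
  lam <- spec$ef_loading
  A_bar <- sum(w * A_g)
  var_c <- sum(w * (A_g - A_bar)^2) +
    sum(w * (lam^2 * bbar_g^2 + (1 - lam^2) * b2_g / 16))
  cov_between <- sum(w * A_g * m_g)
  k1 <- lam * sum(w * bbar_g * s_g)
  latent_link <- spec$ef_link / (spec$ef_attenuation %||% 1)
  if (abs(latent_link) >= 1) {
    stop(sprintf(
      "infeasible EF correlation structure: ef_link = %.2f implies latent link %.2f",
      spec$ef_link, latent_link))
  }
  rho_w <- (latent_link * sqrt(var_c) - cov_between) / k1
  if (!is.finite(rho_w) || abs(rho_w) >= 1) {
    stop(sprintf(
      "infeasible EF correlation structure: ef_link = %.2f requires within-group factor correlation %.3f",
      spec$ef_link, rho_w))
  }
  list(mu_bar = mu_bar, v_pool = v_pool, mu_g = mu_g, tau_g = tau_g,
       rho_w = rho_w, battery = battery)
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a full two-group cohort
#'
#' Draws per-participant observer parameters from the group distributions in
#' a [cohort_spec()], simulates one complete session per participant, and
#' generates the cognitive battery with the specified EF-efficiency link.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort` with elements
#'   `participants` (tibble in the participants-file format),
#'   `sessions` (tibble binding all session tables),
#'   `true_params` (tibble of generative per-participant parameters).
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_spec(n_older = 4, n_younger = 4, seed = 7))
#' coh$participants
#' }
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ef <- ef_structure(spec)
  n <- spec$n_older + spec$n_younger
  group <- rep(c("older", "younger"), c(spec$n_older, spec$n_younger))
  ids <- sprintf("%s%02d", ifelse(group == "older", "O", "Y"),
                 c(seq_len(spec$n_older), seq_len(spec$n_younger)))
  seeds <- derive_seeds(spec$seed, n + 1)

  draws <- with_rng_seed(seeds[n + 1], {
    par2 <- function(p) cbind(mean = vapply(p, `[`, numeric(1), 1),
                              sd = vapply(p, `[`, numeric(1), 2))
    pick <- function(tab, g, what) tab[g, what]
    sigma_s <- vapply(group, function(g)
      rnorm_trunc(1, pick(par2(spec$sigma_s), g, "mean"),
                  pick(par2(spec$sigma_s), g, "sd"), 0.5), numeric(1))
    sigma_c <- vapply(group, function(g)
      stats::rlnorm(1, spec$sigma_c[[g]][1], spec$sigma_c[[g]][2]), numeric(1))
    rt_a <- vapply(group, function(g)
      rnorm_trunc(1, spec$rt_alpha[[g]][1], spec$rt_alpha[[g]][2], 250),
      numeric(1))
    # beta is negative (responses slow down towards the PSE); keep its sign
    rt_b <- vapply(group, function(g)
      -rnorm_trunc(1, -spec$rt_beta[[g]][1], spec$rt_beta[[g]][2], 10),
      numeric(1))
    rt_g <- vapply(group, function(g)
      rnorm_trunc(1, spec$rt_gamma[[g]][1], spec$rt_gamma[[g]][2], 5),
      numeric(1))

    # cognitive battery linked to latent efficiency
    u <- (-sigma_c - ef$mu_g[group]) / ef$tau_g[group]
    f <- ef$rho_w * u + sqrt(1 - ef$rho_w^2) * stats::rnorm(n)
    lam <- spec$ef_loading
    score <- function(measure) {
      eta <- stats::rnorm(n)
      x <- lam * f + sqrt(1 - lam^2) * eta
      mg <- vapply(ef$battery, function(gp) gp[[measure]][1], numeric(1))
      sg <- vapply(ef$battery, function(gp) gp[[measure]][2], numeric(1))
      mg[group] + sg[group] * x
    }
    dsst <- pmax(score("dsst"), 5)
    tmtb <- pmax(-score("tmtb"), 5)   # back to seconds
    vstc <- pmax(-score("vstc"), 5)
    lps3 <- pmax(score("lps3"), 1)
    dspan <- vapply(group, function(g) {
      gp <- ef$battery[[g]]$digit_span
      max(round(stats::rnorm(1, gp[1], gp[2])), 2)
    }, numeric(1))
    age <- vapply(group, function(g) {
      gp <- ef$battery[[g]]
      min(max(round(stats::rnorm(1, gp$age[1], gp$age[2])), gp$age_range[1]),
          gp$age_range[2])
    }, numeric(1))
    list(sigma_s = sigma_s, sigma_c = sigma_c, rt_a = rt_a, rt_b = rt_b,
         rt_g = rt_g, dsst = dsst, tmtb = tmtb, vstc = vstc, lps3 = lps3,
         dspan = dspan, age = age)
  })

  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    prm <- observer_params(sigma_s = draws$sigma_s[i], bias = 0,
                           sigma_c = draws$sigma_c[i], lapse = spec$lapse,
                           rt_alpha = draws$rt_a[i], rt_beta = draws$rt_b[i],
                           rt_gamma = draws$rt_g[i],
                           rt_noise_sd = spec$rt_noise_sd)
    sessions[[i]] <- simulate_session(prm, spec$design, seed = seeds[i],
                                      participant_id = ids[i])
  }

  participants <- tibble::tibble(
    participant_id = ids, age_group = group, age = draws$age,
    dsst = draws$dsst, tmt_b_s = draws$tmtb, vst_c_s = draws$vstc,
    lps3 = draws$lps3, digit_span = draws$dspan)
  true_params <- tibble::tibble(
    participant_id = ids, age_group = group,
    sigma_s = draws$sigma_s, sigma_c = draws$sigma_c,
    efficiency = (-draws$sigma_c - ef$mu_bar) / sqrt(ef$v_pool),
    rt_alpha = draws$rt_a, rt_beta = draws$rt_b, rt_gamma = draws$rt_g)
  structure(list(participants = participants,
                 sessions = dplyr::bind_rows(sessions),
                 true_params = true_params,
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d participants, %d trials total\n",
              nrow(x$participants), nrow(x$sessions)))
  invisible(x)
}
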