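#' Executive-function composite score
#'
#' Combines the four executive-function measures into one score per
#' participant. All measures are first oriented so that higher = better
#' cognitive control: DSST and LPS-3 enter as-is, the two completion times
#' (TMT-B, VST-C) are negated. Each oriented measure is z-scored over the
#' pooled sample and the EF score is the mean of the four z-scores.
#' Participants missing any measure are dropped with a warning.
#'
#' @param participants Tibble with `participant_id`, `dsst`, `tmt_b_s`,
#'   `vst_c_s`, `lps3`.
#' @return Tibble: `participant_id`, `z_dsst`, `z_tmtb`, `z_vstc`,
#'   `z_lps3`, `ef`.
#' @export
ef_composite <- function(participants) {
  need <- c("dsst", "tmt_b_s", "vst_c_s", "lps3")
  stopifnot(all(c("participant_id", need) %in% names(participants)))
  complete <- stats::complete.cases(participants[need])
  if (any(!complete)) {
    warning("excluding ", sum(!complete),
            " participant(s) with missing EF measures: ",
            paste(participants$participant_id[!complete], collapse = ", "))
    participants <- participants[complete, , drop = FALSE]
  }
  z <- function(x) as.numeric(scale(x))
  tibble::tibble(
    participant_id = participants$participant_id,
    z_dsst = z(participants$dsst),
    z_tmtb = z(-participants$tmt_b_s),
    z_vstc = z(-participants$vst_c_s),
    z_lps3 = z(participants$lps3)
  ) |>
    dplyr::mutate(ef = (.data$z_dsst + .data$z_tmtb + .data$z_vstc +
                          .data$z_lps3) / 4)
}

#' Mixed-design ANOVA (one between, one within factor)
#'
#' Classical univariate sums-of-squares decomposition for a design with one
#' between-subjects factor (e.g. age group) and one within-subjects factor
#' (e.g. confidence set), one observation per participant and within-level.
#' With two within levels the sphericity assumption is vacuous. Reports F,
#' degrees of freedom, two-sided p and partial eta squared
#' (\eqn{\eta_p^2 = SS_{effect}/(SS_{effect}+SS_{error})}) for the between
#' main effect, the within main effect and their interaction.
#'
#' If the between factor has a single level the design degenerates to a
#' one-way repeated-measures ANOVA and only the within effect is reported;
#' with two within levels its F then equals the squared paired t statistic.
#'
#' @param data Long-format tibble.
#' @param value,participant,within,between Column names (strings).
#' @return Tibble: `effect`, `df1`, `df2`, `F`, `p`, `pes`.
#' @export
mixed_anova <- function(data, value, participant, within, between) {
  y <- data[[value]]
  subj <- factor(data[[participant]])
  w <- factor(data[[within]])
  g <- factor(data[[between]])
  tab <- table(subj, w)
  if (any(tab != 1)) stop("incomplete within-subject cells: every participant needs exactly one value per within level")
  grand <- mean(y)
  n_w <- nlevels(w)
  subj_means <- tapply(y, subj, mean)
  subj_group <- tapply(as.character(g), subj, `[`, 1)
  group_means <- tapply(y, g, mean)
  n_subj_g <- table(factor(subj_group, levels = levels(g)))

  ss_subj <- n_w * sum((subj_means - grand)^2)
  ss_group <- n_w * sum(as.numeric(n_subj_g) * (group_means - grand)^2)
  ss_subj_err <- ss_subj - ss_group
  cell_means <- tapply(y, list(g, w), mean)
  w_means <- tapply(y, w, mean)
  ss_within_factor <- length(levels(subj)) * sum((w_means - grand)^2)
  ss_cells <- sum(t(as.numeric(n_subj_g) * (cell_means - grand)^2))
  ss_inter <- ss_cells - ss_group - ss_within_factor
  ss_total <- sum((y - grand)^2)
  ss_w_err <- ss_total - ss_subj - ss_within_factor - ss_inter

  n_s <- length(levels(subj)); n_g <- nlevels(g)
  if (n_g == 1) {
    ss_w_err_1 <- ss_total - ss_subj - ss_within_factor
    df1 <- n_w - 1; df2 <- (n_s - 1) * (n_w - 1)
    f <- (ss_within_factor / df1) / (ss_w_err_1 / df2)
    return(tibble::tibble(
      effect = "within", df1 = df1, df2 = df2, F = f,
      p = stats::pf(f, df1, df2, lower.tail = FALSE),
      pes = ss_within_factor / (ss_within_factor + ss_w_err_1)))
  }
  df <- list(group = c(n_g - 1, n_s - n_g),
             within = c(n_w - 1, (n_s - n_g) * (n_w - 1)),
             interaction = c((n_g - 1) * (n_w - 1), (n_s - n_g) * (n_w - 1)))
  ss_eff <- c(group = ss_group, within = ss_within_factor,
              interaction = ss_inter)
  ss_err <- c(group = ss_subj_err, within = ss_w_err, interaction = ss_w_err)
  if (any(ss_err <= .Machine$double.eps * max(1, ss_total))) {
    warning("degenerate (zero) error variance; F statistics undefined")
  }
  out <- lapply(names(ss_eff), function(e) {
    ms_eff <- ss_eff[[e]] / df[[e]][1]
    ms_err <- ss_err[[e]] / df[[e]][2]
    f <- ms_eff / ms_err
    tibble::tibble(effect = e, df1 = df[[e]][1], df2 = df[[e]][2], F = f,
                   p = stats::pf(f, df[[e]][1], df[[e]][2], lower.tail = FALSE),
                   pes = ss_eff[[e]] / (ss_eff[[e]] + ss_err[[e]]))
  })
  dplyr::bind_rows(out)
}

percentile_ci <- function(stat_fun, resample_fun, n_boot, seed, conf = 0.95) {
  if (n_boot <= 0) return(c(NA_real_, NA_real_))
  with_rng_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) stat_fun(resample_fun()),
                    numeric(1))
    stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE, na.rm = TRUE)
  })
}

#' Two-sample comparison with Levene-gated degrees of freedom
#'
#' Compares two samples with a t-test. For independent samples, Levene's
#' test (mean-centred, alpha = 0.05) decides between the Student test
#' (equal variances) and the Welch test with adjusted fractional degrees of
#' freedom. Cohen's d uses the pooled SD for independent samples and the SD
#' of the differences for paired samples. A 95% percentile bootstrap CI of
#' the mean difference is computed from `n_boot` resamples (resampling each
#' sample independently — participants are the resampling unit — or pairs
#' for paired comparisons).
#'
#' @param a,b Numeric samples (equal length if `paired`).
#' @param paired Paired comparison?
#' @param n_boot Bootstrap resamples (default 2000; 0 skips the CI).
#' @param seed Seed for the bootstrap.
#' @return Tibble with `statistic`, `df`, `p`, `effect_size` (Cohen's d),
#'   `ci_low`, `ci_high`, `method`.
#' @export
t_compare <- function(a, b, paired = FALSE, n_boot = 2000, seed = 1L) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired) stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("zero variance in both samples")
  }
  if (paired) {
    d_i <- a - b
    if (stats::sd(d_i) == 0) {
      if (mean(d_i) != 0) stop("zero variance in the paired differences")
      # identical samples: no effect by definition
      return(tibble::tibble(statistic = 0, df = length(d_i) - 1, p = 1,
                            effect_size = 0, ci_low = 0, ci_high = 0,
                            method = "paired t"))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    d <- mean(d_i) / stats::sd(d_i)
    method <- "paired t"
    ci <- percentile_ci(
      mean, function() sample(d_i, replace = TRUE), n_boot, seed)
  } else {
    lev <- car::leveneTest(
      c(a, b), factor(rep(c("a", "b"), c(length(a), length(b)))),
      center = mean)
    equal_var <- lev[["Pr(>F)"]][1] >= 0.05
    tt <- stats::t.test(a, b, var.equal = equal_var)
    sd_pool <- sqrt(((length(a) - 1) * stats::var(a) +
                       (length(b) - 1) * stats::var(b)) /
                      (length(a) + length(b) - 2))
    d <- (mean(a) - mean(b)) / sd_pool
    method <- if (equal_var) "Student t" else "Welch t"
    ci <- percentile_ci(
      function(s) mean(s$a) - mean(s$b),
      function() list(a = sample(a, replace = TRUE),
                      b = sample(b, replace = TRUE)),
      n_boot, seed)
  }
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, effect_size = d,
                 ci_low = ci[1], ci_high = ci[2], method = method)
}

#' One-sample t-test with effect size
#'
#' Standard one-sample t-test against `null_value`;
#' Cohen's d = (mean - null) / SD.
#'
#' @param values Numeric sample (n >= 2, non-zero variance).
#' @param null_value Null hypothesis mean (default 0).
#' @return Tibble with `statistic`, `df`, `p`, `effect_size`.
#' @export
one_sample_t <- function(values, null_value = 0) {
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0) stop("zero variance")
  tt <- stats::t.test(values, mu = null_value)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 effect_size = (mean(values) - null_value) / stats::sd(values))
}

#' Pearson and first-order partial correlation with bootstrap CI
#'
#' Pearson correlation between `x` and `y` with a two-sided p-value. When a
#' `control` covariate is supplied, the first-order partial correlation
#' \deqn{r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}}
#' is reported with df = n - 3. The 95% percentile bootstrap CI resamples
#' complete observation tuples.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param control Optional covariate (e.g. a binary group indicator).
#' @param n_boot Bootstrap resamples (default 2000; 0 skips the CI).
#' @param seed Seed for the bootstrap.
#' @return Tibble with `estimate` (r), `statistic` (t), `df`, `p`,
#'   `ci_low`, `ci_high`, `method`.
#' @export
correlation <- function(x, y, control = NULL, n_boot = 2000, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ctl <- control
  if (!is.null(ctl)) {
    stopifnot(length(ctl) == length(x))
    ctl <- as.numeric(factor(ctl))
    if (stats::sd(ctl) == 0) stop("constant control covariate")
  }
  partial_r <- function(x, y, z) {
    rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  n <- length(x)
  if (is.null(ctl)) {
    r <- stats::cor(x, y)
    df <- n - 2
    method <- "Pearson"
    stat_fun <- function(idx) stats::cor(x[idx], y[idx])
  } else {
    r <- partial_r(x, y, ctl)
    df <- n - 3
    method <- "partial Pearson"
    stat_fun <- function(idx) partial_r(x[idx], y[idx], ctl[idx])
  }
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  ci <- percentile_ci(stat_fun,
                      function() sample.int(n, replace = TRUE),
                      n_boot, seed)
  tibble::tibble(estimate = r, statistic = t_stat, df = df, p = p,
                 ci_low = ci[1], ci_high = ci[2], method = method)
}
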