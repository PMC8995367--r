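#' Analyse a single participant's session
#'
#' Runs the per-participant pipeline: RT filtering, confidence-set split,
#' psychometric fits of both sets, deviance checks, CMI and its transform,
#' RT cells and the exponential RT model fit.
#'
#' @param trials One participant's session tibble.
#' @param rt_low_ms,rt_high_ms RT filter bounds (ms).
#' @return A list: `fit_chosen`, `fit_unsorted` (psychometric fits),
#'   `cmi`, `cmi_transformed`, `rt_fit`, `rt_cells`, `exclusion_rate`,
#'   `median_rt_chosen`, `median_rt_unsorted`.
#' @export
analyse_participant <- function(trials, rt_low_ms = 100, rt_high_ms = 3000) {
  sets <- split_sets(trials)
  fit_chosen <- fit_cumulative_gaussian(aggregate_proportions(sets$chosen))
  fit_unsorted <- fit_cumulative_gaussian(aggregate_proportions(sets$unsorted))
  cmi_val <- cmi(fit_chosen$sensitivity, fit_unsorted$sensitivity)

  filt_chosen <- filter_rts(sets$chosen, rt_low_ms, rt_high_ms)
  filt_unsorted <- filter_rts(sets$unsorted, rt_low_ms, rt_high_ms)
  rt_sets <- list(chosen = filt_chosen$kept, unsorted = filt_unsorted$kept)
  cells <- cell_medians(rt_sets, fit_unsorted)
  rt_fit <- tryCatch(fit_rt_model(cells), error = function(e) NULL)

  list(fit_chosen = fit_chosen, fit_unsorted = fit_unsorted,
       cmi = cmi_val, cmi_transformed = transform_cmi(cmi_val),
       rt_fit = rt_fit, rt_cells = cells,
       exclusion_rate = filt_unsorted$exclusion$rate[1],
       median_rt_chosen = stats::median(filt_chosen$kept$rt_ms),
       median_rt_unsorted = stats::median(filt_unsorted$kept$rt_ms))
}

#' Run the full study analysis
#'
#' End-to-end orchestration on a cohort (simulated via [simulate_cohort()]
#' or assembled from session/participant tables): per-participant RT
#' filtering, confidence-set split, psychometric fits, CMI with outlier
#' exclusion by Tukey fences over the pooled sample, exponential RT model
#' fits, EF composite, and the group statistics (mixed ANOVAs on sensitivity
#' and median RT, one-sample and between-group CMI t-tests on raw and
#' transformed scales, PSE set comparisons, EF / digit-span group contrasts,
#' and CMI correlations with EF and digit span, plain and age-controlled).
#' Outlier participants are dropped from group statistics but retained,
#' flagged, in the per-participant table.
#'
#' @param cohort A `cohort` (list with `participants` and `sessions`).
#' @param n_boot Bootstrap resamples for CIs (default 2000).
#' @param seed Seed for all bootstrap resampling.
#' @param rt_low_ms,rt_high_ms RT filter bounds (ms).
#' @return An object of class `study_report`: `confidence_results`,
#'   `rt_fits`, `group_stats`, `maps`, `exclusions`, `provenance`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_spec(n_older = 6, n_younger = 6, seed = 11))
#' rep <- run_study(coh, n_boot = 200, seed = 1)
#' rep$group_stats
#' }
#' @export
run_study <- function(cohort, n_boot = 2000, seed = 1L,
                      rt_low_ms = 100, rt_high_ms = 3000) {
  participants <- cohort$participants
  sessions <- cohort$sessions
  ids <- participants$participant_id
  stopifnot(all(sessions$participant_id %in% ids))

  per <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    trials <- sessions[sessions$participant_id == ids[i], , drop = FALSE]
    per[[i]] <- tryCatch(
      analyse_participant(trials, rt_low_ms, rt_high_ms),
      error = function(e) stop("participant ", ids[i],
                               ", per-participant analysis: ",
                               conditionMessage(e)))
  }

  conf <- tibble::tibble(
    participant_id = ids,
    age_group = participants$age_group,
    pse_chosen = vapply(per, function(p) p$fit_chosen$mu, numeric(1)),
    pse_unsorted = vapply(per, function(p) p$fit_unsorted$mu, numeric(1)),
    sensitivity_chosen = vapply(per, function(p) p$fit_chosen$sensitivity, numeric(1)),
    sensitivity_unsorted = vapply(per, function(p) p$fit_unsorted$sensitivity, numeric(1)),
    deviance_chosen = vapply(per, function(p) p$fit_chosen$deviance, numeric(1)),
    deviance_unsorted = vapply(per, function(p) p$fit_unsorted$deviance, numeric(1)),
    cmi = vapply(per, function(p) p$cmi, numeric(1)),
    cmi_transformed = vapply(per, function(p) p$cmi_transformed, numeric(1)),
    exclusion_rate = vapply(per, function(p) p$exclusion_rate, numeric(1)),
    median_rt_chosen = vapply(per, function(p) p$median_rt_chosen, numeric(1)),
    median_rt_unsorted = vapply(per, function(p) p$median_rt_unsorted, numeric(1))
  )
  conf$outlier <- flag_outliers(conf$cmi)

  rt_fits <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    f <- per[[i]]$rt_fit
    tibble::tibble(participant_id = ids[i],
                   age_group = participants$age_group[i],
                   alpha = if (is.null(f)) NA_real_ else f$alpha,
                   beta = if (is.null(f)) NA_real_ else f$beta,
                   gamma = if (is.null(f)) NA_real_ else f$gamma,
                   rss = if (is.null(f)) NA_real_ else f$rss,
                   n_cells = if (is.null(f)) NA_integer_ else f$n_cells)
  }))

  ef <- ef_composite(participants)
  keep <- !conf$outlier
  kept <- conf[keep, , drop = FALSE]
  kept_rt <- rt_fits[keep, , drop = FALSE]
  kept_ef <- ef[match(kept$participant_id, ef$participant_id), , drop = FALSE]
  kept_part <- participants[keep, , drop = FALSE]
  older <- kept$age_group == "older"
  seeds <- derive_seeds(seed, 24)

  long_sens <- tidyr::pivot_longer(
    kept[, c("participant_id", "age_group", "sensitivity_chosen",
             "sensitivity_unsorted")],
    cols = dplyr::starts_with("sensitivity"),
    names_to = "set", names_prefix = "sensitivity_", values_to = "value")
  long_rt <- tidyr::pivot_longer(
    kept[, c("participant_id", "age_group", "median_rt_chosen",
             "median_rt_unsorted")],
    cols = dplyr::starts_with("median_rt"),
    names_to = "set", names_prefix = "median_rt_", values_to = "value")

  an_sens <- mixed_anova(long_sens, "value", "participant_id", "set", "age_group")
  an_rt <- mixed_anova(long_rt, "value", "participant_id", "set", "age_group")

  row_of <- function(name, x, extra = list()) {
    tibble::tibble(test = name,
                   estimate = extra$estimate %||% NA_real_,
                   statistic = x$statistic %||% NA_real_,
                   df = x$df %||% NA_real_, p = x$p %||% NA_real_,
                   effect_size = x$effect_size %||% NA_real_,
                   ci_low = x$ci_low %||% NA_real_,
                   ci_high = x$ci_high %||% NA_real_)
  }
  anova_rows <- function(an, label) {
    tibble::tibble(test = paste0(label, ": ", an$effect),
                   estimate = NA_real_, statistic = an$F, df = an$df2,
                   p = an$p, effect_size = an$pes,
                   ci_low = NA_real_, ci_high = NA_real_)
  }
  cor_row <- function(name, ct) {
    tibble::tibble(test = name, estimate = ct$estimate,
                   statistic = ct$statistic, df = ct$df, p = ct$p,
                   effect_size = NA_real_, ci_low = ct$ci_low,
                   ci_high = ct$ci_high)
  }

  stats_tbl <- dplyr::bind_rows(
    anova_rows(an_sens, "sensitivity ANOVA"),
    anova_rows(an_rt, "median RT ANOVA"),
    row_of("CMI vs 0, older", one_sample_t(kept$cmi[older])),
    row_of("CMI vs 0, younger", one_sample_t(kept$cmi[!older])),
    row_of("CMI older vs younger (raw)",
           t_compare(kept$cmi[older], kept$cmi[!older],
                     n_boot = n_boot, seed = seeds[1])),
    row_of("CMI older vs younger (transformed)",
           t_compare(kept$cmi_transformed[older],
                     kept$cmi_transformed[!older],
                     n_boot = n_boot, seed = seeds[2])),
    row_of("PSE chosen vs unsorted, older",
           t_compare(kept$pse_chosen[older], kept$pse_unsorted[older],
                     paired = TRUE, n_boot = n_boot, seed = seeds[3])),
    row_of("PSE chosen vs unsorted, younger",
           t_compare(kept$pse_chosen[!older], kept$pse_unsorted[!older],
                     paired = TRUE, n_boot = n_boot, seed = seeds[4])),
    row_of("EF older vs younger",
           t_compare(kept_ef$ef[older], kept_ef$ef[!older],
                     n_boot = n_boot, seed = seeds[5])),
    row_of("digit span older vs younger",
           t_compare(kept_part$digit_span[older],
                     kept_part$digit_span[!older],
                     n_boot = n_boot, seed = seeds[6])),
    row_of("RT alpha older vs younger",
           t_compare(kept_rt$alpha[older], kept_rt$alpha[!older],
                     n_boot = n_boot, seed = seeds[7])),
    row_of("RT beta older vs younger",
           t_compare(kept_rt$beta[older], kept_rt$beta[!older],
                     n_boot = n_boot, seed = seeds[8])),
    row_of("RT gamma older vs younger",
           t_compare(kept_rt$gamma[older], kept_rt$gamma[!older],
                     n_boot = n_boot, seed = seeds[9])),
    cor_row("CMI ~ EF",
            correlation(kept$cmi, kept_ef$ef, n_boot = n_boot,
                        seed = seeds[10])),
    cor_row("CMI ~ EF | age group",
            correlation(kept$cmi, kept_ef$ef, control = kept$age_group,
                        n_boot = n_boot, seed = seeds[11])),
    cor_row("CMI ~ digit span",
            correlation(kept$cmi, kept_part$digit_span, n_boot = n_boot,
                        seed = seeds[12]))
  )

  maps <- lapply(c(older = "older", younger = "younger"), function(gr) {
    choice_probability_map(
      sessions[sessions$participant_id %in%
                 kept$participant_id[kept$age_group == gr], , drop = FALSE])
  })

  structure(list(
    confidence_results = dplyr::left_join(conf, ef, by = "participant_id"),
    rt_fits = rt_fits,
    group_stats = stats_tbl,
    maps = maps,
    exclusions = conf[conf$outlier, c("participant_id", "cmi")],
    provenance = list(seed = seed, n_boot = n_boot,
                      rt_filter_ms = c(rt_low_ms, rt_high_ms),
                      cohort_spec = cohort$spec %||% NULL,
                      package_version = as.character(utils::packageVersion("metaconf")),
                      timestamp = NULL)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  n <- nrow(x$confidence_results)
  cat("Study report:", n, "participants (",
      nrow(x$exclusions), "outlier(s) excluded from group statistics)\n")
  by_group <- x$confidence_results |>
    dplyr::filter(!.data$outlier) |>
    dplyr::summarise(mean_cmi = mean(.data$cmi),
                     mean_sens_unsorted = mean(.data$sensitivity_unsorted),
                     .by = "age_group")
  print(by_group)
  cat("\nGroup statistics:\n")
  print(x$group_stats, n = Inf)
  invisible(x)
}

#' Export the tabular parts of a study report
#'
#' Writes the per-participant confidence results, RT fits, group statistics
#' and the long-format choice-probability maps as comma-separated text.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(report$confidence_results, "confidence_results.csv")
  w(report$rt_fits, "rt_fits.csv")
  w(report$group_stats, "group_stats.csv")
  w(dplyr::bind_rows(report$maps, .id = "age_group"), "choice_maps.csv")
  invisible(dir)
}
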