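#' Split a session into chosen and unsorted confidence sets
#'
#' In the confidence forced-choice paradigm each trial yields two perceptual
#' decisions and one relative confidence judgement. The *chosen* set contains,
#' per trial, exactly the decision selected as more confident; the *unsorted*
#' set is the ensemble of all perceptual decisions (both per trial). Each
#' decision carries the binary confidence code (1 selected, 0 not).
#'
#' @param trials A session tibble (responses filled in).
#' @return A list with decision tibbles `chosen` and `unsorted`
#'   (`nrow(chosen)` = trials, `nrow(unsorted)` = 2 x trials).
#' @examples
#' s <- simulate_session(observer_params(sigma_s = 5), seed = 3)
#' sets <- split_sets(s)
#' c(nrow(sets$chosen), nrow(sets$unsorted))
#' @export
split_sets <- function(trials) {
  if (any(is.na(trials$conf_choice))) {
    stop("missing conf_choice on trials: ",
         paste(utils::head(trials$trial[is.na(trials$conf_choice)], 10),
               collapse = ", "))
  }
  d <- decisions_long(trials)
  list(chosen = d[d$confidence == 1L, , drop = FALSE], unsorted = d)
}

#' Confidence Modulation Index
#'
#' The CMI quantifies metacognitive efficiency as the percentage sensitivity
#' gain of the chosen confidence set over the unsorted set:
#' \deqn{CMI = 100 \times \frac{S_{chosen} - S_{unsorted}}{S_{unsorted}}}
#' where \eqn{S} is psychometric sensitivity (1/sigma). A confidence signal
#' unrelated to the perceptual evidence yields a CMI near zero; the tighter
#' the link between confidence and accuracy, the larger the CMI.
#'
#' @param sens_chosen,sens_unsorted Sensitivities (1/sigma) of the two sets.
#' @return CMI in percent (may be negative).
#' @examples
#' cmi(2, 1)      # 100
#' cmi(1.3125, 1) # 31.25
#' @export
cmi <- function(sens_chosen, sens_unsorted) {
  if (any(sens_unsorted <= 0)) {
    stop("sens_unsorted must be positive (degenerate psychometric fit upstream)")
  }
  100 * (sens_chosen - sens_unsorted) / sens_unsorted
}

#' Arcsine-square-root transform of CMI values
#'
#' CMIs are proportional measures; before entering parametric statistics they
#' are variance-stabilized by the arcsine-square-root transform. Because
#' empirical CMIs can be marginally negative, the transform is extended as an
#' odd function: \eqn{sign(c)\,\arcsin\sqrt{|c|/100}}. It is strictly
#' monotone, maps 0 to 0 and 100 to \eqn{\pi/2}, and reduces to the plain
#' transform on non-negative values. Magnitudes above 100 are clipped to 100
#' with a warning.
#'
#' @param cmi_value Numeric vector of CMIs in percent.
#' @return Transformed values in radians.
#' @export
transform_cmi <- function(cmi_value) {
  if (any(abs(cmi_value) > 100, na.rm = TRUE)) {
    warning("CMI magnitudes above 100 clipped to 100 before transform")
    cmi_value <- pmin(pmax(cmi_value, -100), 100)
  }
  sign(cmi_value) * asin(sqrt(abs(cmi_value) / 100))
}

#' Flag outliers by Tukey fences
#'
#' A value is an outlier when it deviates more than 1.5 interquartile ranges
#' from the quartiles of the complete sample: below `Q1 - 1.5 IQR` or above
#' `Q3 + 1.5 IQR`. Quartiles use linear interpolation (R type 7). Applied
#' once, to the pooled sample.
#'
#' @param values Numeric vector (length >= 4).
#' @param k Fence multiplier (default 1.5).
#' @return Logical vector of flags.
#' @examples
#' flag_outliers(c(1, 2, 3, 4, 100))
#' @export
flag_outliers <- function(values, k = 1.5) {
  stopifnot(length(values) >= 4)
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Mean confidence by task difficulty and correctness
#'
#' Summarizes confidence judgements (binary chosen codes) by absolute
#' contrast difference and correctness of the perceptual decision, collapsing
#' across the other task's difficulty. Decisions at zero contrast difference
#' have no defined correctness and are reported in a separate
#' `"arbitrary"` class. Percentile bootstrap CIs resample decisions within
#' each cell.
#'
#' @param trials A session tibble, or a decision tibble from
#'   [decisions_long()] (possibly several participants).
#' @param n_boot Bootstrap resamples for the 95% CI (0 to skip).
#' @param seed Seed for the bootstrap.
#' @return Tibble: `abs_delta`, `correct`, `mean_confidence`, `n`,
#'   `ci_low`, `ci_high`.
#' @export
confidence_by_difficulty <- function(trials, n_boot = 1000, seed = 1L) {
  d <- if (all(trial_columns %in% names(trials))) decisions_long(trials) else trials
  stopifnot(all(c("delta", "confidence", "correct") %in% names(d)))
  cells <- d |>
    dplyr::mutate(abs_delta = abs(.data$delta)) |>
    dplyr::summarise(mean_confidence = mean(.data$confidence),
                     n = dplyr::n(),
                     .by = c("abs_delta", "correct")) |>
    dplyr::arrange(.data$abs_delta, .data$correct)
  if (n_boot > 0) {
    seeds <- derive_seeds(seed, nrow(cells))
    ci <- lapply(seq_len(nrow(cells)), function(i) {
      x <- d$confidence[abs(d$delta) == cells$abs_delta[i] &
                          d$correct == cells$correct[i]]
      with_rng_seed(seeds[i], {
        bm <- colMeans(matrix(sample(x, length(x) * n_boot, replace = TRUE),
                              ncol = n_boot))
        stats::quantile(bm, c(0.025, 0.975), names = FALSE)
      })
    })
    cells$ci_low <- vapply(ci, `[`, numeric(1), 1)
    cells$ci_high <- vapply(ci, `[`, numeric(1), 2)
  } else {
    cells$ci_low <- NA_real_
    cells$ci_high <- NA_real_
  }
  cells
}

map_conditions <- c("lower-lower", "lower-higher", "higher-lower",
                    "higher-higher", "aggregate")

#' Empirical confidence-choice probability map
#'
#' For every combination of first- and second-task contrast differences,
#' the fraction of trials in which the first perceptual decision was selected
#' as more confident. `condition` restricts the map to one of the four
#' decision combinations (first-decision label, then second, e.g.
#' `"higher-lower"`) or aggregates over all trials. Grid cells without trials
#' are returned with `n = 0` and `p = NA` (undefined).
#'
#' @param trials A session tibble (one or many participants).
#' @param condition One of `"aggregate"` (default), `"lower-lower"`,
#'   `"lower-higher"`, `"higher-lower"`, `"higher-higher"`.
#' @return A tibble of class `confidence_map`: `delta1`, `delta2`,
#'   `condition`, `p`, `n` over the full delta grid.
#' @export
choice_probability_map <- function(trials, condition = "aggregate") {
  if (!condition %in% map_conditions) {
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(map_conditions, collapse = ", "))
  }
  validate_trials(trials)
  sub <- if (condition == "aggregate") trials else {
    labs <- strsplit(condition, "-", fixed = TRUE)[[1]]
    trials[trials$decision1 == labs[1] & trials$decision2 == labs[2], ,
           drop = FALSE]
  }
  grid <- tidyr::expand_grid(delta1 = sort(unique(trials$task1_delta)),
                             delta2 = sort(unique(trials$task2_delta)))
  counts <- sub |>
    dplyr::summarise(n = dplyr::n(),
                     p = mean(.data$conf_choice == 1L),
                     .by = c("task1_delta", "task2_delta")) |>
    dplyr::rename(delta1 = "task1_delta", delta2 = "task2_delta")
  out <- dplyr::left_join(grid, counts, by = c("delta1", "delta2")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  condition = condition) |>
    dplyr::select("delta1", "delta2", "condition", "p", "n") |>
    dplyr::arrange(.data$delta1, .data$delta2)
  class(out) <- c("confidence_map", class(out))
  out
}
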