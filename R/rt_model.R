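#' Median response times per stimulus-intensity cell
#'
#' Prepares the input of the exponential RT model. Stimulus values are first
#' normalized per participant: \eqn{S = (\Delta - PSE)/\sigma}, the signed
#' distance between the stimulus level and the point of subjective equality
#' in standard-deviation units of the (unsorted-set) psychometric function.
#' For each confidence set (chosen, unsorted) and each of the design's
#' signed levels, the cell records the median RT, the mean confidence code
#' `C` of the included decisions (1 throughout the chosen set), and the cell
#' size. Both sets share the unsorted-set normalization. Decisions should
#' already be RT-filtered via [filter_rts()]. Empty cells are omitted with
#' a warning.
#'
#' @param sets A list with decision tibbles `chosen` and `unsorted`
#'   (from [split_sets()], RT-filtered).
#' @param fit_unsorted The unsorted-set [fit_cumulative_gaussian()] fit used
#'   for normalization.
#' @return A tibble: `set_label`, `delta`, `S`, `median_rt_ms`, `C`, `n`.
#' @export
cell_medians <- function(sets, fit_unsorted) {
  stopifnot(is.list(sets), all(c("chosen", "unsorted") %in% names(sets)))
  one_set <- function(d, label) {
    if (nrow(d) == 0) return(NULL)
    d |>
      dplyr::summarise(S = (.data$delta[1] - fit_unsorted$mu) / fit_unsorted$sigma,
                       median_rt_ms = stats::median(.data$rt_ms),
                       C = mean(.data$confidence),
                       n = dplyr::n(),
                       .by = "delta") |>
      dplyr::mutate(set_label = label)
  }
  out <- dplyr::bind_rows(one_set(sets$chosen, "chosen"),
                          one_set(sets$unsorted, "unsorted"))
  expected <- 2 * length(unique(sets$unsorted$delta))
  if (nrow(out) < expected) {
    warning("omitted ", expected - nrow(out), " empty RT cell(s)")
  }
  dplyr::select(out, "set_label", "delta", "S", "median_rt_ms", "C", "n") |>
    dplyr::arrange(.data$set_label, .data$delta)
}

#' Fit the exponential response-time model
#'
#' Least-squares fit of
#' \deqn{RT(S) = \alpha - \beta\, e^{-S^2/2} - \gamma\, C}
#' to per-cell median RTs, jointly over the chosen and unsorted cells.
#' \eqn{\alpha} is the generic RT, \eqn{\beta} the RT change driven by
#' stimulus intensity (responses slow as \eqn{|S| \to 0}, i.e. as difficulty
#' grows), and \eqn{\gamma} the linear RT change driven by confidence
#' (responses speed up for decisions judged with higher confidence). For
#' fixed regressors the model is linear in \eqn{(\alpha, \beta, \gamma)},
#' so the global least-squares optimum is computed exactly.
#'
#' @param cells A tibble from [cell_medians()] (needs `S`, `median_rt_ms`,
#'   `C`).
#' @return An object of class `rt_model_fit`: `alpha`, `beta`, `gamma`,
#'   `rss`, `n_cells`, `fitted`, `residuals`.
#' @examples
#' cells <- tibble::tibble(S = rep(-3:3, 2), C = rep(c(1, 0.5), each = 7))
#' cells$median_rt_ms <- 500 - 100 * exp(-cells$S^2 / 2) - 50 * cells$C
#' fit_rt_model(cells)
#' @export
fit_rt_model <- function(cells) {
  stopifnot(all(c("S", "median_rt_ms", "C") %in% names(cells)))
  if (nrow(cells) < 4) stop("need at least 4 cells, got ", nrow(cells))
  x_int <- exp(-cells$S^2 / 2)
  if (length(unique(round(x_int, 12))) < 2) {
    stop("gamma/beta unidentifiable: no variation in stimulus intensity exp(-S^2/2)")
  }
  if (length(unique(cells$C)) < 2) {
    stop("gamma unidentifiable: no variation in confidence C across cells")
  }
  X <- cbind(1, -x_int, -cells$C)
  if (qr(X)$rank < 3) {
    stop("unidentifiable design: intensity and confidence regressors are collinear")
  }
  fit <- stats::lm.fit(X, cells$median_rt_ms)
  coefs <- fit$coefficients
  structure(list(alpha = unname(coefs[1]), beta = unname(coefs[2]),
                 gamma = unname(coefs[3]),
                 rss = sum(fit$residuals^2), n_cells = nrow(cells),
                 fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals)),
            class = "rt_model_fit")
}

#' @export
print.rt_model_fit <- function(x, ...) {
  cat(sprintf(
    "RT model fit: alpha = %.1f ms, beta = %.1f ms, gamma = %.1f ms (RSS %.1f over %d cells)\n",
    x$alpha, x$beta, x$gamma, x$rss, x$n_cells))
  invisible(x)
}

#' Predict RT from an exponential RT model fit
#' @param object An `rt_model_fit`.
#' @param newdata Data frame with columns `S` and `C`.
#' @param ... Unused.
#' @return Numeric vector of predicted RTs (ms).
#' @export
predict.rt_model_fit <- function(object, newdata, ...) {
  object$alpha - object$beta * exp(-newdata$S^2 / 2) - object$gamma * newdata$C
}
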