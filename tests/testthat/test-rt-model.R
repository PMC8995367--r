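test_that("RT cells carry medians, normalized intensities and confidence", {
  sets <- split_sets(ref_session())
  fit_u <- suppressWarnings(
    fit_cumulative_gaussian(aggregate_proportions(sets$unsorted)))
  filt <- list(chosen = filter_rts(sets$chosen)$kept,
               unsorted = filter_rts(sets$unsorted)$kept)
  cells <- cell_medians(filt, fit_u)
  expect_equal(nrow(cells), 14)
  expect_true(all(cells$C[cells$set_label == "chosen"] == 1))
  un <- cells[cells$set_label == "unsorted", ]
  expect_true(all(un$C >= 0 & un$C <= 1))
  # S is the signed distance to the PSE in sigma units of the unsorted fit
  expect_equal(cells$S, (cells$delta - fit_u$mu) / fit_u$sigma)
  # unsorted-cell C equals the chosen fraction in that cell
  for (dd in c(-9, 0, 9)) {
    sub <- filt$unsorted[filt$unsorted$delta == dd, ]
    expect_equal(un$C[un$delta == dd], mean(sub$confidence))
  }

  # plain median semantics
  toy <- list(
    chosen = tibble::tibble(delta = 0, rt_ms = c(400, 500, 600), confidence = 1),
    unsorted = tibble::tibble(delta = 0, rt_ms = c(400, 500, 600), confidence = 1))
  suppressWarnings(tc <- cell_medians(toy, list(mu = 0, sigma = 5)))
  expect_equal(tc$median_rt_ms, c(500, 500))
  expect_equal(tc$S, c(0, 0))
  # PSE = 0, sigma = 5, delta = +5 -> S = 1
  toy5 <- list(chosen = tibble::tibble(delta = 5, rt_ms = 400, confidence = 1),
               unsorted = tibble::tibble(delta = 5, rt_ms = 400, confidence = 1))
  suppressWarnings(t5 <- cell_medians(toy5, list(mu = 0, sigma = 5)))
  expect_equal(unique(t5$S), 1)
})

test_that("noiseless cells invert exactly to the generating parameters", {
  cells <- tidyr::expand_grid(S = seq(-3, 3, by = 1),
                              C = c(1, 0.4))
  cells$median_rt_ms <- 500 - 100 * exp(-cells$S^2 / 2) - 50 * cells$C
  f <- fit_rt_model(cells)
  expect_equal(f$alpha, 500, tolerance = 1e-6)
  expect_equal(f$beta, 100, tolerance = 1e-6)
  expect_equal(f$gamma, 50, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
})

test_that("constant RTs yield a flat model", {
  cells <- tidyr::expand_grid(S = c(-2, -1, 0, 1, 2), C = c(1, 0.5))
  cells$median_rt_ms <- 480
  f <- fit_rt_model(cells)
  expect_equal(f$alpha, 480, tolerance = 1e-8)
  expect_equal(f$beta, 0, tolerance = 1e-8)
  expect_equal(f$gamma, 0, tolerance = 1e-8)
})

test_that("unidentifiable designs error with the missing variation named", {
  no_c <- tibble::tibble(S = c(-2, -1, 1, 2), C = 1,
                         median_rt_ms = c(500, 450, 460, 490))
  expect_error(fit_rt_model(no_c), "no variation in confidence")
  no_s <- tibble::tibble(S = c(1, -1, 1, -1), C = c(1, 1, 0, 0),
                         median_rt_ms = c(500, 450, 460, 490))
  expect_error(fit_rt_model(no_s), "no variation in stimulus intensity")
  expect_error(fit_rt_model(no_c[1:3, ]), "at least 4 cells")
})

test_that("the least-squares fit beats a 50^3 grid oracle", {
  sets <- split_sets(ref_session())
  fit_u <- suppressWarnings(
    fit_cumulative_gaussian(aggregate_proportions(sets$unsorted)))
  filt <- list(chosen = filter_rts(sets$chosen)$kept,
               unsorted = filter_rts(sets$unsorted)$kept)
  cells <- cell_medians(filt, fit_u)
  f <- fit_rt_model(cells)
  x <- exp(-cells$S^2 / 2)
  grid <- expand.grid(alpha = seq(300, 700, length.out = 50),
                      beta = seq(0, 250, length.out = 50),
                      gamma = seq(0, 150, length.out = 50))
  pred <- outer(rep(1, nrow(grid)), cells$median_rt_ms)
  rss_grid <- colSums((matrix(cells$median_rt_ms, nrow(cells), nrow(grid)) -
                         (matrix(grid$alpha, nrow(cells), nrow(grid), byrow = TRUE) -
                            outer(x, grid$beta) -
                            outer(cells$C, grid$gamma)))^2)
  expect_lte(f$rss, min(rss_grid) + 1e-9)
})

test_that("fitted sign semantics match slower-when-hard, faster-when-confident", {
  cells <- tidyr::expand_grid(S = seq(-3, 3, by = 1), C = c(1, 0.3))
  cells$median_rt_ms <- 520 - 90 * exp(-cells$S^2 / 2) - 45 * cells$C
  f <- fit_rt_model(cells)
  newd <- data.frame(S = c(0, 2, 0, 0), C = c(1, 1, 1, 0))
  pred <- predict(f, newd)
  expect_lt(pred[1], pred[2])        # harder (S = 0) is slower than easy only
  expect_lt(pred[3], pred[4])        # confident decisions are faster
})
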