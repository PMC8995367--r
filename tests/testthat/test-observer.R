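test_that("observer parameters are validated", {
  expect_error(observer_params(sigma_s = 0), "sigma_s > 0")
  expect_error(observer_params(sigma_s = 5, lapse = 0.2), "lapse")
  expect_error(observer_params(sigma_s = 5, rt_alpha = 120, rt_beta = 100,
                               rt_gamma = 50), "non-positive RTs")
})

test_that("simulated sessions are reproducible and follow the design", {
  p <- ref_params()
  s1 <- simulate_session(p, seed = 9)
  expect_identical(s1, simulate_session(p, seed = 9))
  expect_equal(as.integer(table(s1$task1_delta)), rep(60L, 7))
  expect_true(all(s1$rt1_ms >= 100))
  expect_true(all(s1$conf_choice %in% 1:2))
})

test_that("psychometric behaviour of the observer is monotone in difficulty", {
  for (sg in c(3, 8)) {
    s <- simulate_session(ref_params(sigma_s = sg), seed = 100 + sg)
    d <- decisions_long(s)
    d <- d[d$correct != "arbitrary", ]
    pc <- tapply(d$correct == "correct", abs(d$delta), mean)
    expect_gt(pc[["9"]], pc[["3"]])
  }
})

test_that("expected choice maps are exchangeable, monotone and match Monte Carlo", {
  prm <- observer_params(sigma_s = 7, sigma_c = 0.6, lapse = 0.02)
  spec <- design_spec()
  m <- expected_choice_map(prm, spec)
  # rows index delta1, columns delta2
  wide <- matrix(m$p, nrow = 7, byrow = TRUE)
  # P(a,b) + P(b,a) = 1 for the symmetric generative model
  expect_equal(wide + t(wide), matrix(1, 7, 7), tolerance = 1e-5)
  # equal difficulty, same decision combination -> exactly 1/2
  same <- expected_choice_map(prm, design_spec(levels = c(19, 25), standard = 22),
                              condition = "higher-higher")
  expect_equal(same$p[same$delta1 == same$delta2], c(0.5, 0.5), tolerance = 1e-5)
  # aggregate P increases with |delta1| at fixed delta2
  for (j in 1:7) {
    col <- wide[, j]                      # P as delta1 runs -9 ... 9
    expect_true(all(diff(col[4:7]) > 0))  # |delta1| grows on 0, 3, 6, 9
    expect_true(all(diff(col[1:4]) < 0))  # |delta1| shrinks on -9 ... 0
  }

  # Monte-Carlo oracle on a handful of cells, 10^6 draws each
  mc_cell <- function(d1, d2, n = 1e6) {
    withr::with_seed(31, {
      # lapses flip reports, not confidence evidence, so the aggregate
      # choice probability is lapse-free
      e1 <- rnorm(n, d1 / prm$sigma_s); e2 <- rnorm(n, d2 / prm$sigma_s)
      c1 <- abs(e1) + rnorm(n, 0, prm$sigma_c)
      c2 <- abs(e2) + rnorm(n, 0, prm$sigma_c)
      p <- mean(c1 > c2)
      se <- sqrt(p * (1 - p) / n)
      c(p = p, se = se)
    })
  }
  for (cell in list(c(-9, 0), c(3, 3), c(6, -3))) {
    mc <- mc_cell(cell[1], cell[2])
    q <- m$p[m$delta1 == cell[1] & m$delta2 == cell[2]]
    expect_lt(abs(q - mc["p"]), 3 * mc["se"] + 1e-6)
  }
})

test_that("aggregate monotonicity also holds without confidence noise", {
  prm <- observer_params(sigma_s = 7, sigma_c = 0)
  m <- expected_choice_map(prm, design_spec(levels = c(13, 22, 31), standard = 22))
  wide <- matrix(m$p, nrow = 3)
  expect_equal(wide + t(wide), matrix(1, 3, 3), tolerance = 1e-5)
  expect_equal(m$p[m$delta1 == 0 & m$delta2 == 0], 0.5, tolerance = 1e-6)
  expect_gt(m$p[m$delta1 == 9 & m$delta2 == 0],
            m$p[m$delta1 == 0 & m$delta2 == 0])
})

test_that("empirical maps converge to the expected map", {
  prm <- observer_params(sigma_s = 7, sigma_c = 0.6)
  expected <- expected_choice_map(prm, tol = 1e-6)
  sessions <- dplyr::bind_rows(lapply(1:500, function(i)
    simulate_session(prm, seed = 5000 + i, participant_id = sprintf("s%03d", i))))
  emp <- choice_probability_map(sessions)
  # sup-norm over the grid: at 500 sessions every cell holds ~4300 trials
  # (binomial SE < 0.008), so 0.02 bounds the worst cell at ~2.6 sigma
  expect_lt(max(abs(emp$p - expected$p)), 0.02)
})

test_that("cohort simulation is reproducible and structured by group", {
  spec <- cohort_spec(n_older = 5, n_younger = 5, seed = 21)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$sessions, c2$sessions)
  expect_identical(c1$participants, c2$participants)
  expect_equal(nrow(c1$sessions), 10 * 420)
  tp <- c1$true_params
  expect_true(mean(tp$sigma_s[tp$age_group == "older"]) >
                mean(tp$sigma_s[tp$age_group == "younger"]))
  expect_true(all(c1$participants$digit_span >= 2))
  expect_true(all(c1$participants$tmt_b_s > 0))
})

test_that("infeasible EF correlation structures error before simulation", {
  expect_error(cohort_spec(ef_link = 0.6, ef_attenuation = 0.5),
               "infeasible EF correlation structure")
})
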