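test_that("EF composite averages oriented pooled z-scores", {
  p <- tibble::tibble(participant_id = c("a", "b", "c"),
                      dsst = c(50, 70, 90), tmt_b_s = c(100, 60, 40),
                      vst_c_s = c(80, 50, 35), lps3 = c(12, 18, 24))
  ef <- ef_composite(p)
  # hand computation: z of each oriented measure, then the plain mean
  z <- function(x) (x - mean(x)) / sd(x)
  hand <- (z(p$dsst) + z(-p$tmt_b_s) + z(-p$vst_c_s) + z(p$lps3)) / 4
  expect_equal(ef$ef, hand)
  expect_equal(mean(ef$z_dsst), 0)
  # participant at the pooled mean of everything scores ef = 0
  p2 <- tibble::tibble(participant_id = c("a", "b", "c"),
                       dsst = c(60, 70, 80), tmt_b_s = c(50, 60, 70),
                       vst_c_s = c(40, 50, 60), lps3 = c(15, 20, 25))
  expect_equal(ef_composite(p2)$ef[2], 0)
  # faster TMT-B (fewer seconds) gives the larger z
  expect_gt(ef$z_tmtb[3], ef$z_tmtb[1])
  # missing measures exclude the participant with a warning
  p$lps3[2] <- NA
  expect_warning(ef3 <- ef_composite(p), "missing EF measures: b")
  expect_equal(nrow(ef3), 2)
})

test_that("mixed ANOVA matches aov error strata on unbalanced groups", {
  set.seed(301)
  n_o <- 8; n_y <- 11
  dat <- tidyr::expand_grid(id = sprintf("p%02d", 1:(n_o + n_y)),
                            set = c("chosen", "unsorted"))
  dat$group <- rep(rep(c("o", "y"), c(n_o, n_y)), each = 2)
  dat$value <- rnorm(nrow(dat), mean = 10 + 2 * (dat$group == "y") +
                       1.5 * (dat$set == "chosen"), sd = 1.5)
  mine <- mixed_anova(dat, "value", "id", "set", "group")
  ref <- summary(stats::aov(value ~ group * set + Error(id / set), data = dat))
  f_ref <- c(ref[["Error: id"]][[1]]$`F value`[1],
             ref[["Error: id:set"]][[1]]$`F value`[1:2])
  p_ref <- c(ref[["Error: id"]][[1]]$`Pr(>F)`[1],
             ref[["Error: id:set"]][[1]]$`Pr(>F)`[1:2])
  expect_equal(mine$F, unname(f_ref), tolerance = 1e-10)
  expect_equal(mine$p, unname(p_ref), tolerance = 1e-10)
  expect_equal(mine$df2, c(n_o + n_y - 2, n_o + n_y - 2, n_o + n_y - 2))
})

test_that("mixed ANOVA reproduces a hand-worked toy decomposition", {
  # 4 participants (2 per group), 2 within levels
  dat <- tibble::tibble(
    id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    set = rep(c("w1", "w2"), 4),
    value = c(10, 14, 12, 18, 20, 22, 24, 28))
  out <- mixed_anova(dat, "value", "id", "set", "group")
  # grand mean 18.5; group means 13.5 / 23.5 -> SS_group = 2*2*(5^2+5^2) = 200
  # subject means 12,15,21,26 -> SS_subj = 2*sum((m-18.5)^2) = 2*(42.25+12.25+6.25+56.25) = 234
  # SS_subj_err = 34; w means 16.5/20.5 -> SS_set = 4*(2^2+2^2) = 32
  # cell means g1:(11,16) g2:(22,25): SS_cells = 2*sum((c-18.5)^2) = 2*(56.25+6.25+12.25+42.25)=234
  # SS_inter = 234-200-32 = 2; SS_total = 270; SS_w_err = 270-234-32-2 = 2
  expect_equal(out$F[out$effect == "group"], (200 / 1) / (34 / 2))
  expect_equal(out$F[out$effect == "within"], (32 / 1) / (2 / 2))
  expect_equal(out$F[out$effect == "interaction"], (2 / 1) / (2 / 2))
  expect_equal(out$pes, c(200 / 234, 32 / 34, 2 / 4))
})

test_that("with a single group the within F equals the squared paired t", {
  set.seed(17)
  a <- rnorm(12, 10, 2); b <- a + rnorm(12, 1, 1)
  dat <- tibble::tibble(id = rep(sprintf("p%02d", 1:12), each = 2),
                        group = "all", set = rep(c("x", "y"), 12),
                        value = as.vector(rbind(a, b)))
  out <- mixed_anova(dat, "value", "id", "set", "group")
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(out$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$p, tt$p.value, tolerance = 1e-10)
})

test_that("degenerate ANOVA data warn about zero error variance", {
  dat <- tidyr::expand_grid(id = sprintf("p%d", 1:6), set = c("a", "b"))
  dat$group <- rep(c("g1", "g2"), each = 6)
  dat$value <- 5
  expect_warning(out <- mixed_anova(dat, "value", "id", "set", "group"),
                 "degenerate")
  expect_true(all(!is.finite(out$F) | out$F == 0))
})

test_that("t comparisons match textbook formulas and gate on Levene", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  res <- t_compare(a, b, n_boot = 0)
  sp <- sqrt((var(a) + var(b)) / 2)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$effect_size, (mean(a) - mean(b)) / sp)

  x <- c(5, 5.2, 4.9, 5.1, 5, 4.8, 5.05, 4.95)
  expect_equal(t_compare(x, x, paired = TRUE, n_boot = 0)$statistic, 0)
  expect_equal(t_compare(x, x, paired = TRUE, n_boot = 0)$effect_size, 0)

  # strongly unequal variances -> Welch with fractional df
  set.seed(5)
  h1 <- rnorm(25, 0, 0.5); h2 <- rnorm(30, 0.4, 4)
  res2 <- t_compare(h1, h2, n_boot = 0)
  expect_equal(res2$method, "Welch t")
  expect_gt(abs(res2$df - round(res2$df)), 1e-6)
  expect_lt(res2$df, 53)

  expect_error(t_compare(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("bootstrap CIs are seed-reproducible and cover the estimate", {
  set.seed(8)
  a <- rnorm(20, 1); b <- rnorm(20)
  r1 <- t_compare(a, b, n_boot = 500, seed = 3)
  r2 <- t_compare(a, b, n_boot = 500, seed = 3)
  expect_identical(r1, r2)
  expect_lte(r1$ci_low, mean(a) - mean(b))
  expect_gte(r1$ci_high, mean(a) - mean(b))
  r3 <- t_compare(a, b, n_boot = 500, seed = 4)
  expect_false(identical(r1$ci_low, r3$ci_low))
})

test_that("one-sample t matches the formula and is zero under symmetry", {
  v <- c(-2, -1, 0, 1, 2)
  expect_equal(one_sample_t(v)$statistic, 0)
  w <- c(4, 7, 9)
  res <- one_sample_t(w, null_value = 5)
  expect_equal(res$statistic, (mean(w) - 5) / (sd(w) / sqrt(3)))
  expect_equal(res$effect_size, (mean(w) - 5) / sd(w))
  expect_equal(res$df, 2)
  expect_error(one_sample_t(rep(2, 4)), "zero variance")
})

test_that("correlations match direct formulas, plain and partial", {
  x <- c(1, 2, 4, 6, 9); y <- c(2, 1, 5, 4, 10)
  res <- correlation(x, y, n_boot = 0)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_hand)
  ct <- cor.test(x, y)
  expect_equal(res$p, ct$p.value)
  expect_equal(res$df, 3)

  # control uncorrelated with both: partial reduces to plain (orthogonal z)
  x2 <- c(1, -1, 2, -2, 3, -3); y2 <- c(2, -2, 3, -3, 3.5, -3.5)
  z2 <- c(1, 1, -1, -1, 0, 0) # orthogonal to x2 and y2 by construction
  expect_equal(cor(x2, z2), 0)
  plain <- correlation(x2, y2, n_boot = 0)$estimate
  part <- correlation(x2, y2, control = z2, n_boot = 0)$estimate
  expect_equal(part, plain)

  # partial correlation with binary control = correlation of
  # within-group-centred variables
  set.seed(12)
  g <- rep(c(0, 1), each = 15)
  x3 <- rnorm(30) + g; y3 <- 0.5 * x3 + rnorm(30) + 2 * g
  part2 <- correlation(x3, y3, control = g, n_boot = 0)$estimate
  cx <- x3 - ave(x3, g); cy <- y3 - ave(y3, g)
  expect_equal(part2, cor(cx, cy), tolerance = 1e-12)
  expect_equal(correlation(x3, y3, control = g, n_boot = 0)$df, 27)

  expect_error(correlation(rep(1, 5), 1:5), "constant input")
})
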