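test_that("RMSE and MAPE match hand-computed values and their invariances", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1.1, 1.8), c(1, 2)), 0.1581139, tolerance = 1e-6)
  set.seed(1)
  p <- rnorm(30); o <- rnorm(30)
  perm <- sample(30)
  expect_equal(rmse(p[perm], o[perm]), rmse(p, o), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:2), "equal length")

  expect_equal(as.numeric(mape(c(1, 2), c(1, 2))), 0)
  expect_equal(as.numeric(mape(c(1.1, 1.8), c(1, 2))), 10.0,
               tolerance = 1e-9)
  expect_equal(as.numeric(mape(3 * p^2 + 1, 3 * (o^2 + 1))),
               as.numeric(mape(p^2 + 1 / 3, o^2 + 1)), tolerance = 1e-9)
  m <- mape(c(1, 1), c(0, 2))
  expect_equal(attr(m, "n_excluded"), 1)
  expect_error(mape(c(1), c(0)), "zero")
})

test_that("session totals integrate the 10 s EE series", {
  expect_equal(session_total(rep(1.5, 120)), 30.0)
  expect_equal(session_total(rep(0, 5)), 0)
  expect_error(session_total(numeric(0)), "empty")
  # close to a trapezoidal integration oracle on a smooth trace
  t <- seq(0, 1190, by = 10)
  ee <- 2 + sin(t / 200)
  trap <- sum((ee[-1] + ee[-length(ee)]) / 2 * 10 / 60) +
    ee[1] * 10 / 60 / 2 + ee[length(ee)] * 10 / 60 / 2
  expect_lt(abs(session_total(ee) - trap) / trap, 0.01)
})

test_that("a constant offset gives pure mean bias with zero-width limits", {
  obs <- rep(30, 5)
  ba <- bland_altman(obs, obs - 3)
  expect_equal(ba$mean_bias_pct, 10)
  expect_equal(unname(ba$loa_pct), c(10, 10))
  expect_equal(ba$mean_bias_kcal, 3)
  expect_true(ba$loa_pct["low"] <= ba$mean_bias_pct)
  expect_true(ba$loa_pct["high"] >= ba$mean_bias_pct)
  expect_error(bland_altman(c(30, 31), c(29, 30)), "3 paired")
  expect_error(bland_altman(c(30, 0, 31), c(29, 1, 30)), "positive")
})

test_that("proportional-bias slope is calibrated under the null and recovered under bias", {
  # null: percent error independent of the observed total; the OLS slope
  # should fall within 2 standard errors of zero about 95% of the time
  covered <- 0
  for (seed in 1:100) {
    set.seed(seed)
    obs <- runif(20, 20, 50)
    pct <- rnorm(20, 0, 5)
    pred <- obs * (1 - pct / 100)
    ba <- bland_altman(obs, pred)
    if (abs(ba$fit_slope) < 2 * ba$fit_slope_se) covered <- covered + 1
  }
  expect_gte(covered, 90)

  # planted proportional bias: slope recovered within 2 SE
  set.seed(42)
  obs <- runif(60, 20, 50)
  b <- 0.8
  pct <- -5 + b * obs + rnorm(60, 0, 2)
  ba <- bland_altman(obs, obs * (1 - pct / 100))
  expect_lt(abs(ba$fit_slope - b), 2 * ba$fit_slope_se)
  expect_gt(ba$prop_bias_r, 0.5)
})

# textbook two-way-without-replication decomposition, coded independently
oracle_rm_anova <- function(em) {
  n <- nrow(em); m <- ncol(em)
  grand <- mean(em)
  ss_model <- n * sum((colMeans(em) - grand)^2)
  ss_subj <- m * sum((rowMeans(em) - grand)^2)
  ss_tot <- sum((em - grand)^2)
  ss_err <- ss_tot - ss_model - ss_subj
  ms_model <- ss_model / (m - 1)
  ms_err <- ss_err / ((m - 1) * (n - 1))
  ms_model / ms_err
}

test_that("repeated-measures ANOVA matches the textbook decomposition", {
  set.seed(8)
  em <- matrix(rnorm(10 * 6, 0.6, 0.1), 10, 6,
               dimnames = list(paste0("S", 1:10), paste0("M", 1:6)))
  res <- rm_anova(em)
  expect_equal(res$df_model, 5)
  expect_equal(res$df_error, 45)
  expect_equal(res$f_stat, oracle_rm_anova(em), tolerance = 1e-8)
  expect_equal(res$p_value,
               pf(oracle_rm_anova(em), 5, 45, lower.tail = FALSE),
               tolerance = 1e-8)

  # identical model columns: no model effect at all
  em0 <- matrix(rep(rnorm(10, 0.6, 0.1), 4), 10, 4)
  res0 <- rm_anova(em0)
  expect_equal(res0$f_stat, 0)
  expect_equal(res0$p_value, 1)

  expect_error(rm_anova(em[, 1, drop = FALSE]), ">= 2")
  em_na <- em; em_na[2, 3] <- NA
  expect_error(rm_anova(em_na), "missing")
})

test_that("Fisher LSD uses the pooled error term, unadjusted", {
  set.seed(9)
  em <- matrix(rnorm(8 * 3, 0.5, 0.1), 8, 3,
               dimnames = list(NULL, c("A", "B", "C")))
  res <- rm_anova(em)
  pw <- res$pairwise
  expect_equal(nrow(pw), 3)
  se <- sqrt(2 * res$ms_error / 8)
  i <- which(pw$model_a == "A" & pw$model_b == "B")
  t_ab <- (mean(em[, 1]) - mean(em[, 2])) / se
  expect_equal(pw$t[i], t_ab, tolerance = 1e-9)
  expect_equal(pw$p[i], 2 * pt(abs(t_ab), res$df_error, lower.tail = FALSE),
               tolerance = 1e-9)
})
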