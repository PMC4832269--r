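test_that("residualize removes covariate association and preserves structure", {
  set.seed(41)
  n <- 400
  d <- data.frame(sex = rbinom(n, 1, 0.5),
                  age_days_mri_w1 = rnorm(n, 26500, 250))
  d$tbv_w1 <- 950 + 2 * d$sex + 0.01 * d$age_days_mri_w1 + rnorm(n, 0, 10)
  d$tbv_w1[sample(n, 30)] <- NA
  r <- residualize(d, vars = "tbv_w1")
  obs <- !is.na(r$tbv_w1)
  expect_equal(which(obs), which(!is.na(d$tbv_w1)))  # missing stays missing
  expect_lt(abs(cor(r$tbv_w1[obs], d$sex[obs])), 1e-10)
  expect_lt(abs(cor(r$tbv_w1[obs], d$age_days_mri_w1[obs])), 1e-10)
  # mean-preserving by default; centred on request
  expect_equal(mean(r$tbv_w1, na.rm = TRUE), mean(d$tbv_w1, na.rm = TRUE))
  rc <- residualize(d, vars = "tbv_w1", center = TRUE)
  expect_lt(abs(mean(rc$tbv_w1, na.rm = TRUE)), 1e-10)
  # idempotent
  r2 <- residualize(r, vars = "tbv_w1")
  expect_equal(r2$tbv_w1, r$tbv_w1, tolerance = 1e-10)
})

test_that("residualize matches the normal-equation oracle on a hand fixture", {
  d <- data.frame(sex = c(0, 1, 0, 1, 1),
                  age_days_cog_w1 = c(26400, 26500, 26450, 26550, 26480),
                  matrix_reasoning_w1 = c(10, 14, 11, 15, 12))
  r <- residualize(d, vars = "matrix_reasoning_w1", center = TRUE)
  fit <- lm(matrix_reasoning_w1 ~ age_days_cog_w1 + sex, data = d)
  expect_equal(unname(r$matrix_reasoning_w1), unname(resid(fit)),
               tolerance = 1e-9)
  # constant covariate errors
  d2 <- d; d2$sex <- 1
  expect_error(residualize(d2, vars = "matrix_reasoning_w1"), "constant")
})

test_that("Welch t statistic, df and p", {
  x <- c(1, 2, 3, 4)
  expect_error(welch_t(x, x), NA)
  wt0 <- welch_t(x, x)
  expect_equal(wt0$t, 0)
  expect_equal(wt0$p, 1)
  # equal n, equal sample variance reduces to the pooled df
  wt1 <- welch_t(c(1, 2, 3, 4), c(11, 12, 13, 14))
  expect_equal(wt1$df, 6)
  # textbook computation oracle
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  va <- var(a) / 4; vb <- var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 3 + vb^2 / 3)
  wt <- welch_t(a, b)
  expect_equal(wt$t, t_hand, tolerance = 1e-12)
  expect_equal(wt$df, df_hand, tolerance = 1e-9)
  expect_error(welch_t(c(1, 1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("annualized change metrics are exact and linear", {
  a <- annualized_change(-19.12, 990.32, 89.40, 3)
  expect_equal(a$per_year, -6.373, tolerance = 1e-3)
  expect_equal(round(a$sd_per_year, 3), -0.071)
  expect_equal(round(a$pct_per_year, 2), -0.64)
  z <- annualized_change(0, 100, 10, 3)
  expect_equal(unlist(z), c(per_year = 0, sd_per_year = 0, pct_per_year = 0))
  # linear in the mean change
  a2 <- annualized_change(-38.24, 990.32, 89.40, 3)
  expect_equal(a2$per_year, 2 * a$per_year)
  expect_equal(a2$pct_per_year, 2 * a$pct_per_year)
  expect_error(annualized_change(1, 0, 1, 3))
  expect_error(annualized_change(1, 1, 1, 0))
})
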