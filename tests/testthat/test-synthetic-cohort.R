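test_that("generator config is valid and anchored to the published moments", {
  cfg <- big_config()
  expect_true(all(cfg$tests$loading > 0 & cfg$tests$loading < 1.2))
  offd <- cfg$core_cor[lower.tri(cfg$core_cor)]
  expect_true(all(offd > -1 & offd < 1))
  ev <- eigen(cfg$core_cor, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # the PD repair must not move entries materially
  expect_lt(cfg$pd_adjustment, 0.01)
  # derived change SDs reproduce the published stabilities exactly:
  # stability = (1 + r c) / sqrt(1 + c^2 + 2 r c)
  for (v in c("tbv", "gm", "nawm", "wmh", "fluid", "memory", "speed")) {
    c_ <- cfg$change_sd[[v]]
    r_ <- cfg$core_cor[paste0(v, "_l"), paste0("d_", v)]
    expect_lt(abs((1 + r_ * c_) / sqrt(1 + c_^2 + 2 * r_ * c_) -
                    cfg$stability[[v]]), 0.006)
  }
})

test_that("population moments equal model-implied moments at the generating theta", {
  cfg <- big_config()
  pm <- population_moments(cfg)
  expect_equal(pm$Sigma, t(pm$Sigma))
  expect_gt(min(eigen(pm$Sigma, symmetric = TRUE, only.values = TRUE)$values), 0)
  for (model in c("A", "B")) {
    spec <- build_lds_model(model)
    th <- generating_theta(cfg, spec)
    mom <- implied_moments(spec, th)
    v <- colnames(mom$Sigma)
    expect_equal(mom$Sigma, pm$Sigma[v, v], tolerance = 1e-9)
    expect_equal(mom$mu, pm$mu[v], tolerance = 1e-9)
  }
  # WMH wave-to-wave stability encoded in the population covariance
  r <- pm$Sigma["wmh_w1", "wmh_w2"] /
    sqrt(pm$Sigma["wmh_w1", "wmh_w1"] * pm$Sigma["wmh_w2", "wmh_w2"])
  expect_lt(abs(r - 0.970), 0.005)
})

test_that("zeroing couplings empties the brain-cognition cross-covariance", {
  lc <- ldscoupling:::default_level_cor()
  lc[1:4, 5:7] <- 0; lc[5:7, 1:4] <- 0
  cfg0 <- suppressMessages(generator_config(level_cor = lc,
                                            zero_coupling = TRUE))
  pm <- population_moments(cfg0)
  cogs <- c(ldscoupling:::wave_name(cfg0$tests$test, "w1"),
            ldscoupling:::wave_name(cfg0$tests$test, "w2"))
  vols <- c(ldscoupling:::wave_name(cfg0$volumes$volume, "w1"),
            ldscoupling:::wave_name(cfg0$volumes$volume, "w2"))
  expect_equal(max(abs(pm$Sigma[cogs, vols])), 0, tolerance = 1e-10)
})

test_that("simulated cohorts are deterministic and match the population", {
  cfg <- big_config()
  c1 <- simulate_cohort(cfg, 200, seed = 5)
  c2 <- simulate_cohort(cfg, 200, seed = 5)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(cfg, 200, seed = 6)
  expect_false(identical(c1$tbv_w1, c3$tbv_w1))

  big <- big_cohort()  # n = 20,000 at the defaults
  expect_lt(abs(mean(big$tbv_w1) - 990.32), 990.32 * 0.005)
  expect_lt(abs(sd(big$tbv_w1) - 89.40), 89.40 * 0.03)
  expect_lt(abs(mean(big$wmh_w1) - 12.23), 12.23 * 0.03)
  # residualized sample correlations track the population ones
  pm <- population_moments(cfg)
  rdat <- big_resid()
  for (pair in list(c("wmh_w1", "wmh_w2"), c("tbv_w1", "digit_symbol_w1"),
                    c("gm_w1", "nawm_w1"))) {
    r_pop <- pm$Sigma[pair[1], pair[2]] /
      sqrt(pm$Sigma[pair[1], pair[1]] * pm$Sigma[pair[2], pair[2]])
    r_emp <- cor(rdat[[pair[1]]], rdat[[pair[2]]])
    expect_lt(abs(r_emp - r_pop), 0.025)
  }
  # zero change means leave wave-2 population means at wave-1 values
  cfg0 <- suppressMessages(generator_config(
    change_mean_sd = c(fluid = 0, memory = 0, speed = 0),
    change_mean_raw = c(tbv = 0, gm = 0, nawm = 0, wmh = 0)))
  pm0 <- population_moments(cfg0)
  expect_equal(pm0$mu[["block_design_w2"]], pm0$mu[["block_design_w1"]])
  expect_equal(pm0$mu[["tbv_w2"]], pm0$mu[["tbv_w1"]])
})

test_that("attrition mechanisms hit their targets with the right dependence", {
  cfg <- big_config()
  coh <- simulate_cohort(cfg, 10000, seed = 8)

  mar <- apply_attrition(coh, "MAR", seed = 9)
  drop_frac <- mean(is.na(mar$matrix_reasoning_w2))
  expect_lt(abs(drop_frac - cfg$attrition$cognitive), 0.02)
  # non-returners have lower wave-1 fluid scores (Welch t > 0)
  ret <- !is.na(mar$matrix_reasoning_w2)
  wt <- welch_t(mar$matrix_reasoning_w1[ret], mar$matrix_reasoning_w1[!ret])
  expect_gt(wt$t, 3)

  mcar <- apply_attrition(coh, "MCAR", seed = 9)
  ret2 <- !is.na(mcar$matrix_reasoning_w2)
  comp <- ldscoupling:::w1_composite(mcar, cfg)
  expect_lt(abs(cor(comp, as.numeric(ret2))), 0.03)

  # zero fractions are the identity on the cognitive side
  none <- apply_attrition(coh, "MAR", seed = 9,
                          fractions = list(cognitive = 0, imaging = 0,
                                           imaging_w1 = 1))
  expect_identical(none$matrix_reasoning_w2, coh$matrix_reasoning_w2)
  expect_identical(none$tbv_w2, coh$tbv_w2)
  expect_error(apply_attrition(coh, "MAR", fractions = list(cognitive = 1.2)),
               "out of")
})

test_that("MMSE and dementia flags target low-cognition subjects at set rates", {
  cfg <- big_config()
  coh <- simulate_cohort(cfg, 10000, seed = 13)
  fl <- flag_exclusions(coh, seed = 14)
  expect_lt(abs(mean(fl$mmse_w1 < 24) - cfg$exclusions$mmse_frac), 0.01)
  expect_lt(abs(mean(fl$dementia_dx) - cfg$exclusions$dementia_frac), 0.015)
  expect_true(all(fl$mmse_w1 >= 0 & fl$mmse_w1 <= 30))
  core <- attr(fl, "core")
  expect_lt(mean(core[fl$mmse_w1 < 24, "fluid_l"]), mean(core[, "fluid_l"]))
  expect_lt(mean(core[fl$dementia_dx == 1, "fluid_l"]), mean(core[, "fluid_l"]))
  # zero fractions produce no flags
  f0 <- flag_exclusions(coh, seed = 14,
                        fractions = list(mmse_frac = 0, dementia_frac = 0))
  expect_true(all(f0$mmse_w1 >= 24))
  expect_true(all(f0$dementia_dx == 0))
})

test_that("cohort round-trips to disk with config and seed manifest", {
  coh <- simulate_cohort(big_config(), 60, seed = 2)
  dir <- tempfile()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(back), 60)
  expect_equal(back$tbv_w1, coh$tbv_w1, tolerance = 1e-8)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$seed, 2)
  unlink(dir, recursive = TRUE)
})
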