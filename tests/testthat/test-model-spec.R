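test_that("measurement model obeys identification and invariance counting rules", {
  ind <- list(F = c("a", "b", "c"))
  sp <- build_measurement_model(ind, invariance = TRUE, residual_cov = FALSE)
  labs <- free_labels(sp)
  expect_length(grep("^l_", labs), 2)   # first loading fixed, shared across waves
  expect_length(grep("^i_", labs), 3)   # intercepts shared across waves
  expect_length(grep("^rv_", labs), 6)  # residual variances per wave

  # dropping invariance doubles the loading/intercept inventory
  sp2 <- build_measurement_model(ind, invariance = FALSE, residual_cov = FALSE)
  labs2 <- free_labels(sp2)
  expect_length(grep("^l_", labs2), 4)
  expect_length(grep("^i_", labs2), 6)

  expect_error(build_measurement_model(list(F = "a")), "fewer than 2")
  expect_error(build_measurement_model(list(F = c("a", "b", "c")),
                                       cross_loadings = data.frame(
                                         test = "zz", factor = "F")),
               "unknown test")
})

test_that("fluid intelligence factor carries five free loadings via cross-loads", {
  labs <- free_labels(build_model_A())
  fluid_loads <- grep("\\.fluid$", labs, value = TRUE)
  # 4 indicators (reference fixed) + digit-symbol and symbol-search cross-loads
  expect_length(fluid_loads, 5)
  expect_true(all(c("l_digit_symbol.fluid", "l_symbol_search.fluid")
                  %in% fluid_loads))
})

test_that("latent change score is an exact difference", {
  sp <- model_spec(observed = c("y1", "y2"))
  sp <- add_cov(sp, "y1", "y1", label = "v1")
  sp <- add_mean(sp, "y1", label = "m1")
  sp <- add_cov(sp, "y2", "y2", label = "v2tmp")
  sp <- add_mean(sp, "y2", label = "m2tmp")
  sp <- add_latent_change(sp, "y1", "y2", "d")
  sp$covs <- sp$covs[!(sp$covs$free & sp$covs$label == "v2tmp"), ]
  sp$means <- sp$means[!(sp$means$free & sp$means$label == "m2tmp"), ]

  th <- c(v1 = 2, m1 = 5, v_d = 0.5, m_d = -1, c_d.y1 = -0.3)
  mom <- implied_moments(sp, th)
  # mean(w2) = mean(w1) + mean(delta); cov(w1,w2) = var(w1) + cov(w1,delta)
  expect_equal(mom$mu[["y2"]], 5 - 1)
  expect_equal(mom$Sigma["y1", "y2"], 2 - 0.3)
  expect_equal(mom$Sigma["y2", "y2"], 2 + 0.5 + 2 * (-0.3))

  # degenerate change: zero mean and variance reduces wave 2 to wave 1
  th0 <- c(v1 = 2, m1 = 5, v_d = 0, m_d = 0, c_d.y1 = 0)
  mom0 <- implied_moments(sp, th0)
  expect_equal(mom0$mu[["y2"]], mom0$mu[["y1"]])
  expect_equal(mom0$Sigma["y2", "y2"], mom0$Sigma["y1", "y1"])

  expect_error(add_latent_change(sp, "y1", "y2", "d2"), "duplicate")
})

test_that("built models have the documented structure and moment counts", {
  specA <- build_model_A()
  expect_equal(sum(specA$variables$role == "observed"), 26)
  p <- 26
  expect_equal(p * (p + 1) / 2 + p, 377)
  deltas <- grep("^d_", specA$variables$name, value = TRUE)
  expect_length(deltas, 4)
  # every delta covaries freely with every level (4 families of 4)
  for (d in deltas)
    expect_length(grep(paste0("^c_.*", d, "|", d, "\\."),
                       grep(d, free_labels(specA), value = TRUE)), 7)

  specB <- build_model_B()
  expect_equal(sum(specB$variables$role == "observed"), 30)
  expect_equal(30 * 31 / 2 + 30, 495)
  expect_length(grep("^d_", specB$variables$name, value = TRUE), 6)
  # Table-5 support: all 9 level-change covariances among gm/nawm/wmh free
  for (v in c("gm", "nawm", "wmh")) for (d in c("d_gm", "d_nawm", "d_wmh"))
    expect_true(ldscoupling:::canon_cov_label(paste0(v, "_w1"), d)
                %in% free_labels(specB))
})

test_that("degrees of freedom count moments minus distinct free labels", {
  expect_equal(degrees_of_freedom(saturated_spec(c("a", "b", "c"))), 0)
  # 3-indicator one-factor model with means: 9 moments - 9 free = 0
  expect_equal(degrees_of_freedom(one_factor_spec(3)), 0)
  expect_equal(degrees_of_freedom(build_model_A()), 277)
  expect_equal(degrees_of_freedom(build_model_B()), 349)
  # both parameterizations of the same model agree
  expect_equal(degrees_of_freedom(build_model_A(parameterization = "standardized")), 277)
  expect_equal(degrees_of_freedom(build_model_B(parameterization = "standardized")), 349)
})

test_that("constrain_equal merges labels transitively and validates input", {
  sp <- one_factor_spec(4)
  n0 <- length(free_labels(sp))
  sp2 <- constrain_equal(sp, c("l2", "l3"))
  expect_equal(length(free_labels(sp2)), n0 - 1)
  expect_equal(degrees_of_freedom(sp2), degrees_of_freedom(sp) + 1)
  # transitive through repeated application
  sp3 <- constrain_equal(constrain_equal(sp, c("l2", "l3")), c("l2", "l4"))
  expect_equal(length(free_labels(sp3)), n0 - 2)
  # self-constraint is a no-op
  expect_identical(free_labels(constrain_equal(sp, "l2")), free_labels(sp))
  expect_error(constrain_equal(sp, c("l2", "nope")), "unknown")
})

test_that("model specs round-trip through YAML with label sharing intact", {
  sp <- build_model_A()
  f <- tempfile(fileext = ".yaml")
  write_model_spec(sp, f)
  sp2 <- read_model_spec(f)
  expect_identical(free_labels(sp), free_labels(sp2))
  expect_identical(sp$variables, sp2$variables)
  th <- generating_theta(big_config(), sp)
  m1 <- implied_moments(sp, th)
  m2 <- implied_moments(sp2, th)
  expect_equal(m1$Sigma, m2$Sigma, tolerance = 1e-12)
  expect_equal(m1$mu, m2$mu, tolerance = 1e-12)
  unlink(f)
})

test_that("relaxing an equality constraint recovers the original fit exactly", {
  set.seed(5)
  sp <- one_factor_spec(4)
  F <- rnorm(300)
  d <- data.frame(x1 = F + rnorm(300, 0, 0.7),
                  x2 = 0.9 * F + rnorm(300, 0, 0.7),
                  x3 = 0.8 * F + rnorm(300, 0, 0.7),
                  x4 = 0.7 * F + rnorm(300, 0, 0.7))
  fit_free <- fit_model(sp, d, starts = 2, seed = 1, se = FALSE)
  fit_con <- fit_model(constrain_equal(sp, c("l2", "l3")), d, starts = 2,
                       seed = 1, se = FALSE)
  nt <- nested_diff_test(fit_free, fit_con)
  expect_equal(nt$df_diff, 1)
  expect_gte(nt$chisq_diff, 0)
  # relaxing back: same spec as the original gives the same loglik
  fit_back <- fit_model(sp, d, starts = 2, seed = 2, se = FALSE)
  expect_equal(fit_back$loglik, fit_free$loglik, tolerance = 1e-6)
})
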