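test_that("implied moments follow the covariance algebra", {
  # spec with no paths and diagonal S: Sigma = S, mu = m
  sp <- saturated_spec(c("a", "b"))
  th <- c(v1 = 2, m1 = 1, c12 = 0.5, v2 = 3, m2 = -1)
  mom <- implied_moments(sp, th)
  expect_equal(mom$Sigma, matrix(c(2, .5, .5, 3), 2,
                                 dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(unname(mom$mu), c(1, -1))

  # one factor, two indicators: hand algebra
  sp2 <- one_factor_spec(2)
  th2 <- c(l2 = 0.8, vf = 1.5, rv_x1 = 0.4, rv_x2 = 0.6, m_x1 = 0, m_x2 = 0)
  mom2 <- implied_moments(sp2, th2)
  expect_equal(unname(mom2$Sigma),
               matrix(c(1.5 + 0.4, 0.8 * 1.5,
                        0.8 * 1.5, 0.8^2 * 1.5 + 0.6), 2), tolerance = 1e-12)
})

test_that("implied moments equal the path-tracing oracle on small random specs", {
  set.seed(7)
  for (rep in 1:20) {
    nob <- sample(2:4, 1)
    obs <- paste0("y", seq_len(nob))
    sp <- model_spec(observed = obs, latent = "L")
    th <- c()
    sp <- add_path(sp, "L", obs[1], fixed = 1)
    for (j in seq_len(nob)[-1]) {
      sp <- add_path(sp, "L", obs[j], label = paste0("l", j))
      th[paste0("l", j)] <- runif(1, 0.3, 1.2)
    }
    # a random observed-to-observed regression keeps the graph acyclic
    if (nob >= 3) {
      sp <- add_path(sp, obs[1], obs[nob], label = "b")
      th["b"] <- runif(1, -0.5, 0.5)
    }
    sp <- add_cov(sp, "L", "L", label = "vf"); th["vf"] <- runif(1, 0.5, 2)
    sp <- add_mean(sp, "L", fixed = 0)
    for (v in obs) {
      sp <- add_cov(sp, v, v, label = paste0("rv_", v))
      sp <- add_mean(sp, v, label = paste0("m_", v))
      th[paste0("rv_", v)] <- runif(1, 0.2, 1)
      th[paste0("m_", v)] <- rnorm(1)
    }
    mom <- implied_moments(sp, th)
    orc <- trace_moments(sp, th)
    expect_equal(unname(mom$Sigma), unname(orc$Sigma), tolerance = 1e-9)
    expect_equal(unname(mom$mu), unname(orc$mu), tolerance = 1e-9)
  }
})

test_that("FIML log-likelihood matches closed forms and marginalizes", {
  # one row, one variable, standard normal density at 0
  sp <- saturated_spec("a")
  expect_equal(fiml_loglik(sp, c(v1 = 1, m1 = 0), data.frame(a = 0)),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  # a row observed on one variable contributes its univariate marginal
  sp2 <- saturated_spec(c("a", "b"))
  th2 <- c(v1 = 2, m1 = 1, c12 = 0.8, v2 = 1.5, m2 = -0.5)
  ll_joint <- fiml_loglik(sp2, th2, data.frame(a = 1.3, b = NA))
  expect_equal(ll_joint, dnorm(1.3, 1, sqrt(2), log = TRUE), tolerance = 1e-12)

  # complete data equal the dense multivariate normal log-likelihood
  set.seed(11)
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  sp3 <- saturated_spec(c("a", "b", "c"))
  th3 <- c(v1 = 1.2, m1 = 0.1, c12 = 0.3, c13 = -0.2, v2 = 0.9, m2 = 0,
           c23 = 0.1, v3 = 1.1, m3 = -0.3)
  mom <- implied_moments(sp3, th3)
  expect_equal(fiml_loglik(sp3, th3, as.data.frame(X)),
               dense_mvn_loglik(X, mom$mu, mom$Sigma), tolerance = 1e-10)
})

test_that("saturated log-likelihood matches closed forms under missingness", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x", "y")))
  # complete data: ML moments with denominator n
  sat <- saturated_loglik(X)
  expect_equal(sat$mu, colMeans(X))
  expect_equal(sat$Sigma, crossprod(sweep(X, 2, colMeans(X))) / 20,
               tolerance = 1e-9)
  expect_equal(sat$loglik, dense_mvn_loglik(X, sat$mu, sat$Sigma),
               tolerance = 1e-8)

  # monotone missingness: factored likelihood (x marginal + y|x regression)
  Xm <- X; Xm[11:20, "y"] <- NA
  sat_m <- saturated_loglik(Xm, tol = 1e-12)
  mx <- mean(Xm[, "x"]); vx <- mean((Xm[, "x"] - mx)^2)
  ll_x <- sum(dnorm(Xm[, "x"], mx, sqrt(vx), log = TRUE))
  cc <- Xm[1:10, ]
  b <- cov(cc[, "x"], cc[, "y"]) * 9 / 10 / (mean((cc[, "x"] - mean(cc[, "x"]))^2))
  a <- mean(cc[, "y"]) - b * mean(cc[, "x"])
  res <- cc[, "y"] - a - b * cc[, "x"]
  s2 <- mean(res^2)
  ll_y_given_x <- sum(dnorm(res, 0, sqrt(s2), log = TRUE))
  expect_equal(sat_m$loglik, ll_x + ll_y_given_x, tolerance = 1e-6)

  # EM log-likelihood is non-decreasing over iterations
  set.seed(4)
  X3 <- matrix(rnorm(150), 50, 3)
  X3[sample(150, 40)] <- NA
  X3 <- X3[rowSums(!is.na(X3)) > 0, ]
  colnames(X3) <- c("a", "b", "c")
  lls <- vapply(1:6, function(k)
    saturated_loglik(X3, tol = 0, max_iter = k)$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-8))

  expect_error(saturated_loglik(data.frame(a = c(1, NA, NA), b = c(1, 2, 3))),
               "fewer than 2")
})

test_that("analytic gradient agrees with finite differences", {
  sp <- one_factor_spec(3)
  set.seed(9)
  F <- rnorm(80)
  d <- data.frame(x1 = 1 + F + rnorm(80, 0, .6),
                  x2 = 0.8 * F + rnorm(80, 0, .6),
                  x3 = -1 + 0.6 * F + rnorm(80, 0, .6))
  d$x2[1:10] <- NA  # exercise a second missingness pattern
  ram <- ldscoupling:::compile_ram(sp)
  X <- ldscoupling:::extract_data(d, ram$vars[ram$obs])
  pats <- ldscoupling:::pattern_stats(X)
  th <- c(l2 = 0.7, l3 = 0.5, vf = 0.9, rv_x1 = 0.5, rv_x2 = 0.5,
          rv_x3 = 0.4, m_x1 = 1, m_x2 = 0, m_x3 = -1)
  f_of <- function(t) {
    mom <- ldscoupling:::ram_moments(ram, unname(t[ram$labels]))
    -2 * ldscoupling:::mvn_pattern_loglik(mom$Sigma, mom$mu, pats)$ll
  }
  mom <- ldscoupling:::ram_moments(ram, unname(th[ram$labels]))
  lk <- ldscoupling:::mvn_pattern_loglik(mom$Sigma, mom$mu, pats, grad = TRUE)
  g <- ldscoupling:::ram_grad_chain(ram, mom, lk$Gsig, lk$gmu)
  g_fd <- vapply(seq_along(th), function(j) {
    h <- 1e-6 * max(abs(th[j]), 1)
    tp <- th; tp[j] <- th[j] + h
    tm <- th; tm[j] <- th[j] - h
    (f_of(tp) - f_of(tm)) / (2 * h)
  }, numeric(1))
  expect_equal(g, g_fd, tolerance = 1e-5)
})

test_that("fit_model recovers generating parameters and is deterministic", {
  sp <- one_factor_spec(3)
  # three-indicator model with means is just-identified (df 0)
  truth <- c(l2 = 0.8, l3 = 0.6, vf = 1.5, rv_x1 = 0.5, rv_x2 = 0.7,
             rv_x3 = 0.4, m_x1 = 2, m_x2 = 1, m_x3 = 0)
  mom <- implied_moments(sp, truth)
  set.seed(12)
  X <- MASS::mvrnorm(50000, mom$mu, mom$Sigma)
  colnames(X) <- c("x1", "x2", "x3")
  fit <- fit_model(sp, as.data.frame(X), starts = 2, seed = 1, se = FALSE)
  expect_true(fit$converged)
  # within 3 Monte-Carlo SEs of the truth (loose deterministic bounds)
  expect_equal(unname(fit$theta[names(truth)]), unname(truth),
               tolerance = 0.05)
  # saturated model: chi-square zero
  expect_equal(2 * (fit$loglik_sat - fit$loglik), 0, tolerance = 1e-4)

  # determinism and seed insensitivity at the optimum
  fit_b <- fit_model(sp, as.data.frame(X), starts = 2, seed = 1, se = FALSE)
  expect_identical(fit$theta, fit_b$theta)
  fit_c <- fit_model(sp, as.data.frame(X), starts = 2, seed = 99, se = FALSE)
  expect_equal(fit$theta, fit_c$theta, tolerance = 1e-4)
})

test_that("rows missing every model variable are dropped with a count", {
  sp <- saturated_spec(c("a", "b"))
  d <- data.frame(a = c(1, NA, 2), b = c(0.5, NA, NA))
  fit <- fit_model(sp, d, starts = 1, seed = 1, se = FALSE)
  expect_equal(fit$n, 2)
  expect_equal(fit$n_dropped, 1)
})

test_that("standardized solution matches the closed form and stays bounded", {
  fit <- big_fit("A")
  pt <- parameter_table(fit)
  # single-factor closed form: lambda sqrt(phi) / sqrt(lambda^2 phi + theta)
  lam <- fit$theta[["l_block_design.fluid"]]
  phi <- fit$theta[["v_fluid_w1"]]
  # block_design_w1 variance = lam^2 phi + residual
  th_r <- fit$theta[["rv_block_design_w1"]]
  i <- which(pt$lhs == "fluid_w1" & pt$rhs == "block_design_w1")
  expect_equal(pt$std_est[i], lam * sqrt(phi) / sqrt(lam^2 * phi + th_r),
               tolerance = 1e-6)
  # all level/change standardized covariances are correlations in [-1, 1]
  core <- c("tbv_w1", "fluid_w1", "memory_w1", "speed_w1",
            "d_tbv", "d_fluid", "d_memory", "d_speed")
  cc <- pt[pt$op == "~~" & pt$lhs %in% core & pt$rhs %in% core &
             pt$lhs != pt$rhs, ]
  expect_true(all(abs(cc$std_est) <= 1))
})

test_that("chi-square of an equality-constrained model never beats its parent", {
  set.seed(21)
  sp <- one_factor_spec(4)
  F <- rnorm(400)
  d <- data.frame(x1 = F + rnorm(400, 0, .7), x2 = .9 * F + rnorm(400, 0, .7),
                  x3 = .5 * F + rnorm(400, 0, .7), x4 = .7 * F + rnorm(400, 0, .7))
  f_free <- fit_model(sp, d, starts = 2, seed = 1, se = FALSE)
  f_con <- fit_model(constrain_equal(sp, c("l2", "l4")), d, starts = 2,
                     seed = 1, se = FALSE)
  T_free <- 2 * (f_free$loglik_sat - f_free$loglik)
  T_con <- 2 * (f_con$loglik_sat - f_con$loglik)
  expect_gte(T_con, T_free - 1e-6)
})
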