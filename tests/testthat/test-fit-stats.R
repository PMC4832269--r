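test_that("likelihood-ratio chi-square and its p-value", {
  expect_equal(model_chisq(-100, -100, 10), list(T = 0, p = 1))
  expect_lt(model_chisq(-1000 - 917.990 / 2, -1000, 276)$p, 1e-10)
  # chi-square table check: T = 3.841, df = 1 is the 5% point
  expect_equal(model_chisq(-10 - 3.841 / 2, -10, 1)$p, 0.05, tolerance = 2e-3)
  expect_error(model_chisq(-99, -100, 5), "negative chi-square")
})

test_that("RMSEA reproduces the printed model fits and floors at zero", {
  expect_equal(round(rmsea(917.990, 276, 866), 3), 0.052)
  expect_equal(round(rmsea(1011.757, 348, 866), 3), 0.047)
  expect_equal(rmsea(90, 100, 500), 0)
  # decreasing in n for fixed T, df
  expect_lt(rmsea(200, 100, 2000), rmsea(200, 100, 500))
})

test_that("CFI and TLI follow their definitions", {
  expect_equal(cfi_tli(100, 100, 900, 120)$cfi, 1)
  # model as poor as the baseline: CFI 0
  expect_equal(cfi_tli(900, 100, 900, 120)$cfi, 0)
  ct <- cfi_tli(150, 100, 1100, 120)
  expect_equal(ct$cfi, 1 - 50 / 980, tolerance = 1e-12)       # 0.949
  expect_equal(ct$tli, (1100 / 120 - 1.5) / (1100 / 120 - 1),
               tolerance = 1e-12)                             # 0.939
  expect_equal(round(ct$cfi, 3), 0.949)
  expect_equal(round(ct$tli, 3), 0.939)
  expect_true(is.na(cfi_tli(0, 0, 100, 10)$tli))
})

test_that("nested difference test validates nesting and direction", {
  fit <- big_fit("A")
  nt <- nested_diff_test(fit, fit)
  expect_equal(nt$chisq_diff, 0)
  expect_equal(nt$df_diff, 0)
  expect_equal(nt$p, 1)
  # p-value arithmetic at a printed-style value
  expect_equal(pchisq(6.844, 1, lower.tail = FALSE), 0.0089, tolerance = 1e-3)
})

test_that("Benjamini-Hochberg step-up adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  # all-equal p-values stay put
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # against a by-hand step-up oracle: adj_(i) = min_{j >= i} m p_(j) / j
  set.seed(31)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))^2
    adj <- bh_fdr(p)
    m <- length(p)
    o <- order(p)
    hand <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
    expect_equal(adj[o], hand, tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))         # monotone above raw
    expect_true(all(adj <= 1))                 # capped
    expect_true(all(diff(adj[o]) >= -1e-12))   # non-decreasing in sorted order
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(-0.1, 0.5)), "\\[0, 1\\]")
})
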