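# Synthetic two-wave cohort generator.
#
# The generating model is exactly the latent difference score structure the
# package fits: standardized wave-1 levels for three cognitive factors and
# four brain volumes, latent change scores with their own means/SDs, a joint
# core correlation matrix across levels and changes, factor-analytic test
# indicators with cross-wave correlated residuals, and raw scaling to the
# published cohort means/SDs. Sex and age effects are added on top of the
# residualized scale and are removed again by residualize().

core_names <- function() {
  c("tbv_l", "gm_l", "nawm_l", "wmh_l", "fluid_l", "memory_l", "speed_l",
    paste0("d_", c("tbv", "gm", "nawm", "wmh", "fluid", "memory", "speed")))
}

# change SD (in wave-1 SD units, per study interval) consistent with a
# wave-1 -> wave-2 stability correlation and a level-own-change correlation:
# stability = (1 + r c) / sqrt(1 + c^2 + 2 r c)
solve_change_sd <- function(stability, level_change_r) {
  s2 <- stability^2; r <- level_change_r
  disc <- r^2 * (1 - s2)^2 + (s2 - r^2) * (1 - s2)
  if (s2 <= r^2 || disc < 0)
    stop("no positive change SD is consistent with stability ", stability,
         " and level-change correlation ", r)
  (r * (1 - s2) + sqrt(disc)) / (s2 - r^2)
}

default_level_cor <- function() {
  v <- c("tbv_l", "gm_l", "nawm_l", "wmh_l", "fluid_l", "memory_l", "speed_l")
  R <- diag(7); dimnames(R) <- list(v, v)
  low <- rbind(
    c("tbv_l", "gm_l", 0.877), c("tbv_l", "nawm_l", 0.863),
    c("tbv_l", "wmh_l", 0.099), c("gm_l", "nawm_l", 0.663),
    c("gm_l", "wmh_l", -0.086), c("nawm_l", "wmh_l", -0.264),
    c("fluid_l", "tbv_l", 0.301), c("fluid_l", "gm_l", 0.314),
    c("fluid_l", "nawm_l", 0.300), c("fluid_l", "wmh_l", -0.152),
    c("memory_l", "tbv_l", 0.225), c("memory_l", "gm_l", 0.257),
    c("memory_l", "nawm_l", 0.230), c("memory_l", "wmh_l", -0.172),
    c("speed_l", "tbv_l", 0.273), c("speed_l", "gm_l", 0.270),
    c("speed_l", "nawm_l", 0.336), c("speed_l", "wmh_l", -0.233),
    c("fluid_l", "memory_l", 0.860), c("fluid_l", "speed_l", 0.606),
    c("memory_l", "speed_l", 0.588))
  for (k in seq_len(nrow(low))) {
    x <- as.numeric(low[k, 3])
    R[low[k, 1], low[k, 2]] <- x; R[low[k, 2], low[k, 1]] <- x
  }
  R
}

# published level-change correlations; unprinted brain-cognition couplings
# (non-significant in the study) default to 0; mean-only printed families are
# split into per-path values consistent with the printed means
default_level_change_cor <- function() {
  lv <- c("tbv_l", "gm_l", "nawm_l", "wmh_l", "fluid_l", "memory_l", "speed_l")
  dv <- paste0("d_", c("tbv", "gm", "nawm", "wmh", "fluid", "memory", "speed"))
  M <- matrix(0, 7, 7, dimnames = list(lv, dv))
  M["tbv_l", "d_tbv"] <- -0.121
  M["gm_l", "d_gm"] <- -0.182; M["gm_l", "d_nawm"] <- -0.062
  M["gm_l", "d_wmh"] <- 0.009
  M["nawm_l", "d_gm"] <- 0.036; M["nawm_l", "d_nawm"] <- -0.010
  M["nawm_l", "d_wmh"] <- -0.102
  M["wmh_l", "d_gm"] <- -0.121; M["wmh_l", "d_nawm"] <- -0.285
  M["wmh_l", "d_wmh"] <- 0.596
  M["fluid_l", "d_tbv"] <- 0.060
  M["memory_l", "d_tbv"] <- 0.190
  M["speed_l", "d_tbv"] <- 0.128
  M["fluid_l", "d_nawm"] <- 0.140
  M["memory_l", "d_nawm"] <- 0.175
  M["speed_l", "d_nawm"] <- 0.195
  M["speed_l", "d_wmh"] <- -0.189
  M
}

default_change_cor <- function() {
  dv <- paste0("d_", c("tbv", "gm", "nawm", "wmh", "fluid", "memory", "speed"))
  R <- diag(7); dimnames(R) <- list(dv, dv)
  set2 <- function(a, b, x) { R[a, b] <<- x; R[b, a] <<- x }
  set2("d_gm", "d_nawm", 0.060); set2("d_gm", "d_wmh", -0.140)
  set2("d_nawm", "d_wmh", -0.384)
  set2("d_tbv", "d_fluid", 0.188); set2("d_tbv", "d_memory", -0.087)
  set2("d_tbv", "d_speed", 0.150)
  set2("d_gm", "d_fluid", 0.238); set2("d_gm", "d_memory", 0.041)
  set2("d_gm", "d_speed", 0.180)
  set2("d_nawm", "d_fluid", 0.189); set2("d_nawm", "d_memory", -0.054)
  set2("d_nawm", "d_speed", 0.200)
  set2("d_wmh", "d_fluid", -0.251); set2("d_wmh", "d_memory", -0.172)
  set2("d_wmh", "d_speed", -0.334)
  set2("d_fluid", "d_memory", 0.634); set2("d_fluid", "d_speed", 0.634)
  set2("d_memory", "d_speed", 0.634)
  R
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the published cohort structure: factor loadings and raw
#' wave-1 moments per test, wave-1 level correlations among the three
#' cognitive factors and four brain volumes, wave-to-wave stabilities,
#' level-change and change-change correlations, mean changes (cognition in
#' wave-1 SD units per year, volumes in cm3 across the study), sex offsets
#' for volumes, and the attrition/exclusion rates of the study. Change SDs
#' are derived so that the stability diagonal and the level-own-change
#' correlations both hold exactly. Unprinted couplings of total brain volume
#' with its component tissues are derived from volume additivity
#' (TBV ~ GM + NAWM + WMH); the remaining unprinted couplings are 0.
#'
#' The assembled core correlation matrix is checked for positive
#' definiteness and repaired with [Matrix::nearPD()] when needed; the maximum
#' absolute entry perturbation is recorded as `pd_adjustment`.
#'
#' @param level_cor 7x7 wave-1 level correlation matrix.
#' @param level_change_cor 7x7 matrix of level (rows) by change (columns)
#'   correlations.
#' @param change_cor 7x7 change correlation matrix.
#' @param stability named wave-to-wave correlations per variable.
#' @param change_mean_sd named mean change across the study interval, in
#'   wave-1 SD units (volumes filled in from `change_mean_raw`).
#' @param change_mean_raw named mean volume change across the study, cm3.
#' @param residual_cross_cor cross-wave correlation of each test's residual
#'   (retest correlation of the test-specific component).
#' @param years study interval in years.
#' @param p_male proportion male.
#' @param age_slope_sd_per_year additive age trends (SD per year of age)
#'   applied around each assessment's mean age.
#' @param attrition list: `cognitive` and `imaging` wave-2 dropout fractions,
#'   `imaging_w1` wave-1 imaging coverage, `slope` (log-odds of dropout per
#'   SD of lower wave-1 cognition).
#' @param exclusions list: `mmse_frac` below-24 fraction per wave,
#'   `dementia_frac` diagnosis fraction, and slopes on wave-1 cognition.
#' @param sex_coupling_delta optional named list of core correlations that
#'   differ by sex, e.g. `list("speed_l~d_tbv" = 0.15)` makes the male
#'   correlation exceed the female one by 0.15.
#' @param zero_coupling zero all brain-cognition level-change and
#'   change-change couplings (null generator for type-I calibration).
#' @param wmh_lognormal give WMH volumes a skewed (lognormal-shaped)
#'   marginal with the same mean/SD instead of a normal one.
#' @return A `generator_config` object.
#' @export
generator_config <- function(level_cor = default_level_cor(),
                             level_change_cor = default_level_change_cor(),
                             change_cor = default_change_cor(),
                             stability = c(tbv = 0.966, gm = 0.925,
                                           nawm = 0.949, wmh = 0.970,
                                           fluid = 0.969, memory = 0.896,
                                           speed = 0.867),
                             change_mean_sd = c(fluid = -0.074 * 3,
                                                memory = -0.058 * 3,
                                                speed = -0.147 * 3),
                             change_mean_raw = c(tbv = -19.12, gm = -9.28,
                                                 nawm = -14.46, wmh = 4.06),
                             residual_cross_cor = 0.3,
                             years = 3,
                             p_male = (866 - 337) / 866,
                             age_slope_sd_per_year = c(cognition = -0.05,
                                                       tbv = -0.05, gm = -0.05,
                                                       nawm = -0.05, wmh = 0.05),
                             attrition = list(cognitive = 169 / 866,
                                              imaging = 250 / 731,
                                              imaging_w1 = 657 / 866,
                                              slope = 0.9),
                             exclusions = list(mmse_frac = 16 / 697,
                                               mmse_slope = 1.0,
                                               dementia_frac = 25 / 697,
                                               dementia_slope = 1.5),
                             sex_coupling_delta = NULL,
                             zero_coupling = FALSE,
                             wmh_lognormal = FALSE) {
  reg <- battery_registry()
  vols <- reg$volumes$volume
  facs <- c("fluid", "memory", "speed")

  if (zero_coupling) {
    level_change_cor[c("tbv_l", "gm_l", "nawm_l", "wmh_l"),
                     paste0("d_", facs)] <- 0
    level_change_cor[paste0(facs, "_l"), paste0("d_", vols)] <- 0
    change_cor[paste0("d_", vols), paste0("d_", facs)] <- 0
    change_cor[paste0("d_", facs), paste0("d_", vols)] <- 0
  }

  # change SDs consistent with stability + level-own-change correlation
  own_r <- vapply(c(vols, facs), function(v)
    level_change_cor[paste0(v, "_l"), paste0("d_", v)], numeric(1))
  change_sd <- vapply(c(vols, facs), function(v)
    solve_change_sd(stability[[v]], own_r[[v]]), numeric(1))

  # published volume SDs pool the sexes; the generating (sex-residualized)
  # scale removes the additive sex-offset variance
  reg$volumes$sd_resid <- sqrt(reg$volumes$sd_w1^2 - p_male * (1 - p_male) *
                                 (reg$volumes$male_w1 - reg$volumes$female_w1)^2)

  # mean change in SD units; volumes converted from cm3 across study
  mean_sd <- c(change_mean_raw[vols] /
                 reg$volumes$sd_resid[match(vols, reg$volumes$volume)],
               change_mean_sd[facs])
  names(mean_sd) <- c(vols, facs)

  # TBV couplings implied by additivity TBV ~ GM + NAWM + WMH (only where
  # not printed: TBV appears in Model A only, components in Model B only)
  comp <- c("gm", "nawm", "wmh")
  sL <- reg$volumes$sd_resid[match(comp, reg$volumes$volume)]
  sD <- sL * change_sd[comp]
  Rll <- level_cor[paste0(comp, "_l"), paste0(comp, "_l")]
  Rdd <- change_cor[paste0("d_", comp), paste0("d_", comp)]
  Rld <- level_change_cor[paste0(comp, "_l"), paste0("d_", comp)]
  sd_sumL <- sqrt(drop(t(sL) %*% Rll %*% sL))
  sd_sumD <- sqrt(drop(t(sD) %*% Rdd %*% sD))
  for (j in seq_along(comp)) {
    if (change_cor["d_tbv", paste0("d_", comp[j])] == 0) {
      r <- drop(sD %*% Rdd[, j]) / (sd_sumD * sD[j])
      change_cor["d_tbv", paste0("d_", comp[j])] <- r
      change_cor[paste0("d_", comp[j]), "d_tbv"] <- r
    }
    if (level_change_cor["tbv_l", paste0("d_", comp[j])] == 0)
      level_change_cor["tbv_l", paste0("d_", comp[j])] <-
        drop(sL %*% Rld[, j]) / (sd_sumL * sD[j]) * sD[j]
    if (level_change_cor[paste0(comp[j], "_l"), "d_tbv"] == 0)
      level_change_cor[paste0(comp[j], "_l"), "d_tbv"] <-
        drop(Rld[j, ] %*% sD) / sd_sumD
  }

  cn <- core_names()
  R <- diag(14); dimnames(R) <- list(cn, cn)
  R[1:7, 1:7] <- level_cor[cn[1:7], cn[1:7]]
  R[8:14, 8:14] <- change_cor[cn[8:14], cn[8:14]]
  R[1:7, 8:14] <- level_change_cor[cn[1:7], cn[8:14]]
  R[8:14, 1:7] <- t(level_change_cor[cn[1:7], cn[8:14]])

  pd_adjustment <- 0
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    R2 <- as.matrix(Matrix::nearPD(R, corr = TRUE, keepDiag = TRUE,
                                   posd.tol = 1e-6)$mat)
    dimnames(R2) <- dimnames(R)
    pd_adjustment <- max(abs(R2 - R))
    message("core correlation matrix repaired to nearest PD (max entry ",
            "change ", signif(pd_adjustment, 3), ")")
    R <- R2
  }

  # residual variance per test from standardized loadings and wave-1 factor
  # correlations (1 - communality), rescaled to raw SD later
  Phi <- level_cor[paste0(facs, "_l"), paste0(facs, "_l")]
  theta <- numeric(nrow(reg$tests))
  for (k in seq_len(nrow(reg$tests))) {
    lam <- stats::setNames(numeric(3), facs)
    lam[reg$tests$factor[k]] <- reg$tests$loading[k]
    if (!is.na(reg$tests$cross_factor[k]))
      lam[reg$tests$cross_factor[k]] <- reg$tests$cross_loading[k]
    comm <- drop(lam %*% Phi %*% lam)
    if (comm >= 0.98) stop("communality >= 0.98 for ", reg$tests$test[k])
    theta[k] <- 1 - comm
  }

  structure(list(
    tests = reg$tests, volumes = reg$volumes,
    core_cor = R, change_sd = change_sd, change_mean_sd = mean_sd,
    stability = stability, residual_var = theta,
    residual_cross_cor = residual_cross_cor, years = years,
    p_male = p_male,
    ages = list(cog_w1 = c(72.49, 0.71), cog_w2 = c(76.25, 0.68),
                mri_w1 = c(72.68, 0.72), mri_w2 = c(76.38, 0.65)),
    age_slope_sd_per_year = age_slope_sd_per_year,
    attrition = attrition, exclusions = exclusions,
    sex_coupling_delta = sex_coupling_delta,
    wmh_lognormal = wmh_lognormal,
    pd_adjustment = pd_adjustment
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("generator_config: 12 tests x 2 waves, 4 volumes x 2 waves\n")
  cat("  change SDs (wave-1 SD units/study):",
      paste(names(x$change_sd), round(x$change_sd, 3), collapse = ", "), "\n")
  cat("  PD repair max entry change:", signif(x$pd_adjustment, 3), "\n")
  invisible(x)
}

cohort_observed_vars <- function(config) {
  c(wave_name(config$tests$test, "w1"), wave_name(config$tests$test, "w2"),
    wave_name(config$volumes$volume, "w1"), wave_name(config$volumes$volume, "w2"))
}

# loading matrix of the 32 observed variables on the 14 core variables, and
# residual covariance, on the standardized (wave-1 SD) scale
generator_structure <- function(config) {
  cn <- core_names()
  obs <- cohort_observed_vars(config)
  L <- matrix(0, length(obs), 14, dimnames = list(obs, cn))
  tests <- config$tests
  for (k in seq_len(nrow(tests))) {
    lv <- paste0(tests$factor[k], "_l"); dv <- paste0("d_", tests$factor[k])
    L[wave_name(tests$test[k], "w1"), lv] <- tests$loading[k]
    L[wave_name(tests$test[k], "w2"), lv] <- tests$loading[k]
    L[wave_name(tests$test[k], "w2"), dv] <- tests$loading[k]
    if (!is.na(tests$cross_factor[k])) {
      clv <- paste0(tests$cross_factor[k], "_l")
      cdv <- paste0("d_", tests$cross_factor[k])
      L[wave_name(tests$test[k], "w1"), clv] <- tests$cross_loading[k]
      L[wave_name(tests$test[k], "w2"), clv] <- tests$cross_loading[k]
      L[wave_name(tests$test[k], "w2"), cdv] <- tests$cross_loading[k]
    }
  }
  for (v in config$volumes$volume) {
    L[wave_name(v, "w1"), paste0(v, "_l")] <- 1
    L[wave_name(v, "w2"), paste0(v, "_l")] <- 1
    L[wave_name(v, "w2"), paste0("d_", v)] <- 1
  }
  Theta <- matrix(0, length(obs), length(obs), dimnames = list(obs, obs))
  for (k in seq_len(nrow(tests))) {
    t1 <- wave_name(tests$test[k], "w1"); t2 <- wave_name(tests$test[k], "w2")
    Theta[t1, t1] <- config$residual_var[k]
    Theta[t2, t2] <- config$residual_var[k]
    Theta[t1, t2] <- Theta[t2, t1] <-
      config$residual_cross_cor * config$residual_var[k]
  }
  raw_sd <- c(rep(tests$sd_w1, 2), rep(config$volumes$sd_resid, 2))
  raw_mean_w1 <- c(rep(tests$mean_w1, 2), rep(config$volumes$mean_w1, 2))
  names(raw_sd) <- names(raw_mean_w1) <- obs
  list(L = L, Theta = Theta, raw_sd = raw_sd, raw_mean_w1 = raw_mean_w1)
}

core_moments <- function(config) {
  D <- diag(c(rep(1, 7), config$change_sd[c("tbv", "gm", "nawm", "wmh",
                                            "fluid", "memory", "speed")]))
  Sigma <- D %*% config$core_cor %*% D
  dimnames(Sigma) <- dimnames(config$core_cor)
  mu <- stats::setNames(rep(0, 14), core_names())
  mu[paste0("d_", names(config$change_mean_sd))] <- config$change_mean_sd
  list(Sigma = Sigma, mu = mu)
}

#' Population moments of the synthetic cohort
#'
#' Exact population covariance matrix and mean vector of all observed
#' variables (12 tests and 4 volumes at two waves) implied by the generating
#' parameters, on the residualized (sex/age-adjusted) scale. This is computed
#' by direct factor algebra, independently of the RAM machinery, and must
#' agree with [implied_moments()] of the built models evaluated at the
#' generating parameters.
#'
#' @param config a `generator_config`.
#' @return list with `Sigma`, `mu`.
#' @export
population_moments <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  st <- generator_structure(config)
  cm <- core_moments(config)
  Sigma_std <- st$L %*% cm$Sigma %*% t(st$L) + st$Theta
  mu_std <- drop(st$L %*% cm$mu)
  D <- diag(st$raw_sd)
  Sigma <- D %*% Sigma_std %*% D
  dimnames(Sigma) <- dimnames(Sigma_std)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("population covariance not positive definite")
  list(Sigma = Sigma, mu = st$raw_mean_w1 + st$raw_sd * mu_std)
}

#' Simulate a two-wave synthetic cohort
#'
#' Draws the latent core variables and test residuals from the generating
#' multivariate normal model, assembles raw-scale observed variables, then
#' adds sex offsets (volumes, per wave) and small linear age-in-days trends.
#' Byte-identical output given the same seed. Wave-2 columns are complete;
#' use [apply_attrition()] for dropout and [flag_exclusions()] for MMSE and
#' dementia indicators.
#'
#' @param config a `generator_config`.
#' @param n number of subjects (>= 50).
#' @param seed integer seed.
#' @return A tibble (`id`, `sex` with 1 = male, ages in days, test and volume
#'   columns `*_w1`/`*_w2`, `mmse_w1`, `mmse_w2`, `dementia_dx`), with the
#'   generating config and latent core draws attached as attributes.
#' @export
simulate_cohort <- function(config, n, seed = 1) {
  stopifnot(inherits(config, "generator_config"), n >= 50)
  set.seed(seed)
  st <- generator_structure(config)
  cm <- core_moments(config)
  sex <- stats::rbinom(n, 1, config$p_male)

  core <- matrix(NA_real_, n, 14, dimnames = list(NULL, core_names()))
  delta <- config$sex_coupling_delta
  if (is.null(delta)) {
    core[] <- MASS::mvrnorm(n, cm$mu, cm$Sigma)
  } else {
    D <- diag(c(rep(1, 7), config$change_sd[c("tbv", "gm", "nawm", "wmh",
                                              "fluid", "memory", "speed")]))
    for (s in 0:1) {
      Rs <- config$core_cor
      for (nm in names(delta)) {
        pr <- strsplit(nm, "~", fixed = TRUE)[[1]]
        shift <- delta[[nm]] * (if (s == 1) 0.5 else -0.5)
        Rs[pr[1], pr[2]] <- Rs[pr[1], pr[2]] + shift
        Rs[pr[2], pr[1]] <- Rs[pr[1], pr[2]]
      }
      ev <- eigen(Rs, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-8)
        Rs <- as.matrix(Matrix::nearPD(Rs, corr = TRUE, keepDiag = TRUE)$mat)
      Ss <- D %*% Rs %*% D
      idx <- which(sex == s)
      if (length(idx))
        core[idx, ] <- MASS::mvrnorm(length(idx), cm$mu, Ss)
    }
  }

  obs <- cohort_observed_vars(config)
  X <- core %*% t(st$L)
  tests <- config$tests
  for (k in seq_len(nrow(tests))) {
    th <- config$residual_var[k]
    Sg <- matrix(c(th, config$residual_cross_cor * th,
                   config$residual_cross_cor * th, th), 2)
    E <- MASS::mvrnorm(n, c(0, 0), Sg)
    X[, wave_name(tests$test[k], "w1")] <- X[, wave_name(tests$test[k], "w1")] + E[, 1]
    X[, wave_name(tests$test[k], "w2")] <- X[, wave_name(tests$test[k], "w2")] + E[, 2]
  }
  if (config$wmh_lognormal) {
    # moment-matched skewed marginal on the standardized scale
    sg <- 0.6
    for (w in c("w1", "w2")) {
      v <- wave_name("wmh", w)
      m0 <- mean(X[, v]); s0 <- stats::sd(X[, v])
      z <- (X[, v] - m0) / s0
      X[, v] <- m0 + s0 * (exp(sg * z) - exp(sg^2 / 2)) /
        sqrt((exp(sg^2) - 1) * exp(sg^2))
    }
  }
  X <- sweep(sweep(X, 2L, st$raw_sd[obs], "*"), 2L, st$raw_mean_w1[obs], "+")

  ages <- lapply(config$ages, function(a)
    round(stats::rnorm(n, a[1] * 365.25, a[2] * 365.25)))
  # linear age trends around each assessment's mean age
  for (k in seq_len(nrow(tests))) {
    sl <- config$age_slope_sd_per_year[["cognition"]]
    for (w in c("w1", "w2")) {
      v <- wave_name(tests$test[k], w)
      agev <- ages[[paste0("cog_", w)]]
      X[, v] <- X[, v] + tests$sd_w1[k] * sl *
        (agev - mean(agev)) / 365.25
    }
  }
  for (j in seq_len(nrow(config$volumes))) {
    v0 <- config$volumes$volume[j]
    sl <- config$age_slope_sd_per_year[[v0]]
    for (w in c("w1", "w2")) {
      v <- wave_name(v0, w)
      agev <- ages[[paste0("mri_", w)]]
      X[, v] <- X[, v] + config$volumes$sd_w1[j] * sl *
        (agev - mean(agev)) / 365.25
    }
  }
  # additive sex offsets for volumes, wave-specific (males decline faster)
  for (j in seq_len(nrow(config$volumes))) {
    d1 <- config$volumes$male_w1[j] - config$volumes$female_w1[j]
    d2 <- config$volumes$male_w2[j] - config$volumes$female_w2[j]
    off1 <- ifelse(sex == 1, d1 * (1 - config$p_male), -d1 * config$p_male)
    off2 <- ifelse(sex == 1, d2 * (1 - config$p_male), -d2 * config$p_male)
    X[, wave_name(config$volumes$volume[j], "w1")] <-
      X[, wave_name(config$volumes$volume[j], "w1")] + off1
    X[, wave_name(config$volumes$volume[j], "w2")] <-
      X[, wave_name(config$volumes$volume[j], "w2")] + off2
  }

  cohort <- tibble::as_tibble(as.data.frame(X))
  cohort <- tibble::add_column(cohort, id = seq_len(n), sex = sex,
                               age_days_cog_w1 = ages$cog_w1,
                               age_days_cog_w2 = ages$cog_w2,
                               age_days_mri_w1 = ages$mri_w1,
                               age_days_mri_w2 = ages$mri_w2,
                               .before = 1)
  cohort$mmse_w1 <- NA_real_
  cohort$mmse_w2 <- NA_real_
  cohort$dementia_dx <- NA_integer_
  attr(cohort, "config") <- config
  attr(cohort, "seed") <- seed
  attr(cohort, "core") <- core
  cohort
}

# observed wave-1 cognitive composite (z-scored mean of the 12 wave-1 tests):
# a function of observed data only, so dropout driven by it is MAR
w1_composite <- function(cohort, config) {
  Z <- vapply(seq_len(nrow(config$tests)), function(k) {
    x <- cohort[[wave_name(config$tests$test[k], "w1")]]
    (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  }, numeric(nrow(cohort)))
  rowMeans(Z, na.rm = TRUE)
}

calibrate_intercept <- function(score, slope, target) {
  f <- function(a) mean(stats::plogis(a + slope * score)) - target
  stats::uniroot(f, c(-30, 30))$root
}

#' Apply wave-2 attrition to a synthetic cohort
#'
#' Masks wave-2 cognitive and imaging entries. Under `"MAR"` the dropout
#' probability follows a logistic model on the observed wave-1 cognitive
#' composite (lower cognition, more dropout), with the intercept calibrated
#' so the realized fraction matches the target; `"MCAR"` drops completely at
#' random. Wave-1 imaging coverage below 1 is always completely at random.
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @param mechanism `"MAR"` or `"MCAR"`.
#' @param seed integer seed.
#' @param fractions overrides for the config attrition fractions.
#' @return The cohort with wave-2 entries masked.
#' @export
apply_attrition <- function(cohort, mechanism = c("MAR", "MCAR"), seed = 1,
                            fractions = NULL) {
  mechanism <- match.arg(mechanism)
  config <- attr(cohort, "config")
  fr <- utils::modifyList(config$attrition, as.list(fractions %||% list()))
  for (f in c("cognitive", "imaging"))
    if (fr[[f]] < 0 || fr[[f]] >= 1) stop("dropout fraction out of (0,1): ", f)
  set.seed(seed)
  n <- nrow(cohort)
  score <- -w1_composite(cohort, config)  # higher score = lower cognition

  draw <- function(frac) {
    if (frac == 0) return(rep(FALSE, n))
    p <- if (mechanism == "MCAR") rep(frac, n)
    else stats::plogis(calibrate_intercept(score, fr$slope, frac) +
                         fr$slope * score)
    stats::runif(n) < p
  }
  drop_cog <- draw(fr$cognitive)
  no_mri_w1 <- stats::runif(n) > fr$imaging_w1
  drop_mri <- draw(fr$imaging) | no_mri_w1

  cog_w2 <- c(wave_name(config$tests$test, "w2"), "age_days_cog_w2", "mmse_w2")
  mri_w1 <- c(wave_name(config$volumes$volume, "w1"), "age_days_mri_w1")
  mri_w2 <- c(wave_name(config$volumes$volume, "w2"), "age_days_mri_w2")
  for (v in intersect(cog_w2, names(cohort))) cohort[[v]][drop_cog] <- NA
  for (v in mri_w1) cohort[[v]][no_mri_w1] <- NA
  for (v in mri_w2) cohort[[v]][drop_mri] <- NA
  attr(cohort, "attrition_applied") <- mechanism
  cohort
}

#' Simulate MMSE scores and dementia-diagnosis flags
#'
#' MMSE scores (0-30, ceiling-skewed) are generated from wave-specific fluid
#' intelligence so that a configurable small fraction falls below the
#' conventional screening cut-off of 24 at each wave; dementia diagnoses are
#' assigned by a logistic model on wave-1 cognition calibrated to the target
#' fraction. Flagged subjects therefore have below-average cognitive scores,
#' as in the cohort the generator emulates.
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @param seed integer seed.
#' @param fractions overrides for the config exclusion fractions.
#' @return The cohort with `mmse_w1`, `mmse_w2` and `dementia_dx` filled in.
#' @export
flag_exclusions <- function(cohort, seed = 1, fractions = NULL) {
  config <- attr(cohort, "config")
  ex <- utils::modifyList(config$exclusions, as.list(fractions %||% list()))
  set.seed(seed)
  core <- attr(cohort, "core")
  n <- nrow(cohort)
  fluid_w <- list(w1 = core[, "fluid_l"],
                  w2 = core[, "fluid_l"] + core[, "d_fluid"])
  for (w in c("w1", "w2")) {
    y <- ex$mmse_slope * fluid_w[[w]] + stats::rnorm(n)
    z <- (y - mean(y)) / stats::sd(y)
    if (ex$mmse_frac <= 0) {
      mmse <- pmin(30, pmax(24, round(27.6 + 1.6 * z)))
    } else {
      thr <- stats::quantile(z, ex$mmse_frac)
      mmse <- ifelse(z < thr,
                     pmax(0, pmin(23, round(21.5 + 1.5 * (z - thr)))),
                     pmin(30, pmax(24, round(27.6 + 1.6 * z))))
    }
    keep_na <- is.na(cohort[[wave_name(c("matrix_reasoning"), w)]])
    mmse[keep_na] <- NA
    cohort[[paste0("mmse_", w)]] <- mmse
  }
  score <- -w1_composite(cohort, config)
  if (ex$dementia_frac <= 0) {
    cohort$dementia_dx <- 0L
  } else {
    a <- calibrate_intercept(score, ex$dementia_slope, ex$dementia_frac)
    p <- stats::plogis(a + ex$dementia_slope * score)
    cohort$dementia_dx <- as.integer(stats::runif(n) < p)
  }
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generating parameter values for a built model
#'
#' Maps the generator configuration onto the free parameters of
#' [build_lds_model()] (reference parameterization), giving the population
#' parameter vector at which the model's implied moments equal
#' [population_moments()]. Used to verify the generator-model closure and as
#' the truth column of recovery experiments.
#'
#' @param config a `generator_config`.
#' @param spec a reference-parameterized model from [build_lds_model()].
#' @return named numeric vector over [free_labels()] of the spec.
#' @export
generating_theta <- function(config, spec) {
  stopifnot(identical(attr(spec, "parameterization"), "reference"))
  tests <- config$tests
  facs <- c("fluid", "memory", "speed")
  vols <- if (attr(spec, "brain") == "A") "tbv" else c("gm", "nawm", "wmh")
  ref <- vapply(facs, function(f) tests$test[tests$factor == f][1], character(1))
  # raw factor scale: the reference indicator's loading times its SD
  kap <- vapply(facs, function(f) {
    k <- match(ref[[f]], tests$test)
    tests$loading[k] * tests$sd_w1[k]
  }, numeric(1))
  vol_sd <- stats::setNames(config$volumes$sd_resid, config$volumes$volume)
  core_sd <- c(stats::setNames(vol_sd[vols], paste0(vols, "_w1")),
               stats::setNames(kap, paste0(facs, "_w1")),
               stats::setNames(c(vol_sd[vols] * config$change_sd[vols],
                                 kap * config$change_sd[facs]),
                               paste0("d_", c(vols, facs))))
  core_key <- c(stats::setNames(paste0(vols, "_l"), paste0(vols, "_w1")),
                stats::setNames(paste0(facs, "_l"), paste0(facs, "_w1")),
                stats::setNames(paste0("d_", c(vols, facs)),
                                paste0("d_", c(vols, facs))))
  th <- stats::setNames(rep(NA_real_, length(free_labels(spec))),
                        free_labels(spec))
  for (k in seq_len(nrow(tests))) {
    t0 <- tests$test[k]; f0 <- tests$factor[k]
    lab <- paste0("l_", t0, ".", f0)
    if (lab %in% names(th))
      th[lab] <- tests$loading[k] * tests$sd_w1[k] / kap[[f0]]
    if (!is.na(tests$cross_factor[k])) {
      clab <- paste0("l_", t0, ".", tests$cross_factor[k])
      th[clab] <- tests$cross_loading[k] * tests$sd_w1[k] /
        kap[[tests$cross_factor[k]]]
    }
    th[paste0("i_", t0)] <- tests$mean_w1[k]
    rv <- config$residual_var[k] * tests$sd_w1[k]^2
    th[paste0("rv_", t0, "_w1")] <- rv
    th[paste0("rv_", t0, "_w2")] <- rv
    rc <- paste0("rc_", t0)
    if (rc %in% names(th)) th[rc] <- config$residual_cross_cor *
        config$residual_var[k] * tests$sd_w1[k]^2
  }
  for (f in facs) th[paste0("v_", f, "_w1")] <- kap[[f]]^2
  for (v in vols) {
    th[paste0("v_", v)] <- vol_sd[[v]]^2
    th[paste0("m_", v)] <- config$volumes$mean_w1[match(v, config$volumes$volume)]
  }
  for (x in c(vols, facs)) {
    th[paste0("v_d_", x)] <- core_sd[[paste0("d_", x)]]^2
    th[paste0("m_d_", x)] <- config$change_mean_sd[[x]] *
      (if (x %in% facs) kap[[x]] else vol_sd[[x]])
  }
  # all remaining labels are core covariances, c_<a>.<b> with sorted names
  for (lab in names(th)[is.na(th)]) {
    pr <- strsplit(sub("^c_", "", lab), ".", fixed = TRUE)[[1]]
    if (length(pr) != 2 || !all(pr %in% names(core_key)))
      stop("unmapped generating parameter: ", lab)
    th[lab] <- config$core_cor[core_key[[pr[1]]], core_key[[pr[2]]]] *
      core_sd[[pr[1]]] * core_sd[[pr[2]]]
  }
  th
}

#' Write a cohort, its configuration and seed manifest to a directory
#'
#' @param cohort a cohort tibble.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  config <- attr(cohort, "config")
  cfg <- lapply(config, function(x) {
    if (is.matrix(x)) apply(x, 1, as.list, simplify = FALSE)
    else if (is.data.frame(x)) as.list(x)
    else x
  })
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  jsonlite::write_json(list(seed = attr(cohort, "seed"), n = nrow(cohort)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
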