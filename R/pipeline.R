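# Full analysis pipeline: residualize -> fit -> correlation families -> FDR,
# plus equality tests on the correlation metric, sex-moderation regressions,
# and simulate->fit parameter-recovery experiments.

model_core_vars <- function(brain, parameterization = "reference") {
  vols <- if (brain == "A") "tbv" else c("gm", "nawm", "wmh")
  facs <- c("fluid", "memory", "speed")
  lev_model <- c(if (parameterization == "standardized") paste0("lv_", vols)
                 else wave_name(vols, "w1"), wave_name(facs, "w1"))
  lev_core <- c(paste0(vols, "_l"), paste0(facs, "_l"))
  d <- paste0("d_", c(vols, facs))
  list(vols = vols, facs = facs,
       levels = stats::setNames(lev_model, lev_core),
       deltas = stats::setNames(d, d))
}

# label of the model parameter holding cov(a, b), a/b in core naming
model_cov_label <- function(brain, a, b, parameterization = "reference") {
  mv <- model_core_vars(brain, parameterization)
  map <- c(mv$levels, mv$deltas)
  if (!all(c(a, b) %in% names(map)))
    stop("unknown core variable(s): ", a, ", ", b)
  canon_cov_label(map[[a]], map[[b]])
}

sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

family_table <- function(std, brain, set1, set2, parameterization = "reference") {
  rows <- list()
  done <- character()
  for (a in set1) for (b in set2) {
    if (a == b) next
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% done) next
    done <- c(done, key)
    lab <- model_cov_label(brain, a, b, parameterization)
    i <- match(lab, std$label)
    if (is.na(i)) next
    rows[[length(rows) + 1L]] <-
      tibble::tibble(var1 = a, var2 = b, label = lab, est = std$std_est[i],
                     se = std$std_se[i], z = std$z[i], p = std$p[i])
  }
  do.call(rbind, rows)
}

#' Implied wave-to-wave stability correlations
#'
#' Model-implied correlation between the wave-1 and wave-2 versions of each
#' level variable (manifest volumes and latent cognitive factors).
#'
#' @param fit an `lds_fit` of a model from [build_lds_model()].
#' @return named numeric vector.
#' @export
implied_stabilities <- function(fit) {
  mom <- implied_moments(fit$spec, fit$theta)
  vars <- fit$ram$vars
  base <- unique(sub("_w1$", "", grep("_w1$", vars, value = TRUE)))
  base <- base[paste0(base, "_w2") %in% vars]
  out <- vapply(base, function(b) {
    S <- mom$Sigma_full
    S[paste0(b, "_w1"), paste0(b, "_w2")] /
      sqrt(S[paste0(b, "_w1"), paste0(b, "_w1")] *
             S[paste0(b, "_w2"), paste0(b, "_w2")])
  }, numeric(1))
  facs_vols <- c("tbv", "gm", "nawm", "wmh", "fluid", "memory", "speed")
  out[intersect(facs_vols, names(out))]
}

#' Run the full coupled-change analysis on a cohort
#'
#' Residualizes all battery variables for sex and age, fits the latent
#' difference score model by FIML, and assembles the correlation report:
#' level-level, level-change and change-change standardized estimates with
#' raw and (per model, pooled across the three families) FDR-adjusted
#' p-values, annualized volume-change metrics, cognitive decline in SD/year,
#' implied stabilities, and fit indices.
#'
#' @param data cohort data frame (see [simulate_cohort()] for the schema).
#' @param model `"A"` (total brain volume) or `"B"` (tissue volumes).
#' @param complete_cases drop rows with any missing model variable.
#' @param exclusion `"none"`, `"mmse"` (drop subjects scoring below 24 at
#'   either wave) or `"diagnosis"` (drop subjects with a dementia diagnosis).
#' @param years study interval for annualization.
#' @param se compute standard errors (needed for p-values).
#' @param starts,seed,tol passed to [fit_model()].
#' @return A `correlation_report` object.
#' @export
run_analysis <- function(data, model = c("A", "B"), complete_cases = FALSE,
                         exclusion = c("none", "mmse", "diagnosis"),
                         years = 3, se = TRUE, starts = 5, seed = 1,
                         tol = 1e-4) {
  model <- match.arg(model)
  exclusion <- match.arg(exclusion)
  data <- as.data.frame(data)
  n0 <- nrow(data)
  if (exclusion == "mmse") {
    low <- (!is.na(data$mmse_w1) & data$mmse_w1 < 24) |
      (!is.na(data$mmse_w2) & data$mmse_w2 < 24)
    data <- data[!low, , drop = FALSE]
  } else if (exclusion == "diagnosis") {
    dx <- !is.na(data$dementia_dx) & data$dementia_dx == 1
    data <- data[!dx, , drop = FALSE]
  }
  spec <- build_lds_model(model, parameterization = "reference")
  obs_vars <- spec$variables$name[spec$variables$role == "observed"]
  if (complete_cases)
    data <- data[stats::complete.cases(data[, obs_vars]), , drop = FALSE]
  if (nrow(data) < 100)
    warning("fewer than 100 subjects after exclusions (n = ", nrow(data), ")")

  raw <- data
  data <- residualize(data, vars = intersect(covariate_map()$variable,
                                             names(data)))
  fit <- fit_model(spec, data, starts = starts, seed = seed, tol = tol, se = se)
  if (!fit$converged)
    warning("model did not converge (max |grad| = ", signif(fit$gradnorm, 3),
            "); estimates may be unreliable")
  std <- standardized_solution(fit)
  mv <- model_core_vars(model)
  lev <- names(mv$levels); del <- names(mv$deltas)
  ll <- family_table(std, model, lev, lev)
  lc <- family_table(std, model, lev, del)
  cc <- family_table(std, model, del, del)
  fam <- rbind(cbind(family = "level_level", ll),
               cbind(family = "level_change", lc),
               cbind(family = "change_change", cc))
  fam$p_fdr <- bh_fdr(fam$p)
  fam$sig <- sig_stars(fam$p)
  fam <- tibble::as_tibble(fam)

  # annualized volume changes: raw wave-1 sample moments, model mean change
  vols <- mv$vols
  ann <- do.call(rbind, lapply(vols, function(v) {
    x1 <- raw[[wave_name(v, "w1")]]
    a <- annualized_change(fit$theta[[paste0("m_d_", v)]],
                           mean(x1, na.rm = TRUE), stats::sd(x1, na.rm = TRUE),
                           years)
    tibble::tibble(volume = v, mean_change = fit$theta[[paste0("m_d_", v)]],
                   per_year = a$per_year, sd_per_year = a$sd_per_year,
                   pct_per_year = a$pct_per_year)
  }))
  # cognitive decline in wave-1 factor-SD units per year
  mom <- implied_moments(fit$spec, fit$theta)
  cog <- do.call(rbind, lapply(mv$facs, function(f) {
    sd1 <- sqrt(mom$Sigma_full[wave_name(f, "w1"), wave_name(f, "w1")])
    m <- fit$theta[[paste0("m_d_", f)]]
    tibble::tibble(factor = f, mean_change = m,
                   sd_per_year = m / sd1 / years,
                   decline_sd_per_year = -m / sd1 / years)
  }))

  structure(list(
    model = model, correlations = fam,
    level_level = fam[fam$family == "level_level", ],
    level_change = fam[fam$family == "level_change", ],
    change_change = fam[fam$family == "change_change", ],
    annualized = ann, cognitive_change = cog,
    stabilities = implied_stabilities(fit),
    fit = fit, fit_indices = fit_indices(fit),
    n = fit$n, n_input = n0, exclusion = exclusion,
    complete_cases = complete_cases, seed = seed
  ), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("correlation_report (Model ", x$model, "), n = ", x$n,
      ", exclusion = ", x$exclusion, "\n", sep = "")
  fi <- x$fit_indices
  cat(sprintf("  chisq(%d) = %.3f, RMSEA = %.3f, CFI = %.3f, TLI = %.3f\n",
              fi$df, fi$chisq, fi$rmsea, fi$cfi, fi$tli))
  cat("  change-change correlations:\n")
  cc <- x$change_change
  for (i in seq_len(nrow(cc)))
    cat(sprintf("    %-9s ~ %-9s  r = %6.3f (%.3f)%s  p_fdr = %.3f\n",
                cc$var1[i], cc$var2[i], cc$est[i], cc$se[i], cc$sig[i],
                cc$p_fdr[i]))
  invisible(x)
}

#' Equality tests of coupling correlations
#'
#' For each requested pair of couplings, refits the model in the
#' standardized parameterization (unit-variance levels and changes, so the
#' coupling parameters are correlations), once freely and once with the two
#' correlations constrained equal, and reports the 1-df chi-squared
#' difference test. When `pairs` is omitted they are selected by the rule of
#' testing only where at least one member is significant at raw p < .05:
#' couplings of the same brain change with different cognitive domains, and
#' (Model B) of the same cognitive change with different tissues.
#'
#' @param data cohort data frame.
#' @param model `"A"` or `"B"`.
#' @param pairs list of character 4-vectors `c(a1, b1, a2, b2)` in core
#'   naming, comparing cor(a1, b1) with cor(a2, b2).
#' @param starts,seed,tol passed to [fit_model()].
#' @return tibble with one row per pair: estimates, `chisq_diff`, `df_diff`,
#'   `p`.
#' @export
equality_tests <- function(data, model = c("A", "B"), pairs = NULL,
                           starts = 2, seed = 1, tol = 1e-4) {
  model <- match.arg(model)
  data <- residualize(as.data.frame(data),
                      vars = intersect(covariate_map()$variable, names(data)))
  spec <- build_lds_model(model, parameterization = "standardized")
  fit_free <- fit_model(spec, data, starts = starts, seed = seed, tol = tol,
                        se = TRUE)
  std <- standardized_solution(fit_free)
  mv <- model_core_vars(model, "standardized")

  if (is.null(pairs)) {
    pairs <- list()
    est_p <- function(a, b) {
      i <- match(model_cov_label(model, a, b, "standardized"), std$label)
      std$p[i]
    }
    add_pairs <- function(target, others) {
      for (i in seq_len(length(others) - 1)) for (j in seq(i + 1, length(others))) {
        if (min(est_p(others[i], target), est_p(others[j], target),
                na.rm = TRUE) < 0.05)
          pairs[[length(pairs) + 1L]] <<- c(others[i], target, others[j], target)
      }
    }
    cogs_l <- paste0(mv$facs, "_l"); cogs_d <- paste0("d_", mv$facs)
    for (v in mv$vols) {
      add_pairs(paste0("d_", v), cogs_l)   # level-change, cognition -> brain
      add_pairs(paste0("d_", v), cogs_d)   # change-change
    }
    if (length(mv$vols) > 1) {
      for (f in mv$facs) {
        add_pairs(paste0("d_", f), paste0(mv$vols, "_l"))
        add_pairs(paste0("d_", f), paste0("d_", mv$vols))
      }
    }
  }

  out <- lapply(pairs, function(pr) {
    l1 <- model_cov_label(model, pr[1], pr[2], "standardized")
    l2 <- model_cov_label(model, pr[3], pr[4], "standardized")
    if (l1 == l2)
      return(tibble::tibble(cor1 = paste(pr[1], pr[2], sep = "~"),
                            cor2 = paste(pr[3], pr[4], sep = "~"),
                            est1 = std$std_est[match(l1, std$label)],
                            est2 = std$std_est[match(l2, std$label)],
                            chisq_diff = 0, df_diff = 0L, p = 1))
    cons <- constrain_equal(spec, c(l1, l2))
    start <- fit_free$theta
    start[l1] <- mean(start[c(l1, l2)])
    start <- start[setdiff(names(start), l2)]
    fit_c <- fit_model(cons, data, starts = starts, seed = seed, tol = tol,
                       se = FALSE, start = start)
    nt <- nested_diff_test(fit_free, fit_c)
    tibble::tibble(cor1 = paste(pr[1], pr[2], sep = "~"),
                   cor2 = paste(pr[3], pr[4], sep = "~"),
                   est1 = std$std_est[match(l1, std$label)],
                   est2 = std$std_est[match(l2, std$label)],
                   chisq_diff = nt$chisq_diff, df_diff = nt$df_diff, p = nt$p)
  })
  do.call(rbind, out)
}

# Bartlett factor scores for the three cognitive factors at one wave
bartlett_scores <- function(fit, data, wave) {
  tests <- battery_registry()$tests
  facs <- c("fluid", "memory", "speed")
  pt <- parameter_table(fit)
  Lam <- matrix(0, nrow(tests), 3,
                dimnames = list(wave_name(tests$test, wave), facs))
  nu <- numeric(nrow(tests))
  Th <- numeric(nrow(tests))
  for (k in seq_len(nrow(tests))) {
    v <- wave_name(tests$test[k], wave)
    for (f in facs) {
      i <- which(pt$lhs == wave_name(f, wave) & pt$op == "->" & pt$rhs == v)
      if (length(i)) Lam[v, f] <- pt$est[i]
    }
    nu[k] <- pt$est[pt$lhs == v & pt$op == "~1"]
    Th[k] <- pt$est[pt$lhs == v & pt$op == "~~" & pt$rhs == v]
  }
  X <- as.matrix(data[, rownames(Lam), drop = FALSE])
  ok <- stats::complete.cases(X)
  Xc <- sweep(X[ok, , drop = FALSE], 2L, nu)
  W <- solve(crossprod(Lam, Lam / Th)) %*% t(Lam / Th)
  out <- matrix(NA_real_, nrow(data), 3, dimnames = list(NULL, facs))
  out[ok, ] <- Xc %*% t(W)
  out
}

#' Sex moderation of a coupling via factor-score regression
#'
#' Tests whether sex moderates a level-to-change coupling by regressing the
#' outcome change score on the predictor, sex, and their product, using data
#' residualized for age only. Latent quantities enter as Bartlett factor
#' scores (an approximation that attenuates interaction effects slightly,
#' compared with latent product modeling). Predictor and outcome are
#' z-standardized, so the interaction coefficient is the male-female
#' difference in standardized slopes.
#'
#' @param data cohort data frame (with `sex`, 1 = male).
#' @param predictor wave-1 level in core naming (e.g. `"speed_l"`,
#'   `"tbv_l"`).
#' @param outcome_change change variable in core naming (e.g. `"d_tbv"`).
#' @param fit optional `lds_fit` providing the measurement parameters; fitted
#'   on the age-residualized data when omitted.
#' @param starts,seed passed to [fit_model()] when `fit` is omitted.
#' @return list with `beta_interaction`, `se`, `p`, `n`.
#' @export
sex_moderation <- function(data, predictor, outcome_change, fit = NULL,
                           starts = 2, seed = 1) {
  data <- as.data.frame(data)
  if (length(unique(stats::na.omit(data$sex))) < 2)
    stop("sex moderation needs both sexes in the data")
  rdat <- residualize(data, vars = intersect(covariate_map()$variable,
                                             names(data)),
                      include_sex = FALSE)
  vols <- c("tbv", "gm", "nawm", "wmh")
  needs_scores <- function(v) !(sub("^(d_|)(.*?)(_l|)$", "\\2", v) %in% vols)
  if (is.null(fit) && (needs_scores(predictor) || needs_scores(outcome_change))) {
    brain <- if (grepl("tbv", predictor) || grepl("tbv", outcome_change)) "A"
             else "B"
    fit <- fit_model(build_lds_model(brain), rdat, starts = starts,
                     seed = seed, se = FALSE)
  }
  value_of <- function(v) {
    base <- sub("^(d_)?(.*?)(_l)?$", "\\2", v)
    is_change <- startsWith(v, "d_")
    if (base %in% vols) {
      if (is_change) rdat[[wave_name(base, "w2")]] - rdat[[wave_name(base, "w1")]]
      else rdat[[wave_name(base, "w1")]]
    } else {
      s1 <- bartlett_scores(fit, rdat, "w1")[, base]
      if (is_change) bartlett_scores(fit, rdat, "w2")[, base] - s1 else s1
    }
  }
  pr <- value_of(predictor)
  out <- value_of(outcome_change)
  ok <- stats::complete.cases(pr, out, data$sex)
  z <- function(x) (x - mean(x)) / stats::sd(x)
  d <- data.frame(y = z(out[ok]), x = z(pr[ok]), sex = data$sex[ok])
  m <- stats::lm(y ~ x * sex, data = d)
  cf <- summary(m)$coefficients
  list(beta_interaction = cf["x:sex", "Estimate"],
       se = cf["x:sex", "Std. Error"], p = cf["x:sex", "Pr(>|t|)"],
       n = nrow(d))
}

#' Simulate-and-refit parameter recovery experiment
#'
#' Repeatedly simulates cohorts from a generator configuration, runs the
#' analysis pipeline, and summarizes recovery of the generating coupling
#' correlations: truth, mean estimate, empirical SE, bias, and (when
#' standard errors are computed) coverage of nominal 95% Wald intervals.
#'
#' @param config a `generator_config`.
#' @param n subjects per replicate.
#' @param seed master seed; replicate r uses `seed + r`.
#' @param reps number of replicates.
#' @param model `"A"` or `"B"`.
#' @param params core covariance pairs to track, as a list of
#'   `c(var1, var2)`; defaults to all level/change couplings of the model.
#' @param se compute coverage from per-replicate standard errors.
#' @param starts passed to [fit_model()].
#' @return tibble: one row per tracked parameter.
#' @export
recovery_experiment <- function(config, n, seed = 1, reps = 10,
                                model = c("A", "B"), params = NULL, se = TRUE,
                                starts = 2) {
  model <- match.arg(model)
  mv <- model_core_vars(model)
  core <- c(names(mv$levels), names(mv$deltas))
  if (is.null(params)) {
    params <- list()
    for (i in seq_len(length(core) - 1)) for (j in seq(i + 1, length(core)))
      params[[length(params) + 1L]] <- c(core[i], core[j])
  }
  truth <- vapply(params, function(pr)
    config$core_cor[pr[1], pr[2]], numeric(1))
  nm <- vapply(params, paste, character(1), collapse = "~")
  est <- matrix(NA_real_, reps, length(params), dimnames = list(NULL, nm))
  ses <- est
  for (r in seq_len(reps)) {
    cohort <- simulate_cohort(config, n, seed = seed + r)
    rep_fit <- run_analysis(cohort, model = model, se = se, starts = starts,
                            seed = seed + r)
    std <- standardized_solution(rep_fit$fit)
    for (k in seq_along(params)) {
      lab <- model_cov_label(model, params[[k]][1], params[[k]][2])
      i <- match(lab, std$label)
      est[r, k] <- std$std_est[i]
      ses[r, k] <- std$std_se[i]
    }
  }
  cover <- if (se) colMeans(abs(sweep(est, 2, truth)) <= 1.96 * ses) else NA
  tibble::tibble(param = nm, truth = truth,
                 mean_est = colMeans(est),
                 emp_se = apply(est, 2, stats::sd),
                 bias = colMeans(est) - truth,
                 coverage = cover)
}
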