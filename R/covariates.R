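# Pre-model covariate adjustment, group comparisons, annualized change.

#' Default variable-to-covariate mapping for the two-wave battery
#'
#' Cognitive test scores are adjusted for age in days at cognitive testing of
#' their wave; brain volumes for age in days at MRI scanning of their wave.
#'
#' @return data frame with columns `variable`, `age_var`.
#' @export
covariate_map <- function() {
  reg <- battery_registry()
  rbind(
    data.frame(variable = c(wave_name(reg$tests$test, "w1"),
                            wave_name(reg$tests$test, "w2")),
               age_var = rep(c("age_days_cog_w1", "age_days_cog_w2"),
                             each = nrow(reg$tests)),
               stringsAsFactors = FALSE),
    data.frame(variable = c(wave_name(reg$volumes$volume, "w1"),
                            wave_name(reg$volumes$volume, "w2")),
               age_var = rep(c("age_days_mri_w1", "age_days_mri_w2"),
                             each = nrow(reg$volumes)),
               stringsAsFactors = FALSE))
}

#' Residualize variables for sex and age
#'
#' Replaces each variable by its available-case least-squares residual from a
#' linear regression on age (in days, wave- and modality-matched) and
#' optionally sex. Missing entries stay missing. By default each variable
#' keeps its available-case mean so the longitudinal mean structure (and thus
#' estimated mean change) survives adjustment; `center = TRUE` returns plain
#' zero-mean residuals.
#'
#' @param data data frame containing the variables, their age covariates and
#'   (if used) `sex`.
#' @param vars variables to residualize; defaults to all battery variables
#'   present in `data`.
#' @param map variable-to-age-covariate mapping (see [covariate_map()]).
#' @param include_sex adjust for sex as well as age (sex-difference analyses
#'   adjust for age only).
#' @param center return zero-mean residuals instead of mean-preserving ones.
#' @return `data` with the named variables replaced by residuals.
#' @export
residualize <- function(data, vars = NULL, map = covariate_map(),
                        include_sex = TRUE, center = FALSE) {
  data <- as.data.frame(data)
  if (is.null(vars)) vars <- intersect(map$variable, names(data))
  bad <- setdiff(vars, map$variable)
  if (length(bad)) stop("no covariate mapping for: ", paste(bad, collapse = ", "))
  for (v in vars) {
    av <- map$age_var[match(v, map$variable)]
    need <- c(av, if (include_sex) "sex")
    miss <- setdiff(need, names(data))
    if (length(miss)) stop("data lack covariate(s): ", paste(miss, collapse = ", "))
    obs <- !is.na(data[[v]])
    if (!any(obs)) next
    Z <- cbind(1, as.matrix(data[obs, need, drop = FALSE]))
    storage.mode(Z) <- "double"
    if (anyNA(Z)) stop("covariate missing where ", v, " is observed")
    if (any(apply(Z[, -1, drop = FALSE], 2, stats::sd) == 0))
      stop("constant covariate while residualizing ", v)
    r <- stats::lm.fit(Z, data[[v]][obs])$residuals
    data[[v]][obs] <- r + if (center) 0 else mean(data[[v]][obs])
  }
  data
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' (via [stats::t.test()]), as used for returner versus non-returner and sex
#' comparisons.
#'
#' @param group_a,group_b numeric vectors (`NA` dropped).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    stop("both groups have zero variance; t undefined")
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Annualized change metrics
#'
#' Converts a model-estimated mean change across the study into per-year
#' units: raw change per year, change per year in baseline-SD units, and
#' percent of the baseline mean per year. Baseline moments are the raw wave-1
#' sample mean and SD. All metrics are linear in `mean_change_total`;
#' vectorized over all arguments.
#'
#' @param mean_change_total estimated mean change across the study interval.
#' @param baseline_mean,baseline_sd raw wave-1 mean and SD.
#' @param years nominal study interval in years (default 3).
#' @return tibble with `per_year`, `sd_per_year`, `pct_per_year`.
#' @export
annualized_change <- function(mean_change_total, baseline_mean, baseline_sd,
                              years = 3) {
  stopifnot(all(years > 0), all(baseline_mean != 0), all(baseline_sd > 0))
  per_year <- mean_change_total / years
  tibble::tibble(per_year = per_year,
                 sd_per_year = per_year / baseline_sd,
                 pct_per_year = 100 * per_year / baseline_mean)
}
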