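# Fit indices, nested-model chi-squared tests, and FDR correction.

#' Likelihood-ratio chi-square of a covariance-structure model
#'
#' `T = 2 (loglik_sat - loglik_model)`, referred to a chi-square distribution
#' with the model degrees of freedom.
#'
#' @param model_loglik,saturated_loglik log-likelihoods on the same data.
#' @param df model degrees of freedom.
#' @return list with `T` and `p`.
#' @export
model_chisq <- function(model_loglik, saturated_loglik, df) {
  T <- 2 * (saturated_loglik - model_loglik)
  if (T < -1e-6 * max(1, abs(saturated_loglik)))
    stop("negative chi-square: saturated log-likelihood below model ",
         "log-likelihood beyond tolerance (numerical failure)")
  T <- max(T, 0)
  list(T = T, p = stats::pchisq(T, df, lower.tail = FALSE))
}

#' Root mean square error of approximation
#'
#' `sqrt(max(T - df, 0) / (df * n))`.
#'
#' @param T likelihood-ratio chi-square.
#' @param df model degrees of freedom.
#' @param n analysis sample size.
#' @return RMSEA (scalar).
#' @export
rmsea <- function(T, df, n) {
  stopifnot(df > 0, n > 0)
  sqrt(pmax(T - df, 0) / (df * n))
}

#' Comparative fit index and Tucker-Lewis index
#'
#' Incremental fit relative to an independence baseline:
#' `CFI = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)` and
#' `TLI = (T_b/df_b - T/df) / (T_b/df_b - 1)`.
#'
#' @param T,df model chi-square and degrees of freedom.
#' @param T_b,df_b baseline chi-square and degrees of freedom.
#' @return list with `cfi` and `tli` (`tli` is `NA` when `df = 0`).
#' @export
cfi_tli <- function(T, df, T_b, df_b) {
  stopifnot(df_b > df)
  num <- max(T - df, 0)
  den <- max(T_b - df_b, T - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (df == 0) NA_real_
         else (T_b / df_b - T / df) / (T_b / df_b - 1)
  list(cfi = cfi, tli = tli)
}

#' Fit indices of a fitted model
#'
#' @param fit an `lds_fit`.
#' @param n override the sample size used by RMSEA (defaults to the fitted n).
#' @return list with `chisq`, `df`, `p`, `rmsea`, `cfi`, `tli`, `n`,
#'   `baseline_chisq`, `baseline_df`.
#' @export
fit_indices <- function(fit, n = NULL) {
  stopifnot(inherits(fit, "lds_fit"))
  if (is.null(n)) n <- fit$n
  p <- length(fit$ram$obs)
  cs <- model_chisq(fit$loglik, fit$loglik_sat, fit$df)
  df_b <- p * (p + 1) / 2 + p - fit$baseline_free
  T_b <- 2 * (fit$loglik_sat - fit$loglik_baseline)
  ct <- cfi_tli(cs$T, fit$df, T_b, df_b)
  list(chisq = cs$T, df = fit$df, p = cs$p,
       rmsea = rmsea(cs$T, fit$df, n), cfi = ct$cfi, tli = ct$tli, n = n,
       baseline_chisq = T_b, baseline_df = df_b)
}

#' Write a fit summary as JSON
#'
#' @param fit an `lds_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  jsonlite::write_json(fit_indices(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Chi-squared difference test of nested models
#'
#' Compares an equality-constrained model against the model it nests in,
#' fitted to identical data.
#'
#' @param fit_free the unconstrained fit.
#' @param fit_constrained the constrained (nested) fit.
#' @return list with `chisq_diff`, `df_diff`, `p`.
#' @export
nested_diff_test <- function(fit_free, fit_constrained) {
  stopifnot(inherits(fit_free, "lds_fit"), inherits(fit_constrained, "lds_fit"))
  if (fit_free$n != fit_constrained$n)
    stop("fits use different sample sizes; not comparable")
  if (!setequal(fit_free$ram$vars[fit_free$ram$obs],
                fit_constrained$ram$vars[fit_constrained$ram$obs]))
    stop("fits use different observed variables; not nested")
  ddf <- fit_constrained$df - fit_free$df
  if (ddf < 0)
    stop("constrained model has fewer df than the free model; ",
         "arguments swapped or models not nested")
  dchi <- 2 * (fit_free$loglik - fit_constrained$loglik)
  if (dchi < -1e-4 * max(1, abs(fit_free$loglik)))
    stop("constrained model fits better than the free model; not nested ",
         "or optimization failed")
  dchi <- max(dchi, 0)
  p <- if (ddf == 0) 1 else stats::pchisq(dchi, ddf, lower.tail = FALSE)
  list(chisq_diff = dchi, df_diff = ddf, p = p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]), capped at 1, input
#' order preserved.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}
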