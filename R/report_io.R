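# Report and data export.

#' Write a residualized data matrix as CSV with a provenance header
#'
#' Mirrors the input schema; the first line is a `#`-prefixed provenance
#' comment recording the adjustment applied.
#'
#' @param data a data frame from [residualize()].
#' @param path output file.
#' @param note provenance note to embed.
#' @return `path`, invisibly.
#' @export
write_residualized <- function(data, path,
                               note = "residualized for sex and age (days)") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ldscoupling ", utils::packageVersion("ldscoupling"),
                    ": ", note), con)
  utils::write.csv(as.data.frame(data), con, row.names = FALSE)
  invisible(path)
}

#' Write a correlation report to a directory
#'
#' Emits the correlation families and annualized change tables as CSV, the
#' fit summary as JSON, and a short Markdown summary.
#'
#' @param report a `correlation_report` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "correlation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report$correlations),
                   file.path(dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$annualized),
                   file.path(dir, "annualized_change.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$cognitive_change),
                   file.path(dir, "cognitive_change.csv"), row.names = FALSE)
  write_parameter_table(report$fit, file.path(dir, "parameters.csv"))
  write_fit_summary(report$fit, file.path(dir, "fit.json"))
  fi <- report$fit_indices
  md <- c(
    paste0("# Coupled change analysis, Model ", report$model),
    "",
    paste0("n = ", report$n, "; exclusion = ", report$exclusion,
           "; complete cases = ", report$complete_cases),
    sprintf("chisq(%d) = %.3f, RMSEA = %.3f, CFI = %.3f, TLI = %.3f",
            fi$df, fi$chisq, fi$rmsea, fi$cfi, fi$tli),
    "",
    "Stars follow raw p (*, **, *** at .05/.01/.001); the adjacent column",
    "holds Benjamini-Hochberg adjusted p-values pooled over the level-level,",
    "level-change and change-change families of this model.",
    "",
    "| family | var1 | var2 | r | se | p | p_fdr | sig |",
    "|---|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %.3f | %.3f | %.4f | %.4f | %s |",
            report$correlations$family, report$correlations$var1,
            report$correlations$var2, report$correlations$est,
            report$correlations$se, report$correlations$p,
            report$correlations$p_fdr, report$correlations$sig),
    "",
    paste("Sex-moderation analyses in this package use factor-score product",
          "regression, which slightly attenuates interaction estimates",
          "relative to latent product modeling."))
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}
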