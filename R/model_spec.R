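#' @title Declarative covariance-structure model specifications
#' @description
#' A `model_spec` is a labelled path model over a set of observed and latent
#' variables: directed paths, (co)variances, and means, each either fixed to a
#' value or free with a parameter label. Equality constraints are expressed by
#' sharing a label. The spec compiles to RAM matrices (see [implied_moments()]):
#' \deqn{\Sigma = F (I - A)^{-1} S (I - A)^{-T} F^T, \quad \mu = F (I - A)^{-1} m.}
#' @name model_spec
NULL

new_model_spec <- function() {
  structure(list(
    variables = data.frame(name = character(), role = character(),
                           stringsAsFactors = FALSE),
    paths = data.frame(from = character(), to = character(),
                       label = character(), value = numeric(), free = logical(),
                       stringsAsFactors = FALSE),
    covs = data.frame(var1 = character(), var2 = character(),
                      label = character(), value = numeric(), free = logical(),
                      stringsAsFactors = FALSE),
    means = data.frame(var = character(), label = character(),
                       value = numeric(), free = logical(),
                       stringsAsFactors = FALSE)
  ), class = "model_spec")
}

#' Create an empty model specification
#'
#' @param observed character vector of observed variable names.
#' @param latent character vector of latent variable names.
#' @return A `model_spec` object.
#' @export
model_spec <- function(observed = character(), latent = character()) {
  spec <- new_model_spec()
  spec <- add_variables(spec, observed, "observed")
  spec <- add_variables(spec, latent, "latent")
  spec
}

add_variables <- function(spec, names, role) {
  if (!length(names)) return(spec)
  dup <- intersect(names, spec$variables$name)
  if (length(dup)) stop("variable(s) already declared: ", paste(dup, collapse = ", "))
  if (anyDuplicated(names)) stop("duplicate variable names")
  spec$variables <- rbind(spec$variables,
                          data.frame(name = names, role = role,
                                     stringsAsFactors = FALSE))
  spec
}

check_vars <- function(spec, ...) {
  v <- c(...)
  bad <- setdiff(v, spec$variables$name)
  if (length(bad)) stop("undeclared variable(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

entry <- function(label, fixed, start) {
  if (is.null(fixed)) {
    if (is.null(label)) stop("a free parameter needs a label")
    data.frame(label = label, value = if (is.null(start)) NA_real_ else start,
               free = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(label = NA_character_, value = fixed, free = FALSE,
               stringsAsFactors = FALSE)
  }
}

#' Add a directed path to a model specification
#'
#' @param spec a `model_spec`.
#' @param from,to variable names (the path points `from -> to`).
#' @param label parameter label for a free coefficient; shared labels impose
#'   equality.
#' @param fixed fixed numeric value; exactly one of `label`/`fixed` is used.
#' @param start optional starting value for a free coefficient.
#' @return The updated `model_spec`.
#' @export
add_path <- function(spec, from, to, label = NULL, fixed = NULL, start = NULL) {
  check_vars(spec, from, to)
  if (any(spec$paths$from == from & spec$paths$to == to))
    stop("duplicate path: ", from, " -> ", to)
  spec$paths <- rbind(spec$paths, cbind(data.frame(from = from, to = to,
                                                   stringsAsFactors = FALSE),
                                        entry(label, fixed, start)))
  spec
}

#' Add a covariance (or variance) to a model specification
#'
#' Covariances are symmetric by construction; `add_cov(spec, a, b, ...)` and
#' `add_cov(spec, b, a, ...)` refer to the same entry. `var1 == var2` declares
#' a variance (for endogenous variables, a residual variance).
#'
#' @inheritParams add_path
#' @param var1,var2 variable names.
#' @param replace replace an existing entry instead of erroring.
#' @return The updated `model_spec`.
#' @export
add_cov <- function(spec, var1, var2, label = NULL, fixed = NULL, start = NULL,
                    replace = FALSE) {
  check_vars(spec, var1, var2)
  hit <- (spec$covs$var1 == var1 & spec$covs$var2 == var2) |
         (spec$covs$var1 == var2 & spec$covs$var2 == var1)
  if (any(hit)) {
    if (!replace) stop("duplicate covariance: ", var1, " ~~ ", var2)
    spec$covs <- spec$covs[!hit, , drop = FALSE]
  }
  spec$covs <- rbind(spec$covs, cbind(data.frame(var1 = var1, var2 = var2,
                                                 stringsAsFactors = FALSE),
                                      entry(label, fixed, start)))
  spec
}

#' Add a mean (intercept) to a model specification
#'
#' @inheritParams add_path
#' @param var variable name.
#' @param replace replace an existing entry instead of erroring.
#' @return The updated `model_spec`.
#' @export
add_mean <- function(spec, var, label = NULL, fixed = NULL, start = NULL,
                     replace = FALSE) {
  check_vars(spec, var)
  hit <- spec$means$var == var
  if (any(hit)) {
    if (!replace) stop("duplicate mean entry: ", var)
    spec$means <- spec$means[!hit, , drop = FALSE]
  }
  spec$means <- rbind(spec$means, cbind(data.frame(var = var,
                                                   stringsAsFactors = FALSE),
                                        entry(label, fixed, start)))
  spec
}

spec_labels <- function(spec) {
  c(spec$paths$label[spec$paths$free],
    spec$covs$label[spec$covs$free],
    spec$means$label[spec$means$free])
}

#' Distinct free parameter labels of a specification
#'
#' Labels are returned in order of first appearance (paths, then covariances,
#' then means), the order used for the parameter vector theta.
#'
#' @param spec a `model_spec`.
#' @return character vector of labels.
#' @export
free_labels <- function(spec) unique(spec_labels(spec))

#' Number of observed variables of a specification
#' @param spec a `model_spec`.
#' @return integer count.
#' @export
n_observed <- function(spec) sum(spec$variables$role == "observed")

#' Model degrees of freedom
#'
#' Observed moments (variances, covariances and means: `p(p+1)/2 + p`) minus
#' the number of distinct free parameter labels.
#'
#' @param spec a `model_spec`.
#' @return integer degrees of freedom.
#' @export
degrees_of_freedom <- function(spec) {
  p <- n_observed(spec)
  df <- p * (p + 1) / 2 + p - length(free_labels(spec))
  if (df < 0) stop("negative degrees of freedom: model is under-identified (",
                   length(free_labels(spec)), " free parameters, ",
                   p * (p + 1) / 2 + p, " observed moments)")
  as.integer(df)
}

#' Constrain a set of free parameters to equality
#'
#' All listed labels are replaced by the first, so the named parameters share
#' one free value; the free-parameter count drops by `length(labels) - 1`.
#'
#' @param spec a `model_spec`.
#' @param labels character vector of existing free-parameter labels.
#' @return The updated `model_spec`.
#' @export
constrain_equal <- function(spec, labels) {
  stopifnot(is.character(labels), length(labels) >= 1)
  known <- free_labels(spec)
  bad <- setdiff(labels, known)
  if (length(bad)) stop("unknown or fixed parameter label(s): ",
                        paste(bad, collapse = ", "))
  keep <- labels[1]
  relabel <- function(x) { x$label[x$free & x$label %in% labels] <- keep; x }
  spec$paths <- relabel(spec$paths)
  spec$covs <- relabel(spec$covs)
  spec$means <- relabel(spec$means)
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", sum(x$variables$role == "observed"), "observed,",
      sum(x$variables$role == "latent"), "latent variables\n")
  cat("  ", nrow(x$paths), "paths,", nrow(x$covs), "covariances,",
      nrow(x$means), "means;", length(free_labels(x)), "free parameters, df =",
      tryCatch(degrees_of_freedom(x), error = function(e) NA), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Variable registry for the two-wave brain/cognition battery
# ---------------------------------------------------------------------------

#' Registry of the two-wave cognitive test battery and brain volumes
#'
#' Twelve cognitive tests indicating three latent domains (fluid intelligence,
#' memory, processing speed; two paper-and-pencil speed tests cross-load on
#' fluid intelligence) and four brain tissue volumes, each measured at two
#' waves (mean ages 73 and 76). Loadings, means and SDs are the published
#' wave-1 cohort values used as generator defaults.
#'
#' @return A list with data frames `tests` (test, factor, loading, cross-factor
#'   loading, wave-1 mean/SD) and `volumes` (volume, wave-1/2 overall means and
#'   SDs and male/female means per wave).
#' @export
battery_registry <- function() {
  tests <- data.frame(
    test = c("matrix_reasoning", "block_design", "digit_span_back",
             "letter_number", "logical_memory", "verbal_pairs", "spatial_span",
             "digit_symbol", "symbol_search", "simple_rt", "choice_rt",
             "inspection_time"),
    factor = c("fluid", "fluid", "fluid", "fluid",
               "memory", "memory", "memory",
               "speed", "speed", "speed", "speed", "speed"),
    loading = c(0.651, 0.672, 0.582, 0.649,
                0.629, 0.572, 0.532,
                0.521, 0.427, 0.509, 0.795, 0.523),
    cross_factor = c(NA, NA, NA, NA, NA, NA, NA,
                     "fluid", "fluid", NA, NA, NA),
    cross_loading = c(NA, NA, NA, NA, NA, NA, NA,
                      0.316, 0.384, NA, NA, NA),
    mean_w1 = c(13.17, 33.64, 7.81, 10.91, 74.23, 27.18, 14.70,
                56.40, 24.61, 0.275, 0.649, 111.22),
    sd_w1 = c(4.96, 10.08, 2.29, 3.08, 17.90, 9.46, 2.76,
              12.31, 6.18, 0.052, 0.089, 11.79),
    stringsAsFactors = FALSE)
  # reaction-time and inspection-time scores are reflected so that higher
  # always means better performance; loadings are reported on that scale
  volumes <- data.frame(
    volume = c("tbv", "gm", "nawm", "wmh"),
    mean_w1 = c(990.32, 472.43, 476.89, 12.23),
    sd_w1 = c(89.40, 44.68, 50.55, 12.18),
    mean_w2 = c(975.49, 465.67, 464.25, 15.85),
    sd_w2 = c(90.49, 43.61, 53.10, 14.57),
    male_w1 = c(1038.59, 496.57, 501.13, 12.00),
    male_w2 = c(1022.97, 487.25, 490.28, 16.05),
    female_w1 = c(934.62, 444.57, 448.91, 12.49),
    female_w2 = c(919.53, 440.54, 433.94, 15.61),
    stringsAsFactors = FALSE)
  list(tests = tests, volumes = volumes)
}

wave_name <- function(base, wave) paste0(base, "_", wave)
canon_cov_label <- function(a, b) paste0("c_", paste(sort(c(a, b)), collapse = "."))

# ---------------------------------------------------------------------------
# Builders
# ---------------------------------------------------------------------------

#' Build a two-wave confirmatory factor (measurement) model
#'
#' One latent factor per entry of `indicator_map` at each wave, indicated by
#' the same tests at both waves. Identification fixes the first loading of
#' each factor to 1 (reference-indicator scaling) or, with
#' `parameterization = "standardized"`, fixes the factor variance to 1 and
#' frees all loadings. With `invariance = TRUE` (strong measurement
#' invariance) loadings and indicator intercepts share labels across waves.
#'
#' @param indicator_map named list: factor name -> character vector of test
#'   base names (wave suffixes `_w1`/`_w2` are appended).
#' @param cross_loadings optional data frame with columns `test`, `factor` for
#'   additional loadings.
#' @param invariance logical; share loading/intercept labels across waves.
#' @param residual_cov logical; free the cross-wave residual covariance of
#'   each test (correlated uniquenesses, standard for repeated indicators).
#' @param covary which factor covariances to free: `"all"` (saturated),
#'   `"wave1"` (wave-1 factors only), or `"none"`.
#' @param parameterization `"reference"` or `"standardized"`.
#' @param waves wave suffixes.
#' @return A `model_spec`.
#' @export
build_measurement_model <- function(indicator_map, cross_loadings = NULL,
                                    invariance = TRUE, residual_cov = TRUE,
                                    covary = c("all", "wave1", "none"),
                                    parameterization = c("reference", "standardized"),
                                    waves = c("w1", "w2")) {
  covary <- match.arg(covary)
  parameterization <- match.arg(parameterization)
  stopifnot(is.list(indicator_map), !is.null(names(indicator_map)))
  all_tests <- unlist(indicator_map, use.names = FALSE)
  if (anyDuplicated(all_tests)) stop("a test may indicate only one primary factor")
  if (!is.null(cross_loadings)) {
    stopifnot(all(c("test", "factor") %in% names(cross_loadings)))
    bad <- setdiff(cross_loadings$test, all_tests)
    if (length(bad)) stop("unknown test name(s) in cross_loadings: ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(cross_loadings$factor, names(indicator_map))
    if (length(bad)) stop("unknown factor(s) in cross_loadings: ",
                          paste(bad, collapse = ", "))
  }
  n_ind <- vapply(names(indicator_map), function(f) {
    length(indicator_map[[f]]) +
      if (is.null(cross_loadings)) 0L else sum(cross_loadings$factor == f)
  }, integer(1))
  if (any(n_ind < 2))
    stop("factor(s) with fewer than 2 indicators cannot be identified: ",
         paste(names(indicator_map)[n_ind < 2], collapse = ", "))

  obs <- as.vector(vapply(waves, function(w) wave_name(all_tests, w),
                          character(length(all_tests))))
  lat <- as.vector(vapply(waves, function(w) wave_name(names(indicator_map), w),
                          character(length(indicator_map))))
  spec <- model_spec(observed = obs, latent = lat)

  load_label <- function(test, factor, w) {
    if (invariance) paste0("l_", test, ".", factor)
    else paste0("l_", test, ".", factor, "_", w)
  }
  int_label <- function(test, w) {
    if (invariance) paste0("i_", test) else paste0("i_", test, "_", w)
  }

  for (w in waves) {
    for (f in names(indicator_map)) {
      fac <- wave_name(f, w)
      ind <- indicator_map[[f]]
      for (k in seq_along(ind)) {
        v <- wave_name(ind[k], w)
        if (k == 1L && parameterization == "reference")
          spec <- add_path(spec, fac, v, fixed = 1)
        else
          spec <- add_path(spec, fac, v, label = load_label(ind[k], f, w))
      }
      if (parameterization == "standardized")
        spec <- add_cov(spec, fac, fac, fixed = 1)
      else
        spec <- add_cov(spec, fac, fac, label = paste0("v_", fac))
      spec <- add_mean(spec, fac, fixed = 0)
    }
    if (!is.null(cross_loadings)) {
      for (k in seq_len(nrow(cross_loadings))) {
        spec <- add_path(spec, wave_name(cross_loadings$factor[k], w),
                         wave_name(cross_loadings$test[k], w),
                         label = load_label(cross_loadings$test[k],
                                            cross_loadings$factor[k], w))
      }
    }
    for (t in all_tests) {
      v <- wave_name(t, w)
      spec <- add_cov(spec, v, v, label = paste0("rv_", v))
      spec <- add_mean(spec, v, label = int_label(t, w))
    }
  }
  if (residual_cov && length(waves) == 2) {
    for (t in all_tests)
      spec <- add_cov(spec, wave_name(t, waves[1]), wave_name(t, waves[2]),
                      label = paste0("rc_", t))
  }
  fac_sets <- switch(covary,
    all = list(lat),
    wave1 = list(wave_name(names(indicator_map), waves[1])),
    none = list())
  for (vs in fac_sets) spec <- covary_all(spec, vs)
  spec
}

#' Free all pairwise covariances among a set of variables
#'
#' Adds a labelled free covariance for every pair not already present.
#'
#' @param spec a `model_spec`.
#' @param vars variable names.
#' @return The updated `model_spec`.
#' @export
covary_all <- function(spec, vars) {
  check_vars(spec, vars)
  if (length(vars) < 2) return(spec)
  for (i in seq_len(length(vars) - 1)) {
    for (j in seq(i + 1, length(vars))) {
      hit <- (spec$covs$var1 == vars[i] & spec$covs$var2 == vars[j]) |
             (spec$covs$var1 == vars[j] & spec$covs$var2 == vars[i])
      if (!any(hit))
        spec <- add_cov(spec, vars[i], vars[j],
                        label = canon_cov_label(vars[i], vars[j]))
    }
  }
  spec
}

#' Add a latent change (difference) score between two waves
#'
#' Adds a latent variable `change_name` defined so that
#' `var_wave2 = var_wave1 + change` exactly: the paths
#' `var_wave1 -> var_wave2` and `change -> var_wave2` are fixed to 1 and the
#' wave-2 residual variance and intercept are fixed to 0. The change score
#' gets a free mean and variance (or, with
#' `parameterization = "standardized"`, unit variance and a free scale path)
#' and a free covariance with the wave-1 level. Any previously free variance,
#' mean, or covariances of `var_wave2` are removed: its moments are now
#' structural.
#'
#' @param spec a `model_spec`.
#' @param var_wave1,var_wave2 the two waves of the variable (observed or
#'   latent).
#' @param change_name name for the new latent change variable.
#' @param parameterization `"reference"` (unit path, free change variance) or
#'   `"standardized"` (unit change variance, free scale path).
#' @return The updated `model_spec`.
#' @export
add_latent_change <- function(spec, var_wave1, var_wave2, change_name,
                              parameterization = c("reference", "standardized"),
                              level_var = var_wave1) {
  parameterization <- match.arg(parameterization)
  check_vars(spec, var_wave1, var_wave2)
  if (change_name %in% spec$variables$name)
    stop("change variable name already in use: ", change_name)
  if (any(spec$paths$from == var_wave1 & spec$paths$to == var_wave2))
    stop("duplicate path: a change score for ", var_wave1, " -> ", var_wave2,
         " already exists")
  spec <- add_variables(spec, change_name, "latent")
  spec <- add_path(spec, var_wave1, var_wave2, fixed = 1)
  # wave-2 moments become structural
  drop <- (spec$covs$var1 == var_wave2 | spec$covs$var2 == var_wave2)
  spec$covs <- spec$covs[!drop, , drop = FALSE]
  spec <- add_cov(spec, var_wave2, var_wave2, fixed = 0)
  spec <- add_mean(spec, var_wave2, fixed = 0, replace = TRUE)
  if (parameterization == "reference") {
    spec <- add_path(spec, change_name, var_wave2, fixed = 1)
    spec <- add_cov(spec, change_name, change_name,
                    label = paste0("v_", change_name))
  } else {
    spec <- add_path(spec, change_name, var_wave2,
                     label = paste0("s_", change_name))
    spec <- add_cov(spec, change_name, change_name, fixed = 1)
  }
  spec <- add_mean(spec, change_name, label = paste0("m_", change_name))
  spec <- add_cov(spec, level_var, change_name,
                  label = canon_cov_label(level_var, change_name))
  spec
}

add_manifest_volume <- function(spec, vol, parameterization, waves = c("w1", "w2")) {
  v1 <- wave_name(vol, waves[1]); v2 <- wave_name(vol, waves[2])
  spec <- add_variables(spec, c(v1, v2), "observed")
  if (parameterization == "standardized") {
    # phantom standardized level so level covariances are correlations
    lv <- paste0("lv_", vol)
    spec <- add_variables(spec, lv, "latent")
    spec <- add_path(spec, lv, v1, label = paste0("s_lv_", vol))
    spec <- add_cov(spec, lv, lv, fixed = 1)
    spec <- add_cov(spec, v1, v1, fixed = 0)
    spec <- add_mean(spec, lv, fixed = 0)
  } else {
    spec <- add_cov(spec, v1, v1, label = paste0("v_", vol))
  }
  spec <- add_mean(spec, v1, label = paste0("m_", vol))
  spec <- add_mean(spec, v2, label = "tmp_drop")  # replaced by add_latent_change
  spec <- add_cov(spec, v2, v2, label = "tmp_drop_v")
  spec
}

#' Build the coupled latent difference score model
#'
#' Constructs the full two-wave model coupling brain volume change with change
#' in three latent cognitive domains. Model A includes total brain volume as
#' the single (manifest) brain variable; Model B includes grey matter,
#' normal-appearing white matter, and white matter hyperintensity volumes.
#' All wave-1 levels and all latent change scores are freely intercorrelated,
#' which houses the level-change and change-change couplings of interest.
#'
#' @param brain `"A"` (total brain volume) or `"B"` (grey matter, NAWM, WMH).
#' @param parameterization `"reference"` fixes the first loading of each
#'   factor to 1 and frees variances (the scale on which raw estimates are
#'   reported); `"standardized"` gives every exogenous level and change
#'   variable unit variance so that their covariances are correlations,
#'   the parameterization used for equality constraints on correlations.
#' @param residual_cov free cross-wave residual covariances of each test.
#' @param invariance strong measurement invariance (equal loadings and
#'   intercepts across waves).
#' @return A `model_spec`.
#' @export
build_lds_model <- function(brain = c("A", "B"),
                            parameterization = c("reference", "standardized"),
                            residual_cov = TRUE, invariance = TRUE) {
  brain <- match.arg(brain)
  parameterization <- match.arg(parameterization)
  reg <- battery_registry()
  vols <- if (brain == "A") "tbv" else c("gm", "nawm", "wmh")
  ind <- split(reg$tests$test, reg$tests$factor)[c("fluid", "memory", "speed")]
  cross <- with(reg$tests, data.frame(test = test[!is.na(cross_factor)],
                                      factor = cross_factor[!is.na(cross_factor)],
                                      stringsAsFactors = FALSE))
  spec <- build_measurement_model(ind, cross_loadings = cross,
                                  invariance = invariance,
                                  residual_cov = residual_cov,
                                  covary = "none",
                                  parameterization = parameterization)
  for (v in vols) spec <- add_manifest_volume(spec, v, parameterization)
  # clean the placeholder wave-2 volume entries
  spec$means <- spec$means[!(spec$means$free & spec$means$label == "tmp_drop"), , drop = FALSE]
  spec$covs <- spec$covs[!(spec$covs$free & spec$covs$label == "tmp_drop_v"), , drop = FALSE]
  for (f in c("fluid", "memory", "speed"))
    spec <- add_latent_change(spec, wave_name(f, "w1"), wave_name(f, "w2"),
                              paste0("d_", f), parameterization)
  for (v in vols)
    spec <- add_latent_change(spec, wave_name(v, "w1"), wave_name(v, "w2"),
                              paste0("d_", v), parameterization,
                              level_var = if (parameterization == "standardized")
                                paste0("lv_", v) else wave_name(v, "w1"))
  levels1 <- c(if (parameterization == "standardized") paste0("lv_", vols)
               else wave_name(vols, "w1"),
               wave_name(c("fluid", "memory", "speed"), "w1"))
  deltas <- paste0("d_", c(vols, "fluid", "memory", "speed"))
  spec <- covary_all(spec, c(levels1, deltas))
  attr(spec, "brain") <- brain
  attr(spec, "parameterization") <- parameterization
  spec
}

#' @rdname build_lds_model
#' @param ... passed to [build_lds_model()].
#' @export
build_model_A <- function(...) build_lds_model("A", ...)

#' @rdname build_lds_model
#' @export
build_model_B <- function(...) build_lds_model("B", ...)

# ---------------------------------------------------------------------------
# Serialization
# ---------------------------------------------------------------------------

spec_to_list <- function(spec) {
  ent <- function(d, keys) {
    lapply(seq_len(nrow(d)), function(i) {
      e <- as.list(d[i, keys, drop = FALSE])
      if (d$free[i]) {
        e$label <- d$label[i]
        if (!is.na(d$value[i])) e$start <- d$value[i]
      } else e$fixed <- d$value[i]
      e
    })
  }
  list(variables = lapply(seq_len(nrow(spec$variables)),
                          function(i) as.list(spec$variables[i, ])),
       paths = ent(spec$paths, c("from", "to")),
       covs = ent(spec$covs, c("var1", "var2")),
       means = ent(spec$means, "var"))
}

#' Write a model specification to YAML
#'
#' The YAML dialect has top-level keys `variables:`, `paths:`, `covs:` and
#' `means:`; each entry carries either `label:` (with optional `start:`) or
#' `fixed:`. Round-trips exactly, including shared labels.
#'
#' @param spec a `model_spec`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  yaml::write_yaml(spec_to_list(spec), path, precision = 15)
  invisible(path)
}

#' Read a model specification from YAML
#'
#' @param path file path written by [write_model_spec()].
#' @return A `model_spec`.
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- new_model_spec()
  for (v in x$variables) spec <- add_variables(spec, v$name, v$role)
  geta <- function(e) list(label = e$label, fixed = e$fixed, start = e$start)
  for (e in x$paths) {
    a <- geta(e)
    spec <- add_path(spec, e$from, e$to, label = a$label, fixed = a$fixed,
                     start = a$start)
  }
  for (e in x$covs) {
    a <- geta(e)
    spec <- add_cov(spec, e$var1, e$var2, label = a$label, fixed = a$fixed,
                    start = a$start)
  }
  for (e in x$means) {
    a <- geta(e)
    spec <- add_mean(spec, e$var, label = a$label, fixed = a$fixed,
                     start = a$start)
  }
  spec
}
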