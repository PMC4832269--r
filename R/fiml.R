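# Full-information maximum likelihood machinery for multivariate normal data
# with arbitrary missingness. Rows are grouped by missing-data pattern and each
# pattern is summarized by (n, mean, scatter), so the casewise likelihood
#   ll = sum_i -1/2 [ k_i log 2pi + log det Sigma_(i)
#                     + (x_i - mu_(i))' Sigma_(i)^-1 (x_i - mu_(i)) ]
# costs one Cholesky factorization per pattern, not per row.

pattern_stats <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  obs <- !is.na(X)
  all_missing <- rowSums(obs) == 0L
  n_dropped <- sum(all_missing)
  if (n_dropped) {
    X <- X[!all_missing, , drop = FALSE]
    obs <- obs[!all_missing, , drop = FALSE]
  }
  if (!nrow(X)) stop("no rows with at least one observed value")
  key <- apply(obs, 1L, function(r) rawToChar(as.raw(44L + r)))
  groups <- split(seq_len(nrow(X)), key)
  pats <- lapply(groups, function(rows) {
    o <- which(obs[rows[1L], ])
    Xo <- X[rows, o, drop = FALSE]
    n <- length(rows)
    mu <- colMeans(Xo)
    Xc <- sweep(Xo, 2L, mu)
    list(obs = o, n = n, mean = mu, scatter = crossprod(Xc) / n)
  })
  structure(pats, n = nrow(X), p = ncol(X), n_dropped = n_dropped,
            n_obs_cells = colSums(obs))
}

# loglik (and optionally its moment-space gradient) given observed Sigma, mu
mvn_pattern_loglik <- function(Sigma, mu, pats, grad = FALSE) {
  p <- attr(pats, "p")
  ll <- 0
  if (grad) { Gsig <- matrix(0, p, p); gmu <- numeric(p) }
  for (pt in pats) {
    o <- pt$obs; k <- length(o)
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    d <- pt$mean - mu[o]
    W <- pt$scatter + tcrossprod(d)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    ll <- ll - 0.5 * pt$n * (k * log(2 * pi) + logdet + sum(Sinv * W))
    if (grad) {
      # gradient of f = -2*ll with respect to Sigma_obs and mu_obs
      G <- pt$n * (Sinv - Sinv %*% W %*% Sinv)
      Gsig[o, o] <- Gsig[o, o] + G
      gmu[o] <- gmu[o] - 2 * pt$n * drop(Sinv %*% d)
    }
  }
  if (grad) list(ll = ll, Gsig = Gsig, gmu = gmu) else list(ll = ll)
}

#' Casewise (FIML) log-likelihood of a model at a parameter vector
#'
#' Each row contributes the multivariate normal log-density of its observed
#' subset under the model-implied moments; rows with no observed values are
#' dropped.
#'
#' @param spec a `model_spec`.
#' @param theta named free-parameter vector (see [implied_moments()]).
#' @param data data frame or matrix containing the spec's observed variables;
#'   `NA` marks missing entries.
#' @return the log-likelihood (scalar).
#' @export
fiml_loglik <- function(spec, theta, data) {
  ram <- compile_ram(spec)
  X <- extract_data(data, ram$vars[ram$obs])
  pats <- pattern_stats(X)
  mom <- ram_moments(ram, align_theta(ram, theta))
  res <- mvn_pattern_loglik(mom$Sigma, mom$mu, pats)
  if (!is.finite(res$ll))
    stop("implied covariance is not positive definite for an observed pattern")
  res$ll
}

extract_data <- function(data, vars) {
  if (is.matrix(data)) {
    miss <- setdiff(vars, colnames(data))
  } else {
    miss <- setdiff(vars, names(data))
  }
  if (length(miss)) stop("data lack model variable(s): ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(data)[, vars, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

# ---------------------------------------------------------------------------
# Saturated (unrestricted) model under missingness: EM for the MVN MLE
# ---------------------------------------------------------------------------

#' Saturated log-likelihood of incomplete multivariate normal data
#'
#' Maximum-likelihood mean vector and covariance matrix (denominator `n`) of
#' the observed data under an unrestricted multivariate normal model, via the
#' EM algorithm iterated to a relative log-likelihood change below `tol`.
#' With complete data this equals the closed-form sample moments in one step.
#' This likelihood anchors the model chi-square: `T = 2 (ll_sat - ll_model)`.
#'
#' @param data data frame or matrix; `NA` marks missing entries.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `loglik`, `mu`, `Sigma`, `n`, `iterations`.
#' @export
saturated_loglik <- function(data, tol = 1e-10, max_iter = 10000) {
  X <- as.matrix(as.data.frame(data))
  storage.mode(X) <- "double"
  pats <- pattern_stats(X)
  if (any(attr(pats, "n_obs_cells") < 2L))
    stop("variable(s) observed in fewer than 2 rows: ",
         paste(colnames(X)[attr(pats, "n_obs_cells") < 2L], collapse = ", "))
  res <- saturated_loglik_pats(pats, tol = tol, max_iter = max_iter)
  dimnames(res$Sigma) <- list(colnames(X), colnames(X))
  names(res$mu) <- colnames(X)
  res
}

# Independence (baseline) model under FIML: the likelihood factorizes, so the
# MLE is the univariate available-case MLE per variable.
baseline_loglik <- function(pats) {
  p <- attr(pats, "p")
  sums <- numeric(p); sqs <- numeric(p); ns <- numeric(p)
  for (pt in pats) {
    o <- pt$obs
    ns[o] <- ns[o] + pt$n
    sums[o] <- sums[o] + pt$n * pt$mean
    sqs[o] <- sqs[o] + pt$n * (diag(pt$scatter) + pt$mean^2)
  }
  mu <- sums / ns
  v <- sqs / ns - mu^2
  ll <- sum(-0.5 * ns * (log(2 * pi) + log(v) + 1))
  list(loglik = ll, mu = mu, var = v, n_free = 2L * p)
}
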