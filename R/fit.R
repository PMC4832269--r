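# FIML estimation of a model_spec.
#
# The optimizer works on internally rescaled data (each observed variable
# divided by its pooled SD, wave pairs pooled) so the problem is
# well-conditioned regardless of raw units; estimates are mapped back exactly,
# since the model class is closed under per-variable rescaling. Variances are
# optimized on the log scale; covariances and paths are untransformed.

# scale of each variable: observed -> its data scale; latents inherit the
# scale of the observed variable they reach through fixed unit paths
resolve_scales <- function(ram, s_obs) {
  d <- rep(NA_real_, ram$nv)
  d[ram$obs] <- s_obs
  ones <- which(ram$A == 1, arr.ind = TRUE)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(ones))) {
      i <- ones[k, 1]; j <- ones[k, 2]  # A[i, j]: j -> i, same scale
      if (is.na(d[j]) && !is.na(d[i])) { d[j] <- d[i]; changed <- TRUE }
    }
    if (!changed) break
  }
  d[is.na(d)] <- 1  # standardized phantoms: free paths absorb the scale
  d
}

# multiplicative factor mapping scaled-space estimates to raw-scale estimates
label_kappa <- function(ram, d) {
  kap <- numeric(length(ram$labels))
  for (k in seq_along(ram$labels)) {
    ks <- vapply(ram$pos[[k]], function(q) {
      i <- q[2]; j <- q[3]
      switch(q[1], d[i] / d[j], d[i] * d[j], d[i])
    }, numeric(1))
    if (max(abs(ks / ks[1] - 1)) > 1e-8)
      stop("internal rescaling inconsistent for label ", ram$labels[k])
    kap[k] <- ks[1]
  }
  kap
}

default_starts <- function(ram, pats, d, kappa) {
  p <- length(ram$obs)
  mu0 <- numeric(p); v0 <- numeric(p); ns <- numeric(p)
  for (pt in pats) {
    o <- pt$obs
    ns[o] <- ns[o] + pt$n
    mu0[o] <- mu0[o] + pt$n * pt$mean
    v0[o] <- v0[o] + pt$n * (diag(pt$scatter) + pt$mean^2)
  }
  mu0 <- mu0 / ns
  v0 <- pmax(v0 / ns - mu0^2, 1e-4)
  mu_full <- numeric(ram$nv); mu_full[ram$obs] <- mu0
  v_full <- rep(1, ram$nv); v_full[ram$obs] <- v0

  th <- numeric(length(ram$labels))
  for (k in seq_along(ram$labels)) {
    q <- ram$pos[[k]][[1]]
    i <- q[2]; j <- q[3]
    th[k] <- if (q[1] == 1L) 0.7
    else if (q[1] == 2L) {
      if (i == j) {
        if (ram$roles[i] == "observed") 0.5 * v_full[i] else 0.5
      } else 0
    } else {
      if (ram$roles[i] == "observed") mu_full[i] else 0
    }
    if (!is.na(ram$start[k])) th[k] <- ram$start[k] / kappa[k]
  }
  th
}

#' Fit a model by full-information maximum likelihood
#'
#' Maximizes the casewise multivariate normal likelihood over each row's
#' observed subset (valid under missing-at-random dropout) with a
#' quasi-Newton optimizer, analytic gradients, and jittered multi-start.
#' Standard errors come from the inverse numerical observed information
#' (central differences of the analytic gradient). The saturated and
#' independence-baseline log-likelihoods are computed on the same rows.
#'
#' @param spec a `model_spec`.
#' @param data data frame or matrix with the spec's observed variables; `NA`
#'   marks missing entries. Rows missing all model variables are dropped
#'   (count reported on the result).
#' @param starts number of optimization starts (first from moment-based
#'   heuristics, the rest jittered).
#' @param seed integer seed controlling the jitter; fits are deterministic
#'   given `seed`.
#' @param tol convergence criterion: maximum absolute gradient of -2 loglik,
#'   per observation, at the solution.
#' @param se compute standard errors and the standardized solution's
#'   delta-method errors.
#' @param start optional named vector of starting values (raw scale).
#' @return An object of class `lds_fit`; see [parameter_table()],
#'   [standardized_solution()], [fit_indices()].
#' @export
fit_model <- function(spec, data, starts = 5, seed = 1, tol = 1e-4,
                      se = TRUE, start = NULL) {
  ram <- compile_ram(spec)
  if (degrees_of_freedom(spec) < 0) stop("model has negative df")
  X <- extract_data(data, ram$vars[ram$obs])

  # pooled scale per wave pair (so invariance-shared labels stay consistent)
  base <- sub("_w[0-9]+$", "", colnames(X))
  s_obs <- vapply(seq_len(ncol(X)), function(j) {
    v <- stats::sd(as.vector(X[, base == base[j], drop = FALSE]), na.rm = TRUE)
    if (!is.finite(v) || v <= 0) 1 else v
  }, numeric(1))
  d <- resolve_scales(ram, s_obs)
  kappa <- tryCatch(label_kappa(ram, d), error = function(e) NULL)
  if (is.null(kappa)) {
    # equality constraints tie parameters across differently scaled
    # variables; fall back to fitting on the raw scale
    s_obs <- rep(1, ncol(X))
    d <- resolve_scales(ram, s_obs)
    kappa <- label_kappa(ram, d)
  }
  Xs <- sweep(X, 2L, s_obs, "/")
  pats <- pattern_stats(Xs)
  n <- attr(pats, "n")
  nfree <- length(ram$labels)

  # transform: variances on the log scale
  isv <- ram$is_var
  to_eta <- function(th) { th[isv] <- log(pmax(th[isv], 1e-10)); th }
  to_theta <- function(eta) { eta[isv] <- exp(eta[isv]); eta }
  lower <- rep(-Inf, nfree); lower[isv] <- log(1e-9)

  cache <- new.env(parent = emptyenv())
  compute <- function(eta) {
    if (!is.null(cache$eta) && identical(eta, cache$eta)) return(cache$res)
    th <- to_theta(eta)
    res <- tryCatch({
      mom <- ram_moments(ram, th)
      lk <- mvn_pattern_loglik(mom$Sigma, mom$mu, pats, grad = TRUE)
      if (!is.finite(lk$ll)) list(f = 1e12, g = rep(0, nfree), ll = -Inf)
      else {
        g <- ram_grad_chain(ram, mom, lk$Gsig, lk$gmu)
        geta <- g
        geta[isv] <- g[isv] * th[isv]
        list(f = -2 * lk$ll, g = geta, gtheta = g, ll = lk$ll)
      }
    }, error = function(e) list(f = 1e12, g = rep(0, nfree), ll = -Inf))
    cache$eta <- eta; cache$res <- res
    res
  }

  th0 <- if (!is.null(start)) align_theta(ram, start) / kappa
         else default_starts(ram, pats, d, kappa)
  eta0 <- to_eta(th0)

  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  best <- NULL
  tries <- list()
  for (s in seq_len(max(1L, starts))) {
    eta_s <- if (s == 1L) eta0
    else eta0 + stats::rnorm(nfree) * 0.1 * pmax(abs(eta0), 0.5)
    opt <- stats::nlminb(eta_s, function(e) compute(e)$f,
                         function(e) compute(e)$g, lower = lower,
                         control = list(iter.max = 2000, eval.max = 6000,
                                        rel.tol = 1e-12))
    gn <- max(abs(compute(opt$par)$g))
    # polish: restarting resets the quasi-Newton Hessian approximation,
    # which often escapes premature "relative convergence" stops
    for (round in 1:6) {
      if (gn <= 0.1 * tol * n) break
      opt2 <- stats::nlminb(opt$par, function(e) compute(e)$f,
                            function(e) compute(e)$g, lower = lower,
                            control = list(iter.max = 2000, eval.max = 6000,
                                           rel.tol = 1e-13))
      gn2 <- max(abs(compute(opt2$par)$g))
      no_gain <- opt2$objective > opt$objective - 1e-9 * max(1, abs(opt$objective))
      if (opt2$objective <= opt$objective) { opt <- opt2; gn <- gn2 }
      if (no_gain) break
    }
    tries[[s]] <- list(opt = opt, f = opt$objective, gn = gn)
    if (is.null(best) || opt$objective < best$f - 1e-8 ||
        (abs(opt$objective - best$f) <= 1e-8 && gn < best$gn))
      best <- list(opt = opt, f = opt$objective, gn = gn)
  }

  eta_hat <- best$opt$par
  res_hat <- compute(eta_hat)
  th_hat <- to_theta(eta_hat)
  converged <- is.finite(best$f) && best$gn <= tol * n
  heywood <- any(isv & th_hat < 1e-6)

  sat <- saturated_loglik_pats(pats)
  basel <- baseline_loglik(pats)
  # Jacobian of the per-variable rescaling, to report raw-scale logliks
  ll_shift <- sum(attr(pats, "n_obs_cells") * log(s_obs))
  theta_raw <- stats::setNames(th_hat * kappa, ram$labels)

  vcov_raw <- NULL
  if (se) {
    H <- grad_jacobian(function(th) {
      mom <- ram_moments(ram, th)
      lk <- mvn_pattern_loglik(mom$Sigma, mom$mu, pats, grad = TRUE)
      if (!is.finite(lk$ll)) return(rep(NA_real_, nfree))
      ram_grad_chain(ram, mom, lk$Gsig, lk$gmu)
    }, th_hat)
    vcov_s <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(vcov_s) && all(is.finite(vcov_s)) &&
        all(diag(vcov_s) > -1e-8)) {
      vcov_raw <- diag(kappa) %*% vcov_s %*% diag(kappa)
      dimnames(vcov_raw) <- list(ram$labels, ram$labels)
    }
  }

  fit <- structure(list(
    spec = spec, ram = ram, theta = theta_raw,
    theta_scaled = stats::setNames(th_hat, ram$labels),
    scales = stats::setNames(s_obs, colnames(X)), var_scales = d,
    kappa = stats::setNames(kappa, ram$labels),
    loglik = res_hat$ll - ll_shift,
    loglik_sat = sat$loglik - ll_shift,
    loglik_baseline = basel$loglik - ll_shift,
    baseline_free = basel$n_free,
    n = n, n_dropped = attr(pats, "n_dropped"),
    df = degrees_of_freedom(spec),
    converged = converged, heywood = heywood,
    gradnorm = best$gn, iterations = best$opt$iterations,
    restarts = max(1L, starts),
    vcov = vcov_raw, pats = pats, seed = seed
  ), class = "lds_fit")
  fit$partable <- build_partable(fit, se = se)
  fit
}

# saturated loglik reusing already-computed pattern statistics
saturated_loglik_pats <- function(pats, tol = 1e-10, max_iter = 10000) {
  p <- attr(pats, "p"); n <- attr(pats, "n")
  complete <- length(pats) == 1L && length(pats[[1]]$obs) == p
  if (complete) {
    mu <- pats[[1]]$mean; Sigma <- pats[[1]]$scatter
    return(list(loglik = mvn_pattern_loglik(Sigma, mu, pats)$ll,
                mu = mu, Sigma = Sigma, n = n, iterations = 0L))
  }
  em_saturated(pats, tol = tol, max_iter = max_iter)
}

em_saturated <- function(pats, tol = 1e-10, max_iter = 10000) {
  p <- attr(pats, "p"); n <- attr(pats, "n")
  mu <- numeric(p); v <- numeric(p); ns <- numeric(p)
  for (pt in pats) {
    o <- pt$obs
    ns[o] <- ns[o] + pt$n
    mu[o] <- mu[o] + pt$n * pt$mean
    v[o] <- v[o] + pt$n * (diag(pt$scatter) + pt$mean^2)
  }
  mu <- mu / ns
  v <- pmax(v / ns - mu^2, 1e-12)
  Sigma <- diag(v, p)
  ll_old <- -Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p); T2 <- matrix(0, p, p)
    for (pt in pats) {
      o <- pt$obs; ms <- setdiff(seq_len(p), o); np <- pt$n
      Sxx <- pt$scatter + tcrossprod(pt$mean)
      T1[o] <- T1[o] + np * pt$mean
      T2[o, o] <- T2[o, o] + np * Sxx
      if (length(ms)) {
        Amat <- Sigma[ms, o, drop = FALSE] %*% chol2inv(chol(Sigma[o, o, drop = FALSE]))
        bcond <- Sigma[ms, ms, drop = FALSE] - Amat %*% Sigma[o, ms, drop = FALSE]
        cvec <- mu[ms] - drop(Amat %*% mu[o])
        T1[ms] <- T1[ms] + np * (cvec + drop(Amat %*% pt$mean))
        Sxe <- np * (tcrossprod(pt$mean, cvec) + Sxx %*% t(Amat))
        See <- np * (bcond + tcrossprod(cvec) + Amat %*% Sxx %*% t(Amat) +
                       Amat %*% tcrossprod(pt$mean, cvec) +
                       tcrossprod(cvec, drop(Amat %*% pt$mean)))
        T2[o, ms] <- T2[o, ms] + Sxe
        T2[ms, o] <- T2[ms, o] + t(Sxe)
        T2[ms, ms] <- T2[ms, ms] + See
      }
    }
    mu <- T1 / n
    Sigma <- (T2 / n - tcrossprod(mu))
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- mvn_pattern_loglik(Sigma, mu, pats)$ll
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * max(1, abs(ll_old))) break
    ll_old <- ll
  }
  list(loglik = ll, mu = mu, Sigma = Sigma, n = n, iterations = it)
}

# central-difference Jacobian of a gradient function (numerical observed
# information when applied to the gradient of -2 loglik)
grad_jacobian <- function(gfun, th, rel_step = 1e-4) {
  k <- length(th)
  H <- matrix(NA_real_, k, k)
  for (j in seq_len(k)) {
    h <- rel_step * max(abs(th[j]), 1e-3)
    tp <- th; tp[j] <- th[j] + h
    tm <- th; tm[j] <- th[j] - h
    H[, j] <- (gfun(tp) - gfun(tm)) / (2 * h)
  }
  H
}

# ---------------------------------------------------------------------------
# Parameter table and standardized solution
# ---------------------------------------------------------------------------

partable_rows <- function(spec) {
  blk <- function(d, lhs, op, rhs) {
    if (!nrow(d)) return(NULL)
    data.frame(label = d$label, lhs = d[[lhs]], op = rep(op, nrow(d)),
               rhs = if (is.null(rhs)) rep("", nrow(d)) else d[[rhs]],
               value = d$value, free = d$free, stringsAsFactors = FALSE)
  }
  rbind(blk(spec$paths, "from", "->", "to"),
        blk(spec$covs, "var1", "~~", "var2"),
        blk(spec$means, "var", "~1", NULL))
}

# standardized values for every parameter-table row at scaled theta
std_values <- function(ram, rows, th_scaled, d) {
  mom <- ram_moments(ram, th_scaled)
  sdv <- sqrt(pmax(diag(mom$Sigma_full), 0))
  names(sdv) <- ram$vars
  M <- ram_fill(ram, th_scaled)
  out <- numeric(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    i <- match(rows$lhs[r], ram$vars)
    if (rows$op[r] == "->") {
      j <- match(rows$rhs[r], ram$vars)
      out[r] <- if (sdv[j] > 0) M$A[j, i] * sdv[i] / sdv[j] else NA_real_
    } else if (rows$op[r] == "~~") {
      j <- match(rows$rhs[r], ram$vars)
      den <- sdv[i] * sdv[j]
      out[r] <- if (den > 0) M$S[i, j] / den else NA_real_
    } else {
      out[r] <- if (sdv[i] > 0) mom$mu_full[i] / sdv[i] else NA_real_
    }
  }
  out
}

build_partable <- function(fit, se = TRUE) {
  ram <- fit$ram
  rows <- partable_rows(fit$spec)
  est <- ifelse(rows$free, fit$theta[rows$label], rows$value)
  se_v <- rep(NA_real_, nrow(rows))
  if (!is.null(fit$vcov))
    se_v[rows$free] <- sqrt(pmax(diag(fit$vcov)[rows$label[rows$free]], 0))
  z <- est / se_v
  pval <- 2 * stats::pnorm(-abs(z))
  std <- std_values(ram, rows, fit$theta_scaled, fit$var_scales)
  std_se <- rep(NA_real_, nrow(rows))
  if (se && !is.null(fit$vcov)) {
    th <- fit$theta_scaled
    J <- matrix(NA_real_, nrow(rows), length(th))
    for (j in seq_along(th)) {
      h <- 1e-5 * max(abs(th[j]), 1e-3)
      tp <- th; tp[j] <- th[j] + h
      tm <- th; tm[j] <- th[j] - h
      J[, j] <- (std_values(ram, rows, tp, fit$var_scales) -
                   std_values(ram, rows, tm, fit$var_scales)) / (2 * h)
    }
    vs <- diag(1 / fit$kappa) %*% fit$vcov %*% diag(1 / fit$kappa)
    std_se <- sqrt(pmax(rowSums((J %*% vs) * J), 0))
    std_se[!rows$free & apply(abs(J) < 1e-12, 1, all)] <- NA_real_
  }
  tibble::tibble(label = rows$label, lhs = rows$lhs, op = rows$op,
                 rhs = rows$rhs, free = rows$free, est = est, se = se_v,
                 z = z, p = pval, std_est = std, std_se = std_se)
}

#' Parameter table of a fitted model
#'
#' One row per declared path, covariance and mean, with raw estimates,
#' standard errors, Wald z and p, and the standardized solution with
#' delta-method standard errors.
#'
#' @param fit an `lds_fit` from [fit_model()].
#' @return A tibble.
#' @export
parameter_table <- function(fit) {
  stopifnot(inherits(fit, "lds_fit"))
  fit$partable
}

#' Standardized solution of a fitted model
#'
#' Loadings and paths are rescaled by the implied standard deviations of
#' their endpoints, covariances are converted to correlations, and means are
#' expressed in endpoint-SD units; standard errors by the delta method on the
#' correlation metric.
#'
#' @param fit an `lds_fit`.
#' @return A tibble with columns `label`, `lhs`, `op`, `rhs`, `std_est`,
#'   `std_se`, `z`, `p`.
#' @export
standardized_solution <- function(fit) {
  pt <- parameter_table(fit)
  z <- pt$std_est / pt$std_se
  tibble::tibble(label = pt$label, lhs = pt$lhs, op = pt$op, rhs = pt$rhs,
                 std_est = pt$std_est, std_se = pt$std_se, z = z,
                 p = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.lds_fit <- function(x, ...) {
  cat("lds_fit:", length(x$theta), "free parameters, n =", x$n,
      if (x$n_dropped) paste0("(", x$n_dropped, " empty rows dropped)"), "\n")
  cat("  loglik =", format(x$loglik), " saturated =", format(x$loglik_sat),
      " df =", x$df, "\n")
  cat("  converged:", x$converged, " (max |grad| =", format(x$gradnorm),
      ")  Heywood:", x$heywood, "\n")
  invisible(x)
}

#' Export the parameter table as CSV
#'
#' Columns exactly: label, lhs, op, rhs, est, se, z, p, std_est, std_se.
#'
#' @param fit an `lds_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(fit, path) {
  pt <- parameter_table(fit)
  utils::write.csv(pt[, c("label", "lhs", "op", "rhs", "est", "se", "z", "p",
                          "std_est", "std_se")], path, row.names = FALSE)
  invisible(path)
}
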