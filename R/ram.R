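# RAM compilation: a model_spec maps into matrices
#   A (directed paths, A[to, from]), S (symmetric covariances), m (means)
# with free entries driven by a labelled parameter vector theta.

compile_ram <- function(spec) {
  ord <- order(spec$variables$role != "observed")  # observed first, stable
  vars <- spec$variables$name[ord]
  roles <- spec$variables$role[ord]
  nv <- length(vars)
  idx <- stats::setNames(seq_len(nv), vars)
  A <- matrix(0, nv, nv, dimnames = list(vars, vars))
  S <- matrix(0, nv, nv, dimnames = list(vars, vars))
  m <- stats::setNames(numeric(nv), vars)

  labels <- free_labels(spec)
  pos <- stats::setNames(vector("list", length(labels)), labels)
  push <- function(lab, mat, i, j) pos[[lab]][[length(pos[[lab]]) + 1L]] <<- c(mat, i, j)

  has_mean <- logical(nv)
  for (k in seq_len(nrow(spec$paths))) {
    p <- spec$paths[k, ]
    i <- idx[[p$to]]; j <- idx[[p$from]]
    if (p$free) push(p$label, 1L, i, j) else A[i, j] <- p$value
  }
  for (k in seq_len(nrow(spec$covs))) {
    cv <- spec$covs[k, ]
    i <- idx[[cv$var1]]; j <- idx[[cv$var2]]
    if (cv$free) push(cv$label, 2L, i, j)
    else { S[i, j] <- cv$value; S[j, i] <- cv$value }
  }
  for (k in seq_len(nrow(spec$means))) {
    mn <- spec$means[k, ]
    i <- idx[[mn$var]]
    has_mean[i] <- TRUE
    if (mn$free) push(mn$label, 3L, i, i) else m[i] <- mn$value
  }
  # every variable must be reachable from the mean structure
  if (!all(has_mean))
    stop("variable(s) lack a mean/intercept entry: ",
         paste(vars[!has_mean], collapse = ", "))

  # a label is a variance iff all its positions are S-diagonal entries
  is_var <- vapply(pos, function(pp)
    all(vapply(pp, function(q) q[1] == 2L && q[2] == q[3], logical(1))),
    logical(1))
  mixed <- vapply(pos, function(pp) {
    any(vapply(pp, function(q) q[1] == 2L && q[2] == q[3], logical(1))) &&
      !all(vapply(pp, function(q) q[1] == 2L && q[2] == q[3], logical(1)))
  }, logical(1))
  if (any(mixed))
    stop("label(s) shared between a variance and a non-variance entry: ",
         paste(labels[mixed], collapse = ", "))

  # start values recorded on the spec (first non-NA per label)
  start <- stats::setNames(rep(NA_real_, length(labels)), labels)
  fill_start <- function(d, lab_col = "label") {
    ok <- d$free & !is.na(d$value)
    for (k in which(ok)) if (is.na(start[[d[[lab_col]][k]]]))
      start[[d[[lab_col]][k]]] <<- d$value[k]
  }
  fill_start(spec$paths); fill_start(spec$covs); fill_start(spec$means)

  list(spec = spec, vars = vars, roles = roles, nv = nv,
       obs = which(roles == "observed"),
       A = A, S = S, m = m,
       labels = labels, pos = pos, is_var = is_var, start = start)
}

ram_fill <- function(ram, theta) {
  A <- ram$A; S <- ram$S; m <- ram$m
  for (k in seq_along(ram$labels)) {
    v <- theta[k]
    for (q in ram$pos[[k]]) {
      if (q[1] == 1L) A[q[2], q[3]] <- v
      else if (q[1] == 2L) { S[q[2], q[3]] <- v; S[q[3], q[2]] <- v }
      else m[q[2]] <- v
    }
  }
  list(A = A, S = S, m = m)
}

ram_moments <- function(ram, theta) {
  M <- ram_fill(ram, theta)
  IA <- diag(ram$nv) - M$A
  B <- tryCatch(solve(IA), error = function(e)
    stop("(I - A) is singular: the structural part contains a cycle"))
  Sigma_full <- B %*% M$S %*% t(B)
  mu_full <- drop(B %*% M$m)
  list(Sigma_full = Sigma_full, mu_full = mu_full, B = B, S = M$S,
       Sigma = Sigma_full[ram$obs, ram$obs, drop = FALSE],
       mu = mu_full[ram$obs])
}

#' Model-implied observed moments
#'
#' Computes the model-implied covariance matrix and mean vector of the
#' observed variables at a parameter vector, via the RAM identities
#' `Sigma = F (I-A)^-1 S (I-A)^-T F'` and `mu = F (I-A)^-1 m`.
#'
#' @param spec a `model_spec` (or a compiled RAM object).
#' @param theta named numeric vector of free parameter values; names must
#'   cover [free_labels()] of the spec. Unnamed vectors are taken in
#'   registry order.
#' @return list with `Sigma` (observed covariance), `mu` (observed means),
#'   and the full-variable versions `Sigma_full`, `mu_full`.
#' @export
implied_moments <- function(spec, theta) {
  ram <- if (inherits(spec, "model_spec")) compile_ram(spec) else spec
  theta <- align_theta(ram, theta)
  mom <- ram_moments(ram, theta)
  dimnames(mom$Sigma) <- list(ram$vars[ram$obs], ram$vars[ram$obs])
  names(mom$mu) <- ram$vars[ram$obs]
  dimnames(mom$Sigma_full) <- list(ram$vars, ram$vars)
  names(mom$mu_full) <- ram$vars
  mom[c("Sigma", "mu", "Sigma_full", "mu_full")]
}

align_theta <- function(ram, theta) {
  if (!is.null(names(theta))) {
    miss <- setdiff(ram$labels, names(theta))
    if (length(miss)) stop("theta is missing parameter(s): ",
                           paste(miss, collapse = ", "))
    theta <- theta[ram$labels]
  } else if (length(theta) != length(ram$labels)) {
    stop("theta has length ", length(theta), ", expected ", length(ram$labels))
  }
  unname(theta)
}

# Gradient of a moment-space objective with respect to theta.
# Gsig = dF/dSigma_obs (symmetric, obs x obs), gmu = dF/dmu_obs.
ram_grad_chain <- function(ram, mom, Gsig, gmu) {
  nv <- ram$nv
  Gf <- matrix(0, nv, nv); Gf[ram$obs, ram$obs] <- Gsig
  gmf <- numeric(nv); gmf[ram$obs] <- gmu
  B <- mom$B
  H <- crossprod(B, Gf) %*% B          # B' Gf B
  Q <- mom$Sigma_full %*% Gf %*% B     # for A entries
  u <- drop(crossprod(B, gmf))         # B' gmu
  muf <- mom$mu_full
  g <- numeric(length(ram$labels))
  for (k in seq_along(ram$labels)) {
    acc <- 0
    for (q in ram$pos[[k]]) {
      i <- q[2]; j <- q[3]
      if (q[1] == 1L) acc <- acc + 2 * Q[j, i] + u[i] * muf[j]
      else if (q[1] == 2L) acc <- acc + if (i == j) H[i, i] else 2 * H[i, j]
      else acc <- acc + u[i]
    }
    g[k] <- acc
  }
  g
}
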