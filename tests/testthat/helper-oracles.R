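# Independent oracles and shared fixtures.

# brute-force path-tracing oracle for implied moments: (I - A)^-1 expanded as
# a power series, a different route than the solve() used by the engine
trace_moments <- function(spec, theta) {
  ram <- ldscoupling:::compile_ram(spec)
  M <- ldscoupling:::ram_fill(ram, ldscoupling:::align_theta(ram, theta))
  B <- diag(ram$nv)
  P <- diag(ram$nv)
  for (k in 1:25) {
    P <- P %*% M$A
    B <- B + P
  }
  stopifnot(max(abs(P)) < 1e-10)  # must be (effectively) acyclic
  Sigma <- B %*% M$S %*% t(B)
  list(Sigma = Sigma[ram$obs, ram$obs, drop = FALSE],
       mu = drop(B %*% M$m)[ram$obs])
}

# dense multivariate normal log-likelihood, computed row by row
dense_mvn_loglik <- function(X, mu, Sigma) {
  k <- ncol(X)
  Sinv <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  sum(apply(X, 1, function(x) {
    d <- x - mu
    -0.5 * (k * log(2 * pi) + ld + drop(t(d) %*% Sinv %*% d))
  }))
}

# one-factor spec with m indicators (first loading fixed to 1)
one_factor_spec <- function(m = 3) {
  obs <- paste0("x", seq_len(m))
  sp <- model_spec(observed = obs, latent = "F")
  sp <- add_path(sp, "F", "x1", fixed = 1)
  for (j in seq_len(m)[-1])
    sp <- add_path(sp, "F", obs[j], label = paste0("l", j))
  sp <- add_cov(sp, "F", "F", label = "vf")
  sp <- add_mean(sp, "F", fixed = 0)
  for (v in obs) {
    sp <- add_cov(sp, v, v, label = paste0("rv_", v))
    sp <- add_mean(sp, v, label = paste0("m_", v))
  }
  sp
}

# saturated spec over the given observed variables
saturated_spec <- function(obs) {
  sp <- model_spec(observed = obs)
  for (i in seq_along(obs)) {
    sp <- add_cov(sp, obs[i], obs[i], label = paste0("v", i))
    sp <- add_mean(sp, obs[i], label = paste0("m", i))
    if (i < length(obs)) for (j in seq(i + 1, length(obs)))
      sp <- add_cov(sp, obs[i], obs[j], label = paste0("c", i, j))
  }
  sp
}

# shared large-cohort fixture: one simulation at the generator defaults and
# one converged fit per model, reused across test files
.fixture <- new.env(parent = emptyenv())

big_cohort <- function() {
  if (is.null(.fixture$cohort)) {
    .fixture$config <- suppressMessages(generator_config())
    .fixture$cohort <- simulate_cohort(.fixture$config, 20000, seed = 20)
    .fixture$resid <- residualize(as.data.frame(.fixture$cohort))
  }
  .fixture$cohort
}

big_config <- function() { big_cohort(); .fixture$config }
big_resid <- function() { big_cohort(); .fixture$resid }

big_fit <- function(model = "A") {
  key <- paste0("fit", model)
  if (is.null(.fixture[[key]])) {
    spec <- build_lds_model(model)
    .fixture[[key]] <- fit_model(spec, big_resid(), starts = 2, seed = 20,
                                 se = TRUE)
  }
  .fixture[[key]]
}

big_std <- function(model = "A") {
  key <- paste0("std", model)
  if (is.null(.fixture[[key]]))
    .fixture[[key]] <- standardized_solution(big_fit(model))
  .fixture[[key]]
}

std_cor <- function(model, a, b) {
  std <- big_std(model)
  std$std_est[match(ldscoupling:::model_cov_label(model, a, b), std$label)]
}
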