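# Independent oracles used across tests; none of these call the code paths
# they check.

# iterate the per-step enrichment recursion x <- x + beta0 + beta1 * x
iterate_recursion <- function(beta0, beta1, x0, n_steps) {
  x <- x0
  for (i in seq_len(n_steps)) x <- x + beta0 + beta1 * x
  x
}

# ordinary least squares of observed discrimination on observed diet d15N
ols_delta_fit <- function(obs) {
  unname(coef(lm(discrimination ~ diet_d15n, data = obs)))
}

# invert the forward curve numerically by bisection (no logs)
bisect_tp <- function(params, base, consumer, tol = 1e-12) {
  f <- function(tp) {
    params$delta15N_lim -
      (params$delta15N_lim - base$delta15N) * exp(-params$k * (tp - base$tl)) -
      consumer
  }
  uniroot(f, c(base$tl - 5, 60), tol = tol)$root
}

quick_mcmc <- function(seed = 1L, n_iter = 3000L, burn = 1000L,
                       chains = 2L, thin = 1L) {
  mcmc_control(n_iter, burn, thin = thin, chains = chains, seed = seed)
}
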