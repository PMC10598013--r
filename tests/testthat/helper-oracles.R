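# independent oracles used across test files

# kernel weight by direct log-gamma evaluation
lgamma_weight <- function(j, order) {
  exp(lgamma(j + order) - lgamma(order) - lgamma(j + 1))
}

# naive O(n^2) double-loop realization of the memory-convolution scheme,
# written directly from the closed-form solution (independent of the
# solver's vectorized update)
brute_force_solve <- function(rhs, orders, x0, n_steps, h = 1) {
  d <- length(x0)
  X <- matrix(NA_real_, n_steps + 1L, d)
  X[1L, ] <- x0
  F <- matrix(0, n_steps, d)
  for (n in seq_len(n_steps)) {
    F[n, ] <- rhs(X[n, ])
    for (i in seq_len(d)) {
      th <- orders[i]
      acc <- 0
      for (lam in 0:(n - 1L)) {
        w <- exp(lgamma(n - lam - 1 + th) - lgamma(n - lam))
        acc <- acc + w * F[lam + 1L, i]
      }
      X[n + 1L, i] <- x0[i] + h^th / gamma(th) * acc
    }
  }
  X
}

# hand-unrolled fractional sum straight from the definition
brute_force_frac_sum <- function(values, order) {
  n <- length(values)
  out <- numeric(n)
  for (k in seq_len(n)) {
    acc <- 0
    for (j in seq_len(k)) {
      m <- k - j
      acc <- acc + exp(lgamma(m + order) - lgamma(order) - lgamma(m + 1)) *
        values[j]
    }
    out[k] <- acc
  }
  out
}

# linear fractional map long-run check.  Stable fractional maps decay
# only algebraically (like n^{-order}) and components with tiny
# eigenvalue modulus barely move on any finite horizon, so the
# falsifiable observables are: a stable system never grows, an unstable
# one eventually does.
simulate_linear_decay <- function(A, orders, n_steps = 3000L,
                                  x0 = NULL) {
  d <- nrow(A)
  if (is.null(x0)) x0 <- rep(1, d)
  tr <- tryCatch(
    solve_incommensurate(function(x) as.vector(A %*% x), orders,
                         x0, n_steps),
    error = function(e) NULL)               # solver aborts on overflow
  if (is.null(tr))
    return(list(decayed = FALSE, bounded = FALSE,
                tail_norm = Inf, head_norm = NA_real_))
  nrm <- apply(abs(tr$states), 1L, max)
  head_norm <- max(nrm[seq_len(max(2L, n_steps %/% 10L))])
  tail_norm <- max(nrm[(n_steps - n_steps %/% 10L):(n_steps + 1L)])
  list(decayed = tail_norm < 0.3 * head_norm,
       bounded = all(is.finite(nrm)) && max(nrm) < 1e6 * head_norm,
       tail_norm = tail_norm, head_norm = head_norm)
}

# does the simulated long-run behaviour agree with a stability verdict?
verdict_agrees <- function(predicted_stable, sim) {
  if (predicted_stable)
    sim$bounded && sim$tail_norm <= 1.05 * sim$head_norm
  else
    !sim$bounded || sim$tail_norm > 2 * sim$head_norm
}

fixture_path <- function() {
  system.file("extdata", "ml_parameter_groups.json", package = "fracml")
}
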