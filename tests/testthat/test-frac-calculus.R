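test_that("kernel weights match the log-gamma oracle and its identities", {
  # order 1: all weights are 1 (plain running sum)
  expect_equal(kernel_weights(1, 5)$weights, rep(1, 5))

  # frozen values from the direct log-gamma oracle
  expect_equal(kernel_weights(0.5, 3)$weights, c(1, 0.5, 0.375),
               tolerance = 1e-14)

  # deep-tail weight agrees with the high-precision gamma oracle
  w <- kernel_weights(0.3, 200)$weights
  expect_equal(w[200], lgamma_weight(199, 0.3), tolerance = 1e-10)
  for (ord in c(0.2, 0.55, 0.9)) {
    w <- kernel_weights(ord, 150)$weights
    expect_equal(w, vapply(0:149, lgamma_weight, numeric(1), order = ord),
                 tolerance = 1e-12)
    # strict monotone decay for orders in (0,1)
    expect_true(all(diff(w) < 0))
    expect_true(all(w > 0))
    # telescoping identity: sum_{j<n} c_j = Gamma(n+ord)/(Gamma(ord+1)Gamma(n))
    n <- length(w)
    expect_equal(sum(w),
                 exp(lgamma(n + ord) - lgamma(ord + 1) - lgamma(n)),
                 tolerance = 1e-12)
  }

  expect_error(kernel_weights(0, 5), "order")
  expect_error(kernel_weights(1.2, 5), "order")
  expect_error(kernel_weights(0.5, 0), "n_terms")
})

test_that("fractional sum reduces to known cases and the brute-force oracle", {
  # order 1 is the running sum
  x <- c(3, -1, 2, 7)
  expect_equal(fractional_sum(x, 1), cumsum(x))

  # constant input, order 0.5: hand-unrolled definition
  expect_equal(fractional_sum(rep(1, 4), 0.5),
               brute_force_frac_sum(rep(1, 4), 0.5), tolerance = 1e-14)

  # impulse response: a single nonzero entry reproduces the weight kernel
  e <- c(0, 0, 5, 0, 0, 0)
  expect_equal(fractional_sum(e, 0.7),
               c(0, 0, 5 * kernel_weights(0.7, 4)$weights))

  # random input, generic order
  set.seed(7)
  z <- rnorm(12)
  expect_equal(fractional_sum(z, 0.3), brute_force_frac_sum(z, 0.3),
               tolerance = 1e-12)
  expect_error(fractional_sum(numeric(0), 0.5), "non-empty")
})

test_that("integer difference implements the signed binomial formula", {
  expect_equal(integer_difference(c(1, 2, 3, 4), 1), c(1, 1, 1))
  # second difference of a quadratic is constant 2
  k <- 0:8
  expect_equal(integer_difference(k^2, 2), rep(2, 7))
  # q-fold composition oracle
  set.seed(11)
  z <- rnorm(15)
  expect_equal(integer_difference(z, 3), diff(diff(diff(z))))
  expect_error(integer_difference(1:3, 0), "positive")
  expect_error(integer_difference(1:3, 3), "longer")
})

test_that("Caputo difference = fractional sum of the first difference", {
  expect_equal(caputo_difference(rep(4.2, 9), 0.6), rep(0, 8))
  # identity ramp: first difference is all ones
  expect_equal(caputo_difference(0:6, 0.5),
               fractional_sum(rep(1, 6), 0.5))
  set.seed(3)
  z <- rnorm(10)
  expect_equal(caputo_difference(z, 0.7),
               brute_force_frac_sum(diff(z), 0.3), tolerance = 1e-12)
  expect_error(caputo_difference(z, 1), "strictly")
})

test_that("solver matches the Euler limit and the double-sum oracle", {
  # order 1, constant rhs: x(n) = x0 + c n
  tr <- solve_commensurate(function(x) 2.5, 1, 1, 100)
  expect_equal(tr$states[, 1], 1 + 2.5 * (0:100))

  # order 1 equals the plain forward map on a (contracting) nonlinear rhs
  f <- function(x) 0.1 * c(x[2], -sin(x[1]) - x[2])
  tr <- solve_commensurate(f, 1, c(0.3, 0), 100)
  X <- matrix(NA_real_, 101, 2)
  X[1, ] <- c(0.3, 0)
  for (k in 1:100) X[k + 1, ] <- X[k, ] + f(X[k, ])
  expect_equal(unname(tr$states), X, tolerance = 1e-12)

  # scalar decay, order 0.5, hand-unrolled convolution
  tr <- solve_commensurate(function(x) -x, 0.5, 1, 3)
  bf <- brute_force_solve(function(x) -x, 0.5, 1, 3)
  expect_equal(unname(tr$states), bf, tolerance = 1e-13)

  # generic nonlinear 2D system, n = 50, both orders commensurate
  g <- function(x) c(-0.2 * x[1] + 0.1 * x[2]^2, -0.3 * x[2] + 0.05)
  tr <- solve_commensurate(g, 0.7, c(1, -1), 50)
  expect_equal(unname(tr$states),
               brute_force_solve(g, c(0.7, 0.7), c(1, -1), 50),
               tolerance = 1e-12)
})

test_that("incommensurate solver: consistency, decoupling, oracle", {
  g <- function(x) c(-0.2 * x[1], -0.4 * x[2])
  # equal orders reproduce the commensurate solver bit for bit
  a <- solve_incommensurate(g, c(0.6, 0.6), c(1, 2), 30)
  b <- solve_commensurate(g, 0.6, c(1, 2), 30)
  expect_identical(a$states, b$states)

  # decoupled linear rhs: each component equals its scalar solve
  m <- solve_incommensurate(g, c(1, 0.5), c(1, 2), 40)
  e1 <- solve_commensurate(function(x) -0.2 * x, 1, 1, 40)
  e2 <- solve_commensurate(function(x) -0.4 * x, 0.5, 2, 40)
  expect_equal(m$states[, 1], e1$states[, 1], tolerance = 1e-13)
  expect_equal(m$states[, 2], e2$states[, 1], tolerance = 1e-13)

  # coupled system against the brute-force oracle
  h <- function(x) c(-0.3 * x[1] + 0.2 * x[2], 0.1 * x[1] - 0.25 * x[2])
  tr <- solve_incommensurate(h, c(0.9, 0.45), c(1, -0.5), 50)
  expect_equal(unname(tr$states),
               brute_force_solve(h, c(0.9, 0.45), c(1, -0.5), 50),
               tolerance = 1e-12)

  expect_error(solve_incommensurate(h, c(0.9, 0.5, 0.1), c(1, 1), 10),
               "dimension")
})

test_that("solver is linear in the initial condition for linear rhs", {
  A <- matrix(c(-0.3, 0.2, 0.1, -0.25), 2, 2)
  g <- function(x) as.vector(A %*% x)
  x1 <- c(1, 0); x2 <- c(0.2, -0.7)
  s1 <- solve_commensurate(g, 0.8, x1, 60)$states
  s2 <- solve_commensurate(g, 0.8, x2, 60)$states
  s12 <- solve_commensurate(g, 0.8, x1 + x2, 60)$states
  expect_equal(s12, s1 + s2, tolerance = 1e-10)
})

test_that("short memory converges monotonically to full memory", {
  g <- function(x) -0.5 * x
  full <- solve_commensurate(g, 0.6, 1, 120)$states[, 1]
  errs <- vapply(c(10, 30, 60, 120), function(L)
    max(abs(solve_commensurate(g, 0.6, 1, 120,
                               memory_length = L)$states[, 1] - full)),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-15))
  expect_equal(errs[4], 0)
})

test_that("divergence aborts with a step diagnostic", {
  expect_error(solve_commensurate(function(x) x^2, 0.9, 2, 200),
               "step")
})

test_that("trajectory container invariants hold", {
  tr <- solve_commensurate(function(x) -x, 0.5, 1, 20, step = 0.5)
  expect_length(tr$times, nrow(tr$states))
  expect_true(all(diff(tr$times) > 0))
  df <- as.data.frame(tr)
  expect_named(df, c("time", "u1"))
})
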