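test_that("steady-state current: definition, limits and critical points", {
  p <- ml_group("i", "2d")$params
  u <- c(-70, -20, 5, 40)
  w <- gating_functions(u, p)$w_inf
  expect_equal(steady_state_current(u, p), ionic_current(u, w, p))
  # leak-dominated asymptotics
  expect_lt(steady_state_current(-500, p), -500)
  expect_gt(steady_state_current(500, p), 500)
  # exactly two critical points, confirmed against a dense-grid scan
  crit <- fracml:::steady_state_critical_points(p)
  expect_length(crit, 2L)
  grid <- seq(-120, 140, length.out = 2e5)
  dv <- diff(steady_state_current(grid, p))
  flips <- which(dv[-1] * dv[-length(dv)] < 0)
  expect_length(flips, 2L)
  expect_equal(crit, grid[flips + 1L], tolerance = 1e-3)
})

test_that("2D equilibrium count follows the applied current window", {
  p <- ml_group("i", "2d")$params
  crit <- fracml:::steady_state_critical_points(p)
  Im_max <- steady_state_current(crit[1], p)
  Im_min <- steady_state_current(crit[2], p)
  expect_lt(Im_min, Im_max)
  # below the window and above it: one equilibrium
  expect_length(find_equilibria_2d(p, Im = Im_min - 10), 1L)
  expect_length(find_equilibria_2d(p, Im = Im_max + 10), 1L)
  # inside: three, with branch labels 1, 2, 3
  eqs <- find_equilibria_2d(p, Im = (Im_min + Im_max) / 2)
  expect_length(eqs, 3L)
  expect_equal(vapply(eqs, function(e) e$branch, numeric(1)), c(1, 2, 3))
  # locations agree with a brute-force sign-change scan
  Im <- (Im_min + Im_max) / 2
  grid <- seq(-120, 140, length.out = 1e6)
  v <- steady_state_current(grid, p) - Im
  sc <- which(v[-1] * v[-length(v)] < 0)
  expect_length(sc, 3L)
  expect_equal(vapply(eqs, function(e) unname(e$location[1]), numeric(1)),
               grid[sc], tolerance = 1e-3)
  # gating consistency u2* = w_inf(u1*)
  for (e in eqs)
    expect_equal(unname(e$location[2]),
                 unname(gating_functions(e$location[1], p)$w_inf))
})

test_that("3D equilibrium: pinned potential, residual, assumption check", {
  expect_equal(unname(find_equilibrium_3d(
    ml_group("i", "3d")$params)$location[1]), -0.22)
  expect_equal(unname(find_equilibrium_3d(
    ml_group("iii", "3d")$params)$location[1]), 0)
  for (g in c("i", "ii", "iii")) {
    p <- ml_group(g, "3d")$params
    eq <- find_equilibrium_3d(p)
    expect_lt(max(abs(rhs_3d(eq$location, p))), 1e-9)
  }
  bad <- ml_params_3d(WCa = 0.9, WK = 2, WL = 0.5, FCa = 1, FK = -0.7,
                      FL = -0.5, F1 = -0.01, F2 = 0.15, F4 = 0.05,
                      phi = 0.033, F0 = 1, theta = 0.005)
  expect_warning(find_equilibrium_3d(bad), "assumption")
})

test_that("analytic Jacobians match central finite differences", {
  fd_jac <- function(f, x, h = 1e-6) {
    d <- length(x)
    J <- matrix(0, d, d)
    for (j in seq_len(d)) {
      e <- numeric(d); e[j] <- h
      J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
    }
    J
  }
  p <- ml_group("ii", "2d")$params
  eq <- find_equilibria_2d(p, Im = 100)[[1]]
  J <- ml_jacobian(p, eq$location, Im = 100)
  expect_equal(J, fd_jac(function(s) rhs_2d(s, p, Im = 100), eq$location),
               tolerance = 1e-6)
  # printed structure of the (2,1) entry: phi * ell * w_inf'
  g <- gating_functions(eq$location[1], p)
  expect_equal(J[2, 1],
               unname(p$phi * g$ell *
                        fracml:::d_w_inf(eq$location[1], p$F3, p$F4)))
  # off-equilibrium state as well (ell' term active)
  s <- c(-35, 0.4)
  expect_equal(ml_jacobian(p, s, Im = 100),
               fd_jac(function(z) rhs_2d(z, p, Im = 100), s),
               tolerance = 1e-6)
  for (g3 in c("i", "iii")) {
    p3 <- ml_group(g3, "3d")$params
    eq3 <- find_equilibrium_3d(p3)
    J3 <- ml_jacobian(p3, eq3$location)
    expect_equal(J3, fd_jac(function(s) rhs_3d(s, p3), eq3$location),
                 tolerance = 1e-5)
    expect_equal(J3[3, ], c(p3$theta, 0, 0))
  }
  # the alternative cosh-argument rendering stays differentiable too
  palt <- ml_group("iii", "3d")$params
  palt$ell_arg <- "F2"
  s3 <- c(0.05, 0.3, 0.02)
  expect_equal(ml_jacobian(palt, s3),
               fd_jac(function(s) rhs_3d(s, palt), s3), tolerance = 1e-5)
})

test_that("Hopf threshold order follows the arccos law", {
  expect_equal(as.numeric(hopf_threshold_2d(0, 1)), 1)
  expect_equal(as.numeric(hopf_threshold_2d(2, 1)), 0)
  expect_equal(as.numeric(hopf_threshold_2d(sqrt(2), 1)), 0.5)
  expect_equal(attr(hopf_threshold_2d(-0.1, 1), "status"),
               "stable-all-orders")
  expect_equal(attr(hopf_threshold_2d(3, 1), "status"),
               "unstable-all-orders")
  expect_true(is.na(hopf_threshold_2d(1, -0.5)))
  expect_equal(attr(hopf_threshold_2d(1, -0.5), "status"), "saddle")
})

test_that("characteristic cubic and eigenvalue roundtrip", {
  cb <- cubic_coefficients_3d(diag(c(-1, -2, -3)))
  expect_equal(unname(cb$coefficients), c(6, 11, 6))
  for (g in c("i", "ii", "iii")) {
    eq <- find_equilibrium_3d(ml_group(g, "3d")$params)
    w <- eq$cubic
    res <- vapply(eq$eigenvalues, function(l)
      Mod(l^3 + w[1] * l^2 + w[2] * l + w[3]), numeric(1))
    expect_lt(max(res), 1e-8)
    # positive discriminant <=> all-real spectrum for these fixtures
    expect_gt(eq$discriminant, 0)
    expect_true(all(abs(Im(eq$eigenvalues)) < 1e-10))
  }
  expect_error(cubic_coefficients_3d(diag(2)), "3 x 3")
})

test_that("Matignon classification and saddle ranks", {
  expect_equal(classify_equilibrium(c(-1, -2), 0.9), "stable")
  expect_equal(classify_equilibrium(c(1 + 1i, 1 - 1i), 0.4), "stable")
  expect_equal(classify_equilibrium(c(2, -1, -1), 0.9), "saddle-rank-1")
  expect_equal(classify_equilibrium(c(2, 3, -1), 0.9), "saddle-rank-2")
  expect_equal(classify_equilibrium(c(0.5, 0.2), 0.5), "unstable")
  expect_equal(classify_equilibrium(c(1 + 1i, 1 - 1i), 0.5),
               "hopf-boundary")
})

test_that("critical order of a 3 x 3 spectrum", {
  J <- matrix(c(1, -1, 0, 1, 1, 0, 0, 0, -2), 3, 3)  # eigen 1 +- i, -2
  expect_equal(as.numeric(critical_order_3d(J)), 0.5)
  Jr <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, -1), 3, 3)  # pure imaginary pair
  expect_equal(as.numeric(critical_order_3d(Jr)), 1)
  expect_equal(attr(critical_order_3d(-diag(3)), "status"),
               "stable-all-orders")
})

test_that("commensurate stability region test", {
  expect_true(commensurate_stability_test(-1, 0.5))
  expect_false(commensurate_stability_test(0.5, 0.5))
  # prediction matches long-run decay of the scalar fractional map
  r <- simulate_linear_decay(matrix(-0.8), 0.7, 5000L)
  expect_true(commensurate_stability_test(-0.8, 0.7))
  expect_true(r$decayed)
})

test_that("incommensurate criterion: LCM, cross-checks, simulation", {
  sp <- order_spec(c(1 / 2, 1 / 3))
  expect_equal(sp$H, 6)
  expect_false(sp$commensurate)
  # equal orders agree with the commensurate verdict on random matrices
  set.seed(42)
  for (k in 1:6) {
    J <- matrix(rnorm(4, sd = 0.4), 2, 2)
    ev <- eigen(J, only.values = TRUE)$values
    expect_equal(incommensurate_stability_test(J, c(0.5, 0.5))$stable,
                 commensurate_stability_test(ev, 0.5),
                 info = paste("matrix", k))
  }
  # stable diagonal system decays in simulation
  J <- diag(c(-0.1, -0.1))
  out <- incommensurate_stability_test(J, c(1 / 2, 1 / 3))
  expect_true(out$stable)
  expect_true(simulate_linear_decay(J, c(1 / 2, 1 / 3), 8000L)$decayed)
  # companion-matrix roots agree with polyroot on the same polynomial
  poly <- fracml:::poly_det(list(
    list(c(0, 1), c(-0.3)), list(c(0.2), c(-1, 0, 1))))
  r1 <- sort(Mod(fracml:::poly_roots(poly)))
  r2 <- sort(Mod(polyroot(poly)))
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_error(incommensurate_stability_test(diag(2), c(0.5, exp(-1))),
               "rational")
})

test_that("branch-2 equilibria are saddles for every order", {
  p <- ml_group("i", "2d")$params
  crit <- fracml:::steady_state_critical_points(p)
  window <- steady_state_current(crit, p)
  for (Im in seq(min(window) + 1, max(window) - 1, length.out = 4)) {
    eqs <- find_equilibria_2d(p, Im = Im)
    mid <- Filter(function(e) e$branch == 2, eqs)
    expect_length(mid, 1L)
    expect_lt(mid[[1]]$zeta, 0)
    for (ord in c(0.2, 0.6, 1))
      expect_match(classify_equilibrium(mid[[1]]$eigenvalues, ord),
                   "saddle")
  }
})

test_that("classification flips exactly at the Hopf threshold order", {
  p <- ml_group("ii", "2d")$params
  eq <- find_equilibria_2d(p, Im = 100)[[1]]
  th <- as.numeric(eq$hopf_order)
  expect_equal(classify_equilibrium(eq$eigenvalues, th - 1e-6), "stable")
  expect_equal(classify_equilibrium(eq$eigenvalues, th + 1e-6), "unstable")
  # bisection localization of the flip agrees with the closed form
  lo <- 0.01; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (classify_equilibrium(eq$eigenvalues, mid) == "stable") lo <- mid
    else hi <- mid
  }
  expect_equal((lo + hi) / 2, th, tolerance = 1e-6)
})

test_that("theory verdicts agree with simulated decay on random systems", {
  set.seed(2026)
  n_ok <- 0L; n_tot <- 0L
  for (k in 1:24) {
    d <- sample(2:3, 1)
    J <- matrix(rnorm(d * d, sd = 0.35), d, d)
    ord <- sample(c(0.5, 0.75, 0.25), 1)
    ev <- eigen(J, only.values = TRUE)$values
    # skip near-boundary spectra
    margin <- min(abs(abs(Arg(ev)) - ord * pi / 2))
    if (margin < 1e-3) next
    pred <- commensurate_stability_test(ev, ord)
    sim <- simulate_linear_decay(J, rep(ord, d), 4000L)
    n_tot <- n_tot + 1L
    n_ok <- n_ok + verdict_agrees(pred, sim)
  }
  expect_gte(n_tot, 20L)
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("the printed modulus bound overstates the stability region", {
  # at order 0.75 the scalar map decays for lambda = -1.6 but diverges
  # for lambda = -1.75: the flip sits at 2^0.75 = 1.68, inside the
  # factor-2 variant (bound 3.36) but on the default bound
  expect_true(commensurate_stability_test(-1.6, 0.75))
  expect_false(commensurate_stability_test(-1.75, 0.75))
  expect_true(commensurate_stability_test(-1.75, 0.75,
                                          printed_bound = TRUE))
  s_ok <- simulate_linear_decay(matrix(-1.6), 0.75, 3000L)
  s_bad <- simulate_linear_decay(matrix(-1.75), 0.75, 3000L)
  expect_true(s_ok$decayed)
  expect_false(s_bad$bounded)
})
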