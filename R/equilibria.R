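sech2 <- function(x) 1 / cosh(x)^2

# analytic gating derivatives; F3 already resolved for the 3D model
d_r_inf <- function(u1, params) {
  sech2((u1 - params$F1) / params$F2) / (2 * params$F2)
}
d_w_inf <- function(u1, F3, F4) sech2((u1 - F3) / F4) / (2 * F4)
d_ell   <- function(u1, ref, F4) sinh((u1 - ref) / (2 * F4)) / (2 * F4)

# partial of the ionic current wrt u1 at fixed u2 (driving-force
# derivative is 1 under both conventions)
ibar_du1 <- function(u1, u2, params, u3 = NULL) {
  g <- gating_functions(u1, params, u3)
  drive <- if (params$ca_drive == "unit") u1 - 1 else u1 - params$FCa
  params$WCa * (d_r_inf(u1, params) * drive + g$r_inf) +
    params$WK * u2 + params$WL
}

#' Steady-state membrane current
#'
#' The applied current required to hold the membrane at `u1` with the
#' potassium gate at its steady state:
#' \eqn{I_\infty(u_1) = \bar I(u_1, w_\infty(u_1))}.  Its two critical
#' points split the real line into three monotone branches, which
#' organize the equilibrium structure of the two-variable model.
#'
#' @param u1 membrane potential (vectorized).
#' @param params an `"ml_params_2d"`.
#' @return steady-state current value(s).
#' @export
steady_state_current <- function(u1, params) {
  g <- gating_functions(u1, params)
  ionic_current(u1, g$w_inf, params)
}

# derivative of the steady-state current (analytic)
steady_state_current_deriv <- function(u1, params) {
  g <- gating_functions(u1, params)
  ibar_du1(u1, g$w_inf, params) +
    params$WK * (u1 - params$FK) * d_w_inf(u1, params$F3, params$F4)
}

# critical points u1_max < u1_min of the steady-state current
steady_state_critical_points <- function(params, u1_range = NULL) {
  if (is.null(u1_range)) {
    anchors <- c(params$FK, params$FL, params$FCa, params$F1, params$F3)
    span <- diff(range(anchors))
    u1_range <- range(anchors) + c(-0.3, 0.3) * max(span, 1)
  }
  grid <- seq(u1_range[1L], u1_range[2L], length.out = 4001L)
  dv <- steady_state_current_deriv(grid, params)
  sgn <- which(dv[-1L] * dv[-length(dv)] < 0)
  crit <- vapply(sgn, function(i)
    stats::uniroot(function(u) steady_state_current_deriv(u, params),
                   c(grid[i], grid[i + 1L]), tol = 1e-12)$root, numeric(1))
  sort(crit)
}

#' Analytic Jacobian of the membrane models
#'
#' Closed-form partial derivatives of [rhs_2d()] / [rhs_3d()] at a
#' state.  For the slow-fast model the third row is
#' \eqn{(\theta, 0, 0)} and the slow variable enters the fast rows
#' through `Im(u3)` and the gating half-activation `F3(u3)`.
#'
#' @param params an `"ml_params_2d"` or `"ml_params_3d"`.
#' @param state state vector (length 2 or 3), typically an equilibrium.
#' @param Im applied current (2D model; defaults to `params$Im`).
#' @return the d x d Jacobian matrix.
#' @export
ml_jacobian <- function(params, state, Im = NULL) {
  if (inherits(params, "ml_params_2d")) {
    u1 <- state[1L]; u2 <- state[2L]
    g <- gating_functions(u1, params)
    J21 <- params$phi * (d_ell(u1, params$F3, params$F4) * (g$w_inf - u2) +
                           g$ell * d_w_inf(u1, params$F3, params$F4))
    matrix(c(-ibar_du1(u1, u2, params) / params$C,
             -params$WK * (u1 - params$FK) / params$C,
             J21,
             -params$phi * g$ell),
           2L, 2L, byrow = TRUE)
  } else {
    u1 <- state[1L]; u2 <- state[2L]; u3 <- state[3L]
    F3 <- gating_half_activation_3d(u3, params)
    g <- gating_functions(u1, params, u3 = u3)
    ell_ref <- if (params$ell_arg == "F3") F3 else params$F2
    dl_u1 <- d_ell(u1, ell_ref, params$F4)
    dw_u1 <- d_w_inf(u1, F3, params$F4)
    # F3(u3) = F3_base - u3, so d/du3 = +d/du1 on the (u1 - F3) argument
    dw_u3 <- dw_u1
    dl_u3 <- if (params$ell_arg == "F3") dl_u1 else 0
    J <- matrix(0, 3L, 3L)
    J[1L, 1L] <- -ibar_du1(u1, u2, params, u3 = u3) / params$C
    J[1L, 2L] <- -params$WK * (u1 - params$FK) / params$C
    J[1L, 3L] <- params$Im_slope / params$C
    J[2L, 1L] <- params$phi * (dl_u1 * (g$w_inf - u2) + g$ell * dw_u1)
    J[2L, 2L] <- -params$phi * g$ell
    J[2L, 3L] <- params$phi * (dl_u3 * (g$w_inf - u2) + g$ell * dw_u3)
    J[3L, 1L] <- params$theta
    J
  }
}

new_equilibrium_report <- function(location, branch, params, Im, order) {
  J <- ml_jacobian(params, location, Im = Im)
  ev <- eigen(J, only.values = TRUE)$values
  rep <- list(location = location, branch = branch, jacobian = J,
              eigenvalues = ev, order = order,
              classification = classify_equilibrium(ev, order))
  if (length(location) == 2L) {
    rep$chi <- sum(diag(J))
    rep$zeta <- J[1L, 1L] * J[2L, 2L] - J[1L, 2L] * J[2L, 1L]
    rep$hopf_order <- hopf_threshold_2d(rep$chi, rep$zeta)
  } else {
    cb <- cubic_coefficients_3d(J)
    rep$cubic <- cb$coefficients
    rep$discriminant <- cb$discriminant
    rep$hopf_order <- critical_order_3d(J)
  }
  class(rep) <- "equilibrium_report"
  rep
}

#' @export
print.equilibrium_report <- function(x, ...) {
  d <- length(x$location)
  cat(sprintf("Equilibrium (%s)%s: %s\n",
              paste(signif(x$location, 6), collapse = ", "),
              if (d == 2L) paste0(", branch ", x$branch) else "",
              x$classification))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 5),
                              collapse = ", "), "\n")
  th <- x$hopf_order
  cat("  critical order:", format(as.numeric(th), digits = 6),
      paste0("(", attr(th, "status"), ")"), "\n")
  invisible(x)
}

#' Equilibria of the two-variable model
#'
#' Solves \eqn{I_\infty(u_1) = I_m} by bracketed root finding on the
#' three monotone branches delimited by the critical points of the
#' steady-state current.  Depending on the applied current the model has
#' one, two or three equilibria; each is reported with its branch label
#' (1 = left/lower, 2 = middle, 3 = right/upper), analytic Jacobian,
#' trace, determinant, eigenvalues, Hopf threshold order and Matignon
#' classification at the supplied order.
#'
#' @param params an `"ml_params_2d"`.
#' @param Im applied current (defaults to `params$Im`).
#' @param order fractional order used for the classification label.
#' @param u1_range optional search interval for the critical points.
#' @return list of `"equilibrium_report"` objects.
#' @export
find_equilibria_2d <- function(params, Im = params$Im, order = 1,
                               u1_range = NULL) {
  crit <- steady_state_critical_points(params, u1_range)
  f <- function(u) steady_state_current(u, params) - Im
  roots <- list()
  # walk outward (doubling steps) until f attains the requested sign;
  # the steady-state current is unbounded in both directions, so this
  # terminates whenever the corresponding root exists
  seek <- function(from, dir, sgn) {
    step <- max(abs(from), 1)
    for (i in 1:60) {
      cand <- from + dir * step
      if (sign(f(cand)) == sgn || f(cand) == 0) return(cand)
      step <- step * 2
    }
    stop("root bracketing failed: steady-state current never crosses Im",
         call. = FALSE)
  }
  add_root <- function(lo, hi, branch) {
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return()
    r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    roots[[length(roots) + 1L]] <<- c(r, branch)
  }
  if (length(crit) >= 2L) {
    u1max <- crit[1L]; u1min <- crit[length(crit)]
    if (f(u1max) >= 0) add_root(seek(u1max, -1, -1), u1max, 1L)
    add_root(u1max, u1min, 2L)
    if (f(u1min) <= 0) add_root(u1min, seek(u1min, +1, +1), 3L)
  } else {
    # monotone steady-state current: single branch
    add_root(seek(0, -1, -1), seek(0, +1, +1), 1L)
  }
  if (!length(roots))
    stop("no equilibrium found for Im = ", Im, call. = FALSE)
  lapply(roots, function(r) {
    u1s <- r[1L]
    u2s <- gating_functions(u1s, params)$w_inf
    new_equilibrium_report(c(u1 = u1s, u2 = u2s), branch = r[2L],
                           params = params, Im = Im, order = order)
  })
}

#' Equilibrium of the slow-fast three-variable model
#'
#' The slow equation pins \eqn{u_1^* = -F_0}; the slow variable
#' \eqn{u_3^*} is the unique root of the non-increasing map
#' \eqn{u_3 \mapsto I_m(u_3) - \bar I(-F_0, \bar w(-F_0, u_3))},
#' located by monotone bisection; \eqn{u_2^* = \bar w(u_1^*, u_3^*)}.
#' The standing assumption \eqn{F_0 + F_K < 0} is checked and a warning
#' (not an error) is emitted if it fails.
#'
#' @param params an `"ml_params_3d"`.
#' @param order fractional order used for the classification label.
#' @return an `"equilibrium_report"` with the 3 x 3 Jacobian, cubic
#'   characteristic coefficients, discriminant and critical order.
#' @export
find_equilibrium_3d <- function(params, order = 1) {
  if (params$F0 + params$FK >= 0)
    warning("assumption F0 + FK < 0 violated; equilibrium may not be unique")
  u1s <- -params$F0
  f <- function(u3) {
    w <- gating_functions(u1s, params, u3 = u3)$w_inf
    applied_current_3d(u3, params) - ionic_current(u1s, w, params, u3 = u3)
  }
  lo <- -1; hi <- 1
  for (i in 1:60) {
    if (f(lo) > 0) break
    lo <- lo * 2
  }
  for (i in 1:60) {
    if (f(hi) < 0) break
    hi <- hi * 2
  }
  if (f(lo) <= 0 || f(hi) >= 0)
    stop("no sign change bracketed for the slow-variable equation",
         call. = FALSE)
  u3s <- stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
  u2s <- gating_functions(u1s, params, u3 = u3s)$w_inf
  new_equilibrium_report(c(u1 = u1s, u2 = u2s, u3 = u3s), branch = 1L,
                         params = params, Im = NULL, order = order)
}

#' Hopf threshold order of a planar equilibrium
#'
#' For an equilibrium with Jacobian trace \eqn{\chi} and determinant
#' \eqn{\zeta > 0}, asymptotic stability of the fractional-order system
#' requires \eqn{\chi < 2\sqrt{\zeta}\cos(\vartheta\pi/2)}.  The
#' threshold order at which a complex pair crosses the Matignon boundary
#' is \deqn{\vartheta^* = \frac{2}{\pi}
#'   \cos^{-1}\!\left(\frac{\chi}{2\sqrt{\zeta}}\right).}
#' If \eqn{\chi < 0} the equilibrium is stable for every order in
#' (0, 1] and the function returns 1; if \eqn{\chi \ge 2\sqrt\zeta} it is
#' unstable for every order and the function returns 0; if
#' \eqn{\zeta \le 0} the equilibrium is a saddle and no threshold exists
#' (`NA` with status `"saddle"`).
#'
#' @param chi Jacobian trace.
#' @param zeta Jacobian determinant.
#' @return numeric threshold in \[0, 1\] (or `NA`), with attribute
#'   `"status"` one of `"stable-all-orders"`, `"hopf"`,
#'   `"unstable-all-orders"`, `"saddle"`.
#' @export
hopf_threshold_2d <- function(chi, zeta) {
  if (zeta <= 0)
    return(structure(NA_real_, status = "saddle"))
  if (chi < 0)
    return(structure(1, status = "stable-all-orders"))
  r <- chi / (2 * sqrt(zeta))
  if (r >= 1)
    return(structure(0, status = "unstable-all-orders"))
  structure(2 / pi * acos(r), status = "hopf")
}

#' Characteristic cubic of a 3 x 3 Jacobian
#'
#' Coefficients of \eqn{\lambda^3 + \varpi_1\lambda^2 + \varpi_2\lambda
#' + \varpi_3} with \eqn{\varpi_1 = -\mathrm{tr}\,J}, \eqn{\varpi_2} the
#' sum of principal 2-minors, \eqn{\varpi_3 = -\det J}, together with
#' the standard cubic discriminant
#' \eqn{D = 18\varpi_1\varpi_2\varpi_3 - 4\varpi_1^3\varpi_3 +
#' \varpi_1^2\varpi_2^2 - 4\varpi_2^3 - 27\varpi_3^2}
#' (\eqn{D > 0}: three distinct real eigenvalues; \eqn{D < 0}: one real
#' eigenvalue and a complex-conjugate pair).
#'
#' @param jacobian a real 3 x 3 matrix.
#' @return list with `coefficients` (`w1`, `w2`, `w3`) and
#'   `discriminant`.
#' @export
cubic_coefficients_3d <- function(jacobian) {
  if (!is.matrix(jacobian) || any(dim(jacobian) != 3L))
    stop("`jacobian` must be a 3 x 3 matrix", call. = FALSE)
  J <- jacobian
  w1 <- -sum(diag(J))
  w2 <- (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]) +
        (J[1, 1] * J[3, 3] - J[1, 3] * J[3, 1]) +
        (J[2, 2] * J[3, 3] - J[2, 3] * J[3, 2])
  w3 <- -det(J)
  D <- 18 * w1 * w2 * w3 - 4 * w1^3 * w3 + w1^2 * w2^2 - 4 * w2^3 -
    27 * w3^2
  list(coefficients = c(w1 = w1, w2 = w2, w3 = w3), discriminant = D)
}

#' Matignon classification of an equilibrium
#'
#' A fractional-order equilibrium is asymptotically stable iff every
#' Jacobian eigenvalue satisfies \eqn{|\arg\lambda| > \vartheta\pi/2}.
#' Eigenvalues violating the condition count towards the saddle rank;
#' an eigenvalue on the boundary (within `tol`) flags a Hopf-type
#' boundary.
#'
#' @param eigenvalues complex (or real) eigenvalue vector.
#' @param order fractional order \eqn{\vartheta \in (0, 1]}.
#' @param tol boundary detection tolerance on \eqn{|\arg\lambda| -
#'   \vartheta\pi/2}.
#' @return character label: `"stable"`, `"unstable"`,
#'   `"saddle-rank-<k>"` or `"hopf-boundary"`.
#' @export
classify_equilibrium <- function(eigenvalues, order, tol = 1e-9) {
  if (!length(eigenvalues)) stop("empty eigenvalue list", call. = FALSE)
  if (order <= 0 || order > 1)
    stop("`order` must lie in (0, 1]", call. = FALSE)
  a <- abs(Arg(as.complex(eigenvalues)))
  b <- order * pi / 2
  if (any(abs(a - b) < tol)) return("hopf-boundary")
  k <- sum(a < b)
  if (k == 0L) "stable"
  else if (k == length(a)) "unstable"
  else paste0("saddle-rank-", k)
}

#' Critical fractional order of a three-dimensional equilibrium
#'
#' The Matignon boundary order \eqn{\vartheta^* = (2/\pi)\min_\lambda
#' |\arg\lambda|} of the Jacobian eigenvalues: the equilibrium is stable
#' for \eqn{\vartheta < \vartheta^*} and unstable for
#' \eqn{\vartheta > \vartheta^*}.  When every eigenvalue lies in the
#' open left half plane the equilibrium is stable for all orders in
#' (0, 1] and the function returns 1; a positive real eigenvalue forces
#' \eqn{\vartheta^* = 0} (unstable for every order).
#'
#' @param jacobian real Jacobian matrix (any dimension).
#' @return numeric threshold with attribute `"status"` one of
#'   `"stable-all-orders"`, `"hopf"`, `"unstable-all-orders"`.
#' @export
critical_order_3d <- function(jacobian) {
  ev <- eigen(jacobian, only.values = TRUE)$values
  a <- abs(Arg(as.complex(ev)))
  if (all(a > pi / 2))
    return(structure(1, status = "stable-all-orders"))
  th <- 2 / pi * min(a)
  structure(th, status = if (th > 0) "hopf" else "unstable-all-orders")
}

#' Commensurate discrete-map stability test
#'
#' Stability condition for the linearized commensurate Caputo
#' delta-difference system of order \eqn{\vartheta \in (0,1)}: every
#' Jacobian eigenvalue must satisfy both
#' \deqn{|\lambda| \le \left(2\cos\frac{|\arg\lambda| - \pi}
#'   {2 - \vartheta}\right)^{\vartheta} \quad\text{and}\quad
#'   |\arg\lambda| \ge \frac{\vartheta\pi}{2}.}
#' Some statements of this criterion carry a leading factor 2 on the
#' modulus bound; direct simulation of the scalar map locates the
#' decay/divergence flip at \eqn{2^\vartheta} on the negative real axis
#' (e.g. between 1.6 and 1.75 for \eqn{\vartheta = 0.75}), matching the
#' bound above, so the factor-2 variant is available only behind
#' `printed_bound = TRUE`.
#'
#' @param eigenvalues complex (or real) eigenvalue vector.
#' @param order fractional order in (0, 1).
#' @param printed_bound use the (looser) factor-2 modulus bound.
#' @return logical: `TRUE` iff every eigenvalue lies in the stability
#'   region.
#' @export
commensurate_stability_test <- function(eigenvalues, order,
                                        printed_bound = FALSE) {
  if (order <= 0 || order >= 1)
    stop("`order` must lie strictly in (0, 1)", call. = FALSE)
  ev <- as.complex(eigenvalues)
  a <- abs(Arg(ev))
  base <- pmax(2 * cos((a - pi) / (2 - order)), 0)
  bound <- (if (printed_bound) 2 else 1) * base^order
  all(Mod(ev) <= bound & a >= order * pi / 2)
}

# ---- rational order utilities -------------------------------------------

# continued-fraction rationalization of a fractional order
rationalize_order <- function(x, max_denominator = 1000L, tol = 1e-12) {
  for (den in seq_len(max_denominator)) {
    num <- round(x * den)
    if (num >= 1 && abs(num / den - x) < tol) {
      g <- gcd_int(num, den)
      return(c(numerator = num / g, denominator = den / g))
    }
  }
  stop(sprintf(paste0("order %g has no rational form with denominator <= %d; ",
                      "supply a rationalized order"), x, max_denominator),
       call. = FALSE)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
lcm_int <- function(a, b) a / gcd_int(a, b) * b

#' Per-component fractional order specification
#'
#' Stores the order of each state component together with the rational
#' forms \eqn{\vartheta_\iota = w_\iota / \sigma_\iota} (reduced) and
#' their least common denominator \eqn{H}, as needed by the
#' incommensurate stability test.
#'
#' @param orders numeric vector of orders in (0, 1\].
#' @param max_denominator largest denominator tried when rationalizing.
#' @return object of class `"order_spec"` with fields `orders`,
#'   `numerators`, `denominators`, `H`, `commensurate`.
#' @export
order_spec <- function(orders, max_denominator = 1000L) {
  if (any(orders <= 0) || any(orders > 1))
    stop("all orders must lie in (0, 1]", call. = FALSE)
  rf <- vapply(orders, rationalize_order, numeric(2),
               max_denominator = max_denominator)
  H <- Reduce(lcm_int, rf["denominator", ])
  structure(list(orders = orders,
                 numerators = unname(rf["numerator", ]),
                 denominators = unname(rf["denominator", ]),
                 H = H,
                 commensurate = length(unique(orders)) == 1L),
            class = "order_spec")
}

# ---- polynomial helpers for the incommensurate criterion ----------------

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}
poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) if (a[i] != 0)
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}
# determinant of a matrix of polynomials (list-of-lists, coef ascending)
poly_det <- function(M) {
  d <- length(M)
  if (d == 1L) return(M[[1L]][[1L]])
  acc <- NULL
  for (i in seq_len(d)) {
    minor <- lapply(seq_len(d)[-i], function(r) M[[r]][-1L])
    term <- poly_mul(M[[i]][[1L]], poly_det(minor))
    if (i %% 2L == 0L) term <- -term
    acc <- if (is.null(acc)) term else poly_add(acc, term)
  }
  acc
}

# roots of a polynomial (ascending coefficients) via companion matrix
poly_roots <- function(coef) {
  while (length(coef) > 1L && coef[length(coef)] == 0)
    coef <- coef[-length(coef)]
  n <- length(coef) - 1L
  if (n < 1L) return(complex(0))
  monic <- coef / coef[n + 1L]
  Cm <- matrix(0, n, n)
  if (n > 1L) Cm[cbind(2:n, 1:(n - 1L))] <- 1
  Cm[, n] <- -monic[1:n]
  eigen(Cm, only.values = TRUE)$values
}

#' Incommensurate discrete-system stability test
#'
#' For a system whose components carry rational fractional orders
#' \eqn{\vartheta_\iota = w_\iota/\sigma_\iota} with least common
#' denominator \eqn{H}, stability of the linearization \eqn{J} is
#' decided by the roots of
#' \deqn{\det\left(\mathrm{diag}(\rho^{H\vartheta_1}, \dots,
#'   \rho^{H\vartheta_n}) - (1 - \rho^H)\, J\right) = 0:}
#' the zero solution is locally asymptotically stable iff every root
#' lies outside the region
#' \eqn{K^\xi = \{ w : |w| \le (2\cos(|\arg w|/\xi))^\xi,\;
#' |\arg w| \le \xi\pi/2 \}} with \eqn{\xi = 1/H}.  The determinant is
#' expanded symbolically into a univariate polynomial and its roots are
#' obtained as companion-matrix eigenvalues.
#'
#' @param jacobian real n x n Jacobian matrix.
#' @param orders numeric vector of n orders, or an [order_spec()].
#' @param degree_cap refuse polynomials beyond this degree.
#' @return list with `stable` (logical), `roots` (complex vector),
#'   `H`, and `inside` (logical vector marking roots inside the
#'   instability region).
#' @export
incommensurate_stability_test <- function(jacobian, orders,
                                          degree_cap = 600L) {
  J <- as.matrix(jacobian)
  spec <- if (inherits(orders, "order_spec")) orders else order_spec(orders)
  n <- nrow(J)
  if (length(spec$orders) != n)
    stop("orders length must match the Jacobian dimension", call. = FALSE)
  H <- spec$H
  m <- round(H * spec$orders)          # integer exponents H * theta_i
  if (max(c(m, H)) * n > degree_cap)
    stop("polynomial degree exceeds `degree_cap`; reduce denominators",
         call. = FALSE)
  # entry (i, j): delta_ij * rho^{m_i} - (1 - rho^H) * J[i, j]
  M <- lapply(seq_len(n), function(i) lapply(seq_len(n), function(j) {
    p <- numeric(H + 1L)
    p[1L] <- -J[i, j]
    p[H + 1L] <- J[i, j]
    if (i == j) {
      q <- numeric(m[i] + 1L)
      q[m[i] + 1L] <- 1
      p <- poly_add(p, q)
    }
    p
  }))
  rts <- poly_roots(poly_det(M))
  xi <- 1 / H
  a <- abs(Arg(rts))
  inside <- a <= xi * pi / 2 &
    Mod(rts) <= (2 * cos(pmin(a / xi, pi / 2)))^xi
  list(stable = !any(inside), roots = rts, H = H, inside = inside)
}
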