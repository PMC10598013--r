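#' Parameter set for the two-variable Morris-Lecar neuron
#'
#' Bundles the biophysical constants of the conductance-based membrane
#' model: maximal conductances of the calcium, potassium and leak
#' currents, their reversal potentials, the tanh gating constants, the
#' gating rate and the membrane capacitance.
#'
#' @param C membrane capacitance (> 0).
#' @param WCa,WK,WL maximal conductances of the Ca2+, K+ and leak
#'   currents (> 0).
#' @param FCa,FK,FL reversal potentials.
#' @param F1,F2 half-activation and slope of the fast calcium gate
#'   (`F2 != 0`).
#' @param F3,F4 half-activation and slope of the potassium gate
#'   (`F4 != 0`).
#' @param phi potassium gating rate constant (> 0).
#' @param Im applied current.
#' @param ca_drive calcium driving force convention: `"FCa"` uses
#'   `u1 - FCa` (dimensional model), `"unit"` uses `u1 - 1`
#'   (dimensionless model).
#' @return object of class `"ml_params_2d"`.
#' @export
ml_params_2d <- function(C, WCa, WK, WL, FCa, FK, FL, F1, F2, F3, F4,
                         phi, Im = 0, ca_drive = c("FCa", "unit")) {
  ca_drive <- match.arg(ca_drive)
  stopifnot(C > 0, WCa > 0, WK > 0, WL > 0, F2 != 0, F4 != 0, phi > 0)
  structure(list(C = C, WCa = WCa, WK = WK, WL = WL, FCa = FCa, FK = FK,
                 FL = FL, F1 = F1, F2 = F2, F3 = F3, F4 = F4, phi = phi,
                 Im = Im, ca_drive = ca_drive),
            class = "ml_params_2d")
}

#' Parameter set for the three-variable slow-fast Morris-Lecar neuron
#'
#' The dimensionless slow-fast extension: the fast pair (membrane
#' potential `u1`, potassium gate `u2`) is driven by a slow variable
#' `u3` that modulates both the applied current,
#' `Im(u3) = Im_intercept + Im_slope * u3`, and the potassium gating
#' half-activation, `F3(u3) = F3_base - u3`.  The slow equation is
#' `theta * (u1 + F0)` with time-scale ratio `theta` in (0, 1).  The
#' calcium driving force is `u1 - 1` (dimensionless convention).
#'
#' `ell_arg` selects the argument of the gating-rate cosh term:
#' `"F3"` (default) uses the slow-modulated half-activation, keeping the
#' gate consistent with its steady-state curve; `"F2"` uses the fixed
#' calcium slope constant instead, as some renderings of the model print.
#'
#' @param WCa,WK,WL maximal conductances.
#' @param FCa,FK,FL reversal potentials (`FCa` retained for reference;
#'   the driving force is `u1 - 1`).
#' @param F1,F2 calcium gating constants.
#' @param F4 potassium gating slope.
#' @param phi gating rate constant.
#' @param F0 slow-variable offset; the equilibrium has `u1* = -F0`.
#' @param theta slow/fast time-scale ratio in (0, 1).
#' @param C membrane capacitance (1 in the dimensionless groups).
#' @param Im_intercept,Im_slope affine law of the slow applied current.
#' @param F3_base intercept of the slow gating half-activation.
#' @param ell_arg `"F3"` or `"F2"`, see Details.
#' @return object of class `"ml_params_3d"`.
#' @export
ml_params_3d <- function(WCa, WK, WL, FCa, FK, FL, F1, F2, F4, phi,
                         F0, theta, C = 1,
                         Im_intercept = 0.08, Im_slope = -0.03,
                         F3_base = 0.08, ell_arg = c("F3", "F2")) {
  ell_arg <- match.arg(ell_arg)
  stopifnot(C > 0, WCa > 0, WK > 0, WL > 0, F2 != 0, F4 != 0, phi > 0,
            theta > 0, theta < 1)
  structure(list(WCa = WCa, WK = WK, WL = WL, FCa = FCa, FK = FK, FL = FL,
                 F1 = F1, F2 = F2, F4 = F4, phi = phi, F0 = F0,
                 theta = theta, C = C, Im_intercept = Im_intercept,
                 Im_slope = Im_slope, F3_base = F3_base, ell_arg = ell_arg,
                 ca_drive = "unit"),
            class = "ml_params_3d")
}

#' Slow-modulated applied current and gating half-activation
#'
#' @param u3 slow variable value(s).
#' @param params an `"ml_params_3d"` object.
#' @return numeric: `Im(u3)` resp. `F3(u3)`.
#' @export
applied_current_3d <- function(u3, params) {
  params$Im_intercept + params$Im_slope * u3
}

#' @rdname applied_current_3d
#' @export
gating_half_activation_3d <- function(u3, params) {
  params$F3_base - u3
}

#' Registry of published Morris-Lecar parameter groups
#'
#' Returns the fixed parameter groups used throughout the package.
#' For the two-variable model, group `"i"` is the dimensional class-I
#' excitable set (C = 20, calcium driving force `u1 - FCa`) and group
#' `"ii"` is the class-II set obtained from it by the overrides
#' WCa = 4.4, F3 = 2, F4 = 30, phi = 0.04.  For the slow-fast
#' three-variable model, groups `"i"`, `"ii"` and `"iii"` are the three
#' dimensionless sets (C = 1, driving force `u1 - 1`,
#' Im(u3) = 0.08 - 0.03 u3, F3(u3) = 0.08 - u3).
#'
#' @param group one of `"i"`, `"ii"`, `"iii"` (`"iii"` only for the
#'   3D model).
#' @param model `"2d"` or `"3d"`.
#' @return a list with elements `group`, `model`, `params` (an
#'   `"ml_params_2d"` or `"ml_params_3d"`), and `applied_currents`
#'   (the published applied-current values associated with the group;
#'   for the 3D model the current follows the `Im(u3)` law and the
#'   element is `NULL`).
#' @export
ml_group <- function(group = c("i", "ii", "iii"), model = c("2d", "3d")) {
  group <- match.arg(group)
  model <- match.arg(model)
  if (model == "2d") {
    if (group == "iii")
      stop("2D model defines groups \"i\" (class I) and \"ii\" (class II) only",
           call. = FALSE)
    base <- ml_params_2d(C = 20, WCa = 4, WK = 8, WL = 2,
                         FCa = 120, FK = -84, FL = -60,
                         F1 = -1.2, F2 = 18, F3 = 12, F4 = 17.4,
                         phi = 0.067, Im = 40)
    if (group == "i") {
      list(group = "i", model = "2d", params = base,
           applied_currents = c(40, 42, 43, 45, 50))
    } else {
      p <- base
      p$WCa <- 4.4; p$F3 <- 2; p$F4 <- 30; p$phi <- 0.04; p$Im <- 100
      list(group = "ii", model = "2d", params = p,
           applied_currents = c(90, 100))
    }
  } else {
    tab <- list(
      i   = list(WCa = 0.9,  F4 = 0.04, F0 = 0.22, theta = 0.003),
      ii  = list(WCa = 1.36, F4 = 0.16, F0 = 0.1,  theta = 0.003),
      iii = list(WCa = 0.9,  F4 = 0.05, F0 = 0,    theta = 0.005))
    g <- tab[[group]]
    p <- ml_params_3d(WCa = g$WCa, WK = 2, WL = 0.5, FCa = 1, FK = -0.7,
                      FL = -0.5, F1 = -0.01, F2 = 0.15, F4 = g$F4,
                      phi = 0.033, F0 = g$F0, theta = g$theta, C = 1)
    list(group = group, model = "3d", params = p, applied_currents = NULL)
  }
}

#' Published reference values attached to the parameter groups
#'
#' Worked-example numbers published alongside the parameter groups:
#' critical fractional orders (Hopf threshold orders) and an equilibrium
#' membrane potential.  They are used only as anchors when scanning
#' which (group, applied current) combination a published threshold
#' belongs to; all reported quantities are recomputed by the package.
#'
#' @return named list of published reference values.
#' @export
ml_reference_values <- function() {
  list(
    hopf_order_2d_phase_portrait = 0.89342,  # class-II phase-portrait study
    hopf_order_2d_group_i  = 0.83241,
    hopf_order_2d_group_ii = 0.96720,
    critical_order_3d_group_iii = 0.7391,
    equilibrium_u1_2d_phase_portrait = 6.23101
  )
}

#' Steady-state gating curves and gating rate
#'
#' The tanh/cosh gating functions of the membrane model:
#' \deqn{r_\infty(u_1) = \tfrac12\left(1 + \tanh\frac{u_1 - F_1}{F_2}\right),
#' \quad w_\infty(u_1) = \tfrac12\left(1 + \tanh\frac{u_1 - F_3}{F_4}\right),
#' \quad \ell(u_1) = \cosh\frac{u_1 - F_3}{2 F_4}.}
#' For the slow-fast model the potassium half-activation is the
#' slow-modulated `F3(u3)`, supplied through `u3`.
#'
#' @param u1 membrane potential (vectorized).
#' @param params `"ml_params_2d"` or `"ml_params_3d"`.
#' @param u3 slow variable, required for `"ml_params_3d"`.
#' @return list with components `r_inf`, `w_inf`, `ell`.
#' @export
gating_functions <- function(u1, params, u3 = NULL) {
  if (inherits(params, "ml_params_3d")) {
    if (is.null(u3)) stop("`u3` is required for the 3D model", call. = FALSE)
    F3 <- gating_half_activation_3d(u3, params)
    ell_ref <- if (params$ell_arg == "F3") F3 else params$F2
  } else {
    F3 <- params$F3
    ell_ref <- params$F3
  }
  list(r_inf = 0.5 * (1 + tanh((u1 - params$F1) / params$F2)),
       w_inf = 0.5 * (1 + tanh((u1 - F3) / params$F4)),
       ell   = cosh((u1 - ell_ref) / (2 * params$F4)))
}

#' Total ionic membrane current
#'
#' \deqn{\bar I(u_1, u_2) = W_{Ca}\, r_\infty(u_1)\,(u_1 - d) +
#'   W_K\, u_2\, (u_1 - F_K) + W_L\, (u_1 - F_L),}
#' where the calcium driving force `d` is `u1 - FCa` in the dimensional
#' model and `u1 - 1` in the dimensionless one.
#'
#' @param u1,u2 membrane potential and gating variable (vectorized).
#' @param params parameter object.
#' @param u3 slow variable (3D model only; enters through the gating).
#' @return numeric ionic current.
#' @export
ionic_current <- function(u1, u2, params, u3 = NULL) {
  g <- gating_functions(u1, params, u3)
  drive <- if (params$ca_drive == "unit") u1 - 1 else u1 - params$FCa
  params$WCa * g$r_inf * drive + params$WK * u2 * (u1 - params$FK) +
    params$WL * (u1 - params$FL)
}

#' Right-hand side of the two-variable membrane model
#'
#' \deqn{\dot u_1 = (I_m - \bar I(u_1, u_2)) / C, \qquad
#'       \dot u_2 = \varphi\, \ell(u_1)\, (w_\infty(u_1) - u_2).}
#' The capacitance division is performed here, so the solver sees the
#' membrane equation already in normalized form.
#'
#' @param state numeric vector `c(u1, u2)`.
#' @param params an `"ml_params_2d"`.
#' @param Im applied current; defaults to `params$Im`.
#' @return derivative vector of length 2.
#' @export
rhs_2d <- function(state, params, Im = params$Im) {
  u1 <- state[1L]; u2 <- state[2L]
  g <- gating_functions(u1, params)
  c((Im - ionic_current(u1, u2, params)) / params$C,
    params$phi * g$ell * (g$w_inf - u2))
}

#' Right-hand side of the slow-fast three-variable model
#'
#' The fast pair as in [rhs_2d()] but with the slow-modulated applied
#' current `Im(u3)` and gating half-activation `F3(u3)`; the slow
#' variable obeys \eqn{\dot u_3 = \theta (u_1 + F_0)}.
#'
#' @param state numeric vector `c(u1, u2, u3)`.
#' @param params an `"ml_params_3d"`.
#' @param Im optional constant applied current overriding the `Im(u3)`
#'   law (used by the reduced cluster model).
#' @return derivative vector of length 3.
#' @export
rhs_3d <- function(state, params, Im = NULL) {
  u1 <- state[1L]; u2 <- state[2L]; u3 <- state[3L]
  g <- gating_functions(u1, params, u3 = u3)
  drive <- if (is.null(Im)) applied_current_3d(u3, params) else Im
  c((drive - ionic_current(u1, u2, params, u3 = u3)) / params$C,
    params$phi * g$ell * (g$w_inf - u2),
    params$theta * (u1 + params$F0))
}
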