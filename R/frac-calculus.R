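#' Falling-factorial kernel weights of the discrete fractional sum
#'
#' Computes the Grunwald-type weights
#' \deqn{c_j = \frac{\Gamma(j+\vartheta)}{\Gamma(\vartheta)\,\Gamma(j+1)},
#'       \qquad j = 0, 1, \dots, n-1,}
#' which appear in the delta fractional sum and in the explicit
#' memory-convolution solver for Caputo delta-difference systems.  The
#' weights are evaluated by the stable multiplicative recurrence
#' \eqn{c_0 = 1}, \eqn{c_j = c_{j-1}(j-1+\vartheta)/j}; direct gamma
#' quotients overflow for arguments above roughly 170 and are never used.
#'
#' For \eqn{\vartheta = 1} every weight equals 1 (the running sum); for
#' \eqn{\vartheta \in (0,1)} the weights decay monotonically, which is the
#' algebraic expression of fading memory.
#'
#' @param order fractional order \eqn{\vartheta \in (0, 1]}.
#' @param n_terms number of weights to generate (at least 1).
#' @param step time step \eqn{h > 0}; stored for use by the solver, which
#'   scales the memory convolution by \eqn{h^\vartheta}.
#' @return an object of class `"kernel_weights"`: a list with elements
#'   `order`, `step`, and the numeric vector `weights` of length `n_terms`.
#' @examples
#' kernel_weights(0.5, 4)$weights  # 1, 0.5, 0.375, 0.3125
#' @export
kernel_weights <- function(order, n_terms, step = 1) {
  if (!is.numeric(order) || length(order) != 1L || is.na(order) ||
      order <= 0 || order > 1)
    stop("`order` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(n_terms) || length(n_terms) != 1L || is.na(n_terms) ||
      n_terms < 1)
    stop("`n_terms` must be a positive integer", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("`step` must be positive", call. = FALSE)
  n_terms <- as.integer(n_terms)
  w <- numeric(n_terms)
  w[1L] <- 1
  if (n_terms > 1L) {
    j <- seq_len(n_terms - 1L)
    w <- cumprod(c(1, (j - 1 + order) / j))
  }
  structure(list(order = order, step = step, weights = w),
            class = "kernel_weights")
}

#' @export
print.kernel_weights <- function(x, ...) {
  cat("Fractional kernel weights: order", x$order, ", step", x$step,
      ",", length(x$weights), "terms\n")
  print(utils::head(x$weights, 8L))
  if (length(x$weights) > 8L) cat("...\n")
  invisible(x)
}

#' Delta fractional sum on the integer time scale
#'
#' Applies the fractional sum operator \eqn{\Delta^{-\vartheta}} of order
#' \eqn{\vartheta > 0} to a sequence sampled on \eqn{\{a, a+1, \dots\}}.
#' On the shifted time scale the operator is the discrete convolution of
#' the sequence with the falling-factorial weights: the k-th output value
#' is \eqn{\sum_{j=0}^{k-1} c_{k-1-j}\,F_j} with
#' \eqn{c_m = \Gamma(m+\vartheta)/(\Gamma(\vartheta)\Gamma(m+1))}.
#' For \eqn{\vartheta = 1} this is the plain running sum.
#'
#' @param values numeric vector of samples \eqn{F(a), F(a+1), \dots}.
#' @param order fractional order \eqn{\vartheta > 0}.
#' @return numeric vector of the same length: the fractional sum evaluated
#'   at the successive points of the shifted time scale.
#' @export
fractional_sum <- function(values, order) {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (!is.numeric(order) || length(order) != 1L || is.na(order) || order <= 0)
    stop("`order` must be positive", call. = FALSE)
  n <- length(values)
  # weights for order > 1 follow the same recurrence
  j <- seq_len(max(n - 1L, 0L))
  w <- if (n > 1L) cumprod(c(1, (j - 1 + order) / j)) else 1
  out <- numeric(n)
  for (k in seq_len(n)) out[k] <- sum(w[k:1] * values[seq_len(k)])
  out
}

#' Integer-order forward difference
#'
#' The q-th forward difference via the signed binomial expansion
#' \deqn{\Delta^q F(k) = \sum_{\chi=0}^{q} \binom{q}{\chi} (-1)^{q-\chi}
#'       F(k+\chi).}
#' For `q = 1` this is the first forward difference `diff(values)`.
#'
#' @param values numeric vector, longer than `q`.
#' @param q positive integer difference order.
#' @return numeric vector of length `length(values) - q`.
#' @export
integer_difference <- function(values, q = 1L) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q != round(q))
    stop("`q` must be a positive integer", call. = FALSE)
  q <- as.integer(q)
  n <- length(values)
  if (n <= q) stop("sequence must be longer than `q`", call. = FALSE)
  coef <- choose(q, 0:q) * (-1)^(q - (0:q))
  vapply(seq_len(n - q), function(k) sum(coef * values[k:(k + q)]), numeric(1))
}

#' Caputo delta fractional difference of a sequence
#'
#' For \eqn{\vartheta \in (0, 1)} the Caputo difference is the fractional
#' sum of order \eqn{1 - \vartheta} applied to the first forward
#' difference: \eqn{{}^c\Delta^\vartheta F = \Delta^{-(1-\vartheta)}
#' \Delta^1 F}, living on the shifted time scale.  A constant sequence
#' therefore maps to zero.
#'
#' @param values numeric vector of length at least 2.
#' @param order fractional order \eqn{\vartheta \in (0, 1)}.
#' @return numeric vector of length `length(values) - 1`.
#' @export
caputo_difference <- function(values, order) {
  if (!is.numeric(order) || length(order) != 1L || is.na(order) ||
      order <= 0 || order >= 1)
    stop("`order` must lie strictly in (0, 1)", call. = FALSE)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  fractional_sum(integer_difference(values, 1L), 1 - order)
}

new_trajectory <- function(times, states, orders, step, memory_length) {
  colnames(states) <- paste0("u", seq_len(ncol(states)))
  structure(list(times = times, states = states, orders = orders,
                 step = step, memory_length = memory_length),
            class = "ml_trajectory")
}

#' @export
print.ml_trajectory <- function(x, ...) {
  cat("Discrete fractional-order trajectory:",
      nrow(x$states) - 1L, "steps,", ncol(x$states), "state components\n")
  cat("  orders:", paste(signif(x$orders, 6), collapse = ", "),
      " step h =", x$step,
      if (is.finite(x$memory_length)) paste(" memory L =", x$memory_length)
      else " full memory", "\n")
  invisible(x)
}

#' @export
as.data.frame.ml_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Explicit memory-convolution solver, commensurate order
#'
#' Iterates the discrete Caputo-difference initial value problem
#' \deqn{x(n) = x(0) + \frac{h^\vartheta}{\Gamma(\vartheta)}
#'   \sum_{\lambda=0}^{n-1}
#'   \frac{\Gamma(n-\lambda-1+\vartheta)}{\Gamma(n-\lambda)}\, f(x(\lambda)),}
#' the explicit numerical realization of the Caputo delta-difference
#' system \eqn{{}^c\Delta^\vartheta x = f(x)}.  With `step = 1` and
#' \eqn{\vartheta = 1} the scheme degenerates to the forward Euler map
#' \eqn{x(n+1) = x(n) + f(x(n))}; for \eqn{\vartheta < 1} every new state
#' depends on the entire history through the decaying kernel weights
#' (full memory, quadratic cost).  An optional short-memory truncation
#' keeps only the `memory_length` most recent terms.
#'
#' The right-hand side is evaluated at stored past states; any
#' capacitance division (membrane equation) is expected to be performed
#' inside `rhs` itself.
#'
#' @param rhs function of the state vector returning the derivative
#'   vector (same length).
#' @param order commensurate fractional order \eqn{\vartheta \in (0, 1]}.
#' @param x0 numeric initial state vector.
#' @param n_steps number of steps to take.
#' @param step time step \eqn{h > 0} (default 1, reproducing the
#'   dimensionless scheme exactly).
#' @param memory_length number of most recent memory terms retained;
#'   `Inf` (default) keeps the full history.
#' @return an `"ml_trajectory"` with `n_steps + 1` rows (initial state
#'   included).
#' @seealso [solve_incommensurate()] for distinct per-component orders.
#' @export
solve_commensurate <- function(rhs, order, x0, n_steps, step = 1,
                               memory_length = Inf) {
  solve_incommensurate(rhs, rep(order, length(x0)), x0, n_steps,
                       step = step, memory_length = memory_length)
}

#' Explicit memory-convolution solver, incommensurate orders
#'
#' As [solve_commensurate()], but each state component \eqn{\iota}
#' carries its own fractional order \eqn{\vartheta_\iota} and is updated
#' with its own kernel weights.  When all orders coincide the result is
#' bit-identical to the commensurate solver.
#'
#' @param rhs function of the state vector returning the derivative vector.
#' @param orders numeric vector of per-component orders in \eqn{(0, 1]},
#'   one per state component.
#' @param x0 numeric initial state vector.
#' @param n_steps number of steps.
#' @param step time step \eqn{h > 0}.
#' @param memory_length short-memory truncation length; `Inf` = full.
#' @return an `"ml_trajectory"`.
#' @export
solve_incommensurate <- function(rhs, orders, x0, n_steps, step = 1,
                                 memory_length = Inf) {
  d <- length(x0)
  if (length(orders) != d)
    stop("length(orders) must equal the state dimension", call. = FALSE)
  if (any(!is.finite(orders)) || any(orders <= 0) || any(orders > 1))
    stop("all orders must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(n_steps) || n_steps < 1)
    stop("`n_steps` must be at least 1", call. = FALSE)
  if (!is.numeric(step) || step <= 0)
    stop("`step` must be positive", call. = FALSE)
  if (is.na(memory_length) || memory_length <= 0)
    stop("`memory_length` must be positive", call. = FALSE)
  n_steps <- as.integer(n_steps)
  L <- if (is.finite(memory_length)) as.integer(memory_length) else n_steps

  # one weight vector per distinct order; columns of F share them
  uo <- unique(orders)
  wt <- lapply(uo, function(o) kernel_weights(o, n_steps)$weights)
  grp <- match(orders, uo)
  hpow <- step^orders

  X <- matrix(NA_real_, n_steps + 1L, d)
  X[1L, ] <- x0
  F <- matrix(0, n_steps, d)
  x <- x0
  for (k in seq_len(n_steps)) {
    f <- rhs(x)
    if (length(f) != d || any(!is.finite(f)))
      stop(sprintf("solver divergence: non-finite right-hand side at step %d",
                   k), call. = FALSE)
    F[k, ] <- f
    lo <- max(1L, k - L + 1L)
    idx <- lo:k
    x <- x0
    for (g in seq_along(uo)) {
      cols <- which(grp == g)
      cw <- wt[[g]][(k - lo + 1L):1L]          # weights c_{k-lambda-1}
      x[cols] <- x0[cols] + hpow[cols] *
        as.vector(crossprod(F[idx, cols, drop = FALSE], cw))
    }
    if (any(!is.finite(x)))
      stop(sprintf("solver divergence: non-finite state at step %d", k),
           call. = FALSE)
    X[k + 1L, ] <- x
  }
  new_trajectory(times = step * (0:n_steps), states = X, orders = orders,
                 step = step,
                 memory_length = if (is.finite(memory_length)) L else Inf)
}
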