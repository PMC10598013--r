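#' Erdos-Renyi coupling graph for a neuron population
#'
#' Draws a G(N, p) random graph with edge probability
#' `p = mean_degree / (N - 1)`, so the expected node degree equals
#' `mean_degree`.  Nodes left isolated by the draw are rewired to one
#' uniformly chosen neighbour (and the event is recorded), because the
#' diffusive coupling normalizes by the node degree.
#'
#' @param n population size (>= 2).
#' @param mean_degree target average degree in (0, n - 1\].
#' @param seed RNG seed; identical seeds give identical graphs.
#' @return object of class `"er_network"`: list with the symmetric 0/1
#'   `adjacency` matrix (zero diagonal), `n`, `p`, `seed`, `degrees`
#'   and `rewired` (indices of initially isolated nodes).
#' @export
build_er_network <- function(n, mean_degree, seed = 1L) {
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  p <- mean_degree / (n - 1)
  if (p <= 0 || p > 1)
    stop("`mean_degree` must lie in (0, n - 1]", call. = FALSE)
  drawn <- withr_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    iso <- which(rowSums(A) == 0)
    for (i in iso) {
      j <- sample(setdiff(seq_len(n), i), 1L)
      A[i, j] <- A[j, i] <- 1
    }
    list(A = matrix(as.numeric(A), n, n), iso = iso)
  })
  structure(list(adjacency = drawn$A, n = n, p = p, seed = seed,
                 degrees = rowSums(drawn$A), rewired = drawn$iso),
            class = "er_network")
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' @export
print.er_network <- function(x, ...) {
  cat("Erdos-Renyi network: n =", x$n, ", p =", signif(x$p, 4),
      ", mean degree =", signif(mean(x$degrees), 4),
      ", seed =", x$seed, "\n")
  invisible(x)
}

#' Two-block fractional-order assignment
#'
#' The population of size `n = r + s` is split by node index: the first
#' `r` neurons carry order `theta`, the remaining `s` carry order `phi`.
#'
#' @param n population size.
#' @param r,s block sizes (must sum to `n`).
#' @param theta,phi fractional orders of the two blocks.
#' @return numeric vector of length `n`.
#' @export
assign_orders <- function(n, r, s, theta, phi) {
  if (r + s != n) stop("partition error: r + s must equal n", call. = FALSE)
  if (r < 0 || s < 0) stop("block sizes must be non-negative", call. = FALSE)
  c(rep(theta, r), rep(phi, s))
}

#' Coupled-population right-hand side
#'
#' Each neuron follows the two-variable membrane model with an
#' additional degree-normalized diffusive (electrical) coupling on the
#' membrane potential:
#' \deqn{\frac{W_\epsilon}{\sum_j c_{ij}} \sum_j c_{ij}
#'       (u_{1j} - u_{1i}),}
#' while the gating variable is uncoupled.
#'
#' @param states n x 2 matrix, columns `u1`, `u2`.
#' @param network an `"er_network"`.
#' @param params shared `"ml_params_2d"`.
#' @param Im applied current (common to all neurons).
#' @param coupling electrical coupling strength \eqn{W_\epsilon \ge 0}.
#' @return n x 2 matrix of derivatives.
#' @export
rhs_network <- function(states, network, params, Im = params$Im,
                        coupling = 0) {
  u1 <- states[, 1L]; u2 <- states[, 2L]
  deg <- network$degrees
  if (any(deg == 0))
    stop("zero-degree node: coupling normalizer undefined", call. = FALSE)
  g <- gating_functions(u1, params)
  ion <- ionic_current(u1, u2, params)
  couple <- coupling * (as.vector(network$adjacency %*% u1) / deg - u1)
  cbind((Im - ion + couple) / params$C,
        params$phi * g$ell * (g$w_inf - u2))
}

#' Simulate a mixed-order coupled population
#'
#' Integrates the coupled membrane model with the incommensurate
#' memory-convolution scheme: both state components of neuron
#' \eqn{\iota} are updated with that neuron's own fractional order.  A
#' short-memory truncation (default 500 steps) keeps the cost at
#' O(N T L).
#'
#' @param network an `"er_network"`.
#' @param params shared `"ml_params_2d"`.
#' @param orders per-neuron order vector (length n), e.g. from
#'   [assign_orders()].
#' @param x0 n x 2 matrix of initial states.
#' @param n_steps number of steps.
#' @param Im applied current.
#' @param coupling electrical coupling strength.
#' @param step time step.
#' @param memory_length short-memory length (default 500; `Inf` for
#'   full memory).
#' @return an `"ml_trajectory"` whose state matrix has 2n columns
#'   (`u1` of all nodes, then `u2` of all nodes) and attribute
#'   `"n_nodes"`.
#' @export
simulate_network <- function(network, params, orders, x0, n_steps,
                             Im = params$Im, coupling = 0, step = 1,
                             memory_length = 500) {
  n <- network$n
  if (length(orders) != n)
    stop("`orders` must have one entry per node", call. = FALSE)
  if (!is.matrix(x0) || nrow(x0) != n || ncol(x0) != 2L)
    stop("`x0` must be an n x 2 matrix", call. = FALSE)
  rhs <- function(x) {
    s <- matrix(x, n, 2L)
    as.vector(rhs_network(s, network, params, Im = Im, coupling = coupling))
  }
  traj <- solve_incommensurate(rhs, rep(orders, 2L), as.vector(x0),
                               n_steps, step = step,
                               memory_length = memory_length)
  attr(traj, "n_nodes") <- n
  traj
}

#' Extract the membrane-potential block of a network trajectory
#'
#' @param traj trajectory returned by [simulate_network()].
#' @return (steps + 1) x n matrix of `u1` traces.
#' @export
network_voltages <- function(traj) {
  n <- attr(traj, "n_nodes")
  if (is.null(n)) stop("not a network trajectory", call. = FALSE)
  traj$states[, seq_len(n), drop = FALSE]
}

#' Reduced-order cluster model specification
#'
#' When the coupled population settles into cluster synchronization the
#' network collapses onto two (optionally three) mean-field oscillators,
#' each a copy of the slow-fast three-variable neuron integrated at its
#' own fractional order.  The coupling each cluster receives is scaled
#' by the fraction of the population in the opposing cluster:
#' \eqn{\wp_\epsilon = s/N} and \eqn{\wp_0 = r/N} for the two-cluster
#' model, plus \eqn{\wp_1 = x/N} for a third cluster.
#'
#' @param orders numeric vector of 2 or 3 cluster orders.
#' @param r,s,x cluster sizes (x only for three clusters; defaults to
#'   an equal-thirds split when three orders are given and `x` is
#'   missing).
#' @param n population size represented (`r + s` or `r + s + x`).
#' @param coupling electrical coupling strength.
#' @param params an `"ml_params_3d"`.
#' @param Im optional constant applied current overriding the
#'   slow-variable law.
#' @return object of class `"reduced_model_spec"`.
#' @export
reduced_model_spec <- function(orders, r = NULL, s = NULL, x = NULL,
                               n = NULL, coupling = 0, params, Im = NULL) {
  k <- length(orders)
  if (!k %in% 2:3) stop("2 or 3 cluster orders required", call. = FALSE)
  if (is.null(r) && is.null(s) && is.null(x)) {
    # default: equal partition of the represented population
    if (is.null(n)) n <- 99L
    r <- s <- n / k
    if (k == 3L) x <- n / k
  } else if (k == 3L && is.null(x)) {
    if (is.null(n)) stop("supply `x` or `n` for three clusters",
                         call. = FALSE)
    x <- n - r - s
  }
  sizes <- if (k == 2L) c(r, s) else c(r, s, x)
  if (is.null(n)) n <- sum(sizes)
  if (abs(sum(sizes) - n) > 1e-9)
    stop("cluster sizes must sum to n", call. = FALSE)
  probs <- c(p_eps = sizes[2L] / n, p_0 = sizes[1L] / n,
             p_1 = if (k == 3L) sizes[3L] / n else NA_real_)
  structure(list(orders = orders, sizes = sizes, n = n, probs = probs,
                 coupling = coupling, params = params, Im = Im),
            class = "reduced_model_spec")
}

#' Simulate the reduced-order cluster model
#'
#' Integrates 2 or 3 coupled copies of the slow-fast three-variable
#' neuron, one per synchronized cluster, each at its own fractional
#' order.  The membrane equations carry the cluster couplings
#' \eqn{W_\epsilon \wp_\epsilon (u_{1\Phi} - u_{1\vartheta})} on the
#' first cluster, \eqn{W_\epsilon \wp_0 (u_{1\vartheta} - u_{1\Phi})}
#' on the second, and (three-cluster case)
#' \eqn{W_\epsilon \wp_1 (u_{1\gamma} - u_{1\vartheta})} on the third.
#'
#' @param spec a [reduced_model_spec()].
#' @param x0 k x 3 matrix of initial cluster states (k = number of
#'   clusters).
#' @param n_steps number of steps.
#' @param step time step (default 0.1; the dimensionless slow-fast
#'   model is stiff at h = 1).
#' @param memory_length short-memory length (`Inf` = full).
#' @return an `"ml_trajectory"` with 3k columns (u1, u2, u3 of cluster
#'   1, then cluster 2, ...) and attribute `"n_clusters"`.
#' @export
simulate_reduced <- function(spec, x0, n_steps, step = 0.1,
                             memory_length = Inf) {
  k <- length(spec$orders)
  if (!is.matrix(x0) || nrow(x0) != k || ncol(x0) != 3L)
    stop("`x0` must be a k x 3 matrix of cluster states", call. = FALSE)
  p <- spec$params
  W <- spec$coupling
  pr <- spec$probs
  rhs <- function(x) {
    s <- matrix(x, k, 3L, byrow = TRUE)
    u1 <- s[, 1L]
    cpl <- numeric(k)
    cpl[1L] <- W * pr[["p_eps"]] * (u1[2L] - u1[1L])
    cpl[2L] <- W * pr[["p_0"]] * (u1[1L] - u1[2L])
    if (k == 3L) cpl[3L] <- W * pr[["p_1"]] * (u1[3L] - u1[1L])
    d <- t(vapply(seq_len(k), function(i) {
      dd <- rhs_3d(s[i, ], p, Im = spec$Im)
      dd[1L] <- dd[1L] + cpl[i] / p$C
      dd
    }, numeric(3)))
    as.vector(t(d))
  }
  traj <- solve_incommensurate(rhs, rep(spec$orders, each = 3L),
                               as.vector(t(x0)), n_steps, step = step,
                               memory_length = memory_length)
  attr(traj, "n_clusters") <- k
  traj
}
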