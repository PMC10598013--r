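#' Spike detection on a membrane-potential trace
#'
#' Marks local maxima of the `u1` component exceeding a threshold and
#' separated by a refractory window.  The default threshold is the
#' midpoint of the post-transient voltage range, which adapts to both
#' the dimensional (mV-scale) and dimensionless models.
#'
#' @param traj an `"ml_trajectory"` (the first state column is used) or
#'   a numeric vector.
#' @param threshold spike threshold; `NULL` for the adaptive midpoint.
#' @param refractory minimal number of samples between spikes.
#' @param transient fraction of the record discarded before detection.
#' @return object of class `"spike_train"`: list with `times`,
#'   `amplitudes`, `isi`, `threshold`, `refractory`.
#' @export
detect_spikes <- function(traj, threshold = NULL, refractory = 3L,
                          transient = 0) {
  if (inherits(traj, "ml_trajectory")) {
    v <- traj$states[, 1L]
    t <- traj$times
  } else {
    v <- as.numeric(traj)
    t <- seq_along(v) - 1
  }
  if (length(v) < 3L) stop("trajectory too short", call. = FALSE)
  keep <- seq.int(floor(transient * length(v)) + 1L, length(v))
  v <- v[keep]; t <- t[keep]
  if (is.null(threshold)) threshold <- mean(range(v))
  core <- 2:(length(v) - 1L)
  peaks <- core[v[core] >= v[core - 1L] & v[core] > v[core + 1L] &
                  v[core] > threshold]
  if (length(peaks) > 1L) {
    sel <- peaks[1L]
    for (p in peaks[-1L])
      if (p - sel[length(sel)] >= refractory) sel <- c(sel, p)
    peaks <- sel
  }
  structure(list(times = t[peaks], amplitudes = v[peaks],
                 isi = diff(t[peaks]), threshold = threshold,
                 refractory = refractory),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("Spike train:", length(x$times), "spikes")
  if (length(x$isi))
    cat(", mean ISI", signif(mean(x$isi), 4),
        ", ISI CV", signif(stats::sd(x$isi) / mean(x$isi), 3))
  cat("\n")
  invisible(x)
}

#' Classify the firing regime of a trajectory
#'
#' Deterministic rule-based labelling of the post-transient dynamics:
#' * `quiescent` - peak-to-peak amplitude below `eps_q` (absolute, or
#'   relative to `ref_amplitude` when supplied);
#' * `MMO` - mixed-mode oscillations: small- and large-amplitude peaks
#'   coexist (smallest/largest peak prominence below `mmo_ratio`);
#' * `bursting` - inter-spike-interval distribution splits into
#'   within-burst and between-burst groups (largest ISI exceeds
#'   `gap_factor` times the median ISI);
#' * `tonic` - otherwise.
#'
#' @param traj an `"ml_trajectory"` or numeric voltage vector.
#' @param transient fraction discarded (default 0.5: fractional memory
#'   makes transients long).
#' @param eps_q quiescence amplitude cut; interpreted relative to
#'   `ref_amplitude` when that is given.
#' @param ref_amplitude reference oscillation amplitude (e.g. at order
#'   1) for the relative quiescence cut.
#' @param gap_factor ISI bimodality factor for burst detection.
#' @param mmo_ratio small/large peak amplitude ratio below which peaks
#'   count as subthreshold oscillations.
#' @param refractory passed to [detect_spikes()].
#' @return object of class `"regime_label"`: list with `label` and
#'   `evidence`.
#' @export
classify_regime <- function(traj, transient = 0.5, eps_q = 0.01,
                            ref_amplitude = NULL, gap_factor = 3,
                            mmo_ratio = 0.4, refractory = 3L) {
  v <- if (inherits(traj, "ml_trajectory")) traj$states[, 1L]
       else as.numeric(traj)
  if (length(v) < 10L || floor(transient * length(v)) >= length(v) - 3L)
    stop("trajectory shorter than the transient window", call. = FALSE)
  post <- v[(floor(transient * length(v)) + 1L):length(v)]
  amp <- diff(range(post))
  cut <- if (is.null(ref_amplitude)) eps_q else eps_q * ref_amplitude
  evidence <- list(amplitude = amp, quiescence_cut = cut)
  if (amp < cut)
    return(structure(list(label = "quiescent", evidence = evidence),
                     class = "regime_label"))
  # all local maxima (no threshold): needed to see small MMO peaks
  core <- 2:(length(post) - 1L)
  pk <- core[post[core] >= post[core - 1L] & post[core] > post[core + 1L]]
  if (!length(pk)) {
    # monotone drift towards rest: no oscillation at all
    evidence$peak_ratio <- NA_real_
    return(structure(list(label = "quiescent", evidence = evidence),
                     class = "regime_label"))
  }
  pk_amp <- post[pk] - min(post)
  big <- max(pk_amp)
  evidence$peak_ratio <- if (length(pk_amp) > 1L) min(pk_amp) / big else 1
  spikes <- detect_spikes(post, refractory = refractory)
  evidence$n_spikes <- length(spikes$times)
  evidence$isi_cv <- if (length(spikes$isi) > 1L)
    stats::sd(spikes$isi) / mean(spikes$isi) else NA_real_
  label <-
    if (length(pk_amp) > 2L && evidence$peak_ratio < mmo_ratio &&
        sum(pk_amp / big < mmo_ratio) > 1L &&
        sum(pk_amp / big >= mmo_ratio) > 1L) "MMO"
    else if (length(spikes$isi) >= 3L &&
             max(spikes$isi) > gap_factor * stats::median(spikes$isi))
      "bursting"
    else "tonic"
  structure(list(label = label, evidence = evidence),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat("Regime:", x$label, "(amplitude",
      signif(x$evidence$amplitude, 4), ")\n")
  invisible(x)
}

#' Synchronization error of a coupled population
#'
#' The instantaneous global error is the mean absolute deviation of the
#' node voltages from the population mean,
#' \eqn{E(t) = \frac1N \sum_\iota |u_{1\iota}(t) - \bar u_1(t)|};
#' with a cluster partition the same statistic is also computed within
#' each cluster.  The time average is taken over the post-transient
#' window.
#'
#' @param traj network trajectory from [simulate_network()], or a
#'   (time x nodes) voltage matrix.
#' @param clusters optional list of node-index vectors partitioning the
#'   population.
#' @param transient fraction of the record discarded.
#' @return list with `global` (time-averaged error), `per_time`
#'   (error trace), and `within` (named per-cluster averages, when
#'   `clusters` given).
#' @export
sync_error <- function(traj, clusters = NULL, transient = 0.5) {
  V <- if (inherits(traj, "ml_trajectory")) network_voltages(traj)
       else as.matrix(traj)
  if (ncol(V) < 2L) stop("need at least 2 nodes", call. = FALSE)
  keep <- (floor(transient * nrow(V)) + 1L):nrow(V)
  V <- V[keep, , drop = FALSE]
  err <- function(M) rowMeans(abs(M - rowMeans(M)))
  per_time <- err(V)
  out <- list(global = mean(per_time), per_time = per_time)
  if (!is.null(clusters)) {
    idx <- sort(unlist(clusters))
    if (!identical(idx, seq_len(ncol(V))))
      stop("`clusters` must partition the node set", call. = FALSE)
    out$within <- vapply(clusters, function(cl)
      if (length(cl) > 1L) mean(err(V[, cl, drop = FALSE])) else 0,
      numeric(1))
  }
  out
}

#' Bifurcation sweep over fractional order or applied current
#'
#' For every grid value the model is simulated, the transient discarded,
#' and all post-transient local extrema of the membrane potential are
#' recorded; a collapsing extremum band signals the loss of the
#' oscillation at the stability boundary.  Divergent grid points are
#' recorded as missing and the sweep continues.
#'
#' @param params `"ml_params_2d"` or `"ml_params_3d"`.
#' @param sweep `"order"` or `"current"` (the latter for the 2D model
#'   only).
#' @param grid monotone numeric grid of sweep values.
#' @param order fractional order used when sweeping the current.
#' @param Im applied current used when sweeping the order (2D).
#' @param x0 initial state (defaults: `c(-20, 0.1)` for 2D,
#'   `c(0.1, 0.2, 0.05)` for 3D).
#' @param n_steps steps per grid point.
#' @param step time step.
#' @param transient fraction discarded.
#' @param memory_length solver memory truncation.
#' @return data frame with columns `value` (grid value) and `peak`
#'   (one row per recorded extremum; `NA` peak for divergent points),
#'   of class `"bifurcation_sweep"`.
#' @export
bifurcation_sweep <- function(params, sweep = c("order", "current"),
                              grid, order = 1, Im = NULL, x0 = NULL,
                              n_steps = 1200L, step = NULL,
                              transient = 0.5, memory_length = Inf) {
  sweep <- match.arg(sweep)
  if (is.unsorted(grid) && is.unsorted(rev(grid)))
    stop("`grid` must be monotone", call. = FALSE)
  is2d <- inherits(params, "ml_params_2d")
  if (is.null(x0)) x0 <- if (is2d) c(-20, 0.1) else c(0.1, 0.2, 0.05)
  if (is.null(step)) step <- if (is2d) 1 else 0.1
  if (is.null(Im) && is2d) Im <- params$Im
  rows <- lapply(grid, function(g) {
    th <- if (sweep == "order") g else order
    cur <- if (sweep == "current") g else Im
    rhs <- if (is2d) function(s) rhs_2d(s, params, Im = cur)
           else function(s) rhs_3d(s, params)
    tr <- tryCatch(
      solve_commensurate(rhs, th, x0, n_steps, step = step,
                         memory_length = memory_length),
      error = function(e) NULL)
    if (is.null(tr)) return(data.frame(value = g, peak = NA_real_))
    v <- tr$states[, 1L]
    post <- v[(floor(transient * length(v)) + 1L):length(v)]
    core <- 2:(length(post) - 1L)
    ext <- core[(post[core] - post[core - 1L]) *
                  (post[core + 1L] - post[core]) < 0]
    pks <- if (length(ext)) post[ext] else range(post)
    data.frame(value = g, peak = pks)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bifurcation_sweep", class(out))
  out
}

#' Order at which an oscillation collapses in a sweep
#'
#' Helper reading a [bifurcation_sweep()] result: the largest grid value
#' whose post-transient peak-to-peak extremum band is below `eps`
#' (quiescent), together with the adjacent oscillatory grid value.
#'
#' @param sw a `"bifurcation_sweep"` data frame (order sweep,
#'   increasing grid).
#' @param eps amplitude cut separating quiescent from oscillatory.
#' @return list with `flip_below` (largest quiescent grid value) and
#'   `flip_above` (smallest oscillatory grid value above it), either
#'   possibly `NA`.
#' @export
sweep_flip_point <- function(sw, eps) {
  vals <- unique(sw$value)
  amp <- vapply(vals, function(v) {
    p <- sw$peak[sw$value == v]
    if (all(is.na(p))) return(NA_real_)
    diff(range(p, na.rm = TRUE))
  }, numeric(1))
  quiet <- !is.na(amp) & amp < eps
  flip_below <- if (any(quiet)) max(vals[quiet]) else NA_real_
  above <- vals[!quiet & vals > ifelse(is.na(flip_below), -Inf, flip_below)]
  list(flip_below = flip_below,
       flip_above = if (length(above)) min(above) else NA_real_)
}
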