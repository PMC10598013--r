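run_config_defaults <- function() {
  list(model = "2d", group = "i", order = 1, orders = NULL,
       current = NULL, steps = 1000L, step_size = NULL, memory = Inf,
       n = 100L, mean_degree = 7, coupling = 0, r = 65L, s = 35L,
       seed = 1L, transient = 0.5, out = NULL)
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration file (or takes a named list), fills in
#' defaults, and validates the result against the configuration schema.
#' Unknown keys are rejected; the `r + s = n` partition constraint and
#' order ranges are enforced.  The fully resolved configuration is
#' returned and can be written next to run outputs for reproducibility.
#'
#' @param source path to a JSON file, or a named list of settings.
#' @return validated configuration list of class `"run_config"`.
#' @export
load_config <- function(source = list()) {
  cfg <- if (is.character(source))
    jsonlite::read_json(source, simplifyVector = TRUE)
  else source
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, cfg)
  if (!out$model %in% c("2d", "3d", "network", "reduced"))
    stop("config error: model must be 2d, 3d, network or reduced",
         call. = FALSE)
  if (!out$group %in% c("i", "ii", "iii"))
    stop("config error: group must be i, ii or iii", call. = FALSE)
  ords <- c(out$order, out$orders)
  if (any(ords <= 0) || any(ords > 1))
    stop("config error: orders must lie in (0, 1]", call. = FALSE)
  if (out$model == "network" && out$r + out$s != out$n)
    stop("config error: partition r + s must equal n", call. = FALSE)
  if (out$steps < 1) stop("config error: steps must be >= 1", call. = FALSE)
  if (is.null(out$step_size))
    out$step_size <- if (out$model %in% c("3d", "reduced")) 0.1 else 1
  structure(out, class = "run_config")
}

#' Write a trajectory as CSV
#'
#' Columnar text with header `time,u1,u2[,u3,...]`, one row per step,
#' full double precision (17 significant digits), deterministic given
#' identical inputs.
#'
#' @param traj an `"ml_trajectory"`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, function(col) format(col, digits = 17, trim = TRUE,
                                         scientific = FALSE),
                character(nrow(df)))
  lines <- c(paste(names(df), collapse = ","),
             apply(matrix(num, nrow(df)), 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a network as a plain edge list
#'
#' One `i j` pair per line (0-based node indices, i < j), preceded by no
#' header; metadata (n, p, seed) goes to a JSON side file when
#' `meta_path` is given.
#'
#' @param network an `"er_network"`.
#' @param path edge-list file path.
#' @param meta_path optional JSON metadata path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, meta_path = NULL) {
  A <- network$adjacency
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  writeLines(sprintf("%d %d", idx[, 1L] - 1L, idx[, 2L] - 1L), path)
  if (!is.null(meta_path))
    jsonlite::write_json(list(n = network$n, p = network$p,
                              seed = network$seed),
                         meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path edge-list file.
#' @param n number of nodes.
#' @return an `"er_network"` (with `p` and `seed` unset).
#' @export
read_edge_list <- function(path, n) {
  e <- utils::read.table(path, col.names = c("i", "j"))
  A <- matrix(0, n, n)
  A[cbind(e$i + 1L, e$j + 1L)] <- 1
  A <- A + t(A)
  A[A > 1] <- 1
  structure(list(adjacency = A, n = n, p = NA_real_, seed = NA_integer_,
                 degrees = rowSums(A), rewired = integer(0)),
            class = "er_network")
}

report_equilibrium <- function(rep) {
  out <- list(
    location = unname(rep$location),
    branch = rep$branch,
    eigenvalues_re = Re(rep$eigenvalues),
    eigenvalues_im = Im(rep$eigenvalues),
    classification = rep$classification,
    critical_order = as.numeric(rep$hopf_order),
    critical_order_status = attr(rep$hopf_order, "status"))
  if (!is.null(rep$chi)) { out$chi <- rep$chi; out$zeta <- rep$zeta }
  if (!is.null(rep$cubic)) {
    out$cubic <- unname(rep$cubic)
    out$discriminant <- rep$discriminant
  }
  out
}

#' Stability report for a parameter group
#'
#' Computes, for every requested applied current (2D) or for the unique
#' equilibrium (3D), the equilibria with their Jacobians, eigenvalues,
#' Hopf threshold orders and Matignon classifications.  For the 2D
#' model the report also carries a pairing scan: because the published
#' worked examples do not state unambiguously which (group, current)
#' combination each printed threshold belongs to, the scan records, for
#' each published anchor value, the scanned combination whose computed
#' threshold lies closest.
#'
#' @param group `"i"`, `"ii"` or `"iii"`.
#' @param model `"2d"` or `"3d"`.
#' @param currents applied currents to scan (2D; defaults to the
#'   group's published currents).
#' @param order fractional order for classification labels.
#' @param anchors named numeric vector of published threshold values to
#'   pair against (2D only; default [ml_reference_values()] thresholds).
#' @return list (JSON-serializable) of class `"stability_report"`.
#' @export
stability_report <- function(group, model = c("2d", "3d"),
                             currents = NULL, order = 1,
                             anchors = NULL) {
  model <- match.arg(model)
  fx <- ml_group(group, model)
  if (model == "3d") {
    rep <- find_equilibrium_3d(fx$params, order = order)
    out <- list(group = group, model = model,
                equilibrium = report_equilibrium(rep))
  } else {
    if (is.null(currents)) currents <- fx$applied_currents
    per_current <- lapply(currents, function(Im) {
      eq <- find_equilibria_2d(fx$params, Im = Im, order = order)
      list(Im = Im, n_equilibria = length(eq),
           equilibria = lapply(eq, report_equilibrium))
    })
    names(per_current) <- paste0("Im_", currents)
    # pairing scan against published anchors
    if (is.null(anchors)) {
      rv <- ml_reference_values()
      anchors <- c(phase_portrait = rv$hopf_order_2d_phase_portrait,
                   group_i = rv$hopf_order_2d_group_i,
                   group_ii = rv$hopf_order_2d_group_ii)
    }
    finite_th <- lapply(per_current, function(pc) {
      th <- vapply(pc$equilibria, function(e) e$critical_order, numeric(1))
      st <- vapply(pc$equilibria, function(e) e$critical_order_status,
                   character(1))
      th[st != "hopf"] <- NA_real_
      th
    })
    pairing <- lapply(seq_along(anchors), function(i) {
      best <- NULL
      for (j in seq_along(per_current)) {
        th <- finite_th[[j]]
        # fall back on the boundary values when no interior threshold exists
        if (all(is.na(th)))
          th <- vapply(per_current[[j]]$equilibria,
                       function(e) e$critical_order, numeric(1))
        for (k in seq_along(th)) {
          if (is.na(th[k])) next
          d <- abs(th[k] - anchors[i])
          if (is.null(best) || d < best$abs_error)
            best <- list(anchor = unname(anchors[i]),
                         Im = per_current[[j]]$Im,
                         equilibrium_index = k,
                         computed = th[k], abs_error = d)
        }
      }
      best
    })
    names(pairing) <- names(anchors)
    out <- list(group = group, model = model, per_current = per_current,
                pairing_scan = pairing)
  }
  class(out) <- c("stability_report", class(out))
  out
}

#' Write any report as JSON
#'
#' @param report a list (e.g. from [stability_report()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
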