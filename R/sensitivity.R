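#' Select a refinement level from a metric sequence
#'
#' Given metrics measured on successively refined levels (meshes or time
#' steps), computes the relative change between consecutive levels and
#' selects the coarsest level whose change to the next-finer level is
#' below the tolerance for every tracked metric. If no change falls
#' below the tolerance, the finest level is selected and flagged as
#' non-converged.
#'
#' @param metrics numeric vector (one metric) or matrix (levels x
#'   metrics) of metric values per refinement level.
#' @param tolerance relative-change threshold (e.g. 0.02 for 2%).
#' @return List with `selected` (level index), `relative_changes`
#'   (matrix, one row fewer than levels), `converged` (logical).
#' @examples
#' select_refinement_level(c(10, 9.5, 9.3, 9.28), 0.02)$selected  # 3
#' @export
select_refinement_level <- function(metrics, tolerance) {
  m <- as.matrix(metrics)
  if (nrow(m) < 2L) stop("need at least two levels")
  if (!(tolerance > 0)) stop("tolerance must be positive")
  nl <- nrow(m)
  rel <- abs(m[-1L, , drop = FALSE] - m[-nl, , drop = FALSE]) /
    pmax(abs(m[-nl, , drop = FALSE]), 1e-300)
  ok <- apply(rel <= tolerance, 1L, all)
  if (any(ok)) {
    list(selected = which(ok)[1L], relative_changes = rel, converged = TRUE)
  } else {
    list(selected = nl, relative_changes = rel, converged = FALSE)
  }
}

# metrics tracked by both sensitivity studies: average outlet velocity,
# average and maximum wall shear stress, average wall-deformation
# surrogate
.sensitivity_metrics <- function(field, mesh, dt) {
  bf <- mesh$boundary_faces
  out <- bf[bf$tag %in% c("outlet1", "outlet2"), , drop = FALSE]
  v_out <- mean(abs(field$u[cbind(out$i + 1L, out$j)]))
  wss <- wall_shear_stress(field, mesh)
  defo <- wall_deformation_estimate(field$gamma,
                                    ifelse(is.na(mesh$wall_dist), 0,
                                           mesh$wall_dist), dt)
  c(avg_outlet_velocity = v_out,
    avg_wss = mean(wss$tau), max_wss = max(wss$tau),
    avg_deformation = mean(defo[mesh$mask]))
}

.new_sensitivity_report <- function(axis, levels, metrics, tolerance) {
  sel <- if (!is.null(tolerance))
    select_refinement_level(metrics, tolerance)
  else list(selected = NA_integer_,
            relative_changes = {
              nl <- nrow(metrics)
              abs(metrics[-1L, , drop = FALSE] -
                    metrics[-nl, , drop = FALSE]) /
                pmax(abs(metrics[-nl, , drop = FALSE]), 1e-300)
            }, converged = NA)
  structure(list(axis = axis, levels = levels, metrics = metrics,
                 relative_changes = sel$relative_changes,
                 selected_level = sel$selected, converged = sel$converged,
                 tolerance = tolerance),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity report (%s axis), %d levels\n",
              x$axis, nrow(x$metrics)))
  print(cbind(x$levels, as.data.frame(x$metrics)))
  if (!is.na(x$selected_level))
    cat(sprintf("selected level: %d (%sconverged at tolerance %g)\n",
                x$selected_level, if (isTRUE(x$converged)) "" else "NOT ",
                x$tolerance))
  invisible(x)
}

#' Grid-independence study
#'
#' Solves the same transient problem on successively finer meshes and
#' reports the tracked metrics (average outlet velocity, average and
#' maximum wall shear stress, average wall-deformation surrogate), their
#' relative changes between consecutive levels, and the selected mesh:
#' the coarsest level whose change to the next-finer level is below the
#' tolerance for all metrics.
#'
#' @param geometry a [build_bifurcation()] geometry.
#' @param blood a [blood_case()].
#' @param waveform inlet driving (waveform, constant, or function).
#' @param outlet an [outlet_condition()].
#' @param cell_sizes strictly decreasing cell sizes (m), >= 3 levels.
#' @param config a [solver_config()] shared by all levels.
#' @param mode mesh mode, as in [generate_mesh()].
#' @param tolerance relative-change threshold; default 0.02.
#' @return A `sensitivity_report` (axis `"mesh"`).
#' @export
grid_independence <- function(geometry, blood, waveform, outlet, cell_sizes,
                              config = solver_config(),
                              mode = "axisymmetric_tube", tolerance = 0.02) {
  if (length(cell_sizes) < 3L)
    stop("need at least 3 cell sizes")
  if (any(diff(cell_sizes) >= 0))
    stop("cell_sizes must be strictly decreasing (coarse to fine)")
  metrics <- NULL
  elems <- integer(length(cell_sizes))
  for (l in seq_along(cell_sizes)) {
    mesh <- generate_mesh(geometry, cell_sizes[l], mode)
    elems[l] <- mesh$element_count
    sol <- tryCatch(
      solve_transient(mesh, config, blood, waveform, outlet,
                      snapshot_times = config$dt * config$n_steps),
      error = function(e) stop("solve failed at level ", l, " (cell size ",
                               cell_sizes[l], " m): ", conditionMessage(e)))
    metrics <- rbind(metrics,
                     .sensitivity_metrics(sol$final, mesh, config$dt))
  }
  levels <- data.frame(cell_size_m = cell_sizes, elements = elems)
  .new_sensitivity_report("mesh", levels, metrics, tolerance)
}

#' Time-step-sensitivity study
#'
#' Solves the same problem on one mesh under several `(dt, n_steps)`
#' plans and reports the tracked metrics at a common comparison time
#' (by default the latest time all plans reach). No level is selected
#' unless a tolerance is supplied.
#'
#' @param mesh a [generate_mesh()] mesh shared by all plans.
#' @inheritParams grid_independence
#' @param step_plans list of `c(dt, n_steps)` pairs (>= 2 plans).
#' @param compare_time comparison time (s); default the latest common
#'   horizon. Must be within every plan's horizon.
#' @param config a [solver_config()] template (dt/n_steps overridden per
#'   plan).
#' @param tolerance optional relative-change threshold for selection.
#' @return A `sensitivity_report` (axis `"timestep"`).
#' @export
timestep_sensitivity <- function(mesh, blood, waveform, outlet, step_plans,
                                 config = solver_config(),
                                 compare_time = NULL, tolerance = NULL) {
  if (length(step_plans) < 2L) stop("need at least 2 step plans")
  horizons <- vapply(step_plans, function(pl) pl[1] * pl[2], numeric(1))
  if (is.null(compare_time)) compare_time <- min(horizons)
  if (any(compare_time > horizons + 1e-9))
    stop("comparison time ", compare_time,
         " s exceeds a plan's simulated horizon (min horizon ",
         min(horizons), " s)")
  metrics <- NULL
  for (l in seq_along(step_plans)) {
    pl <- step_plans[[l]]
    cfg <- config
    cfg$dt <- pl[1]
    cfg$n_steps <- as.integer(ceiling(compare_time / pl[1] - 1e-9))
    sol <- tryCatch(
      solve_transient(mesh, cfg, blood, waveform, outlet,
                      snapshot_times = compare_time),
      error = function(e) stop("solve failed at plan ", l, " (dt = ",
                               pl[1], " s): ", conditionMessage(e)))
    metrics <- rbind(metrics,
                     .sensitivity_metrics(sol$fields[[1L]], mesh, pl[1]))
  }
  levels <- data.frame(dt_s = vapply(step_plans, `[`, numeric(1), 1L),
                       n_steps = vapply(step_plans, `[`, numeric(1), 2L))
  .new_sensitivity_report("timestep", levels, metrics, tolerance)
}
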