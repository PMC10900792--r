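#' Study configuration
#'
#' Assembles and validates the configuration of a comparative
#' hemodynamics study: geometry, mesh, solver, waveform, outlet
#' pressure, the blood cases to run, snapshot times and the analysis
#' planes. All lengths are meters, times seconds, pressures Pa. The
#' `seed` field is reserved for forward compatibility; the pipeline is
#' fully deterministic.
#'
#' @param geometry named list of [build_bifurcation()] arguments.
#' @param mesh named list: `mode` (`"axisymmetric_tube"` or
#'   `"planar_bifurcation"`) and `cell_size` (m).
#' @param solver named list of [solver_config()] arguments.
#' @param waveform named list of [cardiac_waveform()] arguments.
#' @param outlet_pressure outlet gauge pressure (Pa).
#' @param cases blood cases to run (registered names).
#' @param snapshot_times analysis snapshot times (s), within the
#'   simulated horizon.
#' @param n_planes number of cross-sectional planes.
#' @param comparison_planes plane indices used for the per-case
#'   trendline comparison (default: planes 4, 15, 19, 21, 23, 28 and
#'   the outlet plane 30).
#' @param out_dir default output directory for [write_report()].
#' @param seed reserved (deterministic pipeline).
#' @return An object of class `study_config`.
#' @export
study_config <- function(geometry = list(),
                         mesh = list(mode = "axisymmetric_tube",
                                     cell_size = 5e-4),
                         solver = list(),
                         waveform = list(),
                         outlet_pressure = 13332,
                         cases = blood_case_names(),
                         snapshot_times = c(0.08, 0.12, 0.2, 0.28, 0.4),
                         n_planes = 30L,
                         comparison_planes = c(4L, 15L, 19L, 21L, 23L,
                                               28L, 30L),
                         out_dir = "carotidflow_out",
                         seed = 1L) {
  unknown <- setdiff(cases, blood_case_names())
  if (length(unknown))
    stop("unknown blood case(s): ", paste(unknown, collapse = ", "),
         "; registered: ", paste(blood_case_names(), collapse = ", "))
  scfg <- do.call(solver_config, solver)
  horizon <- scfg$dt * scfg$n_steps
  if (any(snapshot_times <= 0 | snapshot_times > horizon + 1e-9))
    stop("snapshot times must lie within the simulated horizon (0, ",
         horizon, "] s")
  if (any(comparison_planes < 1 | comparison_planes > n_planes))
    stop("comparison_planes must index into 1..n_planes")
  structure(list(geometry = geometry, mesh = mesh, solver = solver,
                 waveform = waveform, outlet_pressure = outlet_pressure,
                 cases = cases, snapshot_times = snapshot_times,
                 n_planes = as.integer(n_planes),
                 comparison_planes = as.integer(comparison_planes),
                 out_dir = out_dir, seed = seed),
            class = "study_config")
}

.ranking_quantities <- c("velocity", "pressure", "wss", "strain_rate")

#' Run the comparative blood-case study
#'
#' End-to-end pipeline: builds the geometry and one shared mesh, runs
#' the transient solve for every requested blood case under identical
#' boundary conditions (so differences isolate the rheology), computes
#' plane-wise statistics at every snapshot, fits linear trendlines of
#' the per-plane averages over the comparison planes, and classifies
#' each case high/average/low per hemodynamic quantity and statistic
#' (velocity, pressure, wall shear, strain rate x min/avg/max), the
#' structure of a comparative blood-type table.
#'
#' @param config a [study_config()].
#' @return An object of class `comparison_result` with elements
#'   `plane_stats` (tidy data frame over cases, planes, snapshots),
#'   `global` (per-case global summaries at the final snapshot),
#'   `trendlines` (per case and quantity), `ranking` (quantity x
#'   statistic x case labels), `fields` (final `flow_field` per case),
#'   `mesh`, `planes`, and the echoed `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  geometry <- do.call(build_bifurcation, config$geometry)
  mesh <- generate_mesh(geometry, config$mesh$cell_size, config$mesh$mode)
  scfg <- do.call(solver_config, config$solver)
  waveform <- do.call(cardiac_waveform, config$waveform)
  outlet <- outlet_condition(config$outlet_pressure)
  planes <- plane_positions(config$n_planes)

  plane_stats <- list()
  global <- list()
  trend <- list()
  fields <- list()
  for (case in config$cases) {
    blood <- load_blood_case(case)
    sol <- tryCatch(
      solve_transient(mesh, scfg, blood, waveform, outlet,
                      config$snapshot_times),
      error = function(e) stop("stage solve_transient failed for case '",
                               case, "': ", conditionMessage(e)))
    for (k in seq_along(sol$fields)) {
      ps <- plane_statistics(sol$fields[[k]], mesh, planes,
                             density = blood$density, dt = scfg$dt)
      ps$case <- case
      plane_stats[[length(plane_stats) + 1L]] <- ps
    }
    fin <- sol$fields[[length(sol$fields)]]
    fields[[case]] <- fin
    gs <- hemodynamic_summary(fin, mesh, density = blood$density,
                              dt = scfg$dt)
    gs$case <- case
    gs$pressure_drop <- pressure_drop(fin, mesh)
    global[[case]] <- gs
    # trendlines of per-plane averages over the comparison planes
    psf <- plane_statistics(fin, mesh, planes, density = blood$density,
                            dt = scfg$dt)
    for (q in .ranking_quantities) {
      sub <- psf[psf$quantity == q & psf$plane %in% config$comparison_planes,
                 , drop = FALSE]
      sub <- sub[is.finite(sub$avg), , drop = FALSE]
      if (nrow(sub) >= 2L && length(unique(sub$z_m)) >= 2L) {
        co <- linear_trendline(sub$z_m, sub$avg)
        trend[[length(trend) + 1L]] <-
          data.frame(case = case, quantity = q, slope = co[["slope"]],
                     intercept = co[["intercept"]])
      }
    }
  }
  global <- do.call(rbind, global)
  rownames(global) <- NULL

  ranking <- list()
  if (length(config$cases) >= 3L) {
    for (q in .ranking_quantities) {
      for (st in c("max", "avg", "min")) {
        vals <- vapply(config$cases, function(case) {
          g <- global[global$case == case & global$quantity == q, ]
          g[[st]]
        }, numeric(1))
        lab <- classify_levels(vals)
        ranking[[length(ranking) + 1L]] <-
          data.frame(quantity = q, statistic = st,
                     case = names(lab), level = unname(lab))
      }
    }
  }
  structure(list(
    plane_stats = do.call(rbind, plane_stats),
    global = global,
    trendlines = if (length(trend)) do.call(rbind, trend) else NULL,
    ranking = if (length(ranking)) do.call(rbind, ranking) else NULL,
    fields = fields, mesh = mesh, planes = planes, config = config
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison_result: %d case(s) on a %s mesh (%d cells)\n",
              length(x$fields), x$mesh$mode, x$mesh$element_count))
  if (!is.null(x$ranking)) {
    wide <- stats::reshape(x$ranking, idvar = c("quantity", "statistic"),
                           timevar = "case", direction = "wide")
    names(wide) <- sub("^level\\.", "", names(wide))
    print(wide, row.names = FALSE)
  }
  invisible(x)
}

#' Write a study report
#'
#' Writes the comparative study to disk: tidy CSV plane statistics per
#' case, the global summary, the trendline coefficients, the ranking
#' table (quantity x statistic x case, mirroring a comparative
#' blood-type table), one legacy-VTK snapshot per case, and a run
#' metadata log. CSV content is deterministic for identical results.
#'
#' @param result a [run_study()] result.
#' @param out_dir output directory (created if needed).
#' @return Character vector of the files written (the manifest),
#'   invisibly.
#' @export
write_report <- function(result, out_dir = result$config$out_dir) {
  stopifnot(inherits(result, "comparison_result"))
  if (!length(result$fields))
    stop("empty result: no blood cases were run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  manifest <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    manifest <<- c(manifest, p)
  }
  for (case in names(result$fields)) {
    wcsv(result$plane_stats[result$plane_stats$case == case, ],
         sprintf("plane_statistics_%s.csv", case))
    vp <- file.path(out_dir, sprintf("field_%s.vtk", case))
    write_vtk(result$fields[[case]], result$mesh, vp)
    manifest <- c(manifest, vp)
  }
  wcsv(result$global, "global_summary.csv")
  if (!is.null(result$trendlines)) wcsv(result$trendlines, "trendlines.csv")
  if (!is.null(result$ranking)) wcsv(result$ranking, "ranking_table.csv")
  meta <- file.path(out_dir, "run_metadata.txt")
  writeLines(c(
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("carotidflow version: %s",
            as.character(utils::packageVersion("carotidflow"))),
    sprintf("R version: %s", R.version.string),
    "configuration:",
    yaml::as.yaml(unclass(result$config))
  ), meta)
  manifest <- c(manifest, meta)
  invisible(manifest)
}
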