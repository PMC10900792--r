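#' Write a flow field as a legacy-VTK structured grid
#'
#' ASCII legacy VTK (`DATASET STRUCTURED_GRID`) with cell data:
#' pressure (Pa), effective viscosity (Pa s), strain rate (1/s), a
#' fluid/solid mask, and the cell-centred velocity vector (m/s).
#' Readable by ParaView and VisIt. The 2D grid is written with a zero
#' third coordinate.
#'
#' @param field a `flow_field`.
#' @param mesh the mesh the field lives on.
#' @param path output file path (`.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(field, mesh, path) {
  nz <- mesh$nz; ny <- mesh$ny
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 7)
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl(sprintf("carotidflow field t=%g s (%s)", field$time, mesh$mode))
  wl("ASCII")
  wl("DATASET STRUCTURED_GRID")
  wl(sprintf("DIMENSIONS %d %d 1", nz + 1L, ny + 1L))
  wl(sprintf("POINTS %d float", (nz + 1L) * (ny + 1L)))
  pts <- expand.grid(z = mesh$zf, y = mesh$yf)
  writeLines(paste(num(pts$z), num(pts$y), "0"), con)
  ncell <- nz * ny
  wl(sprintf("CELL_DATA %d", ncell))
  scalar <- function(name, m) {
    wl(sprintf("SCALARS %s float 1", name))
    wl("LOOKUP_TABLE default")
    writeLines(num(as.vector(m)), con)
  }
  scalar("pressure", field$p)
  scalar("viscosity", field$mu)
  scalar("strain_rate", field$gamma)
  scalar("fluid_mask", mesh$mask * 1)
  ucc <- (field$u[1:nz, , drop = FALSE] +
            field$u[2:(nz + 1L), , drop = FALSE]) / 2
  vcc <- (field$v[, 1:ny, drop = FALSE] +
            field$v[, 2:(ny + 1L), drop = FALSE]) / 2
  wl("VECTORS velocity float")
  writeLines(paste(num(as.vector(ucc)), num(as.vector(vcc)), "0"), con)
  invisible(path)
}

#' Read a study configuration file
#'
#' Reads a sectioned key-value (YAML) configuration file and builds a
#' [study_config()]. Unknown keys are rejected by `study_config`'s
#' argument matching. Lengths are in meters, times in seconds,
#' pressures in Pa.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' Write a study configuration file
#'
#' @param config a [study_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
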