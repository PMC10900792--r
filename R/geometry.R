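#' Parametric carotid bifurcation geometry
#'
#' An idealized Y-geometry: the common carotid artery (CCA, inlet) divides
#' into the internal carotid (ICA, the larger branch) and the external
#' carotid (ECA, the smaller branch). The axial coordinate has its origin
#' at the bifurcation-apex region; the default span covers the analysis
#' window from -31 mm (plane 1) to +18 mm (plane 30). All lengths in
#' meters, angles in degrees from the CCA axis.
#'
#' @param r_cca CCA (inlet) radius (m).
#' @param r_ica ICA radius (m); must exceed `r_eca`.
#' @param r_eca ECA radius (m).
#' @param branch_angle_ica,branch_angle_eca branch angles (degrees).
#' @param z_inlet axial inlet position (m), must be <= -0.031.
#' @param z_outlet axial outlet position (m), must be >= 0.018.
#' @param wall_thickness arterial wall thickness (m), metadata for the
#'   deformation surrogate.
#' @param wall_elastic_modulus arterial wall Young's modulus (Pa), metadata.
#' @return An object of class `bifurcation_geometry`.
#' @examples
#' build_bifurcation()
#' @export
build_bifurcation <- function(r_cca = 3.1e-3, r_ica = 2.2e-3, r_eca = 1.7e-3,
                              branch_angle_ica = 25, branch_angle_eca = 25,
                              z_inlet = -31e-3, z_outlet = 18e-3,
                              wall_thickness = 0.5e-3,
                              wall_elastic_modulus = 1e6) {
  stopifnot(is.numeric(r_cca), is.numeric(r_ica), is.numeric(r_eca))
  if (any(c(r_cca, r_ica, r_eca) <= 0))
    stop("all radii must be positive")
  if (r_ica <= r_eca)
    stop("ICA radius (", r_ica, ") must exceed ECA radius (", r_eca,
         "): the internal carotid is the larger branch")
  if (!(z_inlet < 0 && z_outlet > 0))
    stop("require z_inlet < 0 < z_outlet (origin at the bifurcation apex)")
  if (z_inlet > -31e-3 + 1e-12 || z_outlet < 18e-3 - 1e-12)
    stop("axial extent must cover the analysis window [-31 mm, +18 mm]; got [",
         z_inlet * 1e3, ", ", z_outlet * 1e3, "] mm")
  if (branch_angle_ica <= 0 || branch_angle_ica >= 90 ||
      branch_angle_eca <= 0 || branch_angle_eca >= 90)
    stop("branch angles must lie in (0, 90) degrees")
  structure(list(r_cca = r_cca, r_ica = r_ica, r_eca = r_eca,
                 branch_angle_ica = branch_angle_ica,
                 branch_angle_eca = branch_angle_eca,
                 z_inlet = z_inlet, z_outlet = z_outlet,
                 wall_thickness = wall_thickness,
                 wall_elastic_modulus = wall_elastic_modulus),
            class = "bifurcation_geometry")
}

#' @export
print.bifurcation_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "Carotid Y-geometry: CCA r = %.2f mm -> ICA r = %.2f mm / ",
    "ECA r = %.2f mm (angles %g/%g deg), z in [%.1f, %.1f] mm\n"),
    x$r_cca * 1e3, x$r_ica * 1e3, x$r_eca * 1e3,
    x$branch_angle_ica, x$branch_angle_eca,
    x$z_inlet * 1e3, x$z_outlet * 1e3))
  invisible(x)
}

#' Axial positions of the cross-sectional analysis planes
#'
#' Thirty planes span the artery: plane 1 at -31 mm, plane 16 at 0 mm
#' (bifurcation apex region), plane 30 at +18 mm, uniformly spaced within
#' each of the two segments. A different plane count keeps the three
#' anchors and splits the remaining planes proportionally.
#'
#' @param n_planes number of planes (>= 3); default 30.
#' @param z_first,z_mid,z_last anchor positions (m).
#' @param mid_index index of the plane pinned at `z_mid`; default 16 for
#'   30 planes, otherwise the proportional position.
#' @return Numeric vector of axial positions (m), strictly increasing.
#' @examples
#' plane_positions()[c(1, 16, 30)] * 1e3  # -31, 0, 18 mm
#' @export
plane_positions <- function(n_planes = 30L, z_first = -31e-3, z_mid = 0,
                            z_last = 18e-3, mid_index = NULL) {
  if (n_planes < 3) stop("need at least 3 planes (two segments)")
  if (!(z_first < z_mid && z_mid < z_last))
    stop("anchors must satisfy z_first < z_mid < z_last")
  if (is.null(mid_index))
    mid_index <- if (n_planes == 30L) 16L else max(2L, min(n_planes - 1L,
      round(1 + (n_planes - 1) * (z_mid - z_first) / (z_last - z_first))))
  if (mid_index <= 1 || mid_index >= n_planes)
    stop("mid_index must be interior to 1..n_planes")
  c(seq(z_first, z_mid, length.out = mid_index),
    seq(z_mid, z_last, length.out = n_planes - mid_index + 1L)[-1L])
}

# fluid-region indicator for the planar Y-bifurcation (vectorized in x)
# z <= -L_t      : CCA channel, half-width r_cca, centered at 0
# -L_t < z <= 0  : linear flare of center and half-width into the mouth
# z > 0          : two bands (ICA above, ECA below) diverging at the
#                  branch angles, separated by the growing apex wedge
.bif_region <- function(geom, transition_length = 6e-3) {
  w_ica <- 2 * geom$r_ica
  w_eca <- 2 * geom$r_eca
  hw0 <- (w_ica + w_eca) / 2           # mouth half-width at z = 0
  x0 <- (w_ica - w_eca) / 2            # mouth center
  ti <- tan(geom$branch_angle_ica * pi / 180)
  te <- tan(geom$branch_angle_eca * pi / 180)
  lt <- transition_length
  function(x, z) {
    if (z <= 0) {
      f <- if (z <= -lt) 0 else 1 + z / lt
      cen <- f * x0
      hw <- geom$r_cca + f * (hw0 - geom$r_cca)
      abs(x - cen) <= hw
    } else {
      (x >= z * ti & x <= z * ti + w_ica) |
        (x <= -z * te & x >= -z * te - w_eca)
    }
  }
}

#' Generate a structured staggered mesh
#'
#' Two reduced-dimensional modes stand in for a full 3D tetrahedral mesh:
#' * `"axisymmetric_tube"`: a straight tube of radius `r_cca` meshed in
#'   (r, z); used for analytic-oracle validation and single-vessel runs.
#' * `"planar_bifurcation"`: a 2D Y-channel (channel widths equal to the
#'   vessel diameters) on a Cartesian grid with staircase-masked walls.
#'
#' Cells are uniform squares of side `target_cell_size`. Boundary faces
#' are tagged `inlet`, `outlet1` (ICA / tube outlet), `outlet2` (ECA),
#' `wall`, or `axis` (tube centerline), and each boundary face carries
#' exactly one tag.
#'
#' @param geometry a [build_bifurcation()] geometry.
#' @param target_cell_size cell edge length (m); must not exceed the
#'   smallest vessel radius.
#' @param mode `"axisymmetric_tube"` or `"planar_bifurcation"`.
#' @param transition_length flare length (m) from the CCA cross-section
#'   into the bifurcation mouth (planar mode).
#' @param axial_cell_size axial cell length (m); defaults to
#'   `target_cell_size`. A coarser axial spacing is adequate for
#'   streamwise-invariant (fully developed) verification runs.
#' @return An object of class `flow_mesh`.
#' @examples
#' m <- generate_mesh(build_bifurcation(), 0.5e-3, "axisymmetric_tube")
#' m$element_count
#' @export
generate_mesh <- function(geometry, target_cell_size,
                          mode = c("axisymmetric_tube", "planar_bifurcation"),
                          transition_length = 6e-3,
                          axial_cell_size = target_cell_size) {
  stopifnot(inherits(geometry, "bifurcation_geometry"))
  mode <- match.arg(mode)
  h <- target_cell_size
  if (!(is.numeric(h) && h > 0)) stop("target_cell_size must be positive")
  r_min <- min(geometry$r_cca, geometry$r_ica, geometry$r_eca)
  if (h > r_min)
    stop("refinement error: cell size ", h, " m exceeds the smallest vessel ",
         "radius ", r_min, " m; refine the mesh")
  zlen <- geometry$z_outlet - geometry$z_inlet
  nz <- max(4L, round(zlen / axial_cell_size))
  dz <- zlen / nz
  zf <- geometry$z_inlet + dz * (0:nz)
  zc <- (zf[-1] + zf[-(nz + 1)]) / 2

  if (mode == "axisymmetric_tube") {
    R <- geometry$r_cca
    ny <- max(4L, round(R / h))
    dy <- R / ny
    yf <- dy * (0:ny)
    yc <- (yf[-1] + yf[-(ny + 1)]) / 2
    mask <- matrix(TRUE, nz, ny)
    rw_c <- yc        # radius weight (per-radian areas/volumes)
    rw_f <- yf
    axis_weight <- TRUE
  } else {
    region <- .bif_region(geometry, transition_length)
    ti <- tan(geometry$branch_angle_ica * pi / 180)
    te <- tan(geometry$branch_angle_eca * pi / 180)
    x_max <- geometry$z_outlet * ti + 2 * geometry$r_ica + h
    x_min <- -(geometry$z_outlet * te + 2 * geometry$r_eca) - h
    ny <- max(4L, ceiling((x_max - x_min) / h))
    dy <- (x_max - x_min) / ny
    yf <- x_min + dy * (0:ny)
    yc <- (yf[-1] + yf[-(ny + 1)]) / 2
    mask <- matrix(FALSE, nz, ny)
    for (i in seq_len(nz)) mask[i, ] <- region(yc, zc[i])
    rw_c <- rep(1, ny)
    rw_f <- rep(1, ny + 1L)
    axis_weight <- FALSE
  }

  mesh <- structure(list(
    mode = mode, geometry = geometry,
    nz = nz, ny = ny, dz = dz, dy = dy,
    zf = zf, zc = zc, yf = yf, yc = yc,
    rw_c = rw_c, rw_f = rw_f, axisymmetric = axis_weight,
    mask = mask, cell_size = h,
    element_count = sum(mask)
  ), class = "flow_mesh")
  mesh$boundary_faces <- .boundary_faces(mesh)
  mesh$wall_dist <- .wall_distance(mesh)
  mesh
}

#' @export
print.flow_mesh <- function(x, ...) {
  cat(sprintf(paste0("flow_mesh (%s): %d x %d grid, %d fluid cells, ",
                     "cell size %.3g mm\n"),
              x$mode, x$nz, x$ny, x$element_count, x$cell_size * 1e3))
  invisible(x)
}

# Enumerate boundary faces of the fluid region with unique tags.
# A boundary face separates a fluid cell from a solid cell or from the
# domain exterior. dir = "z" faces are normal to the axial direction
# (face index i in 0..nz at y-row j); dir = "y" faces are normal to the
# cross direction (face index j in 0..ny at z-column i).
.boundary_faces <- function(mesh) {
  out <- list()
  mask <- mesh$mask
  nz <- mesh$nz; ny <- mesh$ny
  # z-oriented faces
  for (j in seq_len(ny)) {
    fl <- mask[, j]
    for (i in 0:nz) {
      left <- if (i >= 1) fl[i] else NA
      right <- if (i < nz) fl[i + 1] else NA
      lf <- isTRUE(left); rf <- isTRUE(right)
      if (lf == rf && !is.na(left) && !is.na(right)) next  # interior or solid
      if (!lf && !rf) next
      tag <- if (i == 0 && rf) "inlet"
      else if (i == nz && lf) {
        if (mesh$mode == "axisymmetric_tube") "outlet1"
        else if (mesh$yc[j] > 0) "outlet1" else "outlet2"
      } else "wall"
      out[[length(out) + 1L]] <- data.frame(tag = tag, dir = "z",
                                            i = i, j = j)
    }
  }
  # y-oriented faces
  for (i in seq_len(nz)) {
    fl <- mask[i, ]
    for (j in 0:ny) {
      below <- if (j >= 1) fl[j] else NA
      above <- if (j < ny) fl[j + 1] else NA
      bf <- isTRUE(below); af <- isTRUE(above)
      if (bf == af && !is.na(below) && !is.na(above)) next
      if (!bf && !af) next
      tag <- if (j == 0 && af && mesh$axisymmetric) "axis" else "wall"
      out[[length(out) + 1L]] <- data.frame(tag = tag, dir = "y",
                                            i = i, j = j)
    }
  }
  do.call(rbind, out)
}

# Per-fluid-cell distance from cell center to the nearest tagged wall
# face (used by the wall-deformation surrogate). Solid cells are NA.
.wall_distance <- function(mesh) {
  bf <- mesh$boundary_faces
  wf <- bf[bf$tag == "wall", , drop = FALSE]
  wd <- matrix(NA_real_, mesh$nz, mesh$ny)
  if (nrow(wf) == 0) return(wd)
  # wall-face center coordinates
  wz <- ifelse(wf$dir == "z", mesh$zf[wf$i + 1L], mesh$zc[wf$i])
  wy <- ifelse(wf$dir == "z", mesh$yc[wf$j], mesh$yf[wf$j + 1L])
  idx <- which(mesh$mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    wd[i, j] <- sqrt(min((wz - mesh$zc[i])^2 + (wy - mesh$yc[j])^2))
  }
  wd
}

#' Cross-sectional inlet area of a mesh
#'
#' Area of the meshed inlet face: `pi * r^2` for the axisymmetric tube
#' (the midpoint quadrature of `2 pi r dr` is exact on a uniform grid),
#' the captured channel width (times unit depth) for the planar mode.
#'
#' @param mesh a [generate_mesh()] mesh.
#' @return Area (m^2; per unit depth in planar mode).
#' @export
inlet_area <- function(mesh) {
  bf <- mesh$boundary_faces
  inl <- bf[bf$tag == "inlet", , drop = FALSE]
  if (mesh$axisymmetric)
    sum(2 * pi * mesh$rw_c[inl$j] * mesh$dy)
  else
    nrow(inl) * mesh$dy
}
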