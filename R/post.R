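#' Wall shear stress along the vessel wall
#'
#' Magnitude of the viscous traction at each lateral wall face,
#' \eqn{\tau = \mu_{eff} |\partial u_t/\partial n|}, evaluated with a
#' one-sided difference between the no-slip wall and the wall-adjacent
#' cell-centre tangential velocity (a half cell away). Staircase wall
#' faces normal to the cross direction carry the dominant tangential
#' (axial) velocity and are the faces reported.
#'
#' @param field a `flow_field`.
#' @param mesh the [generate_mesh()] mesh the field was solved on.
#' @return A data frame with one row per wall face: `z`, `y` (face
#'   centre, m), `tau` (Pa, non-negative), `cell_i`, `cell_j` (adjacent
#'   fluid cell).
#' @export
wall_shear_stress <- function(field, mesh) {
  stopifnot(inherits(field, "flow_field"), inherits(mesh, "flow_mesh"))
  bf <- mesh$boundary_faces
  wf <- bf[bf$tag == "wall" & bf$dir == "y", , drop = FALSE]
  if (is.null(bf) || !nrow(wf))
    stop("mesh has no tagged lateral wall faces")
  nz <- mesh$nz
  ucc <- (field$u[1:nz, , drop = FALSE] +
            field$u[2:(nz + 1L), , drop = FALSE]) / 2
  # adjacent fluid cell: below the face if fluid, otherwise above
  below_ok <- wf$j >= 1L
  below_ok[below_ok] <- mesh$mask[cbind(wf$i[below_ok], wf$j[below_ok])]
  ci <- wf$i
  cj <- ifelse(below_ok, wf$j, wf$j + 1L)
  mu <- field$mu[cbind(ci, cj)]
  ut <- ucc[cbind(ci, cj)]
  tau <- mu * abs(ut) / (mesh$dy / 2)
  data.frame(z = mesh$zc[wf$i], y = mesh$yf[wf$j + 1L], tau = tau,
             cell_i = ci, cell_j = cj)
}

#' Skin-friction coefficient
#'
#' Nondimensionalizes a wall shear stress by the reference dynamic
#' pressure: \eqn{C_f = \tau / (\tfrac12 \rho v_{ref}^2)}. With the
#' whole-blood density 1060 kg/m^3 and the diastolic reference velocity
#' 0.1 m/s, a maximum wall shear of 7.18665 Pa gives the maximum
#' skin-friction coefficient 1.35593.
#'
#' @param tau wall shear stress (Pa), >= 0. Vectorized.
#' @param density reference density (kg/m^3), > 0. Default 1060.
#' @param v_ref reference velocity (m/s), > 0. Default 0.1.
#' @return Dimensionless skin-friction coefficient(s).
#' @examples
#' skin_friction(7.18665)  # 1.35597...
#' @export
skin_friction <- function(tau, density = 1060, v_ref = 0.1) {
  stopifnot(is.numeric(tau))
  if (!(density > 0)) stop("density must be positive")
  if (!(v_ref > 0)) stop("reference velocity v_ref must be positive")
  tau / (0.5 * density * v_ref^2)
}

#' Wall-deformation surrogate
#'
#' The rigid-wall solve has no structural displacement; the deformation
#' surrogate follows the product rule used with the fluid solve: the
#' per-step strain (strain rate times step length, dimensionless) times
#' the cell-to-wall distance,
#' \eqn{d = (\gamma\,\Delta t)\, \delta_{wall}}.
#' This is a surrogate indicator, not a structural displacement.
#'
#' @param strain_rate_value strain-rate magnitude(s) (1/s), >= 0.
#' @param cell_wall_distance distance from the cell centre to the wall
#'   (m), >= 0.
#' @param dt time-step length (s) over which the strain accumulates.
#' @return Deformation surrogate (same product convention as reported by
#'   the summary tables).
#' @export
wall_deformation_estimate <- function(strain_rate_value, cell_wall_distance,
                                      dt = 1) {
  if (any(strain_rate_value < 0) || any(cell_wall_distance < 0) || dt < 0)
    stop("strain rate, wall distance and dt must be non-negative")
  (strain_rate_value * dt) * cell_wall_distance
}

# cell-centre velocity magnitude
.vel_mag <- function(field, mesh) {
  nz <- mesh$nz; ny <- mesh$ny
  ucc <- (field$u[1:nz, , drop = FALSE] +
            field$u[2:(nz + 1L), , drop = FALSE]) / 2
  vcc <- (field$v[, 1:ny, drop = FALSE] +
            field$v[, 2:(ny + 1L), drop = FALSE]) / 2
  sqrt(ucc^2 + vcc^2)
}

.stat3 <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(c(min = NA_real_, avg = NA_real_, max = NA_real_))
  c(min = min(x), avg = mean(x), max = max(x))
}

#' Plane-wise hemodynamic statistics
#'
#' Average, maximum and minimum of velocity magnitude, pressure, strain
#' rate and the wall-deformation surrogate over the fluid cells
#' intersecting each cross-sectional plane, and of wall shear stress and
#' skin friction over the wall faces nearest each plane (each wall face
#' is assigned to its nearest plane by axial position). In the
#' bifurcated region a plane cuts both branches and the statistics pool
#' them.
#'
#' @param field a `flow_field`.
#' @param mesh the mesh the field was solved on.
#' @param plane_axial_positions axial plane positions (m), e.g.
#'   [plane_positions()]; must lie within the mesh axial extent.
#' @param density,v_ref skin-friction reference values (kg/m^3, m/s).
#' @param dt step length (s) for the deformation surrogate.
#' @return A tidy data frame: `plane`, `z_m`, `quantity`
#'   (velocity, pressure, strain_rate, deformation, wss, cf),
#'   `min`, `avg`, `max`, `time`.
#' @export
plane_statistics <- function(field, mesh, plane_axial_positions,
                             density = 1060, v_ref = 0.1, dt = 0.008) {
  stopifnot(inherits(field, "flow_field"), inherits(mesh, "flow_mesh"))
  zp <- plane_axial_positions
  if (any(zp < mesh$zf[1] - 1e-9 | zp > mesh$zf[mesh$nz + 1L] + 1e-9))
    stop("plane position(s) outside the mesh axial extent [",
         mesh$zf[1], ", ", mesh$zf[mesh$nz + 1L], "] m")
  vel <- .vel_mag(field, mesh)
  wss <- wall_shear_stress(field, mesh)
  wss$plane <- vapply(wss$z, function(z) which.min(abs(zp - z)), integer(1))
  defo <- wall_deformation_estimate(field$gamma,
                                    ifelse(is.na(mesh$wall_dist), 0,
                                           mesh$wall_dist), dt)
  out <- vector("list", length(zp))
  for (k in seq_along(zp)) {
    i <- which.min(abs(mesh$zc - zp[k]))
    cells <- which(mesh$mask[i, ])
    rows <- rbind(
      velocity = .stat3(vel[i, cells]),
      pressure = .stat3(field$p[i, cells]),
      strain_rate = .stat3(field$gamma[i, cells]),
      deformation = .stat3(defo[i, cells]),
      wss = .stat3(wss$tau[wss$plane == k]),
      cf = .stat3(skin_friction(wss$tau[wss$plane == k], density, v_ref))
    )
    out[[k]] <- data.frame(plane = k, z_m = zp[k],
                           quantity = rownames(rows),
                           min = rows[, "min"], avg = rows[, "avg"],
                           max = rows[, "max"], time = field$time,
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Global hemodynamic summary
#'
#' Domain-wide minimum / average / maximum of velocity magnitude,
#' pressure, strain rate, wall-deformation surrogate (over fluid cells),
#' and wall shear stress / skin friction (over wall faces).
#'
#' @inheritParams plane_statistics
#' @return A data frame: `quantity`, `min`, `avg`, `max`, `time`.
#' @export
hemodynamic_summary <- function(field, mesh, density = 1060, v_ref = 0.1,
                                dt = 0.008) {
  vel <- .vel_mag(field, mesh)
  wss <- wall_shear_stress(field, mesh)
  defo <- wall_deformation_estimate(field$gamma,
                                    ifelse(is.na(mesh$wall_dist), 0,
                                           mesh$wall_dist), dt)
  m <- mesh$mask
  rows <- rbind(
    velocity = .stat3(vel[m]),
    pressure = .stat3(field$p[m]),
    strain_rate = .stat3(field$gamma[m]),
    deformation = .stat3(defo[m]),
    wss = .stat3(wss$tau),
    cf = .stat3(skin_friction(wss$tau, density, v_ref))
  )
  data.frame(quantity = rownames(rows), min = rows[, "min"],
             avg = rows[, "avg"], max = rows[, "max"],
             time = field$time, row.names = NULL)
}

#' Inlet-to-outlet pressure drop
#'
#' Mean pressure over the inlet-adjacent cells minus the mean over the
#' outlet-adjacent cells.
#'
#' @inheritParams plane_statistics
#' @return Pressure drop (Pa).
#' @export
pressure_drop <- function(field, mesh) {
  pin <- mean(field$p[1L, mesh$mask[1L, ]])
  pout <- mean(field$p[mesh$nz, mesh$mask[mesh$nz, ]])
  pin - pout
}

#' Tertile high/average/low classification
#'
#' Labels each case by the tertile of its value: top third `"high"`,
#' middle `"average"`, bottom `"low"` (by the fractional rank
#' `(position - 1/2) / n`). Tied values share the higher of their
#' labels; if all values are tied every case is `"average"`.
#'
#' @param per_case_values named numeric vector (>= 3 values).
#' @return Named character vector of labels.
#' @examples
#' classify_levels(c(a = 1, b = 2, c = 3, d = 4))
#' @export
classify_levels <- function(per_case_values) {
  x <- per_case_values
  if (length(x) < 3L) stop("need at least 3 values to form tertiles")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("per_case_values must be named")
  if (diff(range(x)) == 0)
    return(stats::setNames(rep("average", length(x)), names(x)))
  ord <- order(x)
  f <- (seq_along(x) - 0.5) / length(x)
  lab <- ifelse(f < 1 / 3, "low", ifelse(f > 2 / 3, "high", "average"))
  labels <- character(length(x))
  labels[ord] <- lab
  # ties share the higher label
  lev <- c(low = 1L, average = 2L, high = 3L)
  for (vx in unique(x[duplicated(x)])) {
    grp <- which(x == vx)
    labels[grp] <- names(lev)[max(lev[labels[grp]])]
  }
  stats::setNames(labels, names(x))
}

#' Ordinary least-squares trendline
#'
#' Slope and intercept of the straight line fitted through `(x, y)`, as
#' drawn through the per-plane comparison values of the four blood
#' cases.
#'
#' @param x,y numeric vectors of equal length; `x` must contain at
#'   least two distinct values.
#' @return Named vector `c(slope = , intercept = )`.
#' @export
linear_trendline <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop("degenerate fit: need at least two distinct x values")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  c(slope = unname(co[2L]), intercept = unname(co[1L]))
}
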