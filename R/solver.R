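#' Solver configuration
#'
#' Time stepping and numerical tolerances for the projection-method flow
#' solver. Time integration is first-order: diffusion and (upwind)
#' advection are treated implicitly, so the cardiac time step
#' (0.008 s) is stable on sub-millimetre grids; `cfl_limit` is an
#' optional accuracy guard (advective CFL number), disabled by default.
#'
#' @param dt time-step size (s), > 0.
#' @param n_steps number of steps for [solve_transient()].
#' @param density fluid density (kg/m^3); `NULL` takes the blood case's.
#' @param body_force volumetric force `c(f_z, f_y)` (N/m^3); default zero
#'   (gravity neglected).
#' @param picard_tol relative nonlinear tolerance on the velocity between
#'   Picard sweeps within a step, in (0, 1).
#' @param poisson_tol pressure-solve tolerance, in (0, 1); the projected
#'   field's discrete divergence is bounded by 10x this value.
#' @param max_inner_iters Picard sweeps per step (default 1: the step is
#'   small relative to the cardiac cycle, so one lagged-viscosity sweep
#'   suffices).
#' @param gamma_floor shear-rate floor (1/s) applied when evaluating the
#'   effective viscosity, avoiding a flat zero-shear plateau.
#' @param cfl_limit advective CFL guard; `Inf` disables. A finite value
#'   makes [advance()] fail with the admissible step size.
#' @param inlet_profile `"plug"` (spatially uniform, the default),
#'   `"parabolic"` (same mean), or a `function(y, t)` returning the
#'   inlet velocity at cross positions `y`.
#' @param viscosity_fn optional `function(gamma)` overriding the Carreau
#'   law (e.g. a power-law or constant viscosity for verification runs).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 0.008, n_steps = 50L, density = NULL,
                          body_force = c(0, 0), picard_tol = 1e-3,
                          poisson_tol = 1e-8, max_inner_iters = 1L,
                          gamma_floor = 1e-6, cfl_limit = Inf,
                          inlet_profile = "plug", viscosity_fn = NULL) {
  if (!(is.numeric(dt) && dt > 0)) stop("dt must be positive")
  if (!(picard_tol > 0 && picard_tol < 1))
    stop("picard_tol must lie in (0, 1)")
  if (!(poisson_tol > 0 && poisson_tol < 1))
    stop("poisson_tol must lie in (0, 1)")
  if (!(cfl_limit > 0)) stop("cfl_limit must be positive")
  stopifnot(length(body_force) == 2L, n_steps >= 1)
  structure(list(dt = dt, n_steps = as.integer(n_steps), density = density,
                 body_force = body_force, picard_tol = picard_tol,
                 poisson_tol = poisson_tol,
                 max_inner_iters = as.integer(max_inner_iters),
                 gamma_floor = gamma_floor, cfl_limit = cfl_limit,
                 inlet_profile = inlet_profile, viscosity_fn = viscosity_fn),
            class = "solver_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# discrete state at one time instant on the staggered grid:
# u axial velocity on z-faces ((nz+1) x ny), v cross velocity on y-faces
# (nz x (ny+1)), p cell-centred gauge pressure, gamma shear-rate
# magnitude and mu effective viscosity at cell centres (nz x ny)
.init_field <- function(mesh, outlet, config, blood) {
  g0 <- matrix(0, mesh$nz, mesh$ny)
  structure(list(
    time = 0,
    u = matrix(0, mesh$nz + 1L, mesh$ny),
    v = matrix(0, mesh$nz, mesh$ny + 1L),
    p = matrix(outlet$gauge_pressure, mesh$nz, mesh$ny),
    gamma = g0,
    mu = .mu_field(config, blood, g0)
  ), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(paste0("flow_field at t = %.4f s: |u|max = %.4g m/s, ",
                     "p in [%.5g, %.5g] Pa\n"),
              x$time, max(abs(x$u)), min(x$p), max(x$p)))
  invisible(x)
}

.mu_field <- function(config, blood, gamma) {
  g <- pmax(gamma, config$gamma_floor)
  if (!is.null(config$viscosity_fn)) {
    m <- config$viscosity_fn(g)
  } else {
    m <- effective_viscosity(blood$carreau, as.vector(g))
  }
  matrix(m, nrow(gamma), ncol(gamma))
}

.inlet_values <- function(mesh, jset, config, waveform, t) {
  val <- if (is.numeric(waveform)) waveform
  else if (is.function(waveform)) waveform(t)
  else inlet_velocity(waveform, t)
  yc <- mesh$yc[jset]
  prof <- config$inlet_profile
  if (is.function(prof)) return(prof(yc, t))
  if (identical(prof, "plug")) return(rep(val, length(jset)))
  if (identical(prof, "parabolic")) {
    if (mesh$axisymmetric) {
      R <- mesh$yf[mesh$ny + 1L]
      return(2 * val * (1 - (yc / R)^2))
    }
    hw <- mesh$geometry$r_cca
    return(1.5 * val * pmax(0, 1 - (yc / hw)^2))
  }
  stop("unknown inlet_profile")
}

# --- static solver operators per mesh --------------------------------------

# Precomputes node numbering, boundary classification, neighbour ids,
# per-node face areas / volumes, the (constant) pressure-Poisson matrix
# and its Cholesky factorisation.
.solver_ops <- function(mesh) {
  nz <- mesh$nz; ny <- mesh$ny; dz <- mesh$dz; dy <- mesh$dy
  mask <- mesh$mask
  rw_c <- mesh$rw_c; rw_f <- mesh$rw_f
  cid <- function(i, j) (j - 1L) * nz + i

  ## u nodes: (nz+1) x ny
  uid <- matrix(seq_len((nz + 1L) * ny), nz + 1L, ny)
  ucl <- matrix(0L, nz + 1L, ny)
  ucl[1L, mask[1L, ]] <- 2L                      # inlet Dirichlet
  ucl[nz + 1L, mask[nz, ]] <- 3L                 # outlet (zero-gradient)
  if (nz > 1) for (iu in 2:nz) {
    both <- mask[iu - 1L, ] & mask[iu, ]
    one <- xor(mask[iu - 1L, ], mask[iu, ])
    ucl[iu, both] <- 1L
    ucl[iu, one] <- 4L                           # staircase wall face, u = 0
  }
  ui <- which(ucl == 1L, arr.ind = TRUE)
  iu <- ui[, 1L]; ju <- ui[, 2L]
  hasS <- ju > 1L; hasN <- ju < ny
  U <- list(
    id = uid, cl = ucl, iu = iu, j = ju,
    self = uid[ui],
    W = uid[cbind(iu - 1L, ju)], E = uid[cbind(iu + 1L, ju)],
    S = ifelse(hasS, uid[cbind(iu, pmax(ju - 1L, 1L))], NA_integer_),
    N = ifelse(hasN, uid[cbind(iu, pmin(ju + 1L, ny))], NA_integer_),
    Aew = rw_c[ju] * dy,
    An = rw_f[ju + 1L] * dz, As = rw_f[ju] * dz,
    Vu = rw_c[ju] * dy * dz,
    cW = cid(iu - 1L, ju), cE = cid(iu, ju),
    cNW = ifelse(hasN, cid(iu - 1L, pmin(ju + 1L, ny)), NA_integer_),
    cNE = ifelse(hasN, cid(iu, pmin(ju + 1L, ny)), NA_integer_),
    cSW = ifelse(hasS, cid(iu - 1L, pmax(ju - 1L, 1L)), NA_integer_),
    cSE = ifelse(hasS, cid(iu, pmax(ju - 1L, 1L)), NA_integer_),
    vSW = cid(iu - 1L, ju), vNW = cid(iu - 1L, ju) + nz * 0L,
    inlet_self = uid[1L, mask[1L, ]], inlet_j = which(mask[1L, ]),
    outlet_self = uid[nz + 1L, mask[nz, ]],
    outlet_W = uid[nz, mask[nz, ]],
    outlet_cW = cid(nz, which(mask[nz, ])),
    zero_self = uid[ucl == 0L | ucl == 4L]
  )
  # v-node ids surrounding each interior u node (for the advecting
  # cross velocity): cells (iu-1, j) and (iu, j), faces j and j+1
  vid <- matrix(seq_len(nz * (ny + 1L)), nz, ny + 1L)
  U$v1 <- vid[cbind(iu - 1L, ju)]
  U$v2 <- vid[cbind(iu - 1L, ju + 1L)]
  U$v3 <- vid[cbind(iu, ju)]
  U$v4 <- vid[cbind(iu, ju + 1L)]

  ## v nodes: nz x (ny+1)
  vcl <- matrix(0L, nz, ny + 1L)
  if (ny > 1) for (jv in 2:ny) {
    both <- mask[, jv - 1L] & mask[, jv]
    vcl[both, jv] <- 1L
  }
  vi <- which(vcl == 1L, arr.ind = TRUE)
  iv <- vi[, 1L]; jv <- vi[, 2L]
  hasW <- iv > 1L; hasE <- iv < nz
  V <- list(
    id = vid, cl = vcl, i = iv, jv = jv,
    self = vid[vi],
    W = ifelse(hasW, vid[cbind(pmax(iv - 1L, 1L), jv)], NA_integer_),
    E = ifelse(hasE, vid[cbind(pmin(iv + 1L, nz), jv)], NA_integer_),
    S = vid[cbind(iv, jv - 1L)], N = vid[cbind(iv, jv + 1L)],
    An = rw_c[jv] * dz, As = rw_c[jv - 1L] * dz,
    Aew = rw_f[jv] * dy,
    Vv = pmax(rw_f[jv], 1e-300) * dy * dz,
    rf = rw_f[jv],
    cS = cid(iv, jv - 1L), cN = cid(iv, jv),
    cWS = ifelse(hasW, cid(pmax(iv - 1L, 1L), jv - 1L), NA_integer_),
    cWN = ifelse(hasW, cid(pmax(iv - 1L, 1L), jv), NA_integer_),
    cES = ifelse(hasE, cid(pmin(iv + 1L, nz), jv - 1L), NA_integer_),
    cEN = ifelse(hasE, cid(pmin(iv + 1L, nz), jv), NA_integer_),
    zero_self = vid[vcl != 1L]
  )
  V$u1 <- uid[cbind(iv, jv - 1L)]
  V$u2 <- uid[cbind(iv + 1L, jv - 1L)]
  V$u3 <- uid[cbind(iv, jv)]
  V$u4 <- uid[cbind(iv + 1L, jv)]

  ## fluid cells and divergence operator
  fc <- which(mask, arr.ind = TRUE)
  fi <- fc[, 1L]; fj <- fc[, 2L]
  Pc <- list(
    i = fi, j = fj, self = cid(fi, fj),
    uW = uid[cbind(fi, fj)], uE = uid[cbind(fi + 1L, fj)],
    vS = vid[cbind(fi, fj)], vN = vid[cbind(fi, fj + 1L)],
    Aew = rw_c[fj] * dy,
    An = rw_f[fj + 1L] * dz, As = rw_f[fj] * dz,
    V = rw_c[fj] * dy * dz
  )

  ## pressure-Poisson matrix (flux-symmetric form), assembled once
  np <- nz * ny
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  add <- function(i, j, x) {
    keep <- x != 0
    ti <<- c(ti, i[keep]); tj <<- c(tj, j[keep]); tx <<- c(tx, x[keep])
  }
  fluid <- function(i, j) i >= 1L & i <= nz & j >= 1L & j <= ny &
    mask[cbind(pmax(pmin(i, nz), 1L), pmax(pmin(j, ny), 1L))]
  diag_acc <- numeric(np)
  # east
  lnk <- fluid(fi + 1L, fj)
  ce <- Pc$Aew / dz
  out_e <- fi == nz
  diag_acc[Pc$self] <- diag_acc[Pc$self] +
    ifelse(out_e, Pc$Aew / (dz / 2), ifelse(lnk, ce, 0))
  add(Pc$self[lnk & !out_e], cid(fi + 1L, fj)[lnk & !out_e],
      -ce[lnk & !out_e])
  # west
  lnk <- fi > 1L & fluid(fi - 1L, fj)
  diag_acc[Pc$self] <- diag_acc[Pc$self] + ifelse(lnk, ce, 0)
  add(Pc$self[lnk], cid(pmax(fi - 1L, 1L), fj)[lnk], -ce[lnk])
  # north
  lnk <- fj < ny & fluid(fi, fj + 1L)
  cn <- Pc$An / dy
  diag_acc[Pc$self] <- diag_acc[Pc$self] + ifelse(lnk, cn, 0)
  add(Pc$self[lnk], cid(fi, pmin(fj + 1L, ny))[lnk], -cn[lnk])
  # south
  lnk <- fj > 1L & fluid(fi, fj - 1L)
  cs <- Pc$As / dy
  diag_acc[Pc$self] <- diag_acc[Pc$self] + ifelse(lnk, cs, 0)
  add(Pc$self[lnk], cid(fi, pmax(fj - 1L, 1L))[lnk], -cs[lnk])
  # solid cells: identity rows; fluid diagonals
  solid <- setdiff(seq_len(np), Pc$self)
  add(c(Pc$self, solid), c(Pc$self, solid),
      c(diag_acc[Pc$self], rep(1, length(solid))))
  Pmat <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(np, np))
  Pchol <- Matrix::Cholesky(Matrix::forceSymmetric(Pmat), LDL = FALSE)

  list(U = U, V = V, Pc = Pc, Pmat = Pmat, Pchol = Pchol,
       nz = nz, ny = ny, dz = dz, dy = dy)
}

# helper: safe indexed lookup, 0 where the index is NA
.g0 <- function(vec, idx) {
  out <- numeric(length(idx))
  ok <- !is.na(idx)
  out[ok] <- vec[idx[ok]]
  out
}

# one momentum-predictor + projection pass at fixed viscosity
.step_solve <- function(ops, mesh, config, rho, un, vn, p, mu, u_in) {
  nz <- ops$nz; ny <- ops$ny; dz <- ops$dz; dy <- ops$dy
  dt <- config$dt
  U <- ops$U; V <- ops$V; Pc <- ops$Pc
  muv <- as.vector(mu)
  unv <- as.vector(un); vnv <- as.vector(vn); pv <- as.vector(p)

  ## ---- u momentum ----
  muW <- muv[U$cW]; muE <- muv[U$cE]
  aW <- muW * U$Aew / dz / U$Vu
  aE <- muE * U$Aew / dz / U$Vu
  hasN <- !is.na(U$N); hasS <- !is.na(U$S)
  muN <- (muW + muE + .g0(muv, U$cNW) + .g0(muv, U$cNE)) / 4
  muS <- (muW + muE + .g0(muv, U$cSW) + .g0(muv, U$cSE)) / 4
  aN <- ifelse(hasN, muN * U$An / dy / U$Vu, 0)
  aS <- ifelse(hasS, muS * U$As / dy / U$Vu, 0)
  aNh <- ifelse(hasN, 0, (muW + muE) / 2 * U$An / (dy / 2) / U$Vu)
  aSh <- ifelse(hasS, 0, (muW + muE) / 2 * U$As / (dy / 2) / U$Vu)
  Uadv <- unv[U$self]
  Vadv <- (vnv[U$v1] + vnv[U$v2] + vnv[U$v3] + vnv[U$v4]) / 4
  azp <- rho * pmax(Uadv, 0) / dz
  azm <- rho * pmax(-Uadv, 0) / dz
  ayp <- rho * pmax(Vadv, 0) / dy
  aym <- rho * pmax(-Vadv, 0) / dy
  diag_u <- rho / dt + aW + aE + aN + aS + aNh + aSh + azp + azm + ayp + aym
  rhs_u <- rho / dt * unv[U$self] - (pv[U$cE] - pv[U$cW]) / dz +
    config$body_force[1L]
  nu_tot <- (nz + 1L) * ny
  ti <- c(U$self, U$self, U$self,
          U$self[hasS], U$self[hasN],
          U$inlet_self, U$zero_self, U$outlet_self, U$outlet_self)
  tjj <- c(U$self, U$W, U$E,
           U$S[hasS], U$N[hasN],
           U$inlet_self, U$zero_self, U$outlet_self, U$outlet_W)
  tx <- c(diag_u, -(aW + azp), -(aE + azm),
          -(aS + ayp)[hasS], -(aN + aym)[hasN],
          rep(1, length(U$inlet_self)), rep(1, length(U$zero_self)),
          rep(1, length(U$outlet_self)), rep(-1, length(U$outlet_self)))
  b <- numeric(nu_tot)
  b[U$self] <- rhs_u
  b[U$inlet_self] <- u_in
  Au <- Matrix::sparseMatrix(i = ti, j = tjj, x = tx,
                             dims = c(nu_tot, nu_tot))
  ustar <- as.vector(Matrix::solve(Au, b))

  ## ---- v momentum ----
  nv_tot <- nz * (ny + 1L)
  vstar <- numeric(nv_tot)
  if (length(V$self)) {
    muS2 <- muv[V$cS]; muN2 <- muv[V$cN]
    muP <- (muS2 + muN2) / 2
    aS2 <- muS2 * V$As / dy / V$Vv
    aN2 <- muN2 * V$An / dy / V$Vv
    hasW <- !is.na(V$W); hasE <- !is.na(V$E)
    muWf <- (muP + .g0(muv, V$cWS) / 2 + .g0(muv, V$cWN) / 2) / 2
    muEf <- (muP + .g0(muv, V$cES) / 2 + .g0(muv, V$cEN) / 2) / 2
    aW2 <- ifelse(hasW, muWf * V$Aew / dz / V$Vv, 0)
    aE2 <- ifelse(hasE, muEf * V$Aew / dz / V$Vv, 0)
    aWh <- ifelse(hasW, 0, muP * V$Aew / (dz / 2) / V$Vv)  # inlet plane v=0
    Uadv2 <- (unv[V$u1] + unv[V$u2] + unv[V$u3] + unv[V$u4]) / 4
    Vadv2 <- vnv[V$self]
    azp2 <- rho * pmax(Uadv2, 0) / dz
    azm2 <- rho * pmax(-Uadv2, 0) / dz
    ayp2 <- rho * pmax(Vadv2, 0) / dy
    aym2 <- rho * pmax(-Vadv2, 0) / dy
    diag_v <- rho / dt + aW2 + aE2 + aS2 + aN2 + aWh +
      azp2 + azm2 + ayp2 + aym2
    if (mesh$axisymmetric) diag_v <- diag_v + muP / V$rf^2
    rhs_v <- rho / dt * vnv[V$self] - (pv[V$cN] - pv[V$cS]) / dy +
      config$body_force[2L]
    ti2 <- c(V$self, V$self[hasW], V$self[hasE], V$self, V$self, V$zero_self)
    tj2 <- c(V$self, V$W[hasW], V$E[hasE], V$S, V$N, V$zero_self)
    tx2 <- c(diag_v, -(aW2 + azp2)[hasW], -(aE2 + azm2)[hasE],
             -(aS2 + ayp2), -(aN2 + aym2), rep(1, length(V$zero_self)))
    b2 <- numeric(nv_tot)
    b2[V$self] <- rhs_v
    Av <- Matrix::sparseMatrix(i = ti2, j = tj2, x = tx2,
                               dims = c(nv_tot, nv_tot))
    vstar <- as.vector(Matrix::solve(Av, b2))
  }

  ## ---- pressure projection ----
  np <- nz * ny
  flux <- Pc$Aew * (ustar[Pc$uE] - ustar[Pc$uW]) +
    Pc$An * vstar[Pc$vN] - Pc$As * vstar[Pc$vS]
  bphi <- numeric(np)
  bphi[Pc$self] <- -rho / dt * flux
  phi <- as.vector(Matrix::solve(ops$Pchol, bphi))

  unew <- ustar
  unew[U$self] <- ustar[U$self] -
    dt / rho * (phi[U$cE] - phi[U$cW]) / dz
  unew[U$outlet_self] <- ustar[U$outlet_self] -
    dt / rho * (0 - phi[U$outlet_cW]) / (dz / 2)
  vnew <- vstar
  if (length(V$self))
    vnew[V$self] <- vstar[V$self] -
      dt / rho * (phi[V$cN] - phi[V$cS]) / dy

  flux2 <- Pc$Aew * (unew[Pc$uE] - unew[Pc$uW]) +
    Pc$An * vnew[Pc$vN] - Pc$As * vnew[Pc$vS]
  maxdiv <- if (length(flux2)) max(abs(flux2 / Pc$V)) else 0

  list(u = matrix(unew, nz + 1L, ny), v = matrix(vnew, nz, ny + 1L),
       p = p + matrix(phi, nz, ny), maxdiv = maxdiv)
}

# generalized shear-rate magnitude gamma = sqrt(2 D:D) at cell centres
.strain_rate_field <- function(u, v, mesh) {
  nz <- mesh$nz; ny <- mesh$ny; dz <- mesh$dz; dy <- mesh$dy
  mask <- mesh$mask
  ucc <- (u[1:nz, , drop = FALSE] + u[2:(nz + 1L), , drop = FALSE]) / 2
  vcc <- (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1L), drop = FALSE]) / 2
  dudz <- (u[2:(nz + 1L), , drop = FALSE] - u[1:nz, , drop = FALSE]) / dz
  dvdy <- (v[, 2:(ny + 1L), drop = FALSE] - v[, 1:ny, drop = FALSE]) / dy
  # du/dy with no-slip walls a half-cell beyond wall-adjacent centres;
  # at the tube axis the mirrored value enforces symmetry
  mask_up <- cbind(mask[, -1L, drop = FALSE], rep(FALSE, nz))
  mask_dn <- cbind(rep(FALSE, nz), mask[, -ny, drop = FALSE])
  val_up <- cbind(ucc[, -1L, drop = FALSE], rep(0, nz))
  val_dn <- cbind(rep(0, nz), ucc[, -ny, drop = FALSE])
  d_up <- ifelse(mask_up, dy, dy / 2)
  d_dn <- ifelse(mask_dn, dy, dy / 2)
  up <- ifelse(mask_up, val_up, 0)
  dn <- ifelse(mask_dn, val_dn, 0)
  if (mesh$axisymmetric) {       # symmetry at r = 0
    dn[, 1L] <- ucc[, 1L]
    d_dn[, 1L] <- dy
  }
  dudy <- (up - dn) / (d_up + d_dn)
  # dv/dz (zero-gradient at the outlet, v = 0 upstream of the inlet)
  mask_e <- rbind(mask[-1L, , drop = FALSE], rep(FALSE, ny))
  mask_w <- rbind(rep(FALSE, ny), mask[-nz, , drop = FALSE])
  val_e <- rbind(vcc[-1L, , drop = FALSE], rep(0, ny))
  val_w <- rbind(rep(0, ny), vcc[-nz, , drop = FALSE])
  d_e <- ifelse(mask_e, dz, dz / 2)
  d_w <- ifelse(mask_w, dz, dz / 2)
  e <- ifelse(mask_e, val_e, 0)
  w <- ifelse(mask_w, val_w, 0)
  e[nz, ] <- vcc[nz, ]; d_e[nz, ] <- dz    # outlet: dv/dz = 0
  dvdz <- (e - w) / (d_e + d_w)
  hoop <- if (mesh$axisymmetric)
    sweep(vcc, 2L, mesh$rw_c, "/") else matrix(0, nz, ny)
  g <- sqrt(2 * (dudz^2 + dvdy^2 + hoop^2) + (dudy + dvdz)^2)
  g[!mask] <- 0
  g
}

#' Advance the flow one time step
#'
#' One incremental pressure-projection step: (i) the effective viscosity
#' is evaluated from the current strain-rate field (Picard lagging),
#' (ii) an implicit momentum predictor is solved with the inlet Dirichlet
#' velocity at `t + dt` and no-slip walls, (iii) a pressure-Poisson solve
#' with the outlet gauge pressure as Dirichlet value, (iv) the velocity
#' is corrected to discrete divergence-freeness. Additional Picard sweeps
#' re-evaluate the viscosity within the step when
#' `config$max_inner_iters > 1`.
#'
#' @param field current `flow_field` (from a previous step or internal
#'   rest initialization).
#' @param mesh a [generate_mesh()] mesh.
#' @param config a [solver_config()].
#' @param blood a [blood_case()] supplying the Carreau law and density.
#' @param waveform inlet driving: a [cardiac_waveform()], a constant
#'   numeric velocity, or a `function(t)`.
#' @param outlet an [outlet_condition()].
#' @param ops precomputed solver operators (internal; built from the mesh
#'   when omitted, and once per run by [solve_transient()]).
#' @return The updated `flow_field` at `field$time + dt`, with attribute
#'   `"maxdiv"` holding the maximum absolute discrete divergence (1/s).
#' @export
advance <- function(field, mesh, config, blood, waveform, outlet,
                    ops = NULL) {
  stopifnot(inherits(field, "flow_field"), inherits(mesh, "flow_mesh"),
            inherits(config, "solver_config"), inherits(blood, "blood_case"),
            inherits(outlet, "outlet_condition"))
  if (is.null(ops)) ops <- .solver_ops(mesh)
  rho <- config$density %||% blood$density
  dt <- config$dt
  if (is.finite(config$cfl_limit)) {
    speed <- max(abs(field$u)) / mesh$dz + max(abs(field$v)) / mesh$dy
    if (speed > 0 && dt * speed > config$cfl_limit)
      stop(sprintf(paste0("CFL violation: dt = %g s gives CFL = %.3g > ",
                          "limit %.3g; admissible dt = %g s"),
                   dt, dt * speed, config$cfl_limit,
                   config$cfl_limit / speed))
  }
  t_new <- field$time + dt
  u_in <- .inlet_values(mesh, ops$U$inlet_j, config, waveform, t_new)
  gamma <- field$gamma
  u_prev <- NULL
  res_hist <- numeric(0)
  for (sweep in seq_len(max(1L, config$max_inner_iters))) {
    mu <- .mu_field(config, blood, gamma)
    sol <- .step_solve(ops, mesh, config, rho, field$u, field$v, field$p,
                       mu, u_in)
    gamma <- .strain_rate_field(sol$u, sol$v, mesh)
    if (!is.null(u_prev)) {
      rel <- max(abs(sol$u - u_prev)) / max(max(abs(sol$u)), 1e-12)
      res_hist <- c(res_hist, rel)
      if (rel < config$picard_tol) break
    }
    u_prev <- sol$u
  }
  if (config$max_inner_iters > 1L && length(res_hist) &&
      res_hist[length(res_hist)] >= config$picard_tol &&
      length(res_hist) >= config$max_inner_iters - 1L)
    stop("Picard iteration did not reach picard_tol = ", config$picard_tol,
         "; residual history: ", paste(signif(res_hist, 3), collapse = ", "))
  structure(list(time = t_new, u = sol$u, v = sol$v, p = sol$p,
                 gamma = gamma, mu = .mu_field(config, blood, gamma)),
            class = "flow_field", maxdiv = sol$maxdiv)
}

#' Transient solve with snapshots
#'
#' Marches `config$n_steps` steps of size `config$dt` from rest
#' (velocity zero, pressure equal to the outlet gauge value; the
#' pulsatile waveform itself ramps the inflow over the first systole) and
#' returns the flow fields at the requested snapshot times (nearest
#' completed step). The run is fully deterministic.
#'
#' @inheritParams advance
#' @param snapshot_times times (s) at which fields are kept; default
#'   `c(0.08, 0.12, 0.2, 0.28, 0.4)` clipped to the simulated horizon.
#'   Must lie in `(0, dt * n_steps]`.
#' @param probe optional `function(field, mesh)` returning a named
#'   numeric vector, evaluated after every step (e.g. a centreline
#'   velocity for waveform comparisons); collected in `probe_log`.
#' @return An object of class `flow_solution`: a list with `fields` (one
#'   `flow_field` per snapshot, named by time), `final` (the last step),
#'   `flux_log` (per-step inlet/outlet volumetric fluxes and the
#'   maximum discrete divergence), and `probe_log` if a probe was given.
#' @export
solve_transient <- function(mesh, config, blood, waveform, outlet,
                            snapshot_times = NULL, probe = NULL) {
  horizon <- config$dt * config$n_steps
  if (is.null(snapshot_times)) {
    snapshot_times <- c(0.08, 0.12, 0.2, 0.28, 0.4)
    snapshot_times <- snapshot_times[snapshot_times <= horizon + 1e-12]
    if (!length(snapshot_times)) snapshot_times <- horizon
  }
  if (any(snapshot_times <= 0 | snapshot_times > horizon + 1e-9))
    stop("snapshot times must lie in (0, ", horizon, "] s")
  ops <- .solver_ops(mesh)
  field <- .init_field(mesh, outlet, config, blood)
  snap_steps <- pmin(pmax(round(snapshot_times / config$dt), 1L),
                     config$n_steps)
  fields <- vector("list", length(snapshot_times))
  names(fields) <- sprintf("t=%g", snapshot_times)
  log <- data.frame(step = seq_len(config$n_steps), time = NA_real_,
                    inlet = NA_real_, outlet1 = NA_real_,
                    outlet2 = NA_real_, maxdiv = NA_real_)
  probes <- if (!is.null(probe)) vector("list", config$n_steps)
  for (s in seq_len(config$n_steps)) {
    field <- advance(field, mesh, config, blood, waveform, outlet, ops)
    fx <- boundary_fluxes(field, mesh)
    log$time[s] <- field$time
    log$inlet[s] <- fx[["inlet"]]
    log$outlet1[s] <- fx[["outlet1"]]
    log$outlet2[s] <- fx[["outlet2"]]
    log$maxdiv[s] <- attr(field, "maxdiv")
    hit <- which(snap_steps == s)
    for (k in hit) fields[[k]] <- field
    if (!is.null(probe))
      probes[[s]] <- c(time = field$time, probe(field, mesh))
  }
  structure(list(fields = fields, final = field, flux_log = log,
                 probe_log = if (!is.null(probe))
                   as.data.frame(do.call(rbind, probes)),
                 snapshot_times = snapshot_times),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow_solution: %d snapshot(s), final t = %.4f s\n",
              length(x$fields), x$final$time))
  invisible(x)
}

#' Iterate to a steady state
#'
#' Repeats [advance()] with a constant inlet velocity until the velocity
#' field stops changing (relative step-to-step change below `tol`).
#'
#' @inheritParams advance
#' @param inlet_value constant inlet velocity (m/s).
#' @param tol relative steady-state tolerance.
#' @param max_steps step budget.
#' @return The steady `flow_field` (attribute `"steps"` holds the count).
#' @export
solve_steady <- function(mesh, config, blood, inlet_value, outlet,
                         tol = 1e-6, max_steps = 500L) {
  ops <- .solver_ops(mesh)
  field <- .init_field(mesh, outlet, config, blood)
  for (s in seq_len(max_steps)) {
    new <- advance(field, mesh, config, blood, inlet_value, outlet, ops)
    rel <- max(abs(new$u - field$u)) / max(max(abs(new$u)), 1e-12)
    field <- new
    if (rel < tol) break
  }
  attr(field, "steps") <- s
  field
}

#' Maximum discrete divergence of a flow field
#'
#' Finite-volume divergence over the fluid cells; after a projection
#' step this is bounded by ten times the pressure-solve tolerance.
#'
#' @inheritParams advance
#' @return Maximum absolute discrete divergence (1/s).
#' @export
check_divergence <- function(field, mesh) {
  stopifnot(inherits(field, "flow_field"), inherits(mesh, "flow_mesh"))
  nz <- mesh$nz; ny <- mesh$ny
  fcells <- which(mesh$mask, arr.ind = TRUE)
  fi <- fcells[, 1L]; fj <- fcells[, 2L]
  Aew <- mesh$rw_c[fj] * mesh$dy
  An <- mesh$rw_f[fj + 1L] * mesh$dz
  As <- mesh$rw_f[fj] * mesh$dz
  V <- mesh$rw_c[fj] * mesh$dy * mesh$dz
  flux <- Aew * (field$u[cbind(fi + 1L, fj)] - field$u[cbind(fi, fj)]) +
    An * field$v[cbind(fi, fj + 1L)] - As * field$v[cbind(fi, fj)]
  max(abs(flux / V))
}

#' Boundary volumetric fluxes
#'
#' Volumetric flux through the inlet and each outlet (m^3/s for the
#' axisymmetric tube, m^2/s per unit depth for the planar mode). At the
#' bifurcation the inlet flux balances the two outlet fluxes.
#'
#' @inheritParams advance
#' @return Named vector `c(inlet = , outlet1 = , outlet2 = )`.
#' @export
boundary_fluxes <- function(field, mesh) {
  stopifnot(inherits(field, "flow_field"), inherits(mesh, "flow_mesh"))
  scale <- if (mesh$axisymmetric) 2 * pi else 1
  bf <- mesh$boundary_faces
  res <- c(inlet = 0, outlet1 = 0, outlet2 = 0)
  inl <- bf[bf$tag == "inlet", , drop = FALSE]
  if (nrow(inl))
    res[["inlet"]] <- sum(scale * mesh$rw_c[inl$j] * mesh$dy *
                            field$u[cbind(inl$i + 1L, inl$j)])
  for (tag in c("outlet1", "outlet2")) {
    out <- bf[bf$tag == tag, , drop = FALSE]
    if (nrow(out))
      res[[tag]] <- sum(scale * mesh$rw_c[out$j] * mesh$dy *
                          field$u[cbind(out$i + 1L, out$j)])
  }
  res
}
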