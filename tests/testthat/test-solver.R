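test_that("rest state with zero inflow is a fixed point", {
  mesh <- tube_mesh_coarse()
  blood <- newtonian_blood()
  cfg <- solver_config(dt = 0.01, n_steps = 1)
  sol <- solve_transient(mesh, cfg, blood, 0, default_outlet,
                         snapshot_times = 0.01)
  f <- sol$final
  expect_equal(max(abs(f$u)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f$v)), 0, tolerance = 1e-12)
  expect_equal(diff(range(f$p)), 0, tolerance = 1e-8)
})

test_that("one step from rest is discretely divergence-free", {
  mesh <- tube_mesh_coarse()
  cfg <- solver_config(dt = 0.008, n_steps = 1)
  sol <- solve_transient(mesh, cfg, newtonian_blood(), cardiac_waveform(),
                         default_outlet, snapshot_times = 0.008)
  f <- sol$final
  expect_gt(max(abs(f$u)), 0)
  expect_lt(check_divergence(f, mesh), 10 * cfg$poisson_tol)
  expect_lt(attr(f, "maxdiv"), 10 * cfg$poisson_tol)
})

test_that("steady Newtonian tube solve recovers the Poiseuille solution", {
  mesh <- tube_mesh_coarse()
  mu <- 0.04; vbar <- 0.1; R <- 3e-3
  cfg <- solver_config(dt = 0.2, n_steps = 1)
  f <- solve_steady(mesh, cfg, newtonian_blood(mu), vbar, default_outlet,
                    tol = 1e-6, max_steps = 200)
  i <- mesh$nz - 5L   # well beyond the entrance length at Re ~ 16
  ucl <- (f$u[i, 1] + f$u[i + 1, 1]) / 2
  expect_equal(ucl, 2 * vbar, tolerance = 0.02)
  # full radial profile against the analytic parabola
  prof <- (f$u[i, ] + f$u[i + 1, ]) / 2
  ana <- 2 * vbar * (1 - (mesh$yc / R)^2)
  expect_lt(sqrt(mean((prof - ana)^2)) / sqrt(mean(ana^2)), 0.02)
  # wall shear stress against 4 mu vbar / R
  wss <- wall_shear_stress(f, mesh)
  tau <- mean(wss$tau[wss$z > 0 & wss$z < 0.015])
  expect_equal(tau, 4 * mu * vbar / R, tolerance = 0.05)
  # viscosity field within the admissible band
  expect_true(all(f$mu >= 0.04 - 1e-12 & f$mu <= 0.04 + 1e-12))
})

test_that("steady power-law tube solve matches the analytic profile", {
  mesh <- fixture_mesh("tube_fine", function()
    generate_mesh(tube_geometry(), 0.2e-3, "axisymmetric_tube",
                  axial_cell_size = 1e-3))
  R <- 3e-3; n <- 0.5; K <- 0.01; G <- 86.07
  cfg <- solver_config(dt = 0.2, n_steps = 1, gamma_floor = 1e-3,
                       viscosity_fn = function(g) K * pmax(g, 1e-3)^(n - 1),
                       inlet_profile = function(y, t)
                         power_law_pipe_profile(R, G, K, n, y))
  f <- solve_steady(mesh, cfg, newtonian_blood(), 0.1, default_outlet,
                    tol = 1e-6, max_steps = 150)
  i <- round(mesh$nz / 2)
  prof <- (f$u[i, ] + f$u[i + 1, ]) / 2
  ana <- power_law_pipe_profile(R, G, K, n, mesh$yc)
  expect_lt(sqrt(mean((prof - ana)^2)) / sqrt(mean(ana^2)), 0.03)
})

test_that("pulsatile Newtonian solve tracks the Womersley series", {
  mesh <- fixture_mesh("tube_wom", function()
    generate_mesh(tube_geometry(), 0.15e-3, "axisymmetric_tube",
                  axial_cell_size = 1e-3))
  R <- 3e-3; Tper <- 0.5; om <- 2 * pi / Tper; rho <- 1060
  mu <- om * rho * R^2 / 9            # Womersley number alpha = 3
  Kp <- 2000
  cfg <- solver_config(dt = Tper / 200, n_steps = 600,
                       inlet_profile = function(y, t)
                         womersley_solution(R, om, Kp, mu, rho, y, t))
  i <- round(mesh$nz / 2)
  probe <- function(field, mesh)
    c(ucl = (field$u[i, 1] + field$u[i + 1, 1]) / 2)
  sol <- solve_transient(mesh, cfg, newtonian_blood(mu), 0, default_outlet,
                         snapshot_times = 3 * Tper, probe = probe)
  last <- sol$probe_log[sol$probe_log$time > 2 * Tper + 1e-9, ]
  ana <- vapply(last$time, function(t)
    womersley_solution(R, om, Kp, mu, rho, mesh$yc[1], t), numeric(1))
  expect_lt(sqrt(mean((last$ucl - ana)^2)) / sqrt(mean(ana^2)), 0.05)
})

test_that("pressure drop grows with viscosity at fixed flow rate", {
  mesh <- tube_mesh_coarse()
  cfg <- solver_config(dt = 0.2, n_steps = 1)
  dps <- vapply(c(0.01, 0.02, 0.04), function(mu) {
    f <- solve_steady(mesh, cfg, newtonian_blood(mu), 0.1, default_outlet,
                      tol = 1e-6, max_steps = 150)
    pressure_drop(f, mesh)
  }, numeric(1))
  expect_true(all(diff(dps) > 0))
})

test_that("centerline error vs Poiseuille decreases under mesh refinement", {
  errs <- vapply(c(0.5e-3, 0.375e-3, 0.3e-3), function(h) {
    mesh <- generate_mesh(tube_geometry(), h, "axisymmetric_tube",
                          axial_cell_size = 1e-3)
    cfg <- solver_config(dt = 0.2, n_steps = 1)
    f <- solve_steady(mesh, cfg, newtonian_blood(0.04), 0.1, default_outlet,
                      tol = 1e-6, max_steps = 150)
    i <- mesh$nz - 5L
    abs((f$u[i, 1] + f$u[i + 1, 1]) / 2 - 0.2) / 0.2
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("transient runs are deterministic and validate snapshots", {
  mesh <- tube_mesh_coarse()
  cfg <- solver_config(dt = 0.008, n_steps = 10)
  run <- function() solve_transient(mesh, cfg, load_blood_case("anemic"),
                                    cardiac_waveform(), default_outlet,
                                    snapshot_times = 0.08)
  a <- run(); b <- run()
  expect_identical(a$final$u, b$final$u)
  expect_identical(a$final$p, b$final$p)
  expect_identical(a$flux_log, b$flux_log)
  expect_error(solve_transient(mesh, cfg, load_blood_case("anemic"),
                               cardiac_waveform(), default_outlet,
                               snapshot_times = 0.2),
               "snapshot")
})

test_that("a finite CFL guard rejects an over-long step and names the cure", {
  mesh <- tube_mesh_coarse()
  cfg <- solver_config(dt = 0.008, n_steps = 1)
  sol <- solve_transient(mesh, cfg, newtonian_blood(), cardiac_waveform(),
                         default_outlet, snapshot_times = 0.008)
  cfg_strict <- solver_config(dt = 0.008, n_steps = 1, cfl_limit = 0.5)
  expect_error(advance(sol$final, mesh, cfg_strict, newtonian_blood(),
                       cardiac_waveform(), default_outlet),
               "admissible dt")
})

test_that("bifurcation flow conserves mass between inlet and outlets", {
  mesh <- bif_mesh_coarse()
  cfg <- solver_config(dt = 0.008, n_steps = 50)
  sol <- solve_transient(mesh, cfg, load_blood_case("healthy_case1"),
                         cardiac_waveform(), default_outlet)
  fl <- sol$flux_log
  imbalance <- abs(fl$inlet - fl$outlet1 - fl$outlet2) /
    pmax(abs(fl$inlet), 1e-12)
  expect_lt(max(imbalance), 0.01)
  # both branches carry forward flow at end-diastole, ICA the larger share
  expect_gt(fl$outlet1[50], fl$outlet2[50])
  expect_gt(fl$outlet2[50], 0)
  # divergence contract holds at every step
  expect_lt(max(fl$maxdiv), 10 * cfg$poisson_tol)
})
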