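test_that("wall shear stress recovers hand-computable shear fields", {
  mesh <- tube_mesh_coarse()
  blood <- newtonian_blood(0.004)
  cfg <- solver_config(dt = 0.01, n_steps = 1)
  sol <- solve_transient(mesh, cfg, blood, 0, default_outlet,
                         snapshot_times = 0.01)
  f <- sol$final
  # zero field: zero shear everywhere
  expect_equal(max(wall_shear_stress(f, mesh)$tau), 0)
  # linear shear near the wall: u = 10 * (R - r), mu = 0.004 -> 0.04 Pa
  R <- mesh$yf[mesh$ny + 1L]
  f2 <- f
  for (j in seq_len(mesh$ny)) f2$u[, j] <- 10 * (R - mesh$yc[j])
  wss <- wall_shear_stress(f2, mesh)
  expect_equal(unique(round(wss$tau, 10)), 0.04)
})

test_that("skin friction applies the dynamic-pressure normalization", {
  # printed worked pair: tau_max = 7.18665 Pa -> Cf_max ~ 1.35593
  expect_equal(skin_friction(7.18665, 1060, 0.1), 1.35593,
               tolerance = 1e-3)
  expect_equal(skin_friction(0), 0)
  # inverse arithmetic: Cf = 0.1 at tau = 0.53 Pa
  expect_equal(skin_friction(0.53, 1060, 0.1), 0.1)
  # linear in tau, quadratic in the reference velocity
  expect_equal(skin_friction(2 * 1.7), 2 * skin_friction(1.7))
  expect_equal(skin_friction(1.7, v_ref = 0.2),
               skin_friction(1.7, v_ref = 0.1) / 4)
  expect_error(skin_friction(1, v_ref = 0), "positive")
  expect_error(skin_friction(1, density = -1), "positive")
})

test_that("wall-deformation surrogate is the pure strain-distance product", {
  expect_equal(wall_deformation_estimate(0, 0.0011427), 0)
  expect_equal(wall_deformation_estimate(75.6475, 0.0011427), 0.086443,
               tolerance = 1e-4)
  s <- c(1.5, 20); d <- c(2e-4, 1e-3)
  expect_equal(wall_deformation_estimate(s, d, dt = 0.008),
               s * 0.008 * d)
  expect_error(wall_deformation_estimate(-1, 1), "non-negative")
})

test_that("plane statistics summarize uniform and Poiseuille fields", {
  mesh <- tube_mesh_coarse()
  cfg <- solver_config(dt = 0.2, n_steps = 1)
  planes <- plane_positions()
  # rest field: uniform pressure on every plane
  sol0 <- solve_transient(mesh, cfg, newtonian_blood(), 0, default_outlet,
                          snapshot_times = 0.2)
  ps0 <- plane_statistics(sol0$final, mesh, planes)
  pr <- ps0[ps0$quantity == "pressure", ]
  expect_equal(pr$min, rep(13332, 30), tolerance = 1e-6)
  expect_equal(pr$max, rep(13332, 30), tolerance = 1e-6)
  # steady Poiseuille: plane max velocity is twice the mean inflow
  f <- solve_steady(mesh, cfg, newtonian_blood(0.04), 0.1, default_outlet,
                    tol = 1e-6, max_steps = 200)
  ps <- plane_statistics(f, mesh, planes)
  vmax <- ps[ps$quantity == "velocity" & ps$z_m > 0.005, "max"]
  expect_equal(vmax, rep(0.2, length(vmax)), tolerance = 0.02)
  # order statistics on every plane and quantity
  ok <- is.finite(ps$avg)
  expect_true(all(ps$min[ok] <= ps$avg[ok] + 1e-12))
  expect_true(all(ps$avg[ok] <= ps$max[ok] + 1e-12))
  expect_error(plane_statistics(f, mesh, 0.5), "extent")
})

test_that("tertile classification follows ranks and the tie rules", {
  expect_equal(classify_levels(c(a = 1, b = 2, c = 3, d = 4)),
               c(a = "low", b = "average", c = "average", d = "high"))
  # degenerate all-tied input
  expect_equal(unname(classify_levels(c(a = 2, b = 2, c = 2))),
               rep("average", 3))
  # partial ties share the higher label
  lab <- classify_levels(c(a = 1, b = 1, c = 3, d = 4))
  expect_equal(lab[["a"]], lab[["b"]])
  expect_equal(lab[["a"]], "average")
  # effective viscosities at physiological shear: diabetic high, anemic low
  mu <- vapply(all_blood_cases(), function(b)
    effective_viscosity(b$carreau, 100), numeric(1))
  names(mu) <- blood_case_names()
  lab2 <- classify_levels(mu)
  expect_equal(lab2[["diabetic"]], "high")
  expect_equal(lab2[["anemic"]], "low")
  expect_error(classify_levels(c(a = 1, b = 2)), "at least 3")
})

test_that("linear trendline is exact on lines and honest on noise", {
  x <- 1:10
  expect_equal(linear_trendline(x, 2 * x + 1),
               c(slope = 2, intercept = 1))
  expect_error(linear_trendline(rep(2, 5), rnorm(5)), "degenerate")
  # noisy line: slope recovered within 3 closed-form standard errors
  set.seed(7)
  n <- 100; sigma <- 0.3
  xs <- seq(0, 1, length.out = n)
  ys <- 0.5 * xs + 0.2 + rnorm(n, sd = sigma)
  co <- linear_trendline(xs, ys)
  se <- sigma / sqrt(sum((xs - mean(xs))^2))
  expect_lt(abs(co[["slope"]] - 0.5), 3 * se)
})
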