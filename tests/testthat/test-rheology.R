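test_that("Carreau viscosity matches the closed form and its limits", {
  an <- load_blood_case("anemic")$carreau
  db <- load_blood_case("diabetic")$carreau

  # zero-shear plateau is exactly mu_0
  expect_identical(effective_viscosity(an, 0), an$mu_0)
  # frozen high-precision evaluations of the closed form
  expect_equal(effective_viscosity(an, 100), 0.00269852366193,
               tolerance = 1e-10)
  expect_equal(effective_viscosity(db, 100), 0.0110535531666,
               tolerance = 1e-10)
  # n = 1 is exactly Newtonian regardless of gamma
  newt <- carreau_parameters(1, 5, 0.003, 0.04)
  expect_equal(effective_viscosity(newt, c(0, 1, 1e4)), rep(0.04, 3))

  expect_error(effective_viscosity(an, -1), "non-negative")
  expect_error(effective_viscosity(an, NaN), "finite")
})

test_that("Carreau viscosity is monotone non-increasing with correct limits", {
  grid <- 10^seq(-3, 5, length.out = 200)
  for (blood in all_blood_cases()) {
    p <- blood$carreau
    mu <- effective_viscosity(p, grid)
    expect_true(all(diff(mu) <= 1e-15), label = paste(blood$name, "monotone"))
    expect_true(all(mu >= p$mu_inf & mu <= p$mu_0))
    expect_identical(effective_viscosity(p, 0), p$mu_0)
    # infinite-shear plateau approached within 1% at gamma = 1e8 / lambda
    expect_lt(effective_viscosity(p, 1e8 / p$lambda_time) / p$mu_inf, 1.01)
  }
})

test_that("blood-case registry holds the four parameter sets", {
  db <- load_blood_case("diabetic")
  expect_equal(db$carreau$mu_0, 0.8592)
  expect_equal(db$carreau$lambda_time, 103.093)
  expect_equal(db$hematocrit, 65)
  h2 <- load_blood_case("healthy_case2")
  expect_equal(h2$carreau$lambda_time, 3.313)
  expect_equal(h2$carreau$n, 0.3568)
  an <- load_blood_case("anemic")
  expect_equal(an$carreau$mu_0, 0.0178)
  expect_equal(an$hematocrit, 25)
  expect_equal(an$density, 1060)
  expect_equal(load_blood_case("anemic", density = 1100)$density, 1100)

  expect_error(load_blood_case("plasma"), "valid names")
  expect_error(carreau_parameters(1.2, 1, 0.003, 0.04), "shear-thinning")
  expect_error(carreau_parameters(0.5, 1, 0.04, 0.003), "mu_0")
  expect_error(blood_case("x", load_blood_case("anemic")$carreau,
                          45, density = -1), "density")
})

test_that("strain-rate magnitude recovers canonical flows and is frame-invariant", {
  # simple shear du/dy = 10 recovers the shear rate
  g <- matrix(0, 2, 2); g[1, 2] <- 10
  expect_equal(strain_rate_magnitude(g), 10)
  # rigid rotation has zero deformation
  w <- matrix(c(0, -3, 3, 0), 2, 2)
  expect_equal(strain_rate_magnitude(w), 0)
  # planar extension diag(a, -a), a = 3: sqrt(2 * (9 + 9)) = 6
  expect_equal(strain_rate_magnitude(diag(c(3, -3))), 6)
  # rotation invariance: gamma(R G R^T) = gamma(G) for random tensors
  set.seed(42)
  for (k in 1:20) {
    G <- matrix(rnorm(9), 3, 3)
    th <- runif(3, 0, 2 * pi)
    R <- matrix(c(cos(th[1]), sin(th[1]), 0,
                  -sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, 3)
    expect_equal(strain_rate_magnitude(R %*% G %*% t(R)),
                 strain_rate_magnitude(G), tolerance = 1e-12)
  }
  expect_error(strain_rate_magnitude(matrix(c(1, Inf, 0, 0), 2, 2)),
               "finite")
  expect_error(strain_rate_magnitude(matrix(1, 2, 3)), "square")
})

test_that("viscosity ordering follows hematocrit at physiological shear", {
  cases <- all_blood_cases()
  expect_equal(viscosity_ordering(cases, 100),
               c("diabetic", "healthy_case2", "healthy_case1", "anemic"))
  # at zero shear the ordering is that of the mu_0 values
  expect_equal(viscosity_ordering(cases, 0),
               c("diabetic", "healthy_case2", "anemic", "healthy_case1"))
  # diabetic dominates anemic across the whole physiological range
  pair <- list(load_blood_case("anemic"), load_blood_case("diabetic"))
  for (g in 10^seq(0, 4, length.out = 25))
    expect_equal(viscosity_ordering(pair, g)[1], "diabetic")
  expect_error(viscosity_ordering(list(), 1), "at least two")
  expect_error(viscosity_ordering(cases[1], 1), "at least two")
})
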