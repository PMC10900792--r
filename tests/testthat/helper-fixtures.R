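# shared fixtures: built in code at test time, no stored data

# constant-viscosity blood stand-in (Carreau with lambda = 0 collapses to
# mu = mu_0 at every shear rate)
newtonian_blood <- function(mu = 0.04) {
  blood_case("newtonian", carreau_parameters(1, 0, mu, mu), 45)
}

# 3 mm tube geometry covering the default analysis window
tube_geometry <- function(r = 3e-3) {
  build_bifurcation(r_cca = r, r_ica = 2.2e-3, r_eca = 1.7e-3)
}

default_outlet <- outlet_condition(13332)

all_blood_cases <- function() lapply(blood_case_names(), load_blood_case)

# meshes reused across tests (built once per test run)
.fixture_env <- new.env(parent = emptyenv())
fixture_mesh <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

tube_mesh_coarse <- function() fixture_mesh("tube_coarse", function()
  generate_mesh(tube_geometry(), 0.3e-3, "axisymmetric_tube",
                axial_cell_size = 1e-3))

bif_mesh_coarse <- function() fixture_mesh("bif_coarse", function()
  generate_mesh(build_bifurcation(), 0.4e-3, "planar_bifurcation"))
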