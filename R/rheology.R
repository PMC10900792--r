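#' Carreau viscosity parameters
#'
#' Constructs a validated set of Carreau constitutive-law coefficients.
#' The Carreau model interpolates between a zero-shear viscosity plateau
#' `mu_0` and an infinite-shear plateau `mu_inf` with characteristic time
#' `lambda_time` and power-law index `n`:
#' \deqn{\mu_{eff}(\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
#'       \left[1+(\lambda\gamma)^2\right]^{(n-1)/2}}
#' Only shear-thinning sets (`0 < n <= 1`) are accepted; whole blood is
#' shear-thinning at all physiological hematocrits.
#'
#' @param n power-law index (dimensionless), in (0, 1].
#' @param lambda_time characteristic time constant (s), >= 0.
#' @param mu_inf infinite-shear viscosity (Pa s), > 0.
#' @param mu_0 zero-shear viscosity (Pa s), >= `mu_inf`.
#' @return An object of class `carreau_parameters`.
#' @examples
#' carreau_parameters(n = 0.33, lambda_time = 12.448,
#'                    mu_inf = 0.00257, mu_0 = 0.0178)
#' @export
carreau_parameters <- function(n, lambda_time, mu_inf, mu_0) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(lambda_time), length(lambda_time) == 1L,
            is.numeric(mu_inf), length(mu_inf) == 1L,
            is.numeric(mu_0), length(mu_0) == 1L)
  if (!(n > 0 && n <= 1))
    stop("power-law index n must satisfy 0 < n <= 1 (shear-thinning); got ", n)
  if (lambda_time < 0)
    stop("lambda_time must be non-negative; got ", lambda_time)
  if (!(mu_inf > 0))
    stop("mu_inf must be positive; got ", mu_inf)
  if (mu_0 < mu_inf)
    stop("mu_0 (", mu_0, ") must be >= mu_inf (", mu_inf, ")")
  structure(list(n = n, lambda_time = lambda_time,
                 mu_inf = mu_inf, mu_0 = mu_0),
            class = "carreau_parameters")
}

#' @export
print.carreau_parameters <- function(x, ...) {
  cat(sprintf(
    "Carreau parameters: n = %g, lambda = %g s, mu_inf = %g Pa.s, mu_0 = %g Pa.s\n",
    x$n, x$lambda_time, x$mu_inf, x$mu_0))
  invisible(x)
}

#' Carreau effective viscosity
#'
#' Evaluates the Carreau law at one or more shear-rate magnitudes.
#' At `gamma = 0` the value is exactly `mu_0`; as `gamma` grows it decays
#' monotonically towards `mu_inf`.
#'
#' @param params a [carreau_parameters()] object (or the `carreau` field
#'   of a [blood_case()]).
#' @param gamma shear-rate magnitude(s) (1/s), >= 0. Vectorized.
#' @return Effective viscosity (Pa s), same length as `gamma`; always in
#'   `[mu_inf, mu_0]`.
#' @examples
#' an <- load_blood_case("anemic")
#' effective_viscosity(an$carreau, 0)    # 0.0178 (zero-shear plateau)
#' effective_viscosity(an$carreau, 100)  # ~0.0027
#' @export
effective_viscosity <- function(params, gamma) {
  if (inherits(params, "blood_case")) params <- params$carreau
  stopifnot(inherits(params, "carreau_parameters"), is.numeric(gamma))
  if (any(!is.finite(gamma)))
    stop("shear rate gamma must be finite")
  if (any(gamma < 0))
    stop("shear rate gamma must be non-negative")
  mu <- params$mu_inf + (params$mu_0 - params$mu_inf) *
    (1 + (params$lambda_time * gamma)^2)^((params$n - 1) / 2)
  # guard against round-off leaving the admissible band
  pmin(pmax(mu, params$mu_inf), params$mu_0)
}

# -- blood-case registry -----------------------------------------------------

# Hematocrit-matched Carreau sets: anemic (Hct 25%), diabetic (Hct 65%),
# two healthy sets (Hct ~45%). Density is a standard whole-blood value,
# overridable per case via blood_case().
.blood_registry <- function() {
  list(
    anemic = list(n = 0.33, lambda_time = 12.448,
                  mu_inf = 0.00257, mu_0 = 0.0178, hematocrit = 25),
    diabetic = list(n = 0.39, lambda_time = 103.093,
                    mu_inf = 0.00802, mu_0 = 0.8592, hematocrit = 65),
    healthy_case1 = list(n = 0.48, lambda_time = 39.418,
                         mu_inf = 0.00345, mu_0 = 0.0161, hematocrit = 45),
    healthy_case2 = list(n = 0.3568, lambda_time = 3.313,
                         mu_inf = 0.0035, mu_0 = 0.056, hematocrit = 45)
  )
}

#' Names of the registered blood cases
#' @return Character vector of the four registered case names.
#' @export
blood_case_names <- function() names(.blood_registry())

#' Construct a blood case
#'
#' A blood case bundles a name, a Carreau parameter set, the hematocrit
#' (red-cell volume fraction, percent) and the mass density.
#'
#' @param name case label (character scalar).
#' @param carreau a [carreau_parameters()] object.
#' @param hematocrit hematocrit count (percent), in (0, 100).
#' @param density mass density (kg/m^3), > 0. Default 1060 (whole blood).
#' @return An object of class `blood_case`.
#' @export
blood_case <- function(name, carreau, hematocrit, density = 1060) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(carreau, "carreau_parameters"),
            is.numeric(hematocrit), hematocrit > 0, hematocrit < 100,
            is.numeric(density))
  if (!(density > 0)) stop("density must be positive; got ", density)
  structure(list(name = name, carreau = carreau,
                 hematocrit = hematocrit, density = density),
            class = "blood_case")
}

#' @export
print.blood_case <- function(x, ...) {
  cat(sprintf("Blood case '%s' (Hct %g%%, rho = %g kg/m^3)\n",
              x$name, x$hematocrit, x$density))
  print(x$carreau)
  invisible(x)
}

#' Load a registered blood case
#'
#' Returns one of the four hematocrit-matched blood cases: `"anemic"`,
#' `"diabetic"`, `"healthy_case1"`, `"healthy_case2"`.
#'
#' @param name registered case name.
#' @param density mass density (kg/m^3); default 1060 for all cases.
#' @return A [blood_case()] object.
#' @examples
#' load_blood_case("diabetic")
#' @export
load_blood_case <- function(name, density = 1060) {
  reg <- .blood_registry()
  if (!is.character(name) || length(name) != 1L || !(name %in% names(reg)))
    stop("unknown blood case '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(reg), collapse = ", "))
  p <- reg[[name]]
  blood_case(name,
             carreau_parameters(p$n, p$lambda_time, p$mu_inf, p$mu_0),
             hematocrit = p$hematocrit, density = density)
}

#' Strain-rate magnitude from a velocity-gradient tensor
#'
#' Computes the generalized shear rate \eqn{\gamma = \sqrt{2\,D\!:\!D}}
#' where \eqn{D = (\nabla v + \nabla v^T)/2} is the rate-of-deformation
#' tensor. In simple shear `du/dy = g` this recovers `g`; for rigid-body
#' rotation it is zero; it is invariant under rotation of coordinates.
#'
#' @param grad_v square numeric matrix (2x2 or 3x3), entry `[i, j]` holding
#'   \eqn{\partial v_i / \partial x_j} (1/s).
#' @return Non-negative scalar shear-rate magnitude (1/s).
#' @examples
#' g <- matrix(0, 2, 2); g[1, 2] <- 10
#' strain_rate_magnitude(g)  # 10
#' @export
strain_rate_magnitude <- function(grad_v) {
  if (!is.matrix(grad_v) || nrow(grad_v) != ncol(grad_v))
    stop("grad_v must be a square matrix")
  if (!all(is.finite(grad_v)))
    stop("grad_v entries must be finite")
  d <- (grad_v + t(grad_v)) / 2
  sqrt(2 * sum(d * d))
}

#' Rank blood cases by effective viscosity
#'
#' Stable descending sort of blood cases by Carreau effective viscosity
#' evaluated at a common shear rate. At physiological shear
#' (`gamma = 100` 1/s) the ordering follows the hematocrit ordering:
#' diabetic (65%) above both healthy cases (45%) above anemic (25%).
#'
#' @param cases list of [blood_case()] objects (at least 2).
#' @param gamma shear rate (1/s), >= 0.
#' @return Character vector of case names, descending viscosity.
#' @export
viscosity_ordering <- function(cases, gamma) {
  if (!is.list(cases) || length(cases) < 2L)
    stop("need at least two blood cases to rank")
  stopifnot(all(vapply(cases, inherits, logical(1), "blood_case")))
  mu <- vapply(cases, function(b) effective_viscosity(b$carreau, gamma),
               numeric(1))
  nm <- vapply(cases, `[[`, character(1), "name")
  nm[order(-mu)]  # order() is a stable sort
}
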