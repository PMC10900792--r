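#' Womersley velocity profile for pulsatile Newtonian pipe flow
#'
#' Analytic solution of the axial momentum equation in a rigid circular
#' tube driven by an oscillatory axial pressure gradient
#' \eqn{-\partial p/\partial z = K\cos(\omega t)}:
#' \deqn{u(r,t) = \Re\left\{\frac{K}{i\rho\omega}\left[1 -
#'   \frac{J_0(\zeta r/R)}{J_0(\zeta)}\right] e^{i\omega t}\right\},
#'   \qquad \zeta = i^{3/2}\alpha,\ \alpha = R\sqrt{\omega\rho/\mu}.}
#' As \eqn{\omega \to 0} the profile reduces to the quasi-steady
#' Poiseuille parabola \eqn{K(R^2-r^2)\cos(\omega t)/(4\mu)}; that branch
#' is used in closed form for very small Womersley numbers. The complex
#' Bessel function \eqn{J_0} is evaluated by its power series, accurate
#' for the moderate Womersley numbers of arterial flow
#' (\eqn{\alpha \lesssim 15}).
#'
#' @param radius tube radius R (m).
#' @param omega angular frequency (rad/s), >= 0.
#' @param pressure_gradient_amplitude K (Pa/m), amplitude of -dp/dz.
#' @param mu dynamic viscosity (Pa s).
#' @param rho density (kg/m^3).
#' @param r radial position(s) (m), in [0, R]. Vectorized.
#' @param t time (s), scalar.
#' @return Axial velocity (m/s) at (r, t).
#' @export
womersley_solution <- function(radius, omega, pressure_gradient_amplitude,
                               mu, rho, r, t) {
  stopifnot(radius > 0, omega >= 0, mu > 0, rho > 0, length(t) == 1L)
  if (any(r < 0 | r > radius + 1e-12))
    stop("radial position r must lie within the tube [0, radius]")
  r <- pmin(r, radius)
  K <- pressure_gradient_amplitude
  alpha <- radius * sqrt(omega * rho / mu)
  if (alpha < 1e-3) {
    # quasi-steady limit: Poiseuille parabola modulated by cos(omega t)
    return(K * (radius^2 - r^2) / (4 * mu) * cos(omega * t))
  }
  zeta <- complex(modulus = alpha, argument = 3 * pi / 4)  # i^{3/2} alpha
  prof <- 1 - .besselJ0_complex(zeta * r / radius) / .besselJ0_complex(zeta)
  Re(K / (1i * rho * omega) * prof * exp(1i * omega * t))
}

# power-series J0 for complex argument; converges rapidly for |z| <~ 25
.besselJ0_complex <- function(z) {
  s <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  q <- -(z / 2)^2
  for (k in 1:120) {
    term <- term * q / k^2
    s <- s + term
    if (all(Mod(term) < 1e-17 * pmax(Mod(s), 1))) break
  }
  s
}

#' Womersley number
#'
#' \eqn{\alpha = R\sqrt{\omega\rho/\mu}}, the ratio of pulsatile inertial
#' to viscous effects.
#'
#' @inheritParams womersley_solution
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(radius, omega, mu, rho) {
  stopifnot(radius > 0, omega >= 0, mu > 0, rho > 0)
  radius * sqrt(omega * rho / mu)
}

#' Steady power-law velocity profile in a circular tube
#'
#' Fully developed velocity profile of an Ostwald-de Waele (power-law)
#' fluid with consistency K and index n driven by a constant axial
#' pressure gradient \eqn{G = -dp/dz}:
#' \deqn{u(r) = \frac{n}{n+1}\left(\frac{G R}{2K}\right)^{1/n} R
#'       \left[1 - (r/R)^{(n+1)/n}\right].}
#' For `n = 1` (K the Newtonian viscosity) this is the Poiseuille
#' parabola; the profile satisfies no-slip at the wall.
#'
#' @param radius tube radius R (m).
#' @param pressure_gradient G = -dp/dz (Pa/m), > 0.
#' @param consistency_K consistency coefficient (Pa s^n), > 0.
#' @param n power-law index, > 0.
#' @param r radial position(s) (m), in [0, R]. Vectorized.
#' @return Axial velocity (m/s).
#' @export
power_law_pipe_profile <- function(radius, pressure_gradient, consistency_K,
                                   n, r) {
  if (!(is.numeric(n) && n > 0)) stop("power-law index n must be positive")
  stopifnot(radius > 0, pressure_gradient > 0, consistency_K > 0)
  if (any(r < 0 | r > radius + 1e-12))
    stop("radial position r must lie within the tube [0, radius]")
  r <- pmin(r, radius)
  n / (n + 1) * (pressure_gradient * radius / (2 * consistency_K))^(1 / n) *
    radius * (1 - (r / radius)^((n + 1) / n))
}
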