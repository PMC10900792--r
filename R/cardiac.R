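#' Pulsatile cardiac inlet waveform
#'
#' The inlet velocity over one cardiac cycle is piecewise: a sinusoidal
#' systolic phase followed by a constant diastolic plateau,
#' \deqn{v(t') = A \sin[4\pi (t' + t_0)] \quad 0 < t' \le T_s, \qquad
#'       v(t') = b \quad T_s < t' \le T,}
#' with `t' = t mod T`. The defaults are the 120 bpm carotid waveform:
#' peak `A = 0.5` m/s, diastolic baseline `b = 0.1` m/s, phase offset
#' `t_0 = 0.0160236` s (chosen so the sine equals the baseline at the
#' phase joints), systole `T_s = 0.218` s, period `T = 0.5` s.
#'
#' @param amplitude peak systolic velocity (m/s).
#' @param baseline diastolic velocity (m/s); `0 < baseline < amplitude`.
#' @param phase_offset time shift inside the sine argument (s).
#' @param systole_duration length of the sinusoidal phase (s), in (0, period).
#' @param period cardiac cycle length (s).
#' @param check_continuity verify the sine meets the baseline at both
#'   phase joints to within `joint_tol`.
#' @param joint_tol phase-joint continuity tolerance (m/s). The default
#'   1e-3 accommodates the published phase offset, which makes the
#'   systole onset continuous to 1e-4 m/s but leaves a ~3e-4 m/s jump
#'   at the systole-to-diastole joint.
#' @return An object of class `cardiac_waveform`.
#' @examples
#' wf <- cardiac_waveform()
#' inlet_velocity(wf, 0.3)  # diastolic plateau: 0.1 m/s
#' @export
cardiac_waveform <- function(amplitude = 0.5, baseline = 0.1,
                             phase_offset = 0.0160236,
                             systole_duration = 0.218, period = 0.5,
                             check_continuity = TRUE, joint_tol = 1e-3) {
  stopifnot(is.numeric(amplitude), is.numeric(baseline),
            is.numeric(phase_offset), is.numeric(systole_duration),
            is.numeric(period))
  if (!(systole_duration > 0 && systole_duration < period))
    stop("systole_duration must lie in (0, period)")
  if (!(amplitude > baseline && baseline > 0))
    stop("require amplitude > baseline > 0; got amplitude = ", amplitude,
         ", baseline = ", baseline)
  wf <- structure(list(amplitude = amplitude, baseline = baseline,
                       phase_offset = phase_offset,
                       systole_duration = systole_duration, period = period),
                  class = "cardiac_waveform")
  if (isTRUE(check_continuity)) {
    # the sine's angular frequency is 4*pi rad/s at the default 0.5 s
    # period; scale with the period so a general waveform stays self-similar
    omega <- 4 * pi * 0.5 / period
    v_start <- amplitude * sin(omega * phase_offset)
    v_end <- amplitude * sin(omega * (systole_duration + phase_offset))
    if (abs(v_start - baseline) > joint_tol ||
        abs(v_end - baseline) > joint_tol)
      stop(sprintf(paste0(
        "waveform discontinuous at phase joints: v(start+) = %.6f, ",
        "v(end) = %.6f, baseline = %.6f (tolerance %g m/s)"),
        v_start, v_end, baseline, joint_tol))
  }
  wf
}

#' @export
print.cardiac_waveform <- function(x, ...) {
  cat(sprintf(paste0("Cardiac waveform: peak %g m/s, baseline %g m/s, ",
                     "systole %g s of a %g s cycle\n"),
              x$amplitude, x$baseline, x$systole_duration, x$period))
  invisible(x)
}

#' Inlet velocity at time t
#'
#' Evaluates the piecewise pulsatile waveform, periodically extended.
#' At exactly `t' = 0` (the left-open boundary of systole) the diastolic
#' value is returned, matching the half-open phase intervals.
#'
#' @param waveform a [cardiac_waveform()].
#' @param t time(s) (s), >= 0. Vectorized.
#' @return Inlet velocity (m/s), in `[baseline, amplitude]` for the
#'   default waveform.
#' @export
inlet_velocity <- function(waveform, t) {
  stopifnot(inherits(waveform, "cardiac_waveform"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("time t must be finite and non-negative")
  tp <- t %% waveform$period
  omega <- 4 * pi * 0.5 / waveform$period
  v <- ifelse(tp > 0 & tp <= waveform$systole_duration,
              waveform$amplitude * sin(omega * (tp + waveform$phase_offset)),
              waveform$baseline)
  v
}

#' Waveform extrema over one cycle
#'
#' Global minimum and maximum of the inlet waveform over one period,
#' found on a dense grid and refined by golden-section search on the
#' sinusoidal branch (the plateau branch is constant).
#'
#' @param waveform a [cardiac_waveform()].
#' @param samples grid points over one period, >= 1000.
#' @return Named numeric vector `c(min = , max = )` (m/s).
#' @examples
#' waveform_extrema(cardiac_waveform())  # c(min = 0.1, max = 0.5)
#' @export
waveform_extrema <- function(waveform, samples = 4096L) {
  stopifnot(inherits(waveform, "cardiac_waveform"))
  if (samples < 1000) stop("samples must be >= 1000 over one period")
  # left-open grid (0, T]
  tg <- seq(0, waveform$period, length.out = samples + 1L)[-1L]
  vg <- inlet_velocity(waveform, tg)
  # refine the systolic branch extrema with optimize() on the smooth sine
  f <- function(t) inlet_velocity(waveform, t)
  eps <- waveform$period / samples
  lo <- eps / 2
  hi <- waveform$systole_duration
  vmax <- max(vg)
  vmin <- min(vg)
  if (hi > lo) {
    opt_max <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)
    opt_min <- stats::optimize(f, c(lo, hi), maximum = FALSE, tol = 1e-12)
    vmax <- max(vmax, opt_max$objective)
    vmin <- min(vmin, opt_min$objective)
  }
  c(min = vmin, max = vmax)
}

#' Cardiac period from heart rate
#'
#' @param heart_rate beats per minute, > 0.
#' @return Cycle length (s): `60 / heart_rate` (0.5 s at 120 bpm).
#' @export
cycle_period <- function(heart_rate) {
  stopifnot(is.numeric(heart_rate))
  if (any(heart_rate <= 0)) stop("heart_rate must be positive")
  60 / heart_rate
}

#' Convert mmHg to Pa
#'
#' @param p pressure (mmHg). Vectorized.
#' @return Pressure (Pa): `p * 133.322` (100 mmHg is about 13332 Pa).
#' @export
mmhg_to_pa <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)))
  p * 133.322
}

#' Outlet pressure condition
#'
#' Fixed static gauge pressure applied at the outlet face(s); the default
#' 13332 Pa is 100 mmHg, the mean of typical systolic/diastolic arterial
#' pressures (120/80 mmHg).
#'
#' @param gauge_pressure static outlet gauge pressure (Pa), > 0.
#' @return An object of class `outlet_condition`.
#' @export
outlet_condition <- function(gauge_pressure = 13332) {
  stopifnot(is.numeric(gauge_pressure), length(gauge_pressure) == 1L)
  if (!(gauge_pressure > 0))
    stop("gauge_pressure must be positive; got ", gauge_pressure)
  structure(list(gauge_pressure = gauge_pressure), class = "outlet_condition")
}

#' Export waveform samples
#'
#' Writes `(t, v)` samples of one or more cycles to CSV for plotting.
#'
#' @param waveform a [cardiac_waveform()].
#' @param path output CSV path.
#' @param n_cycles number of cycles to sample.
#' @param samples_per_cycle grid density.
#' @return The sampled data frame, invisibly.
#' @export
export_waveform_csv <- function(waveform, path, n_cycles = 1,
                                samples_per_cycle = 500L) {
  tg <- seq(0, n_cycles * waveform$period,
            length.out = n_cycles * samples_per_cycle + 1L)[-1L]
  df <- data.frame(t_s = tg, v_m_per_s = inlet_velocity(waveform, tg))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
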