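#' Cardiac-cycle boundary waveforms
#'
#' One beat of boundary data sampled on the simulation grid: a pulmonary-vein
#' pressure profile (mmHg) and a transmitral velocity profile (m/s) with
#' early-filling (E) and atrial-contraction (A) peaks. The default beat is
#' 0.88 s long sampled at 88 steps (dt = 0.01 s), with systole spanning
#' t = 0-0.3 s and diastole t = 0.31-0.88 s; two beats are simulated and the
#' second is analysed. The default profile shapes are a documented
#' configuration (clinical waveforms are not tabulated), not a claim of
#' patient fidelity: the E peak (0.45 m/s at t = 0.50 s) dominates a reduced
#' A peak (0.18 m/s at t = 0.80 s), as expected in atrial fibrillation.
#'
#' @param beat_period beat length (s).
#' @param steps_per_beat samples per beat; `steps_per_beat * dt` must equal
#'   `beat_period`.
#' @param dt time step (s).
#' @param mv_velocity optional numeric vector (m/s) of length
#'   `steps_per_beat`; replaces the default E/A-wave profile. Must give a
#'   positive net outflow.
#' @param pv_pressure optional numeric vector (mmHg) of length
#'   `steps_per_beat`.
#' @param n_beats number of beats to simulate (default 2).
#' @param e_peak,a_peak,base E/A-wave peak speeds and systolic baseline (m/s)
#'   for the default profile.
#' @return an object of class `waveform_set`.
#' @export
waveform_set <- function(beat_period = 0.88, steps_per_beat = 88L,
                         dt = 0.01, mv_velocity = NULL, pv_pressure = NULL,
                         n_beats = 2L, e_peak = 0.45, a_peak = 0.18,
                         base = 0.05) {
  if (abs(steps_per_beat * dt - beat_period) > 1e-9) {
    stop("steps_per_beat * dt must equal beat_period")
  }
  t <- (seq_len(steps_per_beat) - 1L) * dt
  if (is.null(mv_velocity)) {
    mv_velocity <- base +
      e_peak * exp(-((t - 0.50) / 0.07)^2) +
      a_peak * exp(-((t - 0.80) / 0.05)^2)
    mv_velocity <- mv_velocity * (beat_period / 0.88)^0  # shape is unitless in t
  }
  if (length(mv_velocity) != steps_per_beat) {
    stop("mv_velocity must have steps_per_beat samples")
  }
  if (mean(mv_velocity) < 0) {
    stop("mv_velocity must not integrate to a net inflow")
  }
  if (is.null(pv_pressure)) {
    pv_pressure <- 10 +
      2.5 * exp(-((t - 0.35) / 0.10)^2) +   # v wave
      3.5 * exp(-((t - 0.82) / 0.06)^2)     # a wave
  }
  if (length(pv_pressure) != steps_per_beat) {
    stop("pv_pressure must have steps_per_beat samples")
  }
  structure(list(beat_period = beat_period,
                 steps_per_beat = as.integer(steps_per_beat), dt = dt,
                 t = t, mv_velocity = mv_velocity,
                 pv_pressure = pv_pressure, n_beats = as.integer(n_beats)),
            class = "waveform_set")
}

# mv velocity at arbitrary absolute times (s), periodic over the beat,
# linear interpolation on the sample grid.
waveform_mv_at <- function(wf, t) {
  tb <- t %% wf$beat_period
  stats::approx(c(wf$t, wf$beat_period), c(wf$mv_velocity, wf$mv_velocity[1]),
                xout = tb, rule = 2)$y
}
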