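#' Differential pulse voltammetry excitation program
#'
#' Parameters of the DPV measurement protocol: a staircase of base
#' potentials from `start_potential` to `end_potential` in `step_size`
#' increments, each step holding for `step_size / scan_rate` seconds with
#' a superimposed rectangular pulse of height `pulse_amplitude` lasting
#' `pulse_width` seconds at the end of the step. The current is sampled
#' twice per step — immediately before pulse onset and at pulse end — and
#' the difference isolates the Faradaic component. An equilibrium hold at
#' the start potential precedes the scan.
#'
#' Defaults reproduce the acquisition protocol used for the proteinoid
#' recordings: 100 s equilibrium, scan from -8 V to 8 V in 1 mV steps,
#' 0.2 V pulses of 0.08 s, at 1 mV/s.
#'
#' @param equilibrium_time Seconds held at `start_potential` before the scan.
#' @param start_potential,end_potential Scan limits, volts.
#' @param step_size Base-potential increment, volts (> 0).
#' @param pulse_amplitude Pulse height, volts.
#' @param pulse_width Pulse duration, seconds.
#' @param scan_rate Scan rate, volts per second.
#' @return An object of class `dpv_program`.
#' @examples
#' prog <- dpv_program()
#' prog
#' @export
dpv_program <- function(equilibrium_time = 100,
                        start_potential = -8,
                        end_potential = 8,
                        step_size = 0.001,
                        pulse_amplitude = 0.2,
                        pulse_width = 0.08,
                        scan_rate = 0.001) {
  check_scalar(equilibrium_time, "equilibrium_time", nonnegative = TRUE)
  check_scalar(start_potential, "start_potential")
  check_scalar(end_potential, "end_potential")
  check_scalar(step_size, "step_size", positive = TRUE)
  check_scalar(pulse_amplitude, "pulse_amplitude")
  check_scalar(pulse_width, "pulse_width", positive = TRUE)
  check_scalar(scan_rate, "scan_rate", positive = TRUE)
  structure(
    list(equilibrium_time = equilibrium_time,
         start_potential = start_potential, end_potential = end_potential,
         step_size = step_size, pulse_amplitude = pulse_amplitude,
         pulse_width = pulse_width, scan_rate = scan_rate),
    class = "dpv_program"
  )
}

#' @export
print.dpv_program <- function(x, ...) {
  cat(sprintf(
    "<dpv_program> %g V to %g V, step %g V @ %g V/s; pulse %g V x %g s; equilibrium %g s\n",
    x$start_potential, x$end_potential, x$step_size, x$scan_rate,
    x$pulse_amplitude, x$pulse_width, x$equilibrium_time))
  invisible(x)
}

#' Build the DPV applied-potential waveform and sampling schedule
#'
#' Expands a [dpv_program()] into the applied-potential staircase and the
#' two per-step current-sampling instants. The waveform is represented
#' exactly (as piecewise-constant segments), not as a dense sampled
#' vector: the reference program has 16,001 base levels and a dense
#' rendering would be needlessly large. Use [dpv_potential_at()] to
#' evaluate the applied potential at arbitrary times.
#'
#' No electrochemical current response is modelled here — the generator
#' produces the excitation program and its sampling schedule only.
#'
#' @param program A [dpv_program()].
#' @return An object of class `dpv_waveform`: a list with
#'   \describe{
#'     \item{program}{the input program}
#'     \item{base_potentials}{vector of base staircase levels, volts}
#'     \item{step_duration}{seconds each level is held}
#'     \item{step_start}{start time of each step (after equilibrium), s}
#'     \item{pulse_onset, pulse_end}{per-step pulse window, s}
#'     \item{sample_pre, sample_post}{per-step current-sampling instants:
#'       immediately before pulse onset and at pulse end, s}
#'     \item{total_duration}{equilibrium + scan time, s}
#'   }
#' @examples
#' wf <- dpv_waveform(dpv_program(start_potential = 0, end_potential = 0.01,
#'                                step_size = 0.001, scan_rate = 0.001,
#'                                pulse_width = 0.08, equilibrium_time = 1))
#' length(wf$base_potentials)
#' @export
dpv_waveform <- function(program) {
  stopifnot(inherits(program, "dpv_program"))
  step_duration <- program$step_size / program$scan_rate
  if (program$pulse_width >= step_duration) {
    stopf("pulse_width (%g s) must be shorter than the step duration (%g s)",
          program$pulse_width, step_duration)
  }
  span <- program$end_potential - program$start_potential
  if (span < 0) stopf("end_potential must be >= start_potential")
  n_levels <- round(span / program$step_size) + 1L
  direction <- 1
  base <- program$start_potential + (seq_len(n_levels) - 1L) *
    direction * program$step_size
  # snap the last level onto end_potential to kill accumulated FP error
  if (n_levels > 1L) base[n_levels] <- program$end_potential
  step_start <- program$equilibrium_time + (seq_len(n_levels) - 1L) * step_duration
  pulse_onset <- step_start + (step_duration - program$pulse_width)
  pulse_end <- step_start + step_duration
  structure(
    list(program = program,
         base_potentials = base,
         step_duration = step_duration,
         step_start = step_start,
         pulse_onset = pulse_onset,
         pulse_end = pulse_end,
         sample_pre = pulse_onset,   # immediately before pulse onset
         sample_post = pulse_end,    # at pulse end
         total_duration = program$equilibrium_time + n_levels * step_duration),
    class = "dpv_waveform"
  )
}

#' @export
print.dpv_waveform <- function(x, ...) {
  cat(sprintf("<dpv_waveform> %d base levels, %g s/step, total %g s\n",
              length(x$base_potentials), x$step_duration, x$total_duration))
  invisible(x)
}

#' Evaluate the applied DPV potential at given times
#'
#' Piecewise-constant evaluation of the staircase-plus-pulse waveform:
#' during the equilibrium hold the start potential is applied; within a
#' step the base level applies, raised by `pulse_amplitude` inside the
#' pulse window `[pulse_onset, pulse_end)`.
#'
#' @param waveform A [dpv_waveform()].
#' @param t Numeric vector of times in seconds within
#'   `[0, total_duration]`.
#' @return Numeric vector of applied potentials, volts.
#' @export
dpv_potential_at <- function(waveform, t) {
  stopifnot(inherits(waveform, "dpv_waveform"))
  t <- as.numeric(t)
  if (any(t < 0 | t > waveform$total_duration)) {
    stopf("times outside [0, %g] s", waveform$total_duration)
  }
  prog <- waveform$program
  out <- rep(prog$start_potential, length(t))
  in_scan <- t >= prog$equilibrium_time
  if (any(in_scan)) {
    ts <- t[in_scan]
    idx <- pmin(floor((ts - prog$equilibrium_time) / waveform$step_duration) + 1,
                length(waveform$base_potentials))
    v <- waveform$base_potentials[idx]
    pulsed <- ts >= waveform$pulse_onset[idx] & ts < waveform$pulse_end[idx]
    v[pulsed] <- v[pulsed] + prog$pulse_amplitude
    out[in_scan] <- v
  }
  out
}
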