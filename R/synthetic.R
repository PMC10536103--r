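#' Specification for one synthetic spiking trace
#'
#' Describes a single sample's recording to be generated: duration and
#' sampling rate of the grid, the target spike structure (either an exact
#' spike count or a target mean interspike interval — exactly one of the
#' two), the rendered spike shape, baseline and additive noise, the signal
#' unit, and the seed making the trace reproducible.
#'
#' Generated spike trains respect an absolute refractory gap (default 5 s),
#' chosen to equal the detector's minimum peak distance so that a
#' noise-free generated train is exactly recoverable by detection.
#'
#' @param sample_id Text label.
#' @param duration Recording duration in seconds.
#' @param sampling_rate Samples per second (the recordings emulated here
#'   were logged at 1 Hz).
#' @param n_spikes Exact number of spikes to place, or `NULL`.
#' @param mean_isi Target mean interspike interval in seconds, or `NULL`.
#'   Exactly one of `n_spikes`/`mean_isi` must be given.
#' @param spike_amplitude Pulse height above baseline, in signal units.
#' @param spike_width Pulse width in seconds (Gaussian bumps use
#'   `sd = spike_width/4`).
#' @param baseline Constant baseline level in signal units.
#' @param noise_sd Standard deviation of additive Gaussian noise (0 for a
#'   noise-free trace).
#' @param unit `"volt"` or `"microampere"`.
#' @param seed Integer seed; mandatory so cohorts are reproducible.
#' @param refractory Minimum gap between spike times, seconds.
#'
#' @return An object of class `trace_spec`.
#' @examples
#' spec <- trace_spec("demo", duration = 100, n_spikes = 5, seed = 1)
#' generate_spike_times(spec)
#' @export
trace_spec <- function(sample_id = "sample",
                       duration,
                       sampling_rate = 1,
                       n_spikes = NULL,
                       mean_isi = NULL,
                       spike_amplitude = 0.001,
                       spike_width = 2,
                       baseline = 0,
                       noise_sd = 0,
                       unit = "microampere",
                       seed = 1L,
                       refractory = 5) {
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar(spike_amplitude, "spike_amplitude")
  check_scalar(spike_width, "spike_width", positive = TRUE)
  check_scalar(baseline, "baseline")
  check_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  check_scalar(refractory, "refractory", nonnegative = TRUE)
  check_unit(unit)
  if (is.null(n_spikes) == is.null(mean_isi)) {
    stopf("exactly one of `n_spikes` or `mean_isi` must be given")
  }
  if (!is.null(n_spikes)) {
    check_scalar(n_spikes, "n_spikes", nonnegative = TRUE)
    if (n_spikes != round(n_spikes)) stopf("`n_spikes` must be an integer")
    n_spikes <- as.integer(n_spikes)
  }
  if (!is.null(mean_isi)) {
    check_scalar(mean_isi, "mean_isi", positive = TRUE)
    if (mean_isi <= refractory) {
      stopf("`mean_isi` (%g s) must exceed the refractory gap (%g s)",
            mean_isi, refractory)
    }
  }
  structure(
    list(sample_id = as.character(sample_id)[1L], duration = duration,
         sampling_rate = sampling_rate, n_spikes = n_spikes,
         mean_isi = mean_isi, spike_amplitude = spike_amplitude,
         spike_width = spike_width, baseline = baseline,
         noise_sd = noise_sd, unit = unit, seed = as.integer(seed),
         refractory = refractory),
    class = "trace_spec"
  )
}

#' @export
print.trace_spec <- function(x, ...) {
  law <- if (!is.null(x$n_spikes)) sprintf("n_spikes = %d", x$n_spikes)
         else sprintf("mean_isi = %g s", x$mean_isi)
  cat(sprintf("<trace_spec> %s: %g s @ %g Hz, %s, refractory %g s, unit %s\n",
              x$sample_id, x$duration, x$sampling_rate, law, x$refractory,
              x$unit))
  invisible(x)
}

#' Generate spike times for a trace specification
#'
#' Two point-process laws are used, matching the two ways a trace can be
#' specified. With an exact `n_spikes`, spikes are placed uniformly at
#' random subject to the refractory gap (sorted uniform draws in the slack
#' interval, shifted apart by the refractory period), which guarantees the
#' exact count and minimum spacing. With a target `mean_isi`, intervals
#' are drawn from a Poisson process with dead time: each interspike
#' interval is `refractory + Exponential(mean_isi - refractory)`, so the
#' expected interval equals `mean_isi` while no two spikes fall closer
#' than the refractory gap.
#'
#' Spikes are kept at least half a refractory gap away from the recording
#' edges so that every rendered pulse has two neighbours on the sampling
#' grid and remains detectable as a local maximum.
#'
#' @param spec A [trace_spec()].
#' @return Sorted numeric vector of spike times in seconds (possibly
#'   empty), all gaps `>= spec$refractory`.
#' @examples
#' generate_spike_times(trace_spec(duration = 1000, n_spikes = 10, seed = 2))
#' @export
generate_spike_times <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  margin <- spec$refractory / 2
  if (!is.null(spec$n_spikes)) {
    n <- spec$n_spikes
    if (n == 0L) return(numeric(0))
    if (n * spec$refractory > spec$duration) {
      stopf("infeasible: %d spikes with a %g s refractory gap cannot fit in %g s",
            n, spec$refractory, spec$duration)
    }
    lo <- margin
    hi <- spec$duration - margin
    slack <- (hi - lo) - (n - 1L) * spec$refractory
    if (slack < 0) {
      stopf("infeasible: %d spikes with a %g s refractory gap cannot fit in [%g, %g] s",
            n, spec$refractory, lo, hi)
    }
    with_seed(spec$seed, {
      u <- sort(stats::runif(n, 0, slack))
      lo + u + (seq_len(n) - 1L) * spec$refractory
    })
  } else {
    exp_mean <- spec$mean_isi - spec$refractory
    with_seed(spec$seed, {
      # draw in blocks until past the end of the recording
      t_max <- spec$duration - margin
      expected <- ceiling(spec$duration / spec$mean_isi) + 10L
      times <- numeric(0)
      last <- margin
      repeat {
        isis <- spec$refractory + stats::rexp(expected, rate = 1 / exp_mean)
        cand <- last + cumsum(isis)
        times <- c(times, cand[cand <= t_max])
        if (cand[length(cand)] > t_max) break
        last <- cand[length(cand)]
      }
      times
    })
  }
}

#' Render spike times into a sampled trace
#'
#' Each spike is rendered as a Gaussian bump of height `spike_amplitude`
#' above `baseline`, with standard deviation `spike_width/4` (so the bump
#' has effectively compact support of about one `spike_width`), centred at
#' the spike time, plus additive Gaussian noise of standard deviation
#' `noise_sd`. A smooth unimodal pulse — rather than a rectangle — makes
#' the detected peak time well defined on the sampling grid.
#'
#' @param spike_times Sorted spike times within `[0, duration]`.
#' @param spec A [trace_spec()].
#' @return A [potential_trace()] on the grid
#'   `seq(0, duration, by = 1/sampling_rate)`.
#' @examples
#' spec <- trace_spec(duration = 40, n_spikes = 3, noise_sd = 0, seed = 1)
#' tr <- render_trace(c(10, 20, 30), spec)
#' max(tr$values)
#' @export
render_trace <- function(spike_times, spec) {
  stopifnot(inherits(spec, "trace_spec"))
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 0) {
    if (is.unsorted(spike_times, strictly = TRUE)) {
      stopf("`spike_times` must be strictly increasing")
    }
    if (any(spike_times < 0 | spike_times > spec$duration)) {
      stopf("spike times outside [0, %g] s", spec$duration)
    }
    gaps <- diff(spike_times)
    if (length(gaps) > 0 && any(gaps < spec$spike_width)) {
      stopf("rendered pulses would overlap: gap %g s < spike_width %g s",
            min(gaps), spec$spike_width)
    }
  }
  n_pts <- round(spec$duration * spec$sampling_rate) + 1L
  times <- (seq_len(n_pts) - 1L) / spec$sampling_rate
  values <- rep(spec$baseline, n_pts)
  sd_pulse <- spec$spike_width / 4
  for (ts in spike_times) {
    # only touch the grid within +-4 sd of the bump centre
    i0 <- max(1L, ceiling((ts - 4 * sd_pulse) * spec$sampling_rate) + 1L)
    i1 <- min(n_pts, floor((ts + 4 * sd_pulse) * spec$sampling_rate) + 1L)
    idx <- i0:i1
    values[idx] <- values[idx] +
      spec$spike_amplitude * exp(-((times[idx] - ts)^2) / (2 * sd_pulse^2))
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed + 1L, stats::rnorm(n_pts, 0, spec$noise_sd))
    values <- values + noise
  }
  potential_trace(times, values, unit = spec$unit,
                  sampling_rate = spec$sampling_rate,
                  sample_id = spec$sample_id)
}

#' Generate a complete synthetic trace in one call
#'
#' Convenience wrapper: [generate_spike_times()] followed by
#' [render_trace()].
#'
#' @inheritParams generate_spike_times
#' @return A [potential_trace()] with the generated spike times attached
#'   as attribute `"spike_times"`.
#' @export
synth_trace <- function(spec) {
  st <- generate_spike_times(spec)
  tr <- render_trace(st, spec)
  attr(tr, "spike_times") <- st
  tr
}

#' Trace specifications emulating the reference 12-sample cohort
#'
#' Builds one [trace_spec()] per row of the embedded spike-characteristics
#' table, with the row's exact spike count. No recording durations were
#' reported for the cohort, so each duration is taken as
#' `n_spikes * mean_isi` (the total spiking span implied by the printed
#' count and mean interval), rounded up to a whole second.
#'
#' @param noise_sd Additive noise level passed to every spec.
#' @param spike_amplitude Pulse height; the default 0.001 microamperes is
#'   twice the detection threshold of 0.0005.
#' @param seed Base seed; sample `k` uses `seed + k`.
#' @return A named list of [trace_spec()] objects, one per proteinoid.
#' @examples
#' specs <- cohort_specs(seed = 1)
#' names(specs)[1:3]
#' @export
cohort_specs <- function(noise_sd = 0, spike_amplitude = 0.001, seed = 1L) {
  tab <- load_spike_characteristics()
  specs <- lapply(seq_len(nrow(tab)), function(k) {
    trace_spec(
      sample_id = tab$proteinoid[k],
      duration = ceiling(tab$n_spikes[k] * tab$mean_isi_s[k]),
      sampling_rate = 1,
      n_spikes = tab$n_spikes[k],
      spike_amplitude = spike_amplitude,
      noise_sd = noise_sd,
      unit = "microampere",
      seed = as.integer(seed) + k
    )
  })
  names(specs) <- tab$proteinoid
  specs
}
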