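#' Detect spikes by threshold crossing with a minimum peak distance
#'
#' Finds every strict local maximum of the trace whose value is strictly
#' greater than `threshold`, then greedily prunes peaks closer than
#' `min_peak_distance` seconds, keeping the taller of two conflicting
#' peaks (ties broken in favour of the earlier one). The defaults — a
#' threshold of 0.0005 microamperes and a 5 s minimum peak distance —
#' match the parameters used for the reference spike characterisation.
#'
#' The first sample of a flat (plateau) maximum is taken as the spike
#' time, and the first and last samples of the trace can never be peaks
#' because a local maximum needs two neighbours.
#'
#' @param trace A [potential_trace()].
#' @param threshold Spike threshold in the trace's signal units; a peak
#'   must exceed it strictly.
#' @param min_peak_distance Minimum separation between surviving peaks,
#'   seconds.
#' @param threshold_unit Optional unit the threshold is expressed in; if
#'   given it must equal `trace$unit`, otherwise the call errors rather
#'   than comparing microamperes against volts.
#' @return An object of class `spike_train`: list with `sample_id`,
#'   `spike_times` (s), `spike_values`, `threshold_used`,
#'   `min_peak_distance_used`, `unit`.
#' @examples
#' spec <- trace_spec(duration = 40, n_spikes = 3, seed = 1)
#' tr <- synth_trace(spec)
#' detect_spikes(tr)
#' @export
detect_spikes <- function(trace, threshold = 0.0005, min_peak_distance = 5,
                          threshold_unit = NULL) {
  stopifnot(inherits(trace, "potential_trace"))
  check_scalar(threshold, "threshold")
  check_scalar(min_peak_distance, "min_peak_distance", nonnegative = TRUE)
  if (!is.null(threshold_unit)) {
    check_unit(threshold_unit)
    if (threshold_unit != trace$unit) {
      stopf("threshold unit '%s' does not match trace unit '%s'",
            threshold_unit, trace$unit)
    }
  }
  if (length(trace$times) < 3L) {
    stopf("trace too short for peak detection (need >= 3 samples, got %d)",
          length(trace$times))
  }
  v <- trace$values
  # collapse plateaus: runs of equal consecutive values
  r <- rle(v)
  n_runs <- length(r$values)
  run_start <- cumsum(c(1L, r$lengths[-n_runs]))
  is_peak_run <- rep(FALSE, n_runs)
  if (n_runs >= 3L) {
    interior <- 2:(n_runs - 1L)
    is_peak_run[interior] <- r$values[interior] > r$values[interior - 1L] &
      r$values[interior] > r$values[interior + 1L]
  }
  cand_idx <- run_start[is_peak_run & r$values > threshold]
  # greedy pruning: tallest first, earlier time wins ties
  if (length(cand_idx) > 1L && min_peak_distance > 0) {
    ord <- order(-v[cand_idx], trace$times[cand_idx])
    cand_idx <- cand_idx[ord]
    kept_times <- numeric(0)
    kept_idx <- integer(0)
    for (i in cand_idx) {
      ti <- trace$times[i]
      pos <- findInterval(ti, kept_times)
      ok <- (pos == 0L || ti - kept_times[pos] >= min_peak_distance) &&
        (pos == length(kept_times) ||
           kept_times[pos + 1L] - ti >= min_peak_distance)
      if (ok) {
        kept_idx <- c(kept_idx, i)
        kept_times <- sort(c(kept_times, ti))
      }
    }
    cand_idx <- sort(kept_idx)
  }
  structure(
    list(sample_id = trace$sample_id,
         spike_times = trace$times[cand_idx],
         spike_values = v[cand_idx],
         threshold_used = threshold,
         min_peak_distance_used = min_peak_distance,
         unit = trace$unit),
    class = "spike_train"
  )
}

#' Construct a spike train from known spike times
#'
#' Used when spike times come from a generator or an external source
#' rather than from [detect_spikes()].
#'
#' @param spike_times Sorted, strictly increasing spike times in seconds.
#' @param sample_id Text label.
#' @param threshold_used,min_peak_distance_used Detection parameters, if
#'   applicable.
#' @param unit Signal unit of the source trace.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, sample_id = "sample",
                        threshold_used = NA_real_,
                        min_peak_distance_used = NA_real_,
                        unit = "microampere") {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 1L && is.unsorted(spike_times, strictly = TRUE)) {
    stopf("`spike_times` must be strictly increasing")
  }
  structure(
    list(sample_id = as.character(sample_id)[1L], spike_times = spike_times,
         spike_values = rep(NA_real_, length(spike_times)),
         threshold_used = threshold_used,
         min_peak_distance_used = min_peak_distance_used,
         unit = check_unit(unit)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes (threshold %g, min distance %g s)\n",
              x$sample_id, length(x$spike_times), x$threshold_used,
              x$min_peak_distance_used))
  invisible(x)
}

#' Spike-train summary statistics
#'
#' Computes the spike count, the mean interspike interval (arithmetic
#' mean of consecutive spike-time differences, seconds) and the spiking
#' frequency in millihertz, defined as `1000 / mean_isi` so that
#' `frequency_mhz * mean_isi == 1000` identically. With fewer than two
#' spikes the interval and frequency are undefined and reported as `NA`
#' with `defined = FALSE`.
#'
#' @param train A `spike_train`.
#' @return An object of class `spike_stats`: list with `n_spikes`,
#'   `mean_isi` (s), `frequency_mhz`, `defined`.
#' @examples
#' spike_stats(spike_train(c(0, 10)))     # 10 s interval, 100 mHz
#' @export
spike_stats <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  n <- length(train$spike_times)
  if (n < 2L) {
    return(structure(list(n_spikes = n, mean_isi = NA_real_,
                          frequency_mhz = NA_real_, defined = FALSE),
                     class = "spike_stats"))
  }
  mean_isi <- mean(diff(train$spike_times))
  structure(
    list(n_spikes = n, mean_isi = mean_isi,
         frequency_mhz = 1000 / mean_isi, defined = TRUE),
    class = "spike_stats"
  )
}

#' @export
print.spike_stats <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<spike_stats> %d spikes, mean ISI %.2f s, %.2f mHz\n",
                x$n_spikes, x$mean_isi, x$frequency_mhz))
  } else {
    cat(sprintf("<spike_stats> %d spikes, ISI/frequency undefined\n",
                x$n_spikes))
  }
  invisible(x)
}

#' @export
format.spike_stats <- function(x, ...) {
  c(n_spikes = as.character(x$n_spikes),
    mean_isi_s = if (x$defined) sprintf("%.2f", x$mean_isi) else "",
    frequency_mhz = if (x$defined) sprintf("%.2f", x$frequency_mhz) else "")
}

#' Per-sample spike statistics for a cohort of traces
#'
#' Runs [detect_spikes()] and [spike_stats()] on every trace and tabulates
#' the results, one row per sample, together with cohort means of the
#' spike count and mean interspike interval.
#'
#' @param traces A list of [potential_trace()] objects.
#' @param threshold,min_peak_distance Passed to [detect_spikes()].
#' @return A `data.frame` with columns `proteinoid`, `n_spikes`,
#'   `mean_isi_s`, `frequency_mhz`; cohort means are attached as the
#'   attribute `"cohort_means"` (named vector with `n_spikes` and
#'   `mean_isi_s`, the latter averaged over samples where it is defined).
#' @examples
#' specs <- cohort_specs(seed = 1)[1:2]
#' traces <- lapply(specs, synth_trace)
#' cohort_report(traces)
#' @export
cohort_report <- function(traces, threshold = 0.0005, min_peak_distance = 5) {
  if (!is.list(traces) || length(traces) < 1L) {
    stopf("`traces` must be a non-empty list of potential_trace objects")
  }
  rows <- lapply(traces, function(tr) {
    st <- spike_stats(detect_spikes(tr, threshold, min_peak_distance))
    data.frame(proteinoid = tr$sample_id, n_spikes = st$n_spikes,
               mean_isi_s = st$mean_isi, frequency_mhz = st$frequency_mhz,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "cohort_means") <- c(
    n_spikes = mean(out$n_spikes),
    mean_isi_s = mean(out$mean_isi_s, na.rm = TRUE)
  )
  out
}
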