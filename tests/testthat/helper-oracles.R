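# Independent oracles used across the suite. These are deliberately
# naive re-derivations (linear scans, closed forms), kept separate from
# the package implementations they check.

# Exhaustive peak finder: walk the samples, take every strict local
# maximum above threshold (first sample of a plateau; edges excluded),
# then prune pairwise by descending height with an O(k^2) distance check,
# earlier peak winning ties.
brute_force_peaks <- function(times, values, threshold, min_dist) {
  n <- length(values)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (values[i] > values[i - 1L]) {
      j <- i
      while (j < n && values[j + 1L] == values[i]) j <- j + 1L
      if (j < n && values[j + 1L] < values[i] && values[i] > threshold) {
        cand <- c(cand, i)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0L) return(numeric(0))
  ord <- order(-values[cand], times[cand])
  kept <- integer(0)
  for (ci in cand[ord]) {
    ok <- TRUE
    for (k in kept) {
      if (abs(times[ci] - times[k]) < min_dist) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, ci)
  }
  sort(times[kept])
}

# Interspike period of a leaky integrate-and-fire neuron under constant
# suprathreshold drive I, starting from v_reset = 0.
lif_period_closed_form <- function(tau_m, I, v_th) {
  stopifnot(I > v_th)
  tau_m * log(I / (I - v_th))
}

# Literal transcription of the latency-code definition, evaluated
# entrywise with an explicit loop.
reference_latency_code <- function(p, theta, T_window) {
  out <- numeric(length(p))
  supra <- p[p > theta]
  if (length(supra) == 0L) return(out)
  m <- min(supra)
  for (j in seq_along(p)) {
    out[j] <- if (p[j] > theta) T_window - m else 0
  }
  out
}

# Random feasible noise-free trace spec for detector cross-checks.
random_detectable_spec <- function(id, seed) {
  set.seed(seed)
  duration <- sample(200:9500, 1L)
  n_max <- floor(duration / 10)
  n_spikes <- sample(0:min(n_max, 300L), 1L)
  trace_spec(sample_id = paste0("rand-", id), duration = duration,
             sampling_rate = 1, n_spikes = n_spikes,
             spike_amplitude = runif(1, 0.0008, 0.01),
             spike_width = runif(1, 1.5, 3), baseline = 0, noise_sd = 0,
             unit = "microampere", seed = seed)
}
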