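#' Parameters for the recurrent leaky integrate-and-fire network
#'
#' A network of `N` recurrently connected leaky integrate-and-fire
#' neurons receives a scalar input signal through input weights `U` and
#' produces a scalar output through output weights `W_out`. Membrane
#' dynamics follow
#' \deqn{\tau_m \dot v_j = -v_j + U_j F_{in}(t) + \sum_k J_{jk} s_k(t)}
#' with a spike emitted when `v_j >= v_th`, after which `v_j` is reset to
#' `v_reset` and clamped for an absolute refractory period `t_ref`.
#' Spikes drive single-exponential synaptic traces `s_k` with time
#' constant `tau_s` (default `tau_m / 2`), and the network output is
#' `F_out(t) = sum_j W_out[j] * s_j(t)`.
#'
#' @param N Neuron count.
#' @param tau_m Membrane time constant, s.
#' @param v_th Spike threshold (dimensionless potential), must exceed
#'   `v_reset`.
#' @param v_reset Reset potential.
#' @param dt Forward-Euler step, s; must satisfy `dt <= tau_m / 10`.
#' @param t_ref Absolute refractory period, s.
#' @param tau_s Synaptic trace time constant, s (default `tau_m / 2`).
#' @param U Length-N input weight vector (scalar recycled).
#' @param J N x N recurrent weight matrix (default all zero).
#' @param W_out Length-N output weight vector (scalar recycled).
#' @param v0 Initial membrane potentials (default all zero).
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(N, tau_m = 0.02, v_th = 1, v_reset = 0,
                       dt = tau_m / 100, t_ref = 0, tau_s = tau_m / 2,
                       U = 1, J = NULL, W_out = 1, v0 = 0) {
  check_scalar(N, "N", positive = TRUE)
  N <- as.integer(N)
  check_scalar(tau_m, "tau_m", positive = TRUE)
  check_scalar(v_th, "v_th")
  check_scalar(v_reset, "v_reset")
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(t_ref, "t_ref", nonnegative = TRUE)
  check_scalar(tau_s, "tau_s", positive = TRUE)
  if (v_th <= v_reset) stopf("`v_th` must exceed `v_reset`")
  if (dt > tau_m / 10) stopf("`dt` must be <= tau_m / 10 for stable Euler steps")
  expand <- function(x, name) {
    if (length(x) == 1L) x <- rep(as.numeric(x), N)
    if (length(x) != N) stopf("`%s` must have length 1 or N", name)
    as.numeric(x)
  }
  if (is.null(J)) J <- matrix(0, N, N)
  J <- as.matrix(J)
  if (!all(dim(J) == c(N, N))) stopf("`J` must be N x N")
  structure(
    list(N = N, tau_m = tau_m, v_th = v_th, v_reset = v_reset, dt = dt,
         t_ref = t_ref, tau_s = tau_s, U = expand(U, "U"), J = J,
         W_out = expand(W_out, "W_out"), v0 = expand(v0, "v0")),
    class = "lif_params"
  )
}

# Coerce an input signal to a per-step vector on the simulation grid.
# Accepts a constant, a function of time, or a vector of length n_steps.
input_on_grid <- function(F_in, t_grid) {
  if (is.function(F_in)) {
    out <- F_in(t_grid)
    if (length(out) == 1L) out <- rep(out, length(t_grid))
  } else if (length(F_in) == 1L) {
    out <- rep(as.numeric(F_in), length(t_grid))
  } else if (length(F_in) == length(t_grid)) {
    out <- as.numeric(F_in)
  } else {
    stopf("`F_in` must be a constant, a function of time, or a vector of length %d",
          length(t_grid))
  }
  if (!all(is.finite(out))) stopf("`F_in` contains non-finite values")
  out
}

#' Simulate the spiking (leaky integrate-and-fire) network
#'
#' Forward-Euler integration of the LIF dynamics described in
#' [lif_params()]. A spike at step `n` sets the neuron's synaptic trace
#' increment for the next step and resets the membrane; the trace decays
#' exponentially with time constant `tau_s`. The simulation is fully
#' deterministic given the parameters and initial state.
#'
#' @param params A [lif_params()].
#' @param F_in Input signal: a constant, a function of time, or a vector
#'   sampled on the simulation grid.
#' @param duration Simulated time, s.
#' @return List with `times` (step grid, s), `spikes` (data.frame with
#'   columns `time`, `neuron`), `F_out` (output signal per step), and
#'   `v` (final membrane state).
#' @examples
#' p <- lif_params(N = 1, tau_m = 0.02, v_th = 1, U = 1)
#' out <- simulate_lif(p, F_in = 2, duration = 0.5)
#' nrow(out$spikes)
#' @export
simulate_lif <- function(params, F_in, duration) {
  stopifnot(inherits(params, "lif_params"))
  check_scalar(duration, "duration", positive = TRUE)
  n_steps <- ceiling(duration / params$dt)
  t_grid <- (seq_len(n_steps) - 1L) * params$dt
  fin <- input_on_grid(F_in, t_grid)
  N <- params$N
  v <- params$v0
  s <- numeric(N)
  ref_until <- rep(-Inf, N)
  decay_s <- exp(-params$dt / params$tau_s)
  spike_t <- vector("list", 64L)
  spike_n <- vector("list", 64L)
  n_ev <- 0L
  F_out <- numeric(n_steps)
  for (n in seq_len(n_steps)) {
    t_now <- t_grid[n]
    drive <- params$U * fin[n] + as.numeric(params$J %*% s)
    dv <- (-v + drive) * (params$dt / params$tau_m)
    active <- t_now >= ref_until
    v <- v + ifelse(active, dv, 0)
    if (!all(is.finite(v))) {
      stopf("non-finite membrane potential at step %d (t = %g s)", n, t_now)
    }
    fired <- active & v >= params$v_th
    if (any(fired)) {
      v[fired] <- params$v_reset
      ref_until[fired] <- t_now + params$t_ref
      s[fired] <- s[fired] + 1
      n_ev <- n_ev + 1L
      if (n_ev > length(spike_t)) {
        length(spike_t) <- 2L * length(spike_t)
        length(spike_n) <- 2L * length(spike_n)
      }
      spike_t[[n_ev]] <- rep(t_now, sum(fired))
      spike_n[[n_ev]] <- which(fired)
    }
    F_out[n] <- sum(params$W_out * s)
    s <- s * decay_s
  }
  spikes <- data.frame(
    time = unlist(spike_t[seq_len(n_ev)]) %||% numeric(0),
    neuron = unlist(spike_n[seq_len(n_ev)]) %||% integer(0)
  )
  list(times = t_grid, spikes = spikes, F_out = F_out, v = v)
}

#' Parameters for the continuous-variable (rate) network
#'
#' A network of `N_tilde` recurrently connected rate units receives the
#' external input `F_in(t)` through `U_tilde` and, when feedback is
#' enabled, its own output `F_out(t)` through feedback weights `u`.
#' Dynamics are
#' \deqn{\tau \dot x = -x + \tilde J\, \phi(x) + \tilde U F_{in}(t) + u F_{out}(t)}
#' with rates `r = phi(x)` (`phi = tanh` by default) and output
#' `F_out = sum_j W_out[j] * r_j`.
#'
#' @param N_tilde Unit count.
#' @param tau Time constant, s.
#' @param dt Euler step, s; `dt <= tau / 10` enforced.
#' @param phi Pointwise nonlinearity (default `tanh`).
#' @param U_tilde Length-N input weights (scalar recycled).
#' @param u Length-N feedback weights from `F_out` (scalar recycled;
#'   ignored when feedback is off).
#' @param J_tilde N x N recurrent weights (default zero).
#' @param W_out Length-N output weights (scalar recycled).
#' @param x0 Initial state (default zero).
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(N_tilde, tau = 0.1, dt = tau / 100, phi = tanh,
                        U_tilde = 1, u = 0, J_tilde = NULL, W_out = 1,
                        x0 = 0) {
  check_scalar(N_tilde, "N_tilde", positive = TRUE)
  N <- as.integer(N_tilde)
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  if (dt > tau / 10) stopf("`dt` must be <= tau / 10 for stable Euler steps")
  if (!is.function(phi)) stopf("`phi` must be a function")
  expand <- function(x, name) {
    if (length(x) == 1L) x <- rep(as.numeric(x), N)
    if (length(x) != N) stopf("`%s` must have length 1 or N_tilde", name)
    as.numeric(x)
  }
  if (is.null(J_tilde)) J_tilde <- matrix(0, N, N)
  J_tilde <- as.matrix(J_tilde)
  if (!all(dim(J_tilde) == c(N, N))) stopf("`J_tilde` must be N_tilde x N_tilde")
  structure(
    list(N_tilde = N, tau = tau, dt = dt, phi = phi,
         U_tilde = expand(U_tilde, "U_tilde"), u = expand(u, "u"),
         J_tilde = J_tilde, W_out = expand(W_out, "W_out"),
         x0 = expand(x0, "x0")),
    class = "rate_params"
  )
}

#' Simulate the continuous-variable network
#'
#' Forward-Euler integration of the rate dynamics in [rate_params()].
#' With `feedback = "on"` the output generated through `W_out` is fed
#' back into the units through `u`, closing the loop; with
#' `feedback = "off"` the `u F_out` term is dropped.
#'
#' @param params A [rate_params()].
#' @param F_in Input signal (constant, function of time, or per-step
#'   vector).
#' @param duration Simulated time, s.
#' @param feedback `"on"` or `"off"`.
#' @return List with `times`, `x` (n_steps x N state trajectory),
#'   `rates` (`phi(x)`), `F_out`.
#' @examples
#' p <- rate_params(N_tilde = 3, tau = 0.1, U_tilde = 0.5)
#' out <- simulate_rate(p, F_in = 1, duration = 2)
#' tail(out$x[, 1], 1)   # near the fixed point 0.5
#' @export
simulate_rate <- function(params, F_in, duration, feedback = c("off", "on")) {
  stopifnot(inherits(params, "rate_params"))
  feedback <- match.arg(feedback)
  check_scalar(duration, "duration", positive = TRUE)
  n_steps <- ceiling(duration / params$dt)
  t_grid <- (seq_len(n_steps) - 1L) * params$dt
  fin <- input_on_grid(F_in, t_grid)
  N <- params$N_tilde
  x <- params$x0
  X <- matrix(NA_real_, n_steps, N)
  F_out <- numeric(n_steps)
  fb <- feedback == "on"
  f_out_prev <- sum(params$W_out * params$phi(x))
  for (n in seq_len(n_steps)) {
    r <- params$phi(x)
    drive <- as.numeric(params$J_tilde %*% r) + params$U_tilde * fin[n]
    if (fb) drive <- drive + params$u * f_out_prev
    x <- x + (params$dt / params$tau) * (-x + drive)
    if (!all(is.finite(x))) {
      stopf("non-finite state at step %d (t = %g s)", n, t_grid[n])
    }
    X[n, ] <- x
    f_out_prev <- sum(params$W_out * params$phi(x))
    F_out[n] <- f_out_prev
  }
  list(times = t_grid, x = X, rates = params$phi(X), F_out = F_out)
}

#' Drive a network with a detected proteinoid spike train
#'
#' Converts the spike times of a [spike_train] into a pulse-train input
#' signal (rectangular pulses of the given width and amplitude) and runs
#' the spiking network on it, summarising the response.
#'
#' @param train A `spike_train` (detected or constructed).
#' @param params A [lif_params()].
#' @param pulse_width Width of each input pulse, s.
#' @param pulse_amplitude Height of each input pulse.
#' @param duration Simulated time, s; defaults to the last spike time
#'   plus one pulse width (must be positive, so an empty train needs an
#'   explicit duration).
#' @return List with `n_input_spikes`, `n_output_spikes`, `output_rate`
#'   (spikes/s across all neurons), `F_out_mean`, `F_out_max`, and the
#'   full simulation result under `sim`.
#' @examples
#' tr <- spike_train(c(0.1, 0.4, 0.7))
#' p <- lif_params(N = 1, tau_m = 0.02, v_th = 0.5, U = 2)
#' drive_with_proteinoid(tr, p, duration = 1)$n_output_spikes
#' @export
drive_with_proteinoid <- function(train, params, pulse_width = 0.05,
                                  pulse_amplitude = 1, duration = NULL) {
  stopifnot(inherits(train, "spike_train"), inherits(params, "lif_params"))
  check_scalar(pulse_width, "pulse_width", positive = TRUE)
  check_scalar(pulse_amplitude, "pulse_amplitude")
  st <- train$spike_times
  if (is.null(duration)) {
    if (length(st) == 0L) {
      stopf("an empty train needs an explicit `duration`")
    }
    duration <- max(st) + pulse_width
  }
  f_in <- function(t) {
    if (length(st) == 0L) return(numeric(length(t)))
    out <- numeric(length(t))
    for (ts in st) out <- out + (t >= ts & t < ts + pulse_width)
    pulse_amplitude * pmin(out, 1)
  }
  sim <- simulate_lif(params, f_in, duration)
  n_out <- nrow(sim$spikes)
  list(n_input_spikes = length(st),
       n_output_spikes = n_out,
       output_rate = n_out / duration,
       F_out_mean = mean(sim$F_out),
       F_out_max = if (length(sim$F_out)) max(sim$F_out) else 0,
       sim = sim)
}
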