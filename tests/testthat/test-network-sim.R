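test_that("an undriven LIF network is quiescent", {
  p <- lif_params(N = 3, tau_m = 0.02, v_th = 1)
  out <- simulate_lif(p, F_in = 0, duration = 0.5)
  expect_identical(nrow(out$spikes), 0L)
  expect_true(all(out$F_out == 0))
  expect_true(all(out$v == 0))
})

test_that("constant-drive interspike period matches the closed form", {
  tau_m <- 0.02
  v_th <- 1
  I <- 2
  p <- lif_params(N = 1, tau_m = tau_m, v_th = v_th, v_reset = 0,
                  dt = tau_m / 1000, U = 1)
  out <- simulate_lif(p, F_in = I, duration = 0.3)
  isis <- diff(out$spikes$time)
  expect_gt(length(isis), 5)
  period <- mean(isis[-1])   # discard the first, which starts from v0 = 0
  expect_lt(abs(period - lif_period_closed_form(tau_m, I, v_th)) /
              lif_period_closed_form(tau_m, I, v_th), 0.01)
})

test_that("halving the Euler step changes the period estimate by < 0.5%", {
  tau_m <- 0.05
  v_th <- 0.8
  I <- 1.5
  period_at <- function(dt) {
    p <- lif_params(N = 1, tau_m = tau_m, v_th = v_th, dt = dt, U = 1)
    out <- simulate_lif(p, F_in = I, duration = 0.5)
    mean(diff(out$spikes$time))
  }
  t1 <- period_at(tau_m / 1000)
  t2 <- period_at(tau_m / 2000)
  expect_lt(abs(t1 - t2) / t2, 0.005)
})

test_that("membrane potential equals the reset value right after a spike", {
  p <- lif_params(N = 1, tau_m = 0.02, v_th = 1, v_reset = -0.2,
                  dt = 0.02 / 100, U = 1)
  probe <- simulate_lif(p, F_in = 3, duration = 0.5)
  first_spike <- probe$spikes$time[1]
  # stop the simulation on the very step that spiked: final v is the reset
  out <- simulate_lif(p, F_in = 3, duration = first_spike + p$dt / 2)
  expect_identical(nrow(out$spikes), 1L)
  expect_equal(out$v, -0.2)
})

test_that("relabelling neurons permutes the raster consistently", {
  set.seed(31)
  N <- 4
  U <- runif(N, 0.5, 2)
  J <- matrix(runif(N * N, -0.2, 0.4), N, N)
  W_out <- runif(N)
  perm <- c(3, 1, 4, 2)
  p1 <- lif_params(N = N, tau_m = 0.02, v_th = 1, dt = 2e-4,
                   U = U, J = J, W_out = W_out)
  p2 <- lif_params(N = N, tau_m = 0.02, v_th = 1, dt = 2e-4,
                   U = U[perm], J = J[perm, perm], W_out = W_out[perm])
  o1 <- simulate_lif(p1, F_in = 1.5, duration = 0.2)
  o2 <- simulate_lif(p2, F_in = 1.5, duration = 0.2)
  relabel <- match(seq_len(N), perm)   # neuron j of o1 appears as relabel[j] in o2
  a <- o1$spikes
  a$neuron <- relabel[a$neuron]
  a <- a[order(a$time, a$neuron), ]
  b <- o2$spikes[order(o2$spikes$time, o2$spikes$neuron), ]
  expect_equal(a$time, b$time)
  expect_equal(a$neuron, b$neuron)
  expect_equal(o1$F_out, o2$F_out)
})

test_that("rate units relax to the analytic fixed point without recurrence", {
  p <- rate_params(N_tilde = 3, tau = 0.1, dt = 1e-3, U_tilde = c(0.5, -0.3, 0))
  out <- simulate_rate(p, F_in = 1, duration = 3)
  expect_equal(out$x[nrow(out$x), ], c(0.5, -0.3, 0), tolerance = 1e-6)
})

test_that("with all weights zero the rate-network state decays monotonically", {
  p <- rate_params(N_tilde = 4, tau = 0.05, dt = 5e-4, U_tilde = 0,
                   x0 = c(1, -2, 0.5, 3))
  out <- simulate_rate(p, F_in = 0, duration = 1)
  norms <- sqrt(rowSums(out$x^2))
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[length(norms)], 1e-6)
})

test_that("a contracting scalar rate unit converges to the bisection fixed point", {
  J <- 0.8   # |J| * max tanh' = 0.8 < 1: unique fixed point
  U <- 0.7
  fin <- 1
  # oracle: solve x = J*tanh(x) + U*fin by bisection
  g <- function(x) J * tanh(x) + U * fin - x
  lo <- -10; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  x_star <- (lo + hi) / 2
  p <- rate_params(N_tilde = 1, tau = 0.1, dt = 1e-3, U_tilde = U,
                   J_tilde = matrix(J, 1, 1))
  out <- simulate_rate(p, F_in = fin, duration = 5)
  expect_equal(out$x[nrow(out$x), 1], x_star, tolerance = 1e-5)
})

test_that("closing the output feedback loop changes the dynamics as specified", {
  p <- rate_params(N_tilde = 2, tau = 0.1, dt = 1e-3, U_tilde = 0.5,
                   u = 0.3, W_out = 1)
  off <- simulate_rate(p, F_in = 1, duration = 2, feedback = "off")
  on <- simulate_rate(p, F_in = 1, duration = 2, feedback = "on")
  # positive feedback through u must raise the steady output
  expect_gt(on$F_out[length(on$F_out)], off$F_out[length(off$F_out)])
})

test_that("proteinoid spike trains drive the network as pulse inputs", {
  p <- lif_params(N = 1, tau_m = 0.05, v_th = 0.5, dt = 5e-3, U = 3)

  resp0 <- drive_with_proteinoid(spike_train(numeric(0)), p, duration = 2)
  expect_identical(resp0$n_output_spikes, 0L)
  expect_equal(resp0$F_out_mean, 0)

  # periodic 1 Hz input through a strong synapse: relay fires at least
  # once per input pulse
  train <- spike_train(seq(0.5, 9.5, by = 1))
  resp <- drive_with_proteinoid(train, p, pulse_width = 0.2,
                                pulse_amplitude = 1, duration = 10)
  expect_gte(resp$n_output_spikes, resp$n_input_spikes)

  # doubling the input weight never loses output spikes (J = 0)
  set.seed(17)
  for (k in 1:5) {
    st <- sort(runif(6, 0, 5))
    st <- st[c(TRUE, diff(st) > 0.3)]
    tr <- spike_train(st)
    u0 <- runif(1, 0.8, 1.6)
    n1 <- drive_with_proteinoid(tr, lif_params(N = 1, tau_m = 0.05,
                                               v_th = 0.5, dt = 5e-3, U = u0),
                                pulse_width = 0.2, duration = 6)$n_output_spikes
    n2 <- drive_with_proteinoid(tr, lif_params(N = 1, tau_m = 0.05,
                                               v_th = 0.5, dt = 5e-3,
                                               U = 2 * u0),
                                pulse_width = 0.2, duration = 6)$n_output_spikes
    expect_gte(n2, n1)
  }
})

test_that("parameter validation guards the Euler step and thresholds", {
  expect_error(lif_params(N = 1, tau_m = 0.02, dt = 0.01), "dt")
  expect_error(lif_params(N = 1, v_th = 0, v_reset = 0), "v_th")
  expect_error(rate_params(N_tilde = 2, tau = 0.1, dt = 0.05), "dt")
})
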