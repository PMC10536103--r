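test_that("latency encoding follows the shared-latency rule", {
  expect_equal(encode_latency(c(0.4, 0.2, 0.1), theta = 0.5, T_window = 10),
               c(0, 0, 0))
  # both firing neurons share T minus the smallest suprathreshold potential
  expect_equal(encode_latency(c(0.6, 0.4, 0.9), theta = 0.5, T_window = 10),
               c(9.4, 0, 9.4))
  # exact threshold does not fire (strict inequality)
  expect_equal(encode_latency(rep(0.5, 4), theta = 0.5, T_window = 10),
               rep(0, 4))
  expect_error(encode_latency(c(0.1, NA), 0.5, 10), "non-finite")
})

test_that("encoding matches an entrywise transcription of its definition", {
  set.seed(21)
  for (k in 1:200) {
    N <- sample(1:12, 1)
    p <- runif(N, -0.2, 1.2)
    theta <- runif(1, 0, 1)
    T_window <- runif(1, 1, 50)
    expect_equal(encode_latency(p, theta, T_window),
                 reference_latency_code(p, theta, T_window))
  }
})

test_that("encoding commutes with neuron relabelling", {
  set.seed(5)
  for (k in 1:20) {
    p <- runif(8)
    perm <- sample(8)
    c1 <- encode_latency(p, 0.5, 10)
    c2 <- encode_latency(p[perm], 0.5, 10)
    expect_equal(c2, c1[perm])
  }
})

test_that("raising the threshold never creates new code entries", {
  set.seed(6)
  for (k in 1:20) {
    p <- runif(10)
    thetas <- sort(runif(5))
    nz <- vapply(thetas, function(th) sum(encode_latency(p, th, 10) > 0),
                 numeric(1))
    expect_true(all(diff(nz) <= 0))
  }
})

test_that("matrix encoding applies the rule column by column", {
  p <- cbind(c(0.6, 0.4, 0.9), c(0.1, 0.2, 0.3))
  codes <- encode_matrix(p, theta = 0.5, T_window = 10)
  expect_identical(dim(codes), c(3L, 2L))
  expect_equal(codes[, 1], c(9.4, 0, 9.4))
  expect_equal(codes[, 2], c(0, 0, 0))
})

test_that("random weight initialisation is bounded and reproducible", {
  W <- init_weights(10, seed = 42)
  expect_identical(dim(W), c(10L, 10L))
  expect_true(all(W >= -1 & W <= 1))
  expect_identical(W, init_weights(10, seed = 42))
  expect_false(identical(W, init_weights(10, seed = 43)))
})

test_that("the embedded initial weight matrix matches its printed values", {
  W <- load_initial_weights()
  expect_identical(dim(W), c(10L, 10L))
  expect_equal(W[1, ], c(-1, 1, 1, 1, -1, 1, -1, 1, -1, 1))
  expect_equal(W[10, 1], 0.3)
  expect_equal(W[3, 3], -0.4)
  expect_true(all(W >= -1 & W <= 1))
})

test_that("co-activation updates are Hebbian, diagonal-preserving and clipped", {
  W <- matrix(0, 3, 3)
  expect_identical(coactivation_update(W, c(1, 1, 0), learning_rate = 0),
                   W)

  W1 <- coactivation_update(W, c(1, 1, 0), learning_rate = 0.5)
  expect_equal(W1[1, 2], 0.5)
  expect_equal(W1[2, 1], 0.5)
  expect_true(all(W1[3, ] == 0) && all(W1[, 3] == 0))
  expect_equal(diag(W1), diag(W))

  # real-valued latency codes binarise before the outer product
  W2 <- coactivation_update(W, c(9.4, 0, 9.4), learning_rate = 0.5)
  expect_equal(W2[1, 3], 0.5)

  # repeated all-ones updates saturate every off-diagonal entry at +1
  Ws <- matrix(-1, 4, 4)
  diag(Ws) <- -0.5
  for (i in 1:50) Ws <- coactivation_update(Ws, rep(1, 4), 0.1)
  off <- Ws[row(Ws) != col(Ws)]
  expect_true(all(off == 1))
  expect_equal(diag(Ws), rep(-0.5, 4))
})

test_that("weights stay within [-1, 1] under arbitrary update sequences", {
  set.seed(8)
  for (rep in 1:10) {
    N <- sample(2:10, 1)
    W <- init_weights(N, seed = rep)
    for (step in 1:40) {
      code <- runif(N) * rbinom(N, 1, 0.5)
      W <- coactivation_update(W, code, learning_rate = runif(1, 0, 0.5))
    }
    expect_true(all(W >= -1 & W <= 1))
  }
})

test_that("correlated pairs converge to +1, never-co-active pairs stay put", {
  W <- matrix(0, 2, 2)
  for (i in 1:30) W <- coactivation_update(W, c(1, 1), 0.1)
  expect_equal(W[1, 2], 1)
  expect_equal(W[2, 1], 1)

  W0 <- init_weights(2, seed = 3)
  W <- W0
  for (i in 1:30) {
    W <- coactivation_update(W, c(1, 0), 0.1)
    W <- coactivation_update(W, c(0, 1), 0.1)
  }
  expect_equal(W[1, 2], W0[1, 2])
  expect_equal(W[2, 1], W0[2, 1])
})

test_that("connectivity indices measure rectified, activity-weighted drive", {
  z <- psi_ppi(matrix(0, 3, 3), rep(1, 3))
  expect_equal(z$psi, rep(0, 3))
  expect_equal(z$ppi, rep(0, 3))

  W <- matrix(0, 2, 2)
  W[1, 2] <- 1
  idx <- psi_ppi(W, c(1, 0))
  expect_equal(idx$psi[2], 1)
  expect_equal(idx$psi[1], 0)

  # purely inhibitory weights contribute nothing
  Wneg <- matrix(-runif(9), 3, 3)
  expect_equal(psi_ppi(Wneg, rep(0.5, 3))$psi, rep(0, 3))

  # all-zero activity is defined as zero, not NaN
  quiet <- psi_ppi(matrix(1, 3, 3), rep(0, 3))
  expect_equal(quiet$psi, rep(0, 3))

  # bounded in [0, 1] for random bounded weights and activities
  set.seed(12)
  for (k in 1:20) {
    N <- sample(2:10, 1)
    W <- matrix(runif(N * N, -1, 1), N, N)
    a <- runif(N)
    idx <- psi_ppi(W, a)
    expect_true(all(idx$psi >= 0 & idx$psi <= 1))
    expect_true(all(idx$ppi >= 0 & idx$ppi <= 1))
  }
})

test_that("training folds a code matrix into the weights column by column", {
  codes <- cbind(c(1, 1, 0), c(0, 1, 1))
  W <- train_weights(matrix(0, 3, 3), codes, learning_rate = 0.25)
  expect_equal(W[1, 2], 0.25)   # co-active in column 1 only
  expect_equal(W[2, 3], 0.25)   # co-active in column 2 only
  expect_equal(W[1, 3], 0)      # never co-active
})
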