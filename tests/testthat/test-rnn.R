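test_that("activation functions match their defining formulas", {
  expect_equal(apply_activation(0, activation_spec("sigmoid")), 0.5)
  expect_equal(apply_activation(1, activation_spec("sigmoid")),
               1 / (1 + exp(-7.5)))
  expect_equal(apply_activation(c(-1, 2), activation_spec("relu")), c(0, 2))
  expect_equal(apply_activation(0.3, activation_spec("tanh")), tanh(0.3))
  # derivatives agree with central differences
  h <- 1e-6
  for (kind in c("relu", "sigmoid", "tanh")) {
    sp <- activation_spec(kind)
    for (x in c(-0.8, 0.4, 1.7)) {
      num <- (apply_activation(x + h, sp) - apply_activation(x - h, sp)) / (2 * h)
      expect_lt(abs(activation_deriv(x, sp) - num), 1e-5)
    }
  }
})

test_that("initialization hits spectral radius 1.2 with the Dale structure", {
  for (kind in c("relu", "sigmoid", "tanh")) for (dale in c(FALSE, TRUE)) {
    p <- initialize_rnn(kind, dale, N = 20, n_in = 6, n_out = 2, seed = 3)
    sr <- max(Mod(eigen(p$W_rec, only.values = TRUE)$values))
    expect_equal(sr, 1.2, tolerance = 1e-9)
    expect_true(all(p$W_inp >= 0))
    expect_true(all(p$W_out >= 0))
    if (dale) {
      sgn <- p$dale$sign_vector
      expect_equal(sum(sgn > 0),
                   if (kind == "tanh") 10 else 16)  # R_EI = 1 vs 4
      for (j in seq_len(p$N))
        expect_true(all(p$W_rec[, j] * sgn[j] >= 0))
    }
  }
  p100 <- initialize_rnn("tanh", TRUE, N = 100, seed = 1)
  expect_equal(sum(p100$dale$sign_vector > 0), 50)
  expect_error(initialize_rnn("relu", TRUE, N = 7), "incompatible")
})

test_that("the Euler step matches hand computation and has its fixed point", {
  # zero weights, zero input: origin is a fixed point
  p <- initialize_rnn("tanh", FALSE, N = 3, n_in = 2, n_out = 1, seed = 1)
  p$W_rec[] <- 0; p$W_inp[] <- 0
  expect_equal(euler_step(numeric(3), numeric(2), p), numeric(3))
  # gamma = 1 reduces to a pure map
  p1 <- initialize_rnn("sigmoid", FALSE, N = 4, n_in = 2, n_out = 1,
                       seed = 2, tau = 1, dt = 1)
  y <- c(0.1, -0.2, 0.3, 0)
  u <- c(1, 0.5)
  expect_equal(euler_step(y, u, p1),
               drop(apply_activation(p1$W_rec %*% y + p1$W_inp %*% u,
                                     p1$activation)))
  # one-unit scalar arithmetic, with noise terms
  ps <- initialize_rnn("tanh", FALSE, N = 2, n_in = 1, n_out = 1, seed = 3,
                       tau = 10, sigma_inp = 0.05, sigma_rec = 0.02)
  ps$W_rec <- matrix(c(1.5, 0, 0, 0), 2)
  ps$W_inp <- matrix(c(2, 0), 2, 1)
  g <- 0.1
  y <- c(0.4, 0); zeta <- 0.7; xi <- c(-0.3, 0)
  expected <- (1 - g) * 0.4 +
    g * tanh(1.5 * 0.4 + 2 * (0.9 + sqrt(2 * g * 0.05^2) * 0.7) +
               sqrt(2 * g * 0.02^2) * (-0.3))
  expect_equal(euler_step(y, 0.9, ps, zeta, xi)[1], expected)
  expect_error(euler_step(numeric(3), 0.9, ps), "dimension mismatch")
})

test_that("compiled simulation agrees with the R Euler reference", {
  p <- initialize_rnn("sigmoid", TRUE, N = 10, n_in = 3, n_out = 1, seed = 5)
  b <- build_gonogo_batch(values = c(0.2, 0.8), T_steps = 12, t_go_cue = 6)
  resp <- simulate_batch(p, b)
  for (k in 1:2) {
    y <- numeric(10)
    for (t in 1:12) {
      y <- euler_step(y, b$inputs[, t, k], p)
      expect_equal(resp$activity[, t, k], y, tolerance = 1e-12)
    }
    expect_equal(resp$outputs[, , k], p$W_out %*% resp$activity[, , k],
                 ignore_attr = TRUE)
  }
})

test_that("simulations are deterministic and respect activation ranges", {
  b <- build_gonogo_batch(values = c(0.1, 0.6), T_steps = 30, t_go_cue = 15)
  for (kind in c("relu", "sigmoid", "tanh")) {
    p <- initialize_rnn(kind, FALSE, N = 12, n_in = 3, n_out = 1, seed = 6)
    r1 <- simulate_batch(p, b)
    r2 <- simulate_batch(p, b)
    expect_identical(r1$activity, r2$activity)
    rng <- activation_range(p$activation)
    expect_true(all(r1$activity >= rng[1] - 1e-12 &
                      r1$activity <= rng[2] + 1e-12))
    n1 <- simulate_batch(p, b, noise = TRUE, seed = 9)
    n2 <- simulate_batch(p, b, noise = TRUE, seed = 9)
    n3 <- simulate_batch(p, b, noise = TRUE, seed = 10)
    expect_identical(n1$activity, n2$activity)
    expect_false(identical(n1$activity, n3$activity))
  }
})

test_that("the training loss vanishes and scales as documented", {
  T_s <- 8; K <- 3
  mask <- matrix(TRUE, T_s, K)
  o <- array(rnorm(2 * T_s * K), dim = c(2, T_s, K))
  act <- array(0, dim = c(5, T_s, K))
  W1 <- diag(1, 5, 3)                     # orthogonal columns
  expect_equal(training_loss(o, o, mask, act, W1), 0)
  act2 <- array(0.5, dim = c(5, T_s, K))
  l1 <- training_loss(o, o, mask, act2, W1, lambda_r = 0.3)
  l2 <- training_loss(o, o, mask, 2 * act2, W1, lambda_r = 0.3)
  expect_equal(l2, 4 * l1)                # quadratic activity penalty
  W2 <- matrix(1, 5, 3)                   # maximally non-orthogonal
  expect_gt(training_loss(o, o, mask, act, W2, lambda_orth = 0.1), 0)
  expect_error(training_loss(o, o, mask & FALSE, act, W1), "empty")
})

test_that("backpropagated gradients match finite differences", {
  p <- initialize_rnn("sigmoid", TRUE, N = 10, n_in = 3, n_out = 1, seed = 3)
  b <- build_gonogo_batch(values = c(0.2, 0.7, 0.5), T_steps = 20,
                          t_go_cue = 10)
  lg <- actbias:::rnn_loss_grad(p, b, lambda_r = 0.5, lambda_orth = 0.1,
                                noise = FALSE)
  h <- 1e-6
  for (field in c("W_inp", "W_rec", "W_out")) {
    W <- p[[field]]
    idx <- with_seed(4, sample(length(W), min(length(W), 12)))
    for (i in idx) {
      pp <- p; pp[[field]][i] <- W[i] + h
      pm <- p; pm[[field]][i] <- W[i] - h
      num <- (actbias:::rnn_loss_grad(pp, b, 0.5, 0.1, FALSE)$loss -
                actbias:::rnn_loss_grad(pm, b, 0.5, 0.1, FALSE)$loss) / (2 * h)
      expect_equal(lg[[paste0("g", field)]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and never violates the constraints", {
  p0 <- initialize_rnn("relu", TRUE, N = 10, n_in = 3, n_out = 1, seed = 8)
  b <- build_gonogo_batch(T_steps = 40, t_go_cue = 20)
  tr <- train_rnn(p0, b, lambda_r = 0.5, n_iter = 120L, seed = 12,
                  check_constraints = TRUE)
  expect_true(all(is.finite(tr$loss_trace)))
  expect_lt(task_performance(tr$params, b), task_performance(p0, b))
  expect_true(all(tr$params$W_inp >= 0))
  expect_true(all(tr$params$W_out >= 0))
  expect_equal(actbias:::dale_violations(tr$params$W_rec, tr$params$dale), 0L)
  # two-phase schedule runs both phases
  tr2 <- train_rnn(p0, b, lambda_r = c(0, 0.3), n_iter = c(20L, 20L),
                   seed = 12)
  expect_length(tr2$loss_trace, 40)
})

test_that("the memory-task schedule has two phases with the stated weights", {
  sch <- task_training_schedule("memory")
  expect_equal(sch$lambda_r, c(0, 0.3))
  expect_equal(sch$n_iter, c(6000L, 6000L))
  expect_equal(task_training_schedule("cddm"),
               task_training_schedule("gonogo"))
})

test_that("connectivity shuffling preserves the stated structure", {
  p <- initialize_rnn("tanh", FALSE, N = 15, n_in = 6, n_out = 2, seed = 2)
  s <- shuffle_connectivity(p, seed = 5)
  expect_equal(diag(s$W_rec), diag(p$W_rec))
  for (i in seq_len(nrow(p$W_inp)))
    expect_setequal(s$W_inp[i, ], p$W_inp[i, ])
  for (j in seq_len(p$N)) {
    off <- setdiff(seq_len(p$N), j)
    expect_setequal(s$W_rec[off, j], p$W_rec[off, j])
  }
  expect_false(identical(s$W_rec, p$W_rec))
  expect_identical(shuffle_connectivity(p, seed = 5)$W_rec, s$W_rec)
})

test_that("checkpoints round-trip through the text format", {
  p <- initialize_rnn("sigmoid", TRUE, N = 10, n_in = 3, n_out = 1, seed = 4)
  prefix <- file.path(tempdir(), "ckpt_roundtrip")
  save_rnn(p, prefix, loss_trace = c(1, 0.5))
  p2 <- load_rnn(prefix)
  expect_equal(unname(p2$W_rec), unname(p$W_rec), tolerance = 1e-12)
  expect_equal(unname(p2$W_inp), unname(p$W_inp), tolerance = 1e-12)
  expect_equal(p2$activation$kind, "sigmoid")
  expect_equal(p2$dale$sign_vector, p$dale$sign_vector)
  b <- build_gonogo_batch(values = 0.3, T_steps = 10, t_go_cue = 5)
  expect_equal(simulate_batch(p2, b)$activity, simulate_batch(p, b)$activity,
               tolerance = 1e-12)
})
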