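# small CDDM batch shared by the latent tests
latent_test_batch <- function() {
  cache_get("latent_batch", function()
    build_cddm_batch(enumerate_cddm_conditions(c(-1, 1))))
}

# a well-behaved 8-node teacher circuit with the standard input mask
teacher_circuit <- function(seed = 1, n = 8, n_in = 6, n_out = 2) {
  with_seed(seed, {
    w_inp <- matrix(0, n, n_in)
    w_inp[cbind(seq_len(n_in), seq_len(n_in))] <- runif(n_in, 0.5, 1.5)
    w_rec <- matrix(rnorm(n * n, 0, 0.4), n, n)
    diag(w_rec) <- abs(diag(w_rec)) + 0.5
    w_out <- matrix(0, n_out, n)
    w_out[1, 7] <- 1; w_out[2, 8] <- 1
    w_rec[7, 3] <- 1; w_rec[8, 4] <- 1      # sensory nodes drive choice
    list(w_inp = w_inp, w_rec = w_rec, w_out = w_out)
  })
}

test_that("dimensionality reduction for fitting is lossless on low-rank data", {
  Z <- synthetic_response(N = 20, T_steps = 15, K = 6, rank = 5, seed = 1)
  red <- reduce_for_fit(Z, n_pc = 10)
  expect_equal(red$variance_captured, 1.0, tolerance = 1e-10)
  expect_equal(dim(red$z), c(10, 15, 6))
  expect_equal(crossprod(red$basis), diag(10), tolerance = 1e-10,
               ignore_attr = TRUE)
  # round trip through the flat representation is exact
  zf <- actbias:::flatten_tensor(red$z)
  expect_identical(array(zf, dim = dim(red$z)), red$z)
  expect_warning(reduce_for_fit(Z, n_pc = 30), "fewer units")
})

test_that("the latent loss vanishes and scales as documented", {
  n <- 4; n_pc <- 6; T_s <- 10; K <- 3
  x <- array(0, dim = c(n, T_s, K))
  z <- array(0, dim = c(n_pc, T_s, K))
  o <- array(0.3, dim = c(2, T_s, K))
  mask <- matrix(TRUE, T_s, K)
  Q <- diag(1, n_pc, n)
  w0 <- matrix(0, n, n)
  expect_equal(latent_loss(x, z, o, o, mask, Q, w0[, 1:2], w0, w0[1:2, ]), 0)
  w1 <- matrix(0.5, n, n)
  l1 <- latent_loss(x, z, o, o, mask, Q, w1[, 1:2], w1, w1[1:2, ],
                    lambda_w = 0.01)
  l2 <- latent_loss(x, z, o, o, mask, Q, 2 * w1[, 1:2], 2 * w1, 2 * w1[1:2, ],
                    lambda_w = 0.01)
  expect_equal(l2, 4 * l1)
  # for fixed orthonormal Q, x = Q^T z minimizes the embedding term
  z <- array(with_seed(2, rnorm(n_pc * T_s * K)), dim = c(n_pc, T_s, K))
  Qo <- with_seed(3, actbias:::random_orthogonal(n_pc)[, 1:n])
  xstar <- array(apply(z, c(2, 3), function(v) crossprod(Qo, v)),
                 dim = c(n, T_s, K))
  emb_of <- function(x) latent_loss(x, z, o, o, mask, Qo, w0[, 1:2], w0,
                                    w0[1:2, ], lambda_w = 0)
  best <- emb_of(xstar)
  for (s in 1:5)
    expect_gte(emb_of(xstar + array(with_seed(10 + s, rnorm(length(xstar),
                                                            0, 0.1)),
                                    dim = dim(xstar))), best)
})

test_that("fitting respects the embedding and wiring constraints", {
  b <- latent_test_batch()
  tc <- teacher_circuit()
  sim <- actbias:::latent_forward(tc$w_inp, tc$w_rec, tc$w_out, b$inputs,
                                  0.1, activation_spec("tanh"))
  Q_true <- with_seed(5, actbias:::random_orthogonal(12)[, 1:8])
  z <- array(apply(sim$activity, c(2, 3), function(v) Q_true %*% v),
             dim = c(12, dim(sim$activity)[2], dim(sim$activity)[3]))
  fit <- fit_latent_circuit(z, b, "tanh", gamma = 0.1, n = 8,
                            n_restarts = 2, n_iter = 150, seed = 7)
  expect_s3_class(fit, "latent_fit")
  expect_equal(crossprod(fit$Q), diag(8), tolerance = 1e-6,
               ignore_attr = TRUE)
  mask <- actbias:::default_input_mask(8, 6)
  expect_true(all(fit$w_inp[mask == 0] == 0))
  expect_true(all(fit$w_inp >= 0))
  expect_true(all(fit$w_out >= 0))
  # the loss is non-increasing for nearly all optimizer steps (a small
  # fraction of momentum overshoots is tolerated)
  expect_gte(mean(diff(fit$trace) <= 1e-8), 0.95)
  # restart bookkeeping is reproducible
  fit2 <- fit_latent_circuit(z, b, "tanh", gamma = 0.1, n = 8,
                             n_restarts = 2, n_iter = 150, seed = 7)
  expect_identical(fit2$restart, fit$restart)
  expect_identical(fit2$loss, fit$loss)
})

test_that("fit scores are exact for perfect and mean-level reconstructions", {
  b <- latent_test_batch()
  tc <- teacher_circuit(seed = 2)
  act <- activation_spec("tanh")
  sim <- actbias:::latent_forward(tc$w_inp, tc$w_rec, tc$w_out, b$inputs,
                                  0.1, act)
  Q_true <- with_seed(6, actbias:::random_orthogonal(10)[, 1:8])
  z <- array(apply(sim$activity, c(2, 3), function(v) Q_true %*% v),
             dim = c(10, dim(sim$activity)[2], dim(sim$activity)[3]))
  fit <- structure(list(w_inp = tc$w_inp, w_rec = tc$w_rec,
                        w_out = tc$w_out, Q = Q_true, n = 8,
                        activation = act, gamma = 0.1),
                   class = "latent_fit")
  # the teacher's own output against itself as behavioural target
  b_self <- b
  b_self$targets <- sim$outputs
  sc <- score_fit(fit, z, b_self)
  expect_equal(unname(sc["r2_dynamics"]), 1, tolerance = 1e-12)
  expect_equal(unname(sc["r2_behaviour"]), 1, tolerance = 1e-12)
  # an all-zero circuit reproduces only the (zero) grand mean of centred z
  z0 <- z - mean(z)
  fit0 <- fit
  fit0$w_inp[] <- 0; fit0$w_rec[] <- 0; fit0$w_out[] <- 0
  sc0 <- score_fit(fit0, z0, b)
  expect_equal(unname(sc0["r2_dynamics"]), 0, tolerance = 1e-12)
  expect_error(score_fit(fit, z * 0, b), "zero-variance")
})

test_that("fit quality is invariant to relabeling the latent nodes", {
  b <- latent_test_batch()
  tc <- teacher_circuit(seed = 3)
  act <- activation_spec("tanh")
  sim <- actbias:::latent_forward(tc$w_inp, tc$w_rec, tc$w_out, b$inputs,
                                  0.1, act)
  Q <- with_seed(8, actbias:::random_orthogonal(9)[, 1:8])
  z <- array(apply(sim$activity, c(2, 3), function(v) Q %*% v + 0.01),
             dim = c(9, dim(sim$activity)[2], dim(sim$activity)[3]))
  fit <- structure(list(w_inp = tc$w_inp, w_rec = tc$w_rec, w_out = tc$w_out,
                        Q = Q, n = 8, activation = act, gamma = 0.1),
                   class = "latent_fit")
  perm <- with_seed(9, sample(8))
  P <- diag(8)[perm, ]
  fitp <- fit
  fitp$w_rec <- P %*% tc$w_rec %*% t(P)
  fitp$w_inp <- P %*% tc$w_inp
  fitp$w_out <- tc$w_out %*% t(P)
  fitp$Q <- Q %*% t(P)
  expect_equal(score_fit(fitp, z, b), score_fit(fit, z, b),
               tolerance = 1e-12)
})
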