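test_that("flow field and Jacobian follow the defining formulas", {
  p <- initialize_rnn("tanh", FALSE, N = 4, n_in = 2, n_out = 1, seed = 1)
  p$W_rec[] <- 0
  fj <- rhs_and_jacobian(numeric(4), numeric(2), p)
  expect_equal(fj$F, numeric(4))
  expect_equal(fj$J, -diag(4))
  # one-unit tanh with w = 2 at the origin: J = -1 + 2 f'(0) = +1
  p1 <- initialize_rnn("tanh", FALSE, N = 2, n_in = 1, n_out = 1, seed = 2)
  p1$W_rec <- diag(c(2, 0)); p1$W_inp <- matrix(0, 2, 1)
  expect_equal(rhs_and_jacobian(c(0, 0), 0, p1)$J[1, 1], 1)
})

test_that("the analytic Jacobian matches central finite differences", {
  h <- 1e-6
  for (kind in c("sigmoid", "tanh")) {
    p <- initialize_rnn(kind, FALSE, N = 6, n_in = 2, n_out = 1,
                        seed = match(kind, c("sigmoid", "tanh")))
    y <- with_seed(3, rnorm(6, 0, 0.5))
    u <- c(0.8, 0.2)
    J <- rhs_and_jacobian(y, u, p)$J
    for (j in 1:6) {
      e <- numeric(6); e[j] <- h
      num <- (rhs_and_jacobian(y + e, u, p)$F -
                rhs_and_jacobian(y - e, u, p)$F) / (2 * h)
      expect_equal(J[, j], num, tolerance = 1e-5)
    }
  }
})

one_unit_params <- function(kind, w, n_in = 1) {
  p <- initialize_rnn(kind, FALSE, N = 2, n_in = n_in, n_out = 1, seed = 1)
  p$W_rec <- diag(c(w, 0))
  p$W_inp <- matrix(c(1, 0), 2, n_in)
  p
}

# trajectory stand-in spanning the activation range, to seed the searches
line_activity <- function(lo = -1.5, hi = 1.5) {
  a <- array(0, dim = c(2, 40, 5))
  a[1, , ] <- seq(lo, hi, length.out = 200)
  a
}

test_that("a bistable one-unit tanh net yields the three known fixed points", {
  p <- one_unit_params("tanh", 2)
  fps <- find_fixed_points_for_input(c(0), line_activity(), p, seed = 4,
                                     max_points = 10, patience = 40)
  found <- sort(fps$coords[, 1])
  expect_length(found, 3)
  expect_equal(found, c(-0.9575040, 0, 0.9575040), tolerance = 1e-6)
  expect_true(all(fps$residual <= 1e-12))
  expect_equal(fps$stability[order(fps$coords[, 1])],
               c("stable", "unstable", "stable"))
  # stable outer roots: J = -1 + 2 (1 - y*^2) < 0
  expect_equal(Re(fps$lambda0[which.min(fps$coords[, 1])]),
               -1 + 2 * (1 - 0.9575040^2), tolerance = 1e-5)
})

test_that("the finder reproduces the bisection oracle on random one-unit nets", {
  draws <- with_seed(11, data.frame(
    kind = sample(c("relu", "sigmoid", "tanh"), 20, replace = TRUE),
    w = runif(20, -2.5, 2.5),
    u = runif(20, -1, 1)))
  for (i in seq_len(nrow(draws))) {
    kind <- draws$kind[i]; w <- draws$w[i]; u <- draws$u[i]
    p <- one_unit_params(kind, w)
    oracle <- bisect_fixed_points(w, u, p$activation)
    fps <- suppressWarnings(
      find_fixed_points_for_input(c(u), line_activity(-3, 3), p,
                                  seed = 100 + i, max_points = 10,
                                  patience = 60))
    found <- sort(fps$coords[, 1])
    expect_equal(length(found), length(oracle),
                 info = sprintf("draw %d: %s w=%.3f u=%.3f", i, kind, w, u))
    expect_equal(found, sort(oracle), tolerance = 1e-6)
    # stability labels match the sign of the analytic Jacobian
    for (r in seq_along(found)) {
      lab <- fps$stability[order(fps$coords[, 1])][r]
      Jv <- -1 + activation_deriv(w * found[r] + u, p$activation) * w
      expect_equal(lab, if (Jv <= 0) "stable" else "unstable")
    }
  }
})

test_that("zero recurrence gives the unique closed-form fixed point", {
  p <- initialize_rnn("sigmoid", FALSE, N = 6, n_in = 3, n_out = 1, seed = 9)
  p$W_rec[] <- 0
  u <- c(0.5, 1, 0.2)
  act <- array(with_seed(2, rnorm(6 * 40 * 3, 0, 0.3)), dim = c(6, 40, 3))
  fps <- find_fixed_points_for_input(u, act, p, seed = 5, max_points = 10,
                                     patience = 30)
  expect_equal(nrow(fps$coords), 1)
  expect_equal(fps$coords[1, ],
               drop(apply_activation(p$W_inp %*% u, p$activation)),
               tolerance = 1e-8)
  expect_equal(fps$stability, "stable")    # J = -I
})

test_that("accepted fixed points are mutually distinct beyond the threshold", {
  p <- one_unit_params("tanh", 2)
  fps <- find_fixed_points_for_input(c(0), line_activity(), p, seed = 6,
                                     max_points = 10, patience = 60)
  if (nrow(fps$coords) > 1) {
    d <- stats::dist(fps$coords)
    expect_true(all(d > 1e-7))
  }
  # the distinct-count is reproducible across start orders
  counts <- vapply(c(21, 22, 23), function(s)
    nrow(find_fixed_points_for_input(c(0), line_activity(), p, seed = s,
                                     max_points = 10,
                                     patience = 60)$coords), 0L)
  expect_equal(counts, rep(3L, 3))
})

test_that("stable fixed points attract nearby noiseless trajectories", {
  p <- one_unit_params("tanh", 2)
  fps <- find_fixed_points_for_input(c(0), line_activity(), p, seed = 4,
                                     max_points = 10, patience = 40)
  stable <- which(fps$stability == "stable" & Re(fps$lambda0) < -1e-3)
  for (i in stable) {
    fp <- fps$coords[i, ]
    y <- fp + 1e-3
    for (s in 1:50) y <- euler_step(y, c(0), p)
    expect_lt(sqrt(sum((y - fp)^2)), 10 * 1e-3 * sqrt(2))
  }
})

test_that("the CDDM survey queries 50 tagged input conditions", {
  sv <- survey_conditions("cddm")
  expect_equal(ncol(sv$inputs), 50)
  expect_equal(nrow(sv$conditions), 50)
  # context channels one-hot; sensory channels complementary
  expect_true(all(colSums(sv$inputs[1:2, ]) == 1))
  expect_equal(unname(sv$inputs[3, ] + sv$inputs[4, ]), rep(1, 50))
  sg <- survey_conditions("gonogo")
  expect_equal(ncol(sg$inputs), 22)      # 11 values x cue off/on
  expect_true(all(sg$inputs[3, ] == 1))  # bias channel
})

test_that("survey results carry tags from the queried condition set", {
  p <- initialize_rnn("tanh", FALSE, N = 8, n_in = 6, n_out = 2, seed = 3)
  b <- build_cddm_batch(enumerate_cddm_conditions(c(-1, 1)), T_steps = 150)
  act <- simulate_batch(p, b)$activity
  sv <- survey_conditions("cddm", rel_grid = c(-1, 1), irr_grid = c(-1, 1))
  fps <- fixed_point_survey(p, "cddm", act, seed = 2, survey = sv,
                            max_points = 5, patience = 10)
  expect_s3_class(fps, "fp_survey")
  expect_true(all(fps$tags$input_id %in% sv$conditions$input_id))
  expect_true(all(fps$tags$stability %in% c("stable", "unstable")))
  expect_true(all(fps$tags$residual <= 1e-12))
  expect_true(all(table(fps$tags$input_id) <= 5))
  tab <- fp_survey_table(fps, net_id = 7L)
  expect_equal(nrow(tab), nrow(fps$coords))
  expect_true(all(c("net_id", "stability", "coord_0") %in% names(tab)))
})
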