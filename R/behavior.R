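# Behavioural characterization: task performance, psychometric maps,
# out-of-distribution probes, output-subspace alignment, and the
# hand-crafted 3-unit flip-flop network.

#' Task performance of a network
#'
#' Masked mean squared error between the outputs of a noiseless pass over
#' the batch and the task targets (lower is better); used to rank networks
#' and select the top performers.
#'
#' @param params an \code{rnn_params}.
#' @param batch a \code{trial_batch} covering all task conditions.
#' @return non-negative scalar.
#' @export
task_performance <- function(params, batch) {
  resp <- simulate_batch(params, batch, noise = FALSE)
  masked_mse(resp$outputs, batch$targets, batch$mask)
}

#' Psychometric map of a network on the CDDM task
#'
#' For every (motion, colour) coherence cell, simulates \code{n_reps} noisy
#' trials and records the fraction of right choices. The choice on a trial
#' is the sign of the (right - left) output averaged over the final 100 ms
#' of the trial (a tie counts 0.5). Grids may extend beyond the [-1, 1]
#' training range to probe out-of-distribution generalization.
#'
#' @param params an \code{rnn_params} trained on the CDDM task.
#' @param context "motion" or "colour".
#' @param motion_grid,colour_grid coherence values for the two axes.
#' @param n_reps noisy repetitions per cell.
#' @param seed RNG seed.
#' @param T_steps trial duration.
#' @return object of class \code{psychometric_map}: \code{choice}
#'   (motion x colour matrix of right-choice fractions), grids, context.
#' @export
psychometric_map <- function(params, context = "motion",
                             motion_grid = seq(-2, 2, length.out = 21),
                             colour_grid = seq(-2, 2, length.out = 21),
                             n_reps = 64, seed = 1L, T_steps = 300) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  cells <- expand.grid(c_motion = motion_grid, c_colour = colour_grid,
                       KEEP.OUT.ATTRS = FALSE)
  choice <- numeric(nrow(cells))
  win <- max(1, T_steps - 99):T_steps
  # chunk over cells to bound the simulated tensor size
  chunk <- max(1, floor(2e6 / (T_steps * n_reps)))
  idx <- split(seq_len(nrow(cells)), ceiling(seq_len(nrow(cells)) / chunk))
  for (ci in seq_along(idx)) {
    rows <- idx[[ci]]
    conds <- data.frame(context = context,
                        c_motion = rep(cells$c_motion[rows], each = n_reps),
                        c_colour = rep(cells$c_colour[rows], each = n_reps))
    b <- build_cddm_batch(conds, T_steps = T_steps, ood = TRUE)
    resp <- simulate_batch(params, b, noise = TRUE,
                           seed = derive_seed(seed, "psycho_chunk", ci))
    dv <- colMeans(resp$outputs[1, win, ] - resp$outputs[2, win, ])
    dim(dv) <- NULL
    right <- ifelse(dv > 0, 1, ifelse(dv < 0, 0, 0.5))
    choice[rows] <- colMeans(matrix(right, n_reps))
  }
  structure(list(choice = matrix(choice, length(motion_grid),
                                 length(colour_grid),
                                 dimnames = list(motion_grid, colour_grid)),
                 motion_grid = motion_grid, colour_grid = colour_grid,
                 context = context, n_reps = n_reps, seed = seed),
            class = "psychometric_map")
}

#' Sensitivity of choices to the irrelevant stimulus
#'
#' Least-squares linear fit of the right-choice fraction on the irrelevant
#' coherence with the relevant coherence as covariate; returns the slope on
#' the irrelevant axis. Zero means the decision boundary is perfectly
#' aligned with the relevant axis (ideal gating); a rotation of the
#' boundary appears as a non-zero slope.
#'
#' @param map a \code{psychometric_map}, or a list with \code{choice},
#'   \code{motion_grid}, \code{colour_grid}, \code{context}.
#' @return scalar slope.
#' @export
irrelevant_sensitivity <- function(map) {
  cells <- expand.grid(c_motion = map$motion_grid, c_colour = map$colour_grid)
  p <- as.vector(map$choice)
  if (stats::sd(p) < 1e-12)
    stop("degenerate psychometric map: all cells give the same choice")
  rel <- if (map$context == "motion") cells$c_motion else cells$c_colour
  irr <- if (map$context == "motion") cells$c_colour else cells$c_motion
  unname(coef(lm(p ~ rel + irr))["irr"])
}

#' Alignment of network activity with the output subspace
#'
#' The generalized correlation
#' \eqn{\rho = \|W_{out} X\|_F / (\|W_{out}\|_F \|X\|_F)}, computed over
#' the activity \code{X} during the steps at which the network must produce
#' output. \eqn{\rho = 1} when every activity pattern lies along the
#' readout directions (aligned dynamics) and near 0 when activity evolves
#' orthogonally to them (oblique dynamics).
#'
#' @param W_out readout matrix (n_out x N).
#' @param X activity, (N, T_out * K) matrix or (N, T_out, K) tensor.
#' @return scalar in [0, 1].
#' @export
output_alignment_rho <- function(W_out, X) {
  if (length(dim(X)) == 3) X <- flatten_tensor(X)
  nw <- sqrt(sum(W_out^2)); nx <- sqrt(sum(X^2))
  if (nw < 1e-24 || nx < 1e-24) stop("zero-norm readout or activity")
  sqrt(sum((W_out %*% X)^2)) / (nw * nx)
}

#' Output-epoch activity of a simulated batch
#'
#' Restricts a response tensor to the steps where output is required:
#' [200, 300) ms for CDDM, the post-cue window for Go/NoGo and memory.
#'
#' @param resp a \code{response_tensor}.
#' @param task task id.
#' @param t_go_cue Go-cue onset for the cued tasks.
#' @return (N, T_out, K) array.
#' @export
output_epoch_activity <- function(resp, task, t_go_cue = NULL) {
  T_steps <- dim(resp$activity)[2]
  idx <- if (task == "cddm") 201:T_steps
  else {
    if (is.null(t_go_cue)) t_go_cue <- if (task == "gonogo") 30 else 70
    (t_go_cue + 1):T_steps
  }
  resp$activity[, idx, , drop = FALSE]
}

#' Hand-crafted 3-unit tanh flip-flop network
#'
#' One self-excitatory tanh unit per bit: strong self-excitation
#' (\code{w_self} > 1) makes each unit bistable at the roots of
#' \eqn{y = \tanh(w_{self}\, y)}, pulses are mapped one-to-one with gain
#' \code{input_gain}, and the readout is the identity. The same
#' construction with a ReLU activation cannot hold a negative state, so it
#' fails the task.
#'
#' @param n_bits number of bits (= units).
#' @param w_self self-excitation weight.
#' @param input_gain input pulse gain.
#' @param activation activation kind (the tanh default solves the task).
#' @param tau,dt time constants (ms).
#' @return an \code{rnn_params} with \code{n_bits} units.
#' @export
handcrafted_flipflop <- function(n_bits = 3, w_self = 2, input_gain = 2,
                                 activation = "tanh", tau = 10, dt = 1) {
  act <- if (is.character(activation)) activation_spec(activation) else activation
  structure(list(W_inp = diag(input_gain, n_bits),
                 W_rec = diag(w_self, n_bits),
                 W_out = diag(1, n_bits),
                 activation = act, dale = dale_spec(FALSE),
                 tau = tau, dt = dt, sigma_inp = 0, sigma_rec = 0,
                 N = n_bits, n_in = n_bits, n_out = n_bits, seed = NA_integer_),
            class = "rnn_params")
}

#' Verify a flip-flop network over all bit patterns
#'
#' For each of the \eqn{2^{n_{bits}}} sign patterns, drives the network
#' with one pulse per bit and checks that every output holds the sign of
#' its last pulse, within an absolute margin of 0.5, for the remainder of
#' the trial.
#'
#' @param params an \code{rnn_params} with matching bit count.
#' @param T_steps trial duration in steps.
#' @param pulse_width pulse duration in steps.
#' @param hold_steps steps after the pulse over which the state is checked.
#' @param margin required distance of the output from 0, with the correct
#'   sign.
#' @return list: \code{pass} (logical), \code{n_patterns_ok}, per-pattern
#'   data.frame \code{report} with the failing bits.
#' @export
verify_flipflop <- function(params, T_steps = 260, pulse_width = 20,
                            hold_steps = 200, margin = 0.5) {
  n_bits <- params$n_out
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_bits)))
  pulse_sets <- lapply(seq_len(nrow(patterns)), function(i)
    data.frame(bit = seq_len(n_bits), onset = 10, sign = patterns[i, ]))
  batch <- build_flipflop_batch(pulse_sets, n_bits = n_bits,
                                T_steps = T_steps, pulse_width = pulse_width)
  resp <- simulate_batch(params, batch, noise = FALSE)
  check_idx <- (T_steps - hold_steps + 1):T_steps
  report <- do.call(rbind, lapply(seq_len(nrow(patterns)), function(i) {
    ok <- vapply(seq_len(n_bits), function(b) {
      o <- resp$outputs[b, check_idx, i]
      all(o * patterns[i, b] >= margin)
    }, logical(1))
    data.frame(pattern = paste(ifelse(patterns[i, ] > 0, "+", "-"),
                               collapse = ""),
               ok = all(ok),
               failed_bits = paste(which(!ok), collapse = ","))
  }))
  list(pass = all(report$ok), n_patterns_ok = sum(report$ok), report = report)
}
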