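#' Dale's-law connectivity specification
#'
#' When enabled, every unit is excitatory or inhibitory: the column of the
#' recurrent matrix holding a unit's outgoing weights keeps a fixed sign
#' (or zero) throughout training. The ratio of excitatory to inhibitory
#' counts is \code{r_ei} = 4 for ReLU and sigmoid networks and 1 for tanh
#' networks.
#'
#' @param enabled logical.
#' @param r_ei ratio of excitatory to inhibitory unit counts.
#' @return object of class \code{dale_spec}.
#' @export
dale_spec <- function(enabled = FALSE, r_ei = 4) {
  structure(list(enabled = enabled, r_ei = r_ei, sign_vector = NULL),
            class = "dale_spec")
}

default_r_ei <- function(kind) if (kind == "tanh") 1 else 4

#' Initialize a continuous-time RNN
#'
#' Implements the initialization used throughout the study. Without Dale's
#' constraint, recurrent weights are drawn from
#' \eqn{N(1/\sqrt{N}, 1/N^2)} and rescaled so the spectral radius (largest
#' eigenvalue magnitude) equals 1.2. With Dale's constraint, excitatory
#' columns are \eqn{|N(1/\sqrt{N}, 1/N^2)|} and inhibitory columns are
#' \eqn{-|N(R_{E/I}/\sqrt{N}, 1/N^2)|}, followed by the same spectral
#' rescaling. Input and output matrices take absolute values of
#' \eqn{N(1/\sqrt{N}, 1/N^2)} draws and stay non-negative during training.
#'
#' @param activation an \code{\link{activation_spec}} or a kind string.
#' @param dale a \code{\link{dale_spec}}, or \code{TRUE}/\code{FALSE} to use
#'   the default excitatory/inhibitory ratio for the activation.
#' @param N number of units.
#' @param n_in,n_out input / output channel counts.
#' @param seed RNG seed.
#' @param tau membrane time constant (ms).
#' @param dt integration step (ms).
#' @param sigma_inp,sigma_rec input / recurrent noise standard deviations.
#' @param spectral_radius target spectral radius after rescaling.
#' @return object of class \code{rnn_params}.
#' @export
initialize_rnn <- function(activation = "tanh", dale = FALSE, N = 100,
                           n_in = 6, n_out = 2, seed = 1L, tau = 10, dt = 1,
                           sigma_inp = 0.01, sigma_rec = 0.01,
                           spectral_radius = 1.2) {
  if (is.character(activation)) activation <- activation_spec(activation)
  if (!inherits(dale, "dale_spec"))
    dale <- dale_spec(as.logical(dale), default_r_ei(activation$kind))
  if (N < 2) stop("N must be at least 2")
  mu <- 1 / sqrt(N); sdev <- 1 / N
  with_seed(seed, {
    if (dale$enabled) {
      n_exc <- N * dale$r_ei / (dale$r_ei + 1)
      if (abs(n_exc - round(n_exc)) > 1e-9)
        stop("N is incompatible with the excitatory/inhibitory ratio")
      n_exc <- as.integer(round(n_exc))
      sign_vec <- c(rep(1, n_exc), rep(-1, N - n_exc))
      W_rec <- matrix(0, N, N)
      for (j in seq_len(N)) {
        if (sign_vec[j] > 0) {
          W_rec[, j] <- abs(rnorm(N, mu, sdev))
        } else {
          W_rec[, j] <- -abs(rnorm(N, dale$r_ei / sqrt(N), sdev))
        }
      }
      dale$sign_vector <- sign_vec
    } else {
      W_rec <- matrix(rnorm(N * N, mu, sdev), N, N)
    }
    sr <- max(Mod(eigen(W_rec, only.values = TRUE)$values))
    W_rec <- W_rec * spectral_radius / sr
    W_inp <- abs(matrix(rnorm(N * n_in, mu, sdev), N, n_in))
    W_out <- abs(matrix(rnorm(n_out * N, mu, sdev), n_out, N))
  })
  structure(list(W_inp = W_inp, W_rec = W_rec, W_out = W_out,
                 activation = activation, dale = dale, tau = tau, dt = dt,
                 sigma_inp = sigma_inp, sigma_rec = sigma_rec,
                 N = N, n_in = n_in, n_out = n_out, seed = seed),
            class = "rnn_params")
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf("<rnn_params> %s%s, N = %d, n_in = %d, n_out = %d\n",
              x$activation$kind, if (x$dale$enabled) " + Dale" else "",
              x$N, x$n_in, x$n_out))
  invisible(x)
}

gamma_of <- function(params) {
  g <- params$dt / params$tau
  stopifnot(g > 0, g <= 1)
  g
}

#' One Euler step of the RNN dynamics (reference implementation)
#'
#' \deqn{y_{t+1} = (1-\gamma) y_t + \gamma f(W_{rec} y_t +
#'   W_{inp}(u_t + \sqrt{2\gamma\sigma_{inp}^2}\,\zeta) +
#'   \sqrt{2\gamma\sigma_{rec}^2}\,\xi)}
#' with \eqn{\gamma = dt/\tau}. Noise vectors are standard normal draws
#' supplied by the caller (zero vectors for noiseless integration).
#'
#' @param y state vector (length N).
#' @param u input vector (length n_in).
#' @param params an \code{rnn_params}.
#' @param noise_inp,noise_rec standard-normal noise vectors, lengths n_in, N.
#' @return the next state vector.
#' @export
euler_step <- function(y, u, params, noise_inp = numeric(params$n_in),
                       noise_rec = numeric(params$N)) {
  if (length(y) != params$N || length(u) != params$n_in)
    stop("state/input dimension mismatch")
  g <- gamma_of(params)
  a <- params$W_rec %*% y +
    params$W_inp %*% (u + sqrt(2 * g * params$sigma_inp^2) * noise_inp) +
    sqrt(2 * g * params$sigma_rec^2) * noise_rec
  drop((1 - g) * y + g * apply_activation(a, params$activation))
}

#' Simulate an RNN over a trial batch
#'
#' Runs the Euler dynamics forward from the zero state for every trial of
#' the batch and reads out \eqn{\hat{o} = W_{out} y}. With \code{noise}
#' on, process noise is injected at every step; simulations are
#' reproducible given \code{seed}.
#'
#' @param params an \code{rnn_params}.
#' @param batch a \code{trial_batch}.
#' @param noise logical; inject process noise.
#' @param seed RNG seed used when \code{noise} is on.
#' @return object of class \code{response_tensor}: \code{activity}
#'   (N, T, K), \code{outputs} (n_out, T, K).
#' @export
simulate_batch <- function(params, batch, noise = FALSE, seed = 1L) {
  res <- cpp_rnn_forward(params$W_inp, params$W_rec, params$W_out,
                         batch$inputs, numeric(params$N), gamma_of(params),
                         act_kind_code(params$activation),
                         params$activation$slope,
                         params$sigma_inp, params$sigma_rec,
                         noise, as.integer(seed) %% 2147483647L)
  structure(list(activity = res$activity, outputs = res$outputs,
                 noise = noise, seed = if (noise) seed else NA_integer_),
            class = "response_tensor")
}

#' Training loss of the RNN
#'
#' Masked output error \eqn{\langle \|o - \hat{o}\|^2 \rangle}, plus an
#' activity penalty \eqn{\lambda_r \langle \|y\|^2 \rangle}, plus an
#' input-column orthogonality penalty
#' \eqn{\lambda_\perp \langle \|W_{inp}^T W_{inp} -
#' \mathrm{diag}(W_{inp}^T W_{inp})\|^2 \rangle}. Every average runs over
#' all elements of the tensor it touches (masked output entries; all
#' activity entries), matching a plain mean-squared-error implementation.
#'
#' @param outputs,targets (n_out, T, K) tensors.
#' @param mask logical (T, K) matrix of loss-bearing steps.
#' @param activity (N, T, K) tensor.
#' @param W_inp input matrix.
#' @param lambda_r activity penalty weight.
#' @param lambda_orth orthogonality penalty weight.
#' @return scalar loss.
#' @export
training_loss <- function(outputs, targets, mask, activity, W_inp,
                          lambda_r = 0.5, lambda_orth = 0.1) {
  if (!any(mask)) stop("empty training mask")
  G <- crossprod(W_inp)
  off <- G - diag(diag(G), nrow(G))
  masked_mse(outputs, targets, mask) +
    lambda_r * mean(activity^2) +
    lambda_orth * sum(off^2) / length(off)
}

# project parameters back onto the constraint set: non-negative W_inp/W_out
# always; Dale sign pattern on W_rec columns when enabled (entries that
# switched sign are set to zero)
project_constraints <- function(W_inp, W_rec, W_out, dale) {
  W_inp[W_inp < 0] <- 0
  W_out[W_out < 0] <- 0
  if (dale$enabled) {
    sgn <- rep(dale$sign_vector, each = nrow(W_rec))
    W_rec[W_rec * sgn < 0] <- 0
  }
  list(W_inp = W_inp, W_rec = W_rec, W_out = W_out)
}

dale_violations <- function(W_rec, dale) {
  if (!dale$enabled) return(0L)
  sgn <- rep(dale$sign_vector, each = nrow(W_rec))
  sum(W_rec * sgn < 0)
}

adam_state <- function(shapes) {
  lapply(shapes, function(d) list(m = array(0, d), v = array(0, d)))
}

adam_update <- function(st, g, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(state = st, step = lr * mhat / (sqrt(vhat) + eps))
}

# loss and gradients for one full-batch pass (optionally with process noise);
# the orthogonality penalty is added here since it does not touch the dynamics
rnn_loss_grad <- function(params, batch, lambda_r, lambda_orth, noise,
                          noise_seed = 0L) {
  lg <- cpp_train_grad(params$W_inp, params$W_rec, params$W_out,
                       batch$inputs, batch$targets, batch$mask * 1,
                       numeric(params$N), gamma_of(params),
                       act_kind_code(params$activation),
                       params$activation$slope, params$sigma_inp,
                       params$sigma_rec, noise, as.integer(noise_seed),
                       lambda_r)
  G <- crossprod(params$W_inp)
  off <- G - diag(diag(G), nrow(G))
  list(loss = lg$loss + lambda_orth * sum(off^2) / length(off),
       gW_inp = lg$gW_inp +
         lambda_orth * 4 * params$W_inp %*% off / length(off),
       gW_rec = lg$gW_rec, gW_out = lg$gW_out)
}

#' Default training schedule for a task
#'
#' CDDM and Go/NoGo use an activity penalty \eqn{\lambda_r = 0.5} for 5000
#' iterations; the memory-number task is trained in two phases,
#' \eqn{\lambda_r = 0} for 6000 iterations then 0.3 for another 6000.
#'
#' @param task one of "cddm", "gonogo", "memory", "flipflop".
#' @return list with vectors \code{lambda_r} and \code{n_iter} (one entry
#'   per phase).
#' @export
task_training_schedule <- function(task) {
  switch(task,
    cddm = ,
    gonogo = list(lambda_r = 0.5, n_iter = 5000L),
    memory = list(lambda_r = c(0, 0.3), n_iter = c(6000L, 6000L)),
    flipflop = list(lambda_r = 0.1, n_iter = 3000L),
    stop("unknown task: ", task)
  )
}

#' Train an RNN on a trial batch
#'
#' Full-batch Adam (learning rate 0.001, \eqn{\beta_1 = 0.9},
#' \eqn{\beta_2 = 0.999}, \eqn{\epsilon = 10^{-8}}) on
#' \code{\link{training_loss}}, with gradients computed by backpropagation
#' through time. After every update, negative entries of the input and
#' output matrices are set to zero, and (with Dale's constraint) recurrent
#' entries that switched sign are set to zero.
#'
#' @param params an \code{rnn_params}.
#' @param batch a \code{trial_batch} (the full condition set; it is used
#'   whole at every iteration).
#' @param lambda_r activity penalty weight, or a vector of per-phase values.
#' @param n_iter iterations, or a vector matching \code{lambda_r}.
#' @param lambda_orth input-orthogonality penalty weight.
#' @param lr Adam learning rate.
#' @param noise inject process noise during training passes.
#' @param seed RNG seed for the training noise.
#' @param clip_norm global gradient-norm clipping threshold. Backpropagation
#'   through hundreds of steps of initially expansive ReLU dynamics produces
#'   exploding gradients; clipping rescales the full gradient when its
#'   overall norm exceeds this value, leaving well-scaled gradients
#'   untouched. Set to \code{Inf} to disable.
#' @param check_constraints assert the Dale/non-negativity invariants after
#'   every update (testing aid).
#' @return list with the trained \code{params} and the per-iteration
#'   \code{loss_trace}.
#' @export
train_rnn <- function(params, batch, lambda_r = 0.5, n_iter = 5000L,
                      lambda_orth = 0.1, lr = 1e-3, noise = TRUE, seed = 1L,
                      clip_norm = 1, check_constraints = FALSE) {
  stopifnot(length(lambda_r) == length(n_iter))
  st <- adam_state(list(W_inp = dim(params$W_inp), W_rec = dim(params$W_rec),
                        W_out = dim(params$W_out)))
  trace <- numeric(sum(n_iter))
  it <- 0L
  with_seed(seed, {
    for (phase in seq_along(lambda_r)) {
      for (i in seq_len(n_iter[phase])) {
        it <- it + 1L
        lg <- rnn_loss_grad(params, batch, lambda_r[phase], lambda_orth,
                            noise, noise_seed = sample.int(2147483647L, 1))
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (loss = %g at iteration %d)",
                       lg$loss, it))
        trace[it] <- lg$loss
        gn <- sqrt(sum(lg$gW_inp^2) + sum(lg$gW_rec^2) + sum(lg$gW_out^2))
        if (is.finite(clip_norm) && gn > clip_norm) {
          sc <- clip_norm / gn
          lg$gW_inp <- lg$gW_inp * sc
          lg$gW_rec <- lg$gW_rec * sc
          lg$gW_out <- lg$gW_out * sc
        }
        for (nm in c("W_inp", "W_rec", "W_out")) {
          up <- adam_update(st[[nm]], lg[[paste0("g", nm)]], lr, it)
          st[[nm]] <- up$state
          params[[nm]] <- params[[nm]] - up$step
        }
        pr <- project_constraints(params$W_inp, params$W_rec, params$W_out,
                                  params$dale)
        params$W_inp <- pr$W_inp; params$W_rec <- pr$W_rec
        params$W_out <- pr$W_out
        if (check_constraints) {
          stopifnot(all(params$W_inp >= 0), all(params$W_out >= 0),
                    dale_violations(params$W_rec, params$dale) == 0L)
        }
      }
    }
  })
  list(params = params, loss_trace = trace)
}

#' Shuffled-connectivity control network
#'
#' Independently permutes each row of the input matrix (the inputs to one
#' unit) and the off-diagonal entries of each column of the recurrent
#' matrix (the outputs of one unit), leaving the diagonal untouched to
#' preserve each unit's self-excitation.
#'
#' @param params an \code{rnn_params}.
#' @param seed RNG seed.
#' @return a new \code{rnn_params} with shuffled connectivity.
#' @export
shuffle_connectivity <- function(params, seed = 1L) {
  with_seed(seed, {
    for (i in seq_len(nrow(params$W_inp)))
      params$W_inp[i, ] <- sample(params$W_inp[i, ])
    N <- params$N
    for (j in seq_len(N)) {
      off <- setdiff(seq_len(N), j)
      params$W_rec[off, j] <- sample(params$W_rec[off, j])
    }
  })
  params
}

#' Save / load an RNN checkpoint as plain text
#'
#' Weights go to CSV files and metadata (activation, Dale spec, time
#' constants, noise, seed, optional loss trace) to a JSON sidecar.
#'
#' @param params an \code{rnn_params}.
#' @param prefix path prefix for the written files.
#' @param loss_trace optional numeric vector stored in the metadata.
#' @return \code{prefix}, invisibly.
#' @export
save_rnn <- function(params, prefix, loss_trace = NULL) {
  utils::write.csv(params$W_inp, paste0(prefix, "_Winp.csv"), row.names = FALSE)
  utils::write.csv(params$W_rec, paste0(prefix, "_Wrec.csv"), row.names = FALSE)
  utils::write.csv(params$W_out, paste0(prefix, "_Wout.csv"), row.names = FALSE)
  meta <- list(activation = unclass(params$activation),
               dale = unclass(params$dale), tau = params$tau, dt = params$dt,
               sigma_inp = params$sigma_inp, sigma_rec = params$sigma_rec,
               N = params$N, n_in = params$n_in, n_out = params$n_out,
               seed = params$seed, loss_trace = loss_trace)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname save_rnn
#' @export
load_rnn <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  act <- structure(list(kind = meta$activation$kind,
                        slope = meta$activation$slope),
                   class = "activation_spec")
  dale <- structure(list(enabled = meta$dale$enabled, r_ei = meta$dale$r_ei,
                         sign_vector = meta$dale$sign_vector),
                    class = "dale_spec")
  structure(list(
    W_inp = as.matrix(utils::read.csv(paste0(prefix, "_Winp.csv"))),
    W_rec = as.matrix(utils::read.csv(paste0(prefix, "_Wrec.csv"))),
    W_out = as.matrix(utils::read.csv(paste0(prefix, "_Wout.csv"))),
    activation = act, dale = dale, tau = meta$tau, dt = meta$dt,
    sigma_inp = meta$sigma_inp, sigma_rec = meta$sigma_rec, N = meta$N,
    n_in = meta$n_in, n_out = meta$n_out, seed = meta$seed),
    class = "rnn_params")
}
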