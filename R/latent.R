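# Latent-circuit distillation: fit a small constrained RNN whose linearly
# embedded dynamics reproduce a large RNN's responses and task output.

#' Reduce network responses for latent-circuit fitting
#'
#' Projects the (N, T, K) activity tensor onto its first \code{n_pc}
#' principal axes over the unit dimension. The axes are computed from the
#' uncentered second moment (the activity starts at the zero state, and the
#' latent embedding \eqn{Qx} must match the projection from the same
#' origin), and the captured fraction is reported as retained squared norm.
#'
#' @param Z a \code{response_tensor} or (N, T, K) array.
#' @param n_pc number of components (30 in the full study); reduced with a
#'   warning when the network has fewer units.
#' @return list with \code{z} ((n_pc, T, K) tensor), \code{basis}
#'   (N x n_pc, orthonormal columns), \code{variance_captured}.
#' @export
reduce_for_fit <- function(Z, n_pc = 30) {
  A <- if (inherits(Z, "response_tensor")) Z$activity else Z
  d <- dim(A)
  if (d[1] < n_pc) {
    warning("network has fewer units than requested components; using n_pc = ",
            d[1])
    n_pc <- d[1]
  }
  X <- flatten_tensor(A)
  sv <- svd(X, nu = n_pc, nv = 0)
  V <- sv$u                                    # (N, n_pc)
  zf <- crossprod(V, X)                        # (n_pc, T*K)
  list(z = array(zf, dim = c(n_pc, d[2], d[3])), basis = V,
       variance_captured = sum(sv$d[seq_len(n_pc)]^2) / sum(sv$d^2))
}

#' Loss of a latent-circuit fit
#'
#' Masked output error \eqn{\langle \|o - \hat{o}\|^2 \rangle} of the
#' latent readout, plus the embedding term
#' \eqn{\lambda_{emb}\langle \|Qx - z\|^2\rangle} (means over all tensor
#' elements), plus \eqn{\lambda_w} times the mean squared latent weights.
#'
#' @param x (n, T, K) latent activity tensor.
#' @param z (N_PC, T, K) reduced target activity.
#' @param outputs (n_out, T, K) latent-circuit outputs \eqn{w_{out} x}.
#' @param targets,mask task targets and mask.
#' @param Q (N_PC, n) orthonormal embedding.
#' @param w_inp,w_rec,w_out latent weights.
#' @param lambda_emb,lambda_w penalty weights.
#' @return scalar loss.
#' @export
latent_loss <- function(x, z, outputs, targets, mask, Q, w_inp, w_rec, w_out,
                        lambda_emb = 1, lambda_w = 0.01) {
  emb <- z - apply(x, c(2, 3), function(v) Q %*% v)
  dim(emb) <- dim(z)
  masked_mse(outputs, targets, mask) +
    lambda_emb * mean(emb^2) +
    lambda_w * (mean(w_inp^2) + mean(w_rec^2) + mean(w_out^2))
}

default_input_mask <- function(n, n_in) {
  if (n < n_in) stop("latent circuit needs at least one node per input channel")
  mask <- matrix(0, n, n_in)
  mask[cbind(seq_len(n_in), seq_len(n_in))] <- 1
  mask
}

reorthonormalize <- function(Q) {
  qr_ <- qr(Q)
  qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))), ncol(Q))
}

latent_forward <- function(w_inp, w_rec, w_out, U, gamma, act) {
  cpp_rnn_forward(w_inp, w_rec, w_out, U, numeric(nrow(w_rec)), gamma,
                  act_kind_code(act), act$slope, 0, 0, FALSE, 0L)
}

# loss + analytic gradients for one latent-fit iteration; the weight
# penalty is added here
latent_loss_grad <- function(w_inp, w_rec, w_out, Q, z, batch, gamma, act,
                             lambda_emb, lambda_w) {
  lg <- cpp_latent_grad(w_inp, w_rec, w_out, Q, z, batch$inputs,
                        batch$targets, batch$mask * 1, gamma,
                        act_kind_code(act), act$slope, lambda_emb)
  list(loss = lg$loss + lambda_w * (mean(w_inp^2) + mean(w_rec^2) +
                                      mean(w_out^2)),
       gw_inp = lg$gw_inp + 2 * lambda_w * w_inp / length(w_inp),
       gw_rec = lg$gw_rec + 2 * lambda_w * w_rec / length(w_rec),
       gw_out = lg$gw_out + 2 * lambda_w * w_out / length(w_out),
       gQ = lg$gQ)
}

#' Fit a latent circuit to reduced network responses
#'
#' Minimizes \code{\link{latent_loss}} over the latent connectivity
#' (\code{w_rec}, \code{w_inp}, \code{w_out}) and the orthonormal embedding
#' \code{Q} with Adam, from multiple random initializations. The latent
#' circuit integrates the same Euler dynamics (same \eqn{\gamma} and
#' activation) as the source network, without noise. Constraints are
#' re-imposed after every step: negative \code{w_inp}/\code{w_out} entries
#' are clipped to zero, masked \code{w_inp} entries (each input channel is
#' wired to exactly one latent node) are re-zeroed, and \code{Q} is
#' re-orthonormalized by QR retraction.
#'
#' The embedding weight is applied relative to the signal power of the
#' reduced activity: the optimizer weights the embedding term so that it
#' equals \code{lambda_emb} times the fraction of unexplained activity
#' power, \eqn{\sum (Qx - z)^2 / \sum z^2}. A given \code{lambda_emb}
#' therefore trades off the same relative embedding error against squared
#' output error for every source network, even though activity amplitudes
#' differ by an order of magnitude across activation functions.
#'
#' @param z reduced activity ((N_PC, T, K) tensor or the list from
#'   \code{\link{reduce_for_fit}}).
#' @param batch the task \code{trial_batch}.
#' @param activation \code{activation_spec} of the source network.
#' @param gamma integration constant dt/tau of the source network.
#' @param n number of latent nodes.
#' @param n_restarts random initializations; best final loss wins.
#' @param n_iter Adam iterations per restart.
#' @param lambda_emb,lambda_w penalty weights.
#' @param lr Adam learning rate at the first iteration.
#' @param lr_end learning rate at the last iteration (geometric decay in
#'   between); defaults to \code{lr} (no decay).
#' @param input_mask (n, n_in) 0/1 matrix; default wires input channel i to
#'   latent node i.
#' @param seed RNG seed.
#' @return object of class \code{latent_fit}: weights, \code{Q}, fit
#'   metrics \code{r2_dynamics}/\code{r2_behaviour}, \code{loss},
#'   \code{restart}, per-restart \code{losses}.
#' @export
fit_latent_circuit <- function(z, batch, activation, gamma = 0.1, n = 8,
                               n_restarts = 30, n_iter = 1000,
                               lambda_emb = 1, lambda_w = 0.01, lr = 0.01,
                               lr_end = lr, input_mask = NULL, seed = 1L) {
  lr_sched <- lr * (lr_end / lr)^(seq_len(n_iter) / n_iter)
  if (is.list(z) && !is.null(z$z)) z <- z$z
  if (is.character(activation)) activation <- activation_spec(activation)
  n_pc <- dim(z)[1]
  n_in <- dim(batch$inputs)[1]
  n_out <- dim(batch$targets)[1]
  if (is.null(input_mask)) input_mask <- default_input_mask(n, n_in)
  lambda_emb_eff <- lambda_emb / mean(z^2)
  best <- NULL
  losses <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    rs <- derive_seed(seed, "latent_restart", r)
    init <- with_seed(rs, {
      list(w_inp = abs(matrix(rnorm(n * n_in, 0, 1 / sqrt(n)), n, n_in)) *
             input_mask,
           w_rec = matrix(rnorm(n * n, 0, 1 / n), n, n),
           w_out = abs(matrix(rnorm(n_out * n, 0, 1 / sqrt(n)), n_out, n)),
           Q = random_orthogonal(n_pc)[, seq_len(n), drop = FALSE])
    })
    w_inp <- init$w_inp; w_rec <- init$w_rec; w_out <- init$w_out; Q <- init$Q
    st <- adam_state(list(w_inp = dim(w_inp), w_rec = dim(w_rec),
                          w_out = dim(w_out), Q = dim(Q)))
    trace <- numeric(n_iter)
    failed <- FALSE
    for (i in seq_len(n_iter)) {
      lg <- latent_loss_grad(w_inp, w_rec, w_out, Q, z, batch, gamma,
                             activation, lambda_emb_eff, lambda_w)
      if (!is.finite(lg$loss)) { failed <- TRUE; break }
      trace[i] <- lg$loss
      for (nm in c("w_inp", "w_rec", "w_out", "Q")) {
        up <- adam_update(st[[nm]], lg[[paste0("g", nm)]], lr_sched[i], i)
        st[[nm]] <- up$state
        assign(nm, get(nm) - up$step)
      }
      w_inp[w_inp < 0] <- 0
      w_inp <- w_inp * input_mask
      w_out[w_out < 0] <- 0
      Q <- reorthonormalize(Q)
    }
    losses[r] <- if (failed) NA_real_ else trace[n_iter]
    if (!failed && (is.null(best) || losses[r] < best$loss)) {
      best <- list(w_inp = w_inp, w_rec = w_rec, w_out = w_out, Q = Q,
                   loss = losses[r], restart = r, trace = trace)
    }
  }
  if (is.null(best)) stop("all latent-circuit restarts diverged")
  fit <- structure(c(best, list(n = n, activation = activation, gamma = gamma,
                                input_mask = input_mask, lambda_emb = lambda_emb,
                                lambda_w = lambda_w, losses = losses,
                                seed = seed)),
                   class = "latent_fit")
  r2 <- score_fit(fit, z, batch)
  fit$r2_dynamics <- r2[["r2_dynamics"]]
  fit$r2_behaviour <- r2[["r2_behaviour"]]
  fit
}

#' @export
print.latent_fit <- function(x, ...) {
  cat(sprintf("<latent_fit> %d nodes (%s), loss %.4g, R2 dynamics %.3f, R2 behaviour %.3f\n",
              x$n, x$activation$kind, x$loss,
              x$r2_dynamics, x$r2_behaviour))
  invisible(x)
}

#' Simulate the latent circuit of a fit
#'
#' @param fit a \code{latent_fit}.
#' @param batch a \code{trial_batch}.
#' @return list with latent \code{activity} (n, T, K) and \code{outputs}.
#' @export
simulate_latent <- function(fit, batch) {
  fw <- latent_forward(fit$w_inp, fit$w_rec, fit$w_out, batch$inputs,
                       fit$gamma, fit$activation)
  list(activity = fw$activity, outputs = fw$outputs)
}

#' Fit quality of a latent circuit
#'
#' Coefficients of determination with a grand-mean baseline:
#' \code{r2_dynamics} between the embedded latent activity \eqn{Qx} and the
#' reduced responses \eqn{z} over all entries, and \code{r2_behaviour}
#' between the latent output \eqn{w_{out} x} and the task targets on
#' masked steps.
#'
#' @param fit a \code{latent_fit}.
#' @param z reduced activity tensor (or \code{reduce_for_fit} output).
#' @param batch the task \code{trial_batch}.
#' @return named numeric vector (r2_dynamics, r2_behaviour).
#' @export
score_fit <- function(fit, z, batch) {
  if (is.list(z) && !is.null(z$z)) z <- z$z
  sim <- simulate_latent(fit, batch)
  K <- dim(z)[3]
  emb <- vapply(seq_len(K), function(k) fit$Q %*% sim$activity[, , k],
                matrix(0, dim(z)[1], dim(z)[2]))
  ss_res <- sum((emb - z)^2)
  ss_tot <- sum((z - mean(z))^2)
  if (ss_tot < 1e-24) stop("zero-variance target activity")
  n_out <- dim(batch$targets)[1]
  midx <- which(array(rep(batch$mask, each = n_out), dim = dim(batch$targets)))
  o <- batch$targets[midx]
  oh <- sim$outputs[midx]
  ss_tot_o <- sum((o - mean(o))^2)
  if (ss_tot_o < 1e-24) stop("zero-variance behavioural target")
  c(r2_dynamics = 1 - ss_res / ss_tot,
    r2_behaviour = 1 - sum((oh - o)^2) / ss_tot_o)
}

#' Save a latent-circuit fit as plain text
#'
#' @param fit a \code{latent_fit}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
save_latent_fit <- function(fit, prefix) {
  for (nm in c("w_inp", "w_rec", "w_out", "Q"))
    utils::write.csv(fit[[nm]], paste0(prefix, "_", nm, ".csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(n = fit$n, activation = unclass(fit$activation), gamma = fit$gamma,
         loss = fit$loss, restart = fit$restart, seed = fit$seed,
         r2_dynamics = fit$r2_dynamics, r2_behaviour = fit$r2_behaviour,
         losses = fit$losses),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
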