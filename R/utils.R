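#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of \code{expr} and restores the
#' previous RNG state afterwards, so seeded helpers do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic splitting rule used by every pipeline stage: a stage name
#' and an index map a master seed to a reproducible, order-independent
#' child seed that is always a valid 32-bit R integer.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @param index integer stream index within the stage.
#' @return an integer seed.
#' @export
derive_seed <- function(master, stage, index = 1L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729 + index * 15485863) %%
               2147483629)
}

# Haar-distributed random orthogonal matrix (QR of a Gaussian matrix with
# sign-fixed R diagonal).
random_orthogonal <- function(d) {
  qr_ <- qr(matrix(rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), d)
}

# Masked mean squared error between output and target tensors (n_out, T, K),
# averaging over masked steps, channels and trials.
masked_mse <- function(outputs, targets, mask) {
  n_out <- dim(outputs)[1]
  midx <- which(array(rep(mask, each = n_out), dim = dim(outputs)))
  mean((outputs[midx] - targets[midx])^2)
}

# flatten (N, T, K) -> (N, T*K) keeping column order t-major within trial
flatten_tensor <- function(Z) {
  d <- dim(Z)
  matrix(Z, d[1], d[2] * d[3])
}
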