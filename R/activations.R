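#' Activation function specification
#'
#' The three single-unit nonlinearities studied by the package: rectified
#' linear, logistic sigmoid with a fixed slope, and hyperbolic tangent.
#' The sigmoid is \eqn{f(x) = 1/(1 + e^{-s x})} with slope \eqn{s = 7.5}
#' by default.
#'
#' @param kind one of \code{"relu"}, \code{"sigmoid"}, \code{"tanh"}.
#' @param slope slope of the sigmoid; ignored for the other kinds.
#' @return an object of class \code{activation_spec}.
#' @examples
#' f <- activation_spec("sigmoid")
#' apply_activation(0, f)  # 0.5
#' @export
activation_spec <- function(kind = c("relu", "sigmoid", "tanh"), slope = 7.5) {
  kind <- match.arg(kind)
  structure(list(kind = kind, slope = slope), class = "activation_spec")
}

act_kind_code <- function(spec) {
  match(spec$kind, c("relu", "sigmoid", "tanh")) - 1L
}

#' Apply an activation function elementwise
#'
#' @param x numeric vector, matrix or array.
#' @param spec an \code{\link{activation_spec}}.
#' @return the transformed object, same shape as \code{x}.
#' @export
apply_activation <- function(x, spec) {
  switch(spec$kind,
    relu = pmax(x, 0),
    sigmoid = 1 / (1 + exp(-spec$slope * x)),
    tanh = tanh(x),
    stop("unknown activation kind: ", spec$kind)
  )
}

#' Derivative of an activation function
#'
#' Evaluated at the pre-activation \code{x} (the argument of f, not its
#' value). For ReLU the derivative at exactly 0 is taken as 0.
#'
#' @inheritParams apply_activation
#' @return elementwise derivative \eqn{f'(x)}.
#' @export
activation_deriv <- function(x, spec) {
  switch(spec$kind,
    relu = as.numeric(x > 0),
    sigmoid = {
      s <- 1 / (1 + exp(-spec$slope * x))
      spec$slope * s * (1 - s)
    },
    tanh = 1 - tanh(x)^2,
    stop("unknown activation kind: ", spec$kind)
  )
}

#' Range of an activation function's image
#' @inheritParams apply_activation
#' @return length-2 numeric vector (lower, upper).
#' @export
activation_range <- function(spec) {
  switch(spec$kind,
    relu = c(0, Inf),
    sigmoid = c(0, 1),
    tanh = c(-1, 1)
  )
}
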