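#' Right-hand side and Jacobian of the RNN flow field
#'
#' For a constant input \code{u}, the autonomous dynamics are
#' \eqn{F(y, u) = -y + f(W_{rec} y + W_{inp} u)} (in units of \eqn{\tau});
#' fixed points are zeros of \eqn{F}. The Jacobian is
#' \eqn{J = -I + \mathrm{diag}(f'(W_{rec} y + W_{inp} u))\, W_{rec}}.
#'
#' @param y state vector.
#' @param u constant input vector.
#' @param params an \code{rnn_params}.
#' @return list with \code{F} (vector) and \code{J} (matrix).
#' @export
rhs_and_jacobian <- function(y, u, params) {
  a <- drop(params$W_rec %*% y + params$W_inp %*% u)
  Fv <- -y + apply_activation(a, params$activation)
  J <- -diag(params$N) + activation_deriv(a, params$activation) * params$W_rec
  list(F = Fv, J = J)
}

# Damped Newton iteration on F(y, u) = 0 with the analytic Jacobian.
# Returns the final iterate and its squared residual (no convergence error:
# failed starts are simply rejected by the acceptance threshold).
newton_solve <- function(y0, u, params, max_iter = 200, accept_tol = 1e-12) {
  y <- y0
  fj <- rhs_and_jacobian(y, u, params)
  r <- sum(fj$F^2)
  for (i in seq_len(max_iter)) {
    if (r <= accept_tol * 1e-4) break
    step <- tryCatch(solve(fj$J, fj$F), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      y_new <- y - alpha * step
      fj_new <- rhs_and_jacobian(y_new, u, params)
      r_new <- sum(fj_new$F^2)
      if (r_new < r || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    if (r_new >= r) break    # damping exhausted; keep the current iterate
    y <- y_new; fj <- fj_new; r <- r_new
    if (max(abs(alpha * step)) < 1e-14) break
  }
  list(y = y, residual = r)
}

#' Find the fixed points of an RNN under one constant input
#'
#' Repeated Newton searches started from randomly sampled trajectory
#' points: a random trial, a random time step in the second half of the
#' trial, plus zero-mean Gaussian noise (variance 0.01) on every
#' coordinate. A candidate is accepted when \eqn{\|F(y^*, u)\|^2 \le
#' 10^{-12}} and discarded when it lies within Euclidean distance
#' \eqn{10^{-7}} of a previously accepted point. The search stops once
#' \code{max_points} distinct fixed points are found or no new point has
#' been found for \code{patience} consecutive starts.
#'
#' @param u constant input vector.
#' @param activity (N, T, K) activity tensor used to seed the searches.
#' @param params an \code{rnn_params}.
#' @param seed RNG seed.
#' @param max_points stop after this many distinct fixed points.
#' @param patience consecutive unproductive starts before stopping.
#' @param accept_tol squared-residual acceptance threshold.
#' @param dedup_tol minimum distance between distinct fixed points.
#' @return list with \code{coords} (n_fp x N matrix), \code{residual},
#'   \code{stability} (character), \code{lambda0} (principal eigenvalue).
#' @export
find_fixed_points_for_input <- function(u, activity, params, seed = 1L,
                                        max_points = 100L, patience = 100L,
                                        accept_tol = 1e-12, dedup_tol = 1e-7) {
  d <- dim(activity)
  stopifnot(d[1] == params$N)
  coords <- NULL
  with_seed(seed, {
    misses <- 0L
    while (is.null(coords) || nrow(coords) < max_points) {
      if (misses >= patience) break
      k <- sample.int(d[3], 1)
      t0 <- sample(seq.int(floor(d[2] / 2) + 1, d[2]), 1)
      y0 <- activity[, t0, k] + rnorm(params$N, 0, 0.1)
      sol <- newton_solve(y0, u, params, accept_tol = accept_tol)
      new_pt <- sol$residual <= accept_tol &&
        (is.null(coords) ||
           min(sqrt(colSums((t(coords) - sol$y)^2))) > dedup_tol)
      if (new_pt) {
        coords <- rbind(coords, sol$y)
        misses <- 0L
      } else misses <- misses + 1L
    }
  })
  if (is.null(coords)) {
    warning("no fixed points accepted for this input")
    return(list(coords = matrix(0, 0, params$N), residual = numeric(0),
                stability = character(0), lambda0 = complex(0)))
  }
  rownames(coords) <- NULL
  res <- apply(coords, 1, function(y)
    sum(rhs_and_jacobian(y, u, params)$F^2))
  cls <- lapply(seq_len(nrow(coords)), function(i)
    classify_stability(coords[i, ], u, params))
  list(coords = coords, residual = res,
       stability = vapply(cls, `[[`, "", "stability"),
       lambda0 = vapply(cls, `[[`, complex(1), "lambda0"))
}

#' Classify the stability of a fixed point
#'
#' Computes the principal eigenvalue \eqn{\lambda_0} (largest real part,
#' ties broken by larger imaginary magnitude) of the Jacobian at the fixed
#' point; the point is stable iff \eqn{\Re(\lambda_0) \le 0}.
#'
#' @param y fixed-point coordinates.
#' @param u constant input under which the point was found.
#' @param params an \code{rnn_params}.
#' @return list with \code{stability} ("stable"/"unstable") and
#'   \code{lambda0}.
#' @export
classify_stability <- function(y, u, params) {
  ev <- eigen(rhs_and_jacobian(y, u, params)$J, only.values = TRUE)$values
  ord <- order(-Re(ev), -abs(Im(ev)))
  lambda0 <- ev[ord[1]]
  list(stability = if (Re(lambda0) <= 0) "stable" else "unstable",
       lambda0 = as.complex(lambda0))
}

#' Constant-input survey conditions for a task
#'
#' For the CDDM task: both contexts crossed with five relevant and five
#' irrelevant coherences (default \{-1, -0.25, 0, 0.25, 1\} each), 50 input
#' combinations in total, with context and all four sensory channels held
#' constant. For the Go/NoGo and memory tasks: every training input value
#' with the Go cue off and on.
#'
#' @param task task id.
#' @param rel_grid,irr_grid coherence values for the CDDM survey.
#' @param values input values for the Go/NoGo and memory surveys.
#' @return list with \code{inputs} (n_in x n_cond matrix) and
#'   \code{conditions} (data.frame, one row per input).
#' @export
survey_conditions <- function(task = c("cddm", "gonogo", "memory"),
                              rel_grid = c(-1, -0.25, 0, 0.25, 1),
                              irr_grid = rel_grid,
                              values = seq(0, 1, length.out = 11)) {
  task <- match.arg(task)
  if (task == "cddm") {
    conds <- expand.grid(context = c("motion", "colour"), c_rel = rel_grid,
                         c_irr = irr_grid, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    inputs <- vapply(seq_len(nrow(conds)), function(i) {
      motion_first <- conds$context[i] == "motion"
      c_mot <- if (motion_first) conds$c_rel[i] else conds$c_irr[i]
      c_col <- if (motion_first) conds$c_irr[i] else conds$c_rel[i]
      c(if (motion_first) c(1, 0) else c(0, 1),
        coherence_to_channels(c_mot), coherence_to_channels(c_col))
    }, numeric(6))
  } else {
    conds <- expand.grid(value = values, go_cue = c(0, 1),
                         KEEP.OUT.ATTRS = FALSE)
    inputs <- rbind(conds$value, conds$go_cue, 1)
  }
  conds$input_id <- seq_len(nrow(conds))
  list(inputs = inputs, conditions = conds)
}

#' Survey the fixed points of an RNN across task input conditions
#'
#' Runs \code{\link{find_fixed_points_for_input}} for every constant input
#' of \code{\link{survey_conditions}} and aggregates the results, tagging
#' every fixed point by its input condition and stability.
#'
#' @param params an \code{rnn_params}.
#' @param task task id.
#' @param activity (N, T, K) activity tensor used to seed the searches
#'   (a noiseless simulation of the training batch).
#' @param seed RNG seed.
#' @param survey optional precomputed \code{\link{survey_conditions}}.
#' @param ... passed to \code{\link{find_fixed_points_for_input}}.
#' @return object of class \code{fp_survey}: \code{coords} (N_p x N),
#'   \code{tags} data.frame (input condition, stability, residual),
#'   \code{conditions}.
#' @export
fixed_point_survey <- function(params, task, activity, seed = 1L,
                               survey = survey_conditions(task), ...) {
  coords <- NULL
  tags <- NULL
  for (i in seq_len(ncol(survey$inputs))) {
    fps <- suppressWarnings(find_fixed_points_for_input(
      survey$inputs[, i], activity, params,
      seed = derive_seed(seed, "fp_input", i), ...))
    if (nrow(fps$coords) == 0) next
    coords <- rbind(coords, fps$coords)
    tg <- survey$conditions[rep(i, nrow(fps$coords)), , drop = FALSE]
    tg$stability <- fps$stability
    tg$residual <- fps$residual
    tags <- rbind(tags, tg)
  }
  if (is.null(coords)) coords <- matrix(0, 0, params$N)
  rownames(tags) <- NULL
  structure(list(coords = coords, tags = tags,
                 conditions = survey$conditions, task = task),
            class = "fp_survey")
}

#' Export a fixed-point survey as a flat table
#'
#' @param survey an \code{fp_survey}.
#' @param net_id identifier column value.
#' @return data.frame with tag columns followed by coordinate columns.
#' @export
fp_survey_table <- function(survey, net_id = 1L) {
  if (nrow(survey$coords) == 0) return(data.frame())
  co <- as.data.frame(survey$coords)
  names(co) <- paste0("coord_", seq_len(ncol(co)) - 1)
  cbind(data.frame(net_id = net_id), survey$tags, co)
}
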