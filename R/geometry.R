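# Representation summaries and pairwise distances between networks.
#
# All four summaries are variance-normalized after PCA so that summaries
# from different networks share a common scale: every summary is divided by
# the square root of its total variance, giving unit total variance.

pca_scores <- function(X, n_pc, center = TRUE) {
  # rows of X are observations
  if (nrow(X) < n_pc)
    stop("fewer observations (", nrow(X), ") than components (", n_pc, ")")
  if (all(apply(X, 2, stats::sd) < 1e-12))
    stop("degenerate (zero-variance) data; cannot compute components")
  p <- stats::prcomp(X, center = center, scale. = FALSE)
  n_pc <- min(n_pc, ncol(p$x))
  list(scores = p$x[, seq_len(n_pc), drop = FALSE],
       rotation = p$rotation[, seq_len(n_pc), drop = FALSE],
       variance_captured = sum(p$sdev[seq_len(n_pc)]^2) / sum(p$sdev^2))
}

total_variance <- function(S) sum(apply(S, 2, stats::var))

normalize_variance <- function(S) {
  v <- total_variance(S)
  if (v < 1e-24) stop("degenerate summary: zero total variance")
  S / sqrt(v)
}

#' Reduced population trajectories of a network
#'
#' Reshapes the (N, T, K) activity tensor to (N, T*K), projects the unit
#' axis onto the first \code{n_pc} principal components (computed across
#' the T*K population-state samples), and variance-normalizes so summaries
#' from different networks share scale.
#'
#' @param Z a \code{response_tensor} or (N, T, K) array.
#' @param n_pc number of components (10 in the full study).
#' @return object with \code{reduced} ((n_pc, T, K) tensor), \code{F}
#'   (n_pc x T*K matrix used for distances), \code{variance_captured}.
#' @export
reduce_trajectories <- function(Z, n_pc = 10) {
  A <- if (inherits(Z, "response_tensor")) Z$activity else Z
  d <- dim(A)
  X <- flatten_tensor(A)                       # (N, T*K)
  p <- pca_scores(t(X), n_pc)                  # samples = population states
  Fm <- normalize_variance(p$scores)           # (T*K, n_pc)
  structure(list(reduced = array(t(Fm), dim = c(ncol(Fm), d[2], d[3])),
                 F = Fm, variance_captured = p$variance_captured,
                 n_pc = ncol(Fm)),
            class = "trajectory_summary")
}

#' Reduced single-unit selectivity of a network
#'
#' Each unit's tuning profile (a row of the (N, T*K) response matrix) is
#' projected onto the first \code{n_pc} principal components of the
#' time-by-trial axis, giving one point per unit in selectivity space.
#'
#' @inheritParams reduce_trajectories
#' @return object with \code{G} (N x n_pc matrix, one row per unit) and
#'   \code{variance_captured}.
#' @export
reduce_selectivity <- function(Z, n_pc = 10) {
  A <- if (inherits(Z, "response_tensor")) Z$activity else Z
  X <- flatten_tensor(A)                       # rows = units
  p <- pca_scores(X, n_pc)
  structure(list(G = normalize_variance(p$scores),
                 variance_captured = p$variance_captured, n_pc = ncol(p$scores)),
            class = "selectivity_summary")
}

#' Reduced trajectory-endpoint configuration of a network
#'
#' Takes the network state at the last time step of each trial (a (K, N)
#' matrix), projects onto the first \code{n_pc} principal components and
#' variance-normalizes.
#'
#' @inheritParams reduce_trajectories
#' @return object with \code{S} (K x n_pc) and \code{variance_captured}.
#' @export
reduce_endpoints <- function(Z, n_pc = 10) {
  A <- if (inherits(Z, "response_tensor")) Z$activity else Z
  d <- dim(A)
  S <- t(A[, d[2], , drop = TRUE])             # (K, N)
  p <- pca_scores(S, n_pc)
  structure(list(S = normalize_variance(p$scores),
                 variance_captured = p$variance_captured, n_pc = ncol(p$scores)),
            class = "endpoint_summary")
}

#' Projected fixed-point configuration of a network
#'
#' Projects the (N_p, N) fixed-point coordinate matrix of a survey onto its
#' first \code{n_pc} principal components (7 in the full study),
#' variance-normalizes, and carries every point's (input condition,
#' stability) tag through the projection.
#'
#' @param survey an \code{fp_survey}.
#' @param n_pc number of components.
#' @return object with \code{P} (N_p x n_pc), \code{tags}, and
#'   \code{variance_captured}.
#' @export
project_fixed_points <- function(survey, n_pc = 7) {
  if (nrow(survey$coords) < n_pc)
    stop("fewer fixed points than requested components")
  p <- pca_scores(survey$coords, n_pc)
  structure(list(P = normalize_variance(p$scores), tags = survey$tags,
                 variance_captured = p$variance_captured, n_pc = ncol(p$scores)),
            class = "fixedpoint_summary")
}

# integer tag combining input condition and stability, for tag-restricted
# ICP matching
fp_match_tags <- function(tags) {
  as.integer(interaction(tags$input_id, tags$stability, drop = FALSE))
}

#' Regression distance between two trajectory (or endpoint) summaries
#'
#' Fits the least-squares linear map (no intercept) from summary i to
#' summary j and vice versa; each score is the residual mean squared error,
#' and the distance is the average of the two scores, making it symmetric
#' by construction. The distance is zero whenever the two summaries are
#' related by an invertible linear map.
#'
#' @param Fi,Fj summaries (\code{trajectory_summary}, \code{endpoint_summary}
#'   or plain sample-by-component matrices on the same sample grid).
#' @return non-negative scalar.
#' @export
trajectory_distance <- function(Fi, Fj) {
  Ai <- if (is.matrix(Fi)) Fi else if (inherits(Fi, "endpoint_summary")) Fi$S else Fi$F
  Aj <- if (is.matrix(Fj)) Fj else if (inherits(Fj, "endpoint_summary")) Fj$S else Fj$F
  if (!all(dim(Ai) == dim(Aj))) stop("summary shape mismatch")
  res_mse <- function(A, B) {
    M <- qr.solve(A, B)
    mean((A %*% M - B)^2)
  }
  (res_mse(Ai, Aj) + res_mse(Aj, Ai)) / 2
}

#' Iterative-closest-point distance between two point clouds
#'
#' Registers the source cloud onto the target with an orthogonal transform:
#' random orthogonal initialization, closest-point matching (one-to-many
#' matches allowed; restricted to equal tags when tags are given),
#' orthogonal-Procrustes update, iterated to convergence. Each direction
#' keeps the minimum mean squared mismatch over \code{n_tries} random
#' restarts; the distance is the average of the two directional scores.
#'
#' @param Pi,Pj point clouds (n_i x d and n_j x d matrices), or
#'   \code{selectivity_summary} / \code{fixedpoint_summary} objects.
#' @param tags_i,tags_j optional integer tag per point; taken from
#'   fixed-point summaries automatically.
#' @param n_tries random restarts per direction.
#' @param seed RNG seed.
#' @param max_iter,tol ICP convergence controls.
#' @return non-negative scalar.
#' @export
icp_distance <- function(Pi, Pj, tags_i = NULL, tags_j = NULL, n_tries = 60,
                         seed = 1L, max_iter = 100, tol = 1e-6) {
  unpack <- function(P, tags) {
    if (inherits(P, "selectivity_summary")) P <- P$G
    if (inherits(P, "fixedpoint_summary")) {
      tags <- fp_match_tags(P$tags); P <- P$P
    }
    list(P = P, tags = tags)
  }
  a <- unpack(Pi, tags_i); b <- unpack(Pj, tags_j)
  if (nrow(a$P) == 0 || nrow(b$P) == 0) stop("empty point cloud")
  if (ncol(a$P) != ncol(b$P)) stop("point clouds differ in dimension")
  tagged <- !is.null(a$tags) && !is.null(b$tags)
  if (tagged) {
    # harmonize tag levels across the two clouds
    lv <- union(a$tags, b$tags)
    ta <- match(a$tags, lv); tb <- match(b$tags, lv)
  } else ta <- tb <- integer(0)
  register <- function(src, tsrc, tgt, ttgt) {
    if (tagged) {
      keep <- ttgt %in% tsrc
      if (!all(keep)) {
        warning("excluding ", sum(!keep),
                " target points whose tag has no counterpart in the source")
        tgt <- tgt[keep, , drop = FALSE]; ttgt <- ttgt[keep]
      }
      if (nrow(tgt) == 0) stop("no tag overlap between point clouds")
    }
    cpp_icp_register(src, tgt, as.integer(tsrc), as.integer(ttgt),
                     as.integer(n_tries), as.integer(max_iter), tol)
  }
  with_seed(seed, {
    s1 <- register(a$P, ta, b$P, tb)
    s2 <- register(b$P, tb, a$P, ta)
  })
  (s1 + s2) / 2
}

#' Pairwise distance matrix over a list of network summaries
#'
#' @param summaries list of summaries, all of one kind.
#' @param metric "trajectory"/"endpoint" (regression distance) or
#'   "selectivity"/"fixedpoint" (ICP distance).
#' @param seed RNG seed (ICP metrics).
#' @param ... passed to the underlying distance.
#' @return symmetric non-negative matrix with zero diagonal.
#' @export
distance_matrix <- function(summaries,
                            metric = c("trajectory", "selectivity",
                                       "fixedpoint", "endpoint"),
                            seed = 1L, ...) {
  metric <- match.arg(metric)
  M <- length(summaries)
  D <- matrix(0, M, M)
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (j <= i) next
    D[i, j] <- D[j, i] <- if (metric %in% c("trajectory", "endpoint"))
      trajectory_distance(summaries[[i]], summaries[[j]])
    else icp_distance(summaries[[i]], summaries[[j]],
                      seed = derive_seed(seed, "icp_pair", i * M + j), ...)
  }
  attr(D, "metric") <- metric
  D
}

#' Metric multidimensional-scaling embedding of a distance matrix
#'
#' Metric MDS by SMACOF majorization (Guttman transform), with one start
#' from the classical-scaling solution plus random restarts; the solution
#' with the lowest stress-1 is kept. Deterministic given \code{seed}.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param n_dim embedding dimension.
#' @param seed RNG seed.
#' @param n_restarts random restarts (besides the classical start).
#' @param max_iter Guttman iterations per start.
#' @param tol relative stress-improvement stopping threshold.
#' @return list with \code{points} (M x n_dim) and \code{stress}
#'   (stress-1).
#' @export
embed_mds <- function(D, n_dim = 2, seed = 1L, n_restarts = 8,
                      max_iter = 500, tol = 1e-9) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  M <- nrow(D)
  denom <- sum(D^2)
  stress1 <- function(X) {
    E <- as.matrix(stats::dist(X))
    sqrt(sum((E - D)^2) / denom)
  }
  smacof <- function(X) {
    s_prev <- stress1(X)
    for (i in seq_len(max_iter)) {
      E <- as.matrix(stats::dist(X))
      B <- ifelse(E > 1e-12, -D / pmax(E, 1e-12), 0)
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / M
      s <- stress1(X)
      if (s_prev - s < tol * max(s_prev, 1e-12)) break
      s_prev <- s
    }
    list(X = X, stress = stress1(X))
  }
  starts <- with_seed(seed, {
    cls <- suppressWarnings(stats::cmdscale(D, k = n_dim))
    if (ncol(cls) < n_dim)
      cls <- cbind(cls, matrix(0, M, n_dim - ncol(cls)))
    c(list(cls), lapply(seq_len(n_restarts), function(i)
      matrix(rnorm(M * n_dim), M, n_dim) * stats::median(D)))
  })
  fits <- lapply(starts, smacof)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "stress"))]]
  list(points = best$X, stress = best$stress)
}
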