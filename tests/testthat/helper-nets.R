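# Shared fixtures: small trained networks are expensive, so they are built
# once per session and memoised here. Scaled-down study conditions used
# throughout the suite:
#   - bulk cache (architecture comparisons): N = 30 units, CDDM with the
#     {-1, 0, 1} coherence grid (18 conditions), 800 training iterations;
#   - focused cache (latent circuits, psychometrics): N = 30, CDDM with the
#     {-1, -0.25, 0, 0.25, 1} grid (50 conditions), 2000 iterations.

.net_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.net_cache[[key]])) .net_cache[[key]] <- builder()
  .net_cache[[key]]
}

cddm_batch_3 <- function() {
  cache_get("batch3", function()
    build_cddm_batch(enumerate_cddm_conditions(c(-1, 0, 1))))
}

cddm_batch_5 <- function() {
  cache_get("batch5", function()
    build_cddm_batch(enumerate_cddm_conditions(c(-1, -0.25, 0, 0.25, 1))))
}

# one trained net per (architecture, master seed, replicate) on the 3-value
# grid; used by the embedding/silhouette analyses
bulk_net <- function(activation, dale, master_seed, rep) {
  key <- sprintf("bulk_%s_%d_%d_%d", activation, dale, master_seed, rep)
  cache_get(key, function() {
    idx <- match(activation, c("relu", "sigmoid", "tanh")) + 10 * dale
    p0 <- initialize_rnn(activation, dale, N = 30, n_in = 6, n_out = 2,
                         seed = derive_seed(master_seed, "bulk_init",
                                            100 * idx + rep))
    train_rnn(p0, cddm_batch_3(), lambda_r = 0.5, n_iter = 800L,
              seed = derive_seed(master_seed, "bulk_train",
                                 100 * idx + rep))$params
  })
}

# well-trained nets on the 5-value grid for latent-circuit and
# out-of-distribution analyses
focused_net <- function(activation, rep) {
  key <- sprintf("focused_%s_%d", activation, rep)
  cache_get(key, function() {
    p0 <- initialize_rnn(activation, TRUE, N = 30, n_in = 6, n_out = 2,
                         seed = 10 * rep + match(activation,
                                                 c("relu", "sigmoid", "tanh")))
    train_rnn(p0, cddm_batch_5(), lambda_r = 0.5, n_iter = 2000L,
              seed = 300 + rep)$params
  })
}

# one larger net at the scale used for the variance-capture checks
variance_net <- function() {
  cache_get("variance_net", function() {
    p0 <- initialize_rnn("tanh", FALSE, N = 50, n_in = 6, n_out = 2, seed = 21)
    train_rnn(p0, cddm_batch_5(), lambda_r = 0.5, n_iter = 600L,
              seed = 22)$params
  })
}

# scalar bisection oracle: all roots of -y + f(w y + u) on [-3, 3]
bisect_fixed_points <- function(w, u, spec, lower = -3, upper = 3,
                                n_grid = 6000) {
  g <- function(y) -y + apply_activation(w * y + u, spec)
  ys <- seq(lower, upper, length.out = n_grid)
  gs <- vapply(ys, g, 0)
  roots <- numeric(0)   # stays empty when the flow has no fixed point
  for (i in seq_len(n_grid - 1)) {
    if (gs[i] == 0) roots <- c(roots, ys[i])
    else if (gs[i] * gs[i + 1] < 0)
      roots <- c(roots, stats::uniroot(g, c(ys[i], ys[i + 1]),
                                       tol = 1e-12)$root)
  }
  unique(round(roots, 9))
}

# synthetic rank-r response tensor with reproducible structure
synthetic_response <- function(N = 12, T_steps = 20, K = 6, rank = 2,
                               seed = 1) {
  with_seed(seed, {
    U <- matrix(rnorm(N * rank), N, rank)
    V <- matrix(rnorm(rank * T_steps * K), rank, T_steps * K)
    array(U %*% V, dim = c(N, T_steps, K))
  })
}
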