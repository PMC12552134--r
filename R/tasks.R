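#' @useDynLib actbias, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm prcomp sd median quantile coef lm
#' @importFrom utils write.csv modifyList
NULL

# Time convention used throughout: dt = 1 ms, 0-based time on a half-open
# grid. Step index i (1-based, R) covers the time interval [i-1, i) ms, so
# "t < 100 ms" means indices 1..100 and "from 200 ms onwards" means 201..T.

#' Training grid of stimulus coherences
#'
#' The 15 signed coherence values used to build training stimuli:
#' 0, ±0.01, ±0.03, ±0.06, ±0.13, ±0.25, ±0.5, ±1. The grid is symmetric
#' about zero and spans the full [-1, 1] range.
#'
#' @return sorted numeric vector of length 15.
#' @export
coherence_grid <- function() {
  base <- c(0.01, 0.03, 0.06, 0.13, 0.25, 0.5, 1)
  sort(c(-base, 0, base))
}

#' Map a signed coherence to two non-negative sensory channels
#'
#' A coherence \eqn{c \in [-1, 1]} drives two channels with amplitudes
#' \eqn{((1+c)/2, (1-c)/2)}: momentary evidence for the right and left
#' choice. The two amplitudes are non-negative and sum to 1.
#'
#' @param c signed coherence.
#' @param ood allow values outside [-1, 1] (out-of-distribution probes,
#'   where channel amplitudes may exceed the training range).
#' @return numeric vector \code{c(right, left)}.
#' @examples
#' coherence_to_channels(0)     # 0.5 0.5
#' coherence_to_channels(-0.5)  # 0.25 0.75
#' @export
coherence_to_channels <- function(c, ood = FALSE) {
  if (!ood && any(c < -1 | c > 1))
    stop("coherence outside [-1, 1]; set ood = TRUE for out-of-distribution probes")
  cbind(right = (1 + c) / 2, left = (1 - c) / 2)
}

#' Enumerate context-dependent decision-making trial conditions
#'
#' Cartesian product of the two contexts with a motion and a colour
#' coherence grid. With the full 15-value training grid this yields
#' 2 x 15 x 15 = 450 distinct conditions.
#'
#' @param grid coherence values, all distinct, in [-1, 1].
#' @return data.frame with columns \code{context}, \code{c_motion},
#'   \code{c_colour}; one row per condition.
#' @export
enumerate_cddm_conditions <- function(grid = coherence_grid()) {
  if (length(grid) == 0) stop("empty coherence grid")
  if (anyDuplicated(grid)) stop("duplicate values in coherence grid")
  if (any(grid < -1 | grid > 1)) stop("coherence grid values must lie in [-1, 1]")
  conds <- expand.grid(context = c("motion", "colour"), c_motion = grid,
                       c_colour = grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  conds[order(conds$context, conds$c_motion, conds$c_colour), , drop = FALSE]
}

new_trial_batch <- function(task, inputs, targets, mask, labels, dt = 1) {
  stopifnot(is.array(inputs), length(dim(inputs)) == 3L,
            dim(inputs)[2] == dim(targets)[2], dim(inputs)[3] == dim(targets)[3],
            nrow(mask) == dim(inputs)[2], ncol(mask) == dim(inputs)[3],
            nrow(labels) == dim(inputs)[3])
  structure(list(task = task, inputs = inputs, targets = targets,
                 mask = mask, labels = labels, dt = dt),
            class = "trial_batch")
}

#' @export
print.trial_batch <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf("<trial_batch: %s>  %d input channels x %d steps x %d trials\n",
              x$task, d[1], d[2], d[3]))
  invisible(x)
}

#' Build a context-dependent decision-making trial batch
#'
#' Six input channels: two mutually exclusive context cues (motion, colour),
#' then right/left evidence channels for the motion and colour modalities.
#' The context cue is on (amplitude 1) for the whole trial; sensory channels
#' switch on at \code{sensory_onset}. Two output channels (right, left):
#' when the coherence of the cued modality is positive the right target is 1
#' from 200 ms onwards, when negative the left target is 1, and when exactly
#' zero both stay 0. The training mask covers [0, 100) and [200, 300) ms,
#' leaving an unpenalized integration period in between.
#'
#' @param conditions data.frame as returned by
#'   \code{\link{enumerate_cddm_conditions}}.
#' @param T_steps trial duration in steps (1 ms each).
#' @param sensory_onset time (ms) at which sensory channels switch on.
#' @param ood allow coherences outside [-1, 1].
#' @return a \code{trial_batch}; input tensor (6, T, K), targets (2, T, K).
#' @export
build_cddm_batch <- function(conditions = enumerate_cddm_conditions(),
                             T_steps = 300, sensory_onset = 100, ood = FALSE) {
  stopifnot(sensory_onset < T_steps)
  if (!all(conditions$context %in% c("motion", "colour")))
    stop("context must be 'motion' or 'colour'")
  K <- nrow(conditions)
  inputs <- array(0, dim = c(6, T_steps, K),
                  dimnames = list(c("ctx_motion", "ctx_colour", "mot_right",
                                    "mot_left", "col_right", "col_left"),
                                  NULL, NULL))
  targets <- array(0, dim = c(2, T_steps, K),
                   dimnames = list(c("right", "left"), NULL, NULL))
  sens_idx <- (sensory_onset + 1):T_steps
  dec_idx <- if (T_steps > 200) 201:T_steps else integer(0)
  mot <- coherence_to_channels(conditions$c_motion, ood = ood)
  col <- coherence_to_channels(conditions$c_colour, ood = ood)
  for (k in seq_len(K)) {
    ctx <- conditions$context[k]
    inputs[if (ctx == "motion") 1 else 2, , k] <- 1
    inputs[3, sens_idx, k] <- mot[k, 1]
    inputs[4, sens_idx, k] <- mot[k, 2]
    inputs[5, sens_idx, k] <- col[k, 1]
    inputs[6, sens_idx, k] <- col[k, 2]
    c_rel <- if (ctx == "motion") conditions$c_motion[k] else conditions$c_colour[k]
    if (length(dec_idx)) {
      if (c_rel > 0) targets[1, dec_idx, k] <- 1
      if (c_rel < 0) targets[2, dec_idx, k] <- 1
    }
  }
  mask <- matrix(FALSE, T_steps, K)
  mask[1:min(100, T_steps), ] <- TRUE
  if (length(dec_idx)) mask[dec_idx, ] <- TRUE
  new_trial_batch("cddm", inputs, targets, mask, as.data.frame(conditions))
}

heaviside_half <- function(x) ifelse(x > 0, 1, ifelse(x < 0, 0, 0.5))

#' Build a Go/NoGo trial batch
#'
#' Three input channels: the input value (constant over the trial), a Go
#' cue sustained at amplitude 1 from \code{t_go_cue} to trial end, and a
#' constant bias of 1. The single output target is 0 before the cue and a
#' step function of the input value afterwards: 1 if the value exceeds 0.5,
#' 0 if below, 0.5 at exactly 0.5. The mask covers every step except a
#' 5-step grace window after cue onset.
#'
#' @param values input values in [0, 1]; default 11 uniformly spaced.
#' @param t_go_cue Go-cue onset (ms).
#' @param T_steps trial duration in steps.
#' @return a \code{trial_batch} with input tensor (3, T, K).
#' @export
build_gonogo_batch <- function(values = seq(0, 1, length.out = 11),
                               t_go_cue = 30, T_steps = 60) {
  if (t_go_cue >= T_steps) stop("t_go_cue must be before trial end")
  if (any(values < 0 | values > 1)) stop("input values must lie in [0, 1]")
  K <- length(values)
  inputs <- array(0, dim = c(3, T_steps, K),
                  dimnames = list(c("value", "go_cue", "bias"), NULL, NULL))
  targets <- array(0, dim = c(1, T_steps, K))
  cue_idx <- (t_go_cue + 1):T_steps
  for (k in seq_len(K)) {
    inputs[1, , k] <- values[k]
    inputs[2, cue_idx, k] <- 1
    inputs[3, , k] <- 1
    targets[1, cue_idx, k] <- heaviside_half(values[k] - 0.5)
  }
  mask <- matrix(TRUE, T_steps, K)
  grace <- (t_go_cue + 1):min(t_go_cue + 5, T_steps)
  mask[grace, ] <- FALSE
  new_trial_batch("gonogo", inputs, targets, mask,
                  data.frame(value = values, t_go_cue = t_go_cue))
}

#' Build a memory-number trial batch
#'
#' The input value is presented for only 10 ms starting at a randomized
#' onset drawn uniformly from [0, 20] ms; the network must report the value
#' after a Go cue at \code{t_go_cue}. Channel layout and masking follow
#' \code{\link{build_gonogo_batch}}.
#'
#' @param values input values in [0, 1].
#' @param t_go_cue Go-cue onset (ms).
#' @param T_steps trial duration in steps.
#' @param seed RNG seed for the stimulus onsets.
#' @return a \code{trial_batch}; labels record each trial's onset.
#' @export
build_memory_batch <- function(values = seq(0, 1, length.out = 11),
                               t_go_cue = 70, T_steps = 100, seed = 1L) {
  if (t_go_cue >= T_steps) stop("t_go_cue must be before trial end")
  if (any(values < 0 | values > 1)) stop("input values must lie in [0, 1]")
  K <- length(values)
  onsets <- with_seed(seed, sample(0:20, K, replace = TRUE))
  inputs <- array(0, dim = c(3, T_steps, K),
                  dimnames = list(c("value", "go_cue", "bias"), NULL, NULL))
  targets <- array(0, dim = c(1, T_steps, K))
  cue_idx <- (t_go_cue + 1):T_steps
  for (k in seq_len(K)) {
    stim_idx <- (onsets[k] + 1):min(onsets[k] + 10, T_steps)
    inputs[1, stim_idx, k] <- values[k]
    inputs[2, cue_idx, k] <- 1
    inputs[3, , k] <- 1
    targets[1, cue_idx, k] <- values[k]
  }
  mask <- matrix(TRUE, T_steps, K)
  grace <- (t_go_cue + 1):min(t_go_cue + 5, T_steps)
  mask[grace, ] <- FALSE
  new_trial_batch("memory", inputs, targets, mask,
                  data.frame(value = values, t_stim = onsets,
                             t_go_cue = t_go_cue))
}

#' Random pulse schedules for the flip-flop task
#'
#' @param n_bits number of independent memory bits.
#' @param T_steps trial duration in steps.
#' @param n_pulses pulses per bit per trial.
#' @param n_trials number of trials.
#' @param pulse_width pulse duration in steps.
#' @param seed RNG seed.
#' @return list of per-trial data.frames with columns bit, onset, sign.
#' @export
random_flipflop_pulses <- function(n_bits = 3, T_steps = 200, n_pulses = 3,
                                   n_trials = 8, pulse_width = 5, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_trials), function(k) {
      do.call(rbind, lapply(seq_len(n_bits), function(b) {
        slots <- sort(sample.int(floor(T_steps / (2 * pulse_width)) - 1, n_pulses))
        data.frame(bit = b, onset = slots * 2 * pulse_width,
                   sign = sample(c(-1, 1), n_pulses, replace = TRUE))
      }))
    })
  })
}

#' Build a 3-bit flip-flop trial batch
#'
#' Each input channel carries transient +1/-1 pulses; the matching output
#' must hold the sign of the last pulse on that channel until the next
#' pulse, starting from 0 before any pulse arrives.
#'
#' @param pulse_sets list of per-trial data.frames (columns \code{bit},
#'   \code{onset} in ms, \code{sign} in \{-1, +1\}).
#' @param n_bits number of bits (input and output channels).
#' @param T_steps trial duration in steps.
#' @param pulse_width pulse duration in steps.
#' @return a \code{trial_batch} with (n_bits, T, K) inputs and targets.
#' @export
build_flipflop_batch <- function(pulse_sets = random_flipflop_pulses(),
                                 n_bits = 3, T_steps = 200, pulse_width = 5) {
  K <- length(pulse_sets)
  inputs <- array(0, dim = c(n_bits, T_steps, K))
  targets <- array(0, dim = c(n_bits, T_steps, K))
  for (k in seq_len(K)) {
    ps <- pulse_sets[[k]]
    if (!all(ps$sign %in% c(-1, 1))) stop("pulse amplitudes must be -1 or +1")
    for (b in seq_len(n_bits)) {
      pb <- ps[ps$bit == b, , drop = FALSE]
      if (nrow(pb) == 0) next
      pb <- pb[order(pb$onset), , drop = FALSE]
      ends <- pb$onset + pulse_width
      if (any(pb$onset[-1] < ends[-nrow(pb)]))
        stop("overlapping pulses on bit ", b)
      for (p in seq_len(nrow(pb))) {
        idx <- (pb$onset[p] + 1):min(ends[p], T_steps)
        inputs[b, idx, k] <- pb$sign[p]
        if (ends[p] < T_steps)
          targets[b, (ends[p] + 1):T_steps, k] <- pb$sign[p]
      }
    }
  }
  mask <- matrix(TRUE, T_steps, K)
  labels <- data.frame(trial = seq_len(K),
                       n_pulses = vapply(pulse_sets, nrow, 1L))
  new_trial_batch("flipflop", inputs, targets, mask, labels)
}

#' Save / load a trial batch as a plain-text archive
#'
#' Writes the input, target and mask tensors to a flat CSV and the trial
#' labels plus tensor dimensions to a JSON sidecar, so batches can be read
#' outside R.
#'
#' @param batch a \code{trial_batch}.
#' @param path output path prefix; \code{<path>.csv} and \code{<path>.json}
#'   are written.
#' @return \code{path}, invisibly.
#' @export
save_batch <- function(batch, path) {
  arr <- data.frame(inputs = as.vector(batch$inputs))
  utils::write.csv(arr, paste0(path, "_inputs.csv"), row.names = FALSE)
  utils::write.csv(data.frame(targets = as.vector(batch$targets)),
                   paste0(path, "_targets.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mask = as.integer(batch$mask)),
                   paste0(path, "_mask.csv"), row.names = FALSE)
  meta <- list(task = batch$task, dt = batch$dt,
               dim_inputs = dim(batch$inputs), dim_targets = dim(batch$targets),
               dim_mask = dim(batch$mask), labels = batch$labels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_batch
#' @export
load_batch <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  inputs <- array(utils::read.csv(paste0(path, "_inputs.csv"))$inputs,
                  dim = meta$dim_inputs)
  targets <- array(utils::read.csv(paste0(path, "_targets.csv"))$targets,
                   dim = meta$dim_targets)
  mask <- matrix(utils::read.csv(paste0(path, "_mask.csv"))$mask == 1,
                 meta$dim_mask[1], meta$dim_mask[2])
  new_trial_batch(meta$task, inputs, targets, mask,
                  as.data.frame(meta$labels), dt = meta$dt)
}
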