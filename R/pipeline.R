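# Study orchestration: train networks for every architecture, produce
# shuffled-connectivity controls, simulate, compute the four representation
# summaries and their distance matrices, MDS embeddings, fixed points,
# latent circuits and behavioural metrics, with per-stage seeds derived
# from one master seed.

#' The six RNN architectures of the study
#'
#' @return data.frame with columns \code{activation}, \code{dale},
#'   \code{label}.
#' @export
study_architectures <- function() {
  g <- expand.grid(activation = c("relu", "sigmoid", "tanh"),
                   dale = c(TRUE, FALSE), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g$label <- paste0(g$activation, ifelse(g$dale, "_dale", "_nodale"))
  g
}

#' Build an experiment configuration
#'
#' The \code{"paper"} profile matches the full study conditions (100-unit
#' networks, the printed iteration counts, 100 networks per architecture);
#' the \code{"scaled_down"} profile is a reduced set suitable for a
#' workstation (50-unit networks, 1500 iterations, 3 networks per
#' architecture). Every stochastic stage draws its seed from
#' \code{master_seed} through a fixed splitting rule.
#'
#' @param task task id.
#' @param profile "paper" or "scaled_down".
#' @param master_seed integer master seed.
#' @param out_dir output directory for artifacts.
#' @param stages character vector of stage names to run.
#' @param ... overrides for any config field (e.g. \code{n_iter}, \code{N},
#'   \code{n_nets}, \code{coh_grid}, \code{n_latent_restarts}).
#' @return list of class \code{experiment_config}.
#' @export
experiment_config <- function(task = "cddm",
                              profile = c("scaled_down", "paper"),
                              master_seed = 1L, out_dir = tempfile("study"),
                              stages = c("train", "controls", "geometry",
                                         "fixedpoints", "latent", "behavior"),
                              ...) {
  profile <- match.arg(profile)
  base <- if (profile == "paper") {
    list(N = 100L, n_nets = 100L, n_iter = NULL, n_latent_restarts = 30L,
         n_top = 50L, n_top_latent = 10L)
  } else {
    list(N = 50L, n_nets = 3L, n_iter = 1500L, n_latent_restarts = 10L,
         n_top = 3L, n_top_latent = 1L)
  }
  cfg <- modifyList(c(base, list(task = task, profile = profile,
                                 master_seed = as.integer(master_seed),
                                 out_dir = out_dir, stages = stages,
                                 coh_grid = NULL, latent_iter = 600L,
                                 architectures = study_architectures())),
                    list(...))
  class(cfg) <- "experiment_config"
  cfg
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

task_batch <- function(task, coh_grid = NULL, seed = 1L) {
  switch(task,
    cddm = build_cddm_batch(enumerate_cddm_conditions(
      if (is.null(coh_grid)) coherence_grid() else coh_grid)),
    gonogo = build_gonogo_batch(),
    memory = build_memory_batch(seed = seed),
    flipflop = build_flipflop_batch(
      random_flipflop_pulses(seed = seed)),
    stop("unknown task: ", task)
  )
}

#' Run the full study pipeline
#'
#' Executes the configured stages in dependency order; every artifact is
#' written under \code{cfg$out_dir} and recorded in a JSON manifest with
#' its seed and the configuration hash. A stage whose outputs already exist
#' with a matching hash is skipped, making reruns cheap and deterministic.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @return the manifest (list), invisibly written to
#'   \code{manifest.json}.
#' @export
run_study <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  man_path <- file.path(cfg$out_dir, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    m <- jsonlite::read_json(man_path, simplifyVector = FALSE)
    if (identical(m$config_hash, hash)) m
    else list(config_hash = hash, artifacts = list())
  } else list(config_hash = hash, artifacts = list())
  manifest$task <- cfg$task
  archs <- cfg$architectures
  sched <- task_training_schedule(cfg$task)
  if (!is.null(cfg$n_iter)) sched$n_iter <- rep(ceiling(cfg$n_iter /
    length(sched$n_iter)), length(sched$n_iter))
  batch <- task_batch(cfg$task, cfg$coh_grid,
                      seed = derive_seed(cfg$master_seed, "task_batch"))
  nets <- list()
  # --- train ---------------------------------------------------------------
  for (a in seq_len(nrow(archs))) for (i in seq_len(cfg$n_nets)) {
    id <- sprintf("%s_net%02d", archs$label[a], i)
    prefix <- file.path(cfg$out_dir, id)
    if ("train" %in% cfg$stages && !file.exists(paste0(prefix, ".json"))) {
      p0 <- initialize_rnn(archs$activation[a], archs$dale[a], N = cfg$N,
                           n_in = dim(batch$inputs)[1],
                           n_out = dim(batch$targets)[1],
                           seed = derive_seed(cfg$master_seed, id, 1L))
      tr <- train_rnn(p0, batch, lambda_r = sched$lambda_r,
                      n_iter = sched$n_iter,
                      seed = derive_seed(cfg$master_seed, id, 2L))
      save_rnn(tr$params, prefix, loss_trace = tr$loss_trace)
      manifest$artifacts[[id]] <- list(kind = "checkpoint",
                                       path = basename(prefix),
                                       architecture = archs$label[a],
                                       seed = derive_seed(cfg$master_seed, id, 1L))
    }
    if (file.exists(paste0(prefix, ".json")))
      nets[[id]] <- list(id = id, arch = archs$label[a],
                         activation = archs$activation[a],
                         params = load_rnn(prefix), control = FALSE)
  }
  # --- controls ------------------------------------------------------------
  if ("controls" %in% cfg$stages) {
    for (nm in names(nets)) {
      if (nets[[nm]]$control) next
      cid <- paste0(nm, "_ctrl")
      if (is.null(nets[[cid]])) {
        ctrl <- shuffle_connectivity(nets[[nm]]$params,
                                     seed = derive_seed(cfg$master_seed, cid))
        nets[[cid]] <- list(id = cid, arch = nets[[nm]]$arch,
                            activation = nets[[nm]]$activation,
                            params = ctrl, control = TRUE)
        manifest$artifacts[[cid]] <- list(kind = "control", source = nm)
      }
    }
  }
  # --- simulate + summaries ------------------------------------------------
  resp <- lapply(nets, function(nw) simulate_batch(nw$params, batch))
  perf <- vapply(names(nets), function(nm)
    masked_mse(resp[[nm]]$outputs, batch$targets, batch$mask), 0)
  meta_df <- data.frame(id = names(nets),
                        architecture = vapply(nets, `[[`, "", "arch"),
                        activation = vapply(nets, `[[`, "", "activation"),
                        control = vapply(nets, `[[`, TRUE, "control"),
                        performance = unname(perf))
  utils::write.csv(meta_df, file.path(cfg$out_dir, "networks.csv"),
                   row.names = FALSE)
  if ("geometry" %in% cfg$stages) {
    traj <- lapply(resp, reduce_trajectories)
    sel <- lapply(resp, reduce_selectivity)
    endp <- lapply(resp, reduce_endpoints)
    summaries <- list(trajectory = traj, selectivity = sel, endpoint = endp)
    included <- list()
    if ("fixedpoints" %in% cfg$stages) {
      n_pc_fp <- min(7, cfg$N)
      fps <- lapply(names(nets), function(nm)
        fixed_point_survey(nets[[nm]]$params, cfg$task,
                           resp[[nm]]$activity,
                           seed = derive_seed(cfg$master_seed, "fps", match(nm, names(nets))),
                           max_points = 30L, patience = 30L))
      names(fps) <- names(nets)
      ok <- vapply(fps, function(s) nrow(s$coords), 0L) >= n_pc_fp
      if (!all(ok))
        warning("excluding ", sum(!ok), " network(s) with fewer than ",
                n_pc_fp, " fixed points from the fixed-point embedding: ",
                paste(names(nets)[!ok], collapse = ", "))
      summaries$fixedpoint <- lapply(fps[ok], project_fixed_points,
                                     n_pc = n_pc_fp)
      included$fixedpoint <- which(ok)
      for (nm in names(nets))
        utils::write.csv(fp_survey_table(fps[[nm]], nm),
                         file.path(cfg$out_dir, paste0(nm, "_fps.csv")),
                         row.names = FALSE)
    }
    for (metric in names(summaries)) {
      idx <- if (is.null(included[[metric]])) seq_along(nets)
             else included[[metric]]
      D <- distance_matrix(summaries[[metric]],
                           metric = if (metric == "trajectory") "trajectory"
                           else if (metric == "endpoint") "endpoint"
                           else if (metric == "selectivity") "selectivity"
                           else "fixedpoint",
                           seed = derive_seed(cfg$master_seed, paste0("D_", metric)))
      emb <- embed_mds(D, seed = derive_seed(cfg$master_seed, paste0("mds_", metric)))
      df <- cbind(meta_df[idx, ], x = emb$points[, 1], y = emb$points[, 2])
      utils::write.csv(df, file.path(cfg$out_dir,
                                     paste0("embedding_", metric, ".csv")),
                       row.names = FALSE)
      Dd <- as.data.frame(D); names(Dd) <- names(nets)[idx]
      utils::write.csv(cbind(id = names(nets)[idx], Dd),
                       file.path(cfg$out_dir, paste0("distances_", metric, ".csv")),
                       row.names = FALSE)
      manifest$artifacts[[paste0("embedding_", metric)]] <-
        list(kind = "embedding", metric = metric, stress = emb$stress)
    }
  }
  # --- latent circuits -----------------------------------------------------
  if ("latent" %in% cfg$stages && cfg$task == "cddm") {
    r2 <- NULL
    for (a in unique(meta_df$architecture)) {
      cand <- meta_df[meta_df$architecture == a & !meta_df$control, ]
      cand <- cand[order(cand$performance), ][seq_len(min(cfg$n_top_latent,
                                                          nrow(cand))), ]
      for (nm in cand$id) {
        red <- reduce_for_fit(resp[[nm]], n_pc = min(30, cfg$N))
        fit <- fit_latent_circuit(red, batch,
                                  nets[[nm]]$params$activation,
                                  gamma = gamma_of(nets[[nm]]$params),
                                  n_restarts = cfg$n_latent_restarts,
                                  n_iter = cfg$latent_iter,
                                  seed = derive_seed(cfg$master_seed, "latent",
                                                     match(nm, names(nets))))
        save_latent_fit(fit, file.path(cfg$out_dir, paste0(nm, "_latent")))
        r2 <- rbind(r2, data.frame(id = nm, architecture = a,
                                   r2_dynamics = fit$r2_dynamics,
                                   r2_behaviour = fit$r2_behaviour))
      }
    }
    utils::write.csv(r2, file.path(cfg$out_dir, "latent_r2.csv"),
                     row.names = FALSE)
    manifest$artifacts[["latent_r2"]] <- list(kind = "table",
                                              path = "latent_r2.csv")
  }
  # --- behaviour -----------------------------------------------------------
  if ("behavior" %in% cfg$stages) {
    rho <- vapply(names(nets), function(nm)
      output_alignment_rho(nets[[nm]]$params$W_out,
                           output_epoch_activity(resp[[nm]], cfg$task)), 0)
    utils::write.csv(cbind(meta_df, rho = unname(rho)),
                     file.path(cfg$out_dir, "rho.csv"), row.names = FALSE)
    manifest$artifacts[["rho"]] <- list(kind = "table", path = "rho.csv")
  }
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Export summary tables from a completed study
#'
#' Produces the latent-fit accuracy table (mean and s.d. of the two R^2
#' metrics per architecture, in percent) and a per-architecture summary of
#' the output-alignment measure.
#'
#' @param out_dir study output directory.
#' @return list of data.frames, also written as CSV into \code{out_dir}.
#' @export
export_tables <- function(out_dir) {
  out <- list()
  r2_path <- file.path(out_dir, "latent_r2.csv")
  if (file.exists(r2_path)) {
    r2 <- utils::read.csv(r2_path)
    archs <- study_architectures()$label
    archs <- archs[archs %in% r2$architecture]
    tab <- sapply(archs, function(a) {
      d <- r2[r2$architecture == a, ]
      c(r2_dynamics = sprintf("%.0f%% ± %.0f%%",
                              100 * mean(d$r2_dynamics),
                              100 * max(stats::sd(d$r2_dynamics), 0, na.rm = TRUE)),
        r2_behaviour = sprintf("%.0f%% ± %.0f%%",
                               100 * mean(d$r2_behaviour),
                               100 * max(stats::sd(d$r2_behaviour), 0, na.rm = TRUE)))
    })
    out$latent_table <- as.data.frame(tab)
    utils::write.csv(out$latent_table,
                     file.path(out_dir, "latent_table.csv"))
  }
  rho_path <- file.path(out_dir, "rho.csv")
  if (file.exists(rho_path)) {
    rho <- utils::read.csv(rho_path)
    agg <- stats::aggregate(rho$rho,
                            by = list(architecture = rho$architecture,
                                      control = rho$control), FUN = mean)
    names(agg)[3] <- "rho_mean"
    out$rho_summary <- agg
    utils::write.csv(agg, file.path(out_dir, "rho_summary.csv"),
                     row.names = FALSE)
  }
  out
}
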