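#' Pipeline parameters
#'
#' Every analysis parameter surfaced in one place. Defaults are the
#' full-scale settings (deformation kernel 11 mm, varifold kernel 5 mm,
#' 30 trajectory time points, 10 clusters, 3000 clustering restarts,
#' 10 baseline subjects, 5-year test grid from -20 to +10); tests and the
#' worked examples use reduced optimiser budgets and restart counts via
#' the same interface.
#'
#' @param lambda_v deformation kernel width (mm).
#' @param lambda_w varifold kernel width (mm).
#' @param gamma regularity trade-off.
#' @param n_steps RK4 steps for matching geodesics.
#' @param T trajectory time points.
#' @param K number of clusters.
#' @param n_init clustering restarts.
#' @param n_baseline subjects furthest from onset used for the baseline.
#' @param max_iter optimiser iteration cap per registration.
#' @param n_outer_bilateral alternating rounds of the bilateral mean.
#' @param eyo_grid EYO grid for the time-resolved Wald tests.
#' @param seed seed for ordering/clustering randomness.
#' @return list of parameters.
#' @export
pipeline_params <- function(lambda_v = 11, lambda_w = 5, gamma = 0.1,
                            n_steps = 11, T = 30, K = 10, n_init = 3000,
                            n_baseline = 10, max_iter = 200,
                            n_outer_bilateral = 1,
                            eyo_grid = c(-20, -15, -10, -5, 0, 5, 10),
                            seed = 1) {
  as.list(environment())
}

#' Run the spatiotemporal shape analysis on a cohort
#'
#' The full in-memory pipeline: (1) mirror left meshes onto the right side
#' about the estimated cohort mid-sagittal plane; (2) per-subject bilateral
#' mean shapes; (3) baseline shape by iterative centroid of the
#' `n_baseline` subjects furthest from onset; (4) geodesic regression of
#' the population trajectory over EYO; (5) residual deformations of every
#' subject from the trajectory; (6) Jacobi-field transport of the residual
#' momenta to the baseline space; (7) spectral clustering of the trajectory
#' parametrisation; (8) per-cluster amplitude/orientation descriptors;
#' (9) mixed-effects Wald tests.
#'
#' @param cohort list of `SubjectRecord`.
#' @param params a [pipeline_params()] list.
#' @param verbose print stage progress.
#' @return list with all intermediate objects: `mirror_plane`, `means`,
#'   `baseline`, `traj`, `records`, `cluster_model`, `features`,
#'   `analysis`, `params`.
#' @export
run_shape_pipeline <- function(cohort, params = pipeline_params(),
                               verbose = FALSE) {
  p <- params
  say <- function(...) if (verbose) message(...)
  cfg <- match_config(gamma = p$gamma, max_iter = p$max_iter,
                      deform = deform_config(p$lambda_v, p$n_steps),
                      data = varifold_config(p$lambda_w))

  say("mirroring left meshes")
  all_meshes <- unlist(lapply(cohort, function(r)
    list(r$left_mesh, r$right_mesh)), recursive = FALSE)
  plane <- estimate_mirror_plane(all_meshes)
  lefts <- lapply(cohort, function(r) mirror_mesh(r$left_mesh, plane))
  rights <- lapply(cohort, `[[`, "right_mesh")

  say("bilateral mean shapes")
  allv <- do.call(rbind, lapply(c(lefts, rights),
                                function(m) m$vertices))
  shared_grid <- .grid_from_points(allv, p$lambda_v)
  means <- lapply(seq_along(cohort), function(i)
    register_bilateral(rights[[i]], lefts[[i]], init_mid = rights[[i]],
                       control_points = shared_grid, cfg = cfg,
                       n_outer = p$n_outer_bilateral)$mean_mesh)

  eyos <- vapply(cohort, `[[`, 0, "eyo")
  ids <- vapply(cohort, `[[`, "", "subject_id")

  say("baseline centroid")
  base_idx <- order(eyos, ids)[seq_len(min(p$n_baseline, length(cohort)))]
  baseline <- iterative_centroid(means[base_idx], cfg,
                                 order_seed = p$seed)

  say("geodesic regression")
  traj <- geodesic_regression(means, eyos, baseline, cfg, T = p$T)

  say("residual deformations")
  records <- compute_residuals(traj, means, eyos, cfg, subject_ids = ids)

  say("parallel transport")
  records <- transport_residuals(traj, records)

  say("clustering the trajectory parametrisation")
  sim <- similarity_matrix(traj$control_points, traj$beta0,
                           normalise_dist = TRUE, lambda_v = p$lambda_v)
  cl <- cluster_parametrisation(sim, K = p$K, seed = p$seed,
                                n_init = p$n_init)

  say("descriptors and statistics")
  meta <- data.frame(
    subject_id = ids, eyo = eyos,
    group = vapply(cohort, `[[`, "", "group"),
    sex = vapply(cohort, `[[`, "", "sex"),
    site = vapply(cohort, `[[`, "", "site"),
    family_id = vapply(cohort, `[[`, "", "family_id"),
    stringsAsFactors = FALSE)
  feats <- feature_table(cl, records, meta)
  analysis <- analyse_features(feats, eyo_grid = p$eyo_grid)

  list(mirror_plane = plane, means = means, baseline = baseline,
       traj = traj, records = records, cluster_model = cl,
       features = feats, analysis = analysis, params = p)
}

# ------------------------------------------------------------ persistence

#' Save / load a geodesic trajectory
#'
#' The trajectory is fully encoded by `(B0; beta0(0))` plus the control
#' grid and the EYO mapping; snapshots and states are reconstructed by
#' re-shooting on load. Files: `baseline.ply`, `control_points.csv`,
#' `beta0.csv`, `meta.json`.
#'
#' @param traj a `GeodesicTrajectory`.
#' @param dir output directory.
#' @return `dir` (for `save_trajectory`) / the trajectory (for
#'   `load_trajectory`), invisibly for save.
#' @export
save_trajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(traj$baseline, file.path(dir, "baseline.ply"))
  write.csv(traj$control_points, file.path(dir, "control_points.csv"),
            row.names = FALSE)
  write.csv(traj$beta0, file.path(dir, "beta0.csv"), row.names = FALSE)
  cfg <- traj$cfg
  jsonlite::write_json(
    list(eyo_min = traj$eyo_min, eyo_max = traj$eyo_max,
         T = length(traj$time_grid), gamma = cfg$gamma,
         lambda_v = cfg$deform$lambda_v, lambda_w = cfg$data$lambda_w,
         n_steps = cfg$deform$n_steps, max_iter = cfg$max_iter),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  baseline <- read_mesh(file.path(dir, "baseline.ply"))
  cps <- as.matrix(read.csv(file.path(dir, "control_points.csv")))
  beta0 <- as.matrix(read.csv(file.path(dir, "beta0.csv")))
  cfg <- match_config(gamma = meta$gamma, max_iter = meta$max_iter,
                      deform = deform_config(meta$lambda_v, meta$n_steps),
                      data = varifold_config(meta$lambda_w))
  n_steps <- meta$T - 1L
  fwd <- .shoot_forward(unname(cps), unname(beta0), meta$lambda_v, n_steps,
                        vertices = baseline$vertices)
  states <- lapply(seq_len(n_steps + 1), function(s)
    momentum_system(.slice3(fwd$x, s), .slice3(fwd$a, s)))
  snapshots <- lapply(seq_len(n_steps + 1), function(s) {
    m <- baseline; m$vertices <- .slice3(fwd$y, s); m
  })
  structure(list(baseline = baseline, control_points = unname(cps),
                 beta0 = unname(beta0),
                 time_grid = seq(meta$eyo_min, meta$eyo_max,
                                 length.out = meta$T),
                 eyo_min = meta$eyo_min, eyo_max = meta$eyo_max,
                 states = states, snapshots = snapshots, cfg = cfg,
                 diagnostics = NULL),
            class = "GeodesicTrajectory")
}

# ------------------------------------------------------------- run driver

.config_hash <- function(x) {
  # order- and numeric-type-stable digest of a config list (integer vs
  # double must not matter after a YAML round trip)
  x <- rapply(x, as.numeric, classes = "integer", how = "replace")
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

.stage_done <- function(run_dir, stage, hash) {
  f <- file.path(run_dir, stage, ".done")
  file.exists(f) && identical(readLines(f, warn = FALSE)[1], hash)
}

.mark_done <- function(run_dir, stage, hash) {
  writeLines(hash, file.path(run_dir, stage, ".done"))
}

#' Run the pipeline from a config file
#'
#' Config-driven driver over [run_shape_pipeline()]: reads a YAML (or
#' list) config, generates or loads the cohort, runs all stages, and
#' writes the outputs plus a provenance record into a run directory.
#' Rerunning on a completed directory with an unchanged config skips the
#' work and reloads the final results (stage-level `.done` markers carry a
#' config hash).
#'
#' Config keys: `out_dir` (required), either `synth:` (arguments for
#' [synth_config()]) or `cohort_csv:`, plus any [pipeline_params()]
#' arguments and `seed`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return invisible list: the [run_shape_pipeline()] result plus
#'   `run_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config error: key 'out_dir' missing")
  known <- c("out_dir", "synth", "cohort_csv", "seed",
             names(formals(pipeline_params)))
  bad <- setdiff(names(config), known)
  if (length(bad) > 0)
    stop("config error: unknown keys: ", paste(bad, collapse = ", "))
  run_dir <- config$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)

  pargs <- config[intersect(names(config), names(formals(pipeline_params)))]
  params <- do.call(pipeline_params, pargs)
  if (!is.null(config$seed)) params$seed <- config$seed

  # stage: cohort
  synth_dir <- file.path(run_dir, "01_cohort")
  truth <- NULL
  if (!is.null(config$synth)) {
    sargs <- config$synth
    if (!is.null(config$seed) && is.null(sargs$seed))
      sargs$seed <- config$seed
    if (.stage_done(run_dir, "01_cohort", hash)) {
      cohort <- read_cohort(file.path(synth_dir, "cohort.csv"))
    } else {
      gen <- generate_cohort(do.call(synth_config, sargs), dir = synth_dir)
      cohort <- gen$cohort
      truth <- gen$truth
      .mark_done(run_dir, "01_cohort", hash)
    }
  } else if (!is.null(config$cohort_csv)) {
    cohort <- read_cohort(config$cohort_csv)
  } else {
    stop("config error: need either 'synth' or 'cohort_csv'")
  }

  res_file <- file.path(run_dir, "09_stats", "omnibus.csv")
  if (.stage_done(run_dir, "09_stats", hash)) {
    result <- list(
      features = read.csv(file.path(run_dir, "08_features",
                                    "features.csv")),
      analysis = list(
        omnibus = read.csv(res_file),
        at_eyo = if (file.exists(file.path(run_dir, "09_stats",
                                           "at_eyo.csv")))
          read.csv(file.path(run_dir, "09_stats", "at_eyo.csv")) else NULL),
      traj = load_trajectory(file.path(run_dir, "04_trajectory")),
      params = params, skipped = TRUE)
  } else {
    result <- run_shape_pipeline(cohort, params, verbose = TRUE)
    save_trajectory(result$traj, file.path(run_dir, "04_trajectory"))
    save_residuals(result$records, file.path(run_dir, "06_residuals"))
    dir.create(file.path(run_dir, "08_features"), showWarnings = FALSE)
    write.csv(result$features, file.path(run_dir, "08_features",
                                         "features.csv"),
              row.names = FALSE)
    dir.create(file.path(run_dir, "09_stats"), showWarnings = FALSE)
    write.csv(result$analysis$omnibus, res_file, row.names = FALSE)
    if (!is.null(result$analysis$at_eyo))
      write.csv(result$analysis$at_eyo,
                file.path(run_dir, "09_stats", "at_eyo.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(config = config, hash = hash, seed = params$seed,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
           package_version = as.character(utils::packageVersion("shapetraj"))),
      file.path(run_dir, "provenance.json"), auto_unbox = TRUE,
      digits = NA)
    .mark_done(run_dir, "09_stats", hash)
  }
  result$run_dir <- run_dir
  result$truth <- truth
  invisible(result)
}

# ------------------------------------------------- end-to-end truth check

#' Compare pipeline estimates against the generator's ground truth
#'
#' Report for a pipeline result on a synthetic cohort: trajectory endpoint
#' recovery (vertex RMS between the estimated and true final snapshots),
#' residual fit quality (mean final data term), cluster overlap with the
#' planted residual support (Jaccard index of the best-matching cluster),
#' the earliest Bonferroni-significant EYO grid point per descriptor, and
#' optionally the distribution of that earliest point under a parametric
#' bootstrap of the fitted mixed model (simulate from the fitted model,
#' refit, retest).
#'
#' @param result a [run_shape_pipeline()] result.
#' @param truth the `truth` manifest from [generate_cohort()].
#' @param n_boot parametric-bootstrap replicates (0 to skip).
#' @param seed bootstrap seed.
#' @return list report; see fields in the description.
#' @export
end_to_end_truth_check <- function(result, truth, n_boot = 0, seed = 1) {
  missing <- setdiff(c("traj", "records", "cluster_model", "features",
                       "analysis"), names(result))
  if (length(missing) > 0)
    stop("pipeline result lacks stage outputs: ",
         paste(missing, collapse = ", "))
  cfg <- truth$config
  # true final snapshot
  fwd <- .shoot_forward(truth$control_points, truth$beta_truth,
                        cfg$lambda_v, cfg$n_steps,
                        vertices = truth$base_mesh$vertices)
  v_true <- .slice3(fwd$y, cfg$n_steps + 1)
  v_est <- result$traj$snapshots[[length(result$traj$snapshots)]]$vertices
  endpoint_rms <- if (nrow(v_true) == nrow(v_est))
    sqrt(mean(rowSums((v_true - v_est)^2))) else NA_real_

  mean_data_term <- mean(vapply(result$records, `[[`, 0, "data_term"))

  # planted support mapped onto the pipeline's control grid
  w <- .bump_weights(result$traj$control_points, truth$res_centre,
                     truth$res_width)
  planted <- which(w > 0.5 * max(w))
  labs <- result$cluster_model$labels
  jacc <- vapply(seq_len(result$cluster_model$K), function(k) {
    ck <- which(labs == k)
    length(intersect(ck, planted)) / length(union(ck, planted))
  }, 0)
  best_cluster <- which.max(jacc)

  om <- result$analysis$omnibus
  sig <- om[om$p_bonferroni <= 0.05, , drop = FALSE]
  ae <- result$analysis$at_eyo
  earliest <- c(orientation = NA_real_, amplitude = NA_real_)
  for (d in c("orientation", "amplitude")) {
    if (!is.null(ae)) {
      rows <- ae[ae$descriptor == d, , drop = FALSE]
      earliest[d] <- earliest_significant_eyo(rows)
    }
  }

  boot_earliest <- NULL
  if (n_boot > 0 && best_cluster %in%
      sig$cluster[sig$descriptor == "orientation"]) {
    h <- fit_cluster_model(result$features, "orientation", best_cluster)
    if (h$mixed) {
      boot_earliest <- with_seed(seed, {
        sims <- stats::simulate(h$fit, nsim = n_boot)
        vapply(seq_len(n_boot), function(b) {
          tab <- result$features
          tab[[paste0("ori_c", best_cluster)]] <- sims[[b]]
          hb <- suppressWarnings(fit_cluster_model(tab, "orientation",
                                                   best_cluster))
          earliest_significant_eyo(wald_at_eyo(hb, result$params$eyo_grid))
        }, 0)
      })
    }
  }

  list(endpoint_rms = endpoint_rms, mean_data_term = mean_data_term,
       cluster_jaccard = jacc, best_cluster = best_cluster,
       best_jaccard = jacc[best_cluster],
       significant = sig[, c("descriptor", "cluster", "test",
                             "p_bonferroni")],
       earliest_significant = earliest, boot_earliest = boot_earliest)
}
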