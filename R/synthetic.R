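#' Synthetic cohort configuration
#'
#' Configuration for the synthetic bilateral cohort generator, the
#' ground-truth stand-in for a familial-FTD imaging cohort. Defaults mirror
#' the cohort structure the pipeline is designed for: ~200 subjects, a
#' carrier fraction of 113/211, EYO spanning [-40, 20] years,
#' family-clustered subjects over a handful of sites, and thalamus-scale
#' ellipsoid meshes (semi-axes 11 x 7 x 6 mm). The planted disease signal
#' is a residual deformation whose ORIENTATION rotates progressively with
#' EYO at fixed amplitude in carriers past `divergence_onset` (so group
#' differences live in the orientation descriptor, not the amplitude one);
#' `effect_mode = "amplitude"` plants the complementary amplitude-growing
#' effect instead.
#'
#' @param n_subjects cohort size (default 200).
#' @param carrier_fraction carrier probability (default 113/211).
#' @param eyo_range EYO span in years (default `c(-40, 20)`).
#' @param n_families number of families (default 60).
#' @param n_sites number of scanning sites (default 5).
#' @param mesh_subdiv icosphere subdivision level (default 3: 642 vertices;
#'   level 4 gives 2562, closest to real segmentation meshes).
#' @param semi_axes ellipsoid semi-axes in mm (default `c(11, 7, 6)`).
#' @param trajectory_effect scale of the ground-truth trajectory momenta
#'   (default 0.6, giving a few mm of anterior displacement over the span).
#' @param divergence_onset EYO at which carrier residuals begin (default
#'   -10).
#' @param divergence_scale amplitude of the planted residual momenta
#'   (default 0.5, giving surface displacements of a couple of mm, the
#'   scale real cluster deformations show).
#' @param rotation_deg_per_year orientation drift rate past onset
#'   (default 0.5, calibrated so the planted effect sits in the
#'   marginal-detection regime real cohorts show rather than being
#'   overwhelming).
#' @param noise_sd vertex jitter in mm (default 0.15); also scales the
#'   subject- and family-level residual momentum noise (`noise_sd/3` and
#'   `noise_sd/6`).
#' @param effect_mode `"orientation"` (default), `"amplitude"`, or
#'   `"none"`.
#' @param lambda_v deformation kernel width for the ground truth (mm,
#'   default 11).
#' @param n_steps RK4 steps for the generator's shoots (default 11).
#' @param seed RNG seed (recorded in the manifest).
#' @return object of class `SynthConfig`.
#' @export
synth_config <- function(n_subjects = 200, carrier_fraction = 113 / 211,
                         eyo_range = c(-40, 20), n_families = 60,
                         n_sites = 5, mesh_subdiv = 3,
                         semi_axes = c(11, 7, 6), trajectory_effect = 0.6,
                         divergence_onset = -10, divergence_scale = 0.5,
                         rotation_deg_per_year = 0.5, noise_sd = 0.15,
                         effect_mode = c("orientation", "amplitude", "none"),
                         lambda_v = 11, n_steps = 11, seed = 1) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(carrier_fraction >= 0, carrier_fraction <= 1,
            divergence_onset >= eyo_range[1],
            divergence_onset <= eyo_range[2],
            noise_sd >= 0, divergence_scale >= 0)
  structure(as.list(environment()), class = "SynthConfig")
}

#' Icosphere mesh
#'
#' Unit icosahedron refined by `subdiv` rounds of edge-midpoint
#' subdivision with reprojection onto the unit sphere (12, 42, 162, 642,
#' 2562, ... vertices).
#'
#' @param subdiv subdivision level (>= 0).
#' @return a `TriMesh` on the unit sphere.
#' @export
icosphere <- function(subdiv = 2) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  Tr <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
              c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7),
              c(8, 2, 9), c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9),
              c(4, 9, 10), c(5, 10, 6), c(3, 5, 12), c(7, 3, 11),
              c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    verts <- V
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      mid_cache[[key]] <- nrow(verts)
      nrow(verts)
    }
    newT <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(Tr))) {
      i <- Tr[f, 1]; j <- Tr[f, 2]; k <- Tr[f, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); c <- midpoint(k, i)
      newT <- rbind(newT, c(i, a, c), c(j, b, a), c(k, c, b), c(a, b, c))
    }
    V <- verts
    Tr <- newT
  }
  tri_mesh(V, Tr, name = paste0("icosphere", subdiv))
}

#' Thalamus-scale ellipsoid mesh
#'
#' @param semi_axes semi-axes in mm.
#' @param subdiv icosphere subdivision level.
#' @return a `TriMesh`.
#' @export
ellipsoid_mesh <- function(semi_axes = c(11, 7, 6), subdiv = 2) {
  m <- icosphere(subdiv)
  m$vertices <- sweep(m$vertices, 2, semi_axes, `*`)
  m$name <- "ellipsoid"
  m
}

# Gaussian bump weights on control points around a centre
.bump_weights <- function(points, centre, width) {
  d2 <- rowSums(sweep(points, 2, centre)^2)
  exp(-d2 / width^2)
}

#' Generate a synthetic bilateral cohort with known ground truth
#'
#' Builds a thalamus-scale ellipsoid baseline, defines a ground-truth
#' geodesic trajectory by shooting fixed anterior-pole momenta, and for
#' each subject samples EYO, family, site, sex and carrier status, then
#' constructs the right-side mesh as (trajectory snapshot at the subject's
#' EYO) deformed by the subject's residual momenta plus vertex jitter; the
#' left-side mesh is the mirrored pre-jitter shape with independent
#' jitter. Carrier residuals past `divergence_onset` rotate (or grow, in
#' amplitude mode) with EYO; all subjects share the fixed-amplitude base
#' residual plus family- and subject-level momentum noise, so a planted
#' orientation effect changes no amplitudes by construction.
#'
#' @param cfg a [synth_config()].
#' @param dir optional output directory; when given, writes per-subject
#'   PLY meshes, `cohort.csv` and `manifest.json` (the generator's ground
#'   truth) and returns the paths in the result.
#' @return list with `cohort` (list of `SubjectRecord`), `truth` (manifest
#'   list: config, base mesh, control points, trajectory momenta, residual
#'   support weights, per-subject truth), and `dir` (or NULL).
#' @export
generate_cohort <- function(cfg = synth_config(), dir = NULL) {
  with_seed(cfg$seed, {
    base <- ellipsoid_mesh(cfg$semi_axes, cfg$mesh_subdiv)
    dcfg <- deform_config(cfg$lambda_v, cfg$n_steps)
    cps <- build_control_grid(base, dcfg)
    a1 <- cfg$semi_axes[1]; a3 <- cfg$semi_axes[3]

    # ground-truth trajectory: anterior pole drawn posterior-inferior
    w_traj <- .bump_weights(cps, c(a1, 0, 0), cfg$lambda_v)
    dir_traj <- c(-1, 0, -0.25)
    dir_traj <- dir_traj / sqrt(sum(dir_traj^2))
    beta_truth <- cfg$trajectory_effect * outer(w_traj, dir_traj)

    # residual support: an anterior-superior patch one kernel width
    # across (a sub-structure-scale region spanning several control-grid
    # cells, so its detectability does not hinge on where cluster
    # boundaries fall). The planted direction
    # rotates on a 45-degree cone around the local surface normal: the
    # normal component (the part of a deformation the varifold data term
    # sees strongly) is constant, so the observable amplitude is the same
    # for every subject, while the tangential component rotates with EYO --
    # a pure orientation effect.
    res_centre <- c(0.6 * a1, 0, 0.7 * a3)
    w_res <- .bump_weights(cps, res_centre, cfg$lambda_v)
    nrm <- res_centre / cfg$semi_axes^2
    nrm <- nrm / sqrt(sum(nrm^2))
    e1 <- c(0, 1, 0)
    e1 <- e1 - sum(e1 * nrm) * nrm
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    cone <- pi / 4
    dir_at <- function(theta_deg) {
      th <- theta_deg * pi / 180
      cos(cone) * nrm + sin(cone) * (cos(th) * e1 + sin(th) * e2)
    }
    d0 <- dir_at(0)

    n <- cfg$n_subjects
    eyo <- runif(n, cfg$eyo_range[1], cfg$eyo_range[2])
    carrier <- rbinom(n, 1, cfg$carrier_fraction)
    family <- sample(sprintf("F%02d", seq_len(cfg$n_families)), n,
                     replace = TRUE)
    site <- sample(sprintf("site%d", seq_len(cfg$n_sites)), n,
                   replace = TRUE)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    m_sd <- cfg$noise_sd / 3
    f_sd <- cfg$noise_sd / 6
    fam_dirs <- matrix(rnorm(cfg$n_families * 3, sd = f_sd),
                       cfg$n_families, 3,
                       dimnames = list(sprintf("F%02d",
                                               seq_len(cfg$n_families)),
                                       NULL))

    cohort <- vector("list", n)
    subj_truth <- vector("list", n)
    span <- diff(cfg$eyo_range)
    for (i in seq_len(n)) {
      tt <- (eyo[i] - cfg$eyo_range[1]) / span
      fwd <- .shoot_forward(cps, beta_truth * tt, cfg$lambda_v, cfg$n_steps,
                            vertices = base$vertices)
      x_t <- .slice3(fwd$x, cfg$n_steps + 1)
      v_t <- .slice3(fwd$y, cfg$n_steps + 1)

      years_past <- max(0, eyo[i] - cfg$divergence_onset)
      angle <- 0
      amp <- cfg$divergence_scale
      if (cfg$effect_mode == "orientation" && carrier[i] == 1)
        angle <- cfg$rotation_deg_per_year * years_past
      if (cfg$effect_mode == "amplitude" && carrier[i] == 1)
        amp <- amp * (1 + 0.03 * years_past)
      d_i <- dir_at(angle)
      resid <- if (cfg$effect_mode == "none") 0 * outer(w_res, d0)
               else amp * outer(w_res, d_i)
      resid <- resid + outer(w_res, fam_dirs[family[i], ])
      resid <- resid + w_res * matrix(rnorm(length(w_res) * 3, sd = m_sd),
                                      ncol = 3)

      if (max(abs(resid)) > 0) {
        fwd2 <- .shoot_forward(x_t, resid, cfg$lambda_v, cfg$n_steps,
                               vertices = v_t)
        v_subj <- .slice3(fwd2$y, cfg$n_steps + 1)
      } else v_subj <- v_t

      right <- base
      right$vertices <- v_subj
      left <- mirror_mesh(right, 0)
      if (cfg$noise_sd > 0) {
        right$vertices <- right$vertices +
          matrix(rnorm(length(v_subj), sd = cfg$noise_sd), ncol = 3)
        left$vertices <- left$vertices +
          matrix(rnorm(length(v_subj), sd = cfg$noise_sd), ncol = 3)
      }
      sid <- sprintf("S%03d", i)
      right$name <- paste0(sid, "_R"); left$name <- paste0(sid, "_L")
      cohort[[i]] <- subject_record(
        sid, left, right, eyo[i],
        if (carrier[i] == 1) "carrier" else "noncarrier",
        sex[i], site[i], family[i])
      subj_truth[[i]] <- list(subject_id = sid, eyo = eyo[i],
                              carrier = carrier[i], t_internal = tt,
                              angle_deg = angle, amplitude = amp,
                              resid_momenta = resid,
                              control_points_t = x_t)
    }

    truth <- list(config = cfg, base_mesh = base, control_points = cps,
                  beta_truth = beta_truth, w_res = w_res,
                  res_support = which(w_res > 0.5 * max(w_res)),
                  res_centre = res_centre, res_width = cfg$lambda_v,
                  d0 = d0, subjects = subj_truth, seed = cfg$seed)

    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      rows <- lapply(cohort, function(r) {
        lf <- paste0(r$subject_id, "_L.ply")
        rf <- paste0(r$subject_id, "_R.ply")
        write_mesh(r$left_mesh, file.path(dir, lf))
        write_mesh(r$right_mesh, file.path(dir, rf))
        data.frame(subject_id = r$subject_id, left_mesh = lf,
                   right_mesh = rf, eyo = r$eyo, group = r$group,
                   sex = r$sex, site = r$site, family_id = r$family_id,
                   stringsAsFactors = FALSE)
      })
      write.csv(do.call(rbind, rows), file.path(dir, "cohort.csv"),
                row.names = FALSE)
      manifest <- truth
      manifest$config <- unclass(cfg)
      manifest$base_mesh <- list(vertices = base$vertices,
                                 triangles = base$triangles)
      jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                           digits = NA, auto_unbox = TRUE)
    }
    list(cohort = cohort, truth = truth, dir = dir)
  })
}
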