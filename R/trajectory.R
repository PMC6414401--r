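#' Select baseline subjects
#'
#' Returns the `k` subjects furthest from expected symptom onset (smallest,
#' i.e. most negative, EYO); ties broken by lexicographic `subject_id`.
#' These anchor the baseline shape of the population trajectory.
#'
#' @param cohort list of `SubjectRecord`.
#' @param k number of subjects (default 10).
#' @return sub-list of `cohort`.
#' @export
select_baseline_subjects <- function(cohort, k = 10) {
  stopifnot(length(cohort) >= 1, k <= length(cohort))
  eyos <- vapply(cohort, `[[`, 0, "eyo")
  ids <- vapply(cohort, `[[`, "", "subject_id")
  cohort[order(eyos, ids)[seq_len(k)]]
}

#' Diffeomorphic iterative centroid
#'
#' Sequential pairwise-geodesic averaging: starting from the first mesh of
#' a seeded random ordering, the running centroid `C_j` is flowed `1/(j+1)`
#' of the way along the geodesic from `C_j` to the next mesh (momenta from
#' [register()] scaled by `1/(j+1)`, then shot). One pass gives an
#' order-dependent but unbiased template; the ordering seed is recorded so
#' runs are reproducible, and [centroid_order_variability()] reports the
#' spread across orderings.
#'
#' @param meshes list of `TriMesh` in a common frame.
#' @param cfg a [match_config()].
#' @param order_seed integer seed for the visiting order.
#' @return the centroid `TriMesh` (attribute `order` records the ordering).
#' @export
iterative_centroid <- function(meshes, cfg = match_config(), order_seed = 1) {
  stopifnot(length(meshes) >= 1)
  ord <- with_seed(order_seed, sample(length(meshes)))
  C <- meshes[[ord[1]]]
  if (length(meshes) > 1) {
    for (j in 2:length(meshes)) {
      grid <- build_control_grid(C, cfg$deform)
      reg <- tryCatch(register(C, meshes[[ord[j]]], grid, cfg),
                      error = function(e)
                        stop("centroid registration failed at pair ", j,
                             ": ", conditionMessage(e)))
      scaled <- momentum_system(reg$system$points, reg$system$momenta / j)
      C <- flow_mesh(C, geodesic_shoot(scaled, cfg$deform))
    }
  }
  attr(C, "order") <- ord
  C
}

#' Centroid variability across orderings
#'
#' Diagnostic (not a test): recomputes the centroid under several ordering
#' seeds and reports the pairwise varifold distances between the results.
#'
#' @inheritParams iterative_centroid
#' @param seeds integer vector of ordering seeds.
#' @return matrix of pairwise squared varifold distances.
#' @export
centroid_order_variability <- function(meshes, cfg = match_config(),
                                       seeds = 1:5) {
  cents <- lapply(seeds, function(s) iterative_centroid(meshes, cfg, s))
  k <- length(cents)
  D <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j)
    D[i, j] <- D[j, i] <- varifold_sqdist(cents[[i]], cents[[j]], cfg$data)
  D
}

# map an EYO value to the nearest snapshot index (1-based), clamped
.snap_index <- function(eyo, eyo_min, eyo_max, T) {
  tt <- (eyo - eyo_min) / (eyo_max - eyo_min)
  tt <- pmin(1, pmax(0, tt))
  as.integer(round(tt * (T - 1))) + 1L
}

#' Geodesic regression of a population shape trajectory
#'
#' Fits a single geodesic through time-indexed shapes: starting from the
#' baseline `B0` anchored at the earliest observed EYO, the initial
#' regression momenta `beta0` (on the control grid of `B0`) are optimised
#' so that the geodesic, evaluated at each subject's grid-snapped
#' normalised time, minimises
#' \deqn{E = \sum_i d([\phi(B_0,\tilde t_i)],[S_i])^2 + \gamma\|v\|_V^2.}
#' EYO is mapped affinely onto the internal geodesic parameter [0, 1] and
#' discretised onto `T` uniform grid times (`T = 30` by default, about one
#' snapshot every two years over a 60-year span); each data term is
#' evaluated at the subject's nearest grid time. The gradient is the exact
#' discrete adjoint of the RK4 integration with data-term cotangents
#' injected at the interior snapshots.
#'
#' @param shapes list of `TriMesh` in the common frame.
#' @param eyos numeric vector of matching EYO values (>= 2 distinct).
#' @param baseline the baseline `TriMesh` `B0`.
#' @param cfg a [match_config()].
#' @param T number of snapshot time points (default 30).
#' @param control_points optional explicit grid (default:
#'   [build_control_grid()] on the baseline).
#' @return object of class `GeodesicTrajectory`: baseline, control points,
#'   `beta0`, `time_grid` (EYO values of the snapshots), `states` (per
#'   snapshot [momentum_system()]), `snapshots` (per snapshot `TriMesh`),
#'   the EYO mapping, config, and diagnostics.
#' @export
geodesic_regression <- function(shapes, eyos, baseline, cfg = match_config(),
                                T = 30, control_points = NULL) {
  stopifnot(length(shapes) == length(eyos), length(unique(eyos)) >= 2)
  eyo_min <- min(eyos); eyo_max <- max(eyos)
  n_steps <- T - 1L
  if (is.null(control_points))
    control_points <- build_control_grid(baseline, cfg$deform)
  control_points <- matrix(as.numeric(control_points), ncol = 3)
  n <- nrow(control_points)
  lam <- cfg$deform$lambda_v
  snap <- .snap_index(eyos, eyo_min, eyo_max, T)

  K0 <- gauss_kernel_cpp(control_points, control_points, lam)
  ctts <- lapply(shapes, triangle_centres_and_tangents)
  bbs <- vapply(seq_along(shapes), function(i)
    varifold_inner_cpp(ctts[[i]]$centres, ctts[[i]]$tangents,
                       ctts[[i]]$centres, ctts[[i]]$tangents,
                       cfg$data$lambda_w), 0)
  by_snap <- split(seq_along(shapes), snap)

  fn_gr <- function(par) {
    b0 <- matrix(par, n, 3)
    fwd <- .shoot_forward(control_points, b0, lam, n_steps,
                          vertices = baseline$vertices)
    data_term <- 0
    gy_inject <- vector("list", n_steps + 1)
    for (sname in names(by_snap)) {
      s <- as.integer(sname)
      snap_mesh <- baseline
      snap_mesh$vertices <- .slice3(fwd$y, s)
      cta <- triangle_centres_and_tangents(snap_mesh)
      aa <- varifold_inner_cpp(cta$centres, cta$tangents, cta$centres,
                               cta$tangents, cfg$data$lambda_w)
      g <- matrix(0, nrow(baseline$vertices), 3)
      for (i in by_snap[[sname]]) {
        ab <- varifold_inner_cpp(cta$centres, cta$tangents,
                                 ctts[[i]]$centres, ctts[[i]]$tangents,
                                 cfg$data$lambda_w)
        data_term <- data_term + (aa - 2 * ab + bbs[i])
        g <- g - 2 * .varifold_inner_grad_vertices(snap_mesh, ctts[[i]],
                                                   cfg$data)
      }
      g <- g + length(by_snap[[sname]]) *
        2 * .varifold_inner_grad_vertices(snap_mesh, cta, cfg$data)
      gy_inject[[s]] <- g
    }
    Kb0 <- K0 %*% b0
    kin <- sum(b0 * Kb0)
    z <- matrix(0, n, 3)
    zy <- matrix(0, nrow(baseline$vertices), 3)
    bwd <- .shoot_backward(fwd, z, z, zy, gy_inject = gy_inject)
    grad <- bwd$ga + cfg$gamma * 2 * Kb0
    list(value = data_term + cfg$gamma * kin, grad = as.numeric(grad),
         data_term = data_term)
  }

  opt <- .lbfgs(numeric(3 * n), fn_gr, cfg$max_iter, cfg$grad_tol)
  if (!opt$converged)
    warning("geodesic_regression: not converged after ", opt$iterations,
            " iterations; returning best iterate")
  beta0 <- matrix(opt$par, n, 3)
  fwd <- .shoot_forward(control_points, beta0, lam, n_steps,
                        vertices = baseline$vertices)
  states <- lapply(seq_len(n_steps + 1), function(s)
    momentum_system(.slice3(fwd$x, s), .slice3(fwd$a, s)))
  snapshots <- lapply(seq_len(n_steps + 1), function(s) {
    m <- baseline
    m$vertices <- .slice3(fwd$y, s)
    m
  })
  final <- fn_gr(opt$par)
  structure(list(baseline = baseline, control_points = control_points,
                 beta0 = beta0,
                 time_grid = seq(eyo_min, eyo_max, length.out = T),
                 eyo_min = eyo_min, eyo_max = eyo_max,
                 states = states, snapshots = snapshots, cfg = cfg,
                 diagnostics = list(trace = opt$trace,
                                    data_term = final$data_term,
                                    converged = opt$converged,
                                    iterations = opt$iterations)),
            class = "GeodesicTrajectory")
}

#' Snapshot index of a trajectory nearest to an EYO value
#'
#' @param traj a `GeodesicTrajectory`.
#' @param eyo EYO value (clamped to the trajectory span).
#' @return 1-based snapshot index.
#' @export
trajectory_snap_index <- function(traj, eyo) {
  .snap_index(eyo, traj$eyo_min, traj$eyo_max, length(traj$time_grid))
}
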