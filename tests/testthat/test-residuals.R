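# residual extraction against a known trajectory (built without the
# regression optimiser, so errors here are attributable to registration)
resid_traj <- function() {
  base <- small_ellipsoid(axes = c(11, 7, 6))
  cfg <- match_config(gamma = 0.05, max_iter = 40,
                      deform = deform_config(11, 11),
                      data = varifold_config(5))
  grid <- build_control_grid(base, cfg$deform)
  w <- exp(-rowSums(sweep(grid, 2, c(11, 0, 0))^2) / 11^2)
  beta <- 0.5 * outer(w, c(-1, 0, -0.3) / sqrt(1.09))
  fwd <- shapetraj:::.shoot_forward(grid, beta, 11, 10,
                                    vertices = base$vertices)
  states <- lapply(1:11, function(s)
    momentum_system(shapetraj:::.slice3(fwd$x, s),
                    shapetraj:::.slice3(fwd$a, s)))
  snapshots <- lapply(1:11, function(s) {
    m <- base; m$vertices <- shapetraj:::.slice3(fwd$y, s); m
  })
  structure(list(baseline = base, control_points = grid, beta0 = beta,
                 time_grid = seq(-40, 20, length.out = 11),
                 eyo_min = -40, eyo_max = 20, states = states,
                 snapshots = snapshots, cfg = cfg, diagnostics = NULL),
            class = "GeodesicTrajectory")
}

test_that("a subject equal to its snapshot has a near-zero residual", {
  traj <- resid_traj()
  eyo <- traj$time_grid[6]
  rec <- register_out <- compute_residual(traj, traj$snapshots[[6]], eyo)
  diam <- max(dist(traj$baseline$vertices))
  expect_equal(rec$grid_time_index, 6L)
  expect_lt(kinetic_norm_sq(momentum_system(traj$states[[6]]$points,
                                            rec$alpha0),
                            traj$cfg$deform), 1e-4 * diam^2)
})

test_that("a planted residual deformation is recovered", {
  traj <- resid_traj()
  s <- 8
  xs <- traj$states[[s]]$points
  w <- exp(-rowSums(sweep(xs, 2, c(6, 0, 4))^2) / 8^2)
  a_star <- 0.4 * outer(w, c(0, 1, 0.3) / sqrt(1.09))
  subj <- flow_mesh(traj$snapshots[[s]],
                    geodesic_shoot(momentum_system(xs, a_star),
                                   traj$cfg$deform))
  rec <- suppressWarnings(compute_residual(traj, subj, traj$time_grid[s]))
  fl <- flow_mesh(traj$snapshots[[s]],
                  geodesic_shoot(momentum_system(xs, rec$alpha0),
                                 traj$cfg$deform))
  expect_lt(vertex_rms(fl, subj), 0.2)
})

test_that("mirror-image perturbations give approximately opposite momenta", {
  traj <- resid_traj()
  s <- 5
  xs <- traj$states[[s]]$points
  w <- exp(-rowSums(sweep(xs, 2, c(6, 0, 4))^2) / 8^2)
  a_star <- 0.3 * outer(w, c(0, 1, 0.4))
  dc <- traj$cfg$deform
  s1 <- flow_mesh(traj$snapshots[[s]],
                  geodesic_shoot(momentum_system(xs, a_star), dc))
  s2 <- flow_mesh(traj$snapshots[[s]],
                  geodesic_shoot(momentum_system(xs, -a_star), dc))
  r1 <- suppressWarnings(compute_residual(traj, s1, traj$time_grid[s]))
  r2 <- suppressWarnings(compute_residual(traj, s2, traj$time_grid[s]))
  cosang <- sum(r1$alpha0 * r2$alpha0) /
    sqrt(sum(r1$alpha0^2) * sum(r2$alpha0^2))
  expect_lt(cosang, -0.8)
})

test_that("cohort residuals from trajectory-generated subjects sit at the noise floor", {
  set.seed(99)
  traj <- resid_traj()
  noise_sd <- 0.1
  idx <- c(3, 6, 9)
  meshes <- lapply(idx, function(s) {
    m <- traj$snapshots[[s]]
    m$vertices <- m$vertices + matrix(rnorm(length(m$vertices),
                                            sd = noise_sd), ncol = 3)
    m
  })
  # noise floor: varifold distance between two independent jitters of the
  # same snapshot, as the irreducible data term at this noise level
  floor_ref <- mean(vapply(idx, function(s) {
    m1 <- traj$snapshots[[s]]
    m2 <- m1
    m1$vertices <- m1$vertices + matrix(rnorm(length(m1$vertices),
                                              sd = noise_sd), ncol = 3)
    varifold_sqdist(m1, m2, traj$cfg$data)
  }, 0))
  recs <- suppressWarnings(
    compute_residuals(traj, meshes, traj$time_grid[idx]))
  expect_lt(mean(vapply(recs, `[[`, 0, "data_term")), 1.5 * floor_ref)
})

test_that("residual sets round-trip through the array container", {
  set.seed(12)
  mk <- function(id, s, transported) {
    a <- matrix(rnorm(12), 4)
    structure(list(subject_id = id, eyo = -5, grid_time_index = s,
                   alpha0 = a, data_term = 0.5,
                   theta0 = if (transported) a * 2 else NULL),
              class = "ResidualRecord")
  }
  recs <- list(mk("s1", 3L, TRUE), mk("s2", 7L, TRUE))
  dir <- tempfile()
  save_residuals(recs, dir)
  back <- load_residuals(dir)
  expect_equal(back[[2]]$alpha0, recs[[2]]$alpha0, tolerance = 1e-12)
  expect_equal(back[[1]]$theta0, recs[[1]]$theta0, tolerance = 1e-12)
  expect_equal(back[[2]]$grid_time_index, 7L)
  unlink(dir, recursive = TRUE)
})
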