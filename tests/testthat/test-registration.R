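reg_cfg <- function(max_iter = 40, gamma = 0.1, lam_v = 6, lam_w = 3,
                    n_steps = 11)
  match_config(gamma = gamma, max_iter = max_iter,
               deform = deform_config(lam_v, n_steps),
               data = varifold_config(lam_w))

test_that("registering a mesh onto itself keeps momenta at zero", {
  m <- small_ellipsoid()
  cfg <- reg_cfg()
  grid <- build_control_grid(m, cfg$deform)
  reg <- register(m, m, grid, cfg)
  diam <- max(dist(m$vertices))
  expect_lt(kinetic_norm_sq(reg$system, cfg$deform), 1e-4 * diam^2)
  expect_lt(reg$diagnostics$data_term, 1e-6 * varifold_inner(m, m, cfg$data))
})

test_that("a representable translation is recovered to sub-0.1 mm", {
  m <- small_ellipsoid()
  tgt <- translate_mesh(m, c(2, 0, 0))
  cfg <- reg_cfg(max_iter = 60, lam_v = 30)   # kernel larger than the mesh
  grid <- build_control_grid(m, cfg$deform)
  reg <- suppressWarnings(register(m, tgt, grid, cfg))
  fl <- flow_mesh(m, geodesic_shoot(reg$system, cfg$deform))
  expect_lt(vertex_rms(fl, tgt), 0.1)
})

test_that("a shot deformation is recovered (inverse crime) with large data-term reduction", {
  set.seed(21)
  m <- small_ellipsoid()
  cfg <- reg_cfg(max_iter = 60)
  grid <- build_control_grid(m, cfg$deform)
  w <- exp(-rowSums(sweep(grid, 2, c(6, 0, 0))^2) / cfg$deform$lambda_v^2)
  a_star <- 0.35 * outer(w, c(0.5, 1, 0.4))
  tgt <- flow_mesh(m, geodesic_shoot(momentum_system(grid, a_star),
                                     cfg$deform))
  d0 <- varifold_sqdist(m, tgt, cfg$data)
  reg <- suppressWarnings(register(m, tgt, grid, cfg))
  fl <- flow_mesh(m, geodesic_shoot(reg$system, cfg$deform))
  expect_lt(vertex_rms(fl, tgt), 0.2)
  expect_lt(reg$diagnostics$data_term, 0.05 * d0)
})

test_that("the matching gradient matches finite differences on random problems", {
  cfg <- reg_cfg(n_steps = 5)
  set.seed(31)
  for (trial in 1:10) {
    src <- random_patch(nx = 3, ny = 3, sd = 0.3, seed = trial)
    src$vertices <- src$vertices * 2
    tgt <- random_patch(nx = 3, ny = 3, sd = 0.3, seed = 100 + trial)
    tgt$vertices <- tgt$vertices * 2
    grid <- build_control_grid(src, cfg$deform)
    fn <- shapetraj:::.match_fn_gr(src, tgt, grid, cfg)
    par0 <- rnorm(3 * nrow(grid), sd = 0.1)
    g <- fn(par0)$grad
    i <- sample(length(par0), 1)
    e <- rep(0, length(par0)); e[i] <- 1e-5
    fd <- (fn(par0 + e)$value - fn(par0 - e)$value) / 2e-5
    expect_lt(abs(g[i] - fd) / max(abs(fd), 1e-8), 1e-3)
  }
})

test_that("accepted objective values are non-increasing (line-search contract)", {
  m <- small_ellipsoid()
  tgt <- translate_mesh(m, c(1, 0.5, 0))
  cfg <- reg_cfg(max_iter = 25)
  grid <- build_control_grid(m, cfg$deform)
  reg <- suppressWarnings(register(m, tgt, grid, cfg))
  expect_true(all(diff(reg$diagnostics$trace) <= 1e-12))
})

test_that("registration is equivariant under rigid translation of the problem", {
  set.seed(8)
  m <- small_ellipsoid()
  tgt <- m
  tgt$vertices <- tgt$vertices + matrix(rnorm(length(tgt$vertices),
                                              sd = 0.1), ncol = 3)
  cfg <- reg_cfg(max_iter = 15)
  grid <- build_control_grid(m, cfg$deform)
  reg1 <- suppressWarnings(register(m, tgt, grid, cfg))
  sh <- c(7, -3, 2)
  reg2 <- suppressWarnings(register(translate_mesh(m, sh),
                                    translate_mesh(tgt, sh),
                                    sweep(grid, 2, sh, `+`), cfg))
  expect_lt(max(abs(reg1$system$momenta - reg2$system$momenta)), 1e-6)
})

test_that("bilateral mean: identical sides give that side back", {
  m <- small_ellipsoid()
  cfg <- reg_cfg(max_iter = 30)
  grid <- build_control_grid(m, cfg$deform)
  bl <- register_bilateral(m, m, init_mid = m, control_points = grid,
                           cfg = cfg)
  expect_lt(varifold_sqdist(bl$mean_mesh, m, cfg$data),
            1e-6 * varifold_inner(m, m, cfg$data))
})

test_that("bilateral mean of a translated pair lies midway", {
  m <- small_ellipsoid(axes = c(11, 7, 6))
  left <- translate_mesh(m, c(1, 0, 0))
  cfg <- reg_cfg(max_iter = 60, gamma = 0.05, lam_v = 11, lam_w = 5)
  grid <- shapetraj:::.grid_from_points(rbind(m$vertices, left$vertices),
                                        cfg$deform$lambda_v)
  bl <- suppressWarnings(register_bilateral(left, m, init_mid = left,
                                            control_points = grid,
                                            cfg = cfg))
  dl <- varifold_sqdist(bl$mean_mesh, left, cfg$data)
  dr <- varifold_sqdist(bl$mean_mesh, m, cfg$data)
  expect_lt(abs(dl - dr) / max(dl, dr), 0.10)
  # and swapping the inputs leaves the mean unchanged (relative to size)
  bl2 <- suppressWarnings(register_bilateral(m, left, init_mid = left,
                                             control_points = grid,
                                             cfg = cfg))
  diam <- max(dist(m$vertices))
  expect_lt(max(abs(bl$mean_mesh$vertices - bl2$mean_mesh$vertices)) / diam,
            1e-6)
})
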