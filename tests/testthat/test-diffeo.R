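test_that("velocity field has its closed forms", {
  cfg <- deform_config(2, 11)
  sys <- momentum_system(rbind(c(0, 0, 0)), rbind(c(1, 2, 3)))
  expect_equal(velocity_field(sys, rbind(c(0, 0, 0)), cfg)[1, ], c(1, 2, 3))
  # at one kernel width: e^{-1} alpha
  expect_equal(velocity_field(sys, rbind(c(2, 0, 0)), cfg)[1, ],
               exp(-1) * c(1, 2, 3), tolerance = 1e-12)
  z <- momentum_system(rbind(c(0, 0, 0)), rbind(c(0, 0, 0)))
  expect_equal(velocity_field(z, matrix(rnorm(9), 3), cfg),
               matrix(0, 3, 3))
})

test_that("kinetic norm has its closed forms", {
  cfg <- deform_config(3)
  expect_equal(kinetic_norm_sq(momentum_system(rbind(c(0, 0, 0)),
                                               rbind(c(0, 0, 0))), cfg), 0)
  expect_equal(kinetic_norm_sq(momentum_system(rbind(c(1, 1, 1)),
                                               rbind(c(1, 0, 0))), cfg), 1)
  # two coincident points with opposite momenta cancel
  sys <- momentum_system(rbind(c(0, 0, 0), c(0, 0, 0)),
                         rbind(c(2, 1, 0), c(-2, -1, 0)))
  expect_equal(kinetic_norm_sq(sys, cfg), 0)
})

test_that("shooting conserves kinetic energy with 4th-order step scaling", {
  set.seed(42)
  x <- matrix(rnorm(30, sd = 5), 10)
  a <- matrix(rnorm(30, sd = 0.8), 10)
  sys <- momentum_system(x, a)
  drift <- function(ns) {
    p <- geodesic_shoot(sys, deform_config(3, ns))
    H <- vapply(p$states, kinetic_norm_sq, 0, cfg = deform_config(3))
    max(abs(H - H[1])) / H[1]
  }
  d11 <- drift(11)
  d22 <- drift(22)
  expect_lt(d11, 1e-5)
  # RK4: halving the step divides the drift by ~16
  expect_gt(d11 / d22, 8)
  expect_lt(d11 / d22, 32)
})

test_that("degenerate shots are exact: zero momenta and single-point translation", {
  cfg <- deform_config(2, 11)
  x <- matrix(rnorm(15), 5)
  p <- geodesic_shoot(momentum_system(x, x * 0), cfg)
  for (st in p$states) expect_equal(st$points, x)
  # single control point: gradient of K at 0 vanishes -> pure translation
  p1 <- geodesic_shoot(momentum_system(rbind(c(1, 1, 1)),
                                       rbind(c(0.5, -1, 2))), cfg)
  fin <- p1$states[[cfg$n_steps + 1]]
  expect_equal(fin$points[1, ], c(1.5, 0, 3), tolerance = 1e-12)
  expect_equal(fin$momenta[1, ], c(0.5, -1, 2), tolerance = 1e-12)
})

test_that("flow_mesh is consistent with the control-point path and forced cases", {
  cfg <- deform_config(4, 11)
  m <- small_ellipsoid()
  set.seed(3)
  x <- matrix(rnorm(24, sd = 4), 8)
  a <- matrix(rnorm(24, sd = 0.3), 8)
  path <- geodesic_shoot(momentum_system(x, a), cfg)
  # zero momenta: identity
  p0 <- geodesic_shoot(momentum_system(x, a * 0), cfg)
  expect_equal(flow_mesh(m, p0)$vertices, m$vertices)
  # flowing the control points as a "mesh" reproduces the stored path
  fake <- m; fake$vertices <- x
  moved <- suppressWarnings(flow_mesh(fake, path))
  expect_lt(max(abs(moved$vertices - path$states[[12]]$points)), 1e-8)
  # far-field translation: vertices clustered at a single distant control pt
  tiny <- tri_mesh(rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0)),
                   rbind(c(1, 2, 3)))
  tp <- geodesic_shoot(momentum_system(rbind(c(0, 0, 0)),
                                       rbind(c(2, 0, 0))),
                       deform_config(50, 11))
  expect_lt(vertex_rms(flow_mesh(tiny, tp), translate_mesh(tiny, c(2, 0, 0))),
            1e-4)
})

test_that("flowed meshes stay diffeomorphic images for moderate momenta", {
  set.seed(11)
  cfg <- deform_config(3, 11)
  m <- small_ellipsoid(axes = c(3, 2.5, 2))
  for (i in 1:25) {
    x <- matrix(rnorm(12, sd = 2.5), 4)
    a <- matrix(rnorm(12, sd = 0.25), 4)
    fl <- flow_mesh(m, geodesic_shoot(momentum_system(x, a), cfg))
    expect_gt(min(triangle_areas(fl)), 1e-12)
  }
})

test_that("control grids cover the mesh with the documented layout", {
  cube <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                         c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1)),
                   rbind(c(1, 2, 3), c(2, 5, 3), c(1, 2, 4), c(2, 6, 4),
                         c(1, 3, 4), c(3, 7, 4), c(8, 6, 5), c(8, 7, 6)))
  g <- build_control_grid(cube, deform_config(1))
  expect_equal(nrow(g), 64)
  # x varies fastest
  expect_equal(g[2, 1] - g[1, 1], 1)
  expect_equal(g[2, 2], g[1, 2])
  # padding: every vertex within lambda*sqrt(3) of some control point
  m <- small_ellipsoid()
  for (lam in c(2, 5)) {
    g <- build_control_grid(m, deform_config(lam))
    dmin <- apply(m$vertices, 1, function(v)
      min(sqrt(colSums((t(g) - v)^2))))
    expect_lt(max(dmin), lam * sqrt(3))
  }
})

test_that("shooting scaled momenta scales displacements to first order", {
  set.seed(5)
  cfg <- deform_config(3, 11)
  x <- matrix(rnorm(18, sd = 3), 6)
  a <- matrix(rnorm(18), 6)
  disp <- function(s) {
    p <- geodesic_shoot(momentum_system(x, s * a), cfg)
    p$states[[12]]$points - x
  }
  d1 <- disp(1e-3)
  d2 <- disp(2e-3)
  expect_lt(max(abs(d2 - 2 * d1)) / max(abs(d1)), 1e-2)
})
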