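#' Deformation kernel configuration
#'
#' Gaussian reproducing kernel `K(x,y) = exp(-|x-y|^2/lambda_v^2)` (no
#' factor 2 in the denominator) generating the space of admissible velocity
#' fields. The default width of 11 mm is about half the length of a
#' thalamus, so one kernel spans a substructure-scale region. `n_steps` is
#' the number of uniform RK4 steps used to integrate geodesics on [0, 1].
#'
#' @param lambda_v kernel width (mm), > 0.
#' @param n_steps integration steps, >= 2 (default 11).
#' @return object of class `DeformKernelConfig`.
#' @export
deform_config <- function(lambda_v = 11, n_steps = 11) {
  stopifnot(lambda_v > 0, n_steps >= 2)
  structure(list(lambda_v = as.numeric(lambda_v),
                 n_steps = as.integer(n_steps)),
            class = "DeformKernelConfig")
}

#' Control points and momenta
#'
#' A diffeomorphism is parametrised by momentum vectors attached to control
#' points: the velocity field is `v(y) = sum_p K(y, x_p) a_p`.
#'
#' @param points n x 3 control point positions (mm).
#' @param momenta n x 3 momentum vectors.
#' @return object of class `MomentumSystem`.
#' @export
momentum_system <- function(points, momenta) {
  points <- matrix(as.numeric(points), ncol = 3)
  momenta <- matrix(as.numeric(momenta), ncol = 3)
  stopifnot(nrow(points) >= 1, nrow(points) == nrow(momenta),
            all(is.finite(points)), all(is.finite(momenta)))
  structure(list(points = points, momenta = momenta),
            class = "MomentumSystem")
}

#' Velocity field induced by a momentum system
#'
#' @param system a [momentum_system()].
#' @param query_points m x 3 query positions.
#' @param cfg a [deform_config()].
#' @return m x 3 velocity vectors `v(y) = sum_p exp(-|y-x_p|^2/lambda_v^2) a_p`.
#' @export
velocity_field <- function(system, query_points, cfg = deform_config()) {
  query_points <- matrix(as.numeric(query_points), ncol = 3)
  gauss_kernel_cpp(query_points, system$points, cfg$lambda_v) %*%
    system$momenta
}

#' Squared kinetic norm of the initial velocity
#'
#' `|v|_V^2 = sum_{p,q} (a_p . a_q) K(x_p, x_q)`; the regularity term of
#' every matching functional, conserved along geodesics.
#'
#' @inheritParams velocity_field
#' @return non-negative scalar.
#' @export
kinetic_norm_sq <- function(system, cfg = deform_config()) {
  K <- gauss_kernel_cpp(system$points, system$points, cfg$lambda_v)
  sum(system$momenta * (K %*% system$momenta))
}

.empty3 <- matrix(0, 0, 3)

# extract snapshot s (1-based) of a n x 3 x (S+1) state array as a matrix
.slice3 <- function(arr, s) matrix(arr[, , s], ncol = 3)

# forward RK4 integration (in C++) storing every step-start state;
# `vertices` (optional) are flowed passively alongside the control points.
# Returns state arrays `x`, `a` (n x 3 x n_steps+1) and `y`
# (m x 3 x n_steps+1, m = 0 without vertices).
.shoot_forward <- function(points, momenta, lam, n_steps, vertices = NULL) {
  y <- if (is.null(vertices)) .empty3 else vertices
  shoot_forward_cpp(points, momenta, y, lam, n_steps)
}

# reverse sweep of the discrete adjoint (in C++). `gy_inject[[s]]`
# (optional, list of length n_steps+1 with NULL gaps) is an extra vertex
# cotangent added at snapshot s, used by the geodesic regression whose
# data terms live at interior snapshots. Returns the gradient w.r.t. the
# initial (x, a, y).
.shoot_backward <- function(fwd, gx1, ga1, gy1 = NULL, gy_inject = NULL) {
  if (is.null(gy1)) gy1 <- .empty3
  shoot_backward_cpp(fwd$x, fwd$a, fwd$y, fwd$lam, fwd$n_steps,
                     gx1, ga1, gy1, gy_inject)
}

#' Geodesic shooting (exponential map)
#'
#' Integrates the Hamiltonian geodesic equations
#' \deqn{\dot x_p = \sum_q K(x_p,x_q)\,\alpha_q, \qquad
#'       \dot\alpha_p = -\sum_q (\alpha_p\cdot\alpha_q)\,
#'       \nabla_1 K(x_p,x_q)}
#' from t = 0 to 1 with `cfg$n_steps` uniform RK4 steps, returning the full
#' path of `(points, momenta)` states. The kinetic energy is a conserved
#' quantity of the continuous system; its drift along the returned path is
#' the package's core integration diagnostic.
#'
#' @inheritParams velocity_field
#' @return object of class `GeodesicPath`: list with `states` (a list of
#'   `n_steps + 1` [momentum_system()] snapshots) and `kernel` (the config).
#' @export
geodesic_shoot <- function(system, cfg = deform_config()) {
  fwd <- .shoot_forward(system$points, system$momenta, cfg$lambda_v,
                        cfg$n_steps)
  states <- lapply(seq_len(cfg$n_steps + 1), function(s)
    momentum_system(.slice3(fwd$x, s), .slice3(fwd$a, s)))
  structure(list(states = states, kernel = cfg), class = "GeodesicPath")
}

#' Flow a mesh through a geodesic path
#'
#' Integrates each vertex through the time-varying velocity field induced
#' by the path's initial `(points, momenta)` (the same RK4 stepping as
#' [geodesic_shoot()], so flowing the control points themselves reproduces
#' the stored path). Connectivity is unchanged.
#'
#' @param mesh a `TriMesh` in the same frame as the path.
#' @param path a `GeodesicPath`.
#' @return the deformed `TriMesh`.
#' @export
flow_mesh <- function(mesh, path) {
  s0 <- path$states[[1]]
  fwd <- .shoot_forward(s0$points, s0$momenta, path$kernel$lambda_v,
                        path$kernel$n_steps, vertices = mesh$vertices)
  out <- mesh
  out$vertices <- .slice3(fwd$y, path$kernel$n_steps + 1)
  out
}

#' Build a control-point grid over a mesh
#'
#' Axis-aligned grid with spacing `lambda_v` covering the mesh bounding box
#' padded by one spacing on each side; deterministic ordering with x
#' varying fastest. Control points are independent of the mesh vertices:
#' they define the basis on which deformations are decomposed.
#'
#' @param mesh a `TriMesh`.
#' @param cfg a [deform_config()].
#' @return n x 3 matrix of grid points.
#' @export
build_control_grid <- function(mesh, cfg = deform_config()) {
  .grid_from_points(mesh$vertices, cfg$lambda_v)
}

.grid_from_points <- function(points, lam) {
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  axes <- lapply(1:3, function(d) {
    start <- lo[d] - lam
    n <- ceiling((hi[d] + lam - start) / lam) + 1L
    start + lam * (seq_len(n) - 1L)
  })
  g <- expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  unname(as.matrix(g))
}
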