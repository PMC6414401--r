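#' Jacobi-field parallel transport of residual momenta
#'
#' Transports a residual's initial momenta from its snapshot time back to
#' the baseline space along the regression geodesic, one grid interval at a
#' time. At each step the Jacobi field
#' \deqn{J(h) = \partial_\varepsilon\,
#'   \exp_{x(t)}\!\big(h(-\beta_0(t) + \varepsilon\theta)\big)}
#' is realised by a central difference of two perturbed exponentials
#' (shooting the reversed geodesic segment with momenta
#' `h(-beta0(t) +/- eps*theta)`), giving the transported velocity
#' `J/h` on the previous grid's control points, which is converted back to
#' momenta through the kernel matrix. Central differencing gives O(eps^2)
#' accuracy; stepping one interval at a time bounds the finite-eps error
#' uniformly across subjects regardless of how far along the trajectory
#' they sit. Parallel transport is a metric isometry; the discrete scheme
#' preserves the kinetic norm up to integration and finite-eps error.
#'
#' @param traj a `GeodesicTrajectory`.
#' @param record a `ResidualRecord` (from [compute_residual()]).
#' @param eps central-difference perturbation; default
#'   `1e-3 * |beta0(t)|_F / max(|theta|_F, tiny)` per step.
#' @param n_substeps RK4 substeps per grid-interval shoot (default 5).
#' @return the record with `theta0` (n x 3 transported momenta anchored at
#'   the baseline control points) filled in.
#' @export
jacobi_transport <- function(traj, record, eps = NULL, n_substeps = 5) {
  tr_ctx <- .transport_context(traj, n_substeps)
  record$theta0 <- .jacobi_transport_one(tr_ctx, record$grid_time_index,
                                         record$alpha0, eps)
  record
}

#' Transport all residuals of a cohort
#'
#' Fills `theta0` for every record, sharing per-step Cholesky factors of
#' the kernel matrices across subjects.
#'
#' @param traj a `GeodesicTrajectory`.
#' @param records list of `ResidualRecord`.
#' @inheritParams jacobi_transport
#' @return the list of records with `theta0` filled.
#' @export
transport_residuals <- function(traj, records, eps = NULL, n_substeps = 5) {
  tr_ctx <- .transport_context(traj, n_substeps)
  lapply(records, function(r) {
    r$theta0 <- .jacobi_transport_one(tr_ctx, r$grid_time_index, r$alpha0,
                                      eps)
    r
  })
}

# shared per-trajectory state: kernel Cholesky factors per snapshot, cached
# lazily
.transport_context <- function(traj, n_substeps) {
  env <- new.env(parent = emptyenv())
  env$traj <- traj
  env$lam <- traj$cfg$deform$lambda_v
  env$n_intervals <- length(traj$states) - 1L
  env$n_substeps <- as.integer(n_substeps)
  env$chols <- vector("list", length(traj$states))
  env
}

.chol_at <- function(ctx, s) {
  if (is.null(ctx$chols[[s]])) {
    K <- gauss_kernel_cpp(ctx$traj$states[[s]]$points,
                          ctx$traj$states[[s]]$points, ctx$lam)
    ctx$chols[[s]] <- chol(K + diag(1e-10, nrow(K)))
  }
  ctx$chols[[s]]
}

.shoot_endpoint <- function(x, a, lam, n_steps) {
  fwd <- .shoot_forward(x, a, lam, n_steps)
  .slice3(fwd$x, n_steps + 1)
}

.jacobi_transport_one <- function(ctx, s, alpha0, eps = NULL) {
  theta <- alpha0
  if (s <= 1L) return(theta)
  h <- 1 / ctx$n_intervals
  for (t in s:2L) {
    beta <- ctx$traj$states[[t]]$momenta
    x <- ctx$traj$states[[t]]$points
    bnorm <- sqrt(sum(beta^2))
    tnorm <- sqrt(sum(theta^2))
    if (bnorm == 0) next  # straight segment: transport is the identity
    if (tnorm == 0) { theta <- theta * 0; next }
    e <- eps %||% (1e-3 * bnorm / max(tnorm, .Machine$double.xmin))
    if (e * tnorm < 1e3 * .Machine$double.eps * max(1, bnorm))
      stop("jacobi_transport: eps underflow (eps*|theta| below machine ",
           "noise); supply a larger eps")
    Pp <- .shoot_endpoint(x, h * (-beta + e * theta), ctx$lam,
                          ctx$n_substeps)
    Pm <- .shoot_endpoint(x, h * (-beta - e * theta), ctx$lam,
                          ctx$n_substeps)
    vfield <- (Pp - Pm) / (2 * e * h)
    R <- .chol_at(ctx, t - 1L)
    theta <- backsolve(R, forwardsolve(t(R), vfield))
  }
  theta
}
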