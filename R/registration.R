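#' Matching configuration
#'
#' Settings for LDDMM surface matching: the trade-off `gamma` between the
#' varifold data term and the kinetic regularity term, the optimiser
#' budget, and the deformation / varifold kernel configs. `gamma = 0.1`
#' with meshes in mm and unnormalised varifold terms is a workable default;
#' it is exposed because the right balance depends on mesh scale and
#' triangle count.
#'
#' @param gamma regularity trade-off, > 0 (default 0.1).
#' @param max_iter maximum accepted optimiser iterations (default 200).
#' @param grad_tol relative gradient-norm stopping tolerance (default 1e-6).
#' @param deform a [deform_config()].
#' @param data a [varifold_config()].
#' @return object of class `MatchConfig`.
#' @export
match_config <- function(gamma = 0.1, max_iter = 200, grad_tol = 1e-6,
                         deform = deform_config(), data = varifold_config()) {
  stopifnot(gamma > 0, max_iter >= 1, grad_tol > 0)
  structure(list(gamma = gamma, max_iter = as.integer(max_iter),
                 grad_tol = grad_tol, deform = deform, data = data),
            class = "MatchConfig")
}

# Limited-memory BFGS with Armijo backtracking. fn_gr(par) returns
# list(value, grad). Accepted iterates are monotone non-increasing by
# construction; the trace records the objective at each accepted iterate.
.lbfgs <- function(par, fn_gr, max_iter, grad_tol, memory = 7L) {
  ev <- fn_gr(par)
  f <- ev$value; g <- ev$grad
  if (!is.finite(f)) stop("objective not finite at the initial point")
  gnorm0 <- sqrt(sum(g^2))
  Sm <- list(); Ym <- list(); rho <- numeric(0)
  trace <- f
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    gn <- sqrt(sum(g^2))
    if (gn <= grad_tol * max(1, gnorm0)) { converged <- TRUE; break }
    # two-loop recursion
    q <- g
    k <- length(Sm)
    alpha <- numeric(k)
    if (k > 0) {
      for (i in k:1) {
        alpha[i] <- rho[i] * sum(Sm[[i]] * q)
        q <- q - alpha[i] * Ym[[i]]
      }
      gam <- sum(Sm[[k]] * Ym[[k]]) / sum(Ym[[k]] * Ym[[k]])
      q <- gam * q
      for (i in 1:k) {
        beta <- rho[i] * sum(Ym[[i]] * q)
        q <- q + (alpha[i] - beta) * Sm[[i]]
      }
      d <- -q
    } else {
      d <- -g / max(gn, 1e-12)
    }
    dg <- sum(d * g)
    if (!is.finite(dg) || dg >= 0) { d <- -g; dg <- -gn^2 }
    step <- 1
    ok <- FALSE
    for (ls in 1:40) {
      cand <- par + step * d
      evn <- tryCatch(fn_gr(cand), error = function(e) NULL)
      if (!is.null(evn) && is.finite(evn$value) &&
          evn$value <= f + 1e-4 * step * dg) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break
    s <- step * d
    yv <- evn$grad - g
    sy <- sum(s * yv)
    if (is.finite(sy) && sy > 1e-10 * sqrt(sum(s^2)) * sqrt(sum(yv^2))) {
      Sm[[length(Sm) + 1]] <- s
      Ym[[length(Ym) + 1]] <- yv
      rho <- c(rho, 1 / sy)
      if (length(Sm) > memory) {
        Sm <- Sm[-1]; Ym <- Ym[-1]; rho <- rho[-1]
      }
    }
    rel_dec <- (f - evn$value) / max(1, abs(f))
    par <- cand; f <- evn$value; g <- evn$grad
    iters <- it
    trace <- c(trace, f)
    if (rel_dec < 1e-12) { converged <- TRUE; break }
  }
  list(par = par, value = f, grad = g, trace = trace,
       converged = converged, iterations = iters)
}

# objective/gradient for single-target matching; returns closure pieces
.match_fn_gr <- function(source, target, control_points, cfg) {
  lam <- cfg$deform$lambda_v
  n_steps <- cfg$deform$n_steps
  K0 <- gauss_kernel_cpp(control_points, control_points, lam)
  ctt <- triangle_centres_and_tangents(target)
  bb <- varifold_inner_cpp(ctt$centres, ctt$tangents, ctt$centres,
                           ctt$tangents, cfg$data$lambda_w)
  n <- nrow(control_points)
  function(par) {
    a0 <- matrix(par, n, 3)
    fwd <- .shoot_forward(control_points, a0, lam, n_steps,
                          vertices = source$vertices)
    flowed <- source
    flowed$vertices <- .slice3(fwd$y, n_steps + 1)
    cta <- triangle_centres_and_tangents(flowed)
    aa <- varifold_inner_cpp(cta$centres, cta$tangents, cta$centres,
                             cta$tangents, cfg$data$lambda_w)
    ab <- varifold_inner_cpp(cta$centres, cta$tangents, ctt$centres,
                             ctt$tangents, cfg$data$lambda_w)
    data_term <- aa - 2 * ab + bb
    Ka0 <- K0 %*% a0
    kin <- sum(a0 * Ka0)
    gy1 <- 2 * .varifold_inner_grad_vertices(flowed, cta, cfg$data) -
      2 * .varifold_inner_grad_vertices(flowed, ctt, cfg$data)
    z <- matrix(0, n, 3)
    bwd <- .shoot_backward(fwd, z, z, gy1)
    grad <- bwd$ga + cfg$gamma * 2 * Ka0
    list(value = data_term + cfg$gamma * kin, grad = as.numeric(grad),
         data_term = data_term)
  }
}

#' Register a source mesh onto a target mesh
#'
#' Estimates initial momenta `alpha` on the given control points minimising
#' the LDDMM matching functional
#' \deqn{J(\alpha) = d([\phi_\alpha(S)],[T])^2 +
#'   \gamma\,\|v_\alpha\|_V^2}
#' by limited-memory BFGS with Armijo backtracking. The gradient is the
#' exact discrete adjoint of the RK4 integration (it matches central finite
#' differences of the discretised objective).
#'
#' @param source,target `TriMesh` objects in a common frame.
#' @param control_points n x 3 matrix covering the source (see
#'   [build_control_grid()]).
#' @param cfg a [match_config()].
#' @param init optional n x 3 initial momenta (default zero).
#' @return list with `system` (a [momentum_system()] of optimal initial
#'   momenta) and `diagnostics` (objective trace over accepted iterates,
#'   final data term, convergence flag, iteration count).
#' @export
register <- function(source, target, control_points, cfg = match_config(),
                     init = NULL) {
  control_points <- matrix(as.numeric(control_points), ncol = 3)
  n <- nrow(control_points)
  fn_gr <- .match_fn_gr(source, target, control_points, cfg)
  par0 <- if (is.null(init)) numeric(3 * n) else as.numeric(init)
  opt <- .lbfgs(par0, fn_gr, cfg$max_iter, cfg$grad_tol)
  if (!opt$converged)
    warning("register: not converged after ", opt$iterations,
            " iterations; returning best iterate")
  final <- fn_gr(opt$par)
  list(system = momentum_system(control_points, matrix(opt$par, n, 3)),
       diagnostics = list(trace = opt$trace, data_term = final$data_term,
                          converged = opt$converged,
                          iterations = opt$iterations))
}

# joint matching of several sources (flowed by ONE deformation) each to the
# same target, with weights on the data terms
.match_multi_fn_gr <- function(sources, target, control_points, cfg,
                               weights) {
  lam <- cfg$deform$lambda_v
  n_steps <- cfg$deform$n_steps
  K0 <- gauss_kernel_cpp(control_points, control_points, lam)
  ctt <- triangle_centres_and_tangents(target)
  bb <- varifold_inner_cpp(ctt$centres, ctt$tangents, ctt$centres,
                           ctt$tangents, cfg$data$lambda_w)
  n <- nrow(control_points)
  counts <- vapply(sources, function(m) nrow(m$vertices), 0L)
  offs <- cumsum(c(0L, counts))
  allv <- do.call(rbind, lapply(sources, `[[`, "vertices"))
  function(par) {
    a0 <- matrix(par, n, 3)
    fwd <- .shoot_forward(control_points, a0, lam, n_steps, vertices = allv)
    yv <- .slice3(fwd$y, n_steps + 1)
    data_term <- 0
    gy1 <- matrix(0, nrow(allv), 3)
    for (i in seq_along(sources)) {
      rows <- (offs[i] + 1L):offs[i + 1L]
      fl <- sources[[i]]
      fl$vertices <- yv[rows, , drop = FALSE]
      cta <- triangle_centres_and_tangents(fl)
      aa <- varifold_inner_cpp(cta$centres, cta$tangents, cta$centres,
                               cta$tangents, cfg$data$lambda_w)
      ab <- varifold_inner_cpp(cta$centres, cta$tangents, ctt$centres,
                               ctt$tangents, cfg$data$lambda_w)
      data_term <- data_term + weights[i] * (aa - 2 * ab + bb)
      gy1[rows, ] <- weights[i] *
        (2 * .varifold_inner_grad_vertices(fl, cta, cfg$data) -
         2 * .varifold_inner_grad_vertices(fl, ctt, cfg$data))
    }
    Ka0 <- K0 %*% a0
    kin <- sum(a0 * Ka0)
    z <- matrix(0, n, 3)
    bwd <- .shoot_backward(fwd, z, z, gy1)
    grad <- bwd$ga + cfg$gamma * 2 * Ka0
    list(value = data_term + cfg$gamma * kin, grad = as.numeric(grad),
         data_term = data_term)
  }
}

#' Bilateral mean shape of a left/right pair
#'
#' Estimates a subject-specific average shape `S` of a left mesh and an
#' (already mirrored) right mesh by minimising
#' \deqn{\tfrac12\big(d([\chi(L)],[S])^2 + d([\chi(R)],[S])^2\big) +
#'   \gamma\|v\|_V^2}
#' jointly over one deformation `chi` (applied to both sides) and the mean
#' `S`. The scheme alternates (a) re-estimating the momenta of `chi` with
#' `S` fixed, and (b) updating `S` as the vertex-wise average of the two
#' flowed sides (which requires both sides to share connectivity, as
#' bilateral pairs produced by mirroring do), minus the net translation of
#' the flow. The last subtraction fixes the translation gauge of the joint
#' functional: translating `chi` and `S` together changes the objective
#' only through the kinetic term, so without it the mean chases its own
#' initialisation at rate `2/(2+gamma)` per round instead of settling at
#' the kinetically-optimal centre. `S` is seeded with `init_mid` (the left
#' mesh by default); the symmetric data term pulls it midway.
#'
#' @param left,right_mirrored `TriMesh` objects in a common frame with
#'   identical vertex/triangle counts.
#' @param init_mid initial mean mesh (default: `left`).
#' @param control_points n x 3 control points covering both sides.
#' @param cfg a [match_config()].
#' @param n_outer alternating rounds (default 1: register jointly to the
#'   init, average, recentre). More rounds refine the mean when the two
#'   sides nearly coincide but can compound shape distortion when they are
#'   far apart (one smooth field cannot move two overlapping copies
#'   independently, so re-registering to an averaged shape squeezes it).
#' @return list with `mean_mesh` (a `TriMesh`), `system` (the final
#'   [momentum_system()]), and `diagnostics`.
#' @export
register_bilateral <- function(left, right_mirrored, init_mid = NULL,
                               control_points, cfg = match_config(),
                               n_outer = 1) {
  if (nrow(left$vertices) != nrow(right_mirrored$vertices))
    stop("bilateral mean requires both sides to share connectivity")
  control_points <- matrix(as.numeric(control_points), ncol = 3)
  n <- nrow(control_points)
  S <- init_mid %||% left
  par <- numeric(3 * n)
  traces <- list()
  lam <- cfg$deform$lambda_v
  n_steps <- cfg$deform$n_steps
  for (outer in seq_len(n_outer)) {
    fn_gr <- .match_multi_fn_gr(list(left, right_mirrored), S,
                                control_points, cfg, c(0.5, 0.5))
    # fresh momenta each round: the deformation is re-estimated against the
    # updated mean, not accumulated
    opt <- .lbfgs(numeric(3 * n), fn_gr, cfg$max_iter, cfg$grad_tol)
    par <- opt$par
    traces[[outer]] <- opt$trace
    a0 <- matrix(par, n, 3)
    allv <- rbind(left$vertices, right_mirrored$vertices)
    fwd <- .shoot_forward(control_points, a0, lam, n_steps, vertices = allv)
    yv <- .slice3(fwd$y, n_steps + 1)
    nv <- nrow(left$vertices)
    avg <- 0.5 * (yv[seq_len(nv), , drop = FALSE] +
                  yv[nv + seq_len(nv), , drop = FALSE])
    net_shift <- colMeans(yv - allv)
    S$vertices <- sweep(avg, 2, net_shift)
  }
  list(mean_mesh = S,
       system = momentum_system(control_points, matrix(par, n, 3)),
       diagnostics = list(traces = traces))
}
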