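#' Similarity between control-point/momentum pairs
#'
#' Similarity used to cluster the trajectory parametrisation
#' `(B0; beta0(0))`:
#' \deqn{s(p,q) = -w_d\,\|x_p-x_q\|^2 + w_a(\cos(\beta_p,\beta_q)+1) -
#'   w_m\,\big|\,\|\beta_p\|^2-\|\beta_q\|^2\big|}
#' with default weights `(5, 2, 1)`. The cosine of a zero momentum vector
#' with anything is defined as 0. With raw mm distances on an 11 mm grid
#' the distance term dwarfs the others, so by default distances are divided
#' by `lambda_v` before squaring (`normalise_dist = TRUE`); raw distances
#' are available for fidelity experiments.
#'
#' @param control_points n x 3 positions.
#' @param beta0 n x 3 momenta.
#' @param weights numeric length-3 `(w_d, w_a, w_m)` (default `c(5, 2, 1)`).
#' @param normalise_dist divide distances by `lambda_v` before squaring.
#' @param lambda_v kernel width used for normalisation (default 11).
#' @return symmetric n x n similarity matrix.
#' @export
similarity_matrix <- function(control_points, beta0, weights = c(5, 2, 1),
                              normalise_dist = TRUE, lambda_v = 11) {
  x <- matrix(as.numeric(control_points), ncol = 3)
  b <- matrix(as.numeric(beta0), ncol = 3)
  n <- nrow(x)
  D2 <- as.matrix(stats::dist(x))^2
  if (normalise_dist) D2 <- D2 / lambda_v^2
  nb2 <- rowSums(b^2)
  nb <- sqrt(nb2)
  denom <- outer(nb, nb)
  cosM <- b %*% t(b)
  nz <- denom > 0
  cosM[nz] <- cosM[nz] / denom[nz]
  cosM[!nz] <- 0
  cosM <- pmin(1, pmax(-1, cosM))
  S <- -weights[1] * D2 + weights[2] * (cosM + 1) -
    weights[3] * abs(outer(nb2, nb2, `-`))
  (S + t(S)) / 2
}

# Yu-Shi style discretisation of a spectral embedding: find an orthogonal
# rotation R and a discrete indicator M minimising |X R - M|_F by
# alternating argmax assignment and orthogonal Procrustes. Returns labels.
.discretise_embedding <- function(X, K, max_rounds = 30) {
  n <- nrow(X)
  # farthest-first initial rotation columns from embedding rows
  R <- matrix(0, K, K)
  i0 <- sample.int(n, 1)
  R[, 1] <- X[i0, ]
  if (K > 1) {
    c_acc <- rep(0, n)
    for (j in 2:K) {
      c_acc <- c_acc + abs(X %*% R[, j - 1])
      R[, j] <- X[which.min(c_acc), ]
    }
  }
  qrR <- qr(R)
  R <- qr.Q(qrR)
  last <- -Inf
  labels <- NULL
  for (round in seq_len(max_rounds)) {
    Y <- X %*% R
    labels <- max.col(Y, ties.method = "first")
    M <- matrix(0, n, K)
    M[cbind(seq_len(n), labels)] <- 1
    sv <- svd(crossprod(X, M))
    obj <- sum(sv$d)
    if (is.finite(last) && abs(obj - last) < 1e-10 * max(1, abs(obj))) break
    last <- obj
    R <- sv$u %*% t(sv$v)
  }
  labels
}

#' Spectral clustering of the trajectory parametrisation
#'
#' Groups the control points of the regression parametrisation into `K`
#' clusters from a similarity matrix. Similarities are mapped to positive
#' affinities by `exp(s / tau)` with `tau` the interquartile range of the
#' off-diagonal similarities (a scale-free choice; planted-partition
#' recovery is insensitive to `tau` within a factor of four). The
#' normalised affinity `D^{-1/2} A D^{-1/2}` is embedded into its top `K`
#' eigenvectors (rows normalised to unit length) and labels are extracted
#' by the discretisation approach (orthogonal-rotation rounding, more
#' stable than k-means), restarted `n_init` times with a seeded RNG; the
#' labelling with the lowest within-cluster inertia in the embedding space
#' is returned.
#'
#' @param similarity symmetric n x n similarity matrix.
#' @param K number of clusters (default 10).
#' @param seed RNG seed for the restarts.
#' @param n_init number of discretisation restarts (default 3000; a few
#'   tens suffice on well-separated problems).
#' @param tau optional explicit affinity temperature.
#' @return object of class `ClusterModel`: `labels` (length n), `K`,
#'   `similarity`, `tau`, `seed`, `n_init`, `inertia`.
#' @export
cluster_parametrisation <- function(similarity, K = 10, seed = 1,
                                    n_init = 3000, tau = NULL) {
  n <- nrow(similarity)
  stopifnot(n >= K, K >= 1)
  if (K == n) {
    return(structure(list(labels = seq_len(n), K = K,
                          similarity = similarity, tau = NA_real_,
                          seed = seed, n_init = n_init, inertia = 0),
                     class = "ClusterModel"))
  }
  off <- similarity[upper.tri(similarity)]
  if (is.null(tau)) {
    tau <- stats::IQR(off)
    if (!is.finite(tau) || tau <= 0) tau <- max(stats::sd(off), 1)
  }
  A <- exp(similarity / tau)
  d <- rowSums(A)
  if (any(d - diag(A) <= .Machine$double.xmin))
    stop("disconnected affinity graph; use a larger tau")
  L <- A / sqrt(d) / rep(sqrt(d), each = n)
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  X <- eig$vectors[, seq_len(K), drop = FALSE]
  rn <- sqrt(rowSums(X^2))
  rn[rn == 0] <- 1
  X <- X / rn
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      labels <- .discretise_embedding(X, K)
      if (length(unique(labels)) < K) next  # empty cluster: invalid
      cen <- rowsum(X, labels)
      cnt <- as.numeric(table(factor(labels, levels = sort(unique(labels)))))
      cen <- cen / cnt
      inertia <- sum((X - cen[match(labels, sort(unique(labels))), ])^2)
      if (is.null(best) || inertia < best$inertia - 1e-12)
        best <- list(labels = labels, inertia = inertia)
    }
  })
  if (is.null(best)) {
    warning("discretisation produced empty clusters in every restart; ",
            "falling back to k-means in the embedding space")
    km <- with_seed(seed, stats::kmeans(X, K, nstart = 50))
    best <- list(labels = km$cluster, inertia = km$tot.withinss)
  }
  structure(list(labels = best$labels, K = K, similarity = similarity,
                 tau = tau, seed = seed, n_init = n_init,
                 inertia = best$inertia),
            class = "ClusterModel")
}

#' Per-cluster mean momentum vectors
#'
#' For each subject, averages the rows of the transported residual momenta
#' `theta0` over each cluster's control points.
#'
#' @param model a `ClusterModel`.
#' @param theta0 n x 3 transported momenta of one subject, anchored at the
#'   clustered control points.
#' @return K x 3 matrix of mean vectors (row k = cluster k).
#' @export
cluster_mean_vectors <- function(model, theta0) {
  theta0 <- matrix(as.numeric(theta0), ncol = 3)
  stopifnot(nrow(theta0) == length(model$labels))
  f <- factor(model$labels, levels = seq_len(model$K))
  cnt <- as.numeric(table(f))
  out <- rowsum(theta0, f) / cnt
  unname(out)
}

#' Amplitude and orientation descriptors
#'
#' Reduces each subject's per-cluster mean vector `nu` to two uncorrelated
#' scalars. The amplitude is the Euclidean norm. The orientation starts
#' from the three direction angles `acos(nu_a / |nu|)` (a zero vector is
#' assigned the neutral angles `(pi/2, pi/2, pi/2)`); within each cluster
#' the subjects' 3-angle vectors are centred and projected onto their first
#' principal eigenvector, giving one scalar per subject; the eigenvector
#' sign is fixed so its largest-magnitude component is positive.
#'
#' @param nu numeric array `N_subjects x K x 3` of cluster mean vectors.
#' @param meta data.frame with N rows: `subject_id`, `eyo`, `group`,
#'   `sex`, `site`, `family_id`.
#' @return a `ClusterFeatureTable` data.frame: the metadata columns plus
#'   `amp_c1..amp_cK` and `ori_c1..ori_cK`.
#' @export
amplitude_and_orientation <- function(nu, meta) {
  stopifnot(length(dim(nu)) == 3, dim(nu)[3] == 3,
            dim(nu)[1] == nrow(meta))
  N <- dim(nu)[1]; K <- dim(nu)[2]
  amp <- matrix(0, N, K)
  ori <- matrix(0, N, K)
  for (k in seq_len(K)) {
    vk <- nu[, k, , drop = TRUE]
    if (N == 1) vk <- matrix(vk, 1, 3)
    nr <- sqrt(rowSums(vk^2))
    amp[, k] <- nr
    ang <- matrix(pi / 2, N, 3)
    pos <- nr > 0
    if (any(pos))
      ang[pos, ] <- acos(pmin(1, pmax(-1, vk[pos, , drop = FALSE] /
                                        nr[pos])))
    cen <- sweep(ang, 2, colMeans(ang))
    if (sum(cen^2) < 1e-24) {
      ori[, k] <- 0
    } else {
      ev <- eigen(crossprod(cen) / max(1, N - 1), symmetric = TRUE)$vectors[, 1]
      if (ev[which.max(abs(ev))] < 0) ev <- -ev
      ori[, k] <- as.numeric(cen %*% ev)
    }
  }
  colnames(amp) <- paste0("amp_c", seq_len(K))
  colnames(ori) <- paste0("ori_c", seq_len(K))
  out <- cbind(meta, as.data.frame(amp), as.data.frame(ori))
  class(out) <- c("ClusterFeatureTable", class(out))
  out
}

#' Build the full feature table from transported residuals
#'
#' Convenience wrapper: stacks [cluster_mean_vectors()] over subjects and
#' applies [amplitude_and_orientation()].
#'
#' @param model a `ClusterModel`.
#' @param records list of `ResidualRecord` with `theta0` filled.
#' @param meta data.frame of per-subject covariates (one row per record).
#' @return a `ClusterFeatureTable`.
#' @export
feature_table <- function(model, records, meta) {
  N <- length(records)
  nu <- array(0, c(N, model$K, 3))
  for (i in seq_len(N)) {
    if (is.null(records[[i]]$theta0))
      stop("record ", i, " has no transported momenta; run ",
           "transport_residuals() first")
    nu[i, , ] <- cluster_mean_vectors(model, records[[i]]$theta0)
  }
  amplitude_and_orientation(nu, meta)
}
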