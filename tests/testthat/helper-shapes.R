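# Shared fixtures and independent oracles. Fixtures are built in code; no
# binary data.

# one unit right triangle in the z = 0 plane
unit_triangle <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
}

tetrahedron <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# small random open mesh: jittered planar grid patch
random_patch <- function(nx = 4, ny = 3, sd = 0.1, seed = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  V <- cbind(g$x, g$y, 0) + matrix(rnorm(nrow(g) * 3, sd = sd), ncol = 3)
  idx <- function(i, j) (j - 1) * nx + i
  Tr <- NULL
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    Tr <- rbind(Tr, c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  tri_mesh(V, Tr)
}

# independent O(M^2) double-loop varifold oracle (plain R, no shared code
# with the implementation path)
varifold_inner_oracle <- function(ma, mb, lam) {
  ct <- function(m) {
    k <- nrow(m$triangles)
    cs <- matrix(0, k, 3); ts <- matrix(0, k, 3)
    for (f in seq_len(k)) {
      v <- m$vertices[m$triangles[f, ], ]
      cs[f, ] <- colMeans(v)
      e1 <- v[2, ] - v[1, ]; e2 <- v[3, ] - v[1, ]
      ts[f, ] <- 0.5 * c(e1[2] * e2[3] - e1[3] * e2[2],
                         e1[3] * e2[1] - e1[1] * e2[3],
                         e1[1] * e2[2] - e1[2] * e2[1])
    }
    list(c = cs, t = ts)
  }
  A <- ct(ma); B <- ct(mb)
  s <- 0
  for (k in seq_len(nrow(A$c))) for (l in seq_len(nrow(B$c))) {
    s <- s + exp(-sum((A$c[k, ] - B$c[l, ])^2) / lam^2) *
      sum(A$t[k, ] * B$t[l, ])^2 /
      (sqrt(sum(A$t[k, ]^2)) * sqrt(sum(B$t[l, ]^2)))
  }
  s
}

varifold_sqdist_oracle <- function(ma, mb, lam) {
  varifold_inner_oracle(ma, ma, lam) -
    2 * varifold_inner_oracle(ma, mb, lam) +
    varifold_inner_oracle(mb, mb, lam)
}

# mm-scale ellipsoid for registration-type tests
small_ellipsoid <- function(subdiv = 1, axes = c(6, 4, 3)) {
  m <- icosphere(subdiv)
  m$vertices <- sweep(m$vertices, 2, axes, `*`)
  m
}

translate_mesh <- function(mesh, v) {
  mesh$vertices <- sweep(mesh$vertices, 2, v, `+`)
  mesh
}

vertex_rms <- function(a, b) sqrt(mean(rowSums((a$vertices - b$vertices)^2)))

# feature table from a simple generative model, for the stats tests
sim_feature_table <- function(n = 200, n_fam = 50, b_grp = 0, b_int = 0,
                              fam_sd = 1, res_sd = 1, seed = 1,
                              hinge = FALSE, onset = -10) {
  set.seed(seed)
  fam <- sample(n_fam, n, replace = TRUE)
  eyo <- runif(n, -40, 20)
  grp <- rbinom(n, 1, 113 / 211)
  eff <- if (hinge) b_int * grp * pmax(0, eyo - onset)
         else b_grp * grp + b_int * grp * eyo
  y <- eff + rnorm(n_fam, sd = fam_sd)[fam] + rnorm(n, sd = res_sd)
  data.frame(subject_id = paste0("s", seq_len(n)), eyo = eyo,
             group = ifelse(grp == 1, "carrier", "noncarrier"),
             sex = sample(c("M", "F"), n, TRUE),
             site = sample(paste0("site", 1:5), n, TRUE),
             family_id = paste0("f", fam),
             amp_c1 = y, ori_c1 = y,
             stringsAsFactors = FALSE)
}
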