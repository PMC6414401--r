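test_that("similarity matrix follows the printed formula", {
  x <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0))
  S <- similarity_matrix(x, b, normalise_dist = FALSE)
  # diagonal: -0 + 2(cos 0 + 1) - 0 = 4 for any nonzero momentum
  expect_equal(unname(diag(S)), rep(4, 3))
  # coincident points, opposite equal-norm momenta: 0 + 2(-1+1) - 0 = 0
  expect_equal(S[1, 2], 0)
  # 1 mm apart, identical unit momenta: -5 + 4 - 0 = -1
  expect_equal(S[1, 3], -1)
  expect_true(isSymmetric(S))
  # zero-momentum convention: cos := 0
  S0 <- similarity_matrix(rbind(c(0, 0, 0), c(0, 0, 0)),
                          rbind(c(0, 0, 0), c(1, 0, 0)),
                          normalise_dist = FALSE)
  expect_equal(S0[1, 2], 2 - 1)   # 2(0+1) - |0 - 1|
  # normalisation divides distances by lambda_v before squaring
  Sn <- similarity_matrix(x, b, normalise_dist = TRUE, lambda_v = 2)
  expect_equal(Sn[1, 3], -5 / 4 + 4)
})

test_that("spectral clustering recovers a planted partition exactly and deterministically", {
  set.seed(11)
  n1 <- 30; n2 <- 25
  pts <- rbind(cbind(rnorm(n1, 0, .5), rnorm(n1, 0, .5), rnorm(n1, 0, .5)),
               cbind(rnorm(n2, 30, .5), rnorm(n2, 0, .5), rnorm(n2, 0, .5)))
  mom <- rbind(matrix(rep(c(1, 0, 0), n1), ncol = 3, byrow = TRUE),
               matrix(rep(c(0, 1, 0), n2), ncol = 3, byrow = TRUE))
  sim <- similarity_matrix(pts, mom)
  truth <- rep(1:2, c(n1, n2))
  agree <- function(l) max(mean(l == truth), mean(l == 3 - truth))
  cl <- cluster_parametrisation(sim, K = 2, seed = 1, n_init = 50)
  expect_equal(agree(cl$labels), 1)
  expect_true(all(table(cl$labels) > 0))
  # same seed: identical labels; other seeds: same partition
  cl2 <- cluster_parametrisation(sim, K = 2, seed = 1, n_init = 50)
  expect_identical(cl$labels, cl2$labels)
  for (sd in c(7, 23)) {
    expect_equal(agree(cluster_parametrisation(sim, K = 2, seed = sd,
                                               n_init = 50)$labels), 1)
  }
  # the planted partition survives a 4x change of temperature
  for (f in c(0.25, 4)) {
    clt <- cluster_parametrisation(sim, K = 2, seed = 1, n_init = 50,
                                   tau = cl$tau * f)
    expect_equal(agree(clt$labels), 1)
  }
})

test_that("K = n yields singletons and labels are reorder-equivariant", {
  set.seed(2)
  pts <- matrix(rnorm(24, sd = 3), 8)
  mom <- matrix(rnorm(24), 8)
  sim <- similarity_matrix(pts, mom)
  cl <- cluster_parametrisation(sim, K = 8, seed = 1, n_init = 5)
  expect_identical(sort(cl$labels), 1:8)
  # permutation of the points permutes the labels (up to relabelling)
  set.seed(3)
  n1 <- 12; n2 <- 12
  pts2 <- rbind(cbind(rnorm(n1), rnorm(n1), rnorm(n1)),
                cbind(rnorm(n2, 25), rnorm(n2), rnorm(n2)))
  mom2 <- matrix(rnorm(3 * (n1 + n2)), ncol = 3)
  perm <- sample(n1 + n2)
  s1 <- similarity_matrix(pts2, mom2)
  s2 <- similarity_matrix(pts2[perm, ], mom2[perm, ])
  l1 <- cluster_parametrisation(s1, K = 2, seed = 4, n_init = 30)$labels
  l2 <- cluster_parametrisation(s2, K = 2, seed = 4, n_init = 30)$labels
  expect_true(all(l1[perm] == l2[1]) || all(l1[perm] == 3 - l2))
})

test_that("cluster mean vectors match a hand-rolled group-by mean", {
  model <- structure(list(labels = c(1, 2, 1, 3, 2), K = 3),
                     class = "ClusterModel")
  # constant rows: every mean equals that row
  th <- matrix(rep(c(1, 2, 3), each = 5), 5)
  expect_equal(cluster_mean_vectors(model, th),
               matrix(rep(c(1, 2, 3), each = 3), 3))
  # opposite vectors in one cluster cancel
  th2 <- rbind(c(1, 0, 0), c(5, 5, 5), c(-1, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_equal(cluster_mean_vectors(model, th2)[1, ], c(0, 0, 0))
  # random fixture vs aggregate()
  set.seed(4)
  th3 <- matrix(rnorm(15), 5)
  byhand <- as.matrix(aggregate(th3, list(model$labels), mean)[, -1])
  expect_lt(max(abs(cluster_mean_vectors(model, th3) - unname(byhand))),
            1e-12)
})

test_that("amplitude and orientation descriptors behave as specified", {
  meta1 <- data.frame(subject_id = "s", eyo = 0, group = "carrier",
                      sex = "M", site = "a", family_id = "f")
  ft <- amplitude_and_orientation(array(c(3, 0, 0), c(1, 1, 3)), meta1)
  expect_equal(ft$amp_c1, 3)
  # all subjects sharing one direction: centred projection is all-zero
  nu <- array(rep(c(1, 2, 2), each = 10), c(10, 1, 3))
  meta10 <- data.frame(subject_id = paste0("s", 1:10), eyo = 0,
                       group = "carrier", sex = "M", site = "a",
                       family_id = paste0("f", 1:10))
  ft2 <- amplitude_and_orientation(nu, meta10)
  expect_equal(ft2$ori_c1, rep(0, 10))
  expect_equal(ft2$amp_c1, rep(3, 10))
})

test_that("a planted 30-degree direction split separates groups in orientation only", {
  set.seed(14)
  N <- 100
  grp <- rep(c(0, 1), each = 50)
  th <- 30 * pi / 180
  R30 <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  nu <- array(0, c(N, 1, 3))
  for (i in 1:N) {
    d <- c(0, 1, 0.2) + rnorm(3, sd = 0.05)
    if (grp[i] == 1) d <- as.numeric(R30 %*% d)
    nu[i, 1, ] <- d / sqrt(sum(d^2)) * 2
  }
  meta <- data.frame(subject_id = paste0("s", 1:N), eyo = 0,
                     group = ifelse(grp == 1, "carrier", "noncarrier"),
                     sex = "M", site = "a", family_id = paste0("f", 1:N))
  ft <- amplitude_and_orientation(nu, meta)
  expect_gt(abs(t.test(ft$ori_c1 ~ ft$group)$statistic), 5)
  expect_equal(diff(tapply(ft$amp_c1, ft$group, mean)), c(noncarrier = 0))
})

test_that("amplitude and orientation are uncorrelated on isotropic vectors", {
  set.seed(1)
  nu <- array(rnorm(3000), c(1000, 1, 3))
  meta <- data.frame(subject_id = paste0("s", 1:1000), eyo = 0,
                     group = "carrier", sex = "M", site = "a",
                     family_id = "f")
  ft <- amplitude_and_orientation(nu, meta)
  expect_lt(abs(cor(ft$amp_c1, ft$ori_c1)), 0.1)
})

test_that("a global rotation of the momenta leaves amplitudes unchanged and orientation scores consistent", {
  set.seed(15)
  n <- 40; N <- 60
  labels <- rep(1:4, each = 10)
  model <- structure(list(labels = labels, K = 4), class = "ClusterModel")
  thetas <- lapply(1:N, function(i) {
    outer(rep(1, n), rnorm(3, sd = 0.5)) +
      matrix(rnorm(3 * n, sd = 0.05), ncol = 3)
  })
  th <- 15 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  meta <- data.frame(subject_id = paste0("s", 1:N), eyo = 0,
                     group = "carrier", sex = "M", site = "a",
                     family_id = paste0("f", 1:N))
  nu1 <- array(0, c(N, 4, 3)); nu2 <- nu1
  for (i in 1:N) {
    nu1[i, , ] <- cluster_mean_vectors(model, thetas[[i]])
    nu2[i, , ] <- cluster_mean_vectors(model, thetas[[i]] %*% t(R))
  }
  f1 <- amplitude_and_orientation(nu1, meta)
  f2 <- amplitude_and_orientation(nu2, meta)
  for (k in 1:4) {
    expect_lt(max(abs(f1[[paste0("amp_c", k)]] - f2[[paste0("amp_c", k)]])),
              1e-6)
    # orientation scores after a small rigid rotation stay essentially the
    # same 1-d summary (PCA refit; sign and scale may drift slightly)
    expect_gt(abs(cor(f1[[paste0("ori_c", k)]], f2[[paste0("ori_c", k)]])),
              0.95)
  }
})
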