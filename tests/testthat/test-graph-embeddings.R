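test_that("heat-kernel weights match definition and loop oracle", {
  v <- list(c(0, 0), c(1, 0), c(0, 2))
  W <- heat_kernel_weights(v, t = 1)
  expect_equal(diag(W), rep(1, 3))
  expect_equal(W[1, 2], exp(-1))
  expect_equal(W[1, 3], exp(-4))
  expect_error(heat_kernel_weights(v, t = 0), "positive")

  # identical items -> all-ones
  expect_equal(heat_kernel_weights(list(1:3, 1:3, 1:3), 2),
               matrix(1, 3, 3))

  set.seed(5)
  mats <- replicate(4, matrix(rnorm(4), 2, 2), simplify = FALSE)
  expect_equal(heat_kernel_weights(mats, 0.7),
               oracle_heat_weights(mats, 0.7), tolerance = 1e-14)
})

test_that("build_graph produces valid Laplacians and degenerate cases", {
  # two identical samples in one class: L = [[1,-1],[-1,1]]
  m0 <- matrix(1:4 * 1.0, 2, 2)
  set <- matrix_set(list(m0, m0, m0 + 1, m0 + 1), c(1, 1, 2, 2))
  g <- build_graph(set, t = 1)
  expect_equal(g$L[[1]], matrix(c(1, -1, -1, 1), 2, 2))

  # identical class means -> B all ones, H annihilates constants
  expect_equal(g$H %*% rep(1, set$Z), matrix(0, set$Z, 1), tolerance = 1e-14)

  # Laplacian PSD and zero row sums on random sets
  set.seed(6)
  rs <- random_matrix_set(5, Z = 3)
  g2 <- build_graph(rs, t = 2)
  for (s in 1:3) {
    L <- g2$L[[s]]
    expect_lt(max(abs(rowSums(L))), 1e-12)
    expect_gt(min(eigen(L, symmetric = TRUE)$values), -1e-10)
  }
  # class with one sample is rejected
  expect_error(build_graph(matrix_set(list(m0, m0, m0 + 1), c(1, 1, 2)), 1),
               "at least 2 samples")
})

test_that("Laplacian quadratic form equals the weighted pairwise sum", {
  set.seed(8)
  rs <- random_matrix_set(4, Z = 2, nf = 2, ng = 3)
  g <- build_graph(rs, t = 1.5)
  a <- rnorm(6)
  total_quad <- 0
  brute <- 0
  for (s in 1:2) {
    idx <- which(rs$labels == s)
    X <- vapply(rs$matrices[idx], vec, numeric(6))
    total_quad <- total_quad + drop(t(a) %*% X %*% g$L[[s]] %*% t(X) %*% a)
    y <- drop(t(a) %*% X)
    W <- g$W[[s]]
    for (i in seq_along(idx)) for (j in seq_along(idx))
      brute <- brute + 0.5 * W[i, j] * (y[i] - y[j])^2
  }
  expect_equal(total_quad, brute, tolerance = 1e-10 * max(1, abs(brute)))
})

test_that("DLPP separates well-separated point clouds", {
  set.seed(9)
  # two clouds along the first coordinate, separation 10 sigma
  mats <- c(lapply(1:10, function(i) matrix(rnorm(4, 0, 1), 1, 4)),
            lapply(1:10, function(i) matrix(rnorm(4, c(10, 0, 0, 0), 1), 1, 4)))
  set <- matrix_set(mats, rep(1:2, each = 10))
  fit <- fit_dlpp(set, d = 1, t = 100)  # t on the scale of the sq distances
  y <- embed_features(fit, set)
  mu <- tapply(y[, 1], set$labels, mean)
  s2 <- tapply(y[, 1], set$labels, sd)
  fisher <- abs(diff(mu)) / sqrt(mean(s2^2))
  expect_gt(fisher, 10 / sqrt(2) * 0.5)
  expect_error(fit_dlpp(set, d = 0), "d must be")
})

test_that("duplicating every sample leaves the DLPP subspace unchanged", {
  set.seed(10)
  rs <- random_matrix_set(5, Z = 2, nf = 2, ng = 2)
  dup <- matrix_set(c(rs$matrices, rs$matrices), c(rs$labels, rs$labels))
  f1 <- fit_dlpp(rs, d = 2, t = 5)
  f2 <- fit_dlpp(dup, d = 2, t = 5)
  expect_lt(max(principal_angles(f1$projection, f2$projection)), 1e-6)
})

test_that("one-sided methods collapse to their vector versions on n x 1 matrices", {
  set.seed(12)
  mats <- c(lapply(1:6, function(i) matrix(rnorm(4, 0), 4, 1)),
            lapply(1:6, function(i) matrix(rnorm(4, 2), 4, 1)))
  set <- matrix_set(mats, rep(1:2, each = 6))
  # with N_g = 1 the row-side scatters equal the vectorized scatters exactly.
  # A strong common ridge keeps the shared denominator well conditioned, so
  # the two (algebraically identical) formulations agree to solver precision.
  v2d <- fit_2ddlpp(set, d = 4, t = 1, ridge_eps = 0.1)
  v1d <- fit_dlpp(set, d = 4, t = 1, ridge_eps = 0.1)
  expect_equal(v2d$eigenvalues, v1d$eigenvalues, tolerance = 1e-8)

  l2d <- fit_2dlda(set, d = 4)
  l1d <- fit_lda(set, d = 4)
  expect_equal(l2d$eigenvalues, l1d$eigenvalues, tolerance = 1e-8)
})

test_that("2DDLPP scatters are symmetric PSD and handle degenerate within-class spread", {
  set.seed(13)
  rs <- random_matrix_set(6, Z = 2, nf = 3, ng = 5)
  fit <- fit_2ddlpp(rs, d = 2, t = 1)
  for (S in list(fit$P_w, fit$P_b)) {
    expect_equal(S, t(S), tolerance = 1e-12)
    expect_gt(min(eigen(S, symmetric = TRUE)$values), -1e-10)
  }

  # identical samples within each class, distinct means: P_w = 0 but the
  # regularized solve still returns d directions with small residual
  m1 <- matrix(1:6 * 1.0, 2, 3); m2 <- m1 + 3
  set0 <- matrix_set(list(m1, m1, m2, m2), c(1, 1, 2, 2))
  f0 <- fit_2ddlpp(set0, d = 2, t = 1)
  expect_equal(max(abs(f0$P_w)), 0)
  expect_length(f0$eigenvalues, 2)
  expect_true(all(is.finite(f0$projection)))
})

test_that("LDA recovers the separating axis and obeys the rank bound", {
  set.seed(14)
  mats <- c(lapply(1:15, function(i) matrix(c(rnorm(1, 0), rnorm(3, 0, 1)), 1, 4)),
            lapply(1:15, function(i) matrix(c(rnorm(1, 10), rnorm(3, 0, 1)), 1, 4)))
  set <- matrix_set(mats, rep(1:2, each = 15))
  fit <- fit_lda(set, d = 4)
  a <- fit$projection[, 1]
  expect_gt(abs(a[1]) / sqrt(sum(a^2)), 0.95)
  # Z - 1 = 1 informative direction; the rest collapse to ~0 eigenvalues
  expect_lt(fit$eigenvalues[2] / fit$eigenvalues[1], 1e-6)
})

test_that("embedding transform obeys shape contracts and is deterministic", {
  set.seed(15)
  rs <- random_matrix_set(5, Z = 2, nf = 3, ng = 4)
  f_m <- fit_2ddlpp(rs, d = 2, t = 1)
  out <- embed_features(f_m, rs)
  expect_equal(dim(out), c(10, 2 * 4))  # d x N_g vectorized
  f_v <- fit_dlpp(rs, d = 3, t = 1)
  out_v <- embed_features(f_v, rs)
  expect_equal(dim(out_v), c(10, 3))
  expect_identical(out_v, embed_features(f_v, rs))
  expect_error(embed_features(f_v, rs, d = 5), "range")

  # orthonormal full-dimension projection preserves pairwise distances
  p <- 3 * 4
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  iso <- structure(list(kind = "dlpp", projection = Q, eigenvalues = rep(1, p),
                        d = p, input_shape = c(3, 4)),
                   class = "embedding_model")
  yi <- embed_features(iso, rs)
  v <- do.call(rbind, lapply(rs$matrices, vec))
  expect_equal(as.numeric(dist(yi)), as.numeric(dist(v)), tolerance = 1e-10)
})

test_that("embeddings are invariant to sample ordering up to sign", {
  set.seed(16)
  rs <- random_matrix_set(5, Z = 2, nf = 2, ng = 3)
  perm <- sample(length(rs$matrices))
  rsp <- matrix_set(rs$matrices[perm], rs$labels[perm])
  f1 <- fit_2ddlpp(rs, d = 2, t = 1)
  f2 <- fit_2ddlpp(rsp, d = 2, t = 1)
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-8)
  expect_lt(max(principal_angles(f1$projection, f2$projection)), 1e-6)
})

test_that("generalized eigenpairs agree with a dense brute-force solver", {
  set.seed(17)
  for (p in c(4, 8)) {
    A <- crossprod(matrix(rnorm(p * p), p))
    B <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
    got <- b2ddlpp:::geigen_sd(A, B)
    want <- oracle_geigen(A, B)
    expect_equal(got$values, want$values, tolerance = 1e-8)
    expect_lt(b2ddlpp:::geigen_residual(A, B, got$values, got$vectors), 1e-8)
  }
})
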