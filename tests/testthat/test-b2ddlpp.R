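test_that("within-class covariances match hand evaluation on a 2-sample class", {
  # X1 - X2 = [[1,0],[0,0]]: both ordered pairs contribute, so
  # psi = (2 * W12 / (2*2)) * diag(1, 0) with W12 = exp(-1)
  X1 <- matrix(c(1, 0, 0, 0), 2, 2)
  X2 <- matrix(0, 2, 2)
  Y <- matrix(5, 2, 2)  # second class, two identical samples
  set <- matrix_set(list(X1, X2, Y, Y), c(1, 1, 2, 2))
  g <- build_graph(set, t = 1)
  w12 <- exp(-1)
  expect_equal(within_class_psi(set, g), (w12 / 2) * diag(c(1, 0)),
               tolerance = 1e-14)
  expect_equal(within_class_phi(set, g), (w12 / 2) * diag(c(1, 0)),
               tolerance = 1e-14)

  # identical samples everywhere -> zero scatter
  set0 <- matrix_set(list(Y, Y, Y + 1, Y + 1), c(1, 1, 2, 2))
  g0 <- build_graph(set0, 1)
  expect_equal(max(abs(within_class_psi(set0, g0))), 0)
  expect_equal(max(abs(within_class_phi(set0, g0))), 0)
})

test_that("psi, phi, S_BL, S_BR match the nested-loop oracles", {
  set.seed(20)
  for (rep in 1:3) {
    rs <- random_matrix_set(3, Z = 3, nf = 3, ng = 4, sd = 0.4)
    g <- build_graph(rs, t = 1)
    expect_equal(within_class_psi(rs, g),
                 oracle_psi(rs$matrices, rs$labels, 1), tolerance = 1e-12)
    expect_equal(within_class_phi(rs, g),
                 oracle_phi(rs$matrices, rs$labels, 1), tolerance = 1e-12)
    bs <- between_scatter(rs, g)
    want <- oracle_between(rs$matrices, rs$labels, 1)
    expect_equal(bs$S_BL, want$S_BL, tolerance = 1e-12)
    expect_equal(bs$S_BR, want$S_BR, tolerance = 1e-12)
  }
})

test_that("trace conservation ties phi, psi and the weighted total distance", {
  set.seed(21)
  for (rep in 1:10) {
    nf <- sample(2:4, 1); ng <- sample(2:5, 1)
    rs <- random_matrix_set(sample(3:5, 1), Z = 2, nf = nf, ng = ng, sd = 0.5)
    g <- build_graph(rs, t = 1)
    phi <- within_class_phi(rs, g)
    psi <- within_class_psi(rs, g)
    tot <- oracle_total_weighted_distance(rs$matrices, rs$labels, 1)
    expect_equal(2 * ng * sum(diag(phi)), tot, tolerance = 1e-10 * max(1, tot))
    expect_equal(2 * nf * sum(diag(psi)), tot, tolerance = 1e-10 * max(1, tot))
  }
})

test_that("between-class scatters: hand case, degeneracy, Kronecker form", {
  # Z = 2, F1 - F2 = [[1,0],[0,0]] -> S_BL = B12 diag(1,0), S_BR = diag(1,0)
  F1 <- matrix(c(1, 0, 0, 0), 2, 2)
  set <- matrix_set(list(F1, F1, matrix(0, 2, 2), matrix(0, 2, 2)),
                    c(1, 1, 2, 2))
  g <- build_graph(set, 1)
  bs <- between_scatter(set, g)
  b12 <- exp(-1)
  expect_equal(bs$S_BL, b12 * diag(c(1, 0)), tolerance = 1e-14)
  expect_equal(bs$S_BR, diag(c(1, 0)), tolerance = 1e-14)

  # equal class means -> degenerate
  m <- matrix(1:4 * 1.0, 2, 2)
  set_eq <- matrix_set(list(m, m + diag(c(0, 0)), m, m), c(1, 1, 2, 2))
  g_eq <- build_graph(set_eq, 1)
  expect_error(between_scatter(set_eq, g_eq), "between-class")

  # rank-1 mean difference: vectorized between scatter is exactly
  # S_BR %x% S_BL up to the trace normalization
  u <- c(1, 2); v <- c(0.5, -1)   # F1 - F2 = u v'
  D <- u %*% t(v)
  setk <- matrix_set(list(D, D, matrix(0, 2, 2), matrix(0, 2, 2)),
                     c(1, 1, 2, 2))
  gk <- build_graph(setk, 1)
  bsk <- between_scatter(setk, gk)
  # vec(uv') = v kron u, so the vectorized between scatter B * vec(D)vec(D)'
  # factors exactly as S_BR %x% S_BL
  Bab <- exp(-sum(D^2))
  expect_equal(bsk$S_BR %x% bsk$S_BL, Bab * tcrossprod(vec(D)),
               tolerance = 1e-10)
})

test_that("fit_b2ddlpp satisfies its eigen contracts", {
  set.seed(22)
  rs <- random_matrix_set(6, Z = 3, nf = 3, ng = 4, sd = 0.4)
  fit <- fit_b2ddlpp(rs, t = 1)
  # descending, nonnegative within tolerance
  expect_true(all(diff(fit$lambda) <= 1e-12))
  expect_true(all(diff(fit$gamma) <= 1e-12))
  expect_gt(min(fit$lambda), -1e-10)
  expect_gt(min(fit$gamma), -1e-10)
  # residuals of both generalized problems
  phi_r <- b2ddlpp:::ridge_regularize(fit$phi, fit$ridge_eps)
  psi_r <- b2ddlpp:::ridge_regularize(fit$psi, fit$ridge_eps)
  expect_lt(b2ddlpp:::geigen_residual(fit$S_BL, phi_r, fit$lambda, fit$U), 1e-8)
  expect_lt(b2ddlpp:::geigen_residual(fit$S_BR, psi_r, fit$gamma, fit$V), 1e-8)
  # eigenvalues agree with explicit phi^-1 S_BL
  expect_equal(fit$lambda, sort(Re(eigen(solve(phi_r, fit$S_BL))$values),
                                decreasing = TRUE), tolerance = 1e-8)
  # selection order is a permutation of the full index grid
  key <- paste(fit$selection_order[, 1], fit$selection_order[, 2])
  expect_equal(sort(key), sort(paste(rep(1:3, 4), rep(1:4, each = 3))))
})

test_that("exact rank-1 mean difference makes one eigenvalue product dominate", {
  set.seed(23)
  u <- c(0, 1, 0); v <- c(0, 0, 1, 0)
  M1 <- matrix(0, 3, 4)
  M2 <- 3 * u %*% t(v)
  # mean-preserving +/- perturbation pairs keep the class means EXACT, so
  # S_BL and S_BR are exactly rank one and only lambda_1 * gamma_1 survives
  E1 <- matrix(rnorm(12, sd = 0.3), 3, 4)
  E2 <- matrix(rnorm(12, sd = 0.3), 3, 4)
  rs <- matrix_set(list(M1 + E1, M1 - E1, M2 + E2, M2 - E2), c(1, 1, 2, 2))
  fit <- fit_b2ddlpp(rs, t = 1e6)  # wide kernel: weights ~ 1
  prods <- fit$lambda[fit$selection_order[, 1]] *
    fit$gamma[fit$selection_order[, 2]]
  expect_lt(prods[2] / prods[1], 1e-6)
})

test_that("fit is invariant to sample order up to column sign", {
  set.seed(24)
  rs <- random_matrix_set(5, Z = 2, nf = 3, ng = 4)
  perm <- sample(length(rs$matrices))
  fitp <- fit_b2ddlpp(matrix_set(rs$matrices[perm], rs$labels[perm]), t = 1)
  fit <- fit_b2ddlpp(rs, t = 1)
  expect_equal(fit$lambda, fitp$lambda, tolerance = 1e-9)
  expect_equal(abs(fit$U), abs(fitp$U), tolerance = 1e-6)
  expect_equal(abs(fit$V), abs(fitp$V), tolerance = 1e-6)
})

test_that("transform selects entries of U'XV in product order", {
  set.seed(25)
  rs <- random_matrix_set(4, Z = 2, nf = 3, ng = 4)
  fit <- fit_b2ddlpp(rs, t = 1)
  X <- rs$matrices[[1]]
  # d = 1 is the top-ranked bilinear form u_l' X v_j
  top <- fit$selection_order[1, ]
  y1 <- transform_b2ddlpp(fit, rs, d = 1)[1, ]
  expect_equal(y1, drop(crossprod(fit$U[, top[1]], X %*% fit$V[, top[2]])),
               tolerance = 1e-12)
  expect_error(transform_b2ddlpp(fit, rs, d = 0), "d must be")
  expect_error(transform_b2ddlpp(fit, rs, d = 13), "d must be")

  # full d is a permutation of vec(U'XV); X reconstructable when U, V invertible
  yf <- transform_b2ddlpp(fit, rs, d = 12)[1, ]
  Y <- crossprod(fit$U, X %*% fit$V)
  expect_equal(sort(yf), sort(vec(Y)), tolerance = 1e-12)
  Xrec <- t(solve(fit$U)) %*% Y %*% solve(fit$V)
  expect_equal(Xrec, X, tolerance = 1e-8)
})

test_that("vec(U'XV) equals (V kron U)' vec(X)", {
  set.seed(26)
  for (rep in 1:5) {
    X <- matrix(rnorm(12), 3, 4)
    U <- matrix(rnorm(9), 3, 3)
    V <- matrix(rnorm(16), 4, 4)
    lhs <- vec(crossprod(U, X %*% V))
    rhs <- drop(t(V %x% U) %*% vec(X))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("planted (row, column) support is recovered from matrix-Gaussian data", {
  hits <- 0
  for (s in 1:20) {
    u <- c(0, 1, 0); v <- c(0, 0, 1, 0)
    M2 <- 2.5 * u %*% t(v)
    rs <- generate_matrix_gaussian_set(list(matrix(0, 3, 4), M2),
                                       diag(3) * 0.3, diag(4) * 0.3,
                                       15, seed = 100 + s)
    fit <- fit_b2ddlpp(rs, t = 1e6)
    top <- fit$selection_order[1, ]
    # the top-ranked left/right eigenvectors must be dominated by the
    # planted row (2) and column (3)
    lu <- fit$U[, top[1]]; rv <- fit$V[, top[2]]
    if (which.max(abs(lu)) == 2 && which.max(abs(rv)) == 3) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
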