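# Independent brute-force oracles used to pin down every estimator.
# These are deliberately written as plain double loops over the defining
# sums, sharing no code with the package implementations.

oracle_heat_weights <- function(items, t) {
  n <- length(items)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    W[i, j] <- exp(-sum((items[[i]] - items[[j]])^2) / t)
  W
}

# psi = 1/(2 Nf) sum_s sum_{i,j} (Xi - Xj)'(Xi - Xj) Wij
oracle_psi <- function(mats, labels, t) {
  nf <- nrow(mats[[1]]); ng <- ncol(mats[[1]])
  S <- matrix(0, ng, ng)
  for (s in unique(labels)) {
    idx <- which(labels == s)
    for (i in idx) for (j in idx) {
      D <- mats[[i]] - mats[[j]]
      w <- exp(-sum(D^2) / t)
      S <- S + w * (t(D) %*% D)
    }
  }
  S / (2 * nf)
}

# phi = 1/(2 Ng) sum_s sum_{i,j} (Xi - Xj)(Xi - Xj)' Wij
oracle_phi <- function(mats, labels, t) {
  nf <- nrow(mats[[1]]); ng <- ncol(mats[[1]])
  S <- matrix(0, nf, nf)
  for (s in unique(labels)) {
    idx <- which(labels == s)
    for (i in idx) for (j in idx) {
      D <- mats[[i]] - mats[[j]]
      w <- exp(-sum(D^2) / t)
      S <- S + w * (D %*% t(D))
    }
  }
  S / (2 * ng)
}

oracle_class_means <- function(mats, labels) {
  lapply(sort(unique(labels)), function(s) {
    ms <- mats[labels == s]
    Reduce(`+`, ms) / length(ms)
  })
}

# S_BL = 1/2 sum_{a,b} (Fa - Fb)(Fa - Fb)' Bab ;
# S_BR = tr(S_BL)^-1 * 1/2 sum_{a,b} (Fa - Fb)'(Fa - Fb) Bab
oracle_between <- function(mats, labels, t) {
  means <- oracle_class_means(mats, labels)
  Z <- length(means)
  nf <- nrow(means[[1]]); ng <- ncol(means[[1]])
  SBL <- matrix(0, nf, nf); SBR <- matrix(0, ng, ng)
  for (a in seq_len(Z)) for (b in seq_len(Z)) {
    D <- means[[a]] - means[[b]]
    w <- exp(-sum(D^2) / t)
    SBL <- SBL + w * (D %*% t(D)) / 2
    SBR <- SBR + w * (t(D) %*% D) / 2
  }
  list(S_BL = SBL, S_BR = SBR / sum(diag(SBL)))
}

# Total heat-kernel-weighted squared Frobenius distance over within-class
# ordered pairs.
oracle_total_weighted_distance <- function(mats, labels, t) {
  tot <- 0
  for (s in unique(labels)) {
    idx <- which(labels == s)
    for (i in idx) for (j in idx) {
      d2 <- sum((mats[[i]] - mats[[j]])^2)
      tot <- tot + exp(-d2 / t) * d2
    }
  }
  tot
}

# Dense generalized eigensolve via explicit inversion, for cross-checking
# the Cholesky-based solver on small instances.
oracle_geigen <- function(A, B) {
  e <- eigen(solve(B, A))
  ord <- order(-Re(e$values))
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}

# A small labeled set of random matrices with Z classes.
random_matrix_set <- function(n_per_class, Z = 2, nf = 3, ng = 4, sd = 0.5,
                              mean_scale = 1) {
  mats <- list(); labels <- integer(0)
  for (s in seq_len(Z)) {
    M <- matrix(mean_scale * stats::rnorm(nf * ng), nf, ng)
    for (i in seq_len(n_per_class)) {
      mats[[length(mats) + 1L]] <- M + matrix(stats::rnorm(nf * ng, sd = sd), nf, ng)
      labels <- c(labels, s)
    }
  }
  matrix_set(mats, labels)
}

# Principal angles between the column spaces of two matrices.
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(sv, -1), 1))
}

# Tiny epoched set for pipeline tests: quick but still separable.
quick_synth <- function(seed, trials_per_class = 16, erd_depth = 0.6,
                        noise_sd = 0.4, trial_len_s = 1.5, n_channels = 6) {
  generate_dataset(synthetic_config(
    trials_per_class = trials_per_class, trial_len_s = trial_len_s,
    n_channels = n_channels, erd_depth = erd_depth, noise_sd = noise_sd,
    seed = seed))
}
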