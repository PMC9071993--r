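# Heat-kernel weight graphs and the four comparison embeddings:
# LDA, 2DLDA, DLPP and 2DDLPP.
#
# DLPP-family methods minimize the heat-kernel-weighted within-class spread
# of the projected samples over the weighted spread of the projected class
# means; the solutions are the smallest-eigenvalue directions of a
# generalized eigenproblem. LDA-family methods maximize the classical Fisher
# ratio and keep the largest-eigenvalue directions. Weights are always
# computed from the original (unprojected) data over ALL within-class pairs
# (a complete within-class graph; no k-nearest-neighbor truncation).

#' Heat-kernel similarity weights
#'
#' `W[i, j] = exp(-||item_i - item_j||_F^2 / t)`, with unit diagonal. Items
#' may be vectors or matrices of one common shape; the Frobenius (Euclidean)
#' norm is used either way. `t` controls the locality scale; following common
#' practice for CSP-derived features it defaults to 1 throughout the package.
#'
#' @param items list of numeric vectors or matrices, all the same shape.
#' @param t positive heat-kernel bandwidth.
#' @return symmetric `n x n` weight matrix with entries in `(0, 1]`.
#' @export
heat_kernel_weights <- function(items, t = 1) {
  if (t <= 0) stop("heat-kernel parameter t must be positive", call. = FALSE)
  n <- length(items)
  W <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d2 <- sum((items[[i]] - items[[j]])^2)
      W[i, j] <- W[j, i] <- exp(-d2 / t)
    }
  }
  W
}

#' Build the within/between-class weight graph
#'
#' Computes per-class heat-kernel weight matrices `W_s` with their Laplacians
#' `L_s = D_s - W_s`, the class mean matrices `F_s`, the between-class weight
#' matrix `B` over the class means, and `H = E - B` where `E` is the diagonal
#' of `B`'s row sums. All Laplacians annihilate the constant vector and are
#' positive semidefinite.
#'
#' @param set a [matrix_set()]; every class needs at least 2 samples.
#' @param t heat-kernel bandwidth (default 1).
#' @return A `weight_graph` list with `W` (per-class list), `L` (per-class
#'   Laplacians), `means`, `B`, `E`, `H`, `t`.
#' @export
build_graph <- function(set, t = 1) {
  stopifnot(inherits(set, "matrix_set"))
  if (any(set$n_s < 2))
    stop("every class needs at least 2 samples to form within-class weights",
         call. = FALSE)
  by_class <- split_by_class(set)
  W <- lapply(by_class, heat_kernel_weights, t = t)
  L <- lapply(W, function(w) diag(rowSums(w)) - w)
  means <- class_means(set)
  B <- heat_kernel_weights(means, t = t)
  E <- diag(rowSums(B), set$Z)
  structure(
    list(W = W, L = L, means = means, B = B, E = E, H = E - B, t = t,
         Z = set$Z, n_s = set$n_s),
    class = "weight_graph")
}

# --- shared embedding plumbing -------------------------------------------

new_embedding <- function(kind, projection, values, d, means, extra = list()) {
  projection <- unit_norm_columns(projection)
  structure(
    c(list(kind = kind, projection = projection, eigenvalues = values, d = d,
           class_means = means), extra),
    class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("%s embedding: projection %d x %d (d = %d)\n",
              toupper(x$kind), nrow(x$projection), ncol(x$projection), x$d))
  invisible(x)
}

# Data matrix of vectorized samples, columns ordered as stored.
vectorized_data <- function(set) {
  vapply(set$matrices, vec, numeric(set$N_f * set$N_g))
}

# Block-diagonal within-class Laplacian aligned with sample order.
assemble_block_laplacian <- function(set, graph) {
  n <- length(set$matrices)
  Lfull <- matrix(0, n, n)
  for (s in seq_len(set$Z)) {
    idx <- which(set$labels == s)
    Lfull[idx, idx] <- graph$L[[s]]
  }
  Lfull
}

# --- DLPP (vector) --------------------------------------------------------

#' Discriminant locality preserving projection (vector form)
#'
#' Vectorizes each feature matrix and solves
#' `X L X' a = lambda F H F' a`, where `X` stacks the vectorized samples as
#' columns, `L` is the block-diagonal within-class Laplacian and `F` holds
#' the vectorized class means. The `d` directions with the smallest
#' eigenvalues are retained (small within-class spread relative to
#' between-class mean spread). The denominator is ridge-regularized before
#' the solve because its rank cannot exceed `Z - 1`.
#'
#' @param set a [matrix_set()].
#' @param d number of output dimensions, `1 <= d <= N_f * N_g`.
#' @param t heat-kernel bandwidth (default 1).
#' @param ridge_eps ridge coefficient for the denominator (default `1e-6`).
#' @return An `embedding_model` of kind `"dlpp"`.
#' @export
fit_dlpp <- function(set, d, t = 1, ridge_eps = 1e-6) {
  p <- set$N_f * set$N_g
  if (d < 1 || d > p) stop(sprintf("d must be in 1..%d", p), call. = FALSE)
  graph <- build_graph(set, t)
  X <- vectorized_data(set)
  Lfull <- assemble_block_laplacian(set, graph)
  num <- X %*% Lfull %*% t(X)
  Fm <- vapply(graph$means, vec, numeric(p))
  den <- Fm %*% graph$H %*% t(Fm)
  sol <- geigen_sd_reg(num, den, ridge_eps)
  ord <- rev(seq_len(p))  # ascending eigenvalues
  new_embedding("dlpp", sol$vectors[, ord[seq_len(d)], drop = FALSE],
                sol$values[ord][seq_len(d)], d, graph$means,
                list(t = t, input_shape = c(set$N_f, set$N_g),
                     ridge_eps_used = sol$ridge_eps))
}

# --- 2DDLPP (one-sided matrix) -------------------------------------------

# Weighted pair scatter 0.5 * sum_ij w_ij (X_i - X_j)(X_i - X_j)' over rows.
row_pair_scatter <- function(mats, W) {
  nf <- nrow(mats[[1]])
  S <- matrix(0, nf, nf)
  n <- length(mats)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    D <- mats[[i]] - mats[[j]]
    S <- S + W[i, j] * tcrossprod(D)
  }
  S / 2
}

#' Two-dimensional DLPP (one-sided, left projection)
#'
#' Operates on the feature matrices directly. Builds the `N_f x N_f`
#' within-class pair scatter `P_w = 1/2 sum_s sum_ij W_ij^s (X_i - X_j)(X_i - X_j)'`
#' and the between-class mean scatter
#' `P_b = 1/2 sum_ij B_ij (F_i - F_j)(F_i - F_j)'`, solves
#' `P_w a = lambda P_b a` and keeps the `d` smallest-eigenvalue directions.
#' The transform is the left projection `Y = A'X` (the scatters live on the
#' row side, which for FBCSP feature matrices is the spectral side).
#'
#' @inheritParams fit_dlpp
#' @param d number of output rows, `1 <= d <= N_f`.
#' @return An `embedding_model` of kind `"2ddlpp"`.
#' @export
fit_2ddlpp <- function(set, d, t = 1, ridge_eps = 1e-6) {
  if (d < 1 || d > set$N_f)
    stop(sprintf("d must be in 1..%d", set$N_f), call. = FALSE)
  graph <- build_graph(set, t)
  by_class <- split_by_class(set)
  Pw <- matrix(0, set$N_f, set$N_f)
  for (s in seq_len(set$Z))
    Pw <- Pw + row_pair_scatter(by_class[[s]], graph$W[[s]])
  Pb <- row_pair_scatter(graph$means, graph$B)
  sol <- geigen_sd_reg(Pw, Pb, ridge_eps)
  ord <- rev(seq_len(set$N_f))
  new_embedding("2ddlpp", sol$vectors[, ord[seq_len(d)], drop = FALSE],
                sol$values[ord][seq_len(d)], d, graph$means,
                list(t = t, input_shape = c(set$N_f, set$N_g),
                     P_w = Pw, P_b = Pb, ridge_eps_used = sol$ridge_eps))
}

# --- LDA / 2DLDA ----------------------------------------------------------

#' Fisher linear discriminant analysis on vectorized feature matrices
#'
#' Classical LDA: maximizes `a' S_b a / a' S_w a` with the usual total
#' within-class and between-class scatters of the vectorized samples; keeps
#' the `d` largest-eigenvalue directions. At most `Z - 1` directions carry
#' discriminative information; the within-class scatter is
#' ridge-regularized.
#'
#' @inheritParams fit_dlpp
#' @return An `embedding_model` of kind `"lda"`.
#' @export
fit_lda <- function(set, d, ridge_eps = 1e-6) {
  p <- set$N_f * set$N_g
  if (d < 1 || d > p) stop(sprintf("d must be in 1..%d", p), call. = FALSE)
  X <- vectorized_data(set)
  means <- class_means(set)
  mu <- rowMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (s in seq_len(set$Z)) {
    ms <- vec(means[[s]])
    idx <- which(set$labels == s)
    Xc <- X[, idx, drop = FALSE] - ms
    Sw <- Sw + tcrossprod(Xc)
    Sb <- Sb + set$n_s[s] * tcrossprod(ms - mu)
  }
  sol <- geigen_sd_reg(Sb, Sw, ridge_eps)
  new_embedding("lda", sol$vectors[, seq_len(d), drop = FALSE],
                sol$values[seq_len(d)], d, means,
                list(input_shape = c(set$N_f, set$N_g), S_w = Sw, S_b = Sb,
                     ridge_eps_used = sol$ridge_eps))
}

#' One-sided two-dimensional LDA
#'
#' Row-side (left projection) analogue of Fisher LDA on the feature
#' matrices: `Sw = sum_s sum_i (X_i - F_s)(X_i - F_s)'`,
#' `Sb = sum_s n_s (F_s - Fbar)(F_s - Fbar)'`; keeps the `d` largest
#' generalized eigenvalue directions, transform `Y = A'X`.
#'
#' @inheritParams fit_2ddlpp
#' @return An `embedding_model` of kind `"2dlda"`.
#' @export
fit_2dlda <- function(set, d, ridge_eps = 1e-6) {
  if (d < 1 || d > set$N_f)
    stop(sprintf("d must be in 1..%d", set$N_f), call. = FALSE)
  means <- class_means(set)
  Fbar <- Reduce(`+`, set$matrices) / length(set$matrices)
  Sw <- matrix(0, set$N_f, set$N_f); Sb <- matrix(0, set$N_f, set$N_f)
  for (s in seq_len(set$Z)) {
    idx <- which(set$labels == s)
    for (i in idx) {
      D <- set$matrices[[i]] - means[[s]]
      Sw <- Sw + tcrossprod(D)
    }
    Db <- means[[s]] - Fbar
    Sb <- Sb + set$n_s[s] * tcrossprod(Db)
  }
  sol <- geigen_sd_reg(Sb, Sw, ridge_eps)
  new_embedding("2dlda", sol$vectors[, seq_len(d), drop = FALSE],
                sol$values[seq_len(d)], d, means,
                list(input_shape = c(set$N_f, set$N_g), S_w = Sw, S_b = Sb,
                     ridge_eps_used = sol$ridge_eps))
}

# --- transform ------------------------------------------------------------

#' Project a feature-matrix set through a fitted embedding
#'
#' Vector methods (`lda`, `dlpp`) emit one length-`d` vector per trial from
#' the vectorized matrix; one-sided matrix methods (`2dlda`, `2ddlpp`)
#' left-project `Y = A'X` and return the `d x N_g` result vectorized to
#' length `d * N_g` for the classifier.
#'
#' @param model an `embedding_model`.
#' @param set a [matrix_set()] with the shape the model was fitted on.
#' @param d optional truncation `<=` the fitted `d` (directions are nested).
#' @return numeric matrix, one row per trial.
#' @export
embed_features <- function(model, set, d = model$d) {
  stopifnot(inherits(model, "embedding_model"), inherits(set, "matrix_set"))
  if (d < 1 || d > model$d) stop("d out of fitted range", call. = FALSE)
  if (any(model$input_shape != c(set$N_f, set$N_g)))
    stop("matrix shape differs from the fitted model", call. = FALSE)
  A <- model$projection[, seq_len(d), drop = FALSE]
  feats <- if (model$kind %in% c("lda", "dlpp")) {
    lapply(set$matrices, function(X) drop(crossprod(A, vec(X))))
  } else {
    lapply(set$matrices, function(X) vec(crossprod(A, X)))
  }
  do.call(rbind, feats)
}
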