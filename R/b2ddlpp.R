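# Bilinear 2D discriminant locality preserving projection.
#
# The within-class pair scatter of the spatial-spectral feature matrices is
# modeled as Kronecker-separable, following the matrix-variate Gaussian view
# in which cov(vec X) = psi %x% phi with a spectral (row) covariance phi and
# a spatial (column) covariance psi. Both within-class covariances and both
# between-class scatters are estimated as heat-kernel-weighted pair sums;
# the two resulting generalized eigenproblems give left/right projections
# U and V, the bilinear transform Y = U'XV, and a feature ranking by the
# eigenvalue products lambda_l * gamma_j.

#' Spatial (column-side) within-class covariance
#'
#' `psi = 1/(2 N_f) * sum_s sum_{i,j} (X_i^s - X_j^s)'(X_i^s - X_j^s) W_ij^s`,
#' an `N_g x N_g` symmetric positive-semidefinite matrix. Both ordered pairs
#' `(i, j)` and `(j, i)` contribute.
#'
#' @param set a [matrix_set()].
#' @param graph a [build_graph()] built from the same set.
#' @return `N_g x N_g` matrix.
#' @export
within_class_psi <- function(set, graph) {
  check_graph_match(set, graph)
  by_class <- split_by_class(set)
  S <- matrix(0, set$N_g, set$N_g)
  for (s in seq_len(set$Z)) {
    mats <- by_class[[s]]
    W <- graph$W[[s]]
    n <- length(mats)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      D <- mats[[i]] - mats[[j]]
      S <- S + W[i, j] * crossprod(D)
    }
  }
  S / (2 * set$N_f)
}

#' Spectral (row-side) within-class covariance
#'
#' `phi = 1/(2 N_g) * sum_s sum_{i,j} (X_i^s - X_j^s)(X_i^s - X_j^s)' W_ij^s`,
#' an `N_f x N_f` matrix; the row-side twin of [within_class_psi()]. The two
#' estimators share all weighted squared Frobenius distances, so
#' `2 N_g trace(phi) == 2 N_f trace(psi)` always holds.
#'
#' @inheritParams within_class_psi
#' @return `N_f x N_f` matrix.
#' @export
within_class_phi <- function(set, graph) {
  check_graph_match(set, graph)
  by_class <- split_by_class(set)
  S <- matrix(0, set$N_f, set$N_f)
  for (s in seq_len(set$Z)) {
    mats <- by_class[[s]]
    W <- graph$W[[s]]
    n <- length(mats)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      D <- mats[[i]] - mats[[j]]
      S <- S + W[i, j] * tcrossprod(D)
    }
  }
  S / (2 * set$N_g)
}

check_graph_match <- function(set, graph) {
  stopifnot(inherits(set, "matrix_set"), inherits(graph, "weight_graph"))
  if (graph$Z != set$Z || !all(vapply(seq_len(set$Z), function(s)
    nrow(graph$W[[s]]) == set$n_s[s], logical(1))))
    stop("graph was not built from this matrix set", call. = FALSE)
}

#' Between-class scatters of the class-mean matrices
#'
#' Left scatter `S_BL = 1/2 sum_{a,b} (F_a - F_b)(F_a - F_b)' B_ab`
#' (`N_f x N_f`) and right scatter
#' `S_BR = trace(S_BL)^-1 * 1/2 sum_{a,b} (F_a - F_b)'(F_a - F_b) B_ab`
#' (`N_g x N_g`), with heat-kernel weights
#' `B_ab = exp(-||F_a - F_b||_F^2 / t)` between class means. The
#' `1/trace(S_BL)` factor keeps the Kronecker product `S_BR %x% S_BL` on the
#' scale of the vectorized between-class scatter.
#'
#' @inheritParams within_class_psi
#' @return list with `S_BL` and `S_BR`.
#' @export
between_scatter <- function(set, graph) {
  check_graph_match(set, graph)
  if (set$Z < 2) stop("need at least 2 classes", call. = FALSE)
  means <- graph$means
  B <- graph$B
  SBL <- matrix(0, set$N_f, set$N_f)
  SBR_raw <- matrix(0, set$N_g, set$N_g)
  for (a in seq_len(set$Z)) for (b in seq_len(set$Z)) {
    if (a == b) next
    D <- means[[a]] - means[[b]]
    SBL <- SBL + B[a, b] * tcrossprod(D)
    SBR_raw <- SBR_raw + B[a, b] * crossprod(D)
  }
  SBL <- SBL / 2
  SBR_raw <- SBR_raw / 2
  tr <- sum(diag(SBL))
  if (tr <= 0)
    stop("no between-class structure: all class means are equal (or between-class weights underflowed)",
         call. = FALSE)
  list(S_BL = SBL, S_BR = SBR_raw / tr)
}

#' Fit the bilinear discriminant projection
#'
#' Implements the one-shot bilinear training procedure: estimate the
#' within-class covariances `phi` (spectral) and `psi` (spatial) and the
#' between-class scatters `S_BL`, `S_BR`; ridge-regularize `phi` and `psi`;
#' solve the two generalized symmetric-definite eigenproblems
#' `S_BL u = lambda phi u` and `S_BR v = gamma psi v` (equivalent to the
#' eigendecompositions of `phi^-1 S_BL` and `psi^-1 S_BR`, but numerically
#' symmetric); sort both eigenvalue sets in descending order; and rank every
#' feature position `(l, j)` of the bilinear transform `Y = U'XV` by the
#' product `lambda_l * gamma_j`, largest first, ties broken by ascending
#' `(l, j)`.
#'
#' @param set a [matrix_set()]; at least 2 classes with 2 samples each.
#' @param t heat-kernel bandwidth (default 1).
#' @param ridge_eps ridge coefficient for `phi` and `psi` (default `1e-6`).
#' @return A `bilinear_model` with `U` (`N_f x N_f`), `V` (`N_g x N_g`),
#'   `lambda`, `gamma`, `selection_order` (2-column matrix of `(l, j)` index
#'   pairs, one row per feature in priority order), plus the estimated
#'   scatters and fit settings.
#' @examples
#' M <- list(matrix(0, 3, 4), matrix(c(1, rep(0, 11)), 3, 4))
#' set <- generate_matrix_gaussian_set(M, diag(3), diag(4), 10, seed = 2)
#' fit <- fit_b2ddlpp(set)
#' head(fit$selection_order)
#' @export
fit_b2ddlpp <- function(set, t = 1, ridge_eps = 1e-6) {
  stopifnot(inherits(set, "matrix_set"))
  if (set$Z < 2) stop("need at least 2 classes", call. = FALSE)
  graph <- build_graph(set, t)
  phi <- within_class_phi(set, graph)
  psi <- within_class_psi(set, graph)
  bs <- between_scatter(set, graph)
  left <- geigen_sd_reg(bs$S_BL, phi, ridge_eps)
  right <- geigen_sd_reg(bs$S_BR, psi, ridge_eps)
  if (any(!is.finite(left$values)) || any(!is.finite(right$values)))
    stop("non-finite eigenvalues in the bilinear solve", call. = FALSE)
  grid_l <- rep(seq_len(set$N_f), times = set$N_g)
  grid_j <- rep(seq_len(set$N_g), each = set$N_f)
  products <- left$values[grid_l] * right$values[grid_j]
  ord <- order(-products, grid_l, grid_j)
  sel <- cbind(l = grid_l[ord], j = grid_j[ord])
  structure(
    list(U = unit_norm_columns(left$vectors),
         V = unit_norm_columns(right$vectors),
         lambda = left$values, gamma = right$values,
         selection_order = sel,
         phi = phi, psi = psi, S_BL = bs$S_BL, S_BR = bs$S_BR,
         t = t, ridge_eps = c(left = left$ridge_eps, right = right$ridge_eps),
         input_shape = c(set$N_f, set$N_g)),
    class = "bilinear_model")
}

#' @export
print.bilinear_model <- function(x, ...) {
  cat(sprintf("Bilinear discriminant model: U %d x %d, V %d x %d\n",
              nrow(x$U), ncol(x$U), nrow(x$V), ncol(x$V)))
  cat(sprintf("Top eigenvalue product %.4g at (l = %d, j = %d)\n",
              x$lambda[x$selection_order[1, 1]] * x$gamma[x$selection_order[1, 2]],
              x$selection_order[1, 1], x$selection_order[1, 2]))
  invisible(x)
}

#' Bilinear transform with eigenvalue-product feature selection
#'
#' Per trial computes `Y = U'XV` and emits the entries of `Y` at the first
#' `d` positions of the fitted selection order (descending
#' `lambda_l * gamma_j`), in that order.
#'
#' @param model a [fit_b2ddlpp()] model.
#' @param set a [matrix_set()] with the fitted shape.
#' @param d number of features to keep, `1 <= d <= N_f * N_g`.
#' @return numeric matrix, one row per trial, `d` columns.
#' @export
transform_b2ddlpp <- function(model, set, d) {
  stopifnot(inherits(model, "bilinear_model"), inherits(set, "matrix_set"))
  if (any(model$input_shape != c(set$N_f, set$N_g)))
    stop("matrix shape differs from the fitted model", call. = FALSE)
  p <- set$N_f * set$N_g
  if (d < 1 || d > p) stop(sprintf("d must be in 1..%d", p), call. = FALSE)
  idx <- model$selection_order[seq_len(d), , drop = FALSE]
  feats <- lapply(set$matrices, function(X) {
    Y <- crossprod(model$U, X %*% model$V)
    Y[idx]
  })
  do.call(rbind, feats)
}
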