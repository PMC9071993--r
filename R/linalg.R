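# Internal linear-algebra helpers shared by CSP and the graph embeddings.

#' Generalized symmetric-definite eigendecomposition
#'
#' Solves `A v = lambda B v` for symmetric `A` and symmetric positive-definite
#' `B` via the Cholesky reduction `B = R'R`, computing the ordinary symmetric
#' eigendecomposition of `R^-T A R^-1` and back-transforming the vectors.
#' Both inputs are symmetrized first; ties keep `eigen()`'s deterministic
#' ordering. Eigenvector signs are fixed so the largest-magnitude coefficient
#' of each vector is positive, which makes results reproducible across
#' linear-algebra backends.
#'
#' @param A symmetric numeric matrix (numerator of the Rayleigh quotient).
#' @param B symmetric positive-definite matrix (denominator).
#' @return list with `values` (descending) and `vectors` (columns, B-orthonormal).
#' @keywords internal
#' @noRd
geigen_sd <- function(A, B) {
  A <- (A + t(A)) / 2
  B <- (B + t(B)) / 2
  R <- tryCatch(chol(B), error = function(e) {
    stop("denominator matrix is not positive definite; regularize before solving",
         call. = FALSE)
  })
  Rinv <- backsolve(R, diag(nrow(B)))
  M <- crossprod(Rinv, A %*% Rinv)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  V <- Rinv %*% e$vectors
  V <- fix_eigvec_signs(V)
  list(values = e$values, vectors = V)
}

# Largest-magnitude entry of each column made positive (first such entry on
# exact ties).
fix_eigvec_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' Ridge regularization proportional to the mean diagonal scale
#'
#' Returns `S + eps * trace(S)/dim * I`; used wherever a scatter or covariance
#' denominator can be rank-deficient (small classes, feature count above
#' sample count). When `trace(S)` is zero the identity scaled by `eps` is
#' added so the solve stays defined.
#' @keywords internal
#' @noRd
ridge_regularize <- function(S, eps) {
  p <- nrow(S)
  scale <- sum(diag(S)) / p
  if (scale <= 0) scale <- 1
  S + diag(eps * scale, p)
}

# Regularized generalized solve with ridge escalation. Starts from
# `eps * trace/dim` on the denominator; if the Cholesky factorization still
# fails (the denominator can be singular to machine precision whenever
# heat-kernel weights underflow or classes are few), the ridge grows by 1e3
# per attempt, with a message, until the solve succeeds.
geigen_sd_reg <- function(A, B, eps, max_eps = 1e6) {
  repeat {
    out <- tryCatch(geigen_sd(A, ridge_regularize(B, eps)),
                    error = function(e) NULL)
    if (!is.null(out)) {
      out$ridge_eps <- eps
      return(out)
    }
    eps <- eps * 1e3
    if (eps > max_eps)
      stop("generalized eigenproblem unsolvable even with heavy regularization",
           call. = FALSE)
    message(sprintf("denominator numerically singular; escalating ridge to %g", eps))
  }
}

# Columns rescaled to unit Euclidean norm. Generalized eigenvectors come out
# B-orthonormal, whose scale blows up when the denominator matrix is tiny
# (heat-kernel weights can be arbitrarily small); unit norm keeps projected
# features on a sane numeric scale without changing any direction.
unit_norm_columns <- function(V) {
  sweep(V, 2, pmax(sqrt(colSums(V^2)), .Machine$double.xmin), "/")
}

# Max residual ||A v - lambda B v|| over unit-normalized retained eigenpairs.
geigen_residual <- function(A, B, values, vectors) {
  res <- 0
  for (k in seq_along(values)) {
    v <- vectors[, k]
    v <- v / sqrt(sum(v^2))
    res <- max(res, sqrt(sum((A %*% v - values[k] * (B %*% v))^2)))
  }
  res
}
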