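# One-versus-rest filter-bank CSP.
#
# For every (band, class) pair a CSP problem is solved with that class as
# the positive partition; per trial the 2m log-normalized-variance features
# from each class's filters are laid out class-major along the columns and
# bands along the rows, yielding the N_f x N_g spatial-spectral feature
# matrix (N_g = 2 * m * Numclass) that the embedding methods consume.

# Trace-normalized spatial covariance of one trial (channels x samples).
trial_covariance <- function(X) {
  C <- tcrossprod(X)
  C / sum(diag(C))
}

#' Fit common spatial patterns for one band and one positive class
#'
#' Computes trace-normalized per-trial covariances, averages them within the
#' positive and negative partitions, and solves the composite generalized
#' eigenproblem `C+ w = lambda (C+ + C-) w`. The `m` eigenvectors with the
#' largest eigenvalues (maximal positive-class variance) and the `m` with the
#' smallest are retained, in that order, so column 1 of `W` is the strongest
#' positive-class filter. If the composite covariance is numerically
#' rank-deficient a ridge `eps * trace / n_channels` is added automatically
#' with a message.
#'
#' @param band_trials numeric 3-axis array `trials x channels x samples`
#'   (one band of one fold's training data).
#' @param is_positive logical per trial; both partitions must be non-empty.
#' @param m number of filter pairs; `2 * m <= n_channels`.
#' @param ridge_eps ridge coefficient used when the composite covariance
#'   cannot be factorized (default `1e-8`).
#' @return A `csp_filters` object with `W` (`channels x 2m`), eigenvalues
#'   `lambda` of the retained filters, and `m`.
#' @export
csp_fit <- function(band_trials, is_positive, m, ridge_eps = 1e-8) {
  stopifnot(length(dim(band_trials)) == 3,
            length(is_positive) == dim(band_trials)[1])
  n_ch <- dim(band_trials)[2]
  if (2 * m > n_ch)
    stop(sprintf("2m = %d exceeds the %d available channels", 2 * m, n_ch),
         call. = FALSE)
  if (!any(is_positive) || all(is_positive))
    stop("both the positive and negative partitions must be non-empty",
         call. = FALSE)
  covs <- lapply(seq_len(dim(band_trials)[1]),
                 function(tr) trial_covariance(band_trials[tr, , , drop = TRUE]))
  Cp <- Reduce(`+`, covs[is_positive]) / sum(is_positive)
  Cn <- Reduce(`+`, covs[!is_positive]) / sum(!is_positive)
  comp <- Cp + Cn
  sol <- tryCatch(geigen_sd(Cp, comp), error = function(e) {
    message("composite covariance rank-deficient; applying ridge regularization")
    geigen_sd(Cp, ridge_regularize(comp, ridge_eps))
  })
  keep <- c(seq_len(m), seq(n_ch - m + 1, n_ch))
  structure(
    list(W = sol$vectors[, keep, drop = FALSE],
         lambda = sol$values[keep], m = m),
    class = "csp_filters")
}

#' CSP log-variance features of one trial
#'
#' Projects a `channels x samples` trial through the spatial filters and
#' returns `f_k = log(var_k / sum_j var_j)`, the standard FBCSP feature.
#' The normalization makes features invariant to global amplitude scaling.
#'
#' @param trial numeric `channels x samples` matrix.
#' @param filters a [csp_fit()] object.
#' @return numeric vector of length `2m`.
#' @export
csp_features <- function(trial, filters) {
  stopifnot(inherits(filters, "csp_filters"),
            nrow(trial) == nrow(filters$W))
  proj <- crossprod(filters$W, trial)
  v <- apply(proj, 1, stats::var)
  if (any(v <= 0))
    stop(sprintf("zero-variance projection for spatial filter %d", which(v <= 0)[1]),
         call. = FALSE)
  log(v / sum(v))
}

#' Fit the full one-versus-rest filter-bank CSP model
#'
#' Solves one CSP problem per (band, class) pair with that class as the
#' positive partition against the rest. The layout of transformed feature
#' matrices is frozen in the model: rows follow the band order, columns are
#' class-major (class 1's 2m features, then class 2's, ...).
#'
#' @param banded a [apply_filter_bank()] result.
#' @param m number of CSP filter pairs, typically 1..4.
#' @return An `ovr_fbcsp` model.
#' @export
fit_ovr_fbcsp <- function(banded, m) {
  stopifnot(inherits(banded, "band_filtered"), banded$Z >= 2)
  n_bands <- dim(banded$data)[1]
  filters <- vector("list", n_bands)
  for (b in seq_len(n_bands)) {
    band_data <- banded$data[b, , , , drop = TRUE]
    if (length(dim(band_data)) != 3) dim(band_data) <- dim(banded$data)[2:4]
    filters[[b]] <- lapply(seq_len(banded$Z), function(cls)
      csp_fit(band_data, banded$labels == cls, m))
  }
  structure(
    list(filters = filters, m = m, Z = banded$Z, bands = banded$bands,
         n_channels = dim(banded$data)[3],
         layout = "rows: bands in design order; cols: class-major, 2m CSP features per class"),
    class = "ovr_fbcsp")
}

#' @export
print.ovr_fbcsp <- function(x, ...) {
  cat(sprintf("OVR-FBCSP model: %d bands x %d classes, m = %d (N_g = %d)\n",
              length(x$filters), x$Z, x$m, 2 * x$m * x$Z))
  invisible(x)
}

#' Transform band-filtered epochs to spatial-spectral feature matrices
#'
#' Emits one `N_f x N_g` matrix per trial (`N_g = 2 * m * Numclass`): row `r`
#' holds band `r`'s features, laid out class-major per the fitted layout.
#'
#' @param model a fitted [fit_ovr_fbcsp()] model.
#' @param banded band-filtered epochs from the same montage and band set.
#' @return A [matrix_set()] labeled with the trials' classes.
#' @export
transform_ovr_fbcsp <- function(model, banded) {
  stopifnot(inherits(model, "ovr_fbcsp"), inherits(banded, "band_filtered"))
  if (dim(banded$data)[1] != length(model$filters))
    stop("band count differs from the fitted model", call. = FALSE)
  if (dim(banded$data)[3] != model$n_channels)
    stop("channel montage differs from the fitted model", call. = FALSE)
  n_trials <- dim(banded$data)[2]
  n_bands <- length(model$filters)
  ng <- 2 * model$m * model$Z
  mats <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    X <- matrix(0, n_bands, ng)
    for (b in seq_len(n_bands)) {
      trial <- banded$data[b, tr, , , drop = TRUE]
      if (is.null(dim(trial))) dim(trial) <- dim(banded$data)[3:4]
      feats <- unlist(lapply(model$filters[[b]], function(flt)
        csp_features(trial, flt)))
      X[b, ] <- feats
    }
    stopifnot(ncol(X) == ng)
    mats[[tr]] <- X
  }
  matrix_set(mats, banded$labels)
}
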