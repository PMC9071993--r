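# Core containers: epoched EEG and labeled sets of spatial-spectral feature
# matrices. Every downstream module consumes one of these two.

#' Validate and package epoched EEG
#'
#' Wraps a `trials x channels x samples` array and per-trial class labels into
#' a validated `epoched_eeg` object. Class labels are re-mapped to contiguous
#' integers `1..Z` (the mapping is recorded in `label_map`) and basic sanity
#' constraints are enforced: finite data, at least one second of signal per
#' trial, and at least two trials per class (one-trial classes make both CSP
#' covariances and within-class scatters undefined).
#'
#' @param raw numeric 3-axis array, `n_trials x n_channels x n_samples`
#'   (microvolts by convention; the pipeline is scale-invariant).
#' @param labels integer-like vector of per-trial class ids, length `n_trials`.
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_names optional character vector of length `n_channels`.
#' @return An `epoched_eeg` list with elements `data`, `labels` (re-mapped to
#'   `1..Z`), `fs`, `channel_names`, `label_map` (original label of each
#'   contiguous class id), `Z`, and per-class counts `n_s`.
#' @examples
#' x <- array(rnorm(4 * 2 * 300), dim = c(4, 2, 300))
#' ep <- validate_epochs(x, c(1, 1, 2, 2), fs = 250)
#' ep$Z
#' @export
validate_epochs <- function(raw, labels, fs, channel_names = NULL) {
  if (length(dim(raw)) != 3L)
    stop("`raw` must be a 3-axis array (trials x channels x samples)", call. = FALSE)
  n_trials <- dim(raw)[1]
  n_channels <- dim(raw)[2]
  n_samples <- dim(raw)[3]
  if (length(labels) != n_trials)
    stop(sprintf("length(labels) == %d but first axis has %d trials",
                 length(labels), n_trials), call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  if (n_samples < fs)
    stop(sprintf("trials have %d samples < fs = %g; need at least 1 s of data",
                 n_samples, fs), call. = FALSE)
  if (!all(is.finite(raw))) {
    bad <- which(!is.finite(raw), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite sample at trial %d, channel %d", bad[1], bad[2]),
         call. = FALSE)
  }
  if (!is.null(channel_names) && length(channel_names) != n_channels)
    stop("channel_names length does not match channel axis", call. = FALSE)

  uniq <- sort(unique(labels))
  Z <- length(uniq)
  if (Z < 2L)
    stop("need at least 2 classes; got a single class", call. = FALSE)
  mapped <- match(labels, uniq)
  n_s <- tabulate(mapped, nbins = Z)
  if (any(n_s < 2L))
    stop(sprintf("class %s has fewer than 2 trials", uniq[which(n_s < 2L)[1]]),
         call. = FALSE)

  structure(
    list(data = raw, labels = as.integer(mapped), fs = fs,
         channel_names = channel_names, label_map = uniq,
         Z = Z, n_s = n_s),
    class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched EEG: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("Classes (%d): %s trials\n", x$Z,
              paste(x$n_s, collapse = "/")))
  invisible(x)
}

#' Column-major vectorization
#'
#' Stacks the columns of a matrix into one vector, the `vec` operator. This
#' convention is fixed globally: the Kronecker-separable covariance identity
#' `cov(vec X) = psi %x% phi` (column covariance `psi`, row covariance `phi`)
#' and the bilinear projection identity `vec(U'XV) = t(V %x% U) vec(X)` hold
#' only under column stacking.
#'
#' @param X numeric matrix.
#' @return numeric vector of length `nrow(X) * ncol(X)`.
#' @seealso [unvec()] for the inverse.
#' @export
vec <- function(X) {
  stopifnot(is.matrix(X))
  dim(X) <- NULL
  X
}

#' Inverse of column-major vectorization
#' @param v numeric vector of length `n_rows * n_cols`.
#' @param n_rows,n_cols target dimensions.
#' @export
unvec <- function(v, n_rows, n_cols) {
  stopifnot(length(v) == n_rows * n_cols)
  matrix(v, nrow = n_rows, ncol = n_cols)
}

#' Bundle labeled feature matrices
#'
#' A `matrix_set` holds one `N_f x N_g` spatial-spectral feature matrix per
#' trial together with its class label; it is the common input of all the
#' embedding methods. All matrices must share one shape and class ids must be
#' contiguous `1..Z`.
#'
#' @param matrices list of numeric matrices of identical dimension.
#' @param labels integer class ids in `1..Z`, one per matrix.
#' @return A `matrix_set` with `matrices`, `labels`, `Z`, `n_s`, `N_f`, `N_g`.
#' @export
matrix_set <- function(matrices, labels) {
  stopifnot(is.list(matrices), length(matrices) >= 1L,
            length(labels) == length(matrices))
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all matrices must share identical (N_f, N_g)", call. = FALSE)
  if (any(!vapply(matrices, function(m) all(is.finite(m)), logical(1))))
    stop("non-finite values in feature matrices", call. = FALSE)
  labels <- as.integer(labels)
  Z <- max(labels)
  if (!setequal(unique(labels), seq_len(Z)))
    stop("labels must be contiguous 1..Z", call. = FALSE)
  n_s <- tabulate(labels, nbins = Z)
  structure(
    list(matrices = matrices, labels = labels, Z = Z, n_s = n_s,
         N_f = dims[1, 1], N_g = dims[2, 1]),
    class = "matrix_set")
}

#' @export
print.matrix_set <- function(x, ...) {
  cat(sprintf("Feature-matrix set: %d trials of %d x %d, %d classes (%s)\n",
              length(x$matrices), x$N_f, x$N_g, x$Z,
              paste(x$n_s, collapse = "/")))
  invisible(x)
}

# Split a matrix_set by class -> list of lists of matrices.
split_by_class <- function(set) {
  lapply(seq_len(set$Z), function(s) set$matrices[set$labels == s])
}

# Class mean matrices F_s.
class_means <- function(set) {
  lapply(split_by_class(set), function(ms) Reduce(`+`, ms) / length(ms))
}
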