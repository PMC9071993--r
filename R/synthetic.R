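# Synthetic motor-imagery EEG with planted, recoverable structure.
#
# Each trial is a sum of band-limited oscillatory sources projected through
# fixed channel mixing patterns, plus broadband sensor noise. Class identity
# is encoded the way event-related desynchronization (ERD) is observed in
# real motor imagery: the source "belonging" to a class has its amplitude
# attenuated during that class's trials, so class information lives purely in
# band-power over spatial patterns -- exactly what CSP-type methods recover.

#' Configuration for the synthetic ERD generator
#'
#' Defaults describe a small two-class left/right-hand benchmark: 8 channels
#' at 250 Hz, 3 s trials, 60 trials per class, two orthogonally mixed mu-band
#' (8-12 Hz) sources with 50% amplitude suppression (a strong but
#' physiological ERD depth) and broadband noise at half the source's channel
#' amplitude. Sized to run the full pipeline in seconds.
#'
#' @param n_classes number of classes (>= 2). Each class suppresses source
#'   `((class - 1) %% n_sources) + 1`.
#' @param n_channels number of channels (>= 4).
#' @param fs sampling rate (Hz).
#' @param trial_len_s trial length in seconds.
#' @param trials_per_class trials per class.
#' @param source_bands list of `c(low, high)` Hz pairs, one per source.
#' @param mixing_patterns list of unit-norm channel vectors, one per source;
#'   pairwise absolute cosine must be < 0.95. Default: the first
#'   `length(source_bands)` canonical basis vectors.
#' @param erd_depth fractional amplitude reduction in `[0, 1)` applied to the
#'   suppressed source of each class; 0 makes classes indistinguishable.
#' @param noise_sd standard deviation of white sensor noise per channel.
#' @param seed integer RNG seed; the generator is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_classes = 2, n_channels = 8, fs = 250,
                             trial_len_s = 3, trials_per_class = 60,
                             source_bands = list(c(8, 12), c(8, 12)),
                             mixing_patterns = NULL,
                             erd_depth = 0.5, noise_sd = 0.5, seed = 1L) {
  stopifnot(n_classes >= 2, n_channels >= 4, fs > 0, trial_len_s * fs >= fs,
            trials_per_class >= 2)
  if (erd_depth < 0 || erd_depth >= 1)
    stop("erd_depth must be in [0, 1)", call. = FALSE)
  if (noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)
  k <- length(source_bands)
  if (is.null(mixing_patterns)) {
    if (k > n_channels)
      stop("more sources than channels; supply mixing_patterns", call. = FALSE)
    mixing_patterns <- lapply(seq_len(k), function(i) {
      p <- numeric(n_channels); p[i] <- 1; p
    })
  }
  stopifnot(length(mixing_patterns) == k)
  for (p in mixing_patterns)
    if (length(p) != n_channels) stop("mixing pattern length != n_channels", call. = FALSE)
  mixing_patterns <- lapply(mixing_patterns, function(p) p / sqrt(sum(p^2)))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      cs <- abs(sum(mixing_patterns[[i]] * mixing_patterns[[j]]))
      if (cs >= 0.95)
        stop(sprintf("mixing patterns %d and %d nearly collinear (|cos| = %.3f)",
                     i, j, cs), call. = FALSE)
    }
  }
  structure(
    list(n_classes = n_classes, n_channels = n_channels, fs = fs,
         trial_len_s = trial_len_s, trials_per_class = trials_per_class,
         source_bands = source_bands, mixing_patterns = mixing_patterns,
         erd_depth = erd_depth, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_config")
}

# Unit-variance band-limited source: white noise shaped with the same
# Chebyshev-II design used by the analysis filter bank, then rescaled.
band_limited_source <- function(n, band, fs, order = 6, attenuation_db = 40) {
  flt <- signal::cheby2(order / 2, attenuation_db, W = band / (fs / 2),
                        type = "pass")
  # pad so filter transients do not bias the trial's variance
  pad <- 4 * fs
  x <- signal::filtfilt(flt, stats::rnorm(n + 2 * pad))
  x <- x[(pad + 1):(pad + n)]
  x / stats::sd(x)
}

#' Generate a synthetic ERD data set
#'
#' Draws `trials_per_class * n_classes` trials of
#' `trial = sum_k a_k(class) * p_k * s_k(t) + noise`, where `s_k` is a fresh
#' unit-variance band-limited source per trial, `p_k` its mixing pattern, and
#' `a_k(class) = 1 - erd_depth` when source `k` is the class's suppressed
#' source (1 otherwise). Trials are interleaved across classes and the result
#' is bit-reproducible given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return An `epoched_eeg` object.
#' @examples
#' ep <- generate_dataset(synthetic_config(trials_per_class = 4, trial_len_s = 1))
#' dim(ep$data)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_samples <- round(config$trial_len_s * config$fs)
  n_src <- length(config$source_bands)
  n_trials <- config$trials_per_class * config$n_classes
  labels <- rep(seq_len(config$n_classes), times = config$trials_per_class)
  data <- array(0, dim = c(n_trials, config$n_channels, n_samples))
  for (tr in seq_len(n_trials)) {
    cls <- labels[tr]
    suppressed <- ((cls - 1L) %% n_src) + 1L
    trial <- matrix(stats::rnorm(config$n_channels * n_samples,
                                 sd = config$noise_sd),
                    nrow = config$n_channels)
    for (k in seq_len(n_src)) {
      amp <- if (k == suppressed) 1 - config$erd_depth else 1
      s <- band_limited_source(n_samples, config$source_bands[[k]], config$fs)
      trial <- trial + amp * outer(config$mixing_patterns[[k]], s)
    }
    data[tr, , ] <- trial
  }
  validate_epochs(data, labels, config$fs)
}

#' Sample a labeled set from matrix-variate Gaussians
#'
#' Draws `n_per_class` matrices per class from the matrix-variate normal with
#' class mean `M_per_class[[s]]`, row covariance `phi` and column covariance
#' `psi`, via `X = M + t(chol(phi)) %*% E %*% chol(psi)` with `E` iid standard
#' normal, so that `cov(vec X) = psi %x% phi`. Used for covariance-recovery
#' and planted-structure tests of the bilinear embedding.
#'
#' @param M_per_class list of `N_f x N_g` class mean matrices.
#' @param phi `N_f x N_f` symmetric positive-definite row covariance.
#' @param psi `N_g x N_g` symmetric positive-definite column covariance.
#' @param n_per_class draws per class.
#' @param seed integer RNG seed.
#' @return A [matrix_set()].
#' @export
generate_matrix_gaussian_set <- function(M_per_class, phi, psi, n_per_class,
                                         seed = 1L) {
  stopifnot(is.list(M_per_class), length(M_per_class) >= 1, n_per_class >= 1)
  nf <- nrow(M_per_class[[1]]); ng <- ncol(M_per_class[[1]])
  stopifnot(nrow(phi) == nf, ncol(phi) == nf, nrow(psi) == ng, ncol(psi) == ng)
  if (max(abs(phi - t(phi))) > 1e-10 || max(abs(psi - t(psi))) > 1e-10)
    stop("phi and psi must be symmetric", call. = FALSE)
  Lphi <- tryCatch(t(chol(phi)), error = function(e)
    stop("phi is not positive definite", call. = FALSE))
  Rpsi <- tryCatch(chol(psi), error = function(e)
    stop("psi is not positive definite", call. = FALSE))
  set.seed(as.integer(seed))
  mats <- list(); labels <- integer(0)
  for (s in seq_along(M_per_class)) {
    for (i in seq_len(n_per_class)) {
      E <- matrix(stats::rnorm(nf * ng), nf, ng)
      mats[[length(mats) + 1L]] <- M_per_class[[s]] + Lphi %*% E %*% Rpsi
      labels <- c(labels, s)
    }
  }
  matrix_set(mats, labels)
}
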