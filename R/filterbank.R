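# Bandpass filter bank: nine contiguous 4 Hz Chebyshev type II bands
# spanning 4-40 Hz, the standard FBCSP front end covering mu and beta rhythms.

default_bands <- function() {
  lows <- seq(4, 36, by = 4)
  lapply(lows, function(lo) c(lo, lo + 4))
}

#' Design the FBCSP filter bank
#'
#' Designs one bandpass filter per band using a Chebyshev type II prototype.
#' The defaults are nine contiguous 4 Hz bands from 4 to 40 Hz, filter order
#' 6 and 40 dB stopband attenuation. Chebyshev II keeps the passband
#' maximally flat (all ripple is in the stopband), giving low signal
#' distortion across each analysis band. Band edges are the design's
#' stopband-specification edges; every designed filter is checked for
#' stability (all poles strictly inside the unit circle).
#'
#' @param fs sampling rate in Hz.
#' @param bands list of `c(low, high)` pairs in Hz; default the nine 4 Hz
#'   bands `(4,8), (8,12), ..., (36,40)`.
#' @param order even bandpass filter order, at least 2 (default 6).
#' @param attenuation_db stopband attenuation in dB (default 40).
#' @return A `filter_bank` object holding the band list and one `signal`
#'   filter (b/a coefficients) per band.
#' @examples
#' fb <- design_filter_bank(250)
#' length(fb$bands)  # 9
#' @export
design_filter_bank <- function(fs, bands = default_bands(), order = 6,
                               attenuation_db = 40) {
  stopifnot(fs > 0, length(bands) >= 1)
  if (order < 2 || order %% 2 != 0)
    stop("`order` must be an even integer >= 2 (bandpass orders double)", call. = FALSE)
  nyq <- fs / 2
  filters <- vector("list", length(bands))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1])
      stop("each band must be c(low, high) with 0 < low < high", call. = FALSE)
    if (b[2] >= nyq)
      stop(sprintf("band (%g, %g) Hz reaches the Nyquist frequency %g Hz",
                   b[1], b[2], nyq), call. = FALSE)
    flt <- signal::cheby2(order / 2, attenuation_db, W = b / nyq,
                          type = "pass")
    poles <- polyroot(rev(flt$a))
    if (any(Mod(poles) >= 1 - 1e-10))
      stop(sprintf("unstable filter design for band (%g, %g) Hz", b[1], b[2]),
           call. = FALSE)
    filters[[i]] <- flt
  }
  structure(
    list(bands = bands, order = order, design = "chebyshev-II",
         stopband_attenuation_db = attenuation_db, fs = fs, filters = filters),
    class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  rng <- range(unlist(x$bands))
  cat(sprintf("Chebyshev-II filter bank: %d bands over %g-%g Hz, order %d, %g dB @ %g Hz\n",
              length(x$bands), rng[1], rng[2], x$order,
              x$stopband_attenuation_db, x$fs))
  invisible(x)
}

# Single zero-phase (or causal) bandpass pass over one vector.
apply_one_filter <- function(flt, x, zero_phase) {
  if (zero_phase) signal::filtfilt(flt, x) else signal::filter(flt, x)
}

#' Apply the filter bank to epoched EEG
#'
#' Filters every trial and channel independently with each band of the bank.
#' By default filtering is zero-phase (forward-backward) so the filter's group
#' delay does not shift trial windows relative to cue onset; set
#' `zero_phase = FALSE` for a single causal pass.
#'
#' @param epochs an [validate_epochs()] object; `epochs$fs` must equal the
#'   bank's design rate.
#' @param fb a [design_filter_bank()] object.
#' @param zero_phase logical; forward-backward filtering (default `TRUE`).
#' @return A `band_filtered` object whose `data` has shape
#'   `n_bands x n_trials x n_channels x n_samples`, plus `fs`, `labels`,
#'   `bands`.
#' @export
apply_filter_bank <- function(epochs, fb, zero_phase = TRUE) {
  stopifnot(inherits(epochs, "epoched_eeg"), inherits(fb, "filter_bank"))
  if (!isTRUE(all.equal(epochs$fs, fb$fs)))
    stop(sprintf("epochs sampled at %g Hz but filter bank designed for %g Hz",
                 epochs$fs, fb$fs), call. = FALSE)
  d <- dim(epochs$data)
  n_bands <- length(fb$bands)
  out <- array(0, dim = c(n_bands, d[1], d[2], d[3]))
  for (b in seq_len(n_bands)) {
    flt <- fb$filters[[b]]
    for (tr in seq_len(d[1])) {
      for (ch in seq_len(d[2])) {
        out[b, tr, ch, ] <- apply_one_filter(flt, epochs$data[tr, ch, ],
                                             zero_phase)
      }
    }
  }
  structure(
    list(data = out, fs = epochs$fs, labels = epochs$labels,
         bands = fb$bands, Z = epochs$Z, n_s = epochs$n_s),
    class = "band_filtered")
}

#' @export
print.band_filtered <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Band-filtered epochs: %d bands x %d trials x %d channels x %d samples\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

# Magnitude response (dB) of one bank filter on a frequency grid in Hz,
# evaluated directly from the transfer function on the unit circle.
filter_response_db <- function(fb, band_index, freqs_hz) {
  flt <- fb$filters[[band_index]]
  w <- 2 * pi * freqs_hz / fb$fs
  h <- vapply(w, function(om) {
    zb <- exp(-1i * om * (seq_along(flt$b) - 1))
    za <- exp(-1i * om * (seq_along(flt$a) - 1))
    Mod(sum(flt$b * zb) / sum(flt$a * za))
  }, numeric(1))
  20 * log10(pmax(h, .Machine$double.xmin))
}
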