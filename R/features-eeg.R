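#' EEG feature extraction configuration
#'
#' Parameters mapping a raw single-channel signal to feature vectors:
#' the signal is cut into overlapping windows, each window is decomposed
#' with a full wavelet-packet tree, and the variance of the coefficients
#' in each retained frequency band becomes one feature.  The defaults
#' follow the standard recipe for single-electrode person recognition:
#' 4 s windows with 50% overlap, decomposition level 3, and retention of
#' the bands between 0 and 60 Hz (at 160 Hz sampling this gives eight
#' 10 Hz bands of which six are retained).
#'
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 4).
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @param level wavelet-packet decomposition level (default 3).
#' @param band numeric length-2 vector, retained band limits in Hz
#'   (default `c(0, 60)`); must lie within `[0, fs/2]`.
#' @param wavelet wavelet family (default `"db4"`; see [wpd_nodes()]).
#' @return an object of class `eeg_config`.
#' @export
eeg_config <- function(fs, window_s = 4, overlap = 0.5, level = 3,
                       band = c(0, 60), wavelet = "db4") {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("fs must be a positive sampling rate in Hz")
  }
  if (overlap < 0 || overlap >= 1) abort("overlap must be in [0, 1)")
  level <- as.integer(level)
  if (level < 1L) abort("level must be >= 1")
  if (length(band) != 2L || band[1L] < 0 || band[2L] > fs / 2 ||
      band[1L] >= band[2L]) {
    abort("band must be increasing limits within [0, fs/2]")
  }
  wavelet_filter_pair(wavelet)  # validates the name
  structure(list(fs = fs, window_s = window_s, overlap = overlap,
                 level = level, band = band, wavelet = wavelet),
            class = "eeg_config")
}

#' @export
print.eeg_config <- function(x, ...) {
  cat(sprintf(
    "<eeg_config> fs = %g Hz, %g s windows (%.0f%% overlap), WPD level %d (%s), band %g-%g Hz\n",
    x$fs, x$window_s, 100 * x$overlap, x$level, x$wavelet,
    x$band[1L], x$band[2L]))
  invisible(x)
}

#' Segment a signal into overlapping windows
#'
#' Window length is `w = round(window_s * fs)` samples and the hop
#' `round(w * (1 - overlap))`; with 50% overlap consecutive windows
#' share exactly half their samples and tile the signal without gaps.
#'
#' @param x numeric signal.
#' @param config an [eeg_config()].
#' @return a `count x w` numeric matrix, one window per row, in order.
#' @examples
#' cfg <- eeg_config(fs = 160)
#' dim(window_signal(rnorm(19200), cfg))   # 59 windows of 640 samples
#' @export
window_signal <- function(x, config) {
  stopifnot(inherits(config, "eeg_config"))
  if (!all(is.finite(x))) abort("signal contains non-finite values")
  w <- round(config$window_s * config$fs)
  hop <- round(w * (1 - config$overlap))
  if (hop < 1L) abort("overlap too large: hop would be < 1 sample")
  if (length(x) < w) {
    abort(sprintf("signal too short: %d samples, need at least %d",
                  length(x), w))
  }
  count <- floor((length(x) - w) / hop) + 1L
  starts <- (seq_len(count) - 1L) * hop
  out <- matrix(0, count, w)
  for (i in seq_len(count)) out[i, ] <- x[starts[i] + seq_len(w)]
  out
}

# retained node indices (frequency order, 1-based) whose band lies
# within config$band; node k of 2^level spans [k-1, k) * fs / 2^(level+1)
retained_nodes <- function(config) {
  width <- config$fs / 2^(config$level + 1L)
  k <- seq_len(2L^config$level)
  lo <- (k - 1L) * width
  hi <- k * width
  keep <- which(lo >= config$band[1L] & hi <= config$band[2L])
  if (length(keep) == 0L) abort("no wavelet-packet band lies within the retained limits")
  keep
}

#' Wavelet-packet variance features of one window
#'
#' Full wavelet-packet decomposition of the window to the configured
#' level; terminal nodes are taken in increasing frequency order and
#' those whose band lies entirely within the retained limits are kept.
#' The feature vector is the sample variance of each retained node's
#' coefficients.
#'
#' @param x numeric window; length must be divisible by `2^level`.
#' @param config an [eeg_config()].
#' @return named numeric vector (one variance per retained band, lowest
#'   frequency first).
#' @export
wpd_variance_features <- function(x, config) {
  stopifnot(inherits(config, "eeg_config"))
  nodes <- wpd_nodes(x, config$level, config$wavelet)
  keep <- retained_nodes(config)
  width <- config$fs / 2^(config$level + 1L)
  v <- vapply(nodes[keep], var, numeric(1))
  names(v) <- sprintf("band_%g_%g", (keep - 1L) * width, keep * width)
  v
}

#' Extract a feature table from a raw signal
#'
#' Runs [window_signal()] and [wpd_variance_features()]: one feature row
#' per window.  Deterministic.
#'
#' @param x numeric signal.
#' @param config an [eeg_config()].
#' @param class optional class label attached to every row (prepended
#'   as a `class` column), for building training tables.
#' @return tibble with one row per window and one column per retained
#'   band (plus `class` if given).
#' @export
extract_eeg_features <- function(x, config, class = NULL) {
  win <- window_signal(x, config)
  feats <- t(apply(win, 1L, wpd_variance_features, config = config))
  out <- tibble::as_tibble(as.data.frame(feats))
  if (!is.null(class)) {
    out <- dplyr::bind_cols(tibble::tibble(class = class), out)
  }
  out
}
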