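# Wavelet packet decomposition with periodized boundaries.
#
# A full binary tree of low/high-pass filter-and-decimate steps; the
# level-d terminal nodes tile [0, fs/2] into 2^d equal bands once put in
# frequency (sequency) order.  Periodization keeps every node at length
# n / 2^d with no boundary padding, which is what we want for variance
# features on fixed-length windows.

# Daubechies scaling (low-pass decomposition) filters, standard
# normalization (sum = sqrt(2)).
daub_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db3 = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db5 = c(0.0033357252854737712, -0.012580751999081999,
          -0.006241490212798274, 0.07757149384004572, -0.032244869584638375,
          -0.24229488706638203, 0.13842814590132074, 0.7243085284377729,
          0.6038292697971896, 0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.004777257510945511,
          0.0005538422011614961, -0.03158203931748603, 0.027522865530305727,
          0.09750160558732304, -0.12976686756726194, -0.22626469396543983,
          0.31525035170919763, 0.7511339080210954, 0.49462389039845306,
          0.11154074335010947),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282, -0.044088253930794755,
          -0.017369301001807547, 0.12874742662047847, 0.0004724845739132828,
          -0.2840155429615469, -0.015829105256349306, 0.5853546836542067,
          0.6756307362972898, 0.31287159091429995, 0.05441584224310401))

wavelet_filter_pair <- function(wavelet) {
  if (identical(wavelet, "haar")) wavelet <- "db1"
  lo <- daub_filters[[wavelet]]
  if (is.null(lo)) {
    abort(sprintf("unknown wavelet '%s' (available: %s)", wavelet,
                  paste(names(daub_filters), collapse = ", ")))
  }
  # quadrature mirror: hi[m] = (-1)^(m+1) * lo[flen - 1 - m] (0-based)
  flen <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(flen)
  list(lo = lo, hi = hi)
}

# One periodized filter-and-decimate step.
#   out[k] = sum_m f[m] * x[(2k + flen/2 - m) mod n],  k = 0..n/2-1
# (0-based), matching the usual periodization convention.
dwt_step <- function(x, f) {
  n <- length(x)
  if (n %% 2L != 0L) abort("signal length must be even for a periodized step")
  flen <- length(f)
  k <- seq.int(0L, n / 2L - 1L)
  out <- numeric(n / 2L)
  base <- 2L * k + flen %/% 2L
  for (m in seq_len(flen)) {
    out <- out + f[m] * x[(base - (m - 1L)) %% n + 1L]
  }
  out
}

#' Wavelet packet terminal-node coefficients
#'
#' Decomposes a signal with a full wavelet-packet tree to the given
#' level using periodized Daubechies filters, and returns the terminal
#' node coefficient vectors in frequency (sequency) order, so that node
#' k of 2^level spans approximately `[k, k + 1) * fs / 2^(level + 1)` Hz.
#'
#' @param x numeric signal; its length must be divisible by `2^level`.
#' @param level decomposition depth (>= 1).
#' @param wavelet filter name: `"haar"`/`"db1"`, `"db2"`, `"db3"`,
#'   `"db4"` (default), `"db5"`, `"db6"` or `"db8"`.
#' @return list of `2^level` numeric vectors, lowest frequency band
#'   first.
#' @export
wpd_nodes <- function(x, level = 3, wavelet = "db4") {
  level <- as.integer(level)
  if (level < 1L) abort("level must be >= 1")
  if (length(x) < 2L^level || length(x) %% 2L^level != 0L) {
    abort(sprintf(
      "signal length %d is not divisible by 2^level = %d",
      length(x), 2L^level))
  }
  if (!all(is.finite(x))) abort("signal contains non-finite values")
  f <- wavelet_filter_pair(wavelet)
  nodes <- list(x)
  flips <- FALSE   # TRUE when the node's band ordering is reversed
  for (d in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    nxt_flips <- logical(2L * length(nodes))
    for (i in seq_along(nodes)) {
      lo <- dwt_step(nodes[[i]], f$lo)
      hi <- dwt_step(nodes[[i]], f$hi)
      # frequency ordering: a node reached through an odd number of
      # high-pass steps lists its children high-pass first (Gray-code /
      # sequency ordering); a high-pass step toggles that parity
      if (flips[i]) {
        nxt[[2L * i - 1L]] <- hi
        nxt[[2L * i]] <- lo
        nxt_flips[2L * i - 1L] <- FALSE
        nxt_flips[2L * i] <- TRUE
      } else {
        nxt[[2L * i - 1L]] <- lo
        nxt[[2L * i]] <- hi
        nxt_flips[2L * i - 1L] <- FALSE
        nxt_flips[2L * i] <- TRUE
      }
    }
    nodes <- nxt
    flips <- nxt_flips
  }
  nodes
}
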