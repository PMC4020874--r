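#' Flat grayscale opening of a 2-D map
#'
#' Erosion followed by dilation with a flat rectangular structuring element
#' (edge replication at the borders).  Opening removes structures narrower
#' than the element while leaving slowly varying content untouched; with the
#' default 33x33 element on an `(n, i)` deformation map it passes the slow
#' air-puff response and suppresses oscillations shorter than ~33 frames.
#'
#' @param map numeric matrix `(N, I)`.
#' @param se odd 2-vector `(columns, frames)`; default `c(33, 33)`.
#' @return opened map, everywhere `<=` the input (anti-extensivity).
#' @export
grayscale_opening <- function(map, se = c(33L, 33L)) {
  stopifnot(is.matrix(map), is.numeric(map))
  if (any(!is.finite(map))) stop("map must be finite")
  se <- as.integer(se)
  stopifnot(length(se) == 2L, all(se %% 2 == 1), all(se >= 1))
  if (se[1] > nrow(map) || se[2] > ncol(map))
    stop("dimension error: structuring element larger than the map")
  dilate_rect_cpp(erode_rect_cpp(map, se[1], se[2]), se[1], se[2])
}

#' Rapidly changing component of the corneal deflection
#'
#' Subtracts the grayscale opening from the deflection map,
#' `L_Q = L_TR - opening(L_TR)`, retaining only structures whose extent in
#' `(n, i)` is smaller than the structuring element — the fast (150–500 Hz)
#' corneal oscillations riding on the slow puff response.
#'
#' @param L_TR `N x I` corneal deflection map (or a
#'   `deformation_decomposition`).
#' @param se structuring element passed to [grayscale_opening].
#' @return `N x I` map of the fast component (non-negative).
#' @export
fast_component <- function(L_TR, se = c(33L, 33L)) {
  if (inherits(L_TR, "deformation_decomposition")) L_TR <- L_TR$L_TR
  out <- L_TR - grayscale_opening(L_TR, se)
  attr(out, "role") <- "fast"
  out
}

default_bands <- function(N) {
  list(left = seq(max(1L, round(N / 8)), round(3 * N / 8)),
       right = seq(round(5 * N / 8), min(N, round(7 * N / 8))))
}

#' Left/right border signals of the fast map
#'
#' Averages the fast component over a lateral band of columns on each side
#' of the corneal apex, yielding one time signal per side.  The default
#' bands, columns `[N/8, 3N/8]` and `[5N/8, 7N/8]`, cover the lateral cornea
#' while excluding both the apex and the border columns (which are zero by
#' construction of the eyeball separation).
#'
#' @param L_Q `N x I` fast map.
#' @param bands list with integer vectors `left` and `right` of column
#'   indices; `NULL` for the defaults.
#' @return list with `L_QL` and `L_QR`, numeric vectors of length `I`, and
#'   the bands used.
#' @export
border_signals <- function(L_Q, bands = NULL) {
  stopifnot(is.matrix(L_Q))
  N <- nrow(L_Q)
  if (is.null(bands)) bands <- default_bands(N)
  if (any(c(bands$left, bands$right) < 1L) ||
      any(c(bands$left, bands$right) > N))
    stop("config error: band columns outside [1, N]")
  list(L_QL = colMeans(L_Q[bands$left, , drop = FALSE]),
       L_QR = colMeans(L_Q[bands$right, , drop = FALSE]),
       bands = bands)
}

#' One-sided magnitude spectrum of a border signal
#'
#' Plain (rectangular-window, unpadded) FFT magnitude.  Bin `k` (1-based,
#' bin 1 = DC) maps to frequency `(k - 1) / (I * frame_interval_s)` Hz.
#'
#' @param signal real vector of length `I >= 16`.
#' @param frame_interval_s seconds per frame.
#' @return list with `magnitude` (length `floor(I/2) + 1`), `freq_hz` and
#'   `bin` (1-based).
#' @export
deformation_spectrum <- function(signal, frame_interval_s = 231e-6) {
  I <- length(signal)
  if (I < 16L) stop("too-short error: need at least 16 frames for a spectrum")
  mag <- Mod(fft(signal))
  k <- seq_len(I %/% 2 + 1L)
  list(magnitude = mag[k],
       freq_hz = (k - 1) / (I * frame_interval_s),
       bin = k)
}

# signed frequency (Hz) of every FFT bin of a length-I record
fft_freqs <- function(I, frame_interval_s) {
  k <- 0:(I - 1)
  k[k > I / 2] <- k[k > I / 2] - I
  k / (I * frame_interval_s)
}

#' Band decomposition of a border signal
#'
#' Splits a signal into a slow component (region I: `|f| < 150` Hz, DC
#' included) and a fast oscillatory component (region II:
#' `200 <= |f| <= 500` Hz) by conjugate-symmetric FFT masking, so both
#' components are real.  Bins falling in the 150–200 Hz gap belong to
#' neither component.  The analytic (one-sided, doubled) version of the
#' region-II component is also returned; its modulus is the smooth
#' oscillation envelope used by the duration feature.
#'
#' @param signal real vector of length `I`.
#' @param frame_interval_s seconds per frame.
#' @param region_I_max upper edge (exclusive) of region I, Hz.
#' @param region_II length-2 numeric, inclusive band of region II, Hz.
#' @return list with `comp_I`, `comp_II`, `comp_I_plus_II`, and
#'   `comp_II_envelope` (all length `I`).
#' @export
band_components <- function(signal, frame_interval_s = 231e-6,
                            region_I_max = 150, region_II = c(200, 500)) {
  I <- length(signal)
  f <- fft_freqs(I, frame_interval_s)
  fv <- fft(signal)
  m1 <- abs(f) < region_I_max
  m2 <- abs(f) >= region_II[1] & abs(f) <= region_II[2]
  comp_I <- Re(fft(fv * m1, inverse = TRUE)) / I
  comp_II <- Re(fft(fv * m2, inverse = TRUE)) / I
  m2a <- m2 & f > 0
  analytic <- fft(2 * fv * m2a, inverse = TRUE) / I
  list(comp_I = comp_I,
       comp_II = comp_II,
       comp_I_plus_II = comp_I + comp_II,
       comp_II_envelope = Mod(analytic))
}

#' Full fast-dynamics analysis of a corneal deflection map
#'
#' Convenience wrapper chaining [fast_component], [border_signals],
#' [deformation_spectrum] and [band_components] for both sides.
#'
#' @param L_TR `N x I` deflection map or a `deformation_decomposition`.
#' @param frame_interval_s seconds per frame.
#' @param se structuring element of the opening.
#' @param bands lateral bands for [border_signals] (`NULL` = defaults).
#' @return list of class `fast_dynamics` with `L_Q`, `L_QL`, `L_QR`,
#'   `F_QL`, `F_QR` (spectrum lists), `comp_L`, `comp_R` (band component
#'   lists) and `freq_hz`.
#' @export
fast_dynamics <- function(L_TR, frame_interval_s = 231e-6,
                          se = c(33L, 33L), bands = NULL) {
  if (inherits(L_TR, "deformation_decomposition")) L_TR <- L_TR$L_TR
  L_Q <- fast_component(L_TR, se)
  sig <- border_signals(L_Q, bands)
  F_QL <- deformation_spectrum(sig$L_QL, frame_interval_s)
  F_QR <- deformation_spectrum(sig$L_QR, frame_interval_s)
  structure(list(L_Q = L_Q, L_QL = sig$L_QL, L_QR = sig$L_QR,
                 bands = sig$bands,
                 F_QL = F_QL, F_QR = F_QR, freq_hz = F_QL$freq_hz,
                 comp_L = band_components(sig$L_QL, frame_interval_s),
                 comp_R = band_components(sig$L_QR, frame_interval_s)),
            class = "fast_dynamics")
}

#' @export
print.fast_dynamics <- function(x, ...) {
  peak <- which.max(pmax(x$F_QL$magnitude[-1], x$F_QR$magnitude[-1])) + 1L
  cat(sprintf("<fast_dynamics> %d frames | peak non-DC bin %d (%.0f Hz)\n",
              length(x$L_QL), peak, x$freq_hz[peak]))
  invisible(x)
}
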