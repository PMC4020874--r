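#' Relative corneal deformation
#'
#' Removes the resting corneal shape by subtracting the first frame's contour
#' profile from every frame: `L_T(n, i) = L_P(n, i) - L_P(n, 1)`.  Positive
#' values mean displacement toward the eye interior (downward in the image).
#'
#' @param contour `N x I` contour map (rows = image columns, cols = frames).
#' @return `N x I` deformation map; its first column is identically zero.
#' @export
relative_deformation <- function(contour) {
  stopifnot(is.matrix(contour))
  out <- contour - contour[, 1]
  attr(out, "role") <- "deformation"
  out
}

#' Separate whole-eyeball displacement from corneal deflection
#'
#' During the air puff the whole globe retro-displaces in the socket while
#' the cornea itself deflects.  At the left and right image borders the
#' cornea is assumed undeformed, so the deformation observed there is pure
#' eyeball motion; it is extended across the image width as an affine (in
#' `n`) displacement field
#' `L_TO(n, i) = (L_T(N, i) - L_T(1, i)) / (N - 1) * (n - 1) + L_T(1, i)`
#' and the corneal deflection is the remainder `L_TR = L_T - L_TO`.
#'
#' The two-weight form `(1 - t) * left + t * right` is used so that the
#' border identities `L_TO(1, i) = L_T(1, i)` and `L_TO(N, i) = L_T(N, i)`
#' hold bit-exactly in floating point.  The returned `L_T` is re-assembled
#' as the exact sum `L_TO + L_TR`, making the conservation identity hold
#' bitwise by construction; it can differ from the supplied map by at most
#' one unit in the last place in the interior (and not at all at the
#' borders or in frame 1).
#'
#' @param L_T `N x I` relative deformation map.
#' @param band_width number of border columns averaged on each side when
#'   estimating the border motion (1 = single border column; wider bands
#'   resist border noise but relax the exact border identities).
#' @return list of class `deformation_decomposition` with `L_T`, `L_TO`
#'   (eyeball) and `L_TR` (cornea), all `N x I`.
#' @export
separate_eyeball <- function(L_T, band_width = 1L) {
  stopifnot(is.matrix(L_T))
  N <- nrow(L_T)
  band_width <- as.integer(band_width)
  if (band_width < 1L || band_width > N %/% 2)
    stop("`band_width` must be between 1 and N/2")
  left <- colMeans(L_T[seq_len(band_width), , drop = FALSE])
  right <- colMeans(L_T[(N - band_width + 1L):N, , drop = FALSE])
  t_n <- (seq_len(N) - 1) / (N - 1)
  L_TO <- outer(1 - t_n, left) + outer(t_n, right)
  L_TR <- L_T - L_TO
  L_T <- L_TO + L_TR          # conservation holds bitwise by construction
  attr(L_T, "role") <- "deformation"
  attr(L_TO, "role") <- "eyeball"
  attr(L_TR, "role") <- "cornea"
  structure(list(L_T = L_T, L_TO = L_TO, L_TR = L_TR,
                 band_width = band_width),
            class = "deformation_decomposition")
}

#' @export
print.deformation_decomposition <- function(x, ...) {
  cat(sprintf("<deformation_decomposition> %d cols x %d frames | max deflection %.2f px | max eyeball %.2f px\n",
              nrow(x$L_T), ncol(x$L_T), max(x$L_TR), max(x$L_TO)))
  invisible(x)
}

#' Maximum corneal deflection amplitude
#'
#' The global maximum of the corneal deflection map over all columns and
#' frames, in pixels.  This is the quantity the tonometer itself reports as
#' the deformation amplitude (up to the instrument's calibration).
#'
#' @param x a `deformation_decomposition` or an `L_TR` matrix.
#' @return single number (px).
#' @export
max_deflection <- function(x) {
  if (inherits(x, "deformation_decomposition")) x <- x$L_TR
  stopifnot(is.matrix(x))
  max(x)
}

#' Center-line traces of a decomposition
#'
#' Convenience export of the apex-column time courses of the three maps,
#' in tidy form.
#'
#' @param decomp a `deformation_decomposition`.
#' @param frame_interval_s seconds per frame, for the time axis.
#' @param column image column to trace (default: the center, `round(N/2)`).
#' @return data.frame with `frame`, `time_s`, `L_T`, `L_TO`, `L_TR` (px).
#' @export
centerline_traces <- function(decomp, frame_interval_s = 231e-6,
                              column = NULL) {
  stopifnot(inherits(decomp, "deformation_decomposition"))
  N <- nrow(decomp$L_T)
  if (is.null(column)) column <- round(N / 2)
  I <- ncol(decomp$L_T)
  data.frame(frame = seq_len(I),
             time_s = (seq_len(I) - 1) * frame_interval_s,
             L_T = decomp$L_T[column, ],
             L_TO = decomp$L_TO[column, ],
             L_TR = decomp$L_TR[column, ])
}
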