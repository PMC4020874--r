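#' Edge-extraction parameters
#'
#' Bundles every tunable of the outer-edge detectors.  Defaults follow the
#' values used throughout the package's reference pipeline: a 3x3x3 median
#' pre-filter, an Otsu correction factor of 0.5 (the per-column threshold is
#' halved because the corneal edge can be very high-contrast), Canny with a
#' high threshold of 0.1 on unit-normalized gradient magnitude and Gaussian
#' sigma 0.99, a 3x3 closing of the Canny map, 3x3 median smoothing of the
#' contour, and a 10 px bound on the admissible frame-to-frame contour jump.
#'
#' @param median_mask 3-vector, odd sizes, of the spatio-temporal median mask.
#' @param v_r Otsu correction factor in `(0, 1]`.
#' @param canny_threshold high hysteresis threshold in `(0, 1)`.
#' @param canny_low_ratio low threshold as a fraction of the high one.
#' @param canny_sigma Gaussian standard deviation (px).
#' @param closing_se 2-vector, odd, closing structuring element (px).
#' @param contour_median_mask 2-vector, odd, contour smoothing mask.
#' @param max_jump_px validity bound on interframe contour displacement.
#' @param subpixel refine the integer topmost-row contour to sub-pixel
#'   precision by locating the half-maximum intensity crossing (see the
#'   methods vignette); keeps amplitude recovery quantization-free.
#' @return list of class `edge_params`.
#' @export
edge_params <- function(median_mask = c(3L, 3L, 3L),
                        v_r = 0.5,
                        canny_threshold = 0.1,
                        canny_low_ratio = 0.4,
                        canny_sigma = 0.99,
                        closing_se = c(3L, 3L),
                        contour_median_mask = c(3L, 3L),
                        max_jump_px = 10,
                        subpixel = TRUE) {
  stopifnot(length(median_mask) == 3L, all(median_mask %% 2 == 1),
            all(median_mask >= 1))
  if (v_r <= 0 || v_r > 1) stop("`v_r` must be in (0, 1]")
  if (canny_threshold <= 0 || canny_threshold >= 1)
    stop("`canny_threshold` must be in (0, 1)")
  stopifnot(length(closing_se) == 2L, all(closing_se %% 2 == 1),
            length(contour_median_mask) == 2L,
            all(contour_median_mask %% 2 == 1),
            max_jump_px > 0, canny_sigma > 0,
            canny_low_ratio > 0, canny_low_ratio <= 1)
  structure(list(median_mask = as.integer(median_mask), v_r = v_r,
                 canny_threshold = canny_threshold,
                 canny_low_ratio = canny_low_ratio,
                 canny_sigma = canny_sigma,
                 closing_se = as.integer(closing_se),
                 contour_median_mask = as.integer(contour_median_mask),
                 max_jump_px = max_jump_px, subpixel = isTRUE(subpixel)),
            class = "edge_params")
}

#' 3-D median filtering of an image sequence
#'
#' Each voxel is replaced by the median of its `mask` neighbourhood across
#' rows, columns and frames; borders are handled by edge replication.  The
#' default 3x3x3 mask removes sensor salt noise without deleting the thin
#' corneal contour (larger masks do).
#'
#' @param seq an [image_sequence].
#' @param mask odd 3-vector `(rows, cols, frames)`.
#' @return the filtered [image_sequence].
#' @export
median_filter_seq <- function(seq, mask = c(3L, 3L, 3L)) {
  stopifnot(inherits(seq, "image_sequence"))
  mask <- as.integer(mask)
  stopifnot(length(mask) == 3L, all(mask %% 2 == 1), all(mask >= 1))
  if (any(mask > seq$dims))
    stop("dimension error: median mask larger than the sequence")
  d <- seq$dims
  out <- median3d_cpp(as.numeric(seq$data), d[1], d[2], d[3],
                      mask[1], mask[2], mask[3])
  image_sequence(out, frame_interval_s = seq$frame_interval_s, meta = seq$meta)
}

# 256-bin histogram of values in [0,1]; value 1 falls in the last bin
otsu_bin_counts <- function(x, levels = 256L) {
  idx <- pmin(floor(x * levels) + 1L, levels)
  tabulate(idx, nbins = levels)
}

# between-class variance for every candidate split of a histogram;
# candidate j puts bins 1..j in the background class, threshold value j/levels
otsu_sigma_b <- function(counts) {
  levels <- length(counts)
  total <- sum(counts)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(counts)[-levels]
  w1 <- total - w0
  s0 <- cumsum(counts * mids)[-levels]
  mu_t <- sum(counts * mids)
  sb <- rep(0, levels - 1L)
  valid <- w0 > 0 & w1 > 0
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (mu_t - s0[valid]) / w1[valid]
  sb[valid] <- (w0[valid] / total) * (w1[valid] / total) * (mu0 - mu1)^2
  sb
}

#' Otsu threshold of a set of intensities
#'
#' Maximizes the between-class variance over a 256-bin histogram of `[0, 1]`.
#' Candidate threshold `j/256` splits bins `1..j` from `j+1..256`; the lowest
#' maximizing candidate is returned (deterministic tie-break).
#'
#' @param values numeric vector in `[0, 1]` with at least 2 distinct values.
#' @param levels histogram resolution (default 256).
#' @return the threshold, a value in `(0, 1)`.
#' @export
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("degenerate input: Otsu needs at least 2 distinct values")
  counts <- otsu_bin_counts(values, levels)
  sb <- otsu_sigma_b(counts)
  which.max(sb) / levels
}

# per-column Otsu thresholds for one frame, vectorized over columns;
# columns with fewer than 2 occupied bins get NA
otsu_threshold_cols <- function(frame, levels = 256L) {
  N <- ncol(frame)
  idx <- pmin(floor(frame * levels) + 1L, levels)
  counts <- matrix(tabulate(idx + levels * (col(frame) - 1L),
                            nbins = levels * N), nrow = levels)
  mids <- (seq_len(levels) - 0.5) / levels
  total <- colSums(counts)
  w0 <- apply(counts, 2L, cumsum)[-levels, , drop = FALSE]
  s0 <- apply(counts * mids, 2L, cumsum)[-levels, , drop = FALSE]
  mu_t <- colSums(counts * mids)
  w1 <- rep(total, each = levels - 1L) - w0
  sb <- matrix(0, levels - 1L, N)
  valid <- w0 > 0 & w1 > 0
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (rep(mu_t, each = levels - 1L)[valid] - s0[valid]) / w1[valid]
  sb[valid] <- (w0[valid] / rep(total, each = levels - 1L)[valid]) *
    (w1[valid] / rep(total, each = levels - 1L)[valid]) * (mu0 - mu1)^2
  thr <- apply(sb, 2L, which.max) / levels
  nbins_used <- colSums(counts > 0)
  thr[nbins_used < 2L] <- NA_real_
  thr
}

# first set row per column of a logical matrix; NA where a column has none
first_set_row <- function(bin) {
  apply(bin, 2L, function(cl) {
    w <- which(cl)
    if (length(w)) w[1L] else NA_real_
  })
}

# vertical (along-row) Gaussian blur of a 3-D intensity array; band-limits
# the edge profile so that sub-pixel interpolation is well conditioned
blur_rows <- function(arr, sigma = 1) {
  r <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  k <- k / sum(k)
  M <- dim(arr)[1]
  out <- arr * 0
  for (d in (-r):r) {
    idx <- pmin(pmax(seq_len(M) + d, 1L), M)
    out <- out + k[d + r + 1L] * arr[idx, , , drop = FALSE]
  }
  out
}

# sub-pixel refinement of an integer contour.  In a +-window row band around
# the detected row of each (column, frame), the crossing of the half level
# between the local background and foreground intensity is located on a
# Gaussian-smoothed profile by cubic (Catmull-Rom) inverse interpolation.
# The smoothing turns the rendered/physical edge ramp into a near-erf
# profile whose half-level crossing is the true edge position, removing the
# sawtooth bias that plain linear interpolation has on hard 1-px ramps.
refine_subpixel <- function(data, contour_int, window = 3L, blur_sigma = 1.5) {
  M <- dim(data)[1]; N <- dim(data)[2]; I <- dim(data)[3]
  if (blur_sigma > 0) data <- blur_rows(data, blur_sigma)
  offs <- (-window - 2L):(window + 3L)         # extra rows for cubic + level pass
  n_idx <- rep(seq_len(N), times = I)
  i_idx <- rep(seq_len(I), each = N)
  m0 <- as.vector(contour_int)
  ok <- !is.na(m0)
  out <- m0
  if (!any(ok)) return(matrix(out, N, I))
  m0k <- m0[ok]; nk <- n_idx[ok]; ik <- i_idx[ok]
  V <- vapply(offs, function(d) {
    mm <- pmin(pmax(m0k + d, 1L), M)
    data[cbind(mm, nk, ik)]
  }, numeric(length(m0k)))
  core <- 3:(length(offs) - 2L)                # offsets -window .. window+1
  s_grid <- seq(0, 1, by = 1 / 16)

  # cubic (Catmull-Rom) inverse interpolation of the first upward crossing
  # of level `tlev` inside the core window; returns sub-pixel row (or m0)
  locate <- function(tlev) {
    sub <- m0k
    found <- rep(FALSE, length(m0k))
    for (d in core[-length(core)]) {
      a <- V[, d]; b <- V[, d + 1L]
      cross <- !found & a < tlev & b >= tlev & (b - a) > 0
      if (any(cross)) {
        y0 <- V[cross, d - 1L]; y1 <- a[cross]; y2 <- b[cross]; y3 <- V[cross, d + 2L]
        tl <- tlev[cross]
        c1 <- 0.5 * (y2 - y0)
        c2 <- y0 - 2.5 * y1 + 2 * y2 - 0.5 * y3
        c3 <- 1.5 * (y1 - y2) + 0.5 * (y3 - y0)
        frac <- (tl - y1) / (y2 - y1)          # fallback: linear
        prev <- y1; prev_s <- 0
        done <- rep(FALSE, length(tl))
        for (ss in s_grid[-1]) {
          cur <- y1 + c1 * ss + c2 * ss^2 + c3 * ss^3
          hit <- !done & prev < tl & cur >= tl & (cur - prev) > 0
          if (any(hit))
            frac[hit] <- prev_s + (ss - prev_s) * (tl[hit] - prev[hit]) /
              (cur[hit] - prev[hit])
          done <- done | hit
          prev <- cur; prev_s <- ss
        }
        frac <- pmin(pmax(frac, 0), 1)
        sub[cross] <- m0k[cross] + offs[d] + frac
        found[cross] <- TRUE
      }
    }
    sub
  }

  # linear interpolation of the blurred profile at real offset `delta`
  # from the current sub-pixel estimate
  sample_at <- function(sub, delta) {
    pos <- pmin(pmax(sub + delta, 1), M)
    fl <- floor(pos)
    fr <- pos - fl
    v1 <- data[cbind(pmin(fl, M), nk, ik)]
    v2 <- data[cbind(pmin(fl + 1, M), nk, ik)]
    v1 * (1 - fr) + v2 * fr
  }

  # pass 1: half level between the window min and max (coarse)
  lo <- apply(V[, core, drop = FALSE], 1L, min)
  hi <- apply(V[, core, drop = FALSE], 1L, max)
  sub <- locate((lo + hi) / 2)
  # pass 2: background/foreground re-sampled at fixed sub-pixel offsets from
  # the pass-1 edge, so the half level no longer depends on where the edge
  # falls within the pixel grid (removes the residual sawtooth bias)
  lo2 <- sample_at(sub, -2.5)
  hi2 <- sample_at(sub, 2.5)
  good <- hi2 - lo2 > 0.05                     # keep pass 1 on flat profiles
  tlev2 <- (lo + hi) / 2
  tlev2[good] <- (lo2[good] + hi2[good]) / 2
  sub <- locate(tlev2)

  out[ok] <- pmin(pmax(sub, 1), M)
  matrix(out, N, I)
}

#' Outer-edge extraction by column-wise Otsu thresholding
#'
#' Route one of the two detectors.  Every image column is binarized at
#' `v_r * p_r(n, i)`, where `p_r` is the column's Otsu threshold; the binary
#' frame is eroded with a 3x3 structuring element and XOR-ed with itself,
#' which leaves exactly the 8-connected inner boundary of the bright region;
#' the contour is the topmost boundary row of each column.  Columns where no
#' pixel survives carry the missing-marker `NA`.
#'
#' @param seq a (median-filtered) [image_sequence].
#' @param params an [edge_params] list.
#' @param refine_on optional [image_sequence] (typically the unfiltered
#'   original) whose intensities are used for the sub-pixel refinement;
#'   defaults to `seq` itself.
#' @return contour map, an `N x I` matrix of row positions (attribute
#'   `role = "contour"`), `NA` marking failed columns.
#' @export
extract_edge_otsu <- function(seq, params = edge_params(), refine_on = NULL) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- seq$dims
  contour <- matrix(NA_real_, d[2], d[3])
  for (i in seq_len(d[3])) {
    frame <- seq$data[, , i]
    thr <- params$v_r * otsu_threshold_cols(frame)
    thr[is.na(thr)] <- Inf                      # degenerate columns: no foreground
    LB <- sweep(frame, 2L, thr, ">") * 1
    LE <- erode_rect_cpp(LB, 3L, 3L)
    LK <- LB == 1 & LE == 0
    contour[, i] <- first_set_row(LK)
  }
  if (params$subpixel) {
    ref <- if (is.null(refine_on)) seq$data else refine_on$data
    contour <- refine_subpixel(ref, contour)
  }
  attr(contour, "role") <- "contour"
  contour
}

#' Outer-edge extraction by Canny edge detection
#'
#' Route two (the pipeline default): per frame, a Canny edge map at the
#' configured threshold/sigma, morphologically closed with a 3x3 structuring
#' element to bridge small gaps, then the topmost edge row per column.
#'
#' @inheritParams extract_edge_otsu
#' @return contour map as in [extract_edge_otsu].
#' @export
extract_edge_canny <- function(seq, params = edge_params(), refine_on = NULL) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- seq$dims
  contour <- matrix(NA_real_, d[2], d[3])
  high <- params$canny_threshold
  low <- params$canny_low_ratio * high
  for (i in seq_len(d[3])) {
    edges <- canny_cpp(seq$data[, , i], params$canny_sigma, low, high)
    closed <- erode_rect_cpp(dilate_rect_cpp(edges * 1, params$closing_se[1],
                                             params$closing_se[2]),
                             params$closing_se[1], params$closing_se[2])
    contour[, i] <- first_set_row(closed > 0.5)
  }
  if (params$subpixel) {
    ref <- if (is.null(refine_on)) seq$data else refine_on$data
    contour <- refine_subpixel(ref, contour)
  }
  attr(contour, "role") <- "contour"
  contour
}

#' Contour validity report
#'
#' A detected contour is accepted when no column in any frame is missing and
#' the frame-to-frame displacement of every contour point stays below
#' `max_jump_px`.
#'
#' @param contour `N x I` contour map (`NA` = missing).
#' @param params an [edge_params] list (only `max_jump_px` is used).
#' @return list of class `contour_validity` with `ok`, `n_discontinuities`
#'   (count of missing entries) and `max_interframe_jump` (px).
#' @export
validate_contour <- function(contour, params = edge_params()) {
  stopifnot(is.matrix(contour))
  n_missing <- sum(is.na(contour))
  jumps <- abs(contour[, -1, drop = FALSE] - contour[, -ncol(contour), drop = FALSE])
  max_jump <- if (all(is.na(jumps))) 0 else max(jumps, na.rm = TRUE)
  structure(list(ok = n_missing == 0L && max_jump < params$max_jump_px,
                 n_discontinuities = n_missing,
                 max_interframe_jump = max_jump),
            class = "contour_validity")
}

#' @export
print.contour_validity <- function(x, ...) {
  cat(sprintf("<contour_validity> ok: %s | missing points: %d | max interframe jump: %.2f px\n",
              x$ok, x$n_discontinuities, x$max_interframe_jump))
  invisible(x)
}

#' Fill missing contour columns by within-frame linear interpolation
#'
#' Isolated detection failures are interpolated from the nearest valid
#' columns of the same frame (constant extrapolation at the frame borders).
#' A frame with no valid column at all cannot be repaired and aborts.
#'
#' @param contour `N x I` contour map.
#' @return contour map without `NA` entries.
#' @export
interpolate_contour <- function(contour) {
  stopifnot(is.matrix(contour))
  N <- nrow(contour)
  for (i in seq_len(ncol(contour))) {
    col_i <- contour[, i]
    bad <- is.na(col_i)
    if (!any(bad)) next
    if (all(bad))
      stop(sprintf("contour validity error: frame %d has no detected edge", i))
    contour[bad, i] <- approx(which(!bad), col_i[!bad], xout = which(bad),
                              rule = 2)$y
  }
  attr(contour, "role") <- "contour"
  contour
}

#' Median smoothing of a contour map
#'
#' Removes residual single-point detection errors with a 2-D median over the
#' `(n, i)` map (3x3 by default, edge replication).
#'
#' @param contour `N x I` contour map without missing values.
#' @param mask odd 2-vector.
#' @return smoothed contour map.
#' @export
smooth_contour <- function(contour, mask = c(3L, 3L)) {
  stopifnot(is.matrix(contour))
  if (any(is.na(contour)))
    stop("smooth_contour expects an interpolated contour (no missing values)")
  mask <- as.integer(mask)
  stopifnot(length(mask) == 2L, all(mask %% 2 == 1))
  out <- median2d_cpp(contour, mask[1], mask[2])
  attr(out, "role") <- "contour"
  out
}
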