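#' Parameters of a synthetic air-puff phantom sequence
#'
#' Defines a fully known ground-truth scene: a bright corneal arc on a dark
#' background whose outer contour is
#' `c(n, i) = baseline(n) + eyeball(n, i) + deflection(n, i) + ripple(n, i)`.
#' The baseline is a parabolic arc (apex up); the deflection is a
#' raised-cosine pulse in time times a raised-cosine bump in `n` with finite
#' support strictly inside the image borders (at least 20 undeformed border
#' columns on each side, the assumption of the eyeball separation); the
#' eyeball displacement is affine in `n` between the two border time
#' courses; the ripple is a boxcar-gated sinusoid sharing the deflection's
#' spatial support.  Frames are rendered with linear intensity interpolation
#' at the top edge so the true contour position is sub-pixel, plus optional
#' bright iris-like bands and additive Gaussian sensor noise.
#'
#' Spatial defaults scale with the image width so reduced-size phantoms
#' remain geometrically similar to the full 200 x 576 x 140 acquisition.
#'
#' @param dims `(M, N, I)` of the rendered sequence.
#' @param frame_interval_s seconds per frame.
#' @param apex_row baseline contour row at the apex (px from the top).
#' @param sagitta extra contour depth at the image borders (px).
#' @param band_thickness,band_intensity thickness (px) and peak intensity of
#'   the corneal band.
#' @param deflection_amplitude peak inward deflection (px).
#' @param deflection_center,deflection_width center column and full support
#'   width of the spatial bump; `NULL` = `N/2` and `0.6 N`.
#' @param deflection_onset,deflection_duration first frame and length of the
#'   raised-cosine deflection pulse (frames); the pulse peaks at
#'   `onset + duration/2`.
#' @param eyeball_left,eyeball_right peak displacement (px) of the left /
#'   right border time course; unequal values tilt the globe.
#' @param eyeball_onset,eyeball_duration start and rise time (frames) of the
#'   smooth monotone eyeball ramp (holds its peak afterwards).
#' @param ripple_freq_hz,ripple_amplitude,ripple_start,ripple_stop,ripple_phase
#'   fast-oscillation frequency (Hz, must stay below Nyquist), amplitude
#'   (px), boxcar gate (frames, inclusive) and phase (rad).
#' @param ripple_width full width of the ripple's raised-cosine spatial
#'   support; `NULL` = as wide as the border-column margin allows
#'   (`min(0.9 N, N - 42)`).  Fast oscillations are lateral surface waves,
#'   so their support is wider than the deflection bump and covers the
#'   lateral bands used by [border_signals].
#' @param ripple_side `"both"`, `"left"` or `"right"` — which lateral half of
#'   the spatial support carries the ripple.
#' @param iris_rows `NULL` or `c(first, last)` rows of a bright iris-like
#'   band below the cornea.
#' @param iris_intensity intensity of that band.
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (intensity units; the result is clipped to `[0, 1]`).
#' @param seed RNG seed; a fixed seed makes the phantom byte-identical.
#' @return validated list of class `phantom_params`.
#' @export
phantom_params <- function(dims = c(200L, 576L, 140L),
                           frame_interval_s = 231e-6,
                           apex_row = 55, sagitta = 30,
                           band_thickness = 25, band_intensity = 0.95,
                           deflection_amplitude = 30,
                           deflection_center = NULL, deflection_width = NULL,
                           deflection_onset = 20, deflection_duration = 100,
                           eyeball_left = 0, eyeball_right = 0,
                           eyeball_onset = 35, eyeball_duration = 80,
                           ripple_freq_hz = 300, ripple_amplitude = 0,
                           ripple_start = 45, ripple_stop = 95,
                           ripple_phase = 0, ripple_side = "both",
                           ripple_width = NULL,
                           iris_rows = NULL, iris_intensity = 0.85,
                           noise_sigma = 0, seed = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 3L))
  M <- dims[1]; N <- dims[2]; I <- dims[3]
  if (is.null(deflection_center)) deflection_center <- (N + 1) / 2
  if (is.null(deflection_width)) deflection_width <- round(0.6 * N)
  if (deflection_center - deflection_width / 2 < 21 ||
      deflection_center + deflection_width / 2 > N - 20)
    stop("parameter error: deflection support must leave >= 20 undeformed border columns")
  if (is.null(ripple_width)) ripple_width <- min(0.9 * N, N - 42)
  if ((N + 1) / 2 - ripple_width / 2 < 21 ||
      (N + 1) / 2 + ripple_width / 2 > N - 20)
    stop("parameter error: ripple support must leave >= 20 undeformed border columns")
  if (ripple_freq_hz >= 1 / (2 * frame_interval_s))
    stop("parameter error: ripple frequency at or above Nyquist")
  if (noise_sigma < 0) stop("parameter error: noise_sigma must be >= 0")
  if (frame_interval_s <= 0) stop("parameter error: frame_interval_s must be > 0")
  if (deflection_onset < 2)
    stop("parameter error: deflection must start after the baseline frame (onset >= 2)")
  if (eyeball_onset < 2)
    stop("parameter error: eyeball motion must start after the baseline frame")
  if (ripple_start < 2 || ripple_stop < ripple_start || ripple_stop > I)
    stop("parameter error: ripple gate must lie in [2, I]")
  max_depth <- apex_row + sagitta + deflection_amplitude +
    max(eyeball_left, eyeball_right, 0) + abs(ripple_amplitude) +
    band_thickness
  if (max_depth > M - 2)
    stop("parameter error: scene deeper than the image (reduce amplitudes or band thickness)")
  ripple_side <- match.arg(ripple_side, c("both", "left", "right"))
  structure(as.list(environment())[c(
    "dims", "frame_interval_s", "apex_row", "sagitta", "band_thickness",
    "band_intensity", "deflection_amplitude", "deflection_center",
    "deflection_width", "deflection_onset", "deflection_duration",
    "eyeball_left", "eyeball_right", "eyeball_onset", "eyeball_duration",
    "ripple_freq_hz", "ripple_amplitude", "ripple_start", "ripple_stop",
    "ripple_phase", "ripple_side", "ripple_width", "iris_rows", "iris_intensity",
    "noise_sigma", "seed")],
    class = "phantom_params")
}

raised_cosine_pulse <- function(i, onset, duration) {
  # 0 -> 1 -> 0 over [onset, onset + duration], zero outside
  x <- (i - onset) / duration
  ifelse(x >= 0 & x <= 1, 0.5 * (1 - cos(2 * pi * x)), 0)
}

raised_cosine_ramp <- function(i, onset, duration) {
  # smooth monotone 0 -> 1 over [onset, onset + duration], then holds
  x <- pmin(pmax((i - onset) / duration, 0), 1)
  0.5 * (1 - cos(pi * x))
}

#' Generate a synthetic phantom sequence with ground truth
#'
#' @param params a [phantom_params] list.
#' @return list of class `corneal_phantom` with `sequence` (an
#'   [image_sequence]) and `truth`, which carries the true contour map, the
#'   true eyeball (`L_TO`) and cornea (`L_TR`) parts of the relative
#'   deformation, the true ripple signal, the true maximum deflection
#'   amplitude and the true ripple duration in frames.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  M <- p$dims[1]; N <- p$dims[2]; I <- p$dims[3]
  if (!is.null(p$seed)) set.seed(p$seed)
  n <- seq_len(N); i <- seq_len(I)

  nc <- p$deflection_center
  baseline <- p$apex_row + p$sagitta * ((n - nc) / ((N - 1) / 2))^2

  g <- ifelse(abs(n - nc) <= p$deflection_width / 2,
              0.5 * (1 + cos(pi * (n - nc) / (p$deflection_width / 2))), 0)
  h <- raised_cosine_pulse(i, p$deflection_onset, p$deflection_duration)
  deflection <- p$deflection_amplitude * outer(g, h)

  s <- raised_cosine_ramp(i, p$eyeball_onset, p$eyeball_duration)
  b1 <- p$eyeball_left * s
  bN <- p$eyeball_right * s
  t_n <- (n - 1) / (N - 1)
  eyeball <- outer(1 - t_n, b1) + outer(t_n, bN)

  gate <- as.numeric(i >= p$ripple_start & i <= p$ripple_stop)
  rsig <- p$ripple_amplitude * gate *
    sin(2 * pi * p$ripple_freq_hz * (i - 1) * p$frame_interval_s + p$ripple_phase)
  rc <- (N + 1) / 2
  g_rip <- ifelse(abs(n - rc) <= p$ripple_width / 2,
                  0.5 * (1 + cos(pi * (n - rc) / (p$ripple_width / 2))), 0)
  g_r <- switch(p$ripple_side,
                both = g_rip,
                left = g_rip * (n <= rc),
                right = g_rip * (n >= rc))
  ripple <- outer(g_r, rsig)

  contour <- baseline + eyeball + deflection + ripple    # N x I
  L_TR_true <- deflection + ripple

  data <- array(0, dim = c(M, N, I))
  m <- seq_len(M)
  iris <- NULL
  for (k in i) {
    D <- outer(m, contour[, k], "-")                     # depth below contour
    cover <- pmin(pmax(D + 0.5, 0), 1) * pmin(pmax(p$band_thickness - D + 0.5, 0), 1)
    fall <- matrix(1, M, N)
    pos <- D > 0
    fall[pos] <- 0.55 + 0.45 * exp(-D[pos] / 20)
    frame <- p$band_intensity * cover * fall
    if (!is.null(p$iris_rows)) {
      band <- matrix(m >= p$iris_rows[1] & m <= p$iris_rows[2], M, N) &
        (D > p$band_thickness + 4)
      frame[band] <- pmax(frame[band], p$iris_intensity)
    }
    data[, , k] <- frame
  }
  if (p$noise_sigma > 0)
    data <- data + rnorm(length(data), 0, p$noise_sigma)
  data <- pmin(pmax(data, 0), 1)

  truth <- list(contour = contour,
                L_T = contour - contour[, 1],
                L_TO = eyeball,
                L_TR = L_TR_true,
                ripple_signal = rsig,
                max_deflection = max(L_TR_true),
                ripple_duration_frames =
                  if (p$ripple_amplitude > 0) p$ripple_stop - p$ripple_start + 1L
                  else 0L)
  structure(list(sequence = image_sequence(data, p$frame_interval_s,
                                           meta = list(source = "synthetic phantom")),
                 truth = truth, params = p),
            class = "corneal_phantom")
}

#' @export
print.corneal_phantom <- function(x, ...) {
  cat(sprintf("<corneal_phantom> dims %s | true max deflection %.2f px | ripple %g px @ %g Hz\n",
              paste(x$params$dims, collapse = "x"),
              x$truth$max_deflection,
              x$params$ripple_amplitude, x$params$ripple_freq_hz))
  invisible(x)
}

#' Default four-class cohort recipes
#'
#' Parameter ranges emulating the four observed deformation classes:
#' class 1 = strong eyeball tilt with weak ripple, class 2 = weak tilt and
#' weak ripple, class 3 = weak tilt with strong ripple, class 4 = strong
#' tilt and strong ripple.  Ranges are in pixels (amplitudes) and Hz.
#'
#' @return named list of per-class parameter ranges.
#' @export
default_class_recipes <- function() {
  list(`1` = list(tilt = c(34, 44), ripple = c(0.2, 0.5)),
       `2` = list(tilt = c(8, 14),  ripple = c(0.2, 0.5)),
       `3` = list(tilt = c(8, 14),  ripple = c(2.5, 4)),
       `4` = list(tilt = c(34, 44), ripple = c(2.5, 4)))
}

#' Generate (and optionally analyse) a synthetic cohort
#'
#' Samples per-eye phantom parameters from per-class recipes, renders each
#' sequence and, when `analyze = TRUE`, runs the full analysis pipeline to
#' obtain the measured `(w1, w2, w3)` features.
#'
#' @param n_eyes number of eyes; classes are assigned round-robin.
#' @param class_recipes list as returned by [default_class_recipes].
#' @param dims phantom dimensions (the frame count should stay at 140 so the
#'   spectral bin arithmetic matches the reference acquisition).
#' @param seed RNG seed controlling the whole cohort.
#' @param analyze run [run_pipeline] per eye and append measured features.
#' @param keep_sequences retain the rendered sequences in the result (memory
#'   heavy; off by default).
#' @param noise_sigma sensor noise of every rendered eye.
#' @return list of class `phantom_cohort` with `table` (a data.frame of
#'   `eye`, `class`, sampled parameters and — if analysed — `w1`, `w2`,
#'   `w3`) and optionally `sequences`.
#' @export
generate_cohort <- function(n_eyes = 12L,
                            class_recipes = default_class_recipes(),
                            dims = c(200L, 576L, 140L),
                            seed = 1L, analyze = TRUE,
                            keep_sequences = FALSE,
                            noise_sigma = 0.01) {
  n_eyes <- as.integer(n_eyes)
  if (n_eyes == 0L)
    return(structure(list(table = data.frame(), sequences = list()),
                     class = "phantom_cohort"))
  set.seed(seed)
  classes <- rep(seq_along(class_recipes), length.out = n_eyes)
  rows <- vector("list", n_eyes)
  seqs <- if (keep_sequences) vector("list", n_eyes) else NULL
  cfg <- pipeline_config()
  for (e in seq_len(n_eyes)) {
    rec <- class_recipes[[classes[e]]]
    tilt <- runif(1, rec$tilt[1], rec$tilt[2])
    ramp <- runif(1, rec$ripple[1], rec$ripple[2])
    freq <- runif(1, 250, 350)
    ph <- phantom_params(dims = dims,
                         deflection_amplitude = runif(1, 18, 25),
                         eyeball_left = runif(1, 2, 4),
                         eyeball_right = runif(1, 2, 4) + tilt,
                         ripple_amplitude = ramp,
                         ripple_freq_hz = freq,
                         ripple_start = 45, ripple_stop = 95,
                         noise_sigma = noise_sigma,
                         seed = sample.int(2^31 - 1, 1))
    phantom <- generate_phantom(ph)
    row <- data.frame(eye = e, class = names(class_recipes)[classes[e]],
                      tilt = tilt, ripple_amplitude = ramp,
                      ripple_freq_hz = freq,
                      deflection_amplitude = ph$deflection_amplitude)
    if (analyze) {
      rep_e <- run_pipeline(phantom$sequence, config = cfg)
      row <- cbind(row, rep_e$features[, c("w1", "w2", "w3")])
    }
    rows[[e]] <- row
    if (keep_sequences) seqs[[e]] <- phantom$sequence
  }
  structure(list(table = do.call(rbind, rows), sequences = seqs),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d eyes, %d class(es)\n",
              nrow(x$table),
              length(unique(x$table$class))))
  invisible(x)
}
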