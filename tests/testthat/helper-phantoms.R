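# shared fixture builders: everything is generated in code at test time

# reduced-size phantom geometry (shorter image, narrower field) used by the
# closed-loop unit tests; the frame count stays at 140 so the spectral bin
# arithmetic matches the full-size acquisition
small_phantom_params <- function(...) {
  defaults <- list(dims = c(120L, 192L, 140L), apex_row = 40, sagitta = 15,
                   band_thickness = 18)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

# flat bright slab: rows top..bottom at `value`, everything else dark
make_slab_seq <- function(M = 80L, N = 60L, I = 5L, top = 30L, bottom = 45L,
                          value = 1, frame_interval_s = 231e-6) {
  arr <- array(0, dim = c(M, N, I))
  arr[top:bottom, , ] <- value
  image_sequence(arr, frame_interval_s = frame_interval_s)
}

# naive 3-D median oracle with replicate borders (clamped windows)
median3d_oracle <- function(arr, k) {
  d <- dim(arr)
  out <- arr
  r <- k %/% 2
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    ii <- pmin(pmax((i - r[1]):(i + r[1]), 1L), d[1])
    jj <- pmin(pmax((j - r[2]):(j + r[2]), 1L), d[2])
    ll <- pmin(pmax((l - r[3]):(l + r[3]), 1L), d[3])
    out[i, j, l] <- median(arr[ii, jj, ll])
  }
  out
}

# naive 2-D median oracle with replicate borders
median2d_oracle <- function(m, k) {
  d <- dim(m)
  out <- m
  r <- k %/% 2
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ii <- pmin(pmax((i - r[1]):(i + r[1]), 1L), d[1])
    jj <- pmin(pmax((j - r[2]):(j + r[2]), 1L), d[2])
    out[i, j] <- median(m[ii, jj])
  }
  out
}

# naive grayscale opening oracle: sliding min then sliding max, clamped windows
opening_oracle <- function(m, k) {
  d <- dim(m)
  r <- k %/% 2
  er <- m
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ii <- pmin(pmax((i - r[1]):(i + r[1]), 1L), d[1])
    jj <- pmin(pmax((j - r[2]):(j + r[2]), 1L), d[2])
    er[i, j] <- min(m[ii, jj])
  }
  di <- er
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ii <- pmin(pmax((i - r[1]):(i + r[1]), 1L), d[1])
    jj <- pmin(pmax((j - r[2]):(j + r[2]), 1L), d[2])
    di[i, j] <- max(er[ii, jj])
  }
  di
}

# brute-force Otsu: try all candidate splits of the 256-bin histogram and
# return the threshold maximizing between-class variance
otsu_oracle <- function(values, levels = 256L) {
  idx <- pmin(floor(values * levels) + 1L, levels)
  counts <- tabulate(idx, nbins = levels)
  mids <- (seq_len(levels) - 0.5) / levels
  total <- sum(counts)
  best_j <- 1L
  best_sb <- -Inf
  for (j in seq_len(levels - 1L)) {
    w0 <- sum(counts[1:j]); w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:j] * mids[1:j]) / w0
    mu1 <- sum(counts[(j + 1):levels] * mids[(j + 1):levels]) / w1
    sb <- (w0 / total) * (w1 / total) * (mu0 - mu1)^2
    if (sb > best_sb + 1e-15) {
      best_sb <- sb
      best_j <- j
    }
  }
  best_j / levels
}

# inner 8-connected boundary oracle: shape pixels with at least one background
# 8-neighbour inside the image (out-of-image neighbours replicate, i.e. count
# as foreground)
inner_boundary_oracle <- function(shape) {
  d <- dim(shape)
  out <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!shape[i, j]) next
    ii <- pmin(pmax((i - 1):(i + 1), 1L), d[1])
    jj <- pmin(pmax((j - 1):(j + 1), 1L), d[2])
    out[i, j] <- any(!shape[ii, jj])
  }
  out
}

# tone burst: sinusoid gated over [from, to], phase referenced to gate start
tone_burst <- function(freq_hz, from, to, I = 140L, dt = 231e-6, phase = 0,
                       quadrature = FALSE) {
  i <- seq_len(I)
  carrier <- if (quadrature) cos else sin
  carrier(2 * pi * freq_hz * (i - from) * dt + phase) *
    as.numeric(i >= from & i <= to)
}
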