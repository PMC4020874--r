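#' Construct a corneal image sequence
#'
#' The basic container of the package: an `M x N x I` block of grayscale
#' intensities where `m` indexes image rows (growing downward, toward the eye
#' interior), `n` indexes image columns (left to right across the cornea) and
#' `i` indexes frames in time.  Intensities are normalized to `[0, 1]`.
#'
#' @param data numeric 3-D array `(M, N, I)` with finite values in `[0, 1]`.
#' @param frame_interval_s seconds between consecutive frames.  The default,
#'   231 microseconds, is the value consistent with a 140-frame record
#'   resolving oscillations up to ~500 Hz on FFT bins 7--15.
#' @param meta optional named list of free-form metadata kept alongside the
#'   pixel data (acquisition notes, provenance, ...).
#' @return an object of class `image_sequence` with elements `data`, `dims`,
#'   `frame_interval_s` and `meta`.
#' @export
image_sequence <- function(data, frame_interval_s = 231e-6, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x columns x frames)")
  d <- dim(data)
  if (any(d < 3L))
    stop("dimension error: all of M, N, I must be >= 3 (a 3x3x3 median mask must fit)")
  if (!all(is.finite(data)))
    stop("all intensities must be finite")
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 1)
    stop("intensities must lie in [0, 1]; rescale on input")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be a single positive number")
  structure(list(data = data,
                 dims = as.integer(d),
                 frame_interval_s = as.numeric(frame_interval_s),
                 meta = meta),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- x$dims
  cat(sprintf("<image_sequence> %d x %d x %d (rows x cols x frames), dt = %g us\n",
              d[1], d[2], d[3], x$frame_interval_s * 1e6))
  invisible(x)
}

frame_as_gray <- function(px, what) {
  # png/tiff readers return a matrix for grayscale or an array with a channel
  # dimension; sequences are single-channel so extra channels are rejected
  if (is.matrix(px)) return(px)
  if (is.array(px) && length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) return(px[, , 1L])
    stop(sprintf("%s: expected a single-channel grayscale frame, got %d channels",
                 what, dim(px)[3]))
  }
  stop(sprintf("%s: unsupported pixel layout", what))
}

#' Read an image sequence from disk
#'
#' Reads either a multi-page grayscale TIFF stack or a directory of per-frame
#' PNG/TIFF images (ordered lexicographically by file name).  8- and 16-bit
#' samples are rescaled to `[0, 1]` by the dtype maximum (done by the readers).
#'
#' A JSON sidecar (`<path>.json` for a stack, `meta.json` inside a directory)
#' is honoured if present and may carry `frame_interval_s`.
#'
#' @param path file (TIFF stack) or directory of frames.
#' @param format one of `"auto"`, `"tiff_stack"`, `"image_dir"`.
#' @param frame_interval_s used when no sidecar provides one.
#' @return an [image_sequence].
#' @export
read_sequence <- function(path, format = c("auto", "tiff_stack", "image_dir"),
                          frame_interval_s = 231e-6) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "image_dir" else "tiff_stack"
  meta <- list()
  if (format == "tiff_stack") {
    if (!file.exists(path)) stop("path does not exist: ", path)
    frames <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(frames) || (is.array(frames) && !is.list(frames)))
      frames <- list(frames)
    sidecar <- paste0(path, ".json")
  } else {
    if (!dir.exists(path)) stop("path does not exist: ", path)
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (any(grepl("\\.bmp$", list.files(path), ignore.case = TRUE)))
      stop("BMP frames are not supported; convert to PNG or TIFF")
    if (length(files) == 0L) stop("empty input: no PNG/TIFF frames found in ", path)
    frames <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
      else tiff::readTIFF(f)
    })
    sidecar <- file.path(path, "meta.json")
  }
  if (length(frames) == 0L) stop("empty input: zero frames in ", path)
  frames <- lapply(seq_along(frames), function(k)
    frame_as_gray(frames[[k]], sprintf("frame %d", k)))
  d1 <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d1), logical(1))
  if (!all(same))
    stop("dimension error: frames have mixed resolutions")
  arr <- array(unlist(frames, use.names = FALSE), dim = c(d1, length(frames)))
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$frame_interval_s))
      frame_interval_s <- as.numeric(meta$frame_interval_s)
  }
  image_sequence(arr, frame_interval_s = frame_interval_s, meta = meta)
}

#' Write an image sequence to disk
#'
#' @param seq an [image_sequence].
#' @param path target file (TIFF stack) or directory (per-frame PNGs named
#'   `f0001.png`, ...).
#' @param format `"tiff_stack"` or `"image_dir"`.
#' @param bits bits per sample (8 or 16); quantization bounds the write/read
#'   round-trip error by `1/(2^bits - 1)`.
#' @return `path`, invisibly.  A JSON sidecar with the dims and frame interval
#'   is written next to the data.
#' @export
write_sequence <- function(seq, path, format = c("tiff_stack", "image_dir"),
                           bits = 8L) {
  stopifnot(inherits(seq, "image_sequence"), bits %in% c(8L, 16L))
  format <- match.arg(format)
  I <- seq$dims[3]
  meta <- list(dims = seq$dims, frame_interval_s = seq$frame_interval_s)
  if (format == "tiff_stack") {
    frames <- lapply(seq_len(I), function(i) seq$data[, , i])
    tiff::writeTIFF(frames, path, bits.per.sample = bits)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_len(I))
      png::writePNG(seq$data[, , i],
                    file.path(path, sprintf("f%04d.png", i)))
    jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write a 2-D deformation/contour map as CSV (or quantized TIFF)
#'
#' Maps are `N x I` matrices: rows indexed by image column `n`, columns by
#' frame `i`.  The CSV layout has a header row of frame indices and a first
#' column with `n`; it is lossless for doubles (17 significant digits).
#' Missing contour values (`NA`) become empty cells.  The TIFF form is a
#' 16-bit visualization with an affine scale recorded in a JSON sidecar.
#'
#' @param map numeric matrix `(N, I)`, `NA` allowed as the missing-marker.
#' @param path output file.
#' @param format `"csv"` (lossless) or `"tiff"`.
#' @param role optional role tag stored in the header/sidecar
#'   (`"contour"`, `"deformation"`, `"eyeball"`, `"cornea"`, `"fast"`,
#'   `"pattern"`, `"error"`).
#' @export
write_map <- function(map, path, format = c("csv", "tiff"), role = NULL) {
  format <- match.arg(format)
  if (!is.matrix(map) || !is.numeric(map))
    stop("`map` must be a numeric matrix (N x I)")
  if (any(is.infinite(map))) stop("map values must be finite or NA")
  if (format == "csv") {
    ch <- matrix("", nrow(map), ncol(map))
    idx <- !is.na(map)
    ch[idx] <- sprintf("%.17g", map[idx])   # lossless; NA -> empty cell
    df <- data.frame(n = seq_len(nrow(map)), ch,
                     stringsAsFactors = FALSE, check.names = FALSE)
    names(df) <- c("n", seq_len(ncol(map)))
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(role)) writeLines(paste0("# role: ", role), con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else {
    lo <- min(map, na.rm = TRUE); hi <- max(map, na.rm = TRUE)
    scale <- if (hi > lo) hi - lo else 1
    img <- (map - lo) / scale
    img[is.na(img)] <- 0
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
    jsonlite::write_json(list(offset = lo, scale = scale, role = role,
                              missing_as = 0),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a CSV map written by [write_map]
#'
#' @param path CSV file.
#' @return numeric matrix `(N, I)` with empty cells restored as `NA`; the
#'   role tag (if stored) is attached as attribute `"role"`.
#' @export
read_map <- function(path) {
  first <- readLines(path, n = 1L)
  role <- NULL
  skip <- 0L
  if (startsWith(first, "# role:")) {
    role <- trimws(sub("# role:", "", first, fixed = TRUE))
    skip <- 1L
  }
  df <- read.csv(path, check.names = FALSE, skip = skip)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  if (!is.null(role)) attr(m, "role") <- role
  m
}
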