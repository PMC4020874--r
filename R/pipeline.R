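#' Pipeline configuration
#'
#' All knobs of the stage sequence (median filtration, edge extraction,
#' eyeball separation, fast dynamics, features) in one validated object.
#' Unknown keys are rejected, and a configuration round-trips losslessly
#' through its JSON file form ([config_to_json] / [config_from_json]).
#'
#' @param edge_route `"canny"` (default, the more reliable detector) or
#'   `"otsu"`.
#' @param edge an [edge_params] list.
#' @param se2 structuring element of the slow/fast opening (columns, frames).
#' @param bands lateral bands for [border_signals]; `NULL` = defaults.
#' @param border_band_width border columns averaged in [separate_eyeball].
#' @param w2_bins 1-based spectral bin window of [feature_w2].
#' @param w3_threshold envelope fraction of [feature_w3].
#' @param frame_interval_s `NULL` to take the sequence's own value.
#' @param keep_maps retain intermediate maps in the report.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(edge_route = c("canny", "otsu"),
                            edge = edge_params(),
                            se2 = c(33L, 33L),
                            bands = NULL,
                            border_band_width = 1L,
                            w2_bins = 7:15,
                            w3_threshold = 0.8,
                            frame_interval_s = NULL,
                            keep_maps = TRUE) {
  edge_route <- match.arg(edge_route)
  stopifnot(inherits(edge, "edge_params"),
            length(se2) == 2L, all(se2 %% 2 == 1),
            w3_threshold > 0, w3_threshold <= 1)
  structure(list(edge_route = edge_route, edge = edge,
                 se2 = as.integer(se2), bands = bands,
                 border_band_width = as.integer(border_band_width),
                 w2_bins = as.integer(w2_bins),
                 w3_threshold = w3_threshold,
                 frame_interval_s = frame_interval_s,
                 keep_maps = isTRUE(keep_maps)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config].
#' @param path JSON file.
#' @export
config_to_json <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- unclass(config)
  obj$edge <- unclass(obj$edge)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(obj), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  edge <- if (!is.null(obj$edge)) do.call(edge_params, obj$edge) else edge_params()
  obj$edge <- edge
  do.call(pipeline_config, obj)
}

#' Run the full corneal-deformation analysis pipeline
#'
#' Executes the stage sequence: median filtration of the raw sequence, outer
#' corneal edge extraction (Canny or column-Otsu route), contour validation,
#' interpolation of missing columns and 3x3 median smoothing, relative
#' deformation, eyeball/cornea separation, fast-dynamics band analysis, and
#' the three dynamic features.  When a trained tree is supplied the eye is
#' also assigned a deformation class.
#'
#' @param x an [image_sequence] or a path readable by [read_sequence].
#' @param config a [pipeline_config].
#' @param tree optional `cart_tree` for classification.
#' @param out_dir optional directory; when given, the feature table
#'   (`features.csv`), a JSON report and the main maps (CSV) are written
#'   there.
#' @param strict abort (with a diagnostic dump if `out_dir` is set) when the
#'   contour validity rule fails; `strict = FALSE` records the failure in
#'   the report and continues.
#' @return list of class `corneal_report`: `features` (one-row data.frame),
#'   `class` (label or `NA`), `validity`, `max_deflection`, `fast`
#'   (the `fast_dynamics` object), `decomposition` and `contour` (when
#'   `keep_maps`), `timings_s`, and the `config` used.
#' @export
run_pipeline <- function(x, config = pipeline_config(), tree = NULL,
                         out_dir = NULL, strict = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(x)) x <- read_sequence(x)
  stopifnot(inherits(x, "image_sequence"))
  dt <- if (is.null(config$frame_interval_s)) x$frame_interval_s
        else config$frame_interval_s
  timings <- c()
  tic <- function(expr) system.time(expr)[["elapsed"]]

  filtered <- NULL
  timings["median_filter"] <- tic(
    filtered <- median_filter_seq(x, config$edge$median_mask))

  contour <- NULL
  timings["edge"] <- tic(
    contour <- switch(config$edge_route,
                      canny = extract_edge_canny(filtered, config$edge, refine_on = x),
                      otsu = extract_edge_otsu(filtered, config$edge, refine_on = x)))

  validity <- validate_contour(contour, config$edge)
  if (!validity$ok && strict) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_map(contour, file.path(out_dir, "contour_failed.csv"),
                role = "contour")
    }
    stop(sprintf(paste0("contour validity failure: %d missing point(s), ",
                        "max interframe jump %.1f px (limit %g)"),
                 validity$n_discontinuities, validity$max_interframe_jump,
                 config$edge$max_jump_px))
  }

  decomp <- fd <- features <- NULL
  timings["separation"] <- tic({
    contour <- smooth_contour(interpolate_contour(contour),
                              config$edge$contour_median_mask)
    L_T <- relative_deformation(contour)
    decomp <- separate_eyeball(L_T, config$border_band_width)
  })
  timings["fast_dynamics"] <- tic(
    fd <- fast_dynamics(decomp, frame_interval_s = dt,
                        se = config$se2, bands = config$bands))
  timings["features"] <- tic(
    features <- compute_features(decomp, fd, se = config$se2,
                                 w2_bins = config$w2_bins,
                                 w3_threshold = config$w3_threshold,
                                 frame_interval_s = dt))

  cls <- if (!is.null(tree)) predict(tree, features) else NA_character_
  report <- structure(list(features = features, class = cls,
                           validity = validity,
                           max_deflection = max_deflection(decomp),
                           fast = fd,
                           decomposition = if (config$keep_maps) decomp,
                           contour = if (config$keep_maps) contour,
                           timings_s = timings,
                           frame_interval_s = dt,
                           config = config),
                      class = "corneal_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feat <- cbind(report$features, class = report$class)
  write.csv(feat, file.path(out_dir, "features.csv"), row.names = FALSE)
  if (!is.null(report$decomposition)) {
    write_map(report$contour, file.path(out_dir, "contour.csv"), role = "contour")
    write_map(report$decomposition$L_T, file.path(out_dir, "L_T.csv"),
              role = "deformation")
    write_map(report$decomposition$L_TO, file.path(out_dir, "L_TO.csv"),
              role = "eyeball")
    write_map(report$decomposition$L_TR, file.path(out_dir, "L_TR.csv"),
              role = "cornea")
    write_map(report$fast$L_Q, file.path(out_dir, "L_Q.csv"), role = "fast")
  }
  spec <- data.frame(bin = report$fast$F_QL$bin,
                     freq_hz = report$fast$F_QL$freq_hz,
                     magnitude_L = report$fast$F_QL$magnitude,
                     magnitude_R = report$fast$F_QR$magnitude)
  write.csv(spec, file.path(out_dir, "spectra.csv"), row.names = FALSE)
  meta <- list(features = as.list(report$features),
               class = report$class,
               validity = unclass(report$validity),
               max_deflection = report$max_deflection,
               frame_interval_s = report$frame_interval_s,
               timings_s = as.list(report$timings_s),
               package_version = as.character(utils::packageVersion("corneadyn")))
  jsonlite::write_json(meta, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.corneal_report <- function(x, ...) {
  f <- x$features
  cat("<corneal_report>\n")
  cat(sprintf("  contour ok: %s | max deflection: %.2f px\n",
              x$validity$ok, x$max_deflection))
  cat(sprintf("  w1 = %.2f px | w2 = %.3f | w3 = %.0f frames (%.2f ms)\n",
              f$w1, f$w2, f$w3, f$w3_ms))
  if (!is.na(x$class)) cat(sprintf("  deformation class: %s\n", x$class))
  cat(sprintf("  total time: %.1f s\n", sum(x$timings_s)))
  invisible(x)
}
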