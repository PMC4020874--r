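#' Per-eye response pattern
#'
#' Builds the expected response `L_V(n, i)` of the cornea plus eyeball for
#' one eye: the apex-column eyeball displacement (constant across `n` within
#' a frame) plus the slowly varying part of the corneal deflection (its
#' grayscale opening).
#'
#' @param L_TO `N x I` eyeball displacement map.
#' @param L_TR `N x I` corneal deflection map.
#' @param se structuring element of the opening.
#' @return `N x I` pattern map.
#' @export
build_pattern <- function(L_TO, L_TR, se = c(33L, 33L)) {
  stopifnot(is.matrix(L_TO), is.matrix(L_TR),
            all(dim(L_TO) == dim(L_TR)))
  N <- nrow(L_TO)
  center <- round(N / 2)
  out <- matrix(L_TO[center, ], nrow = N, ncol = ncol(L_TO), byrow = TRUE) +
    grayscale_opening(L_TR, se)
  attr(out, "role") <- "pattern"
  out
}

#' Deviation of the observed deformation from the per-eye pattern
#'
#' `L_delta = L_T - L_V`, elementwise.  What remains is the fast corneal
#' ripple plus the part of the eyeball motion not captured by the apex
#' column (e.g. tilt of the globe).
#'
#' @param L_T observed relative deformation map.
#' @param L_V pattern map from [build_pattern].
#' @return `N x I` error map.
#' @export
pattern_error <- function(L_T, L_V) {
  stopifnot(is.matrix(L_T), is.matrix(L_V))
  if (!all(dim(L_T) == dim(L_V)))
    stop("dimension error: L_T and L_V differ in shape")
  out <- L_T - L_V
  attr(out, "role") <- "error"
  out
}

#' Feature w(1): maximum pattern-error amplitude
#'
#' The maximum over all columns and frames of the pattern error — the
#' largest deviation of the eye's response from its own pattern, dominated
#' by the eyeball deflection during force application.  Pixels.
#'
#' @param L_delta error map from [pattern_error].
#' @return single number (px).
#' @export
feature_w1 <- function(L_delta) {
  stopifnot(is.matrix(L_delta))
  max(L_delta)
}

#' Feature w(2): peak spectral magnitude in the fast band
#'
#' The maximum of the two border-signal magnitude spectra over 1-based FFT
#' bins 7–15 — the window covering the 150–500 Hz range of fast corneal
#' oscillations on a 140-frame record.
#'
#' @param F_QL,F_QR spectrum lists from [deformation_spectrum] (or bare
#'   magnitude vectors).
#' @param bins 1-based bin window, default `7:15`.
#' @return single number (spectral magnitude units).
#' @export
feature_w2 <- function(F_QL, F_QR, bins = 7:15) {
  ml <- if (is.list(F_QL)) F_QL$magnitude else F_QL
  mr <- if (is.list(F_QR)) F_QR$magnitude else F_QR
  if (length(ml) < max(bins) || length(mr) < max(bins))
    stop("spectra too short for the requested bin window")
  max(c(ml[bins], mr[bins]))
}

#' Feature w(3): duration of the fast corneal oscillation
#'
#' The oscillation envelope `e(i)` is the pointwise maximum over the left
#' and right region-II components; the duration is the span of frames where
#' the envelope stays at or above 80 % of its maximum,
#' `w3 = last - first + 1`.  The default envelope is the rectified
#' instantaneous value `|comp_II|`; because the span is taken between the
#' first and last crossing, interior rectification dips do not affect it.
#' `envelope = "analytic"` uses the smooth Hilbert magnitude instead.
#'
#' @param comp_II_L,comp_II_R region-II component signals: either lists
#'   from [band_components] or bare real vectors.
#' @param threshold envelope fraction defining the duration (default 0.8).
#' @param frame_interval_s seconds per frame, for the millisecond value.
#' @param envelope `"abs"` (default) or `"analytic"`.
#' @return list with `frames` and `ms` (`ms` is `NA` when no frame interval
#'   is supplied); an all-zero envelope gives 0 frames.
#' @export
feature_w3 <- function(comp_II_L, comp_II_R, threshold = 0.8,
                       frame_interval_s = NULL,
                       envelope = c("abs", "analytic")) {
  envelope <- match.arg(envelope)
  env_of <- function(x) {
    if (is.list(x)) {
      if (envelope == "analytic" && !is.null(x$comp_II_envelope))
        return(x$comp_II_envelope)
      x <- x$comp_II
    }
    if (envelope == "analytic") analytic_envelope(x) else abs(x)
  }
  e <- pmax(env_of(comp_II_L), env_of(comp_II_R))
  pk <- max(e)
  frames <- if (pk <= 0) 0L else {
    idx <- which(e >= threshold * pk)
    diff(range(idx)) + 1L
  }
  list(frames = as.numeric(frames),
       ms = if (is.null(frame_interval_s)) NA_real_
            else frames * frame_interval_s * 1e3)
}

# analytic-signal modulus of a real vector (one-sided spectrum doubling)
analytic_envelope <- function(x) {
  I <- length(x)
  fv <- fft(x)
  h <- numeric(I)
  h[1] <- 1
  if (I %% 2 == 0) {
    h[I / 2 + 1] <- 1
    h[2:(I / 2)] <- 2
  } else {
    h[2:((I + 1) / 2)] <- 2
  }
  Mod(fft(fv * h, inverse = TRUE) / I)
}

#' Features of one analysed eye
#'
#' Assembles the `(w1, w2, w3)` feature vector from a deformation
#' decomposition and its fast-dynamics analysis.
#'
#' @param decomp a `deformation_decomposition`.
#' @param fd a `fast_dynamics` object for the same eye.
#' @param se structuring element of the pattern opening.
#' @param w2_bins bin window of [feature_w2].
#' @param w3_threshold envelope fraction of [feature_w3].
#' @param frame_interval_s seconds per frame.
#' @return data.frame with one row: `w1`, `w2`, `w3` (frames), `w3_ms`.
#' @export
compute_features <- function(decomp, fd, se = c(33L, 33L), w2_bins = 7:15,
                             w3_threshold = 0.8, frame_interval_s = 231e-6) {
  stopifnot(inherits(decomp, "deformation_decomposition"),
            inherits(fd, "fast_dynamics"))
  L_V <- build_pattern(decomp$L_TO, decomp$L_TR, se)
  L_delta <- pattern_error(decomp$L_T, L_V)
  w3 <- feature_w3(fd$comp_L, fd$comp_R, threshold = w3_threshold,
                   frame_interval_s = frame_interval_s)
  data.frame(w1 = feature_w1(L_delta),
             w2 = feature_w2(fd$F_QL, fd$F_QR, bins = w2_bins),
             w3 = w3$frames, w3_ms = w3$ms)
}

#' Gini impurity of a label multiset
#'
#' `1 - sum(p^2)` over the class proportions `p`.
#'
#' @param labels vector of class labels.
#' @return impurity in `[0, 1)`.
#' @export
gini_impurity <- function(labels) {
  p <- tabulate(factor(labels)) / length(labels)
  1 - sum(p^2)
}

cart_leaf <- function(y, levels) {
  counts <- table(factor(y, levels = levels))
  # majority label, ties broken toward the lowest label
  label <- levels[which.max(counts)]
  list(type = "leaf", label = label,
       counts = as.integer(counts), n = length(y),
       purity = max(counts) / length(y),
       impure = length(unique(y)) > 1L)
}

cart_grow <- function(X, y, levels) {
  n <- length(y)
  if (length(unique(y)) <= 1L) return(cart_leaf(y, levels))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2L) next
    thr <- (v[-length(v)] + v[-1]) / 2
    for (t in thr) {
      lf <- X[, j] <= t
      nl <- sum(lf)
      imp <- (nl * gini_impurity(y[lf]) +
              (n - nl) * gini_impurity(y[!lf])) / n
      # deterministic tie-break: strictly better, else keep the earlier
      # candidate (lower feature index, then lower threshold)
      if (is.null(best) || imp < best$imp - 1e-12) {
        best <- list(j = j, t = t, imp = imp, lf = lf)
      }
    }
  }
  if (is.null(best)) return(cart_leaf(y, levels))  # duplicate conflicting rows
  list(type = "split",
       feature = best$j,
       feature_name = colnames(X)[best$j],
       threshold = best$t,
       n = n,
       left = cart_grow(X[best$lf, , drop = FALSE], y[best$lf], levels),
       right = cart_grow(X[!best$lf, , drop = FALSE], y[!best$lf], levels))
}

#' Train an unpruned CART classifier (Gini impurity)
#'
#' Greedy binary axis-aligned splitting: at each node every midpoint between
#' consecutive sorted unique values of every feature is scored by the
#' weighted Gini impurity of the induced partition; the best split recurses
#' until leaves are pure.  No pruning and no minimum node size — appropriate
#' for the small, well-separated cohorts this classifier is built for.
#' Identical feature vectors with conflicting labels end in an impure leaf
#' (flagged, majority label, lowest-label tie-break).  Ties between splits
#' go to the lowest feature index, then the lowest threshold.
#'
#' @param features data.frame or matrix, rows = samples, columns = numeric
#'   features (e.g. `w1`, `w2`, `w3`).
#' @param labels class labels (coerced to character), one per row.
#' @return object of class `cart_tree`.
#' @export
train_cart <- function(features, labels) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.character(labels)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (nrow(X) != length(y)) stop("features and labels disagree in length")
  levels <- sort(unique(y))
  structure(list(root = cart_grow(X, y, levels),
                 features = colnames(X), classes = levels),
            class = "cart_tree")
}

cart_route <- function(node, x) {
  while (node$type == "split") {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$label
}

#' Classify feature vectors with a trained tree
#'
#' @param object a `cart_tree`.
#' @param newdata data.frame/matrix with the training feature columns, or a
#'   bare numeric vector for a single sample.
#' @param ... unused.
#' @return character vector of class labels (use `as.integer` for the
#'   1–4 deformation classes).
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  X <- as.matrix(as.data.frame(newdata))
  if (all(object$features %in% colnames(X))) {
    X <- X[, object$features, drop = FALSE]
  } else if (ncol(X) >= length(object$features)) {
    X <- X[, seq_along(object$features), drop = FALSE]
  } else {
    stop("`newdata` lacks the training features: ",
         paste(object$features, collapse = ", "))
  }
  storage.mode(X) <- "double"
  apply(X, 1L, function(row) cart_route(object$root, row))
}

#' @rdname predict.cart_tree
#' @param tree a `cart_tree`.
#' @param fv feature vector(s).
#' @export
classify <- function(tree, fv) predict(tree, fv)

count_nodes <- function(node) {
  if (node$type == "leaf") return(c(leaves = 1L, splits = 0L))
  count_nodes(node$left) + count_nodes(node$right) + c(leaves = 0L, splits = 1L)
}

#' @export
print.cart_tree <- function(x, ...) {
  nn <- count_nodes(x$root)
  cat(sprintf("<cart_tree> %d split(s), %d leaves | classes: %s\n",
              nn["splits"], nn["leaves"], paste(x$classes, collapse = ", ")))
  print_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s* class %s (n=%d%s)\n", pad, node$label, node$n,
                  if (node$impure) ", IMPURE" else ""))
    } else {
      cat(sprintf("%s%s <= %.4g ?\n", pad, node$feature_name, node$threshold))
      print_node(node$left, indent + 1L)
      print_node(node$right, indent + 1L)
    }
  }
  print_node(x$root, 1L)
  invisible(x)
}

#' Serialize / restore a decision tree as JSON
#'
#' @param tree a `cart_tree`.
#' @param path output (input) JSON file.
#' @return `tree_to_json` returns `path` invisibly; `tree_from_json` returns
#'   the restored `cart_tree`.
#' @export
tree_to_json <- function(tree, path) {
  stopifnot(inherits(tree, "cart_tree"))
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

relist_node <- function(node) {
  if (node$type == "leaf") {
    node$counts <- as.integer(unlist(node$counts))
    return(node)
  }
  node$left <- relist_node(node$left)
  node$right <- relist_node(node$right)
  node
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  obj$root <- relist_node(obj$root)
  obj$features <- unlist(obj$features)
  obj$classes <- unlist(obj$classes)
  structure(obj, class = "cart_tree")
}

#' Reference feature table of ten analysed eyes
#'
#' A bundled table of the three dynamic features and the assigned
#' deformation class for ten right eyes, used as the reference training set
#' for the four-class decision tree.
#'
#' @return data.frame with columns `eye`, `w1`, `w2`, `w3`, `class`.
#' @export
eye_feature_table <- function() {
  path <- system.file("extdata", "eye_features_reference.csv",
                      package = "corneadyn", mustWork = TRUE)
  read.csv(path)
}
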