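#' Extract a square image patch centered on a cell
#'
#' Crops a \code{crop_px} square window centered on the (possibly
#' fractional) pixel coordinate, replicating edge pixels where the window
#' leaves the frame, then resizes to \code{out_px} with bilinear
#' interpolation (half-pixel-center convention, so an exact 2:1 reduction
#' averages 2x2 blocks and preserves the mean).
#'
#' @param frame Image matrix (rows y, columns x).
#' @param center_px Numeric \code{c(x, y)} center, 0-based pixel
#'   coordinates; must lie inside the frame.
#' @param crop_px Side of the square crop in pixels.
#' @param out_px Output side length (128 for the full-scale model).
#' @return An \code{out_px} square matrix.
#' @export
extract_patch <- function(frame, center_px, crop_px, out_px = 128) {
  stopifnot(is.matrix(frame), length(center_px) == 2, crop_px >= 1, out_px >= 1)
  H <- nrow(frame); W <- ncol(frame)
  cx <- center_px[1]; cy <- center_px[2]
  if (cx < 0 || cx > W - 1 || cy < 0 || cy > H - 1)
    stop("invalid center: coordinate outside the frame")
  offs <- (0:(crop_px - 1L)) - floor(crop_px / 2)
  rows <- pmin(pmax(round(cy) + offs, 0L), H - 1L) + 1L  # edge replication
  cols <- pmin(pmax(round(cx) + offs, 0L), W - 1L) + 1L
  crop <- frame[rows, cols, drop = FALSE]
  if (crop_px == out_px) return(crop)
  resize_bilinear(crop, out_px)
}

# Separable bilinear resize with half-pixel sample centers:
# src = (dst + 0.5) * n_in / n_out - 0.5, clamped to the valid range.
resize_bilinear <- function(img, out_px) {
  interp_matrix <- function(n_in, n_out) {
    src <- ((0:(n_out - 1L)) + 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- floor(src)
    hi <- pmin(lo + 1, n_in - 1)
    w <- src - lo
    M <- matrix(0, n_out, n_in)
    idx <- seq_len(n_out)
    M[cbind(idx, lo + 1)] <- M[cbind(idx, lo + 1)] + (1 - w)
    M[cbind(idx, hi + 1)] <- M[cbind(idx, hi + 1)] + w
    M
  }
  Mr <- interp_matrix(nrow(img), out_px)
  Mc <- interp_matrix(ncol(img), out_px)
  Mr %*% img %*% t(Mc)
}

#' Min-max normalize a patch to \[0, 1\]
#'
#' Subtracts the minimum intensity of the patch, then divides by the
#' maximum of the result. A constant patch (zero range) maps to all
#' zeros.
#'
#' @param patch Image matrix with finite values.
#' @return A matrix with min 0 and max 1 (or all zeros when constant).
#' @examples
#' normalize_patch(matrix(c(2, 4, 6, 4), 2))
#' @export
normalize_patch <- function(patch) {
  stopifnot(all(is.finite(patch)))
  patch <- patch - min(patch)
  m <- max(patch)
  if (m > 0) patch <- patch / m
  patch
}

patch_transforms <- function() {
  c("identity", "hflip", "vflip", "rot90", "rot180", "rot270")
}

# Apply one planar isometry to a square patch. rot90 is a 90-degree
# counterclockwise rotation of the displayed image (y down).
apply_patch_transform <- function(patch, transform) {
  n <- nrow(patch)
  switch(transform,
    identity = patch,
    hflip  = patch[, n:1, drop = FALSE],
    vflip  = patch[n:1, , drop = FALSE],
    rot90  = t(patch)[n:1, , drop = FALSE],
    rot180 = patch[n:1, n:1, drop = FALSE],
    rot270 = t(patch)[, n:1, drop = FALSE],
    stop("unknown transform"))
}

#' Geometric augmentation of a labelled patch
#'
#' Returns the six training variants of a patch: the identity, the
#' horizontal and vertical reflections, and the rotations by 90, 180 and
#' 270 degrees. Because a rotated image of a right-moving cell shows a
#' cell moving in a different quadrant, each label is transformed by the
#' same isometry (see [transform_label()]); \code{fixed_labels = TRUE}
#' keeps the original label on every variant instead.
#'
#' @param patch Square image matrix.
#' @param label Integer direction label in \code{0:3}.
#' @param fixed_labels Keep labels untransformed.
#' @return A list of six \code{list(patch, label, transform)} entries.
#' @export
augment_patch <- function(patch, label, fixed_labels = FALSE) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch))
    stop("augmentation requires a square patch")
  lapply(patch_transforms(), function(tr) {
    list(patch = apply_patch_transform(patch, tr),
         label = if (fixed_labels) as.integer(label)
                 else transform_label(label, tr),
         transform = tr)
  })
}

#' Augment a whole patch set
#'
#' @param x H x W x N array of patches.
#' @param labels Integer labels of length N.
#' @param fixed_labels Keep labels untransformed.
#' @return A list with \code{x} (H x W x 6N array) and \code{labels}
#'   (length 6N); variants of one source patch are contiguous.
#' @export
augment_dataset <- function(x, labels, fixed_labels = FALSE) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == length(labels))
  trs <- patch_transforms()
  n <- dim(x)[3]
  out <- array(0, dim = c(dim(x)[1], dim(x)[2], 6L * n))
  lab <- integer(6L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (tr in trs) {
      k <- k + 1L
      out[, , k] <- apply_patch_transform(x[, , i], tr)
      lab[k] <- if (fixed_labels) as.integer(labels[i])
                else transform_label(labels[i], tr)
    }
  }
  list(x = out, labels = lab)
}

#' Stratified train / validation / test split
#'
#' Splits patch indices into train, validation and test sets, stratified
#' by label. Within each class of size n the validation set gets
#' \code{ceiling(n * f_val)} patches, the test set \code{round(n *
#' f_test)}, and training the remainder -- the rounding convention this
#' workflow uses for its reference per-class counts (e.g. 179 patches at
#' (0.6, 0.2, 0.2) give 107/36/36). The assignment is deterministic given
#' the seed.
#'
#' @param labels Integer labels in \code{0:3} (one per patch).
#' @param fractions Train / validation / test fractions summing to 1.
#' @param seed RNG seed for the within-class shuffles.
#' @return A list with \code{split} (character vector \code{"train"},
#'   \code{"val"} or \code{"test"} per patch) and \code{counts} (class x
#'   split table).
#' @export
split_dataset <- function(labels, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  labels <- as.integer(labels)
  set.seed(seed)
  split <- character(length(labels))
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    n <- length(idx)
    if (n == 0L) {
      warning(sprintf("class %d has no samples", k))
      next
    }
    idx <- idx[sample.int(n)]
    n_val <- ceiling(n * fractions[2])
    n_test <- round(n * fractions[3])
    n_train <- n - n_val - n_test
    if (n_train < 0) stop("fractions leave no training samples for a class")
    split[idx] <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  }
  counts <- table(factor(labels, levels = 0:3),
                  factor(split, levels = c("train", "val", "test")))
  dimnames(counts)[[1]] <- direction_name(0:3)
  list(split = split, counts = counts)
}

#' Build a labelled patch dataset from a movie and its annotations
#'
#' For every annotated (cell, frame) anchor, extracts a normalized patch
#' centered on the tracked position in that frame.
#'
#' @param movie H x W x T array (frames indexed from 0 in the tracks).
#' @param tracks Data frame \code{cell_id, frame, x_px, y_px}.
#' @param annotations Data frame from [annotate_all()].
#' @param crop_px Crop window side in pixels.
#' @param out_px Output patch side.
#' @return A list with \code{x} (out_px x out_px x N array of normalized
#'   patches), \code{labels}, and \code{meta} (the annotation rows).
#' @export
build_patch_dataset <- function(movie, tracks, annotations, crop_px,
                                out_px = 128) {
  n <- nrow(annotations)
  x <- array(0, dim = c(out_px, out_px, n))
  for (i in seq_len(n)) {
    row <- tracks[tracks$cell_id == annotations$cell_id[i] &
                  tracks$frame == annotations$frame[i], ]
    if (nrow(row) != 1L)
      stop("annotation without a matching track point")
    p <- extract_patch(movie[, , annotations$frame[i] + 1L],
                       c(row$x_px, row$y_px), crop_px, out_px)
    x[, , i] <- normalize_patch(p)
  }
  list(x = x, labels = as.integer(annotations$label), meta = annotations)
}
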