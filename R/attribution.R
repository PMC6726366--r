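last_conv_index <- function(model) {
  idx <- which(vapply(model$layers, function(l) l$type == "conv", logical(1)))
  if (length(idx) == 0L) stop("model has no convolutional layer")
  max(idx)
}

#' Maximum activation per feature map of a convolutional layer
#'
#' For each feature map of the chosen layer (the last convolutional layer
#' by default), finds the spatial position of its maximum activation --
#' ties broken toward the first position in a row-major scan -- and ranks
#' the maps by that activation (ties keep map-index order). The top-
#' ranked entries are the usual targets for [guided_backprop()].
#'
#' @param model A trained model.
#' @param patch A single normalized patch.
#' @param layer Layer index; default the last convolutional layer.
#' @return A data frame ordered by decreasing activation with columns
#'   \code{feature_map}, \code{row}, \code{col} (1-based), and
#'   \code{activation}.
#' @export
select_max_activations <- function(model, patch, layer = NULL) {
  if (is.null(layer)) layer <- last_conv_index(model)
  if (model$layers[[layer]]$type != "conv")
    stop("activation selection targets a convolutional layer")
  acts <- layer_activations(model, patch)[[layer]]
  d <- dim(acts)
  rows <- integer(d[3]); cols <- integer(d[3]); vals <- numeric(d[3])
  for (k in seq_len(d[3])) {
    flat <- as.vector(t(acts[, , k]))      # row-major scan
    j <- which.max(flat) - 1L              # first max
    rows[k] <- j %/% d[2] + 1L
    cols[k] <- j %% d[2] + 1L
    vals[k] <- flat[j + 1L]
  }
  out <- data.frame(feature_map = seq_len(d[3]), row = rows, col = cols,
                    activation = vals)
  out[order(-out$activation, out$feature_map), , drop = FALSE]
}

resolve_target <- function(model, target, layer = NULL) {
  if (!is.null(target$class)) {
    list(layer = length(model$layers), unit = as.integer(target$class) + 1L)
  } else if (!is.null(target$unit)) {
    list(layer = if (is.null(target$layer)) length(model$layers)
                 else target$layer,
         unit = as.integer(target$unit))
  } else if (!is.null(target$feature_map)) {
    if (is.null(layer)) layer <- last_conv_index(model)
    shapes <- spec_shapes(model$spec)
    d <- shapes[[layer]]$out
    list(layer = layer,
         unit = target$row + d[1] * (target$col - 1L) +
                d[1] * d[2] * (target$feature_map - 1L))
  } else stop("target must give (feature_map, row, col), unit, or class")
}

#' Guided backpropagation saliency map
#'
#' Backpropagates a single post-activation unit -- typically the maximum
#' activation of a feature map in the last convolutional layer, from
#' [select_max_activations()] -- down to pixel space. At every ReLU the
#' backward signal is zeroed where the forward activation was not
#' positive \emph{or} the incoming signal is negative, which keeps only
#' pixel evidence that increases the target and yields the sharp local
#' features (protrusion, trailing edge) this method is known for. A
#' target whose activation is zero gives an all-zero map.
#'
#' @param model A trained model.
#' @param patch A single normalized patch.
#' @param target A list: either \code{list(feature_map, row, col)} (as
#'   one row of [select_max_activations()]), \code{list(layer, unit)}
#'   with a column-major unit index, or \code{list(class = k)} for an
#'   output logit (k in 0..3).
#' @param layer Convolutional layer for \code{feature_map} targets;
#'   default the last.
#' @param guided \code{FALSE} computes the plain gradient instead (no
#'   backward gating).
#' @return A matrix of class \code{saliency_map} (signed reals, patch
#'   size).
#' @export
guided_backprop <- function(model, patch, target, layer = NULL,
                            guided = TRUE) {
  x <- check_patch_input(model, patch)
  tg <- resolve_target(model, target, layer)
  map <- nn_gbp_cpp(model$layers, x, tg$layer, tg$unit, guided)
  structure(map, class = c("saliency_map", class(map)),
            target_layer = tg$layer, target_unit = tg$unit)
}

#' Deep Taylor decomposition relevance map
#'
#' Decomposes the pre-softmax output of one class -- by default the
#' predicted class -- into non-negative per-pixel relevances: the z+ rule
#' in hidden convolutional and fully connected layers (biases excluded),
#' winner-take-all routing through max pooling, identity through ReLU,
#' and the zB rule with box bounds \[0, 1\] at the input layer (patches
#' are min-max normalized to that range). With zero biases the pixel
#' relevances sum to the output relevance R_f. A non-positive R_f
#' carries no positive evidence to decompose; the map is all zeros and a
#' warning is raised.
#'
#' @param model A trained model.
#' @param patch A single normalized patch.
#' @param class_index Class in 0..3; default the predicted class.
#' @return A non-negative matrix of class \code{relevance_map} with
#'   attributes \code{Rf} (output relevance) and \code{class}.
#' @export
deep_taylor <- function(model, patch, class_index = NULL) {
  x <- check_patch_input(model, patch)
  if (is.null(class_index)) class_index <- predict_label(model, patch)[1]
  res <- nn_dtd_cpp(model$layers, x, as.integer(class_index) + 1L)
  if (!res$defined)
    warning("output relevance is not positive; returning an all-zero map")
  map <- pmax(res$map, 0)  # clip ~1e-15 rounding residues of the zB rule
  structure(map, class = c("relevance_map", class(map)),
            Rf = res$Rf, class_index = as.integer(class_index))
}

#' Occlusion sensitivity map
#'
#' Slides a \code{mask_size} square mask over every pixel, replaces the
#' masked window (cropped at borders) by the patch mean (or zero), runs
#' the forward pass, and records the negated class score -- the
#' pre-softmax logit of the patch's class by default. The map is min-max
#' normalized to integers in \[0, 255\]; a flat raw map (e.g. a constant
#' predictor) maps to all zeros.
#'
#' @param model A trained model.
#' @param patch A single normalized patch.
#' @param class_index Class whose score is occluded, usually the true
#'   label of the patch; default the predicted class.
#' @param mask_size Odd mask side, smaller than the patch.
#' @param fill \code{"mean"} or \code{"zero"} mask fill.
#' @param use_softmax Occlude the softmax probability instead of the
#'   logit.
#' @return An integer matrix of class \code{occlusion_map} in \[0, 255\]
#'   with attribute \code{raw} (the unnormalized map).
#' @export
occlusion_map <- function(model, patch, class_index = NULL, mask_size = 7,
                          fill = c("mean", "zero"), use_softmax = FALSE) {
  fill <- match.arg(fill)
  x <- check_patch_input(model, patch)
  if (mask_size %% 2 != 1) stop("mask_size must be odd")
  if (mask_size >= model$input_px) stop("mask must be smaller than the patch")
  if (is.null(class_index)) class_index <- predict_label(model, patch)[1]
  fv <- if (fill == "mean") mean(x) else 0
  raw <- nn_occlusion_cpp(model$layers, x, as.integer(mask_size), fv,
                          as.integer(class_index) + 1L, use_softmax)
  rng <- max(raw) - min(raw)
  norm <- if (rng > 0) round(255 * (raw - min(raw)) / rng) else raw * 0
  storage.mode(norm) <- "integer"
  structure(norm, class = c("occlusion_map", class(norm)), raw = raw,
            class_index = as.integer(class_index), mask_size = mask_size)
}

#' Top-decile hotspot overlap of two attribution maps
#'
#' The fraction of pixels shared by the top 10 percent of each map (both
#' sets have the same size, so this is the intersection over the set
#' size) -- a quantitative check that two attribution methods highlight
#' the same cell regions.
#'
#' @param a,b Attribution maps of equal size (absolute values are
#'   ranked).
#' @param decile Top fraction to compare.
#' @return Shared fraction in \[0, 1\].
#' @export
hotspot_overlap <- function(a, b, decile = 0.1) {
  stopifnot(length(a) == length(b))
  k <- max(1L, round(length(a) * decile))
  ta <- order(abs(as.vector(a)), decreasing = TRUE)[seq_len(k)]
  tb <- order(abs(as.vector(b)), decreasing = TRUE)[seq_len(k)]
  length(intersect(ta, tb)) / k
}

#' Composite attribution figure for one patch
#'
#' Draws the standard panel for inspecting a prediction: the input patch,
#' the guided-backpropagation maps of the feature maps with the top-three
#' maximum activations in the last convolutional layer, and the deep
#' Taylor relevance heatmap.
#'
#' @param model A trained model.
#' @param patch A single normalized patch.
#' @param main Optional title (defaults to the predicted direction).
#' @return Invisibly, a list with the drawn maps.
#' @export
plot_attribution <- function(model, patch, main = NULL) {
  x <- check_patch_input(model, patch)[, , 1]
  cl <- predict_label(model, patch)[1]
  sel <- select_max_activations(model, patch)
  gbps <- lapply(1:3, function(i)
    guided_backprop(model, patch,
                    target = as.list(sel[i, c("feature_map", "row", "col")])))
  dtd <- suppressWarnings(deep_taylor(model, patch, cl))
  show <- function(m, title, col = grDevices::gray.colors(255, 0, 1)) {
    graphics::image(t(m)[, nrow(m):1], col = col, axes = FALSE, asp = 1,
                    main = title, cex.main = 0.9)
  }
  old <- graphics::par(mfrow = c(1, 5), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(old))
  show(x, if (is.null(main)) paste("input:", direction_name(cl)) else main)
  for (i in 1:3) show(abs(gbps[[i]]), sprintf("GBP #%d", i))
  show(dtd, "DTD relevance",
       col = grDevices::hcl.colors(255, "YlOrRd", rev = TRUE))
  invisible(list(input = x, gbp = gbps, dtd = dtd, predicted = cl))
}
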