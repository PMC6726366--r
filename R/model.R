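#' Layer descriptors for CNN specifications
#'
#' Building blocks for [model_spec()]: stride-1 "same"-padded
#' convolutions with odd kernels, 2x2 stride-2 max pooling, and fully
#' connected layers. \code{activation} is \code{"relu"} or
#' \code{"linear"}; \code{dropout} (fully connected only) is applied
#' after the activation during training.
#'
#' @param kernel Convolution kernel side (odd).
#' @param filters Number of convolution filters.
#' @param size Pooling window (= stride).
#' @param units Fully connected output units.
#' @param activation Activation function name.
#' @param dropout Dropout rate in [0, 1).
#' @return A layer descriptor list.
#' @export
conv_layer <- function(kernel, filters, activation = "relu") {
  stopifnot(kernel %% 2 == 1, filters >= 1)
  list(type = "conv", kernel = as.integer(kernel),
       filters = as.integer(filters), activation = activation)
}

#' @rdname conv_layer
#' @export
pool_layer <- function(size = 2) {
  list(type = "maxpool", size = as.integer(size))
}

#' @rdname conv_layer
#' @export
fc_layer <- function(units, activation = "linear", dropout = 0) {
  stopifnot(units >= 1, dropout >= 0, dropout < 1)
  list(type = "fc", units = as.integer(units), activation = activation,
       dropout = dropout)
}

#' CNN architecture for direction prediction
#'
#' The default is the 14-layer architecture used throughout this package:
#' eight stride-1 convolutions (5x5x8, 5x5x32, 3x3x40, 5x5x32, 5x5x48,
#' 5x5x64, 5x5x64, 5x5x72) interleaved with four 2x2 max-pooling layers,
#' then fully connected layers of 1000 (ReLU, dropout) and 4 (linear)
#' units; the softmax over the last layer is the distribution over the
#' four moving directions. Convolutions use "same" zero padding -- the
#' only padding convention under which the four poolings map the input
#' cleanly (128 -> 8, or 64 -> 4 at reduced scale).
#'
#' @param input_px Input patch side length; must be divisible by 16.
#' @param n_classes Output classes.
#' @param dropout Dropout rate of the first fully connected layer.
#' @param layers Optional custom layer list (from [conv_layer()] and
#'   friends) replacing the default architecture.
#' @return An object of class \code{cnn_spec}.
#' @examples
#' spec <- model_spec(input_px = 64)
#' model_summary(build_model(spec, seed = 1))
#' @export
model_spec <- function(input_px = 128, n_classes = 4, dropout = 0.3,
                       layers = NULL) {
  input_px <- as.integer(input_px)
  if (is.null(layers)) {
    if (input_px %% 16L != 0L)
      stop("input_px must be divisible by 16 for the four pooling stages")
    layers <- list(
      conv_layer(5, 8), conv_layer(5, 32), pool_layer(),
      conv_layer(3, 40), conv_layer(5, 32), pool_layer(),
      conv_layer(5, 48), conv_layer(5, 64), pool_layer(),
      conv_layer(5, 64), conv_layer(5, 72), pool_layer(),
      fc_layer(1000, activation = "relu", dropout = dropout),
      fc_layer(n_classes, activation = "linear"))
  }
  structure(list(layers = layers, input_px = input_px, channels = 1L,
                 n_classes = as.integer(n_classes)),
            class = "cnn_spec")
}

# Walk the spec, returning per-layer output shapes (H, W, C) and fan-in.
spec_shapes <- function(spec) {
  H <- spec$input_px; W <- spec$input_px; C <- spec$channels
  flat <- NULL
  shapes <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    lay <- spec$layers[[i]]
    if (lay$type == "conv") {
      if (!is.null(flat)) stop("convolution after a fully connected layer")
      shapes[[i]] <- list(out = c(H, W, lay$filters),
                          fan_in = lay$kernel^2 * C)
      C <- lay$filters
    } else if (lay$type == "maxpool") {
      H <- H %/% lay$size; W <- W %/% lay$size
      shapes[[i]] <- list(out = c(H, W, C), fan_in = NA)
    } else {
      if (is.null(flat)) flat <- H * W * C
      shapes[[i]] <- list(out = lay$units, fan_in = flat)
      flat <- lay$units
    }
  }
  shapes
}

#' Build a model with He-normal initialization
#'
#' Weights of every convolution and fully connected layer are drawn from
#' Normal(0, sqrt(2 / fan_in)) -- fan_in being kernel^2 x input channels
#' for convolutions and the input feature count for fully connected
#' layers -- and biases start at zero. Flattening between the last
#' pooling stage and the first fully connected layer uses R's
#' column-major order (row, then column, then channel).
#'
#' @param spec A [model_spec()].
#' @param seed RNG seed; identical seeds give identical weights.
#' @return An object of class \code{cellheading_model}.
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cnn_spec"))
  set.seed(seed)
  shapes <- spec_shapes(spec)
  C <- spec$channels
  layers <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    lay <- spec$layers[[i]]
    if (lay$type == "conv") {
      k <- lay$kernel
      fan_in <- shapes[[i]]$fan_in
      W <- array(rnorm(k * k * C * lay$filters, 0, sqrt(2 / fan_in)),
                 dim = c(k, k, C, lay$filters))
      layers[[i]] <- list(type = "conv", W = W, b = numeric(lay$filters),
                          activation = lay$activation)
      C <- lay$filters
    } else if (lay$type == "maxpool") {
      layers[[i]] <- list(type = "maxpool", size = lay$size)
    } else {
      fan_in <- shapes[[i]]$fan_in
      W <- matrix(rnorm(fan_in * lay$units, 0, sqrt(2 / fan_in)),
                  fan_in, lay$units)
      layers[[i]] <- list(type = "fc", W = W, b = numeric(lay$units),
                          activation = lay$activation,
                          dropout = lay$dropout)
    }
  }
  structure(list(layers = layers, spec = spec, input_px = spec$input_px,
                 n_classes = spec$n_classes, seed = seed),
            class = "cellheading_model")
}

check_patch_input <- function(model, x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  d <- dim(x)
  if (length(d) != 3L || d[1] != model$input_px || d[2] != model$input_px)
    stop(sprintf("input must be %dx%d patches, got %s", model$input_px,
                 model$input_px, paste(d, collapse = "x")))
  x
}

#' Forward pass: class probabilities for image patches
#'
#' Runs the network in inference mode (dropout off) and applies the
#' softmax to the last layer's activations.
#'
#' @param object A [build_model()] model.
#' @param newdata A single patch matrix or an H x W x N array of
#'   normalized patches.
#' @param type \code{"prob"} for softmax probabilities, \code{"logit"}
#'   for pre-softmax activations, \code{"label"} for argmax labels (ties
#'   broken toward the lowest class index).
#' @param ... Unused.
#' @return An N x n_classes matrix, or an integer label vector.
#' @export
predict.cellheading_model <- function(object, newdata,
                                      type = c("prob", "logit", "label"), ...) {
  type <- match.arg(type)
  x <- check_patch_input(object, newdata)
  out <- nn_forward_cpp(object$layers, x)
  if (type == "label")
    return(apply(out$logits, 1L, which.max) - 1L)  # first max: lowest index
  m <- if (type == "prob") out$probs else out$logits
  colnames(m) <- direction_name(seq_len(object$n_classes) - 1L)[
    seq_len(ncol(m))]
  m
}

#' Predicted direction label for patches
#'
#' Argmax of the class distribution, ties broken toward the lowest class
#' index.
#'
#' @param model A [build_model()] model.
#' @param patch Patch matrix or array.
#' @return Integer labels in \code{0:3}.
#' @export
predict_label <- function(model, patch) {
  predict(model, patch, type = "label")
}

#' Per-layer activations for one patch
#'
#' @param model A model.
#' @param patch A single patch matrix.
#' @return A list of per-layer post-activation outputs (arrays for
#'   convolution/pooling layers, vectors for fully connected layers).
#' @export
layer_activations <- function(model, patch) {
  x <- check_patch_input(model, patch)
  if (dim(x)[3] != 1L) stop("layer_activations takes a single patch")
  nn_activations_cpp(model$layers, x)
}

#' Per-layer shapes and parameter counts
#'
#' @param model A model.
#' @return A data frame with one row per layer (type, output shape,
#'   parameter count) plus a \code{total_params} attribute.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "cellheading_model"))
  shapes <- spec_shapes(model$spec)
  rows <- lapply(seq_along(model$layers), function(i) {
    lay <- model$layers[[i]]
    np <- if (lay$type == "maxpool") 0L else length(lay$W) + length(lay$b)
    out <- shapes[[i]]$out
    data.frame(layer = i, type = lay$type,
               output = paste(out, collapse = "x"), params = np)
  })
  df <- do.call(rbind, rows)
  attr(df, "total_params") <- sum(df$params)
  df
}

#' Total trainable parameter count
#'
#' @param model A model.
#' @return Integer count of weights plus biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l)
    if (l$type == "maxpool") 0L else length(l$W) + length(l$b), integer(1)))
}

#' @export
print.cellheading_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("<cellheading_model> input %dx%d, %d layers, %s parameters\n",
              x$input_px, x$input_px, length(x$layers),
              format(attr(s, "total_params"), big.mark = ",")))
  print(s, row.names = FALSE)
  invisible(x)
}

#' Loss and analytic weight gradients (for checking and custom training)
#'
#' Class-weighted softmax cross-entropy over a batch, normalized by the
#' summed weights, with the analytic gradients of every weight and bias.
#' Dropout is off, so the result is deterministic.
#'
#' @param model A model.
#' @param x Patch array.
#' @param labels Integer labels in \code{0:(n_classes-1)}.
#' @param class_weights Per-class loss weights (default all 1).
#' @return A list with \code{loss} and \code{grads} (per layer, \code{dW}
#'   and \code{db}).
#' @export
model_loss_grad <- function(model, x, labels,
                            class_weights = rep(1, model$n_classes)) {
  x <- check_patch_input(model, x)
  nn_loss_grad_cpp(model$layers, x, as.integer(labels),
                   as.numeric(class_weights))
}

#' Save and load model checkpoints
#'
#' Checkpoints are versioned R serializations of the full model object
#' (architecture specification plus weight and bias arrays keyed by
#' layer), so a reloaded model reproduces predictions bit for bit.
#'
#' @param model A [build_model()] model.
#' @param path Checkpoint file (conventionally \code{.rds}).
#' @return \code{save_model} returns the path invisibly;
#'   \code{load_model} returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cellheading_model"))
  saveRDS(list(format = "cellheading_checkpoint", version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "cellheading_checkpoint"))
    stop("not a cellheading checkpoint")
  ck$model
}
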