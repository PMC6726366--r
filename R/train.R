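#' Training configuration
#'
#' Defaults are the standard settings of this workflow: base learning
#' rate 0.021, momentum 0.5, stratified batches of 46 images, 50 epochs,
#' dropout 0.3, geometric augmentation on, 4 cross-validation folds.
#'
#' @param learning_rate SGD base learning rate.
#' @param momentum SGD momentum.
#' @param batch_size Stratified batch size.
#' @param epochs Training epochs per fold.
#' @param folds Cross-validation folds (>= 2).
#' @param dropout_rate Dropout rate of the first fully connected layer.
#' @param augment Train on the six geometric variants of every patch.
#' @param fixed_labels Keep labels untransformed under augmentation (the
#'   literal-augmentation ablation; geometry argues for transforming
#'   them, which is the default).
#' @param seed Master seed for weight initialization, batch shuffles and
#'   dropout.
#' @return A list of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 0.021, momentum = 0.5,
                         batch_size = 46, epochs = 50, folds = 4,
                         dropout_rate = 0.3, augment = TRUE,
                         fixed_labels = FALSE, seed = 1) {
  stopifnot(learning_rate > 0 || learning_rate == 0, momentum >= 0,
            batch_size >= 1, epochs >= 1, folds >= 2,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 dropout_rate = dropout_rate, augment = augment,
                 fixed_labels = fixed_labels, seed = seed),
            class = "train_config")
}

#' Class weights for imbalanced directions
#'
#' The loss of a sample of class k is multiplied by
#' \code{sum(counts) / (n * counts[k])}, so over-represented directions
#' contribute proportionally less; balanced counts give weight 1 for
#' every class.
#'
#' @param counts Per-class training counts, all positive.
#' @param n_classes Number of classes.
#' @return Numeric weights, one per class.
#' @examples
#' class_weights(c(107, 112, 145, 105))
#' @export
class_weights <- function(counts, n_classes = length(counts)) {
  counts <- as.numeric(counts)
  if (any(counts <= 0)) stop("every class needs a positive training count")
  sum(counts) / (n_classes * counts)
}

#' Stratified mini-batches
#'
#' Splits sample indices into batches whose class proportions match the
#' whole set's within one sample per class: each class's shuffled indices
#' are spread as evenly as possible over \code{ceiling(n / batch_size)}
#' batches (a batch size larger than the dataset gives a single smaller
#' batch). Deterministic given the seed.
#'
#' @param labels Integer class labels.
#' @param batch_size Target batch size.
#' @param seed RNG seed.
#' @return A list of integer index vectors.
#' @export
make_batches <- function(labels, batch_size = 46, seed = 1) {
  n <- length(labels)
  if (n == 0L) stop("empty training set")
  set.seed(seed)
  n_batches <- max(1L, ceiling(n / batch_size))
  batches <- vector("list", n_batches)
  for (k in unique(labels)) {
    idx <- which(labels == k)
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% n_batches
    extra <- length(idx) %% n_batches
    sizes <- rep(base, n_batches)
    if (extra > 0) sizes[sample.int(n_batches, extra)] <- base + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (b in seq_len(n_batches)) {
      if (sizes[b] > 0)
        batches[[b]] <- c(batches[[b]], idx[starts[b]:ends[b]])
    }
  }
  lapply(batches, function(b) b[sample.int(length(b))])
}

#' Train the CNN on one fold
#'
#' Stochastic gradient descent with momentum on the class-weighted
#' softmax cross-entropy (batch loss normalized by the summed weights,
#' which keeps the effective learning rate stable under reweighting).
#' Training patches are augmented sixfold unless disabled; validation
#' patches never are. Validation ACA and MCA are recorded every epoch and
#' the running best checkpoint of each criterion is kept (ties keep the
#' earlier epoch).
#'
#' @param train_x,train_y Training patches (H x W x N array) and labels.
#' @param val_x,val_y Validation patches and labels.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @return A list of class \code{fold_result}: \code{history} (per-epoch
#'   train loss, validation ACA/MCA), \code{best_mca_model},
#'   \code{best_aca_model}, the best values/epochs, and \code{final}
#'   (last-epoch model).
#' @export
train_fold <- function(train_x, train_y, val_x, val_y, spec,
                       config = train_config()) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(config, "train_config"))
  train_y <- as.integer(train_y)
  val_y <- as.integer(val_y)
  if (config$augment) {
    aug <- augment_dataset(train_x, train_y, fixed_labels = config$fixed_labels)
    train_x <- aug$x
    train_y <- aug$labels
  }
  counts <- tabulate(train_y + 1L, nbins = spec$n_classes)
  cw <- class_weights(counts, spec$n_classes)
  model <- build_model(spec, seed = config$seed)
  schedule <- lapply(seq_len(config$epochs), function(e)
    make_batches(train_y, config$batch_size, seed = config$seed + 7919L * e))
  res <- nn_train_cpp(model$layers, train_x, train_y, val_x, val_y,
                      schedule, config$learning_rate, config$momentum,
                      cw, config$dropout_rate,
                      as.integer(config$seed %% .Machine$integer.max))
  wrap_model <- function(layers) {
    m <- model
    m$layers <- layers
    m
  }
  if (any(!is.finite(res$train_loss)))
    stop("training diverged: non-finite loss")
  structure(list(
    history = data.frame(epoch = seq_len(config$epochs),
                         train_loss = res$train_loss,
                         val_aca = res$val_aca, val_mca = res$val_mca),
    best_mca_model = wrap_model(res$best_mca_model),
    best_aca_model = wrap_model(res$best_aca_model),
    final = wrap_model(res$final),
    best_val_mca = res$best_val_mca, best_val_aca = res$best_val_aca,
    best_mca_epoch = res$best_mca_epoch, best_aca_epoch = res$best_aca_epoch,
    class_weights = cw), class = "fold_result")
}

#' Stratified fold assignment
#'
#' Deals each class's shuffled indices round-robin over the folds, so
#' every sample lands in exactly one validation fold and class
#' proportions stay balanced.
#'
#' @param labels Integer class labels.
#' @param folds Number of folds.
#' @param seed RNG seed.
#' @return Integer fold assignment (1..folds) per sample.
#' @export
fold_assignment <- function(labels, folds = 4, seed = 1) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (k in unique(labels)) {
    idx <- which(labels == k)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated training with best-model selection
#'
#' Splits the train+validation pool into stratified folds, trains one
#' model per fold with [train_fold()], and returns the checkpoint with
#' the highest validation score across folds (MCA by default; ties go to
#' the lower fold index, and within a fold to the earlier epoch).
#'
#' @param x,labels The train+validation patch pool.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param select_by Selection criterion, \code{"mca"} or \code{"aca"}.
#' @param verbose Print per-fold progress.
#' @return A list of class \code{cv_result}: the selected \code{model},
#'   \code{fold_results}, \code{selection} (per-fold best scores),
#'   \code{fold_assign}, and \code{selected_fold}.
#' @export
cross_validate <- function(x, labels, spec, config = train_config(),
                           select_by = c("mca", "aca"), verbose = FALSE) {
  select_by <- match.arg(select_by)
  labels <- as.integer(labels)
  assign <- fold_assignment(labels, config$folds, seed = config$seed)
  results <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr <- assign != f
    fold_cfg <- config
    fold_cfg$seed <- config$seed + f
    results[[f]] <- train_fold(x[, , tr, drop = FALSE], labels[tr],
                               x[, , !tr, drop = FALSE], labels[!tr],
                               spec, fold_cfg)
    if (verbose)
      message(sprintf("fold %d/%d: best val MCA %.2f%% (epoch %d), best val ACA %.2f%% (epoch %d)",
                      f, config$folds, results[[f]]$best_val_mca,
                      results[[f]]$best_mca_epoch, results[[f]]$best_val_aca,
                      results[[f]]$best_aca_epoch))
  }
  score <- vapply(results, function(r)
    if (select_by == "mca") r$best_val_mca else r$best_val_aca, numeric(1))
  best_fold <- which.max(score)  # first max: lowest fold index on ties
  model <- if (select_by == "mca") results[[best_fold]]$best_mca_model
           else results[[best_fold]]$best_aca_model
  structure(list(model = model, fold_results = results,
                 selection = data.frame(fold = seq_len(config$folds),
                                        best_val_mca = vapply(results, `[[`,
                                          numeric(1), "best_val_mca"),
                                        best_val_aca = vapply(results, `[[`,
                                          numeric(1), "best_val_aca")),
                 fold_assign = assign, selected_fold = best_fold,
                 select_by = select_by), class = "cv_result")
}

#' Confusion matrix and accuracy metrics
#'
#' ACA (average classification accuracy) is the overall fraction of
#' correct predictions; CCR_k the per-class correct rate; MCA (mean class
#' accuracy) the unweighted mean of the CCR_k, which unlike ACA is
#' insensitive to class imbalance. All accuracies are in percent.
#'
#' @param model A model.
#' @param x Test patches (H x W x N array).
#' @param labels True labels.
#' @return A list of class \code{eval_result}: \code{confusion} (rows =
#'   true, columns = predicted), \code{aca}, \code{mca}, \code{ccr}, and
#'   \code{n}.
#' @export
evaluate_model <- function(model, x, labels) {
  if (length(labels) == 0L) stop("empty test set")
  pred <- predict(model, x, type = "label")
  conf <- confusion_matrix(as.integer(labels), pred, model$n_classes)
  m <- metrics_from_confusion(conf)
  m$n <- length(labels)
  m
}

#' @rdname evaluate_model
#' @param true,pred Integer label vectors.
#' @param n_classes Number of classes.
#' @export
confusion_matrix <- function(true, pred, n_classes = 4) {
  lv <- 0:(n_classes - 1)
  conf <- table(factor(true, levels = lv), factor(pred, levels = lv))
  dimnames(conf) <- list(true = direction_name(lv), predicted = direction_name(lv))
  unclass(conf)
}

#' @rdname evaluate_model
#' @param confusion A square count matrix, rows = true classes.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  rs <- rowSums(confusion)
  ccr <- ifelse(rs > 0, 100 * diag(confusion) / rs, NA_real_)
  if (anyNA(ccr))
    warning("class(es) without test samples excluded from MCA")
  structure(list(confusion = confusion, aca = 100 * sum(diag(confusion)) / total,
                 mca = mean(ccr, na.rm = TRUE), ccr = ccr),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("ACA %.2f%%  MCA %.2f%%\n", x$aca, x$mca))
  print(x$confusion)
  invisible(x)
}
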