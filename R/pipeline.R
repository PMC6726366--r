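#' Run the full direction-prediction pipeline on synthetic data
#'
#' Generates a synthetic movie, annotates moving directions on the
#' evaluation grid, extracts normalized patches at a subset of anchors,
#' splits them into a train+validation pool and a held-out test set,
#' trains the CNN in stratified cross-validation, and evaluates the
#' selected model on the test set.
#'
#' \code{anchors_per_cell} limits how many annotated anchor frames per
#' cell become patches (evenly spaced along the track; \code{Inf} keeps
#' all). One anchor per cell keeps the patch count of a 200-cell movie
#' comparable to a typical manually tracked dataset and the samples
#' independent across cells.
#'
#' @param sim A [sim_config()].
#' @param train A [train_config()].
#' @param patch_px Patch side fed to the CNN (the model input size).
#' @param crop_px Crop window side in movie pixels before resizing.
#' @param anchors_per_cell Annotated anchors kept per cell.
#' @param diameter_um Annotation net-displacement threshold.
#' @param eval_interval_min Evaluation grid spacing in minutes.
#' @param fractions Train/validation/test fractions.
#' @param select_by Cross-validation selection criterion.
#' @param verbose Print progress.
#' @return A list of class \code{pipeline_result} with the dataset
#'   pieces, the \code{cv} result, the selected \code{model}, and the
#'   held-out \code{test} metrics.
#' @export
run_pipeline <- function(sim = sim_config(), train = train_config(),
                         patch_px = 64, crop_px = 128,
                         anchors_per_cell = 1, diameter_um = 18,
                         eval_interval_min = 15,
                         fractions = c(0.6, 0.2, 0.2),
                         select_by = "mca", verbose = FALSE) {
  if (verbose) message("generating synthetic movie...")
  ds <- generate_dataset(sim)
  ann <- do.call(rbind, lapply(ds$trajectories, function(tr)
    annotate_all(tr, diameter_um, eval_interval_min)))
  if (is.null(ann) || nrow(ann) == 0L) stop("no cell crossed the threshold")
  if (is.finite(anchors_per_cell)) {
    keep <- unlist(lapply(split(seq_len(nrow(ann)), ann$cell_id), function(ix) {
      ix[unique(round(seq(1, length(ix), length.out = min(anchors_per_cell,
                                                          length(ix)))))]
    }))
    ann <- ann[sort(keep), , drop = FALSE]
  }
  if (verbose) message(sprintf("extracting %d patches...", nrow(ann)))
  dset <- build_patch_dataset(ds$movie, ds$tracks, ann, crop_px, patch_px)
  sp <- split_dataset(dset$labels, fractions, seed = train$seed)
  pool <- sp$split %in% c("train", "val")
  test <- sp$split == "test"
  spec <- model_spec(input_px = patch_px, dropout = train$dropout_rate)
  if (verbose) message("cross-validated training...")
  cv <- cross_validate(dset$x[, , pool, drop = FALSE], dset$labels[pool],
                       spec, train, select_by = select_by, verbose = verbose)
  metrics <- evaluate_model(cv$model, dset$x[, , test, drop = FALSE],
                            dset$labels[test])
  structure(list(dataset = ds, annotations = ann, patches = dset,
                 split = sp, cv = cv, model = cv$model, test = metrics),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d patches (%d test)  test ACA %.2f%%  MCA %.2f%%\n",
              length(x$patches$labels), x$test$n, x$test$aca, x$test$mca))
  invisible(x)
}

#' Expected accuracy of a uniform-random predictor
#'
#' With four balanced-by-symmetry classes a predictor that guesses
#' uniformly at random has expected ACA and MCA of 25 percent. The
#' analytic value can be cross-checked by Monte Carlo.
#'
#' @param n_classes Number of classes.
#' @param n_draws Monte Carlo draws (0 for the analytic value only).
#' @param seed RNG seed for the draws.
#' @return A list with \code{aca} and \code{mca} (percent; analytic when
#'   \code{n_draws = 0}, simulated otherwise) and \code{analytic} (25).
#' @export
chance_level <- function(n_classes = 4, n_draws = 0, seed = 1) {
  analytic <- 100 / n_classes
  if (n_draws <= 0)
    return(list(aca = analytic, mca = analytic, analytic = analytic))
  set.seed(seed)
  true <- sample.int(n_classes, n_draws, replace = TRUE) - 1L
  pred <- sample.int(n_classes, n_draws, replace = TRUE) - 1L
  m <- metrics_from_confusion(confusion_matrix(true, pred, n_classes))
  list(aca = m$aca, mca = m$mca, analytic = analytic)
}

#' Draw direction-colored overlay boxes on a frame
#'
#' Utility for composing overlay movies: returns the frame as an RGB
#' array with a colored box (red/blue/green/yellow for upper right/upper
#' left/lower left/lower right) of the patch size drawn around each
#' predicted cell.
#'
#' @param frame Grayscale frame matrix in \[0, 1\].
#' @param centers_px Data frame with \code{x_px}, \code{y_px} (0-based)
#'   and \code{label}.
#' @param box_px Box side length in pixels.
#' @param lwd_px Box line width in pixels.
#' @return H x W x 3 RGB array.
#' @export
overlay_directions <- function(frame, centers_px, box_px, lwd_px = 2) {
  rgb_cols <- list(red = c(1, 0, 0), blue = c(0, 0, 1),
                   green = c(0, 1, 0), yellow = c(1, 1, 0))
  H <- nrow(frame); W <- ncol(frame)
  out <- array(rep(frame, 3), dim = c(H, W, 3))
  half <- box_px %/% 2
  for (i in seq_len(nrow(centers_px))) {
    col3 <- rgb_cols[[direction_color(centers_px$label[i])]]
    r0 <- max(1L, round(centers_px$y_px[i]) + 1L - half)
    r1 <- min(H, round(centers_px$y_px[i]) + 1L + half)
    c0 <- max(1L, round(centers_px$x_px[i]) + 1L - half)
    c1 <- min(W, round(centers_px$x_px[i]) + 1L + half)
    for (ch in 1:3) {
      out[r0:min(H, r0 + lwd_px - 1L), c0:c1, ch] <- col3[ch]
      out[max(1L, r1 - lwd_px + 1L):r1, c0:c1, ch] <- col3[ch]
      out[r0:r1, c0:min(W, c0 + lwd_px - 1L), ch] <- col3[ch]
      out[r0:r1, max(1L, c1 - lwd_px + 1L):c1, ch] <- col3[ch]
    }
  }
  out
}
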