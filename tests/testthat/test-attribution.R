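# small helper: fully connected "network" specs over a 4x4 input
fc_spec <- function(...) model_spec(input_px = 4, layers = list(...))

test_that("maximum-activation selection matches exhaustive search", {
  m <- build_model(model_spec(input_px = 64), seed = 2)
  set.seed(30)
  p <- normalize_patch(matrix(runif(64 * 64), 64))
  sel <- select_max_activations(m, p)
  acts <- layer_activations(m, p)[[11]]
  expect_equal(nrow(sel), 72L)                 # one entry per feature map
  # top-3 by ranking equals brute force over all (map, position) triples
  for (i in 1:3) {
    expect_equal(sel$activation[i],
                 sort(apply(acts, 3, max), decreasing = TRUE)[i])
    expect_equal(acts[sel$row[i], sel$col[i], sel$feature_map[i]],
                 sel$activation[i])
  }
  # determinism on a duplicated patch
  expect_identical(sel, select_max_activations(m, p))

  # all-zero patch with zero biases: all activations zero, ranking keeps
  # feature-map order and positions sit at the first row-major cell
  sel0 <- select_max_activations(m, matrix(0, 64, 64))
  expect_equal(sel0$feature_map, 1:72)
  expect_true(all(sel0$activation == 0))
  expect_true(all(sel0$row == 1L & sel0$col == 1L))
})

test_that("guided backpropagation of a linear layer returns its weights", {
  m <- build_model(fc_spec(fc_layer(3, activation = "linear")), seed = 1)
  x <- matrix(runif(16), 4)
  g <- guided_backprop(m, x, target = list(class = 1L))
  expect_equal(as.vector(g), m$layers[[1]]$W[, 2])
})

test_that("with every gate open, guided backprop equals the plain gradient", {
  # positive weights + positive input: all forward activations and all
  # intermediate backward signals are positive, so the GBP gates never
  # close and the map must equal the chain-rule gradient W1 %*% W2
  set.seed(31)
  m <- build_model(fc_spec(fc_layer(5, activation = "relu"),
                           fc_layer(2, activation = "linear")), seed = 3)
  m$layers[[1]]$W <- abs(m$layers[[1]]$W)
  m$layers[[2]]$W <- abs(m$layers[[2]]$W)
  x <- matrix(runif(16, 0.1, 1), 4)
  g <- guided_backprop(m, x, target = list(class = 0L))
  analytic <- m$layers[[1]]$W %*% m$layers[[2]]$W[, 1]
  expect_lt(max(abs(as.vector(g) - analytic)), 1e-6)
  # and the ungated mode agrees as well
  g2 <- guided_backprop(m, x, target = list(class = 0L), guided = FALSE)
  expect_lt(max(abs(as.vector(g2) - analytic)), 1e-12)
})

test_that("the double gate matches a pencil-and-paper two-layer example", {
  # 2x2 input x = (1, 2, 0.5, 1) (column-major); hidden h = relu(W1' x):
  #   W1[,1] = ( 1, 0.5, 0.2,  0.3) -> pre-h1 = 1 + 1 + 0.1 + 0.3 = 2.4 > 0
  #   W1[,2] = (-1, 1.0, 0.4, -0.2) -> pre-h2 = -1 + 2 + 0.2 - 0.2 = 1 > 0
  # output y = h1 - h2, so the backward signal into h is (1, -1); the GBP
  # gate zeroes the negative component and only h1 propagates:
  #   guided map  = W1[,1]
  #   plain grad  = W1[,1] - W1[,2]
  spec <- model_spec(input_px = 2, layers = list(
    fc_layer(2, activation = "relu"), fc_layer(1, activation = "linear")))
  m <- build_model(spec, seed = 1)
  W1 <- cbind(c(1, 0.5, 0.2, 0.3), c(-1, 1, 0.4, -0.2))
  m$layers[[1]]$W <- W1
  m$layers[[2]]$W <- matrix(c(1, -1), 2, 1)
  x <- matrix(c(1, 2, 0.5, 1), 2, 2)
  g <- guided_backprop(m, x, target = list(layer = 2L, unit = 1L))
  expect_equal(as.vector(g), W1[, 1])
  plain <- guided_backprop(m, x, target = list(layer = 2L, unit = 1L),
                           guided = FALSE)
  expect_equal(as.vector(plain), W1[, 1] - W1[, 2])
})

test_that("a non-positive target activation yields an all-zero map", {
  m <- build_model(fc_spec(fc_layer(2, activation = "relu")), seed = 2)
  m$layers[[1]]$W <- -abs(m$layers[[1]]$W)     # forces zero activations
  x <- matrix(runif(16, 0.1, 1), 4)
  g <- guided_backprop(m, x, target = list(layer = 1L, unit = 1L))
  expect_true(all(g == 0))
})

test_that("deep Taylor conserves relevance in a single positive layer", {
  m <- build_model(fc_spec(fc_layer(3, activation = "linear")), seed = 4)
  m$layers[[1]]$W <- abs(m$layers[[1]]$W)
  x <- matrix(runif(16, 0.05, 1), 4)
  d <- deep_taylor(m, x, class_index = 0L)
  Rf <- attr(d, "Rf")
  # R_p = x_p w_p / sum(x w) * R_f for the one-layer z+ case
  manual <- as.vector(x) * m$layers[[1]]$W[, 1] /
    sum(as.vector(x) * m$layers[[1]]$W[, 1]) * Rf
  expect_equal(as.vector(d), manual, tolerance = 1e-6)
  expect_lt(abs(sum(d) - Rf) / Rf, 1e-6)
})

test_that("deep Taylor maps are non-negative and conserve through the CNN", {
  m <- build_model(model_spec(input_px = 64), seed = 7)
  set.seed(33)
  n_def <- 0L
  for (i in 1:10) {
    p <- normalize_patch(matrix(runif(64 * 64), 64))
    d <- suppressWarnings(deep_taylor(m, p))
    Rf <- attr(d, "Rf")
    if (Rf <= 0) { expect_true(all(d == 0)); next }
    n_def <- n_def + 1L
    expect_true(all(d >= 0))
    expect_lt(abs(sum(d) - Rf) / Rf, 1e-3)
  }
  expect_gt(n_def, 5)
})

test_that("a non-positive output relevance warns and returns zeros", {
  m <- build_model(fc_spec(fc_layer(2, activation = "linear")), seed = 5)
  m$layers[[1]]$W <- -abs(m$layers[[1]]$W)
  x <- matrix(runif(16, 0.1, 1), 4)
  expect_warning(d <- deep_taylor(m, x, class_index = 0L), "not positive")
  expect_true(all(d == 0))
})

test_that("occlusion pinpoints the pixel a constructed model reads", {
  spec <- model_spec(input_px = 64, n_classes = 2,
                     layers = list(fc_layer(2, activation = "linear")))
  m <- build_model(spec, seed = 1)
  m$layers[[1]]$W[] <- 0
  m$layers[[1]]$W[33 + 64 * 32, 1] <- 5       # reads pixel (row 33, col 33)
  set.seed(34)
  p <- matrix(runif(64 * 64, 0, 0.2), 64)
  p[33, 33] <- 1                               # bright where the model looks
  om <- occlusion_map(m, p, class_index = 0L, mask_size = 7)
  expect_true(is.integer(om))
  expect_true(all(om >= 0 & om <= 255))
  hits <- which(om == 255L, arr.ind = TRUE)
  expect_true(all(abs(hits[, 1] - 33) <= 3 & abs(hits[, 2] - 33) <= 3))
  expect_true(all(om[which(abs(row(om) - 33) > 3 | abs(col(om) - 33) > 3)] == 0L))
})

test_that("degenerate occlusion normalization maps a flat response to zero", {
  spec <- model_spec(input_px = 64, n_classes = 2,
                     layers = list(fc_layer(2, activation = "linear")))
  m <- build_model(spec, seed = 1)
  m$layers[[1]]$W[] <- 0                       # constant predictor
  p <- matrix(runif(64 * 64), 64)
  om <- occlusion_map(m, p, class_index = 0L)
  expect_true(all(om == 0L))
  expect_error(occlusion_map(m, p, mask_size = 8), "odd")
  expect_error(occlusion_map(m, p, mask_size = 65), "smaller")
})

test_that("the composite attribution figure renders without error", {
  m <- build_model(model_spec(input_px = 64), seed = 2)
  p <- normalize_patch(matrix(runif(64 * 64), 64))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  out <- suppressWarnings(plot_attribution(m, p))
  expect_length(out$gbp, 3L)
  expect_equal(dim(out$dtd), c(64, 64))
})
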