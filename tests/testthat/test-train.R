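# a small architecture for fast training tests
tiny_spec <- function(dropout = 0) {
  model_spec(input_px = 16, dropout = dropout, layers = list(
    conv_layer(3, 6), pool_layer(), conv_layer(3, 8), pool_layer(),
    fc_layer(24, activation = "relu", dropout = dropout),
    fc_layer(4, activation = "linear")))
}

# linearly separable 16x16 patches: a bright blob in the labelled quadrant
blob_patch <- function(label) {
  p <- matrix(0, 16, 16)
  rows <- if (label %in% c(0L, 1L)) 2:7 else 10:15
  cols <- if (label %in% c(0L, 3L)) 10:15 else 2:7
  p[rows, cols] <- 1
  p + matrix(runif(256, 0, 0.1), 16)
}
blob_set <- function(n_per_class) {
  y <- rep(0:3, each = n_per_class)
  x <- array(0, dim = c(16, 16, length(y)))
  for (i in seq_along(y)) x[, , i] <- blob_patch(y[i])
  list(x = x, y = y)
}

test_that("class weights follow sum(N) / (n * N_k)", {
  expect_equal(class_weights(c(50, 50, 50, 50)), rep(1, 4))
  # training counts of the reference dataset, to 4 decimals
  expect_equal(round(class_weights(c(107, 112, 145, 105)), 4),
               c(1.0958, 1.0469, 0.8086, 1.1167))
  expect_equal(class_weights(c(10, 10, 10, 20)), c(1.25, 1.25, 1.25, 0.625))
  expect_error(class_weights(c(5, 0, 5, 5)), "positive")
})

test_that("stratified batches mirror class proportions within one sample", {
  y <- rep(0:3, each = 23)                     # 92 samples, batch 46
  b <- make_batches(y, 46, seed = 1)
  expect_length(b, 2L)
  for (batch in b) {
    tab <- table(factor(y[batch], levels = 0:3))
    expect_true(all(tab >= 11 & tab <= 12))
  }
  expect_setequal(unlist(b), seq_along(y))     # a partition

  # single-class degenerates to plain shuffled batches
  b1 <- make_batches(rep(2L, 10), 4, seed = 2)
  expect_setequal(unlist(b1), 1:10)

  # determinism and small-dataset handling
  expect_identical(make_batches(y, 46, seed = 9), make_batches(y, 46, seed = 9))
  expect_length(make_batches(y, 1000, seed = 1), 1L)
})

test_that("ACA, MCA and CCR follow their formulas", {
  ident <- diag(c(10, 20, 30, 40))
  m <- metrics_from_confusion(ident)
  expect_equal(m$aca, 100)
  expect_equal(m$mca, 100)

  conf <- diag(c(30, 5, 5, 5))
  conf[2, 1] <- 5; conf[3, 1] <- 5; conf[4, 1] <- 5
  m2 <- metrics_from_confusion(conf)
  expect_equal(m2$aca, 75)                     # 45 of 60 correct
  expect_equal(m2$mca, 62.5)                   # (100+50+50+50)/4
  expect_equal(unname(m2$ccr), c(100, 50, 50, 50))

  # MCA ignores imbalance when per-class rates are fixed; ACA does not
  conf3 <- conf
  conf3[1, ] <- conf3[1, ] * 5
  m3 <- metrics_from_confusion(conf3)
  expect_equal(m3$mca, m2$mca)
  expect_gt(m3$aca, m2$aca)
})

test_that("a uniform-random predictor sits at 25 percent", {
  ch <- chance_level(n_draws = 1e5, seed = 1)
  expect_equal(ch$analytic, 25)
  expect_lt(abs(ch$aca - 25), 0.5)
  expect_lt(abs(ch$mca - 25), 0.5)
})

test_that("zero learning rate leaves the initial model untouched", {
  set.seed(20)
  d <- blob_set(6)
  cfg <- train_config(learning_rate = 0, epochs = 3, batch_size = 8,
                      augment = FALSE, dropout_rate = 0, seed = 2)
  fr <- train_fold(d$x, d$y, d$x, d$y, tiny_spec(), cfg)
  init <- build_model(tiny_spec(), seed = cfg$seed)
  base <- evaluate_model(init, d$x, d$y)
  expect_equal(fr$history$val_aca, rep(base$aca, 3))
  expect_equal(fr$history$val_mca, rep(base$mca, 3))
  expect_equal(fr$final$layers[[1]]$W, init$layers[[1]]$W, tolerance = 1e-6)
})

test_that("the network overfits a small separable set to 100 percent", {
  set.seed(21)
  d <- blob_set(10)                            # 40 patches
  cfg <- train_config(learning_rate = 0.021, epochs = 50, batch_size = 46,
                      augment = FALSE, dropout_rate = 0, seed = 3)
  fr <- train_fold(d$x, d$y, d$x, d$y, tiny_spec(), cfg)
  final_train <- evaluate_model(fr$best_aca_model, d$x, d$y)
  expect_equal(final_train$aca, 100)
  # the metric trajectory is reproducible under the same seed
  fr2 <- train_fold(d$x, d$y, d$x, d$y, tiny_spec(), cfg)
  expect_equal(fr$history, fr2$history)
})

test_that("weighted loss under balanced data equals the unweighted loss", {
  set.seed(22)
  d <- blob_set(3)
  m <- build_model(tiny_spec(), seed = 1)
  g1 <- model_loss_grad(m, d$x, d$y, rep(1, 4))
  g2 <- model_loss_grad(m, d$x, d$y, class_weights(c(20, 20, 20, 20)))
  expect_equal(g1$loss, g2$loss)
  expect_equal(g1$grads[[1]]$dW, g2$grads[[1]]$dW)
  # uniform scaling of the weights changes nothing (normalized batch loss)
  g3 <- model_loss_grad(m, d$x, d$y, rep(2.5, 4))
  expect_equal(g1$loss, g3$loss, tolerance = 1e-12)
})

test_that("cross-validation partitions samples and selects by validation MCA", {
  set.seed(23)
  d <- blob_set(12)                            # 48 patches
  cfg <- train_config(epochs = 4, folds = 4, batch_size = 12,
                      augment = FALSE, dropout_rate = 0, seed = 5)
  cv <- cross_validate(d$x, d$y, tiny_spec(), cfg)
  expect_equal(sort(unique(cv$fold_assign)), 1:4)
  expect_equal(as.vector(table(cv$fold_assign)), rep(12, 4))
  best <- cv$selection$best_val_mca[cv$selected_fold]
  expect_equal(best, max(cv$selection$best_val_mca))
  # the selected checkpoint scores what the selection table claims
  val_idx <- cv$fold_assign == cv$selected_fold
  got <- evaluate_model(cv$model, d$x[, , val_idx, drop = FALSE],
                        d$y[val_idx])
  expect_equal(got$mca, best)
})

test_that("augmented training uses six variants of every patch", {
  set.seed(24)
  d <- blob_set(3)
  cfg <- train_config(epochs = 1, batch_size = 46, augment = TRUE,
                      dropout_rate = 0, seed = 6)
  fr <- train_fold(d$x, d$y, d$x, d$y, tiny_spec(), cfg)
  # balanced blob set stays balanced under label-transforming augmentation,
  # so all class weights are 1
  expect_equal(fr$class_weights, rep(1, 4))
})
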