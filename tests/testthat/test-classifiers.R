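# a shared tiny UNet topology keeps these tests fast
tiny_unet <- function(p) {
  build_unet(p, unet_config(dense_units = 64L, reshape = c(4L, 4L, 4L),
                            filters = 4L, kernel = 2L,
                            head_units = c(16L, 32L, 16L)))
}

test_that("the default UNet spec reproduces the published constants", {
  spec <- build_unet(100)
  expect_equal(spec$config$dense_units, 16384L)
  expect_equal(spec$config$reshape, c(32L, 32L, 16L))
  expect_equal(spec$config$filters, 12L)
  expect_equal(spec$config$kernel, 4L)
  expect_equal(spec$config$head_units, c(512L, 1024L, 512L))
  expect_equal(spec$config$num_labels, 1L)

  sh <- spec$shapes
  dim_of <- function(stage) sh$dims[sh$stage == stage]
  expect_identical(dim_of("dense"), "16384")
  expect_identical(dim_of("reshape"), "32x32x16")
  expect_identical(dim_of("conv_1"), "32x32x12")
  expect_identical(dim_of("maxpool_skip"), "31x31x12")
  expect_identical(dim_of("multiply_skip"), "31x31x12")
  expect_identical(dim_of("maxpool_2"), "30x30x12")
  expect_identical(dim_of("decoder_2"), "120x120x12")
  expect_equal(sh$size[sh$stage == "flatten"], 172800)
  expect_identical(utils::tail(sh$stage, 1), "output_sigmoid")
})

test_that("inconsistent reshape overrides are rejected", {
  expect_error(unet_config(dense_units = 100L, reshape = c(5L, 5L, 3L)),
               "multiply")
})

test_that("UNet forward emits one probability per row end to end", {
  set.seed(300)
  spec <- tiny_unet(100)
  nets <- methylkmer:::unet_instantiate(spec)
  x <- matrix(stats::rnorm(7 * 100), 7, 100)
  fw <- methylkmer:::unet_forward(nets, x, training = FALSE)
  probs <- stats::plogis(as.numeric(fw$out))
  expect_length(probs, 7L)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("baseline specs encode their contracts", {
  expect_warning(bk <- build_baseline("ffnn_knn", 20,
                                      list(k_neighbors = 4L)), "odd")
  expect_equal(bk$config$k_neighbors, 3L)
  # Euclidean distance in the KNN space: d((0,0),(3,4)) = 5
  expect_equal(sqrt(sum((c(0, 0) - c(3, 4))^2)), 5)
  cn <- build_baseline("cnn", 100)
  expect_equal(cn$config$side, 10L)
  rs <- build_baseline("resnet", 30)
  expect_equal(rs$config$blocks, 2L)
})

test_that("KNN with K = 1 returns the label of the query itself", {
  set.seed(301)
  sep <- generate_separable(60, 8, seed = 3)
  m <- train_model(build_baseline("ffnn_knn", 8, list(k_neighbors = 1L)),
                   sep$X, sep$labels, epochs = 5, seed = 2)
  xtr <- sep$X[m$train_idx, ]
  preds <- classify(predict(m, xtr))
  expect_identical(preds, sep$labels[m$train_idx])
})

test_that("the KNN stage is live: it differs from the FFNN head alone", {
  # two interleaved clusters the 5-epoch FFNN cannot carve but local
  # neighbourhoods can
  set.seed(302)
  n <- 120
  ang <- stats::runif(n, 0, 2 * pi)
  labels <- rep(0:1, each = n / 2)
  r <- ifelse(labels == 1, 1, 2) + stats::rnorm(n, sd = 0.05)
  x <- cbind(r * cos(ang), r * sin(ang),
             matrix(stats::rnorm(n * 2, sd = 0.1), n, 2))
  colnames(x) <- paste0("f", 1:4)
  m <- train_model(build_baseline("ffnn_knn", 4), x, labels,
                   epochs = 3, seed = 5)
  p_knn <- classify(predict(m, x))
  p_ffnn <- classify(predict(m, x, stage = "ffnn"))
  expect_gt(sum(p_knn != p_ffnn), 0)
})

test_that("training honors the split arithmetic and the 70:30 default", {
  set.seed(303)
  sep <- generate_separable(1000, 10, seed = 6)
  m <- train_model(build_baseline("resnet", 10), sep$X, sep$labels,
                   epochs = 2, seed = 1)
  expect_length(m$train_idx, 700L)
  expect_length(m$test_idx, 300L)
  expect_length(intersect(m$train_idx, m$test_idx), 0L)
  # stratified: class balance preserved in both halves
  expect_equal(mean(sep$labels[m$train_idx]), mean(sep$labels),
               tolerance = 0.01)
  expect_equal(nrow(m$history), 2L)
})

test_that("separable data is learned to high training accuracy", {
  sep <- generate_separable(300, 20, seed = 5)
  m_unet <- train_model(tiny_unet(20), sep$X, sep$labels, epochs = 30,
                        learning_rate = 1e-2, seed = 7)
  expect_gte(utils::tail(m_unet$history$accuracy, 1), 0.95)
  m_cnn <- train_model(build_baseline("cnn", 20), sep$X, sep$labels,
                       epochs = 30, learning_rate = 1e-2, seed = 7)
  expect_gte(utils::tail(m_cnn$history$accuracy, 1), 0.95)
})

test_that("training is bit-reproducible under a fixed seed", {
  sep <- generate_separable(120, 10, seed = 8)
  a <- train_model(build_baseline("resnet", 10), sep$X, sep$labels,
                   epochs = 3, seed = 11)
  b <- train_model(build_baseline("resnet", 10), sep$X, sep$labels,
                   epochs = 3, seed = 11)
  expect_identical(a$history, b$history)
  expect_identical(a$train_idx, b$train_idx)
  expect_identical(predict(a, sep$X), predict(b, sep$X))
})

test_that("label-shuffled training stays at chance on held-out rows", {
  set.seed(304)
  for (seed in 1:3) {
    sep <- generate_separable(400, 12, seed = seed)
    y_shuf <- sample(sep$labels)
    m <- train_model(build_baseline("resnet", 12), sep$X, y_shuf,
                     epochs = 8, seed = seed)
    expect_gte(utils::tail(m$history$val_accuracy, 1), 0.5 - 0.07)
    expect_lte(utils::tail(m$history$val_accuracy, 1), 0.5 + 0.07)
  }
})

test_that("probabilities live in [0,1]; classify is inclusive and monotone", {
  set.seed(305)
  sep <- generate_separable(80, 6, seed = 9)
  m <- train_model(build_baseline("resnet", 6), sep$X, sep$labels,
                   epochs = 3, seed = 2)
  probs <- predict(m, matrix(stats::rnorm(60), 10, 6,
                             dimnames = list(NULL, colnames(sep$X))))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_identical(classify(0.5), 1L)
  expect_identical(classify(c(0.2, 0.5, 0.8)), c(0L, 1L, 1L))
  p <- sort(stats::runif(10))
  expect_true(all(diff(classify(p)) >= 0))
  expect_error(predict(m, matrix(0, 2, 3)), "width")
})

test_that("model summaries tidy and plot", {
  sep <- generate_separable(80, 6, seed = 10)
  m <- train_model(build_baseline("resnet", 6), sep$X, sep$labels,
                   epochs = 3, seed = 2)
  expect_identical(tidy(m), m$history)
  g <- glance(m)
  expect_equal(g$epochs, 3L)
  expect_equal(g$kind, "resnet")
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("training aborts cleanly on both-class and width violations", {
  sep <- generate_separable(40, 5, seed = 11)
  expect_error(train_model(build_baseline("resnet", 5), sep$X,
                           rep(1L, 40)), "both classes")
  expect_error(train_model(build_baseline("resnet", 8), sep$X, sep$labels),
               "width")
  expect_error(train_model(build_baseline("resnet", 5), sep$X, sep$labels,
                           split_fraction = 1.2), "split_fraction")
})
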