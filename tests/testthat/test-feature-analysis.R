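test_that("autoencoder honors shape, determinism and the latent-width rule", {
  set.seed(200)
  x <- matrix(stats::rnorm(200 * 10), 200, 10)
  fit <- autoencoder_fit_transform(x, latent_dim = 3, epochs = 5, seed = 9)
  expect_equal(dim(fit$Z), c(200L, 3L))
  fit2 <- autoencoder_fit_transform(x, latent_dim = 3, epochs = 5, seed = 9)
  expect_identical(fit$Z, fit2$Z)
  expect_error(autoencoder_fit_transform(x, latent_dim = 10), "smaller")
  expect_error(autoencoder_fit_transform(x, latent_dim = 12), "smaller")
})

test_that("constant data is reconstructed to numerical zero loss", {
  x <- matrix(rep(stats::rnorm(8), each = 40), 40, 8)
  fit <- autoencoder_fit_transform(x, latent_dim = 2, epochs = 60, seed = 1)
  expect_lt(utils::tail(fit$state$loss_trace, 1), 1e-3)
})

test_that("autoencoder training reduces reconstruction loss across seeds", {
  set.seed(201)
  x <- matrix(stats::rnorm(120 * 8), 120, 8) %*%
    matrix(stats::rnorm(64), 8, 8)   # correlated, hence compressible
  for (seed in 1:20) {
    fit <- autoencoder_fit_transform(x, latent_dim = 4, epochs = 15,
                                     seed = seed)
    tr <- fit$state$loss_trace
    expect_lte(utils::tail(tr, 1), tr[1])
  }
})

test_that("autoencoder loss trace is non-increasing in moving average", {
  set.seed(202)
  x <- matrix(stats::rnorm(150 * 10), 150, 10)
  fit <- autoencoder_fit_transform(x, latent_dim = 4, epochs = 30, seed = 2)
  ma <- stats::filter(fit$state$loss_trace, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  # trailing-window moving average never rises appreciably
  expect_true(all(diff(ma) < 1e-3))
})

test_that("GAN augmentation preserves originals and honors row contracts", {
  set.seed(210)
  x <- matrix(stats::rpois(100 * 6, 4), 100, 6,
              dimnames = list(NULL, paste0("m", 1:6)))
  labels <- rep(0:1, each = 50)

  none <- gan_augment(x, labels, n_synth_per_class = 0, epochs = 5, seed = 1)
  expect_identical(none$X_aug, x + 0)       # identity when nothing synthesized
  expect_false(any(none$synthetic))

  aug <- gan_augment(x, labels, n_synth_per_class = 50, epochs = 10, seed = 1)
  expect_equal(nrow(aug$X_aug), 200L)
  expect_equal(sum(aug$synthetic), 100L)
  # original rows byte-identical and first
  expect_identical(aug$X_aug[1:100, ], x + 0)
  expect_identical(aug$labels_aug[1:100], as.integer(labels))
  # synthetic rows respect the per-class empirical support
  for (cl in 0:1) {
    xc <- x[labels == cl, ]
    syn <- aug$X_aug[aug$synthetic & aug$labels_aug == cl, , drop = FALSE]
    expect_true(all(sweep(syn, 2, apply(xc, 2, max), "<=")))
    expect_true(all(sweep(syn, 2, apply(xc, 2, min), ">=")))
  }
})

test_that("constant-feature training data forces constant synthetic rows", {
  x <- matrix(5, 30, 4, dimnames = list(NULL, paste0("m", 1:4)))
  labels <- rep(1L, 30)
  aug <- gan_augment(x, labels, n_synth_per_class = 10, epochs = 5, seed = 2)
  expect_true(all(aug$X_aug[aug$synthetic, ] == 5))
})

test_that("a class below 10 rows is refused with a warning", {
  set.seed(211)
  x <- matrix(stats::rnorm(15 * 4), 15, 4)
  labels <- c(rep(0L, 12), rep(1L, 3))
  expect_warning(aug <- gan_augment(x, labels, n_synth_per_class = 5,
                                    epochs = 5, seed = 3), "fewer than 10")
  expect_equal(sum(aug$synthetic & aug$labels_aug == 1), 0L)
  expect_equal(sum(aug$synthetic & aug$labels_aug == 0), 5L)
})

test_that("attention transform preserves width and scales columns by mass", {
  set.seed(220)
  x <- matrix(stats::rnorm(80 * 12), 80, 12,
              dimnames = list(NULL, paste0("m", 1:12)))
  labels <- rep(0:1, 40)
  fit <- mhan_transform(x, labels, heads = 2, d_model = 8, epochs = 3,
                        seed = 4)
  expect_equal(dim(fit$X_weighted), dim(x))
  expect_equal(fit$X_weighted,
               sweep(x, 2, unname(fit$state$weights), "*"))
  # zero attention mass means a zeroed output column
  st0 <- fit$state
  st0$weights[3] <- 0
  out <- mhan_apply(st0, x)
  expect_true(all(out[, 3] == 0))
  expect_identical(out[, -3], fit$X_weighted[, -3])
  # weights are nonnegative and average to 1 (mass sums to 1 over tokens)
  expect_true(all(fit$state$weights >= 0))
  expect_equal(mean(fit$state$weights), 1, tolerance = 1e-9)
})

test_that("attention is deterministic under a fixed seed and checks d_model", {
  set.seed(221)
  x <- matrix(stats::rnorm(40 * 6), 40, 6)
  labels <- rep(0:1, 20)
  a <- mhan_transform(x, labels, heads = 2, d_model = 8, epochs = 2, seed = 5)
  b <- mhan_transform(x, labels, heads = 2, d_model = 8, epochs = 2, seed = 5)
  expect_identical(a$X_weighted, b$X_weighted)
  expect_error(mhan_transform(x, labels, heads = 3, d_model = 8),
               "divisible")
})

test_that("a single token receives all attention and dk = 1 is unscaled", {
  set.seed(222)
  # p = 1: softmax over one key is exactly 1, output equals that token's V
  P <- methylkmer:::positional_encoding(1, 4)
  par <- methylkmer:::mhan_init(1, 4, 2)
  xs <- matrix(stats::rnorm(3), 3, 1)
  fw <- methylkmer:::mhan_forward(par, xs, P, 2, 2)
  expect_equal(as.numeric(fw$A[[1]]), rep(1, 3))
  Tmat <- fw$Tmat
  V1 <- Tmat %*% par$Wv[[1]]
  expect_equal(matrix(fw$U[, , 1:2], 3, 2), V1, ignore_attr = TRUE)
  # dk = 1: scores are raw dot products (scale factor sqrt(1) = 1)
  expect_equal(sqrt(1), 1)
})
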