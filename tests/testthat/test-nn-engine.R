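# Central finite differences validate every layer's analytic gradient.

fd_check <- function(net, x, y, part_idx, param, idx, analytic,
                     eps = 1e-6, tol = 1e-5) {
  loss_at <- function(net) {
    fw <- methylkmer:::nn_forward(net, x, TRUE)
    methylkmer:::bce_loss(fw$out, y)$loss
  }
  np <- net; nq <- net
  np[[part_idx]][[param]][idx] <- np[[part_idx]][[param]][idx] + eps
  nq[[part_idx]][[param]][idx] <- nq[[part_idx]][[param]][idx] - eps
  num <- (loss_at(np) - loss_at(nq)) / (2 * eps)
  expect_equal(analytic, num, tolerance = tol)
}

test_that("dense, weight-norm, batch-norm and activation gradients are exact", {
  set.seed(101)
  net <- list(methylkmer:::nn_dense(5, 4, weight_norm = TRUE),
              methylkmer:::nn_batchnorm(4),
              methylkmer:::nn_activation("swish"),
              methylkmer:::nn_dense(4, 3),
              methylkmer:::nn_activation("tanh"),
              methylkmer:::nn_dense(3, 1))
  x <- matrix(stats::rnorm(40), 8, 5)
  y <- rep(0:1, 4)
  fw <- methylkmer:::nn_forward(net, x, TRUE)
  ls <- methylkmer:::bce_loss(fw$out, y)
  bw <- methylkmer:::nn_backward(fw$net, fw$caches, ls$dlogits)
  for (case in list(list(1, "v", 3), list(1, "g", 2), list(1, "b", 1),
                    list(2, "gamma", 4), list(2, "beta", 1),
                    list(4, "W", 5), list(6, "W", 2))) {
    fd_check(net, x, y, case[[1]], case[[2]], case[[3]],
             bw$grads[[case[[1]]]][[case[[2]]]][case[[3]]])
  }
})

test_that("conv, maxpool, upsample and residual gradients are exact", {
  set.seed(102)
  x4 <- array(stats::rnorm(4 * 5 * 5 * 2), c(4, 5, 5, 2))
  y <- c(1, 0, 1, 0)
  net <- list(methylkmer:::nn_conv2d(2, 3, 2, padding = "same",
                                     weight_norm = TRUE),
              methylkmer:::nn_activation("swish"),
              methylkmer:::nn_maxpool(2, 1),
              methylkmer:::nn_upsample(2),
              methylkmer:::nn_conv2d(3, 2, 3, padding = "valid"),
              methylkmer:::nn_activation("relu"),
              methylkmer:::nn_flatten(),
              methylkmer:::nn_dense(2 * 6 * 6, 1))
  fw <- methylkmer:::nn_forward(net, x4, TRUE)
  ls <- methylkmer:::bce_loss(fw$out, y)
  bw <- methylkmer:::nn_backward(fw$net, fw$caches, ls$dlogits)
  for (case in list(list(1, "v", 7), list(1, "g", 3), list(5, "W", 11),
                    list(5, "b", 2), list(8, "W", 30))) {
    local({
      loss_at <- function(net) {
        f <- methylkmer:::nn_forward(net, x4, TRUE)
        methylkmer:::bce_loss(f$out, y)$loss
      }
      np <- net; nq <- net
      i <- case[[1]]; nm <- case[[2]]; id <- case[[3]]
      eps <- 1e-6
      np[[i]][[nm]][id] <- np[[i]][[nm]][id] + eps
      nq[[i]][[nm]][id] <- nq[[i]][[nm]][id] - eps
      num <- (loss_at(np) - loss_at(nq)) / (2 * eps)
      expect_equal(bw$grads[[i]][[nm]][id], num, tolerance = 1e-5)
    })
  }

  # residual block: out = x + F(x); zero inner weights give the identity
  p <- 6
  res <- methylkmer:::nn_residual(list(methylkmer:::nn_dense(p, p),
                                       methylkmer:::nn_activation("relu"),
                                       methylkmer:::nn_dense(p, p)))
  res$inner[[1]]$W[] <- 0; res$inner[[1]]$b[] <- 0
  res$inner[[3]]$W[] <- 0; res$inner[[3]]$b[] <- 0
  xr <- matrix(stats::rnorm(18), 3, p)
  fw_r <- methylkmer:::nn_layer_forward(res, xr, TRUE)
  expect_equal(fw_r$out, xr)
})

test_that("UNet skip-multiply graph backpropagates exactly", {
  set.seed(103)
  spec <- build_unet(10, unet_config(dense_units = 32L,
                                     reshape = c(4L, 4L, 2L), filters = 3L,
                                     kernel = 2L, head_units = c(8L, 6L, 4L)))
  nets <- methylkmer:::unet_instantiate(spec)
  x <- matrix(stats::rnorm(50), 5, 10)
  y <- c(1, 0, 1, 0, 1)
  loss_at <- function(nets) {
    f <- methylkmer:::unet_forward(nets, x, TRUE)
    methylkmer:::bce_loss(f$out, y)$loss
  }
  fw <- methylkmer:::unet_forward(nets, x, TRUE)
  ls <- methylkmer:::bce_loss(fw$out, y)
  bw <- methylkmer:::unet_backward(fw$nets, fw$caches, ls$dlogits)
  eps <- 1e-6
  for (case in list(list("pre", 2, "v", 5), list("pre", 4, "gamma", 1),
                    list("mid", 2, "v", 3), list("mid", 5, "g", 2),
                    list("dec", 2, "v", 4), list("head", 4, "W", 7))) {
    part <- case[[1]]; i <- case[[2]]; nm <- case[[3]]; id <- case[[4]]
    np <- nets; nq <- nets
    np[[part]][[i]][[nm]][id] <- np[[part]][[i]][[nm]][id] + eps
    nq[[part]][[i]][[nm]][id] <- nq[[part]][[i]][[nm]][id] - eps
    num <- (loss_at(np) - loss_at(nq)) / (2 * eps)
    expect_equal(bw$grads[[part]][[i]][[nm]][id], num, tolerance = 1e-5)
  }
})

test_that("multi-head attention gradients are exact and rows sum to one", {
  set.seed(104)
  p <- 6; d <- 8; heads <- 2; dk <- 4
  xs <- matrix(stats::rnorm(5 * p), 5, p)
  y <- c(1, 0, 1, 0, 1)
  P <- methylkmer:::positional_encoding(p, d)
  par <- methylkmer:::mhan_init(p, d, heads)
  fw <- methylkmer:::mhan_forward(par, xs, P, heads, dk)
  ls <- methylkmer:::bce_loss(fw$logits, y)
  gr <- methylkmer:::mhan_backward(par, fw, xs, ls$dlogits, heads, dk)
  loss_at <- function(par) {
    f <- methylkmer:::mhan_forward(par, xs, P, heads, dk)
    methylkmer:::bce_loss(f$logits, y)$loss
  }
  eps <- 1e-6
  for (case in list(list("E", 3, NULL), list("Wq", 5, 1), list("Wk", 9, 2),
                    list("Wv", 2, 1), list("Wo", 11, NULL),
                    list("wh", 3, NULL), list("bh", 1, NULL))) {
    nm <- case[[1]]; id <- case[[2]]; h <- case[[3]]
    np <- par; nq <- par
    if (is.null(h)) {
      np[[nm]][id] <- np[[nm]][id] + eps
      nq[[nm]][id] <- nq[[nm]][id] - eps
      an <- gr[[nm]][id]
    } else {
      np[[nm]][[h]][id] <- np[[nm]][[h]][id] + eps
      nq[[nm]][[h]][id] <- nq[[nm]][[h]][id] - eps
      an <- gr[[nm]][[h]][id]
    }
    num <- (loss_at(np) - loss_at(nq)) / (2 * eps)
    expect_equal(an, num, tolerance = 1e-5)
  }
  for (h in seq_len(heads)) {
    expect_equal(apply(fw$A[[h]], c(1, 2), sum),
                 matrix(1, 5, p), tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("the BCE loss is stable at extreme logits", {
  ls <- methylkmer:::bce_loss(matrix(c(500, -500), 2, 1), c(1, 0))
  expect_true(is.finite(ls$loss))
  expect_equal(ls$loss, 0, tolerance = 1e-12)
})
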