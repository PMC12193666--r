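# ---------------------------------------------------------------------------
# Minimal reverse-mode neural-network engine.
#
# The learned components of this package (autoencoder, GAN, multi-head
# attention, UNet and the baseline classifiers) are trained on small tabular
# problems, so the engine favours clarity and testability over raw speed:
# layers are plain lists, forward passes return explicit caches, and
# backward passes are pure functions from (layer, cache, upstream grad) to
# (input grad, parameter grads). Every layer's analytic gradient is checked
# against central finite differences in the test suite.
#
# Tensor conventions: dense layers take n x d matrices; convolutional layers
# take n x H x W x C arrays (batch first, channels last).
# ---------------------------------------------------------------------------

# He-style fan-in scaled init keeps activations O(1) through deep stacks
nn_init_matrix <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

# --- layer constructors ----------------------------------------------------

nn_dense <- function(n_in, n_out, weight_norm = FALSE) {
  l <- list(type = "dense", n_in = n_in, n_out = n_out,
            weight_norm = weight_norm, b = rep(0, n_out))
  if (weight_norm) {
    l$v <- nn_init_matrix(n_in, n_out)
    l$g <- sqrt(colSums(l$v^2))      # init so that W == v at start
  } else {
    l$W <- nn_init_matrix(n_in, n_out)
  }
  l
}

dense_weight <- function(l) {
  if (!l$weight_norm) return(l$W)
  vn <- sqrt(colSums(l$v^2))
  sweep(l$v, 2, l$g / vn, "*")
}

nn_activation <- function(kind = c("relu", "swish", "sigmoid", "tanh", "linear")) {
  list(type = "activation", kind = match.arg(kind))
}

nn_batchnorm <- function(dim, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", dim = dim, gamma = rep(1, dim), beta = rep(0, dim),
       running_mean = rep(0, dim), running_var = rep(1, dim),
       momentum = momentum, eps = eps)
}

nn_conv2d <- function(in_ch, filters, kernel, padding = c("same", "valid"),
                      weight_norm = FALSE) {
  padding <- match.arg(padding)
  k2c <- kernel * kernel * in_ch
  l <- list(type = "conv2d", in_ch = in_ch, filters = filters,
            kernel = kernel, padding = padding, weight_norm = weight_norm,
            b = rep(0, filters))
  if (weight_norm) {
    l$v <- nn_init_matrix(k2c, filters)
    l$g <- sqrt(colSums(l$v^2))
  } else {
    l$W <- nn_init_matrix(k2c, filters)   # (kh*kw*C) x F, im2col layout
  }
  l
}

nn_maxpool <- function(size = 2L, stride = 1L) {
  list(type = "maxpool", size = as.integer(size), stride = as.integer(stride))
}

nn_upsample <- function(factor = 2L) {
  list(type = "upsample", factor = as.integer(factor))
}

nn_reshape <- function(dims) list(type = "reshape", dims = as.integer(dims))

# zero-pad feature columns up to a target width (for square-map reshapes)
nn_pad1d <- function(n_in, n_out) {
  stopifnot(n_out >= n_in)
  list(type = "pad1d", n_in = as.integer(n_in), n_out = as.integer(n_out))
}

nn_flatten <- function() list(type = "flatten")

# residual block: out = x + inner(x); inner is itself a layer list
nn_residual <- function(inner) list(type = "residual", inner = inner)

# --- forward ---------------------------------------------------------------

# returns list(out=, cache=, layer=) — layer comes back because batch norm
# updates its running statistics during training
nn_layer_forward <- function(l, x, training = TRUE) {
  switch(l$type,
    dense = {
      W <- dense_weight(l)
      out <- x %*% W
      out <- sweep(out, 2, l$b, "+")
      list(out = out, cache = list(x = x, W = W), layer = l)
    },
    activation = {
      out <- switch(l$kind,
        relu = pmax(x, 0),
        swish = x * stats::plogis(x),
        sigmoid = stats::plogis(x),
        tanh = tanh(x),
        linear = x)
      list(out = out, cache = list(x = x, out = out), layer = l)
    },
    batchnorm = nn_bn_forward(l, x, training),
    conv2d = nn_conv_forward(l, x),
    maxpool = nn_pool_forward(l, x),
    upsample = {
      f <- l$factor
      d <- dim(x)
      out <- x[, rep(seq_len(d[2]), each = f), rep(seq_len(d[3]), each = f), ,
               drop = FALSE]
      list(out = out, cache = list(in_dim = d), layer = l)
    },
    reshape = {
      n <- dim(x)[1]
      out <- x
      dim(out) <- c(n, l$dims)
      list(out = out, cache = list(in_dim = dim(x)), layer = l)
    },
    pad1d = {
      out <- cbind(x, matrix(0, nrow(x), l$n_out - l$n_in))
      list(out = out, cache = list(), layer = l)
    },
    flatten = {
      d <- dim(x)
      out <- x
      dim(out) <- c(d[1], prod(d[-1]))
      list(out = out, cache = list(in_dim = d), layer = l)
    },
    residual = {
      fw <- nn_forward(l$inner, x, training)
      l$inner <- fw$net
      list(out = x + fw$out, cache = list(inner = fw$caches), layer = l)
    },
    stop("unknown layer type: ", l$type)
  )
}

# batch norm over the last dimension's channels (2D: features; 4D: channels)
nn_bn_forward <- function(l, x, training) {
  d <- dim(x)
  x2 <- if (length(d) == 2) x else matrix(x, ncol = d[length(d)])
  if (training) {
    mu <- colMeans(x2)
    v <- colMeans(sweep(x2, 2, mu, "-")^2)
    l$running_mean <- l$momentum * l$running_mean + (1 - l$momentum) * mu
    l$running_var <- l$momentum * l$running_var + (1 - l$momentum) * v
  } else {
    mu <- l$running_mean
    v <- l$running_var
  }
  inv_sd <- 1 / sqrt(v + l$eps)
  xhat <- sweep(sweep(x2, 2, mu, "-"), 2, inv_sd, "*")
  out2 <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
  out <- out2
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, inv_sd = inv_sd, dims = d,
                    training = training),
       layer = l)
}

# im2col: gather kernel-sized patches into a matrix for a single big GEMM
nn_im2col <- function(x, kernel, pad) {
  d <- dim(x)  # n, H, W, C
  n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (pad > 0) {
    xp <- array(0, c(n, H + 2 * pad, W + 2 * pad, C))
    xp[, pad + seq_len(H), pad + seq_len(W), ] <- x
  } else xp <- x
  OH <- H + 2 * pad - kernel + 1L
  OW <- W + 2 * pad - kernel + 1L
  cols <- matrix(0, n * OH * OW, kernel * kernel * C)
  idx <- 1L
  for (dj in seq_len(kernel)) {
    for (di in seq_len(kernel)) {
      s <- xp[, di + seq_len(OH) - 1L, dj + seq_len(OW) - 1L, , drop = FALSE]
      dim(s) <- c(n * OH * OW, C)
      cols[, idx + seq_len(C) - 1L] <- s
      idx <- idx + C
    }
  }
  list(cols = cols, OH = OH, OW = OW, pad = pad, in_dim = d)
}

nn_conv_forward <- function(l, x) {
  pad <- if (l$padding == "same") (l$kernel - 1L) %/% 2L else 0L
  # "same" with even kernels needs asymmetric padding; pad fully and crop
  pad_hi <- if (l$padding == "same") l$kernel - 1L - pad else 0L
  d <- dim(x)
  if (pad_hi > 0) {
    xp <- array(0, c(d[1], d[2] + pad + pad_hi, d[3] + pad + pad_hi, d[4]))
    xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
    ic <- nn_im2col(xp, l$kernel, 0L)
    ic$outer_pad <- c(pad, pad_hi)
    ic$orig_dim <- d
  } else {
    ic <- nn_im2col(x, l$kernel, pad)
    ic$outer_pad <- c(0L, 0L)
    ic$orig_dim <- d
  }
  W <- if (l$weight_norm) {
    vn <- sqrt(colSums(l$v^2))
    sweep(l$v, 2, l$g / vn, "*")
  } else l$W
  outm <- sweep(ic$cols %*% W, 2, l$b, "+")
  out <- array(outm, c(d[1], ic$OH, ic$OW, l$filters))
  list(out = out, cache = list(ic = ic, W = W), layer = l)
}

nn_pool_forward <- function(l, x) {
  d <- dim(x)
  k <- l$size; s <- l$stride
  OH <- (d[2] - k) %/% s + 1L
  OW <- (d[3] - k) %/% s + 1L
  out <- array(-Inf, c(d[1], OH, OW, d[4]))
  argmax <- array(0L, c(d[1], OH, OW, d[4]))  # which of the k*k offsets won
  off <- 0L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      off <- off + 1L
      s_i <- di + s * (seq_len(OH) - 1L)
      s_j <- dj + s * (seq_len(OW) - 1L)
      cand <- x[, s_i, s_j, , drop = FALSE]
      better <- cand > out
      out[better] <- cand[better]
      argmax[better] <- off
    }
  }
  list(out = out, cache = list(argmax = argmax, in_dim = d, OH = OH, OW = OW),
       layer = l)
}

# --- backward --------------------------------------------------------------

# returns list(dx=, grads=) where grads names match the layer's parameters
nn_layer_backward <- function(l, cache, dout) {
  switch(l$type,
    dense = {
      dW <- crossprod(cache$x, dout)
      db <- colSums(dout)
      dx <- tcrossprod(dout, cache$W)
      if (l$weight_norm) {
        vn <- sqrt(colSums(l$v^2))
        vhat <- sweep(l$v, 2, vn, "/")
        dg <- colSums(dW * vhat)
        dv <- sweep(dW - sweep(vhat, 2, dg, "*"), 2, l$g / vn, "*")
        list(dx = dx, grads = list(v = dv, g = dg, b = db))
      } else {
        list(dx = dx, grads = list(W = dW, b = db))
      }
    },
    activation = {
      x <- cache$x
      dx <- switch(l$kind,
        relu = dout * (x > 0),
        swish = {
          sg <- stats::plogis(x)
          dout * (sg + x * sg * (1 - sg))
        },
        sigmoid = dout * cache$out * (1 - cache$out),
        tanh = dout * (1 - cache$out^2),
        linear = dout)
      list(dx = dx, grads = list())
    },
    batchnorm = nn_bn_backward(l, cache, dout),
    conv2d = nn_conv_backward(l, cache, dout),
    maxpool = {
      d <- cache$in_dim
      k <- l$size; s <- l$stride
      dx <- array(0, d)
      off <- 0L
      for (dj in seq_len(k)) {
        for (di in seq_len(k)) {
          off <- off + 1L
          s_i <- di + s * (seq_len(cache$OH) - 1L)
          s_j <- dj + s * (seq_len(cache$OW) - 1L)
          contrib <- dout * (cache$argmax == off)
          # stride 1 windows overlap: accumulate rather than assign
          dx[, s_i, s_j, ] <- dx[, s_i, s_j, , drop = FALSE] + contrib
        }
      }
      list(dx = dx, grads = list())
    },
    upsample = {
      f <- l$factor
      d <- cache$in_dim
      dx <- array(0, d)
      for (dj in seq_len(f)) {
        for (di in seq_len(f)) {
          dx <- dx + dout[, di + f * (seq_len(d[2]) - 1L),
                          dj + f * (seq_len(d[3]) - 1L), , drop = FALSE]
        }
      }
      list(dx = dx, grads = list())
    },
    reshape = {
      dx <- dout
      dim(dx) <- cache$in_dim
      list(dx = dx, grads = list())
    },
    flatten = {
      dx <- dout
      dim(dx) <- cache$in_dim
      list(dx = dx, grads = list())
    },
    pad1d = {
      list(dx = dout[, seq_len(l$n_in), drop = FALSE], grads = list())
    },
    residual = {
      bw <- nn_backward(l$inner, cache$inner, dout)
      list(dx = dout + bw$dx, grads = list(inner = bw$grads))
    },
    stop("unknown layer type: ", l$type)
  )
}

nn_bn_backward <- function(l, cache, dout) {
  d <- cache$dims
  dout2 <- if (length(d) == 2) dout else matrix(dout, ncol = d[length(d)])
  xhat <- cache$xhat
  m <- nrow(dout2)
  dgamma <- colSums(dout2 * xhat)
  dbeta <- colSums(dout2)
  if (cache$training) {
    dxhat <- sweep(dout2, 2, l$gamma, "*")
    dx2 <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dout2), byrow = TRUE) -
                   xhat * matrix(colMeans(dxhat * xhat), m, ncol(dout2),
                                 byrow = TRUE),
                 2, cache$inv_sd, "*")
  } else {
    dx2 <- sweep(sweep(dout2, 2, l$gamma, "*"), 2, cache$inv_sd, "*")
  }
  dx <- dx2
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

nn_conv_backward <- function(l, cache, dout) {
  ic <- cache$ic
  d_out <- dim(dout)
  doutm <- dout
  dim(doutm) <- c(d_out[1] * d_out[2] * d_out[3], d_out[4])
  dW <- crossprod(ic$cols, doutm)
  db <- colSums(doutm)
  dcols <- tcrossprod(doutm, cache$W)
  # col2im scatter-add back into the (padded) input
  dpad <- array(0, ic$in_dim)
  idx <- 1L
  C <- ic$in_dim[4]
  for (dj in seq_len(l$kernel)) {
    for (di in seq_len(l$kernel)) {
      s <- dcols[, idx + seq_len(C) - 1L, drop = FALSE]
      dim(s) <- c(ic$in_dim[1], ic$OH, ic$OW, C)
      dpad[, di + seq_len(ic$OH) - 1L, dj + seq_len(ic$OW) - 1L, ] <-
        dpad[, di + seq_len(ic$OH) - 1L, dj + seq_len(ic$OW) - 1L,
             , drop = FALSE] + s
      idx <- idx + C
    }
  }
  od <- cache$ic$orig_dim
  pads <- cache$ic$outer_pad
  if (sum(pads) > 0) {
    dx <- dpad[, pads[1] + seq_len(od[2]), pads[1] + seq_len(od[3]), ,
               drop = FALSE]
  } else if (ic$pad > 0) {
    dx <- dpad[, ic$pad + seq_len(od[2]), ic$pad + seq_len(od[3]), ,
               drop = FALSE]
  } else dx <- dpad
  grads <- if (l$weight_norm) {
    vn <- sqrt(colSums(l$v^2))
    vhat <- sweep(l$v, 2, vn, "/")
    dg <- colSums(dW * vhat)
    dv <- sweep(dW - sweep(vhat, 2, dg, "*"), 2, l$g / vn, "*")
    list(v = dv, g = dg, b = db)
  } else list(W = dW, b = db)
  list(dx = dx, grads = grads)
}

# --- sequential network helpers -------------------------------------------

nn_forward <- function(net, x, training = TRUE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    fw <- nn_layer_forward(net[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
    net[[i]] <- fw$layer
  }
  list(out = x, caches = caches, net = net)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    bw <- nn_layer_backward(net[[i]], caches[[i]], dout)
    dout <- bw$dx
    grads[[i]] <- bw$grads
  }
  list(dx = dout, grads = grads)
}

# --- parameter flattening + Adam ------------------------------------------

nn_param_names <- c("W", "b", "v", "g", "gamma", "beta")

nn_get_params <- function(net) {
  lapply(net, function(l) {
    p <- l[intersect(nn_param_names, names(l))]
    if (l$type == "residual") p$inner <- nn_get_params(l$inner)
    p
  })
}

nn_set_params <- function(net, params) {
  for (i in seq_along(net)) {
    p <- params[[i]]
    for (nm in setdiff(names(p), "inner")) net[[i]][[nm]] <- p[[nm]]
    if (!is.null(p$inner)) {
      net[[i]]$inner <- nn_set_params(net[[i]]$inner, p$inner)
    }
  }
  net
}

# elementwise map over two parallel nested param structures; named levels
# (layer parameter lists, residual "inner") are matched by name, unnamed
# levels (the layer sequence itself) by position
nn_map2 <- function(a, b, f) {
  if (!is.list(a)) return(f(a, b))
  out <- a
  keys <- names(a)
  for (i in seq_along(a)) {
    bi <- if (!is.null(keys) && nzchar(keys[i])) b[[keys[i]]] else b[[i]]
    out[[i]] <- nn_map2(a[[i]], bi, f)
  }
  out
}

nn_map1 <- function(a, f) {
  if (!is.list(a)) return(f(a))
  out <- a
  for (i in seq_along(a)) out[[i]] <- nn_map1(a[[i]], f)
  out
}

adam_init <- function(params) {
  list(m = nn_map1(params, function(p) p * 0),
       v = nn_map1(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nn_map2(state$v, grads,
                     function(v, g) beta2 * v + (1 - beta2) * g^2)
  mhat_scale <- 1 / (1 - beta1^state$t)
  vhat_scale <- 1 / (1 - beta2^state$t)
  upd <- nn_map2(state$m, state$v, function(m, v) {
    lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps)
  })
  params <- nn_map2(params, upd, `-`)
  list(params = params, state = state)
}

# --- losses ----------------------------------------------------------------

# numerically stable binary cross-entropy on logits; returns loss + dlogits
bce_loss <- function(logits, y) {
  n <- length(y)
  z <- as.numeric(logits)
  # softplus(z) - y*z, with the log1p(exp(.)) form stable for large |z|
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  p <- stats::plogis(z)
  dlogits <- matrix((p - y) / n, ncol = 1)
  list(loss = loss, dlogits = dlogits, p = p)
}

mse_loss <- function(pred, target) {
  n <- nrow(pred)
  diff <- pred - target
  list(loss = sum(diff^2) / n, dpred = 2 * diff / n)
}
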