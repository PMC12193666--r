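# ---------------------------------------------------------------------------
# Multi-head attention feature weighting.
#
# Each of the p input features is one token. Token j of sample x is the
# d_model-vector  x_j * E[j,] + P[j,]  (learned value embedding E plus fixed
# sinusoidal positional encoding P). Scaled dot-product attention runs per
# head:  A = softmax(Q K' / sqrt(d_k)),  O = A V;  head outputs are
# concatenated and projected by W_o. With labels present, a mean-pooled
# linear head trained with binary cross-entropy drives all parameters, so
# the attention mass concentrates on label-relevant tokens. The per-feature
# attention mass (average incoming attention, scaled so uniform attention
# gives weight 1) is the learned feature weight; the transform multiplies
# each original feature column by its weight, preserving width.
#
# Gradients are derived by hand and verified against finite differences in
# the tests. 3D arrays are (sample, token, channel).
# ---------------------------------------------------------------------------

# sinusoidal positional encoding table, p tokens x d channels
positional_encoding <- function(p, d) {
  pos <- matrix(seq_len(p) - 1, p, d)
  i2 <- matrix(rep(floor((seq_len(d) - 1) / 2) * 2, each = p), p, d)
  angle <- pos / (10000^(i2 / d))
  even <- matrix(rep(seq_len(d) %% 2 == 1, each = p), p, d)  # channels 1,3,.. are sin
  ifelse(even, sin(angle), cos(angle))
}

mhan_init <- function(p, d_model, heads) {
  dk <- d_model %/% heads
  list(
    E = matrix(stats::rnorm(p * d_model, sd = 1 / sqrt(d_model)), p, d_model),
    Wq = lapply(seq_len(heads), function(h)
      matrix(stats::rnorm(d_model * dk, sd = 1 / sqrt(d_model)), d_model, dk)),
    Wk = lapply(seq_len(heads), function(h)
      matrix(stats::rnorm(d_model * dk, sd = 1 / sqrt(d_model)), d_model, dk)),
    Wv = lapply(seq_len(heads), function(h)
      matrix(stats::rnorm(d_model * dk, sd = 1 / sqrt(d_model)), d_model, dk)),
    Wo = matrix(stats::rnorm(d_model * d_model, sd = 1 / sqrt(d_model)),
                d_model, d_model),
    wh = matrix(stats::rnorm(d_model, sd = 1 / sqrt(d_model)), d_model, 1),
    bh = 0
  )
}

# forward pass; attention is computed sample by sample as p x p BLAS
# matmuls (the batched-array formulation spends its time in R slicing)
mhan_forward <- function(par, xs, P, heads, dk) {
  n <- nrow(xs); p <- ncol(xs); d <- ncol(par$E)
  # tokens T[n,j,] = xs[n,j] * E[j,] + P[j,]
  Tok <- array(0, c(n, p, d))
  for (m in seq_len(d)) {
    Tok[, , m] <- sweep(xs, 2, par$E[, m], "*") +
      matrix(P[, m], n, p, byrow = TRUE)
  }
  Tmat <- matrix(Tok, n * p, d)
  Qs <- Ks <- Vs <- As <- vector("list", heads)
  U <- array(0, c(n, p, d))  # concat heads along channels
  for (h in seq_len(heads)) {
    Qs[[h]] <- array(Tmat %*% par$Wq[[h]], c(n, p, dk))
    Ks[[h]] <- array(Tmat %*% par$Wk[[h]], c(n, p, dk))
    Vs[[h]] <- array(Tmat %*% par$Wv[[h]], c(n, p, dk))
    A_h <- array(0, c(n, p, p))
    O_h <- array(0, c(n, p, dk))
    for (i in seq_len(n)) {
      Qi <- matrix(Qs[[h]][i, , ], p, dk)
      Ki <- matrix(Ks[[h]][i, , ], p, dk)
      S <- tcrossprod(Qi, Ki) / sqrt(dk)
      S <- S - apply(S, 1, max)             # row-stable softmax over keys
      A <- exp(S); A <- A / rowSums(A)
      A_h[i, , ] <- A
      O_h[i, , ] <- A %*% matrix(Vs[[h]][i, , ], p, dk)
    }
    As[[h]] <- A_h
    U[, , (h - 1) * dk + seq_len(dk)] <- O_h
  }
  Y <- array(matrix(U, n * p, d) %*% par$Wo, c(n, p, d))
  u <- apply(Y, c(1, 3), mean)              # mean-pool tokens
  logits <- u %*% par$wh + par$bh
  list(logits = logits, Tok = Tok, Tmat = Tmat, Q = Qs, K = Ks, V = Vs,
       A = As, U = U, u = u)
}

mhan_backward <- function(par, cache, xs, dlogits, heads, dk) {
  n <- nrow(xs); p <- ncol(xs); d <- ncol(par$E)
  g <- list()
  g$wh <- crossprod(cache$u, dlogits)
  g$bh <- sum(dlogits)
  du <- dlogits %*% t(par$wh)               # n x d
  dY <- array(0, c(n, p, d))
  for (m in seq_len(d)) dY[, , m] <- matrix(du[, m] / p, n, p)
  dYmat <- matrix(dY, n * p, d)
  Umat <- matrix(cache$U, n * p, d)
  g$Wo <- crossprod(Umat, dYmat)
  dU <- array(dYmat %*% t(par$Wo), c(n, p, d))
  dTmat <- matrix(0, n * p, d)
  g$Wq <- g$Wk <- g$Wv <- vector("list", heads)
  scale <- 1 / sqrt(dk)
  for (h in seq_len(heads)) {
    dQ <- array(0, c(n, p, dk))
    dK <- array(0, c(n, p, dk))
    dV <- array(0, c(n, p, dk))
    for (i in seq_len(n)) {
      dOi <- matrix(dU[i, , (h - 1) * dk + seq_len(dk)], p, dk)
      Ai <- matrix(cache$A[[h]][i, , ], p, p)
      Vi <- matrix(cache$V[[h]][i, , ], p, dk)
      Qi <- matrix(cache$Q[[h]][i, , ], p, dk)
      Ki <- matrix(cache$K[[h]][i, , ], p, dk)
      dAi <- tcrossprod(dOi, Vi)            # p x p
      dV[i, , ] <- crossprod(Ai, dOi)
      dSi <- Ai * (dAi - rowSums(Ai * dAi)) * scale  # softmax backward
      dQ[i, , ] <- dSi %*% Ki
      dK[i, , ] <- crossprod(dSi, Qi)
    }
    dQm <- matrix(dQ, n * p, dk); dKm <- matrix(dK, n * p, dk)
    dVm <- matrix(dV, n * p, dk)
    g$Wq[[h]] <- crossprod(cache$Tmat, dQm)
    g$Wk[[h]] <- crossprod(cache$Tmat, dKm)
    g$Wv[[h]] <- crossprod(cache$Tmat, dVm)
    dTmat <- dTmat + dQm %*% t(par$Wq[[h]]) + dKm %*% t(par$Wk[[h]]) +
      dVm %*% t(par$Wv[[h]])
  }
  dTok <- array(dTmat, c(n, p, d))
  dE <- matrix(0, p, d)
  for (m in seq_len(d)) dE[, m] <- colSums(dTok[, , m] * xs)
  g$E <- dE
  g
}

# incoming-attention column means accumulated without materializing the
# full n x p x p attention arrays (used for the final mass computation)
mhan_mass_streaming <- function(par, xs, P, heads, dk, chunk = 256L) {
  n <- nrow(xs); p <- ncol(xs)
  mass <- rep(0, p)
  for (start in seq(1, n, by = chunk)) {
    rows <- start:min(start + chunk - 1, n)
    fw <- mhan_forward(par, xs[rows, , drop = FALSE], P, heads, dk)
    mass <- mass + mhan_mass(fw, heads) * length(rows)
  }
  mass / n
}

# average incoming attention per token, over samples, heads and queries
mhan_mass <- function(cache, heads) {
  p <- dim(cache$A[[1]])[2]
  mass <- rep(0, p)
  for (h in seq_len(heads)) {
    mass <- mass + apply(cache$A[[h]], 3, mean)
  }
  mass / heads
}

#' Multi-head attention feature re-weighting
#'
#' Treats each feature as a token (value embedding plus sinusoidal
#' positional encoding), runs multi-head scaled dot-product attention over
#' the tokens, and re-weights each original feature column by its learned
#' attention mass — the average attention the corresponding token receives,
#' scaled so uniform attention gives every feature weight 1. When labels are
#' supplied, a mean-pooled classification head trained with binary
#' cross-entropy tunes the attention toward label-relevant features; without
#' labels the mass of the deterministic seeded initialization is used.
#' Output width equals input width, so downstream classifiers keep their
#' input size.
#'
#' @param X Numeric matrix or feature tibble.
#' @param labels Optional binary labels (taken from `X$label` if present).
#' @param heads Number of attention heads (default 4).
#' @param d_model Token embedding dimension, divisible by `heads`
#'   (default 16).
#' @param epochs Training epochs when labels are given (default 15).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_fit_rows Upper bound on rows used for fitting; larger inputs
#'   are subsampled (stratified) to keep attention training affordable
#'   (default 1024).
#' @param seed RNG seed.
#' @return List with `X_weighted` (same shape as the feature part of `X`)
#'   and `state` (class `"meth_mhan"`: parameters, per-feature `weights`,
#'   per-epoch `loss_trace`, and the fitted attention arrays' row sums are
#'   softmax-normalized by construction).
#' @export
mhan_transform <- function(X, labels = NULL, heads = 4L, d_model = 16L,
                           epochs = 15L, batch_size = 64L,
                           learning_rate = 1e-3, max_fit_rows = 1024L,
                           seed = 1L) {
  if (is.data.frame(X) && is.null(labels) && "label" %in% names(X)) {
    labels <- X$label
  }
  x <- as_feature_input(X)
  p <- ncol(x)
  if (d_model %% heads != 0) {
    stop("d_model (", d_model, ") must be divisible by heads (", heads, ")",
         call. = FALSE)
  }
  dk <- d_model %/% heads
  set.seed(seed)
  centers <- colMeans(x)
  scales <- apply(x, 2, stats::sd)
  scales[scales == 0 | !is.finite(scales)] <- 1
  xs <- sweep(sweep(x, 2, centers, "-"), 2, scales, "/")

  fit_rows <- seq_len(nrow(xs))
  if (nrow(xs) > max_fit_rows) {
    if (!is.null(labels)) {
      # stratified subsample keeps both classes represented
      fit_rows <- unlist(lapply(split(fit_rows, labels), function(r) {
        sample(r, round(length(r) * max_fit_rows / nrow(xs)))
      }), use.names = FALSE)
    } else {
      fit_rows <- sample(fit_rows, max_fit_rows)
    }
    fit_rows <- sort(fit_rows)
  }
  xf <- xs[fit_rows, , drop = FALSE]
  yf <- if (!is.null(labels)) as.numeric(labels[fit_rows]) else NULL

  P <- positional_encoding(p, d_model)
  par <- mhan_init(p, d_model, heads)
  loss_trace <- numeric(0)
  if (!is.null(yf) && epochs > 0) {
    opt <- list(m = rapply(par, function(z) z * 0, how = "replace"),
                v = rapply(par, function(z) z * 0, how = "replace"),
                t = 0L)
    n <- nrow(xf)
    loss_trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        rows <- idx[start:min(start + batch_size - 1, n)]
        fw <- mhan_forward(par, xf[rows, , drop = FALSE], P, heads, dk)
        ls <- bce_loss(fw$logits, yf[rows])
        gr <- mhan_backward(par, fw, xf[rows, , drop = FALSE],
                            ls$dlogits, heads, dk)
        gr <- gr[names(par)]
        opt$t <- opt$t + 1L
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        upd <- function(pp, mm, vv, gg) {
          mm2 <- rapply2(mm, gg, function(a, b) b1 * a + (1 - b1) * b)
          vv2 <- rapply2(vv, gg, function(a, b) b2 * a + (1 - b2) * b^2)
          list(
            p = rapply2(pp, rapply2(mm2, vv2, function(m2, v2) {
              learning_rate * (m2 / (1 - b1^opt$t)) /
                (sqrt(v2 / (1 - b2^opt$t)) + eps)
            }), `-`),
            m = mm2, v = vv2)
        }
        st <- upd(par, opt$m, opt$v, gr)
        par <- st$p; opt$m <- st$m; opt$v <- st$v
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1
      }
      loss_trace[ep] <- ep_loss / nb
    }
  }
  # attention mass on the fitted rows defines the feature weights
  mass <- mhan_mass_streaming(par, xf, P, heads, dk)
  weights <- p * mass                       # uniform attention -> all 1
  names(weights) <- colnames(x)
  state <- structure(
    list(par = par, P = P, heads = as.integer(heads),
         d_model = as.integer(d_model), dk = dk, weights = weights,
         centers = centers, scales = scales, loss_trace = loss_trace,
         feature_names = colnames(x), seed = as.integer(seed)),
    class = "meth_mhan"
  )
  list(X_weighted = mhan_apply(state, x), state = state)
}

#' Apply a fitted attention weighting to new data
#'
#' @param state A `"meth_mhan"` object.
#' @param X Matrix or feature tibble with the training-time columns.
#' @return Matrix of the same width with each column scaled by its learned
#'   attention weight.
#' @export
mhan_apply <- function(state, X) {
  stopifnot(inherits(state, "meth_mhan"))
  x <- as_feature_input(X, expected = state$feature_names)
  sweep(x, 2, unname(state$weights), "*")
}

#' @export
print.meth_mhan <- function(x, ...) {
  top <- utils::head(sort(x$weights, decreasing = TRUE), 5)
  cat("Multi-head attention weighting:", length(x$weights), "features,",
      x$heads, "heads, d_model", x$d_model, "\nTop-weighted features:",
      paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

# elementwise binary map over two parallel nested lists of numerics
rapply2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- rapply2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}
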