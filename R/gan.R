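#' GAN-based augmentation of the feature matrix
#'
#' Trains one small generative adversarial network per class on that class's
#' rows and appends `n_synth_per_class` generated rows per class to the
#' dataset. Generator and discriminator play the usual minimax game
#' \deqn{\min_G \max_D \; E_{x \sim P_{data}}[\log D(x)] +
#'       E_{z \sim P_z}[\log(1 - D(G(z)))]}
#' with the nonsaturating generator objective in practice. Generated feature
#' values are clipped to the per-feature `[min, max]` observed in the
#' training class, so synthetic profiles never leave the empirical support.
#' Original rows pass through byte-identical; synthetic rows are flagged in
#' the returned provenance vector. A class with fewer than 10 rows is too
#' small to fit a generator: it is skipped with a warning.
#'
#' @param X Numeric matrix or feature tibble.
#' @param labels Binary labels; taken from `X$label` when omitted.
#' @param n_synth_per_class Synthetic rows to generate per class (default 0).
#' @param epochs Adversarial training epochs per class (default 200).
#' @param noise_dim Dimension of the generator's input noise (default 16).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size for both players (default 1e-3).
#' @param seed RNG seed.
#' @return List with `X_aug` (matrix), `labels_aug`, `synthetic` (logical
#'   provenance vector) and `state` (class `"meth_gan"`, per-class
#'   generator/discriminator parameters and the minimax `value_trace`).
#' @export
gan_augment <- function(X, labels = NULL, n_synth_per_class = 0L,
                        epochs = 200L, noise_dim = 16L, batch_size = 32L,
                        learning_rate = 1e-3, seed = 1L) {
  if (is.data.frame(X) && is.null(labels)) labels <- X$label
  x <- as_feature_input(X)
  stopifnot(!is.null(labels), length(labels) == nrow(x),
            n_synth_per_class >= 0)
  set.seed(seed)
  classes <- sort(unique(labels))
  states <- list()
  synth_x <- list()
  synth_y <- integer()
  for (cl in classes) {
    xc <- x[labels == cl, , drop = FALSE]
    if (nrow(xc) < 10) {
      warning("class ", cl, " has fewer than 10 rows; refusing to ",
              "synthesize for it", call. = FALSE)
      next
    }
    st <- gan_fit_class(xc, epochs, noise_dim, batch_size, learning_rate)
    states[[as.character(cl)]] <- st
    if (n_synth_per_class > 0) {
      g <- gan_generate(st, n_synth_per_class)
      synth_x[[as.character(cl)]] <- g
      synth_y <- c(synth_y, rep(as.integer(cl), n_synth_per_class))
    }
  }
  x_new <- do.call(rbind, c(list(x), unname(synth_x)))
  n_synth <- nrow(x_new) - nrow(x)
  list(
    X_aug = x_new,
    labels_aug = c(as.integer(labels), synth_y),
    synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_synth)),
    state = structure(list(per_class = states, noise_dim = noise_dim,
                           seed = as.integer(seed)),
                      class = "meth_gan")
  )
}

gan_fit_class <- function(xc, epochs, noise_dim, batch_size, lr) {
  p <- ncol(xc)
  centers <- colMeans(xc)
  scales <- apply(xc, 2, stats::sd)
  scales[scales == 0 | !is.finite(scales)] <- 1
  xs <- sweep(sweep(xc, 2, centers, "-"), 2, scales, "/")
  lo <- apply(xc, 2, min)
  hi <- apply(xc, 2, max)

  gen <- list(nn_dense(noise_dim, 32), nn_activation("relu"),
              nn_dense(32, p), nn_activation("linear"))
  dis <- list(nn_dense(p, 32), nn_activation("relu"),
              nn_dense(32, 1), nn_activation("linear"))
  g_par <- nn_get_params(gen); g_opt <- adam_init(g_par)
  d_par <- nn_get_params(dis); d_opt <- adam_init(d_par)
  n <- nrow(xs)
  bs <- min(batch_size, n)
  value_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    rows <- sample.int(n, bs)
    xb <- xs[rows, , drop = FALSE]
    z <- matrix(stats::rnorm(bs * noise_dim), bs, noise_dim)

    # discriminator step: real -> 1, fake -> 0
    gfw <- nn_forward(gen, z, training = TRUE); gen <- gfw$net
    fake <- gfw$out
    dboth <- rbind(xb, fake)
    y <- c(rep(1, bs), rep(0, bs))
    dfw <- nn_forward(dis, dboth, training = TRUE); dis <- dfw$net
    ls <- bce_loss(dfw$out, y)
    dbw <- nn_backward(dis, dfw$caches, ls$dlogits)
    st <- adam_step(nn_get_params(dis), dbw$grads, d_opt, lr = lr)
    d_opt <- st$state; dis <- nn_set_params(dis, st$params)

    # generator step (nonsaturating): push D(G(z)) toward 1
    z <- matrix(stats::rnorm(bs * noise_dim), bs, noise_dim)
    gfw <- nn_forward(gen, z, training = TRUE); gen <- gfw$net
    dfw <- nn_forward(dis, gfw$out, training = TRUE); dis <- dfw$net
    ls_g <- bce_loss(dfw$out, rep(1, bs))
    dbw <- nn_backward(dis, dfw$caches, ls_g$dlogits)
    gbw <- nn_backward(gen, gfw$caches, dbw$dx)
    st <- adam_step(nn_get_params(gen), gbw$grads, g_opt, lr = lr)
    g_opt <- st$state; gen <- nn_set_params(gen, st$params)

    # minimax objective E[log D(x)] + E[log(1 - D(G(z)))]
    p_real <- stats::plogis(as.numeric(dfw$out))  # fake batch probs
    dfw_r <- nn_forward(dis, xb, training = FALSE)
    p_r <- stats::plogis(as.numeric(dfw_r$out))
    value_trace[ep] <- mean(log(pmax(p_r, 1e-12))) +
      mean(log(pmax(1 - p_real, 1e-12)))
  }
  list(gen = gen, centers = centers, scales = scales, lo = lo, hi = hi,
       noise_dim = noise_dim, value_trace = value_trace)
}

gan_generate <- function(st, n) {
  z <- matrix(stats::rnorm(n * st$noise_dim), n, st$noise_dim)
  g <- nn_forward(st$gen, z, training = FALSE)$out
  g <- sweep(sweep(g, 2, st$scales, "*"), 2, st$centers, "+")
  # clip to the training class's empirical per-feature support
  g <- pmin(pmax(g, matrix(st$lo, n, length(st$lo), byrow = TRUE)),
            matrix(st$hi, n, length(st$hi), byrow = TRUE))
  g
}

#' @export
print.meth_gan <- function(x, ...) {
  cat("Per-class GAN augmentation state:",
      length(x$per_class), "class generator(s), noise dim",
      x$noise_dim, "\n")
  invisible(x)
}
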