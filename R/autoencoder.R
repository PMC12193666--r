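#' Autoencoder compression of the feature matrix
#'
#' Fits a dense autoencoder minimizing the mean squared reconstruction error
#' \deqn{\min_{\theta,\phi} \frac1n \sum_i \lVert x_i - g_\theta(f_\phi(x_i))
#' \rVert^2} and returns the latent representation `Z = f_phi(X)` together
#' with the fitted state. Columns are z-scored before fitting (constant
#' columns get unit scale); the same scaling is applied when encoding new
#' data. The encoder is `p -> hidden -> latent` with rectifier
#' nonlinearities and a mirrored decoder; the latent dimension must be
#' strictly smaller than the input width.
#'
#' @param X Numeric matrix or feature tibble (rows = sites). A `label`
#'   column, if present, is ignored — the autoencoder is unsupervised.
#' @param latent_dim Width of the latent space (default 32).
#' @param hidden Width of the intermediate encoder/decoder layer (default 64).
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed RNG seed; fixed seed gives identical latents.
#' @return List with `Z` (n x latent matrix) and `state` (class
#'   `"meth_autoencoder"`; holds encoder/decoder parameters, the per-epoch
#'   full-data reconstruction `loss_trace`, and the column scaling).
#' @export
autoencoder_fit_transform <- function(X, latent_dim = 32L, hidden = 64L,
                                      epochs = 50L, batch_size = 64L,
                                      learning_rate = 1e-3, seed = 1L) {
  x <- as_feature_input(X)
  p <- ncol(x)
  if (latent_dim >= p) {
    stop("latent_dim (", latent_dim, ") must be smaller than the input ",
         "width (", p, ")", call. = FALSE)
  }
  set.seed(seed)
  centers <- colMeans(x)
  scales <- apply(x, 2, stats::sd)
  scales[scales == 0 | !is.finite(scales)] <- 1
  xs <- sweep(sweep(x, 2, centers, "-"), 2, scales, "/")

  net <- list(
    nn_dense(p, hidden), nn_activation("relu"),
    nn_dense(hidden, latent_dim), nn_activation("relu"),
    nn_dense(latent_dim, hidden), nn_activation("relu"),
    nn_dense(hidden, p), nn_activation("linear")
  )
  params <- nn_get_params(net)
  opt <- adam_init(params)
  n <- nrow(xs)
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      rows <- idx[start:min(start + batch_size - 1, n)]
      xb <- xs[rows, , drop = FALSE]
      fw <- nn_forward(net, xb, training = TRUE)
      net <- fw$net
      ls <- mse_loss(fw$out, xb)
      bw <- nn_backward(net, fw$caches, ls$dpred)
      st <- adam_step(nn_get_params(net), bw$grads, opt, lr = learning_rate)
      opt <- st$state
      net <- nn_set_params(net, st$params)
    }
    full <- nn_forward(net, xs, training = FALSE)
    loss_trace[ep] <- mse_loss(full$out, xs)$loss / p  # per-element MSE
  }
  state <- structure(
    list(net = net, centers = centers, scales = scales,
         latent_dim = as.integer(latent_dim), loss_trace = loss_trace,
         feature_names = colnames(x), seed = as.integer(seed)),
    class = "meth_autoencoder"
  )
  list(Z = autoencoder_encode(state, x), state = state)
}

#' Encode data with a fitted autoencoder
#'
#' @param state A `"meth_autoencoder"` object.
#' @param X Matrix or feature tibble with the training-time columns.
#' @return n x latent matrix.
#' @export
autoencoder_encode <- function(state, X) {
  stopifnot(inherits(state, "meth_autoencoder"))
  x <- as_feature_input(X, expected = state$feature_names)
  xs <- sweep(sweep(x, 2, state$centers, "-"), 2, state$scales, "/")
  enc <- state$net[1:4]  # dense/relu/dense/relu encoder half
  z <- nn_forward(enc, xs, training = FALSE)$out
  colnames(z) <- paste0("latent_", seq_len(ncol(z)))
  z
}

#' @export
print.meth_autoencoder <- function(x, ...) {
  cat("Autoencoder:", length(x$centers), "->", x$latent_dim,
      "latent; final reconstruction MSE",
      format(utils::tail(x$loss_trace, 1), digits = 4), "\n")
  invisible(x)
}

# shared coercion: tibble (site_id/label dropped) or matrix -> numeric matrix
as_feature_input <- function(X, expected = NULL) {
  x <- if (is.data.frame(X)) feature_matrix(X) else as.matrix(X)
  storage.mode(x) <- "double"
  if (!is.null(expected)) {
    if (is.null(colnames(x))) {
      if (ncol(x) != length(expected)) {
        stop("input width ", ncol(x), " does not match the fitted width ",
             length(expected), call. = FALSE)
      }
    } else {
      missing <- setdiff(expected, colnames(x))
      if (length(missing)) {
        stop("input lacks fitted feature columns: ",
             paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
      }
      x <- x[, expected, drop = FALSE]
    }
  }
  x
}
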