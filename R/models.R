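#' UNet architecture configuration
#'
#' Declarative knobs of the 1D-adapted UNet. The defaults reproduce the
#' published architecture exactly: a weight-normalized dense layer with
#' 16,384 units reshaped to a 32 x 32 x 16 tensor, 2D convolutions with 12
#' filters of kernel size 4 and swish activation ("same" padding), 2 x 2 max
#' pooling with stride 1 ("valid", so each pool shrinks height and width by
#' one — the only reading under which the saved skip tensor and the later
#' element-wise multiplication have matching shapes), an element-wise
#' multiplicative skip connection, a two-iteration decoder of
#' batch-norm/weight-normalized convolution/2x upsampling, and a dense head
#' of 512/1024/512 rectifier blocks into a single sigmoid output.
#'
#' `unet_config_small()` is the same topology at desk scale (dense 256
#' reshaped to 8 x 8 x 4, 6 filters, kernel 3, head 32/64/32) for training
#' on a single CPU; the full-size default is still what [build_unet()]
#' validates and reports shapes for.
#'
#' @param dense_units Units of the initial dense layer (default 16384).
#' @param reshape Height/width/channels the dense output is reshaped to;
#'   its product must equal `dense_units` (default `c(32, 32, 16)`).
#' @param filters Convolution filters (default 12).
#' @param kernel Convolution kernel size (default 4).
#' @param pool_size,pool_stride Max-pool geometry (defaults 2 and 1).
#' @param decoder_blocks Decoder iterations, each ending in 2x upsampling
#'   (default 2).
#' @param head_units Dense head widths (default `c(512, 1024, 512)`).
#' @param num_labels Output units (default 1, sigmoid binary head).
#' @return List of class `"unet_config"`.
#' @export
unet_config <- function(dense_units = 16384L, reshape = c(32L, 32L, 16L),
                        filters = 12L, kernel = 4L, pool_size = 2L,
                        pool_stride = 1L, decoder_blocks = 2L,
                        head_units = c(512L, 1024L, 512L), num_labels = 1L) {
  cfg <- list(dense_units = as.integer(dense_units),
              reshape = as.integer(reshape), filters = as.integer(filters),
              kernel = as.integer(kernel), pool_size = as.integer(pool_size),
              pool_stride = as.integer(pool_stride),
              decoder_blocks = as.integer(decoder_blocks),
              head_units = as.integer(head_units),
              num_labels = as.integer(num_labels))
  if (prod(cfg$reshape) != cfg$dense_units) {
    stop("reshape dims (", paste(cfg$reshape, collapse = "x"),
         ") must multiply to the dense units (", cfg$dense_units, ")",
         call. = FALSE)
  }
  structure(cfg, class = "unet_config")
}

#' @rdname unet_config
#' @export
unet_config_small <- function() {
  unet_config(dense_units = 256L, reshape = c(8L, 8L, 4L), filters = 6L,
              kernel = 3L, head_units = c(32L, 64L, 32L))
}

#' Build the UNet model specification
#'
#' Encodes the encoder / decoder / output-layer plan and computes the full
#' shape walk analytically (no parameters are allocated until
#' [train_model()]).
#'
#' @param n_features Input feature width (100 after K-best at the pipeline
#'   defaults).
#' @param config A [unet_config()].
#' @return Object of class `"meth_model_spec"` with `kind = "unet"`,
#'   the config, and a `shapes` tibble (stage, output dimensions, size).
#' @examples
#' spec <- build_unet(100)
#' spec$config$dense_units          # 16384
#' spec$shapes
#' @export
build_unet <- function(n_features, config = unet_config()) {
  stopifnot(n_features >= 1, inherits(config, "unet_config"))
  hw <- config$reshape[1:2]
  ch <- config$reshape[3]
  pool_shrink <- config$pool_size - config$pool_stride  # per pool, stride 1
  walk <- list(list(stage = "input", dims = n_features))
  add <- function(stage, dims) walk[[length(walk) + 1]] <<-
    list(stage = stage, dims = dims)
  add("dense", config$dense_units)
  add("reshape", config$reshape)
  add("conv_1", c(hw, config$filters))
  hw_skip <- hw - pool_shrink
  add("maxpool_skip", c(hw_skip, config$filters))
  add("conv_block_x2", c(hw_skip, config$filters))
  add("multiply_skip", c(hw_skip, config$filters))
  hw_enc <- hw_skip - pool_shrink
  add("maxpool_2", c(hw_enc, config$filters))
  hw_dec <- hw_enc
  for (b in seq_len(config$decoder_blocks)) {
    hw_dec <- hw_dec * 2L
    add(paste0("decoder_", b), c(hw_dec, config$filters))
  }
  add("flatten", prod(hw_dec) * config$filters)
  for (i in seq_along(config$head_units)) {
    add(paste0("head_dense_", i), config$head_units[i])
  }
  add("output_sigmoid", config$num_labels)
  shapes <- tibble::tibble(
    stage = vapply(walk, `[[`, character(1), "stage"),
    dims = vapply(walk, function(w) paste(w$dims, collapse = "x"),
                  character(1)),
    size = vapply(walk, function(w) prod(w$dims), numeric(1))
  )
  structure(list(kind = "unet", n_features = as.integer(n_features),
                 config = config, shapes = shapes),
            class = "meth_model_spec")
}

#' Build a baseline model specification
#'
#' Three reference classifiers share the UNet's train/predict contract:
#' \describe{
#'   \item{`cnn`}{features reshaped to a square-ish 2D map (zero-padded),
#'     two convolution + max-pool blocks, dense head.}
#'   \item{`ffnn_knn`}{a one-hidden-layer feed-forward network
#'     \eqn{y_k = f_k(\alpha_k + \sum_j W_{jk} f_j(\alpha_j + \sum_i
#'     W_{ij} x_i))} whose hidden activations become the feature space of a
#'     K-nearest-neighbour vote with Euclidean distance; the predicted
#'     probability is the fraction of the K neighbours labeled methylated.}
#'   \item{`resnet`}{a stack of residual blocks each computing
#'     `H(x) = F(x) + x` on the feature vector — a from-scratch residual
#'     network, not a pretrained image model, since 2D-image weights have no
#'     meaning for tabular k-mer counts.}
#' }
#'
#' @param kind `"cnn"`, `"ffnn_knn"` or `"resnet"`.
#' @param n_features Input feature width.
#' @param config Optional list of overrides: `filters`, `kernel`, `hidden`,
#'   `k_neighbors`, `blocks`, `head_units`.
#' @return Object of class `"meth_model_spec"`.
#' @export
build_baseline <- function(kind = c("cnn", "ffnn_knn", "resnet"),
                           n_features, config = list()) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    cnn = list(filters = c(8L, 16L), kernel = 3L, head_units = 32L),
    ffnn_knn = list(hidden = 64L, k_neighbors = 5L),
    resnet = list(blocks = 2L, head_units = 32L)
  )
  cfg <- utils::modifyList(defaults, config)
  if (kind == "ffnn_knn" && cfg$k_neighbors %% 2 == 0) {
    warning("KNN neighbor count must be odd; using ",
            cfg$k_neighbors - 1L, call. = FALSE)
    cfg$k_neighbors <- cfg$k_neighbors - 1L
  }
  if (kind == "cnn") {
    cfg$side <- as.integer(ceiling(sqrt(n_features)))
  }
  structure(list(kind = kind, n_features = as.integer(n_features),
                 config = cfg),
            class = "meth_model_spec")
}

#' @export
print.meth_model_spec <- function(x, ...) {
  cat("Model spec:", x$kind, "on", x$n_features, "features\n")
  if (!is.null(x$shapes)) print(x$shapes, n = nrow(x$shapes))
  invisible(x)
}

# --- network instantiation -------------------------------------------------

unet_instantiate <- function(spec) {
  cfg <- spec$config
  p <- spec$n_features
  f <- cfg$filters
  ch <- cfg$reshape[3]
  list(
    pre = list(
      nn_batchnorm(p),
      nn_dense(p, cfg$dense_units, weight_norm = TRUE),
      nn_reshape(cfg$reshape),
      nn_batchnorm(ch),
      nn_conv2d(ch, f, cfg$kernel, padding = "same"),
      nn_activation("swish"),
      nn_maxpool(cfg$pool_size, cfg$pool_stride)
    ),
    mid = list(
      nn_batchnorm(f),
      nn_conv2d(f, f, cfg$kernel, padding = "same", weight_norm = TRUE),
      nn_activation("swish"),
      nn_batchnorm(f),
      nn_conv2d(f, f, cfg$kernel, padding = "same", weight_norm = TRUE),
      nn_activation("swish")
    ),
    post = list(nn_maxpool(cfg$pool_size, cfg$pool_stride)),
    dec = unlist(lapply(seq_len(cfg$decoder_blocks), function(b) {
      list(nn_batchnorm(f),
           nn_conv2d(f, f, cfg$kernel, padding = "same", weight_norm = TRUE),
           nn_activation("swish"),
           nn_upsample(2L))
    }), recursive = FALSE),
    head = local({
      hw <- cfg$reshape[1:2] - 2L * (cfg$pool_size - cfg$pool_stride)
      flat <- prod(hw * 2L^cfg$decoder_blocks) * f
      dims <- c(flat, cfg$head_units)
      layers <- list(nn_flatten())
      for (i in seq_along(cfg$head_units)) {
        layers <- c(layers, list(nn_batchnorm(dims[i]),
                                 nn_activation("relu"),
                                 nn_dense(dims[i], dims[i + 1])))
      }
      c(layers, list(nn_dense(dims[length(dims)], cfg$num_labels)))
    })
  )
}

unet_forward <- function(nets, x, training = TRUE) {
  pre <- nn_forward(nets$pre, x, training); nets$pre <- pre$net
  skip <- pre$out
  mid <- nn_forward(nets$mid, skip, training); nets$mid <- mid$net
  prod_t <- mid$out * skip
  post <- nn_forward(nets$post, prod_t, training); nets$post <- post$net
  dec <- nn_forward(nets$dec, post$out, training); nets$dec <- dec$net
  head <- nn_forward(nets$head, dec$out, training); nets$head <- head$net
  list(out = head$out, nets = nets,
       caches = list(pre = pre$caches, mid = mid$caches, post = post$caches,
                     dec = dec$caches, head = head$caches,
                     skip = skip, mid_out = mid$out))
}

unet_backward <- function(nets, caches, dlogits) {
  bh <- nn_backward(nets$head, caches$head, dlogits)
  bd <- nn_backward(nets$dec, caches$dec, bh$dx)
  bp <- nn_backward(nets$post, caches$post, bd$dx)
  dprod <- bp$dx
  dmid_out <- dprod * caches$skip
  dskip_direct <- dprod * caches$mid_out
  bm <- nn_backward(nets$mid, caches$mid, dmid_out)
  dskip <- dskip_direct + bm$dx
  bpre <- nn_backward(nets$pre, caches$pre, dskip)
  list(grads = list(pre = bpre$grads, mid = bm$grads, post = bp$grads,
                    dec = bd$grads, head = bh$grads))
}

sequential_instantiate <- function(spec) {
  cfg <- spec$config
  p <- spec$n_features
  if (spec$kind == "cnn") {
    side <- cfg$side
    f1 <- cfg$filters[1]; f2 <- cfg$filters[2]
    s1 <- side %/% 2L
    s2 <- s1 %/% 2L
    list(seq = list(
      nn_batchnorm(p),
      nn_pad1d(p, side * side),
      nn_reshape(c(side, side, 1L)),
      nn_conv2d(1L, f1, cfg$kernel, padding = "same"),
      nn_activation("relu"),
      nn_maxpool(2L, 2L),
      nn_conv2d(f1, f2, cfg$kernel, padding = "same"),
      nn_activation("relu"),
      nn_maxpool(2L, 2L),
      nn_flatten(),
      nn_dense(s2 * s2 * f2, cfg$head_units),
      nn_activation("relu"),
      nn_dense(cfg$head_units, 1L)
    ))
  } else if (spec$kind == "resnet") {
    blocks <- lapply(seq_len(cfg$blocks), function(b) {
      nn_residual(list(
        nn_batchnorm(p),
        nn_dense(p, p),
        nn_activation("relu"),
        nn_dense(p, p)
      ))
    })
    list(seq = c(list(nn_batchnorm(p)), blocks,
                 list(nn_batchnorm(p), nn_activation("relu"),
                      nn_dense(p, cfg$head_units), nn_activation("relu"),
                      nn_dense(cfg$head_units, 1L))))
  } else if (spec$kind == "ffnn_knn") {
    list(seq = list(
      nn_batchnorm(p),
      nn_dense(p, cfg$hidden),
      nn_activation("relu"),
      nn_dense(cfg$hidden, 1L)
    ))
  } else {
    stop("unknown model kind: ", spec$kind, call. = FALSE)
  }
}

#' Train a classifier on a labeled feature matrix
#'
#' Makes a stratified, seeded 70:30 (by default) train/test split, trains
#' the network of the given spec with minibatch adaptive-moment gradient
#' descent on binary cross-entropy, and records per-epoch training and
#' held-out loss/accuracy. Fixing the seed fixes the split, the parameter
#' initialization and every minibatch, so re-training is bit-reproducible on
#' the same platform.
#'
#' @param spec A `"meth_model_spec"` from [build_unet()] or
#'   [build_baseline()].
#' @param X Feature tibble or numeric matrix.
#' @param y Binary labels; taken from `X$label` when omitted.
#' @param split_fraction Training fraction of the stratified split
#'   (default 0.70).
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed RNG seed.
#' @param split Optional list with integer elements `train` and `test` to
#'   impose an externally computed split (used by [run_pipeline()] so the
#'   feature-analysis stages can be fitted on the training rows only).
#' @param verbose Print per-epoch progress.
#' @return Object of class `"meth_model"`: the spec, fitted parameters,
#'   per-epoch `history` tibble (`epoch`, `loss`, `accuracy`,
#'   `val_loss`, `val_accuracy`), the split row indices, the feature
#'   scaling, and the seed.
#' @export
train_model <- function(spec, X, y = NULL, split_fraction = 0.70,
                        epochs = 50L, batch_size = 64L,
                        learning_rate = 1e-3, seed = 1L, split = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(spec, "meth_model_spec"))
  if (is.data.frame(X) && is.null(y)) y <- X$label
  x <- as_feature_input(X)
  stopifnot(!is.null(y), length(y) == nrow(x))
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("both classes must be present for training", call. = FALSE)
  }
  if (ncol(x) != spec$n_features) {
    stop("feature width ", ncol(x), " does not match the spec (",
         spec$n_features, ")", call. = FALSE)
  }
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(split)) {
    split <- stratified_split(y, split_fraction)
  }
  train_idx <- split$train
  test_idx <- split$test

  centers <- colMeans(x[train_idx, , drop = FALSE])
  scales <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
  scales[scales == 0 | !is.finite(scales)] <- 1
  xs <- sweep(sweep(x, 2, centers, "-"), 2, scales, "/")
  xtr <- xs[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  xte <- xs[test_idx, , drop = FALSE]; yte <- y[test_idx]

  is_unet <- spec$kind == "unet"
  nets <- if (is_unet) unet_instantiate(spec) else sequential_instantiate(spec)
  get_p <- function(nets) lapply(nets, nn_get_params)
  set_p <- function(nets, par) {
    for (nm in names(nets)) nets[[nm]] <- nn_set_params(nets[[nm]], par[[nm]])
    nets
  }
  fwd <- function(nets, xb, training) {
    if (is_unet) unet_forward(nets, xb, training)
    else {
      fw <- nn_forward(nets$seq, xb, training)
      list(out = fw$out, nets = list(seq = fw$net),
           caches = list(seq = fw$caches))
    }
  }
  bwd <- function(nets, caches, dl) {
    if (is_unet) unet_backward(nets, caches, dl)
    else list(grads = list(seq = nn_backward(nets$seq, caches$seq, dl)$grads))
  }

  opt <- adam_init(get_p(nets))
  n <- nrow(xtr)
  hist <- list()
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = batch_size)) {
      rows <- idx[start:min(start + batch_size - 1, n)]
      fw <- fwd(nets, xtr[rows, , drop = FALSE], TRUE)
      nets <- fw$nets
      ls <- bce_loss(fw$out, ytr[rows])
      if (!is.finite(ls$loss)) {
        stop("non-finite training loss at epoch ", ep,
             "; try a smaller learning_rate", call. = FALSE)
      }
      bw <- bwd(nets, fw$caches, ls$dlogits)
      st <- adam_step(get_p(nets), bw$grads, opt, lr = learning_rate)
      opt <- st$state
      nets <- set_p(nets, st$params)
      ep_loss <- ep_loss + ls$loss * length(rows)
      ep_correct <- ep_correct + sum((ls$p >= 0.5) == (ytr[rows] == 1))
    }
    vfw <- fwd(nets, xte, FALSE)
    vls <- bce_loss(vfw$out, yte)
    hist[[ep]] <- tibble::tibble(
      epoch = ep,
      loss = ep_loss / n,
      accuracy = ep_correct / n,
      val_loss = vls$loss,
      val_accuracy = mean((vls$p >= 0.5) == (yte == 1))
    )
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f acc %.3f val_loss %.4f val_acc %.3f",
                      ep, hist[[ep]]$loss, hist[[ep]]$accuracy,
                      hist[[ep]]$val_loss, hist[[ep]]$val_accuracy))
    }
  }
  model <- structure(
    list(spec = spec, nets = nets, centers = centers, scales = scales,
         history = dplyr::bind_rows(hist),
         train_idx = train_idx, test_idx = test_idx,
         feature_names = colnames(x), seed = as.integer(seed)),
    class = "meth_model"
  )
  if (spec$kind == "ffnn_knn") {
    model$knn_train <- ffnn_hidden(model, xtr)
    model$knn_labels <- ytr
  }
  model
}

# hidden-layer activations of the FFNN: the KNN feature space
ffnn_hidden <- function(model, xs) {
  hidden_layers <- model$nets$seq[1:3]  # batchnorm, dense, relu
  nn_forward(hidden_layers, xs, training = FALSE)$out
}

#' Stratified train/test split
#'
#' Samples `fraction` of each class (rounded) into the training set using
#' the current RNG state; indices come back sorted so split membership is a
#' pure function of (labels, fraction, RNG state).
#'
#' @param y Binary label vector.
#' @param fraction Training fraction.
#' @return List with sorted integer vectors `train` and `test`.
#' @export
stratified_split <- function(y, fraction = 0.70) {
  train <- sort(unlist(lapply(split(seq_along(y), y), function(rows) {
    sample(rows, round(length(rows) * fraction))
  }), use.names = FALSE))
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Predict methylation probabilities
#'
#' @param object A trained `"meth_model"`.
#' @param newdata Feature tibble or matrix with the training-time columns.
#' @param stage For FFNN-KNN models: `"knn"` (default, the K-neighbour vote
#'   fraction) or `"ffnn"` (the network head alone).
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.meth_model <- function(object, newdata, stage = c("knn", "ffnn"), ...) {
  stage <- match.arg(stage)
  x <- as_feature_input(newdata, expected = object$feature_names)
  if (ncol(x) != object$spec$n_features) {
    stop("feature width ", ncol(x), " does not match the trained model (",
         object$spec$n_features, ")", call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, object$centers, "-"), 2, object$scales, "/")
  if (object$spec$kind == "ffnn_knn" && stage == "knn") {
    return(knn_vote(object, xs))
  }
  fw <- if (object$spec$kind == "unet") {
    unet_forward(object$nets, xs, training = FALSE)
  } else {
    nn_forward(object$nets$seq, xs, training = FALSE)
  }
  as.numeric(stats::plogis(fw$out))
}

# Euclidean K-nearest-neighbour majority vote in the FFNN's hidden space;
# the returned probability is the fraction of methylated neighbours
knn_vote <- function(model, xs) {
  h <- ffnn_hidden(model, xs)
  tr <- model$knn_train
  k <- model$spec$config$k_neighbors
  d2 <- outer(rowSums(h^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(h)), rowSums(tr^2)) - 2 * tcrossprod(h, tr)
  apply(d2, 1, function(row) {
    nb <- order(row)[seq_len(min(k, length(row)))]
    mean(model$knn_labels[nb] == 1)
  })
}

#' Threshold probabilities into class labels
#'
#' The boundary is inclusive: a probability exactly at the threshold is
#' labeled methylated, mirroring the beta binarization rule.
#'
#' @param probs Probabilities in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer 0/1 vector.
#' @export
classify <- function(probs, threshold = 0.5) {
  stopifnot(all(probs >= 0 & probs <= 1))
  as.integer(probs >= threshold)
}

#' @export
print.meth_model <- function(x, ...) {
  h <- utils::tail(x$history, 1)
  cat("Trained", x$spec$kind, "model:", length(x$train_idx), "train /",
      length(x$test_idx), "test rows,", nrow(x$history), "epochs\n")
  cat(sprintf("Final: loss %.4f acc %.3f val_loss %.4f val_acc %.3f\n",
              h$loss, h$accuracy, h$val_loss, h$val_accuracy))
  invisible(x)
}

#' Tidy / summarize a trained model
#'
#' `tidy()` returns the per-epoch learning curves in long-friendly form;
#' `glance()` returns a one-row summary of the final epoch.
#'
#' @param x A `"meth_model"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.meth_model <- function(x, ...) x$history

#' @rdname tidy.meth_model
#' @export
glance.meth_model <- function(x, ...) {
  h <- utils::tail(x$history, 1)
  tibble::tibble(kind = x$spec$kind, epochs = nrow(x$history),
                 n_train = length(x$train_idx), n_test = length(x$test_idx),
                 loss = h$loss, accuracy = h$accuracy,
                 val_loss = h$val_loss, val_accuracy = h$val_accuracy,
                 seed = x$seed)
}

#' Plot learning curves of a trained model
#'
#' @param object A `"meth_model"`.
#' @param ... Unused.
#' @return A ggplot object with loss and accuracy panels over epochs.
#' @export
autoplot.meth_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "metric", values_to = "value")
  long$panel <- ifelse(grepl("loss", long$metric), "loss", "accuracy")
  long$split <- ifelse(grepl("^val", long$metric), "validation", "training")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL,
                  title = paste("Learning curves:", object$spec$kind)) +
    ggplot2::theme_minimal()
}
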