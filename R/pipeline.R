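#' Build and validate a pipeline run configuration
#'
#' Collects everything a full run needs: input paths (or in-memory
#' objects), the curation parameters, the K-best selection, the optional
#' feature-analysis stage, the classifier and its training budget, and the
#' seed that fixes the split, the preprocessing fit and the network
#' initialization.
#'
#' @param genome Path to a FASTA file, or a named character vector from
#'   [read_fasta()].
#' @param track Path to a methylation track, or a calls tibble from
#'   [read_methylation_track()].
#' @param dialect Track dialect when `track` is a path.
#' @param out_dir Directory for persisted artifacts (`NULL` = keep
#'   everything in memory).
#' @param curation A [curation_config()].
#' @param k Features kept by K-best (default 100).
#' @param score K-best score function.
#' @param preproc Feature-analysis stage: `"none"`, `"ae"`, `"gan"` or
#'   `"mhan"`.
#' @param preproc_args Named list of extra arguments for the stage
#'   (e.g. `latent_dim`, `n_synth_per_class`, `heads`).
#' @param model Classifier kind: `"unet"`, `"cnn"`, `"ffnn_knn"`,
#'   `"resnet"`.
#' @param model_config For `"unet"` a [unet_config()] (default
#'   [unet_config_small()], the desk-scale topology); for baselines a list
#'   of overrides.
#' @param split_fraction Training fraction (default 0.70).
#' @param epochs,batch_size,learning_rate Training budget.
#' @param seed Master seed for the run.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(genome, track, dialect = "simple5", out_dir = NULL,
                       curation = curation_config(), k = 100L,
                       score = "anova_f",
                       preproc = c("none", "ae", "gan", "mhan"),
                       preproc_args = list(),
                       model = c("unet", "cnn", "ffnn_knn", "resnet"),
                       model_config = NULL, split_fraction = 0.70,
                       epochs = 30L, batch_size = 64L, learning_rate = 1e-3,
                       seed = 1L) {
  preproc <- match.arg(preproc)
  model <- match.arg(model)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie in (0, 1)", call. = FALSE)
  }
  # an in-memory genome is a *named* character vector; a path is unnamed
  if (is.character(genome) && is.null(names(genome)) &&
      length(genome) == 1 && !file.exists(genome)) {
    stop("genome file not found: ", genome, call. = FALSE)
  }
  if (is.character(track) && length(track) == 1 && !file.exists(track)) {
    stop("methylation track not found: ", track, call. = FALSE)
  }
  stopifnot(inherits(curation, "curation_config"))
  structure(
    list(genome = genome, track = track, dialect = dialect,
         out_dir = out_dir, curation = curation, k = as.integer(k),
         score = score, preproc = preproc, preproc_args = preproc_args,
         model = model, model_config = model_config,
         split_fraction = split_fraction, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full curation-selection-training-evaluation pipeline
#'
#' Executes the stages in order — curate, K-best select, optional
#' feature-analysis stage (fitted on the training rows only and applied
#' frozen everywhere), train, evaluate on the held-out rows — persisting
#' each intermediate artifact under `out_dir` when one is given: the
#' feature table (CSV), curation report and selection (JSON), model
#' checkpoint (RDS), per-epoch history and ROC/PR curve points (CSV),
#' metrics plus agreement statistics (JSON), and a manifest recording the
#' config hash, seed and per-stage row counts. Re-running with the same
#' config reproduces split membership and selection indices exactly.
#'
#' @param config A [run_config()].
#' @return List of class `"meth_run_report"`: `model`, `metrics`,
#'   `agreement`, `roc`, `pr`, `selection`, `curation_report`, `manifest`,
#'   and `paths` (when artifacts were written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  paths <- list()
  persist <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    invisible(p)
  }

  genome <- stage("read_genome", {
    if (is.character(config$genome) && is.null(names(config$genome)) &&
        length(config$genome) == 1) read_fasta(config$genome)
    else config$genome
  })
  calls <- stage("read_track", {
    if (is.data.frame(config$track)) config$track
    else read_methylation_track(config$track, config$dialect)
  })

  curated <- stage("curate", build_dataset(genome, calls, config$curation))
  features <- curated$features
  persist("features.csv", function(p) write_feature_table(features, p))
  persist("curation_report.json", function(p) {
    jsonlite::write_json(as.list(curated$report), p, auto_unbox = TRUE)
  })

  selection <- stage("select", kbest_select(features, k = config$k,
                                            score = config$score))
  features_sel <- apply_selection(features, selection)
  persist("selection.json", function(p) {
    jsonlite::write_json(list(score = selection$score, k = selection$k,
                              selected = selection$selected,
                              indices = selection$indices),
                         p, auto_unbox = TRUE)
  })

  y <- features_sel$label
  x <- feature_matrix(features_sel)
  set.seed(config$seed)
  split <- stratified_split(y, config$split_fraction)

  pp <- stage("preproc", pipeline_preproc(config, x, y, split))
  x_model <- pp$x
  y_model <- pp$y
  model_split <- pp$split

  spec <- stage("build_model", {
    if (config$model == "unet") {
      build_unet(ncol(x_model), config$model_config %||% unet_config_small())
    } else {
      build_baseline(config$model, ncol(x_model),
                     config$model_config %||% list())
    }
  })
  model <- stage("train", train_model(
    spec, x_model, y_model, split_fraction = config$split_fraction,
    epochs = config$epochs, batch_size = config$batch_size,
    learning_rate = config$learning_rate, seed = config$seed,
    split = model_split
  ))
  persist("model.rds", function(p) saveRDS(model, p))
  persist("history.csv", function(p) readr::write_csv(model$history, p,
                                                      progress = FALSE))

  # held-out evaluation on the original (never synthetic) test rows
  test_idx <- split$test
  probs <- stage("evaluate", predict(model, x_model[model_split$test, ,
                                                    drop = FALSE]))
  truth <- y[test_idx]
  cm <- confusion_matrix(truth, classify(probs))
  metrics <- compute_metrics(cm)
  metrics$auroc <- auroc(truth, probs)
  metrics$auprc <- auprc(truth, probs)
  roc <- roc_curve(truth, probs)
  pr <- pr_curve(truth, probs)
  agreement <- dplyr::bind_cols(
    tryCatch(chi_square_test(cm),
             error = function(e) tibble::tibble(chi2 = NA_real_, df = 1L,
                                                p_value = NA_real_)),
    cohens_kappa(cm)
  )
  persist("metrics.json", function(p) {
    jsonlite::write_json(c(as.list(metrics), as.list(agreement),
                           list(confusion = unclass(cm))),
                         p, auto_unbox = TRUE, digits = NA)
  })
  persist("roc_curve.csv", function(p) readr::write_csv(roc$points, p,
                                                        progress = FALSE))
  persist("pr_curve.csv", function(p) readr::write_csv(pr$points, p,
                                                       progress = FALSE))

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    rows = list(input_calls = unname(curated$report["input"]),
                curated = nrow(features),
                selected_matrix = nrow(features_sel),
                train = length(split$train),
                test = length(split$test),
                synthetic_train = length(model_split$train) -
                  length(split$train)),
    selection_indices = selection$indices,
    model = config$model, preproc = config$preproc,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  persist("manifest.json", function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE)
  })

  structure(
    list(model = model, metrics = metrics, agreement = agreement,
         roc = roc, pr = pr, selection = selection,
         curation_report = curated$report, preproc_state = pp$state,
         manifest = manifest, paths = paths,
         test_truth = truth, test_probs = probs),
    class = "meth_run_report"
  )
}

# fit the configured feature-analysis stage on the training rows only and
# apply it frozen to every row; GAN augmentation appends synthetic rows to
# the training set and never touches originals
pipeline_preproc <- function(config, x, y, split) {
  args <- config$preproc_args
  seed <- config$seed
  switch(config$preproc,
    none = list(x = x, y = y, split = split, state = NULL),
    ae = {
      fit <- do.call(autoencoder_fit_transform, c(
        list(X = x[split$train, , drop = FALSE], seed = seed),
        args))
      list(x = autoencoder_encode(fit$state, x), y = y, split = split,
           state = fit$state)
    },
    mhan = {
      fit <- do.call(mhan_transform, c(
        list(X = x[split$train, , drop = FALSE], labels = y[split$train],
             seed = seed),
        args))
      list(x = mhan_apply(fit$state, x), y = y, split = split,
           state = fit$state)
    },
    gan = {
      n_synth <- args$n_synth_per_class %||% 0L
      args$n_synth_per_class <- NULL
      aug <- do.call(gan_augment, c(
        list(X = x[split$train, , drop = FALSE], labels = y[split$train],
             n_synth_per_class = n_synth, seed = seed),
        args))
      synth <- aug$synthetic
      x_new <- rbind(x, aug$X_aug[synth, , drop = FALSE])
      y_new <- c(y, aug$labels_aug[synth])
      split_new <- list(train = c(split$train,
                                  nrow(x) + seq_len(sum(synth))),
                        test = split$test)
      list(x = x_new, y = y_new, split = split_new, state = aug$state)
    }
  )
}

#' @export
print.meth_run_report <- function(x, ...) {
  cat("Pipeline run:", x$manifest$model, "+", x$manifest$preproc,
      "preprocessing\n")
  cat(sprintf("Held-out: accuracy %.3f, AUROC %.3f, kappa %.3f\n",
              x$metrics$accuracy, x$metrics$auroc, x$agreement$kappa))
  invisible(x)
}

#' Validate a trained model on an external CG-site list
#'
#' Featurizes the listed sites exactly as at training time (same window
#' geometry, same motif columns, same frozen feature-analysis stage),
#' predicts their methylation status, and reports the confusion matrix,
#' threshold metrics, ranking areas, the chi-square independence test and
#' Cohen's kappa of observed vs predicted labels. Sites whose window runs
#' past a contig end are skipped and listed in the result. An optional
#' inter-quartile-range coverage filter (off by default) drops sites whose
#' coverage lies outside `1.5 IQR` of the quartiles, for lists that carry a
#' `coverage` column.
#'
#' @param model A trained `"meth_model"`.
#' @param genome Named character vector from [read_fasta()].
#' @param sites Tibble with columns `contig`, `position` (0-based C),
#'   `strand`, `label` (observed 0/1), optionally `coverage`.
#' @param preproc_state Optional fitted `"meth_autoencoder"` or
#'   `"meth_mhan"` from the training run.
#' @param flank Window flank used at training time (default 249).
#' @param threshold Classification threshold (default 0.5).
#' @param iqr_coverage_filter Apply the optional coverage outlier filter
#'   (default `FALSE`).
#' @return List of class `"meth_validation"`: `metrics`, `agreement`,
#'   `confusion`, `predictions` tibble, `skipped` (site ids whose windows
#'   were out of bounds or filtered).
#' @export
validate_sites <- function(model, genome, sites, preproc_state = NULL,
                           flank = 249L, threshold = 0.5,
                           iqr_coverage_filter = FALSE) {
  stopifnot(inherits(model, "meth_model"), is.data.frame(sites))
  need <- c("contig", "position", "strand", "label")
  missing <- setdiff(need, names(sites))
  if (length(missing)) {
    stop("site list lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  site_id <- paste(sites$contig, sites$position, sites$strand, sep = ":")
  skipped <- character()
  if (iqr_coverage_filter && "coverage" %in% names(sites)) {
    q <- stats::quantile(sites$coverage, c(0.25, 0.75))
    iqr <- q[2] - q[1]
    out <- sites$coverage < q[1] - 1.5 * iqr | sites$coverage > q[2] + 1.5 * iqr
    skipped <- c(skipped, site_id[out])
    sites <- sites[!out, , drop = FALSE]
    site_id <- site_id[!out]
  }
  windows <- purrr::pmap_chr(
    list(sites$contig, sites$position, sites$strand),
    function(contig, position, strand) {
      extract_window(genome, contig, position, strand, flank = flank)
    }
  )
  oob <- is.na(windows)
  skipped <- c(skipped, site_id[oob])
  sites <- sites[!oob, , drop = FALSE]
  site_id <- site_id[!oob]
  windows <- windows[!oob]
  if (!nrow(sites)) stop("no validatable sites remain", call. = FALSE)

  base_features <- if (!is.null(preproc_state)) preproc_state$feature_names
                   else model$feature_names
  counts <- count_motifs(windows, base_features)
  x <- counts
  if (!is.null(preproc_state)) {
    x <- if (inherits(preproc_state, "meth_autoencoder")) {
      autoencoder_encode(preproc_state, counts)
    } else if (inherits(preproc_state, "meth_mhan")) {
      mhan_apply(preproc_state, counts)
    } else if (inherits(preproc_state, "meth_gan")) {
      counts  # augmentation changes training rows, not featurization
    } else {
      stop("unrecognized preproc_state class", call. = FALSE)
    }
  }
  probs <- predict(model, x)
  predicted <- classify(probs, threshold)
  truth <- as.integer(sites$label)
  cm <- confusion_matrix(truth, predicted)
  metrics <- compute_metrics(cm)
  both_classes <- length(unique(truth)) == 2
  metrics$auroc <- if (both_classes) auroc(truth, probs) else NA_real_
  metrics$auprc <- if (both_classes) auprc(truth, probs) else NA_real_
  agreement <- dplyr::bind_cols(
    tryCatch(chi_square_test(cm),
             error = function(e) tibble::tibble(chi2 = NA_real_, df = 1L,
                                                p_value = NA_real_)),
    cohens_kappa(cm)
  )
  structure(
    list(metrics = metrics, agreement = agreement, confusion = cm,
         predictions = tibble::tibble(site_id = site_id, observed = truth,
                                      probability = probs,
                                      predicted = predicted),
         skipped = skipped),
    class = "meth_validation"
  )
}

#' @export
print.meth_validation <- function(x, ...) {
  cat("Validation on", nrow(x$predictions), "sites (",
      length(x$skipped), "skipped )\n")
  cat(sprintf("Accuracy %.3f, kappa %.3f, chi-square p %.3g\n",
              x$metrics$accuracy, x$agreement$kappa, x$agreement$p_value))
  invisible(x)
}
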