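#' Univariate K-best feature selection
#'
#' Scores every motif column against the binary label with a univariate
#' statistic and keeps the k highest-scoring features (ties broken toward the
#' lower column index, so selection is deterministic). Two scores are
#' offered: the one-way ANOVA F statistic between the two classes (default),
#' and a chi-square score for nonnegative count features that compares each
#' feature's per-class totals with the totals expected from the class
#' priors.
#'
#' @param features Feature tibble with a `label` column (see
#'   [build_dataset()]), or a plain numeric matrix plus `labels`.
#' @param k Number of features to keep (default 100).
#' @param score `"anova_f"` or `"chi2"`.
#' @param labels Binary labels; taken from `features$label` when omitted.
#' @return An object of class `"meth_kbest"`: list with `selected` (ordered
#'   character vector of kept feature names), `indices` (their original
#'   column positions), `scores` (per-feature numeric vector), `k`, `score`.
#' @export
kbest_select <- function(features, k = 100L, score = c("anova_f", "chi2"),
                         labels = NULL) {
  score <- match.arg(score)
  if (k <= 0) stop("k must be a positive integer", call. = FALSE)
  if (is.data.frame(features)) {
    if (is.null(labels)) labels <- features$label
    x <- feature_matrix(features)
  } else {
    x <- as.matrix(features)
  }
  if (is.null(labels)) {
    stop("labels are required (supply a 'label' column or the labels argument)",
         call. = FALSE)
  }
  stopifnot(length(labels) == nrow(x))
  if (length(unique(labels)) < 2) {
    stop("labels contain a single class; K-best needs both", call. = FALSE)
  }
  if (score == "chi2" && any(x < 0)) {
    stop("chi2 scoring requires nonnegative features", call. = FALSE)
  }
  s <- switch(score,
              anova_f = anova_f_score(x, labels),
              chi2 = chi2_score(x, labels))
  names(s) <- colnames(x)
  k_eff <- min(as.integer(k), ncol(x))
  # order by decreasing score, ties toward the lower index
  ord <- order(-s, seq_along(s))[seq_len(k_eff)]
  idx <- sort(ord)  # preserve original column order among the selected
  structure(
    list(selected = colnames(x)[idx], indices = idx, scores = s,
         k = k_eff, score = score),
    class = "meth_kbest"
  )
}

# one-way ANOVA F between the two label groups, vectorized over columns;
# zero within-group variance yields a 0 score (flat or degenerate feature)
anova_f_score <- function(x, labels) {
  groups <- split(seq_along(labels), labels)
  n <- nrow(x)
  g <- length(groups)
  grand <- colMeans(x)
  ssb <- rep(0, ncol(x))
  ssw <- rep(0, ncol(x))
  for (rows in groups) {
    xm <- x[rows, , drop = FALSE]
    mu <- colMeans(xm)
    ssb <- ssb + length(rows) * (mu - grand)^2
    ssw <- ssw + colSums(sweep(xm, 2, mu, "-")^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  # a feature with zero within-group variance but real separation is
  # infinitely significant and must rank first; only 0/0 (flat feature)
  # scores zero
  f[is.nan(f)] <- 0
  f
}

# per-class feature totals vs totals expected from the class priors
chi2_score <- function(x, labels) {
  classes <- sort(unique(labels))
  observed <- t(vapply(classes,
                       function(cl) colSums(x[labels == cl, , drop = FALSE]),
                       numeric(ncol(x))))
  priors <- vapply(classes, function(cl) mean(labels == cl), numeric(1))
  expected <- outer(priors, colSums(x))
  s <- colSums((observed - expected)^2 / expected)
  s[!is.finite(s)] <- 0
  s
}

#' Reduce a feature table to the selected columns
#'
#' @param features Feature tibble.
#' @param selection A `"meth_kbest"` object (or a character vector of
#'   feature names).
#' @return The tibble restricted to `site_id`, the selected features in
#'   their original order, and `label` if present.
#' @export
apply_selection <- function(features, selection) {
  keep <- if (inherits(selection, "meth_kbest")) selection$selected
          else as.character(selection)
  missing <- setdiff(keep, names(features))
  if (length(missing)) {
    stop("selected features absent from the table: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  cols <- c(intersect("site_id", names(features)), keep,
            intersect("label", names(features)))
  features[cols]
}

#' @export
print.meth_kbest <- function(x, ...) {
  cat("K-best selection:", x$k, "of", length(x$scores), "features by",
      x$score, "\nTop features:",
      paste(utils::head(x$selected[order(-x$scores[x$indices])], 5),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a K-best selection
#'
#' @param x A `"meth_kbest"` object.
#' @param ... Unused.
#' @return Tibble with one row per original feature: `feature`, `score`,
#'   `rank`, `selected`.
#' @export
tidy.meth_kbest <- function(x, ...) {
  tibble::tibble(
    feature = names(x$scores) %||% as.character(seq_along(x$scores)),
    score = unname(x$scores),
    rank = rank(-x$scores, ties.method = "first"),
    selected = seq_along(x$scores) %in% x$indices
  )
}
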