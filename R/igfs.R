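#' Shannon entropy in bits
#'
#' `-sum(p_i * log2(p_i))` over the observed classes, with `0 * log 0 = 0`.
#'
#' @param labels Non-empty vector of discrete labels.
#' @return Entropy in bits.
#' @export
entropy <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conditional entropy H(Y | X) in bits
#'
#' `sum_v P(X = v) * H(Y | X = v)` over the observed values of the discrete
#' feature.
#'
#' @param feature_values Discrete feature vector.
#' @param labels Label vector of the same length.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(feature_values, labels) {
  if (length(feature_values) != length(labels))
    stop("feature and labels have different lengths")
  n <- length(labels)
  groups <- split(labels, feature_values)
  sum(vapply(groups, function(g) length(g) / n * entropy(g), numeric(1)))
}

#' Information gain IG(X, Y) in bits
#'
#' The reduction in label entropy achieved by conditioning on the feature:
#' `H(Y) - H(Y | X)`. Tiny negative values arising from floating-point
#' rounding (magnitude below 1e-12) are clipped to zero.
#'
#' @inheritParams conditional_entropy
#' @return Information gain in bits.
#' @export
information_gain <- function(feature_values, labels) {
  ig <- entropy(labels) - conditional_entropy(feature_values, labels)
  if (ig < 0 && ig > -1e-12) ig <- 0
  ig
}

#' Fit a discretizer for a numeric column
#'
#' @param column Numeric vector.
#' @param bins Number of bins (>= 2).
#' @param strategy `"equal_width"` (default) or `"equal_frequency"`
#'   (quantile edges).
#' @return A `discretizer` with the fitted interior edges, reusable on
#'   held-out data via [discretize()].
#' @export
fit_discretizer <- function(column, bins = 10L,
                            strategy = c("equal_width", "equal_frequency")) {
  strategy <- match.arg(strategy)
  stopifnot(bins >= 2L)
  if (strategy == "equal_width") {
    lo <- min(column); hi <- max(column)
    if (lo == hi) {
      edges <- numeric(0)  # constant column: everything in bin 0
    } else {
      edges <- lo + (hi - lo) * seq_len(bins - 1L) / bins
    }
  } else {
    if (min(column) == max(column))
      stop("constant column cannot be discretized by equal frequency")
    edges <- unique(stats::quantile(column, probs = seq_len(bins - 1L) / bins,
                                    names = FALSE, type = 7))
  }
  structure(list(bins = as.integer(bins), strategy = strategy, edges = edges),
            class = "discretizer")
}

#' Discretize a numeric column with fitted edges
#'
#' Values are mapped to integer codes `0 .. bins-1` using the interior edges
#' fitted by [fit_discretizer()]; held-out values beyond the fitted range are
#' clipped into the end bins.
#'
#' @param column Numeric vector.
#' @param spec A `discretizer`.
#' @return Integer codes.
#' @export
discretize <- function(column, spec) {
  if (!length(spec$edges)) return(rep(0L, length(column)))
  findInterval(column, spec$edges, left.open = TRUE)
}

#' Information-gain feature selection
#'
#' Discretizes every numeric feature, computes the information gain of each
#' feature for the binary label, ranks features by decreasing gain (ties keep
#' the original column order) and marks as selected those whose gain exceeds
#' the threshold.
#'
#' @param X Feature matrix with column names (or a `tabular_dataset`, in
#'   which case `y` is taken from it).
#' @param y Binary 0/1 labels (ignored when `X` is a `tabular_dataset`).
#' @param bins Bins for numeric discretization (default 10, equal width).
#' @param strategy Discretization strategy, see [fit_discretizer()].
#' @param threshold_rule `"mean_ig"` (select gains above the mean gain,
#'   default), `"fixed"` (above `threshold_value`), or `"top_k"` (the `k`
#'   best by rank).
#' @param threshold_value Threshold in bits for `"fixed"`.
#' @param k Number of features for `"top_k"`.
#' @param schema Optional schema; categorical columns are used as-is,
#'   numeric ones discretized. Without a schema, columns with more than
#'   `bins` distinct values are treated as numeric.
#' @return A `feature_score_table`: data.frame with columns `name`,
#'   `information_gain`, `rank`, `selected`, plus attributes `threshold` and
#'   `discretizers`.
#' @export
select_features <- function(X, y = NULL, bins = 10L,
                            strategy = "equal_width",
                            threshold_rule = c("mean_ig", "fixed", "top_k"),
                            threshold_value = NULL, k = NULL, schema = NULL) {
  if (inherits(X, "tabular_dataset")) {
    if (is.null(schema)) schema <- X$schema
    y <- X$y
    X <- X$X
  }
  threshold_rule <- match.arg(threshold_rule)
  if (ncol(X) < 2L) stop("need at least 2 features")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))

  kinds <- if (!is.null(schema)) vapply(schema, `[[`, character(1), "kind")
  else ifelse(apply(X, 2, function(c) length(unique(c))) > bins,
              "numeric", "categorical")
  discretizers <- stats::setNames(vector("list", ncol(X)), colnames(X))
  ig <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (kinds[j] == "numeric") {
      discretizers[[j]] <- fit_discretizer(v, bins, strategy)
      v <- discretize(v, discretizers[[j]])
    }
    ig[j] <- information_gain(v, y)
  }

  ord <- order(-ig, seq_along(ig))  # stable tie-break by column order
  rank <- integer(length(ig)); rank[ord] <- seq_along(ig)

  selected <- switch(threshold_rule,
    mean_ig = {
      threshold <- mean(ig)
      ig > threshold
    },
    fixed = {
      if (is.null(threshold_value)) stop("fixed rule needs threshold_value")
      threshold <- threshold_value
      ig > threshold
    },
    top_k = {
      if (is.null(k)) stop("top_k rule needs k")
      if (all(ig == 0) && k > 0)
        warning("all information gains are zero; selecting the first ", k,
                " features by column order")
      threshold <- if (k < length(ig)) sort(ig, decreasing = TRUE)[k + 1] else -Inf
      rank <= k
    })

  tab <- data.frame(name = colnames(X), information_gain = ig,
                    rank = rank, selected = selected,
                    stringsAsFactors = FALSE)
  structure(tab[order(tab$rank), ],
            class = c("feature_score_table", "data.frame"),
            threshold = threshold, threshold_rule = threshold_rule,
            discretizers = discretizers)
}

#' Write a feature score table to JSON
#'
#' @param table A `feature_score_table`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  jsonlite::write_json(
    list(threshold = attr(table, "threshold"),
         threshold_rule = attr(table, "threshold_rule"),
         features = as.data.frame(table)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
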