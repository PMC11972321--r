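#' Explain a fitted classifier
#'
#' Model-agnostic explanation layer: global importance is the mean increase
#' in validation loss when each feature column is independently permuted
#' (`n_repeats` shuffles, with the standard deviation over repeats), and
#' local attribution is the central finite-difference sensitivity of the
#' predicted probability at individual samples. The information-gain ranking
#' of the same features is attached for cross-reference.
#'
#' @param model A `pcso_classifier` from [train_with_pcso()].
#' @param X Feature matrix to explain on (typically held-out data).
#' @param y Binary labels for `X`.
#' @param n_repeats Number of permutation repeats (>= 2).
#' @param seed Integer seed for the permutations.
#' @param local_samples Row indices for local sensitivities (default: the
#'   first `min(5, n)` rows).
#' @param fd_step Finite-difference half-step (default 1e-4; features are
#'   assumed z-scored).
#' @return An `explanation_report`: `global` data.frame (`name`,
#'   `importance`, `sd`, `ig`, `ig_rank`, ordered by importance),
#'   `local` matrix (samples x features), `base_loss`.
#' @export
explain <- function(model, X, y, n_repeats = 10L, seed = 1L,
                    local_samples = NULL, fd_step = 1e-4) {
  if (n_repeats < 2L) stop("n_repeats must be at least 2")
  spec <- model$spec
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  p_base <- forward(spec, model$weights, X, model$bn_stats)
  base_loss <- weighted_bce(p_base, y, spec$class_weight)

  set.seed(as.integer(seed))
  imp <- matrix(0, n_repeats, ncol(X))
  for (r in seq_len(n_repeats)) {
    for (j in seq_len(ncol(X))) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      pp <- forward(spec, model$weights, Xp, model$bn_stats)
      imp[r, j] <- weighted_bce(pp, y, spec$class_weight) - base_loss
    }
  }
  ig_tab <- select_features(X, y)
  ig_ord <- match(colnames(X), ig_tab$name)
  global <- data.frame(name = colnames(X),
                       importance = colMeans(imp),
                       sd = apply(imp, 2, stats::sd),
                       ig = ig_tab$information_gain[ig_ord],
                       ig_rank = ig_tab$rank[ig_ord],
                       stringsAsFactors = FALSE)
  global <- global[order(-global$importance), ]

  if (is.null(local_samples)) local_samples <- seq_len(min(5L, nrow(X)))
  local <- t(vapply(local_samples, function(i)
    local_sensitivity(model, X[i, ], fd_step), numeric(ncol(X))))
  rownames(local) <- local_samples
  colnames(local) <- colnames(X)

  structure(list(global = global, local = local, base_loss = base_loss,
                 n_repeats = n_repeats, seed = as.integer(seed)),
            class = "explanation_report")
}

#' Local finite-difference sensitivity of one sample
#'
#' Central difference `(f(x + h e_j) - f(x - h e_j)) / (2h)` of the
#' predicted probability with respect to each feature.
#'
#' @param model A `pcso_classifier`.
#' @param x Single feature vector.
#' @param fd_step Half-step `h`.
#' @return Sensitivity vector, one entry per feature.
#' @export
local_sensitivity <- function(model, x, fd_step = 1e-4) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + fd_step
    xm[j] <- xm[j] - fd_step
    (forward(model$spec, model$weights, matrix(xp, 1), model$bn_stats) -
       forward(model$spec, model$weights, matrix(xm, 1), model$bn_stats)) /
      (2 * fd_step)
  }, numeric(1))
}

#' Write an explanation report to JSON
#'
#' @param report An `explanation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_explanation <- function(report, path) {
  jsonlite::write_json(
    list(global = report$global,
         local = as.data.frame(report$local),
         base_loss = report$base_loss, n_repeats = report$n_repeats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.explanation_report <- function(x, ...) {
  cat("explanation_report: top features by permutation importance\n")
  print(utils::head(x$global, 5))
  invisible(x)
}
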