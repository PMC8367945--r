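# Diagnostic panel selection.
#
# Two resampling procedures run on the training plasma cohort and their
# selected marker sets are intersected:
#   * repeated LASSO: on each of `n_reps` stratified half-subsamples an
#     L1-penalized logistic model is fit with an internally cross-validated
#     penalty (one-standard-error rule); markers selected in strictly more
#     than `count_threshold` repetitions qualify (stability selection);
#   * repeated 2-fold cross-validated random forests: per repetition the
#     samples are split into two stratified folds, a forest is fit on each,
#     and impurity importances are averaged over all fits; the `top_k`
#     markers by mean importance qualify.

#' LASSO selection-frequency stability
#'
#' @param x Markers x samples matrix of methylation levels.
#' @param labels Per-sample group labels (`"cancer"`/`"control"`).
#' @param n_reps Number of half-subsample repetitions (default 500).
#' @param count_threshold Markers qualify when selected in strictly more
#'   repetitions than this (default 60% of `n_reps`, i.e. 300 of 500).
#' @param nfolds Internal cross-validation folds for the penalty path.
#' @param seed Integer seed; the whole procedure is a pure function of
#'   `(x, labels, seed)`.
#' @return Data frame with `marker_id`, `lasso_count`, `lasso_selected`.
#' @export
lasso_stability <- function(x, labels, n_reps = 500L,
                            count_threshold = round(0.6 * n_reps),
                            nfolds = 5L, seed = 1L) {
  stopifnot(is.matrix(x))
  labels <- check_group_labels(labels, ncol(x))
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  counts <- stats::setNames(integer(nrow(x)), rownames(x))
  if (n_reps > 0L) {
    withr::with_seed(as.integer(seed), {
      for (rep in seq_len(n_reps)) {
        for (try in 1:10) {
          idx <- stratified_half(labels)
          if (length(unique(labels[idx])) == 2L && min(table(labels[idx])) >= nfolds) break
          message("degenerate subsample redrawn (repetition ", rep, ")")
        }
        cv <- glmnet::cv.glmnet(
          t(x[, idx, drop = FALSE]), factor(labels[idx]),
          family = "binomial", nfolds = nfolds,
          type.measure = "deviance", standardize = TRUE
        )
        beta <- stats::coef(cv, s = "lambda.1se")[-1, 1]
        hit <- names(beta)[beta != 0]
        counts[hit] <- counts[hit] + 1L
      }
    })
  }
  data.frame(
    marker_id = names(counts),
    lasso_count = as.integer(counts),
    lasso_selected = counts > count_threshold,
    stringsAsFactors = FALSE
  )
}

#' Repeated cross-validated random-forest importance stability
#'
#' @inheritParams lasso_stability
#' @param n_folds Folds per repetition (default 2; a forest is fit on each
#'   fold).
#' @param n_reps Number of repetitions (default 20).
#' @param top_k Number of top markers by mean impurity importance retained.
#' @param num_trees Trees per forest.
#' @param importance Importance measure passed to the forest
#'   (`"impurity"` default, `"permutation"` available).
#' @return Data frame with `marker_id`, `rf_importance` (mean over all fits),
#'   `rf_rank` (ties broken by marker id), `rf_selected`.
#' @export
rf_importance_stability <- function(x, labels, n_folds = 2L, n_reps = 20L,
                                    top_k = 50L, num_trees = 500L,
                                    importance = c("impurity", "permutation"),
                                    seed = 1L) {
  stopifnot(is.matrix(x))
  importance <- match.arg(importance)
  labels <- check_group_labels(labels, ncol(x))
  if (min(table(labels)) < n_folds) {
    stop("each class needs at least `n_folds` samples", call. = FALSE)
  }
  if (top_k > nrow(x)) {
    warning("`top_k` exceeds the number of markers; selecting all markers")
    top_k <- nrow(x)
  }
  imp <- stats::setNames(numeric(nrow(x)), rownames(x))
  n_fits <- 0L
  withr::with_seed(as.integer(seed), {
    for (rep in seq_len(n_reps)) {
      fold <- unlist(lapply(split(seq_along(labels), labels), function(i) {
        stats::setNames(sample(rep_len(seq_len(n_folds), length(i))), i)
      }), use.names = FALSE)
      fold_of <- integer(length(labels))
      fold_of[unlist(split(seq_along(labels), labels), use.names = FALSE)] <- fold
      for (f in seq_len(n_folds)) {
        sel <- fold_of == f
        fit <- ranger::ranger(
          x = t(x[, sel, drop = FALSE]), y = factor(labels[sel]),
          num.trees = num_trees, importance = importance,
          seed = sample.int(.Machine$integer.max, 1L), num.threads = 1L
        )
        imp <- imp + fit$variable.importance[names(imp)]
        n_fits <- n_fits + 1L
      }
    }
  })
  mean_imp <- if (n_fits > 0L) imp / n_fits else imp
  ord <- order(-mean_imp, names(mean_imp))
  rk <- integer(length(mean_imp))
  rk[ord] <- seq_along(ord)
  data.frame(
    marker_id = names(mean_imp),
    rf_importance = as.numeric(mean_imp),
    rf_rank = rk,
    rf_selected = rk <= top_k,
    stringsAsFactors = FALSE
  )
}

#' Intersect the LASSO and random-forest selections
#'
#' @param lasso Output of [lasso_stability()].
#' @param rf Output of [rf_importance_stability()] on the same marker set.
#' @return Data frame combining both (one row per marker) with the `final`
#'   flag; the final panel (ordered by forest importance rank) is attached as
#'   attribute `panel`. An empty intersection triggers a warning.
#' @export
intersect_panels <- function(lasso, rf) {
  stopifnot(is.data.frame(lasso), is.data.frame(rf))
  if (!setequal(lasso$marker_id, rf$marker_id)) {
    stop("LASSO and forest selections cover different marker sets", call. = FALSE)
  }
  out <- merge(lasso, rf, by = "marker_id", sort = FALSE)
  out$final <- out$lasso_selected & out$rf_selected
  panel <- out$marker_id[out$final][order(out$rf_rank[out$final])]
  if (!length(panel)) {
    warning("LASSO and random-forest selections do not overlap: empty panel")
  }
  attr(out, "panel") <- panel
  out
}

#' Run the full stability-selection panel procedure
#'
#' Convenience wrapper chaining [lasso_stability()],
#' [rf_importance_stability()] and [intersect_panels()].
#'
#' @inheritParams lasso_stability
#' @param lasso_reps,lasso_threshold LASSO repetitions and strict count
#'   threshold.
#' @param rf_reps,rf_topk,rf_num_trees Forest repetitions, top-k cut and
#'   forest size.
#' @return List with `stability` (per-marker table), `panel` (character
#'   vector) and `provenance` (parameters and seed).
#' @export
select_panel <- function(x, labels, lasso_reps = 500L,
                         lasso_threshold = round(0.6 * lasso_reps),
                         rf_reps = 20L, rf_topk = 50L, rf_num_trees = 500L,
                         seed = 1L) {
  las <- lasso_stability(x, labels, n_reps = lasso_reps,
                         count_threshold = lasso_threshold, seed = seed)
  rf <- rf_importance_stability(x, labels, n_reps = rf_reps, top_k = rf_topk,
                                num_trees = rf_num_trees, seed = seed + 1L)
  stab <- intersect_panels(las, rf)
  list(
    stability = stab,
    panel = attr(stab, "panel"),
    provenance = list(
      lasso_reps = lasso_reps, lasso_threshold = lasso_threshold,
      lasso_resampling = "stratified 50% subsample, 5-fold CV, 1se rule",
      rf_reps = rf_reps, rf_folds = 2L, rf_topk = rf_topk,
      rf_num_trees = rf_num_trees, rf_importance = "impurity",
      seed = as.integer(seed)
    )
  )
}
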