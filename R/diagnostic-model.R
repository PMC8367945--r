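# Diagnostic modelling and evaluation.
#
# A probability random forest is trained on the selected marker panel; its
# decision threshold is fixed on training data only, by maximizing Youden's J
# (sensitivity + specificity - 1) over out-of-bag scores. Evaluation reports
# AUROC (rank statistic, DeLong CI), AUPRC (step-wise precision-recall
# integration, stratified bootstrap CI), Clopper-Pearson intervals for
# sensitivity/specificity, confusion counts and per-stage sensitivity.

POSITIVE <- "cancer"
NEGATIVE <- "control"
STAGE_LEVELS <- c("0", "I", "II", "III", "IV")

#' Train the random-forest diagnostic model on a marker panel
#'
#' @param x Markers x samples matrix of methylation levels.
#' @param labels Per-sample labels (`"cancer"`/`"control"`).
#' @param panel Non-empty character vector of marker ids (subset of
#'   `rownames(x)`).
#' @param seed Integer seed (the fit is deterministic given it).
#' @param num_trees Number of trees.
#' @return A `panel_model`: list with `panel`, `forest`, `threshold` (Youden
#'   optimal on out-of-bag scores; among ties the largest threshold, favouring
#'   specificity), `medians` (training medians for imputation at prediction
#'   time) and `provenance`.
#' @export
train_classifier <- function(x, labels, panel, seed = 1L, num_trees = 500L) {
  stopifnot(is.matrix(x))
  labels <- check_group_labels(labels, ncol(x))
  if (!length(panel)) stop("refusing to train on an empty panel", call. = FALSE)
  missing_ids <- setdiff(panel, rownames(x))
  if (length(missing_ids)) {
    stop("panel markers absent from matrix: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training requires both classes", call. = FALSE)
  }
  xp <- x[panel, , drop = FALSE]
  medians <- apply(xp, 1, stats::median, na.rm = TRUE)
  xp <- impute_by_row(xp, medians)
  y <- factor(labels, levels = c(NEGATIVE, POSITIVE))
  fit <- ranger::ranger(
    x = t(xp), y = y, probability = TRUE, num.trees = num_trees,
    seed = as.integer(seed), num.threads = 1L
  )
  oob <- fit$predictions[, POSITIVE]
  threshold <- youden_threshold(oob, labels == POSITIVE)
  structure(list(
    panel = panel,
    forest = fit,
    threshold = threshold,
    medians = medians,
    provenance = list(
      seed = as.integer(seed), num_trees = as.integer(num_trees),
      n_train = ncol(x), class_counts = as.list(table(labels)),
      threshold_rule = "Youden J on out-of-bag scores"
    )
  ), class = "panel_model")
}

impute_by_row <- function(x, medians) {
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) {
    x[nas] <- medians[nas[, 1]]
  }
  x
}

# Youden-optimal threshold over observed score cut points; classification is
# score >= threshold. Ties on J resolve to the largest threshold.
youden_threshold <- function(scores, is_pos) {
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    mean(scores[is_pos] >= t) + mean(scores[!is_pos] < t) - 1
  }, numeric(1))
  max(cand[j == max(j)])
}

#' @export
print.panel_model <- function(x, ...) {
  cat("Diagnostic panel model\n")
  cat("  markers:   ", length(x$panel), "\n")
  cat("  threshold: ", format(x$threshold, digits = 4), "\n")
  cat("  training:  ", x$provenance$n_train, "samples\n")
  invisible(x)
}

#' Predict case probabilities for new samples
#'
#' @param model A `panel_model`.
#' @param x Markers x samples matrix containing every panel marker (missing
#'   marker columns are a hard error; missing values are imputed by training
#'   medians with a message).
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "panel_model"), is.matrix(x))
  missing_ids <- setdiff(model$panel, rownames(x))
  if (length(missing_ids)) {
    stop("matrix lacks panel marker(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(x) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  xp <- x[model$panel, , drop = FALSE]
  if (anyNA(xp)) {
    message("imputing ", sum(is.na(xp)), " missing value(s) by training medians")
    xp <- impute_by_row(xp, model$medians)
  }
  pred <- stats::predict(model$forest, data = t(xp), num.threads = 1L)
  stats::setNames(pred$predictions[, POSITIVE], colnames(x))
}

#' AUROC with DeLong confidence interval
#'
#' The point estimate is the Mann-Whitney rank statistic (ties counted 1/2);
#' the 95% CI uses DeLong's variance estimate.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels `"cancer"`/`"control"` per sample.
#' @return List with `auroc`, `ci` (length-2, 95%).
#' @export
roc_analysis <- function(scores, labels) {
  labels <- check_group_labels(labels, length(scores))
  auroc <- rank_auc(scores, labels == POSITIVE)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(NEGATIVE, POSITIVE), direction = "<", quiet = TRUE)
  # pROC warns that the DeLong CI at AUC == 1 degenerates to [1, 1]
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
  list(auroc = auroc, ci = pmin(1, pmax(0, ci)))
}

# Step-wise precision-recall integration (average precision). Tied scores are
# handled as one block using the precision at the block's lower edge, so a
# constant classifier scores exactly the prevalence.
average_precision <- function(scores, is_pos) {
  n_pos <- sum(is_pos)
  if (n_pos == 0L) stop("AUPRC requires at least one positive sample", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  y <- is_pos[o]
  s <- scores[o]
  block <- cumsum(!duplicated(s))
  tp_block <- tapply(y, block, sum)
  n_block <- tapply(y, block, length)
  cum_tp <- cumsum(tp_block)
  cum_n <- cumsum(n_block)
  prec <- cum_tp / cum_n
  sum(tp_block * prec) / n_pos
}

#' AUPRC with stratified bootstrap confidence interval
#'
#' @inheritParams roc_analysis
#' @param n_boot Bootstrap resamples (cases and controls resampled
#'   separately).
#' @param seed Integer seed for the bootstrap.
#' @return List with `auprc`, `ci` (95% percentile).
#' @export
pr_analysis <- function(scores, labels, n_boot = 2000L, seed = 1L) {
  labels <- check_group_labels(labels, length(scores))
  is_pos <- labels == POSITIVE
  est <- average_precision(scores, is_pos)
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      sp <- sample(pos, replace = TRUE)
      sn <- sample(neg, replace = TRUE)
      average_precision(c(sp, sn), c(rep(TRUE, length(sp)), rep(FALSE, length(sn))))
    }, numeric(1))
  })
  list(auprc = est, ci = as.numeric(stats::quantile(boots, c(0.025, 0.975))))
}

#' Evaluate a diagnostic model on a cohort
#'
#' @param model A `panel_model`.
#' @param x Markers x samples matrix.
#' @param labels `"cancer"`/`"control"` per sample.
#' @param stages Optional per-sample stage labels (`0`, `I`-`IV`) for cancer
#'   samples; unknown/missing stages are reported under `"NA"`.
#' @param seed Seed for the AUPRC bootstrap.
#' @return An `eval_report`: confusion counts, sensitivity/specificity with
#'   Clopper-Pearson 95% CIs, AUROC/AUPRC with CIs, per-stage
#'   (n_correct, n_total) and the pooled sensitivity over staged samples.
#' @export
evaluate <- function(model, x, labels, stages = NULL, seed = 1L) {
  labels <- check_group_labels(labels, ncol(x))
  scores <- predict_scores(model, x)
  pred_pos <- scores >= model$threshold
  is_pos <- labels == POSITIVE
  tp <- sum(pred_pos & is_pos)
  fn <- sum(!pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos)
  fp <- sum(pred_pos & !is_pos)
  sens_ci <- stats::binom.test(tp, tp + fn)$conf.int
  spec_ci <- stats::binom.test(tn, tn + fp)$conf.int
  per_stage <- NULL
  if (!is.null(stages)) {
    stages <- as.character(stages)
    if (length(stages) != ncol(x)) {
      stop("`stages` length must match the number of samples", call. = FALSE)
    }
    st <- stages[is_pos]
    st[!(st %in% STAGE_LEVELS)] <- "NA"
    st <- factor(st, levels = c(intersect(STAGE_LEVELS, st), intersect("NA", st)))
    per_stage <- data.frame(
      stage = levels(st),
      n_correct = as.integer(tapply(pred_pos[is_pos], st, sum)),
      n_total = as.integer(table(st)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    sensitivity = tp / (tp + fn), sensitivity_ci = as.numeric(sens_ci),
    specificity = tn / (tn + fp), specificity_ci = as.numeric(spec_ci),
    roc = roc_analysis(scores, labels),
    pr = pr_analysis(scores, labels, seed = seed),
    per_stage = per_stage,
    scores = scores,
    threshold = model$threshold
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f%%", round_half_up(100 * v, 2))
  cat("Diagnostic evaluation\n")
  cat(sprintf("  sensitivity: %s (95%% CI: %s-%s)\n", pct(x$sensitivity),
              pct(x$sensitivity_ci[1]), pct(x$sensitivity_ci[2])))
  cat(sprintf("  specificity: %s (95%% CI: %s-%s)\n", pct(x$specificity),
              pct(x$specificity_ci[1]), pct(x$specificity_ci[2])))
  cat(sprintf("  AUROC: %.4f (95%% CI: %s-%s)\n", x$roc$auroc,
              pct(x$roc$ci[1]), pct(x$roc$ci[2])))
  cat(sprintf("  AUPRC: %.4f (95%% CI: %s-%s)\n", x$pr$auprc,
              pct(x$pr$ci[1]), pct(x$pr$ci[2])))
  if (!is.null(x$per_stage)) {
    for (i in seq_len(nrow(x$per_stage))) {
      cat(sprintf("  stage %-3s sensitivity: %s (%d/%d)\n",
                  x$per_stage$stage[i],
                  pct(x$per_stage$n_correct[i] / x$per_stage$n_total[i]),
                  x$per_stage$n_correct[i], x$per_stage$n_total[i]))
    }
  }
  invisible(x)
}

#' Pool per-stage correct/total counts into an overall sensitivity
#'
#' @param counts Data frame with columns `n_correct`, `n_total` (or a list of
#'   length-2 vectors `c(n_correct, n_total)`).
#' @return Pooled sensitivity as a percentage rounded (half away from zero)
#'   to two decimals.
#' @export
pool_stage_counts <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    if (!length(counts)) stop("no stage counts to pool", call. = FALSE)
    counts <- do.call(rbind, lapply(counts, function(v) {
      data.frame(n_correct = v[1], n_total = v[2])
    }))
  }
  stopifnot(is.data.frame(counts), all(c("n_correct", "n_total") %in% names(counts)))
  if (!nrow(counts)) stop("no stage counts to pool", call. = FALSE)
  if (any(counts$n_total <= 0)) stop("stage totals must be positive", call. = FALSE)
  if (any(counts$n_correct < 0 | counts$n_correct > counts$n_total)) {
    stop("n_correct must lie in [0, n_total]", call. = FALSE)
  }
  round_half_up(100 * sum(counts$n_correct) / sum(counts$n_total), 2)
}

#' Univariate diagnostic power of each marker
#'
#' Each marker is scored by a single-covariate logistic regression; because
#' the fitted probability is monotone in the covariate, its AUROC equals the
#' raw marker AUROC oriented by the sign of the coefficient. Both values are
#' reported.
#'
#' @param x Markers x samples matrix.
#' @param labels `"cancer"`/`"control"` per sample.
#' @return Data frame with `marker_id`, `auc_logistic`, `auc_oriented`,
#'   `direction` (`hyper` when higher levels are case-like).
#' @export
univariate_marker_auc <- function(x, labels) {
  stopifnot(is.matrix(x))
  labels <- check_group_labels(labels, ncol(x))
  if (length(unique(labels)) < 2L) stop("both classes required", call. = FALSE)
  y <- as.integer(labels == POSITIVE)
  is_pos <- labels == POSITIVE
  rows <- lapply(rownames(x), function(id) {
    v <- x[id, ]
    if (length(unique(v[!is.na(v)])) <= 1L) {
      return(data.frame(marker_id = id, auc_logistic = 0.5, auc_oriented = 0.5,
                        direction = "hyper", stringsAsFactors = FALSE))
    }
    fit <- suppressWarnings(stats::glm(y ~ v, family = stats::binomial()))
    beta <- stats::coef(fit)[["v"]]
    auc_fit <- rank_auc(stats::fitted(fit), is_pos)
    auc_raw <- rank_auc(v, is_pos)
    oriented <- if (!is.na(beta) && beta < 0) 1 - auc_raw else auc_raw
    data.frame(marker_id = id, auc_logistic = auc_fit, auc_oriented = oriented,
               direction = if (!is.na(beta) && beta < 0) "hypo" else "hyper",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the top markers by univariate AUROC
#'
#' @param auc_table Output of [univariate_marker_auc()].
#' @param min_auc Markers must exceed this oriented AUROC (strict).
#' @param k Number of markers to keep; if fewer qualify, all qualifying are
#'   returned with a warning. Ties at the cut resolve lexicographically by
#'   marker id.
#' @return Character vector of marker ids, best first.
#' @export
select_top_markers <- function(auc_table, min_auc = 0.75, k = 4L) {
  stopifnot(is.data.frame(auc_table),
            all(c("marker_id", "auc_oriented") %in% names(auc_table)))
  if (!nrow(auc_table)) stop("`auc_table` is empty", call. = FALSE)
  qual <- auc_table[auc_table$auc_oriented > min_auc, , drop = FALSE]
  qual <- qual[order(-qual$auc_oriented, qual$marker_id), , drop = FALSE]
  if (nrow(qual) < k) {
    warning("only ", nrow(qual), " marker(s) exceed AUROC ", min_auc)
  }
  utils::head(qual$marker_id, k)
}

#' Train a combined methylation + mammography model
#'
#' The binary mammography reading joins the panel markers as one additional
#' feature of the forest; training and thresholding are otherwise identical
#' to [train_classifier()].
#'
#' @param x Markers x samples matrix.
#' @param mammography Numeric 0/1 calls per sample (no missing values).
#' @param labels `"cancer"`/`"control"`.
#' @param panel Marker panel.
#' @param seed,num_trees Forest parameters.
#' @return A `panel_model` whose panel includes the pseudo-marker
#'   `"mammography_call"`. Evaluate it on a matrix augmented with
#'   [augment_with_mammography()].
#' @export
combine_with_mammography <- function(x, mammography, labels, panel,
                                     seed = 1L, num_trees = 500L) {
  aug <- augment_with_mammography(x, mammography)
  train_classifier(aug, labels, c(panel, "mammography_call"),
                   seed = seed, num_trees = num_trees)
}

#' Append the mammography call as a pseudo-marker row
#'
#' @inheritParams combine_with_mammography
#' @return Matrix with one extra row `"mammography_call"`.
#' @export
augment_with_mammography <- function(x, mammography) {
  stopifnot(is.matrix(x))
  if (length(mammography) != ncol(x) || anyNA(mammography) ||
      !all(mammography %in% c(0, 1))) {
    stop("`mammography` must be a complete 0/1 vector, one call per sample",
         call. = FALSE)
  }
  rbind(x, mammography_call = as.numeric(mammography))
}

#' Compare two score vectors by paired bootstrap of the AUROC difference
#'
#' Samples are resampled with replacement within each class; both AUROCs are
#' recomputed on each resample. The two-sided p-value comes from recentring
#' the bootstrap differences at zero; the effect size is the observed AUROC
#' difference divided by the bootstrap SD of the difference (a Cohen's-d
#' analogue; method recorded in the result).
#'
#' @param scores_a,scores_b Score vectors over the same samples.
#' @param labels `"cancer"`/`"control"` per sample.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `auc_a`, `auc_b`, `delta`, `p_value`, `effect_size`,
#'   `method`.
#' @export
compare_auc <- function(scores_a, scores_b, labels, n_boot = 2000L, seed = 1L) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must cover the same samples", call. = FALSE)
  }
  labels <- check_group_labels(labels, length(scores_a))
  is_pos <- labels == POSITIVE
  auc_a <- rank_auc(scores_a, is_pos)
  auc_b <- rank_auc(scores_b, is_pos)
  obs <- auc_a - auc_b
  pos_idx <- which(is_pos)
  neg_idx <- which(!is_pos)
  diffs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(pos_idx, replace = TRUE), sample(neg_idx, replace = TRUE))
      ip <- c(rep(TRUE, length(pos_idx)), rep(FALSE, length(neg_idx)))
      rank_auc(scores_a[idx], ip) - rank_auc(scores_b[idx], ip)
    }, numeric(1))
  })
  sd_d <- stats::sd(diffs)
  centred <- diffs - mean(diffs)
  p <- (1 + sum(abs(centred) >= abs(obs))) / (n_boot + 1)
  list(
    auc_a = auc_a, auc_b = auc_b, delta = obs,
    p_value = if (sd_d == 0 && obs == 0) 1 else p,
    effect_size = if (sd_d > 0) obs / sd_d else 0,
    method = "stratified paired bootstrap"
  )
}
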