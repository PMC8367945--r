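# End-to-end pipeline on a synthetic cohort.
#
# Chains every stage of the diagnostic workflow: simulate paired tissue ->
# discover markers -> simulate matched plasma -> concordance filter ->
# simulate the case/control plasma cohort -> split train/validation/test ->
# stability-selection panel -> train the forest -> stage-stratified
# evaluation -> simplified (top-4 / top-1) models -> mammography combination
# and AUROC comparison -> clinicopathologic association scan. Fully
# deterministic given the configuration seed.

#' Run the full diagnostic pipeline on a synthetic cohort
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param split Named integer vector of train/validation/test weights per
#'   cohort; defaults mirror a 160/69/104 sample split and are rescaled to
#'   the configured cohort sizes, stratified by group.
#' @param lasso_reps,rf_reps,rf_topk Panel-selection effort; the default
#'   LASSO repetition count is 100 (the procedure's selection threshold stays
#'   at 60% of repetitions).
#' @param num_trees Forest size for selection and modelling.
#' @param outdir Optional directory; when given, per-stage artifacts (TSV
#'   matrices, marker statistics, panel, JSON report) are written there.
#' @return List with per-stage results: `discovery`, `concordance`,
#'   `retained`, `selection`, `model`, `eval_validation`, `eval_test`,
#'   `univariate`, `top4`, `eval_top4`, `eval_top1`, `combined`,
#'   `auc_comparison`, `association`, `truth`, `provenance`.
#' @export
run_pipeline <- function(config = sim_config(),
                         split = c(train = 160L, validation = 69L, test = 104L),
                         lasso_reps = 100L, rf_reps = 20L, rf_topk = 50L,
                         num_trees = 500L, outdir = NULL) {
  config <- validate_sim_config(config)
  stopifnot(all(c("train", "validation", "test") %in% names(split)))
  seed <- config$seed

  ## 1. tissue discovery
  tp <- simulate_tissue_pairs(config)
  disc <- discover_markers(tp$tumour, tp$normal)
  candidates <- disc$marker_id[disc$pass]
  if (length(candidates) < 2L) {
    stop("pipeline stage 'discover': fewer than 2 candidate markers", call. = FALSE)
  }

  ## 2. matched tissue/plasma concordance
  plasma_matched <- simulate_matched_plasma(tp$tumour, noise_sd = config$noise_sd,
                                            seed = seed + 11L)
  pairs <- data.frame(tissue_id = colnames(tp$tumour),
                      plasma_id = colnames(plasma_matched),
                      stringsAsFactors = FALSE)
  conc <- moderated_paired_t(tp$tumour[candidates, , drop = FALSE],
                             plasma_matched[candidates, , drop = FALSE], pairs)
  retained <- filter_concordant(conc)
  if (length(retained) < 2L) {
    stop("pipeline stage 'concordance': fewer than 2 markers retained", call. = FALSE)
  }

  ## 3. plasma cohort and split
  cohort <- simulate_plasma_cohort(config, tp$truth)
  clin <- cohort$clinical
  assign_split <- function(ids) {
    w <- split / sum(split)
    n <- length(ids)
    counts <- floor(w * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      top_up <- order(w * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[top_up] <- counts[top_up] + 1L
    }
    sample(rep(names(split), counts))
  }
  clin$cohort <- NA_character_
  clin$cohort[clin$group == "cancer"] <-
    withr::with_seed(seed + 21L, assign_split(clin$sample_id[clin$group == "cancer"]))
  clin$cohort[clin$group == "control"] <-
    withr::with_seed(seed + 22L, assign_split(clin$sample_id[clin$group == "control"]))
  x <- cohort$levels[retained, , drop = FALSE]
  sub <- function(which) {
    ids <- clin$sample_id[clin$cohort == which]
    list(x = x[, ids, drop = FALSE],
         labels = clin$group[match(ids, clin$sample_id)],
         stages = clin$stage[match(ids, clin$sample_id)],
         mammo = clin$mammography_call[match(ids, clin$sample_id)])
  }
  train <- sub("train")
  val <- sub("validation")
  test <- sub("test")

  ## 4. panel selection + model
  selection <- select_panel(train$x, train$labels, lasso_reps = lasso_reps,
                            rf_reps = rf_reps, rf_topk = rf_topk,
                            rf_num_trees = num_trees, seed = seed + 31L)
  if (!length(selection$panel)) {
    stop("pipeline stage 'select-panel': empty panel, refusing to train", call. = FALSE)
  }
  model <- train_classifier(train$x, train$labels, selection$panel,
                            seed = seed + 41L, num_trees = num_trees)
  eval_validation <- evaluate(model, val$x, val$labels, val$stages, seed = seed + 42L)
  eval_test <- evaluate(model, test$x, test$labels, test$stages, seed = seed + 43L)

  ## 5. simplified models
  uni <- univariate_marker_auc(train$x[selection$panel, , drop = FALSE], train$labels)
  top4 <- select_top_markers(uni, min_auc = 0.75, k = 4L)
  eval_top4 <- eval_top1 <- NULL
  if (length(top4)) {
    model4 <- train_classifier(train$x, train$labels, top4,
                               seed = seed + 44L, num_trees = num_trees)
    eval_top4 <- evaluate(model4, val$x, val$labels, val$stages, seed = seed + 45L)
    model1 <- train_classifier(train$x, train$labels, top4[1],
                               seed = seed + 46L, num_trees = num_trees)
    eval_top1 <- evaluate(model1, val$x, val$labels, val$stages, seed = seed + 47L)
  }

  ## 6. mammography comparison and combined model
  all_ids <- clin$sample_id
  scores_meth <- predict_scores(model, x[, all_ids, drop = FALSE])
  mammo_all <- clin$mammography_call
  auc_comparison <- compare_auc(scores_meth, mammo_all, clin$group,
                                seed = seed + 51L)
  combined_model <- combine_with_mammography(train$x, train$mammo, train$labels,
                                             selection$panel, seed = seed + 52L,
                                             num_trees = num_trees)
  holdout_ids <- clin$sample_id[clin$cohort != "train"]
  ho <- list(x = x[, holdout_ids, drop = FALSE],
             labels = clin$group[match(holdout_ids, clin$sample_id)],
             stages = clin$stage[match(holdout_ids, clin$sample_id)],
             mammo = clin$mammography_call[match(holdout_ids, clin$sample_id)])
  eval_combined <- evaluate(combined_model,
                            augment_with_mammography(ho$x, ho$mammo),
                            ho$labels, ho$stages, seed = seed + 53L)
  eval_base_holdout <- evaluate(model, ho$x, ho$labels, ho$stages, seed = seed + 54L)

  ## 7. clinicopathologic associations over the panel
  panel_dirs <- disc[disc$marker_id %in% selection$panel,
                     c("marker_id", "direction")]
  burden <- methylation_burden(cohort$levels, panel_dirs)
  association <- association_scan(burden, clin)

  report <- list(
    discovery = disc,
    concordance = conc,
    retained = retained,
    selection = selection,
    model = model,
    eval_validation = eval_validation,
    eval_test = eval_test,
    univariate = uni,
    top4 = top4,
    eval_top4 = eval_top4,
    eval_top1 = eval_top1,
    combined = list(model = combined_model, eval = eval_combined,
                    eval_base = eval_base_holdout),
    auc_comparison = auc_comparison,
    association = association,
    truth = tp$truth,
    clinical = clin,
    provenance = list(
      seed = seed, config = unclass(config)[setdiff(names(config), "stage_probs")],
      split = as.list(split), lasso_reps = lasso_reps, rf_reps = rf_reps,
      rf_topk = rf_topk, num_trees = num_trees
    )
  )
  if (!is.null(outdir)) {
    write_pipeline_artifacts(report, cohort, outdir)
  }
  report
}

write_pipeline_artifacts <- function(report, cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = report$provenance$seed)
  write_meth_matrix(cohort$levels, file.path(outdir, "plasma_matrix.tsv"), prov)
  write_clinical(report$clinical, file.path(outdir, "clinical.csv"), prov)
  utils::write.table(report$discovery, file.path(outdir, "marker_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$selection$stability, file.path(outdir, "stability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$selection$panel, file.path(outdir, "panel.txt"))
  summary <- list(
    panel_size = length(report$selection$panel),
    validation = eval_summary(report$eval_validation),
    test = eval_summary(report$eval_test),
    combined = eval_summary(report$combined$eval),
    auc_comparison = report$auc_comparison[c("auc_a", "auc_b", "delta",
                                             "p_value", "effect_size")],
    provenance = report$provenance
  )
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

eval_summary <- function(ev) {
  if (is.null(ev)) {
    return(NULL)
  }
  list(
    sensitivity = ev$sensitivity, specificity = ev$specificity,
    auroc = ev$roc$auroc, auprc = ev$pr$auprc,
    confusion = as.list(ev$confusion),
    per_stage = ev$per_stage
  )
}
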