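# Compact separable training fixture over a handful of markers.
model_fixture <- function(n_markers = 6, n_cancer = 40, n_control = 30,
                          delta = 0.35, seed = 71) {
  set.seed(seed)
  ids <- sprintf("mk%02d", seq_len(n_markers))
  n <- n_cancer + n_control
  x <- matrix(runif(n_markers * n, 0.2, 0.6), n_markers, n,
              dimnames = list(ids, sprintf("s%03d", seq_len(n))))
  labels <- rep(c("cancer", "control"), c(n_cancer, n_control))
  x[, labels == "cancer"] <- pmin(1, x[, labels == "cancer"] + delta)
  list(x = x, labels = labels)
}

test_that("AUROC matches the pair-counting oracle, including ties", {
  expect_equal(roc_analysis(c(0.9, 0.8, 0.7, 0.6, 0.5),
                            c("cancer", "cancer", "cancer", "control", "control"))$auroc, 1)
  expect_equal(roc_analysis(c(0.9, 0.4, 0.5, 0.3),
                            c("cancer", "cancer", "control", "control"))$auroc, 0.75)
  set.seed(72)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    labels <- sample(c("cancer", "control"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_analysis(scores, labels)$auroc,
                 oracle_auc(scores, labels == "cancer"), tolerance = 1e-12)
  }
  expect_error(roc_analysis(c(0.1, 0.2), c("cancer", "cancer")), "both classes")
})

test_that("permuted labels give chance-level AUROC", {
  set.seed(73)
  labels <- rep(c("cancer", "control"), c(100, 100))
  scores <- runif(200)
  expect_lt(abs(roc_analysis(scores, sample(labels))$auroc - 0.5), 0.1)
})

test_that("AUPRC: perfect separation, constant-score limit, CI coverage", {
  labels <- rep(c("cancer", "control"), c(30, 70))
  perfect <- c(runif(30, 0.8, 1), runif(70, 0, 0.2))
  pr <- pr_analysis(perfect, labels, n_boot = 200, seed = 74)
  expect_equal(pr$auprc, 1)
  flat <- pr_analysis(rep(0.5, 100), labels, n_boot = 200, seed = 74)
  expect_equal(flat$auprc, 0.3)        # prevalence
  mid <- pr_analysis(runif(100), labels, n_boot = 500, seed = 74)
  expect_gte(mid$auprc, mid$ci[1] - 1e-9)
  expect_lte(mid$auprc, mid$ci[2] + 1e-9)
  expect_error(pr_analysis(runif(5), rep("control", 5)), "positive")
})

test_that("training on separable data yields a perfect operating point", {
  fx <- model_fixture()
  model <- train_classifier(fx$x, fx$labels, rownames(fx$x), seed = 75)
  ev <- evaluate(model, fx$x, fx$labels, seed = 76)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(unname(ev$confusion["TP"] + ev$confusion["FN"]), sum(fx$labels == "cancer"))

  model2 <- train_classifier(fx$x, fx$labels, rownames(fx$x), seed = 75)
  expect_identical(model$threshold, model2$threshold)
  expect_identical(predict_scores(model, fx$x), predict_scores(model2, fx$x))

  expect_error(train_classifier(fx$x, fx$labels, character(0)), "empty panel")
  expect_error(train_classifier(fx$x, fx$labels, "missing_marker"), "absent")
})

test_that("prediction validates panel coverage and imputes missing values", {
  fx <- model_fixture()
  model <- train_classifier(fx$x, fx$labels, rownames(fx$x)[1:4], seed = 77)
  expect_error(predict_scores(model, fx$x[1:2, ]), "lacks panel marker")
  expect_length(predict_scores(model, fx$x[, 0]), 0)

  xm <- fx$x
  xm[1, 3] <- NA
  expect_message(sc <- predict_scores(model, xm), "imputing")
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("per-stage counts partition the detected cancers", {
  fx <- model_fixture(n_cancer = 40, n_control = 30)
  stages <- c(sample(c("0", "I", "II", "III"), 40, replace = TRUE),
              rep(NA, 30))
  model <- train_classifier(fx$x, fx$labels, rownames(fx$x), seed = 78)
  ev <- evaluate(model, fx$x, fx$labels, stages, seed = 79)
  expect_equal(sum(ev$per_stage$n_correct), unname(ev$confusion["TP"]))
  expect_equal(sum(ev$per_stage$n_total), sum(fx$labels == "cancer"))
  expect_equal(pool_stage_counts(ev$per_stage),
               round(100 * ev$sensitivity, 2))
})

test_that("pooled stage counts reproduce printed percentage arithmetic", {
  expect_equal(pool_stage_counts(list(c(3, 5), c(32, 40), c(42, 44), c(18, 19))),
               87.96)
  expect_equal(pool_stage_counts(list(c(2, 3), c(14, 16), c(22, 25), c(5, 5))),
               87.76)
  expect_equal(pool_stage_counts(list(c(0, 1))), 0)
  expect_error(pool_stage_counts(list()), "no stage counts")
  expect_error(pool_stage_counts(list(c(2, 0))), "positive")
})

test_that("univariate logistic AUROC equals the oriented rank AUROC", {
  fx <- model_fixture(n_markers = 3, delta = 0.3, seed = 80)
  x <- fx$x
  x["mk03", ] <- 1 - x["mk03", ]       # make one marker hypomethylated
  tab <- univariate_marker_auc(x, fx$labels)
  expect_equal(tab$auc_logistic, tab$auc_oriented, tolerance = 1e-6)
  expect_true(all(tab$auc_oriented > 0.5))
  expect_identical(tab$direction[tab$marker_id == "mk03"], "hypo")

  const <- matrix(0.5, 1, length(fx$labels),
                  dimnames = list("flat", colnames(fx$x)))
  expect_equal(univariate_marker_auc(const, fx$labels)$auc_oriented, 0.5)

  set.seed(81)
  rx <- matrix(runif(4 * 40), 4, 40,
               dimnames = list(letters[1:4], sprintf("s%02d", 1:40)))
  rl <- sample(c("cancer", "control"), 40, replace = TRUE, prob = c(0.5, 0.5))
  rt <- univariate_marker_auc(rx, rl)
  for (i in 1:4) {
    expect_equal(max(rt$auc_oriented[i], 1 - rt$auc_oriented[i]),
                 max(oracle_auc(rx[i, ], rl == "cancer"),
                     1 - oracle_auc(rx[i, ], rl == "cancer")),
                 tolerance = 1e-12)
  }
})

test_that("top-marker selection applies the AUROC floor and tie rules", {
  tab <- data.frame(
    marker_id = c("a", "b", "c", "d", "e"),
    auc_oriented = c(0.94, 0.8, 0.78, 0.76, 0.74)
  )
  expect_identical(select_top_markers(tab), c("a", "b", "c", "d"))
  expect_warning(none <- select_top_markers(tab, min_auc = 1), "0 marker")
  expect_length(none, 0)

  ties <- data.frame(marker_id = c("zz", "aa", "mm"),
                     auc_oriented = c(0.9, 0.8, 0.8))
  expect_identical(select_top_markers(ties, k = 2), c("zz", "aa"))
})

test_that("mammography combination behaves at the degenerate extremes", {
  fx <- model_fixture(n_markers = 4, delta = 0.15, seed = 82)
  base <- train_classifier(fx$x, fx$labels, rownames(fx$x), seed = 83)
  ev_base <- evaluate(base, fx$x, fx$labels, seed = 84)

  # constant mammography adds nothing
  flat <- combine_with_mammography(fx$x, rep(0, ncol(fx$x)), fx$labels,
                                   rownames(fx$x), seed = 83)
  ev_flat <- evaluate(flat, augment_with_mammography(fx$x, rep(0, ncol(fx$x))),
                      fx$labels, seed = 84)
  expect_lt(abs(ev_flat$roc$auroc - ev_base$roc$auroc), 0.05)

  # perfect mammography dominates
  perfect_mam <- as.integer(fx$labels == "cancer")
  comb <- combine_with_mammography(fx$x, perfect_mam, fx$labels,
                                   rownames(fx$x), seed = 83)
  ev_comb <- evaluate(comb, augment_with_mammography(fx$x, perfect_mam),
                      fx$labels, seed = 84)
  expect_gte(ev_comb$sensitivity, ev_base$sensitivity)
  expect_gte(ev_comb$roc$auroc, ev_base$roc$auroc - 1e-9)

  expect_error(augment_with_mammography(fx$x, c(NA, rep(0, ncol(fx$x) - 1))),
               "0/1")
})

test_that("AUROC comparison: null identity and a clear separation case", {
  set.seed(85)
  labels <- rep(c("cancer", "control"), each = 100)
  s <- runif(200)
  same <- compare_auc(s, s, labels, n_boot = 200, seed = 86)
  expect_equal(same$p_value, 1)
  expect_equal(same$effect_size, 0)

  good <- c(runif(100, 0.6, 1), runif(100, 0, 0.4))
  rand <- runif(200)
  cmp <- compare_auc(good, rand, labels, n_boot = 500, seed = 87)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$effect_size, 1)

  perm <- withr::with_seed(88, sample(200))
  cmp_perm <- compare_auc(good[perm], rand[perm], labels[perm],
                          n_boot = 500, seed = 87)
  expect_equal(cmp_perm$delta, cmp$delta, tolerance = 1e-12)
  expect_error(compare_auc(s[1:5], s, labels), "same samples")
})
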