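# Small planted-signal fixture: one strong marker among pure noise.
planted_fixture <- function(n_noise = 99, n_cancer = 108, n_control = 52,
                            delta = 0.4, seed = 51) {
  set.seed(seed)
  m <- n_noise + 1
  ids <- c("planted", sprintf("noise%03d", seq_len(n_noise)))
  n <- n_cancer + n_control
  x <- matrix(runif(m * n, 0.2, 0.8), m, n,
              dimnames = list(ids, sprintf("s%03d", seq_len(n))))
  labels <- rep(c("cancer", "control"), c(n_cancer, n_control))
  x["planted", labels == "cancer"] <-
    pmin(1, x["planted", labels == "cancer"] + delta)
  list(x = x, labels = labels)
}

test_that("LASSO stability counts concentrate on the planted marker", {
  fx <- planted_fixture()
  res <- lasso_stability(fx$x, fx$labels, n_reps = 60, count_threshold = 36,
                         seed = 52)
  planted <- res[res$marker_id == "planted", ]
  noise <- res[res$marker_id != "planted", ]
  expect_gte(planted$lasso_count, 54)          # >= 90% of repetitions
  expect_true(planted$lasso_selected)
  expect_lt(max(noise$lasso_count), 36)
  expect_false(any(noise$lasso_selected))
})

test_that("LASSO selection respects boundary semantics", {
  fx <- planted_fixture(n_noise = 9)
  none <- lasso_stability(fx$x, fx$labels, n_reps = 0, seed = 52)
  expect_true(all(none$lasso_count == 0))
  expect_false(any(none$lasso_selected))

  # strict 'over threshold' rule: count == n_reps does not select
  res <- lasso_stability(fx$x, fx$labels, n_reps = 5, count_threshold = 5,
                         seed = 53)
  expect_false(any(res$lasso_selected))
  expect_error(lasso_stability(fx$x, rep("cancer", ncol(fx$x))), "label|class")
})

test_that("random-forest importance ranks the planted marker first", {
  fx <- planted_fixture(n_noise = 60)
  res <- rf_importance_stability(fx$x, fx$labels, n_reps = 5, top_k = 10,
                                 num_trees = 200, seed = 54)
  expect_identical(res$marker_id[res$rf_rank == 1], "planted")
  expect_true(res$rf_selected[res$marker_id == "planted"])
  expect_equal(sum(res$rf_selected), 10)

  expect_warning(
    all_sel <- rf_importance_stability(fx$x, fx$labels, n_reps = 2, top_k = 1000,
                                       num_trees = 100, seed = 54),
    "top_k"
  )
  expect_true(all(all_sel$rf_selected))
})

test_that("permuting labels destroys the planted marker's importance rank", {
  fx <- planted_fixture(n_noise = 60)
  perm <- withr::with_seed(55, sample(fx$labels))
  res <- rf_importance_stability(fx$x, perm, n_reps = 5, top_k = 10,
                                 num_trees = 200, seed = 56)
  planted_imp <- res$rf_importance[res$marker_id == "planted"]
  noise_imp <- res$rf_importance[res$marker_id != "planted"]
  expect_gt(res$rf_rank[res$marker_id == "planted"], 1)
  expect_lt(planted_imp, max(noise_imp))
})

test_that("panel intersection is the AND of both selections, importance-ordered", {
  las <- data.frame(marker_id = c("A", "B", "C", "D"),
                    lasso_count = c(90, 80, 70, 10),
                    lasso_selected = c(TRUE, TRUE, TRUE, FALSE))
  rf <- data.frame(marker_id = c("A", "B", "C", "D"),
                   rf_importance = c(1, 5, 3, 9),
                   rf_rank = c(4, 2, 3, 1),
                   rf_selected = c(FALSE, TRUE, TRUE, TRUE))
  out <- intersect_panels(las, rf)
  expect_identical(attr(out, "panel"), c("B", "C"))
  expect_identical(out$final, c(FALSE, TRUE, TRUE, FALSE))

  rf_none <- transform(rf, rf_selected = c(FALSE, FALSE, FALSE, TRUE))
  expect_warning(empty <- intersect_panels(las, rf_none), "empty")
  expect_length(attr(empty, "panel"), 0)

  expect_error(intersect_panels(las, rf[1:3, ]), "different marker sets")
})

test_that("stability procedure is a pure function of data and seed", {
  fx <- planted_fixture(n_noise = 30)
  a <- lasso_stability(fx$x, fx$labels, n_reps = 10, seed = 57)
  b <- lasso_stability(fx$x, fx$labels, n_reps = 10, seed = 57)
  expect_identical(a, b)
  r1 <- rf_importance_stability(fx$x, fx$labels, n_reps = 2, top_k = 10,
                                num_trees = 100, seed = 58)
  r2 <- rf_importance_stability(fx$x, fx$labels, n_reps = 2, top_k = 10,
                                num_trees = 100, seed = 58)
  expect_identical(r1, r2)
})

test_that("adding noise markers does not topple the planted marker's count lead", {
  fx <- planted_fixture(n_noise = 20, seed = 59)
  small <- lasso_stability(fx$x, fx$labels, n_reps = 20, seed = 60)
  expect_identical(small$marker_id[which.max(small$lasso_count)], "planted")

  set.seed(61)
  extra <- matrix(runif(40 * ncol(fx$x), 0.2, 0.8), 40, ncol(fx$x),
                  dimnames = list(sprintf("extra%02d", 1:40), colnames(fx$x)))
  big <- lasso_stability(rbind(fx$x, extra), fx$labels, n_reps = 20, seed = 60)
  expect_identical(big$marker_id[which.max(big$lasso_count)], "planted")
})
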