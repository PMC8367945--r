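paired_fixture <- function(n_markers = 200, n_pairs = 40, noise = 0.05,
                           discordant = integer(0), shift = 0.3, seed = 41) {
  set.seed(seed)
  ids <- sprintf("m%04d", seq_len(n_markers))
  base <- runif(n_markers, 0.2, 0.8)
  tissue <- matrix(base + rnorm(n_markers * n_pairs, 0, noise), n_markers, n_pairs,
                   dimnames = list(ids, sprintf("T%02d", seq_len(n_pairs))))
  plasma <- matrix(base + rnorm(n_markers * n_pairs, 0, noise), n_markers, n_pairs,
                   dimnames = list(ids, sprintf("P%02d", seq_len(n_pairs))))
  plasma[discordant, ] <- plasma[discordant, ] + shift
  pairs <- data.frame(tissue_id = colnames(tissue), plasma_id = colnames(plasma))
  list(tissue = tissue, plasma = plasma, pairs = pairs, ids = ids)
}

test_that("variance prior: degenerate and two-marker cases are well-posed", {
  pr <- fit_variance_prior(rep(0.02, 50), df = 9)
  expect_gte(pr$d0, 1e6)
  expect_equal(pr$s0_2, 0.02)

  pr2 <- fit_variance_prior(c(0.01, 0.04), df = 9)
  expect_gt(pr2$d0, 0)
  expect_true(is.finite(pr2$d0))

  expect_error(fit_variance_prior(c(0, 0), df = 9), "positive variances")
  expect_error(fit_variance_prior(c(0.1, 0.2), df = 0), "df")
})

test_that("variance prior recovers known hyperparameters from simulated variances", {
  set.seed(42)
  d0_true <- 4
  s0_true <- 0.01
  df <- 19
  s2 <- s0_true * (rchisq(5000, df) / df) / (rchisq(5000, d0_true) / d0_true)
  pr <- fit_variance_prior(s2, df)
  expect_gte(pr$d0, 3)
  expect_lte(pr$d0, 5)
  expect_lt(abs(pr$s0_2 - s0_true) / s0_true, 0.2)
})

test_that("variance prior agrees with the limma reference implementation", {
  set.seed(43)
  s2 <- 0.02 * (rchisq(800, 15) / 15) / (rchisq(800, 6) / 6)
  pr <- fit_variance_prior(s2, df = 15)
  ref <- limma::fitFDist(s2, df1 = 15)
  expect_equal(pr$d0, ref$df2, tolerance = 0.05)
  expect_equal(pr$s0_2, ref$scale, tolerance = 0.05)
})

test_that("moderated t with d0 = 0 equals the ordinary paired t-test", {
  fx <- paired_fixture(n_markers = 30, n_pairs = 10)
  res <- moderated_paired_t(fx$tissue, fx$plasma, fx$pairs, d0 = 0)
  for (i in c(1, 7, 30)) {
    tt <- t.test(fx$plasma[i, ], fx$tissue[i, ], paired = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-9)
  }
})

test_that("identical tissue and plasma give t = 0, p = 1", {
  fx <- paired_fixture(n_markers = 20, n_pairs = 8)
  self_pairs <- data.frame(tissue_id = colnames(fx$tissue),
                           plasma_id = colnames(fx$tissue))
  res <- moderated_paired_t(fx$tissue, fx$tissue, self_pairs)
  expect_true(all(res$t_mod == 0))
  expect_true(all(res$p == 1))
})

test_that("a planted discordant marker attains the smallest q", {
  fx <- paired_fixture(discordant = 13)
  res <- moderated_paired_t(fx$tissue, fx$plasma, fx$pairs)
  expect_identical(res$marker_id[which.min(res$q)], fx$ids[13])
  # posterior variance is a convex combination of s2 and s0_2
  s0 <- attr(res, "s0_2")
  expect_true(all(res$s2_post >= pmin(res$s2, s0) - 1e-12))
  expect_true(all(res$s2_post <= pmax(res$s2, s0) + 1e-12))
})

test_that("moderated t preserves effect-size ordering at equal variances", {
  set.seed(44)
  n <- 10
  ids <- sprintf("m%02d", 1:8)
  d <- matrix(rnorm(8 * n, 0, 0.1), 8, n)
  d <- t(scale(t(d))) * 0.1                      # equal per-marker variances
  d <- d + seq(0, 0.35, by = 0.05)               # increasing planted means
  tissue <- matrix(0.5, 8, n, dimnames = list(ids, sprintf("T%02d", 1:n)))
  plasma <- tissue + d
  colnames(plasma) <- sprintf("P%02d", 1:n)
  pairs <- data.frame(tissue_id = colnames(tissue), plasma_id = colnames(plasma))
  res <- moderated_paired_t(tissue, plasma, pairs)
  expect_identical(order(abs(res$t_mod)), order(abs(res$mean_paired_diff)))
})

test_that("pairing is validated", {
  fx <- paired_fixture(n_markers = 5, n_pairs = 4)
  bad <- fx$pairs
  bad$plasma_id[1] <- "nope"
  expect_error(moderated_paired_t(fx$tissue, fx$plasma, bad), "unmatched")
  expect_error(moderated_paired_t(fx$tissue, fx$plasma, fx$pairs[1:2, ]), "3 matched")
})

test_that("concordance filtering honours mode and dynamic range", {
  res <- data.frame(
    marker_id = c("agree_wide", "agree_flat", "discord_wide"),
    q = c(0.8, 0.9, 0.001),
    dynamic_range = c(0.3, 0.0, 0.4)
  )
  keep <- filter_concordant(res)
  expect_identical(as.character(keep), "agree_wide")
  expect_identical(attr(keep, "mode"), "keep_concordant")
  sig <- filter_concordant(res, mode = "keep_significant")
  expect_identical(as.character(sig), "discord_wide")
})

test_that("concordance filter separates planted concordant and discordant markers", {
  fx <- paired_fixture(n_markers = 120, discordant = 101:120, seed = 45)
  res <- moderated_paired_t(fx$tissue, fx$plasma, fx$pairs)
  keep <- filter_concordant(res)
  expect_gte(sum(fx$ids[1:100] %in% keep), 90)
  expect_lte(sum(fx$ids[101:120] %in% keep), 2)
})
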