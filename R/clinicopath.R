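# Clinicopathologic association of methylation burden.
#
# Per-patient hyper- and hypomethylation burdens (mean level over the panel
# markers of each direction) are compared across clinical subgroups by
# one-way ANOVA with Bonferroni correction over the scan.

#' Per-sample methylation burden by marker direction
#'
#' @param x Markers x samples matrix.
#' @param directions Data frame with columns `marker_id`, `direction`
#'   (`"hyper"`/`"hypo"`), covering the panel markers (all present in `x`).
#' @return Data frame with `sample_id`, `hyper_mean`, `hypo_mean`; means are
#'   computed over non-missing markers and are `NA` when a direction group is
#'   empty or a sample has no observed marker in it.
#' @export
methylation_burden <- function(x, directions) {
  stopifnot(is.matrix(x), is.data.frame(directions),
            all(c("marker_id", "direction") %in% names(directions)))
  missing_ids <- setdiff(directions$marker_id, rownames(x))
  if (length(missing_ids)) {
    stop("panel markers absent from matrix: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(directions$direction), c("hyper", "hypo"))
  if (length(bad)) stop("unknown direction(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dir_mean <- function(dir) {
    ids <- directions$marker_id[directions$direction == dir]
    if (!length(ids)) {
      return(rep(NA_real_, ncol(x)))
    }
    colMeans(x[ids, , drop = FALSE], na.rm = TRUE)
  }
  out <- data.frame(
    sample_id = colnames(x),
    hyper_mean = dir_mean("hyper"),
    hypo_mean = dir_mean("hypo"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out$hyper_mean[is.nan(out$hyper_mean)] <- NA_real_
  out$hypo_mean[is.nan(out$hypo_mean)] <- NA_real_
  out
}

#' One-way fixed-effects ANOVA
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return List with `F` and `p` (from the F distribution on k-1 and N-k
#'   degrees of freedom).
#' @export
anova_f <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least two values", call. = FALSE)
  }
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ssw <- sum(unlist(lapply(groups, function(x) sum((x - mean(x))^2))))
  ssb <- sum(vapply(groups, function(x) length(x) * (mean(x) - mean(v))^2, numeric(1)))
  if (ssw == 0 && ssb == 0) {
    stop("all values identical: F undefined", call. = FALSE)
  }
  if (ssw == 0) {
    return(list(F = Inf, p = 0))
  }
  ow <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = unname(ow$p.value))
}

#' Bonferroni correction
#'
#' @param p A p-value in \[0, 1\].
#' @param m Number of tests (>= 1).
#' @return `min(1, p * m)`.
#' @export
bonferroni <- function(p, m) {
  stop_if_not_prob(p, "p")
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  pmin(1, p * m)
}

# Clinically standard bins for continuous features.
bin_clinical_feature <- function(feature, values) {
  switch(feature,
    tumour_size_mm = cut(values, c(-Inf, 20, 50, Inf),
                         labels = c("<=20", "20-50", ">50")),
    pos_nodes = cut(values, c(-Inf, 0, 3, 9, Inf),
                    labels = c("0", "1-3", "4-9", ">=10")),
    age = cut(values, c(-Inf, 39, 49, 59, Inf),
              labels = c("<40", "40-49", "50-59", ">=60")),
    factor(values)
  )
}

#' Scan clinicopathologic features for association with methylation burden
#'
#' One ANOVA per (feature, burden direction) over cancer samples, Bonferroni
#' corrected over the scan. Continuous features (tumour size, node count,
#' age) are binned into clinically standard categories; all others are
#' treated as categorical. Feature levels with fewer than two observations
#' are dropped; features left with a single level are skipped with a warning.
#'
#' @param burden Output of [methylation_burden()].
#' @param clinical Clinical table with `sample_id`, `group` and the feature
#'   columns.
#' @param features Character vector of clinical feature names to test.
#' @param m Number of tests for the Bonferroni correction; defaults to the
#'   number of (feature x direction) tests actually performed, and is echoed
#'   in the output.
#' @return Data frame with `feature`, `direction`, `levels`, `F`, `p`,
#'   `p_adjusted`, `m`.
#' @export
association_scan <- function(burden, clinical,
                             features = c("stage", "subtype", "age", "er", "pr",
                                          "her2", "grade", "tumour_size_mm",
                                          "pos_nodes"),
                             m = NULL) {
  stopifnot(is.data.frame(burden), is.data.frame(clinical))
  missing_cols <- setdiff(features, names(clinical))
  if (length(missing_cols)) {
    stop("clinical table lacks feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- merge(burden, clinical, by = "sample_id")
  if ("group" %in% names(dat)) {
    dat <- dat[dat$group == "cancer", , drop = FALSE]
  }
  rows <- list()
  for (feature in features) {
    fac <- bin_clinical_feature(feature, dat[[feature]])
    for (direction in c("hyper", "hypo")) {
      val <- dat[[paste0(direction, "_mean")]]
      ok <- !is.na(val) & !is.na(fac)
      f_ok <- droplevels(fac[ok])
      keep_lvls <- names(which(table(f_ok) >= 2L))
      ok <- ok & fac %in% keep_lvls
      f_ok <- droplevels(fac[ok])
      if (nlevels(f_ok) < 2L) {
        warning("feature '", feature, "' (", direction,
                ") has a single usable level; skipped")
        next
      }
      res <- anova_f(split(val[ok], f_ok))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feature, direction = direction, levels = nlevels(f_ok),
        F = res$F, p = res$p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(feature = character(0), direction = character(0),
                      levels = integer(0), F = numeric(0), p = numeric(0),
                      p_adjusted = numeric(0), m = integer(0)))
  }
  m <- m %||% nrow(out)
  out$p_adjusted <- bonferroni(out$p, m)
  out$m <- m
  out
}
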