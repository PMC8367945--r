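# Tissue marker discovery.
#
# Candidate differentially methylated markers are discovered by comparing
# tumour against normal tissue per marker with the Wilcoxon rank-sum test,
# controlling the false discovery rate by Benjamini-Hochberg, and requiring a
# minimum absolute difference in mean beta value (default 0.2).

#' Wilcoxon rank-sum test
#'
#' Thin, policy-carrying wrapper around [stats::wilcox.test()]: the exact
#' null distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. When every value in both groups is identical the
#' test is degenerate and `p = 1` is returned.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return List with `statistic` (Mann-Whitney U for `a`) and `p.value`
#'   (two-sided).
#' @export
rank_sum_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    stop("both groups must contain at least one value", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = length(a) * length(b) / 2, p.value = 1))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = min(1, wt$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of step-up adjusted q-values (monotone, clipped at 1).
#' @export
bh_adjust <- function(p) {
  if (!length(p)) {
    return(numeric(0))
  }
  stop_if_not_prob(p, "p")
  stats::p.adjust(p, method = "BH")
}

#' Discover differentially methylated markers between two tissue groups
#'
#' @param case,control Markers x samples matrices with identical row names
#'   (e.g. tumour and normal tissue). Each group needs at least 2 samples.
#' @param fdr FDR significance level (marker passes when `q < fdr`).
#' @param min_delta Minimum absolute difference of group mean levels
#'   (inclusive floor).
#' @return Data frame of per-marker statistics: `marker_id`, `mean_case`,
#'   `mean_control`, `delta` (case minus control), `direction`
#'   (`hyper` if `delta > 0` else `hypo`), `statistic`, `p`, `q`, and the
#'   `pass` flag (`q < fdr` and `|delta| >= min_delta`).
#' @export
discover_markers <- function(case, control, fdr = 0.05, min_delta = 0.2) {
  stopifnot(is.matrix(case), is.matrix(control))
  if (is.null(rownames(case)) || !identical(rownames(case), rownames(control))) {
    stop("`case` and `control` must share identical marker row names", call. = FALSE)
  }
  if (ncol(case) < 2L || ncol(control) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  res <- lapply(rownames(case), function(id) {
    a <- case[id, ]
    b <- control[id, ]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    rt <- rank_sum_test(a, b)
    data.frame(
      marker_id = id,
      mean_case = mean(a),
      mean_control = mean(b),
      delta = mean(a) - mean(b),
      statistic = rt$statistic,
      p = rt$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$direction <- ifelse(out$delta > 0, "hyper", "hypo")
  out$q <- bh_adjust(out$p)
  out$pass <- out$q < fdr & abs(out$delta) >= min_delta
  out[, c("marker_id", "mean_case", "mean_control", "delta", "direction",
          "statistic", "p", "q", "pass")]
}

#' Summarize the genomic distribution of a marker set
#'
#' Markers may belong to several categories (e.g. a CpG island in a promoter
#' that is also annotated to a gene body), so the fractions can sum to more
#' than 1. Unannotated markers are counted under `"unknown"` with a warning.
#'
#' @param marker_ids Character vector of markers to summarize.
#' @param annotation Data frame with columns `marker_id` and `category`
#'   (categories such as `promoter_island`, `3'UTR`, `gene_body`,
#'   `intergenic`); a marker may appear on several rows.
#' @return Named numeric vector: fraction of markers in each category.
#' @export
annotate_distribution <- function(marker_ids, annotation) {
  if (!length(marker_ids)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  stopifnot(is.data.frame(annotation),
            all(c("marker_id", "category") %in% names(annotation)))
  ann <- annotation[annotation$marker_id %in% marker_ids, , drop = FALSE]
  ann <- unique(ann[, c("marker_id", "category")])
  missing_ids <- setdiff(marker_ids, ann$marker_id)
  if (length(missing_ids)) {
    warning(length(missing_ids), " marker(s) without annotation counted as 'unknown'")
    ann <- rbind(ann, data.frame(marker_id = missing_ids, category = "unknown"))
  }
  counts <- table(ann$category)
  fractions <- as.numeric(counts) / length(marker_ids)
  stats::setNames(fractions, names(counts))
}
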