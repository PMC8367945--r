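# Tissue-plasma concordance filtering.
#
# Candidate markers found in tissue are only useful in a blood test if the
# matched patient plasma recapitulates the tissue signal. Per marker, paired
# tissue-plasma differences are tested with a moderated t-statistic: the
# per-marker variance of differences is shrunk towards a pooled prior
# estimated by empirical Bayes (scaled-F moment matching on log variances),
# gaining degrees of freedom at the small pair counts typical of matched
# designs. Markers are then retained either because they agree between the
# compartments (default) or because they are significant, and must in either
# case show a dynamic methylation range in plasma.

# Largest finite prior df: variances essentially constant across markers.
D0_CAP <- 1e6

# Newton inversion of the trigamma function (x > 0), as used for
# moments-matching of log-variances to a scaled F distribution.
trigamma_inverse <- function(x) {
  if (x > 1e7) {
    return(1 / sqrt(x))
  }
  if (x < 1e-6) {
    return(1 / x)
  }
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Matches the first two moments of `log(s2)` to the theoretical moments of a
#' scaled F distribution with `df` and `d0` degrees of freedom, giving the
#' shared prior degrees of freedom `d0` and prior variance `s0_2` toward
#' which per-marker variances are shrunk. When the observed variances are
#' (nearly) constant the dispersion equation has no positive solution; `d0`
#' is then reported at a large finite cap and `s0_2` as the mean variance.
#'
#' @param s2 Per-marker sample variances (at least two positive values).
#' @param df Residual degrees of freedom shared by all markers.
#' @return List with `d0` (prior df) and `s0_2` (prior variance).
#' @export
fit_variance_prior <- function(s2, df) {
  if (df <= 0) stop("`df` must be positive", call. = FALSE)
  pos <- s2[!is.na(s2) & s2 > 0]
  if (length(pos) < 2L) {
    stop("need at least two positive variances to estimate the prior", call. = FALSE)
  }
  z <- log(pos)
  evar <- stats::var(z) - trigamma(df / 2)
  if (evar <= 0) {
    return(list(d0 = D0_CAP, s0_2 = mean(pos)))
  }
  d0 <- min(2 * trigamma_inverse(evar), D0_CAP)
  s0_2 <- exp(mean(z) - digamma(df / 2) + digamma(d0 / 2) - log(d0 / df))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated paired t-test between matched tissue and plasma samples
#'
#' For each marker the paired differences (plasma minus tissue) are tested
#' against zero with variance shrinkage: the posterior variance is the
#' df-weighted convex combination `(d0 * s0_2 + df * s2) / (d0 + df)` and the
#' moderated t follows a t distribution on `d0 + df` degrees of freedom.
#' With `d0 = 0` this reduces to the ordinary paired t-test.
#'
#' @param tissue,plasma Markers x samples matrices with identical marker rows.
#' @param pairs Data frame with columns `tissue_id`, `plasma_id` mapping each
#'   tissue sample to exactly one plasma sample (at least 3 pairs).
#' @param d0 Optional prior df override (e.g. 0 for the unmoderated test);
#'   by default the prior is estimated from the data by
#'   [fit_variance_prior()].
#' @return Data frame with one row per marker: `marker_id`,
#'   `mean_paired_diff`, `s2`, `s2_post`, `t_mod`, `df_total`, `p`, `q`
#'   (Benjamini-Hochberg), `dynamic_range` (max minus min plasma level).
#'   The shared prior is attached as attributes `d0` and `s0_2`.
#' @export
moderated_paired_t <- function(tissue, plasma, pairs, d0 = NULL) {
  stopifnot(is.matrix(tissue), is.matrix(plasma), is.data.frame(pairs),
            all(c("tissue_id", "plasma_id") %in% names(pairs)))
  if (is.null(rownames(tissue)) || !identical(rownames(tissue), rownames(plasma))) {
    stop("`tissue` and `plasma` must share identical marker row names", call. = FALSE)
  }
  if (nrow(pairs) < 3L) stop("need at least 3 matched pairs", call. = FALSE)
  if (anyDuplicated(pairs$tissue_id) || anyDuplicated(pairs$plasma_id)) {
    stop("pairing must be one-to-one", call. = FALSE)
  }
  unmatched <- c(setdiff(pairs$tissue_id, colnames(tissue)),
                 setdiff(pairs$plasma_id, colnames(plasma)))
  if (length(unmatched)) {
    stop("unmatched sample id(s): ", paste(unmatched, collapse = ", "), call. = FALSE)
  }
  pl <- plasma[, pairs$plasma_id, drop = FALSE]
  d <- pl - tissue[, pairs$tissue_id, drop = FALSE]
  n <- nrow(pairs)
  df <- n - 1
  mean_d <- rowMeans(d)
  s2 <- rowSums((d - mean_d)^2) / df

  if (is.null(d0)) {
    prior <- if (sum(s2 > 0) >= 2L) {
      fit_variance_prior(s2, df)
    } else {
      list(d0 = D0_CAP, s0_2 = mean(s2))  # degenerate: (almost) all-zero differences
    }
    d0 <- prior$d0
    s0_2 <- prior$s0_2
  } else {
    if (d0 < 0) stop("`d0` must be >= 0", call. = FALSE)
    s0_2 <- 0
  }
  s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
  se <- sqrt(s2_post / n)
  t_mod <- ifelse(se > 0, mean_d / se, ifelse(mean_d == 0, 0, sign(mean_d) * Inf))
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(
    marker_id = rownames(tissue),
    mean_paired_diff = mean_d,
    s2 = s2,
    s2_post = s2_post,
    t_mod = t_mod,
    df_total = df_total,
    p = p,
    q = bh_adjust(p),
    dynamic_range = apply(pl, 1, max) - apply(pl, 1, min),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

#' Filter markers by tissue-plasma concordance and dynamic range
#'
#' Two retention modes are supported because "select markers by a moderated
#' t-test between tissue and plasma at FDR < 0.05" admits two readings:
#' `keep_concordant` (default) retains markers whose tissue and plasma levels
#' do NOT differ (q >= fdr), i.e. concordant markers; `keep_significant`
#' retains the significant ones. In both modes markers must show a dynamic
#' methylation range in plasma of at least `min_range`. The applied mode is
#' recorded on the result.
#'
#' @param results Output of [moderated_paired_t()].
#' @param fdr FDR threshold.
#' @param min_range Minimum plasma dynamic range (max minus min level).
#' @param mode `"keep_concordant"` or `"keep_significant"`.
#' @return Character vector of retained marker ids with attribute `mode`.
#' @export
filter_concordant <- function(results, fdr = 0.05, min_range = 0.1,
                              mode = c("keep_concordant", "keep_significant")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(results),
            all(c("marker_id", "q", "dynamic_range") %in% names(results)))
  if (!nrow(results)) stop("`results` is empty", call. = FALSE)
  keep <- if (mode == "keep_concordant") results$q >= fdr else results$q < fdr
  keep <- keep & results$dynamic_range >= min_range
  structure(results$marker_id[keep], mode = mode)
}
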