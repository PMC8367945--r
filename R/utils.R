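# Internal helpers shared across modules.

# Round half away from zero, as diagnostic tables conventionally print
# percentages (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Clip numeric values into [0, 1]; methylation levels are proportions.
# Written to preserve dim/dimnames (pmin/pmax may drop them).
clip01 <- function(x) {
  x[!is.na(x) & x < 0] <- 0
  x[!is.na(x) & x > 1] <- 1
  x
}

# Stratified index sample: draw `frac` of each group's indices without
# replacement. Returns integer indices into `groups`.
stratified_half <- function(groups, frac = 0.5) {
  idx <- unlist(lapply(split(seq_along(groups), groups), function(i) {
    sample(i, size = max(1L, floor(length(i) * frac)))
  }), use.names = FALSE)
  sort(idx)
}

check_group_labels <- function(labels, n, positive = "cancer", negative = "control") {
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("`labels` length must match the number of samples", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c(positive, negative))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  labels
}

# Rank-statistic AUROC (Mann-Whitney with ties counted 1/2).
rank_auc <- function(scores, is_pos) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC requires both classes to be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
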