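# Read-level co-methylation scoring.
#
# A sequenced bisulfite fragment is summarised by the ordered 0/1 methylation
# calls at the CpG sites it covers. A read is *co-methylated* when at least
# three of those calls are methylated within a sliding window of 3-5
# consecutive CpG sites; the per-region methylation level is the fraction of
# co-methylated reads among reads covering at least three CpGs.

#' Classify a single read by its CpG methylation states
#'
#' A read with fewer than three CpG calls is `"ineligible"` (it cannot enter
#' the denominator of the methylation level). An eligible read is
#' `"co_methylated"` when any window of `w` consecutive CpG sites
#' (`w` in 3..5, truncated at the read length) contains at least three
#' methylated calls, and `"background"` otherwise. Because every qualifying
#' 3- or 4-site window sits inside some 5-site window, the rule is equivalent
#' to scanning windows of length `min(5, length(states))`; the general scan is
#' kept for clarity and is property-tested against exhaustive enumeration.
#'
#' @param states Integer/numeric vector of 0/1 methylation calls ordered by
#'   genomic position.
#' @return One of `"co_methylated"`, `"background"`, `"ineligible"`.
#' @examples
#' classify_read(c(1, 1, 1))          # co_methylated
#' classify_read(c(1, 0))             # ineligible
#' classify_read(c(1, 0, 1, 0, 1))    # co_methylated (3 within a 5-window)
#' @export
classify_read <- function(states) {
  states <- validate_states(states)
  n <- length(states)
  if (n < 3L) {
    return("ineligible")
  }
  cs <- cumsum(c(0L, states))
  for (w in 3:min(5L, n)) {
    win_max <- max(cs[(w + 1L):(n + 1L)] - cs[1:(n + 1L - w)])
    if (win_max >= 3L) {
      return("co_methylated")
    }
  }
  "background"
}

validate_states <- function(states) {
  if (length(states) == 0L) {
    stop("read has no CpG states", call. = FALSE)
  }
  if (anyNA(states) || !all(states %in% c(0, 1))) {
    stop("CpG methylation states must be 0 or 1", call. = FALSE)
  }
  as.integer(states)
}

# Parse the serialized "1,0,1" state string of a read table row.
parse_states <- function(s) {
  lapply(strsplit(as.character(s), ",", fixed = TRUE), function(x) {
    validate_states(suppressWarnings(as.integer(x)))
  })
}

#' Score one target region from its reads
#'
#' Computes the region methylation level: co-methylated reads divided by all
#' reads carrying at least three CpGs. Ineligible reads are excluded from both
#' numerator and denominator; when no read is eligible the level is `NA`
#' (missing), never 0.
#'
#' @param reads Data frame with columns `read_id`, `region_id`, `states`
#'   (comma-separated 0/1 string), all rows from a single region.
#' @return List with `region_id`, `n_eligible`, `n_comethylated`, `level`.
#' @export
region_methylation_level <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("read_id", "region_id", "states") %in% names(reads)))
  region <- unique(as.character(reads$region_id))
  if (length(region) > 1L) {
    stop("reads span multiple regions: ", paste(region, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reads$read_id)) {
    warning("duplicate read_id within region ", region, "; keeping first occurrence")
    reads <- reads[!duplicated(reads$read_id), , drop = FALSE]
  }
  cls <- vapply(parse_states(reads$states), classify_read, character(1))
  n_eligible <- sum(cls != "ineligible")
  n_co <- sum(cls == "co_methylated")
  list(
    region_id = if (length(region)) region else NA_character_,
    n_eligible = n_eligible,
    n_comethylated = n_co,
    level = if (n_eligible > 0L) n_co / n_eligible else NA_real_
  )
}

#' Score all regions of one sample
#'
#' @param reads Data frame of read calls (`read_id`, `region_id`, `states`)
#'   for one sample, possibly covering many regions.
#' @return Named numeric vector of methylation levels keyed by `region_id`
#'   (sorted); regions with no eligible read are `NA`.
#' @export
score_sample <- function(reads) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  by_region <- split(reads, as.character(reads$region_id))
  vapply(by_region, function(r) region_methylation_level(r)$level, numeric(1))
}
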