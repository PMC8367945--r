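# File formats.
#
# Methylation matrices travel as TSV (first column `marker_id`, one column
# per sample), clinical tables as CSV, read calls as TSV with a
# comma-separated 0/1 state string, and region definitions as BED. Output
# files carry a provenance comment header (`# key=value`), which the readers
# skip.

CLINICAL_COLUMNS <- c("sample_id", "group", "specimen", "stage", "subtype",
                      "age", "er", "pr", "her2", "tumour_size_mm",
                      "pos_nodes", "grade", "mammography_call")

provenance_header <- function(provenance) {
  if (is.null(provenance)) {
    return(character(0))
  }
  vals <- vapply(provenance, function(v) paste(format(v), collapse = ","), character(1))
  c(sprintf("# cfmethdx %s", as.character(utils::packageVersion("cfmethdx"))),
    sprintf("# %s=%s", names(provenance), vals))
}

#' Read a methylation matrix from TSV
#'
#' @param path TSV file: first column `marker_id`, one numeric column per
#'   sample, values in \[0, 1\] or NA. Lines starting with `#` are ignored.
#' @return Markers x samples numeric matrix.
#' @export
read_meth_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!nrow(df) || names(df)[1] != "marker_id") {
    stop("matrix file must have a non-empty body with first column 'marker_id'",
         call. = FALSE)
  }
  ids <- as.character(df$marker_id)
  if (anyDuplicated(ids)) {
    stop("duplicated marker_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicated sample columns", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))) &
                   !is.na(as.matrix(df[, -1, drop = FALSE])), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at marker '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  rownames(m) <- ids
  out_of_range <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(out_of_range)) {
    stop(sprintf("methylation level outside [0, 1] at marker '%s', sample '%s'",
                 ids[out_of_range[1, 1]], colnames(m)[out_of_range[1, 2]]),
         call. = FALSE)
  }
  m
}

#' Write a methylation matrix as TSV
#'
#' @param x Markers x samples matrix.
#' @param path Output path.
#' @param provenance Optional named list echoed as `# key=value` header
#'   lines.
#' @export
write_meth_matrix <- function(x, path, provenance = NULL) {
  stopifnot(is.matrix(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(provenance), con)
  df <- data.frame(marker_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

normalize_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s[s %in% c("", "NA", "NOT ASSESSED")] <- NA_character_
  s[s == "DCIS"] <- "0"  # ductal carcinoma in situ = stage 0
  bad <- setdiff(unique(s[!is.na(s)]), STAGE_LEVELS)
  if (length(bad)) {
    stop("unknown stage token(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  s
}

#' Read a clinical sample table from CSV
#'
#' Stages are normalized to `0`, `I`-`IV` or `NA` (`DCIS` is accepted as an
#' alias for stage 0); `group` must be `cancer` or `control`.
#'
#' @param path CSV with header columns `sample_id`, `group`, `specimen`,
#'   `stage`, `subtype`, `age`, `er`, `pr`, `her2`, `tumour_size_mm`,
#'   `pos_nodes`, `grade`, `mammography_call`.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in clinical table", call. = FALSE)
  }
  df$group <- as.character(df$group)
  check_group_labels(df$group, nrow(df))
  df$stage <- normalize_stage(df$stage)
  df
}

#' Write a clinical table as CSV
#'
#' @param clinical Data frame with the standard clinical columns.
#' @param path Output path.
#' @param provenance Optional named list echoed as header comments.
#' @export
write_clinical <- function(clinical, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(provenance), con)
  utils::write.csv(clinical, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-read CpG methylation calls from TSV
#'
#' @param path TSV with columns `read_id`, `region_id`, `states` (comma
#'   separated 0/1, ordered by genomic position).
#' @return Data frame suitable for [score_sample()].
#' @export
read_reads <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(c("read_id", "region_id", "states"), names(df))
  if (length(missing_cols)) {
    stop("read table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  parse_states(df$states)  # validates every row
  df
}

#' Write per-read CpG methylation calls as TSV
#'
#' @param reads Data frame with `read_id`, `region_id`, `states`.
#' @param path Output path.
#' @param provenance Optional named list echoed as header comments.
#' @export
write_reads <- function(reads, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(provenance), con)
  utils::write.table(reads, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read targeted-region definitions from BED
#'
#' BED is 0-based half-open; the returned table is 1-based inclusive, as
#' conventional in R. Uses `rtracklayer` when available, otherwise a plain
#' 4-column parse.
#'
#' @param path BED file with at least chrom, start, end, name.
#' @return Data frame with `region_id`, `chrom`, `start`, `end`.
#' @export
read_regions <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    return(data.frame(
      region_id = gr$name,
      chrom = as.character(gr$seqnames),
      start = gr$start,
      end = gr$end,
      stringsAsFactors = FALSE
    ))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED file needs chrom, start, end, name", call. = FALSE)
  data.frame(region_id = df[[4]], chrom = df[[1]], start = df[[2]] + 1L,
             end = df[[3]], stringsAsFactors = FALSE)
}
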