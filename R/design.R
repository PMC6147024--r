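#' Two-group study design
#'
#' Builds the sample-to-group table that fixes the sign convention of every
#' downstream two-group comparison. The first group level is the reference
#' (group A, e.g. the inducible lines); all differences are reported as
#' group B minus group A, so hypomethylation of group B appears as a
#' negative difference.
#'
#' @param data A data frame with one row per sample.
#' @param sample_col,group_col Column names holding sample ids and group
#'   labels.
#' @param levels Optional character vector of length 2 fixing group order
#'   (reference first). Defaults to order of first appearance.
#' @return A tibble of class `study_design` with columns `sample_id` and
#'   `group` (a two-level factor).
#' @examples
#' study_design(data.frame(
#'   sample_id = c("i1", "i2", "c1", "c2"),
#'   group = c("IND", "IND", "CON", "CON")
#' ))
#' @export
study_design <- function(data, sample_col = "sample_id", group_col = "group",
                         levels = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c(sample_col, group_col) %in% names(data))) {
    abort_field("data", sprintf("must contain columns `%s` and `%s`", sample_col, group_col))
  }
  d <- tibble::tibble(
    sample_id = as.character(data[[sample_col]]),
    group = as.character(data[[group_col]])
  )
  if (anyDuplicated(d$sample_id)) abort_field("sample_id", "sample ids must be unique")
  lv <- levels %||% unique(d$group)
  if (length(lv) != 2L) abort_field("group", "exactly two groups are required")
  if (!all(d$group %in% lv)) abort_field("levels", "levels must cover all group labels")
  d$group <- factor(d$group, levels = lv)
  n <- table(d$group)
  if (any(n < 2L)) abort_field("group", "each group needs at least 2 samples")
  class(d) <- c("study_design", class(d))
  d
}

design_groups <- function(design) levels(design$group)

# sample ids for each group, in design order
group_samples <- function(design, which = c("A", "B")) {
  which <- match.arg(which)
  g <- design_groups(design)[if (which == "A") 1L else 2L]
  design$sample_id[design$group == g]
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @inheritParams study_design
#' @return A [study_design()] tibble.
#' @export
read_design <- function(path, levels = NULL) {
  study_design(readr::read_tsv(path, show_col_types = FALSE), levels = levels)
}

#' @export
write_design <- function(design, path) {
  readr::write_tsv(tibble::tibble(sample_id = design$sample_id,
                                  group = as.character(design$group)), path)
  invisible(path)
}
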