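# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_field <- function(field, msg) {
  rlang::abort(sprintf("invalid `%s`: %s", field, msg), class = "methfrag_validation_error")
}

#' @importFrom rlang abort warn inform .data
NULL

# named-vector or two-column tibble -> named numeric vector keyed by sample
as_sample_vector <- function(x, value_col = "value") {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x)) {
    if (!"sample_id" %in% names(x)) {
      rlang::abort("per-sample input needs a `sample_id` column or names")
    }
    vc <- if (value_col %in% names(x)) value_col else setdiff(names(x), "sample_id")[1]
    return(stats::setNames(x[[vc]], x$sample_id))
  }
  rlang::abort("expected a named numeric vector or a (sample_id, value) data frame")
}

# expression tibble (gene_id + one column per sample) -> numeric matrix
as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) return(expr)
  stopifnot(is.data.frame(expr))
  idcol <- intersect(c("gene_id", "gene"), names(expr))[1]
  if (is.na(idcol)) rlang::abort("expression table needs a `gene_id` column")
  m <- as.matrix(expr[setdiff(names(expr), idcol)])
  rownames(m) <- expr[[idcol]]
  storage.mode(m) <- "double"
  m
}

expr_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "gene_id")
}
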