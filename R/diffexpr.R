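# Two-group differential expression on FPKM matrices, heatmap-ready matrix
# scaling, and a generic hypergeometric over-representation statistic.

#' Call differentially expressed genes on an FPKM matrix
#'
#' p values come from a two-sided two-sample test (Welch by default) on
#' log2(FPKM + eps); the fold change is computed from the group means of
#' the raw FPKM with the same pseudocount,
#' lfc = log2((mean_B + eps) / (mean_A + eps)). A gene is a DEG when
#' q < `alpha` (strict, Benjamini-Hochberg adjusted) and |lfc| >= `min_lfc`
#' (inclusive), mirroring the "FDR-corrected p < 0.05 and log2 fold change
#' of mean FPKM >= 2" rule. Genes with zero FPKM in every sample are
#' excluded and counted; genes constant across all samples get p = 1 by
#' convention.
#'
#' @param expr Data frame with `gene_id` plus one column per sample (FPKM,
#'   non-negative), or an equivalent matrix.
#' @param design A [study_design()].
#' @param alpha FDR level (default 0.05, strict inequality).
#' @param min_lfc Minimum |log2 fold change| (default 2, inclusive).
#' @param eps Pseudocount added to FPKM (default 1).
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return Tibble (class `deg_tbl`): gene_id, mean_A, mean_B, lfc, p, q,
#'   is_deg, direction ("up"/"down" in group B). Attribute
#'   `n_excluded_zero`.
#' @export
call_degs <- function(expr, design, alpha = 0.05, min_lfc = 2, eps = 1,
                      var_equal = FALSE) {
  m <- as_expr_matrix(expr)
  if (any(m < 0, na.rm = TRUE)) abort_field("expr", "FPKM values must be non-negative")
  missing <- setdiff(design$sample_id, colnames(m))
  if (length(missing)) abort_field("expr", paste("samples absent:", paste(missing, collapse = ", ")))
  m <- m[, design$sample_id, drop = FALSE]
  all_zero <- rowSums(m) == 0
  n_zero <- sum(all_zero)
  if (n_zero > 0) rlang::inform(sprintf("excluded %d genes with all-zero FPKM", n_zero))
  m <- m[!all_zero, , drop = FALSE]

  is_b <- design$group[match(colnames(m), design$sample_id)] == design_groups(design)[2]
  lx <- log2(m + eps)
  xa <- lx[, !is_b, drop = FALSE]; xb <- lx[, is_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(m))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  tstat <- (mb - ma) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  constant <- se == 0 | !is.finite(se)
  p[constant & abs(mb - ma) < .Machine$double.eps^0.5] <- 1
  p[constant & abs(mb - ma) >= .Machine$double.eps^0.5] <- 0

  mean_a_raw <- rowMeans(m[, !is_b, drop = FALSE])
  mean_b_raw <- rowMeans(m[, is_b, drop = FALSE])
  lfc <- log2((mean_b_raw + eps) / (mean_a_raw + eps))
  q <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(
    gene_id = rownames(m),
    mean_A = unname(mean_a_raw), mean_B = unname(mean_b_raw),
    lfc = unname(lfc), p = unname(p), q = unname(q),
    is_deg = unname(q < alpha & abs(lfc) >= min_lfc),
    direction = unname(ifelse(lfc >= 0, "up", "down"))
  )
  attr(out, "n_excluded_zero") <- n_zero
  attr(out, "alpha") <- alpha
  attr(out, "min_lfc") <- min_lfc
  attr(out, "eps") <- eps
  class(out) <- c("deg_tbl", class(out))
  out
}

#' Scale an expression matrix for heatmap export
#'
#' `mean_centered_log2` subtracts the row mean from log2(FPKM + eps);
#' `zscore` additionally divides by the row standard deviation. Rows with
#' zero standard deviation become all zeros and are listed in the
#' `constant_genes` attribute.
#'
#' @inheritParams call_degs
#' @param mode Scaling mode.
#' @return Tibble gene_id + scaled sample columns.
#' @export
scale_expression <- function(expr, mode = c("mean_centered_log2", "zscore"),
                             eps = 1) {
  mode <- match.arg(mode)
  m <- log2(as_expr_matrix(expr) + eps)
  if (any(!is.finite(m))) abort_field("expr", "matrix not finite after log transform")
  ctr <- m - rowMeans(m)
  constant <- character()
  if (mode == "zscore") {
    sds <- apply(m, 1, stats::sd)
    zero <- sds == 0
    constant <- rownames(m)[zero]
    sds[zero] <- 1
    ctr <- ctr / sds
    if (length(constant)) {
      rlang::inform(sprintf("%d constant rows scaled to all zeros", length(constant)))
    }
  }
  out <- expr_tibble(ctr)
  attr(out, "constant_genes") <- constant
  attr(out, "mode") <- mode
  out
}

#' Hypergeometric over-representation of a gene set
#'
#' Upper-tail hypergeometric test P(X >= k) for the overlap k between a
#' selected gene list (e.g. the down-regulated DEGs) and an annotated set,
#' within a stated universe.
#'
#' @param selected,annotated Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return One-row tibble: k, n_selected, n_annotated, n_universe, p
#'   (hypergeometric upper tail), fold_enrichment.
#' @examples
#' ora(letters[1:5], letters[1:5], letters[1:20])  # p = 1/choose(20, 5)
#' @export
ora <- function(selected, annotated, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort_field("universe", "must be non-empty")
  selected <- unique(selected); annotated <- unique(annotated)
  if (!all(selected %in% universe)) abort_field("selected", "must be a subset of universe")
  if (!all(annotated %in% universe)) abort_field("annotated", "must be a subset of universe")
  k <- length(intersect(selected, annotated))
  U <- length(universe); A <- length(annotated); S <- length(selected)
  p <- stats::phyper(k - 1, A, U - A, S, lower.tail = FALSE)
  fold <- if (S == 0 || A == 0) NA_real_ else (k / S) / (A / U)
  tibble::tibble(k = k, n_selected = S, n_annotated = A, n_universe = U,
                 p = p, fold_enrichment = fold)
}

#' Over-representation across a collection of gene sets with FDR control
#'
#' @param selected Character vector of selected genes.
#' @param sets Named list of annotated gene sets (e.g. from [read_gmt()]).
#' @param universe Universe of eligible genes; set members outside it are
#'   ignored.
#' @return Tibble with one row per set plus Benjamini-Hochberg `q`.
#' @export
ora_collection <- function(selected, sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  out <- purrr::imap_dfr(sets, function(genes, nm) {
    dplyr::mutate(ora(selected, intersect(genes, universe), universe),
                  set = nm, .before = 1)
  })
  out$q <- stats::p.adjust(out$p, method = "BH")
  dplyr::arrange(out, .data$p)
}

#' Read gene sets in GMT format
#' @param path Path to the GMT file (set name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                  vapply(parts, `[[`, "", 1))
}

#' Read an expression TSV (genes x samples)
#' @param path Path to the TSV; first column gene ids.
#' @export
read_expression <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  names(tbl)[1] <- "gene_id"
  tbl
}

#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}
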