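# Spearman correlation machinery: rho from Pearson correlation of average
# ranks; two-sided p via the t approximation for n >= 10 and the exact
# permutation distribution (conditional on observed ranks, so ties are
# handled) for n < 10.

perm_cache <- new.env(parent = emptyenv())

all_perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) cbind(v[i], all_perms(v[-i]))))
}

perm_index <- function(n) {
  key <- as.character(n)
  if (is.null(perm_cache[[key]])) perm_cache[[key]] <- all_perms(seq_len(n))
  perm_cache[[key]]
}

#' Spearman rank correlation with a two-sided p value
#'
#' Rho is the Pearson correlation of average ranks. For n >= 10 the p
#' value uses the t approximation t = rho * sqrt((n-2)/(1-rho^2)); for
#' n < 10 it is exact, from the full permutation distribution of one rank
#' vector against the other.
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values
#'   are dropped.
#' @return One-row tibble: rho, p, n.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) rlang::abort("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  } else {
    M <- perm_index(n)
    crx <- rx - mean(rx); cry <- ry - mean(ry)
    denom <- sqrt(sum(crx^2) * sum(cry^2))
    rho_perm <- as.vector(matrix(cry[M], nrow(M), n) %*% crx) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  tibble::tibble(rho = rho, p = min(p, 1), n = n)
}

#' Correlate every gene with an anchor gene and with global methylation
#'
#' For each gene in the expression matrix other than the anchor, computes
#' the Spearman correlation of its expression against the anchor gene's
#' expression and against the per-sample global methylation summary (the
#' per-sample median fragment methylation).
#'
#' @param expr Expression table (`gene_id` + sample columns).
#' @param anchor_gene Gene id of the anchor (e.g. "CD274").
#' @param global_meth Named per-sample vector, or a (sample_id, value)
#'   data frame, e.g. `global_summary(fm)$per_sample_median`.
#' @return Tibble: gene_id, rho_anchor, p_anchor, rho_meth, p_meth, n.
#' @export
correlate_genes <- function(expr, anchor_gene, global_meth) {
  m <- as_expr_matrix(expr)
  if (!anchor_gene %in% rownames(m)) abort_field("anchor_gene", "not present in expression matrix")
  gm <- as_sample_vector(global_meth)
  common <- intersect(colnames(m), names(gm))
  if (length(common) < 3L) rlang::abort("fewer than 3 common samples")
  m <- m[, common, drop = FALSE]; gm <- gm[common]
  anchor <- m[anchor_gene, ]
  genes <- setdiff(rownames(m), anchor_gene)
  purrr::map_dfr(genes, function(g) {
    a <- spearman_test(m[g, ], anchor)
    b <- spearman_test(m[g, ], gm)
    tibble::tibble(gene_id = g, rho_anchor = a$rho, p_anchor = a$p,
                   rho_meth = b$rho, p_meth = b$p, n = a$n)
  })
}

#' Cross-correlogram of regulator genes, an anchor gene and the methylome
#'
#' Builds the symmetric Spearman correlation matrix over the expression of
#' a regulator panel (defaults to the DNA methylation machinery:
#' [epigenetic_regulators]), the anchor gene, and the per-sample global
#' methylation level.
#'
#' @inheritParams correlate_genes
#' @param regulators Character vector of regulator gene ids; missing ones
#'   are dropped with a warning.
#' @return A `correlogram` object holding `rho` and `p` matrices and `n`;
#'   see [tidy.correlogram()] and [autoplot.correlogram()].
#' @export
regulator_correlogram <- function(expr, regulators = epigenetic_regulators,
                                  anchor_gene = "CD274", global_meth = NULL) {
  m <- as_expr_matrix(expr)
  missing <- setdiff(regulators, rownames(m))
  if (length(missing)) {
    rlang::warn(paste("regulators absent from expression matrix:",
                      paste(missing, collapse = ", ")))
  }
  regulators <- setdiff(intersect(regulators, rownames(m)), anchor_gene)
  vars <- list()
  for (g in regulators) vars[[g]] <- m[g, ]
  if (anchor_gene %in% rownames(m)) vars[[anchor_gene]] <- m[anchor_gene, ]
  if (!is.null(global_meth)) {
    gm <- as_sample_vector(global_meth)
    common <- intersect(colnames(m), names(gm))
    vars <- lapply(vars, function(v) v[common])
    vars[["global_methylation"]] <- gm[common]
  }
  if (length(vars) < 2L) rlang::abort("need at least two variables to correlate")
  k <- length(vars); nm <- names(vars)
  rho <- matrix(1, k, k, dimnames = list(nm, nm))
  pm <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  n <- length(vars[[1]])
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      st <- spearman_test(vars[[i]], vars[[j]])
      rho[i, j] <- rho[j, i] <- st$rho
      pm[i, j] <- pm[j, i] <- st$p
    }
  }
  structure(list(rho = rho, p = pm, n = n), class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d variables, n = %d samples\n", nrow(x$rho), x$n))
  print(round(x$rho, 2))
  invisible(x)
}

#' Tidy a correlogram into long form
#' @param x A `correlogram`.
#' @param ... Unused.
#' @return Tibble: var1, var2, rho, p (upper triangle only).
#' @export
tidy.correlogram <- function(x, ...) {
  nm <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(var1 = nm[idx[, 1]], var2 = nm[idx[, 2]],
                 rho = x$rho[idx], p = x$p[idx], n = x$n)
}

#' @export
write_correlogram <- function(x, path_tsv, path_json = NULL) {
  readr::write_tsv(tidy.correlogram(x), path_tsv)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(variables = rownames(x$rho), rho = x$rho,
                              p = x$p, n = x$n),
                         path_json, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(path_tsv)
}
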