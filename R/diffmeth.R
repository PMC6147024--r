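# Two-group methylome comparison: global and element-wise summaries,
# F-test DMF calling with Benjamini-Hochberg FDR control, difference-bin
# stratification, and the same machinery applied to array-style probe
# matrices.

# one-way ANOVA (two groups) per row of a masked matrix; closed form
# (F = t^2 with the pooled-variance t). Rows with zero variance within and
# between groups get p = 1 by convention. Optionally coverage-weighted.
row_anova <- function(x, mask, is_b, weights = NULL) {
  x[!mask] <- NA
  w <- if (is.null(weights)) (mask * 1) else ifelse(mask, weights, 0)
  wa <- w[, !is_b, drop = FALSE]; wb <- w[, is_b, drop = FALSE]
  xa <- x[, !is_b, drop = FALSE]; xb <- x[, is_b, drop = FALSE]
  swa <- rowSums(wa); swb <- rowSums(wb)
  ma <- rowSums(wa * xa, na.rm = TRUE) / swa
  mb <- rowSums(wb * xb, na.rm = TRUE) / swb
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  m <- (swa * ma + swb * mb) / (swa + swb)
  ssb <- swa * (ma - m)^2 + swb * (mb - m)^2
  ssw <- rowSums(wa * (xa - ma)^2, na.rm = TRUE) +
    rowSums(wb * (xb - mb)^2, na.rm = TRUE)
  df2 <- na + nb - 2
  f <- (ssb / 1) / (ssw / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  degenerate <- ssw <= 0 & ssb <= .Machine$double.eps^0.75
  p[degenerate] <- 1
  f[degenerate] <- 0
  # ssw == 0 with a real group difference: saturate rather than NaN
  sat <- ssw <= 0 & !degenerate
  f[sat] <- Inf
  p[sat] <- 0
  tibble::tibble(mean_A = unname(ma), mean_B = unname(mb),
                 n_A = unname(na), n_B = unname(nb),
                 F = unname(f), p = unname(p))
}

#' Global, element-wise and repeat-family methylation summary
#'
#' Computes per-sample median fragment methylation, per-group medians over
#' fragment-level group means, a two-sided Wilcoxon rank test between the
#' two fragment-wise group-mean vectors, and per-group medians with median
#' differences for every element class and repeat family present on the
#' fragments.
#'
#' @param fm A `frag_meth` object from [quantify_fragments()]. Element and
#'   repeat labels are taken from its fragment table when present (see
#'   [classify_fragments()]).
#' @param paired Use the signed-rank test with fragments as pairs instead
#'   of the default unpaired rank-sum test.
#' @return A `meth_summary` object; see [tidy.meth_summary()] and
#'   [glance.meth_summary()].
#' @export
global_summary <- function(fm, paired = FALSE) {
  stopifnot(inherits(fm, "frag_meth"))
  design <- fm$design
  is_b <- design$group[match(colnames(fm$meth), design$sample_id)] == design_groups(design)[2]
  if (all(is_b) || !any(is_b)) rlang::abort("both groups must be present")
  x <- fm$meth
  gm_a <- rowMeans(x[, !is_b, drop = FALSE], na.rm = TRUE)
  gm_b <- rowMeans(x[, is_b, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(gm_a) & is.finite(gm_b)
  if (!any(ok)) rlang::abort("no fragment is covered in both groups")
  wt <- if (paired) {
    stats::wilcox.test(gm_a[ok], gm_b[ok], paired = TRUE, exact = FALSE)
  } else {
    stats::wilcox.test(gm_a[ok], gm_b[ok], exact = FALSE)
  }
  per_sample <- apply(x, 2, stats::median, na.rm = TRUE)

  label_summary <- function(sel, label, kind) {
    tibble::tibble(kind = kind, label = label,
                   n_fragments = sum(sel & ok),
                   median_A = stats::median(gm_a[sel & ok]),
                   median_B = stats::median(gm_b[sel & ok]),
                   median_diff = stats::median(gm_b[sel & ok] - gm_a[sel & ok]))
  }
  el <- NULL
  if ("element_class" %in% names(fm$fragments)) {
    el <- purrr::map_dfr(unique(fm$fragments$element_class), function(k) {
      label_summary(fm$fragments$element_class == k, k, "element")
    })
  }
  rp <- NULL
  if ("repeat_families" %in% names(fm$fragments)) {
    fams <- sort(unique(unlist(fm$fragments$repeat_families)))
    rp <- purrr::map_dfr(fams, function(fam) {
      sel <- purrr::map_lgl(fm$fragments$repeat_families, ~ fam %in% .x)
      label_summary(sel, fam, "repeat")
    })
  }
  structure(list(
    per_sample_median = per_sample,
    group_median = c(stats::median(gm_a[ok]), stats::median(gm_b[ok])) |>
      stats::setNames(design_groups(design)),
    median_diff = stats::median(gm_b[ok] - gm_a[ok]),
    wilcoxon = list(statistic = unname(wt$statistic), p.value = wt$p.value,
                    paired = paired),
    elements = dplyr::bind_rows(el, rp),
    n_fragments = sum(ok),
    design = design
  ), class = "meth_summary")
}

#' @export
print.meth_summary <- function(x, ...) {
  g <- names(x$group_median)
  cat(sprintf("<meth_summary> %d fragments\n", x$n_fragments))
  cat(sprintf("  median methylation: %s = %.3f, %s = %.3f (diff %.3f)\n",
              g[1], x$group_median[1], g[2], x$group_median[2], x$median_diff))
  cat(sprintf("  Wilcoxon %s p = %.3g\n",
              if (x$wilcoxon$paired) "signed-rank" else "rank-sum", x$wilcoxon$p.value))
  invisible(x)
}

#' Tidy element-wise and repeat-family medians of a methylation summary
#' @param x A `meth_summary`.
#' @param ... Unused.
#' @export
tidy.meth_summary <- function(x, ...) x$elements %||% tibble::tibble()

#' One-row overview of a methylation summary
#' @param x A `meth_summary`.
#' @param ... Unused.
#' @export
glance.meth_summary <- function(x, ...) {
  g <- names(x$group_median)
  tibble::tibble(median_A = unname(x$group_median[1]),
                 median_B = unname(x$group_median[2]),
                 median_diff = x$median_diff,
                 wilcoxon_statistic = x$wilcoxon$statistic,
                 wilcoxon_p = x$wilcoxon$p.value,
                 n_fragments = x$n_fragments)
}

#' Call differentially methylated fragments (DMFs)
#'
#' Per fragment, a one-way ANOVA F test (two groups, equivalent to the
#' pooled t test squared) on the per-sample methylation proportions,
#' Benjamini-Hochberg adjustment over all tested fragments, and the joint
#' rule q <= `alpha` and |mean difference| >= `delta` (defaults 5% FDR with
#' a 25% mean methylation difference). Fragments covered in fewer than two
#' samples of either group are skipped and counted. A coverage-weighted
#' variant weights each sample by its pooled read count.
#'
#' @param fm A `frag_meth` object.
#' @param alpha FDR level (default 0.05).
#' @param delta Minimum absolute mean methylation difference (default 0.25).
#' @param weighted Coverage-weight the group means and sums of squares.
#' @return A tibble (class `dmf_tbl`) with one row per tested fragment:
#'   group means, `diff` (group B - group A), `F`, `p`, `q`, `is_dmf`, and
#'   `direction` ("hypo" when group B is lower). Attributes `n_skipped`,
#'   `alpha`, `delta`.
#' @export
call_dmfs <- function(fm, alpha = 0.05, delta = 0.25, weighted = FALSE) {
  stopifnot(inherits(fm, "frag_meth"))
  design <- fm$design
  is_b <- design$group[match(colnames(fm$meth), design$sample_id)] == design_groups(design)[2]
  covered_a <- rowSums(fm$mask[, !is_b, drop = FALSE])
  covered_b <- rowSums(fm$mask[, is_b, drop = FALSE])
  testable <- covered_a >= 2 & covered_b >= 2
  n_skipped <- sum(!testable)
  if (n_skipped > 0) {
    rlang::inform(sprintf("skipped %d fragments with <2 covered samples in a group", n_skipped))
  }
  res <- row_anova(fm$meth[testable, , drop = FALSE],
                   fm$mask[testable, , drop = FALSE], is_b,
                   weights = if (weighted) fm$coverage[testable, , drop = FALSE] else NULL)
  out <- dplyr::bind_cols(
    fm$fragments[testable, intersect(c("fragment_id", "chrom", "start", "end",
                                       "element_class", "repeat_families"),
                                     names(fm$fragments))],
    res[c("mean_A", "mean_B", "F", "p")]
  )
  out$diff <- out$mean_B - out$mean_A
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$is_dmf <- out$q <= alpha & abs(out$diff) >= delta
  out$direction <- ifelse(out$diff < 0, "hypo", "hyper")
  out <- dplyr::relocate(out, "diff", .after = "mean_B")
  attr(out, "n_skipped") <- n_skipped
  attr(out, "alpha") <- alpha
  attr(out, "delta") <- delta
  class(out) <- c("dmf_tbl", class(out))
  out
}

#' Stratify DMFs by absolute methylation difference
#'
#' @param dmfs A `dmf_tbl` (rows with `is_dmf` are used when the column is
#'   present, otherwise all rows).
#' @param breakpoints Difference thresholds; counts are of DMFs whose
#'   |diff| strictly exceeds each one.
#' @return Tibble (breakpoint, n_above) with attribute `hypo_fraction`,
#'   the fraction of DMFs with direction "hypo".
#' @export
stratify_dmfs <- function(dmfs, breakpoints = c(0.25, 0.5, 0.75)) {
  d <- if ("is_dmf" %in% names(dmfs)) dmfs[dmfs$is_dmf, , drop = FALSE] else dmfs
  if (nrow(d) == 0L) rlang::abort("no DMFs to stratify")
  out <- tibble::tibble(
    breakpoint = breakpoints,
    n_above = vapply(breakpoints, function(b) sum(abs(d$diff) > b), integer(1))
  )
  attr(out, "hypo_fraction") <- mean(d$diff < 0)
  out
}

#' Fraction of DMFs hypomethylated in group B
#' @param dmfs A `dmf_tbl`.
#' @export
dmf_hypo_fraction <- function(dmfs) {
  d <- if ("is_dmf" %in% names(dmfs)) dmfs[dmfs$is_dmf, , drop = FALSE] else dmfs
  mean(d$diff < 0)
}

#' Two-group comparison of an array-style probe matrix
#'
#' Applies the same ANOVA + Benjamini-Hochberg machinery to a beta-value
#' matrix (probes x samples in [0,1]), covering 450K-style analyses.
#' Probes with non-finite values are dropped with a message.
#'
#' @param beta Data frame with `probe_id` plus one column per sample, or a
#'   numeric matrix with probe rownames.
#' @param design A [study_design()].
#' @inheritParams call_dmfs
#' @return Tibble: probe_id, mean_A, mean_B, diff, F, p, q.
#' @export
probe_group_compare <- function(beta, design, alpha = 0.05) {
  m <- if (is.data.frame(beta)) {
    idcol <- intersect(c("probe_id", "gene_id"), names(beta))[1]
    mm <- as.matrix(beta[setdiff(names(beta), idcol)])
    rownames(mm) <- beta[[idcol]]
    mm
  } else beta
  m <- m[, design$sample_id, drop = FALSE]
  finite <- apply(is.finite(m), 1, all)
  if (any(!finite)) {
    rlang::inform(sprintf("dropped %d probes with non-finite values", sum(!finite)))
    m <- m[finite, , drop = FALSE]
  }
  is_b <- design$group[match(colnames(m), design$sample_id)] == design_groups(design)[2]
  res <- row_anova(m, matrix(TRUE, nrow(m), ncol(m)), is_b)
  out <- tibble::tibble(probe_id = rownames(m)) |>
    dplyr::bind_cols(res[c("mean_A", "mean_B", "F", "p")])
  out$diff <- out$mean_B - out$mean_A
  out$q <- stats::p.adjust(out$p, method = "BH")
  dplyr::relocate(out, "diff", .after = "mean_B")
}

#' @export
write_dmf_table <- function(dmfs, path) {
  out <- dmfs
  if ("repeat_families" %in% names(out)) {
    out$repeat_families <- purrr::map_chr(out$repeat_families, paste, collapse = ",")
  }
  first <- intersect(c("chrom", "start", "end"), names(out))
  readr::write_tsv(dplyr::relocate(tibble::as_tibble(out), dplyr::all_of(first)), path)
  invisible(path)
}
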