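# Joining differential methylation with differential expression through
# genomic context: promoter (-5 kb/+1 kb), gene body (transcript span
# minus the promoter window) and user-supplied gene-linked enhancers.

#' Per-gene promoter and gene-body intervals
#'
#' @param genes Gene table.
#' @param genome_lengths Named chromosome lengths (used to clip promoters);
#'   if `NULL`, promoters are clipped at 0 only.
#' @inheritParams derive_elements
#' @return Tibble: gene_id, chrom, context ("promoter"/"body"), start, end.
#' @export
gene_contexts <- function(genes, genome_lengths = NULL,
                          promoter_up = 5000, promoter_down = 1000) {
  genes <- as_gene_table(genes)
  purrr::pmap_dfr(genes[c("gene_id", "chrom", "strand", "tx_start", "tx_end")],
                  function(gene_id, chrom, strand, tx_start, tx_end) {
    L <- if (is.null(genome_lengths)) Inf else genome_lengths[[chrom]]
    pw <- promoter_window(tx_start, tx_end, strand,
                          if (is.finite(L)) L else tx_end + 1e7,
                          promoter_up, promoter_down)
    body <- IRanges::setdiff(ir(tx_start, tx_end), ir(pw$start, pw$end))
    dplyr::bind_rows(
      tibble::tibble(gene_id = gene_id, chrom = chrom, context = "promoter",
                     start = pw$start, end = pw$end),
      if (length(body)) tibble::tibble(gene_id = gene_id, chrom = chrom,
                                       context = "body", start = ir_tbl(body)$start,
                                       end = ir_tbl(body)$end)
    )
  })
}

#' Read gene-linked enhancer intervals (BED, 4th column = gene id)
#' @param path Path to the BED file.
#' @export
read_enhancer_bed <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "gene_id"),
                           colClasses = c("character", "integer", "integer", "character"))
  tibble::as_tibble(tbl)
}

#' Integrate differentially methylated fragments with DEGs
#'
#' For every differentially expressed gene, finds the called DMFs that
#' overlap (>= 1 bp) its promoter window, its gene body, or user-supplied
#' enhancer intervals linked to it, and labels each pair with a
#' concordance class such as "body-hypo/down". Genes carrying two or more
#' DMFs are flagged (`multi_dmf`).
#'
#' @param dmfs A `dmf_tbl`; rows with `is_dmf` are integrated.
#' @param degs A `deg_tbl`; rows with `is_deg` are integrated.
#' @param genes Gene table on the same assembly as the fragments.
#' @param enhancers Optional tibble (chrom, start, end, gene_id); intervals
#'   without a gene link are an error.
#' @param genome_lengths Optional named chromosome lengths for promoter
#'   clipping.
#' @inheritParams derive_elements
#' @return Tibble (class `integration_tbl`): one row per (gene, DMF,
#'   context) with DEG direction/lfc, DMF diff/direction, concordance
#'   class and the multi-DMF flag. Summarise with
#'   [summarize_concordance()].
#' @export
integrate_dmf_deg <- function(dmfs, degs, genes, enhancers = NULL,
                              genome_lengths = NULL,
                              promoter_up = 5000, promoter_down = 1000) {
  d <- if ("is_dmf" %in% names(dmfs)) dmfs[dmfs$is_dmf, , drop = FALSE] else dmfs
  e <- if ("is_deg" %in% names(degs)) degs[degs$is_deg, , drop = FALSE] else degs
  if (!all(c("chrom", "start", "end") %in% names(d))) {
    abort_field("dmfs", "need chrom/start/end coordinates")
  }
  ctx <- gene_contexts(genes, genome_lengths, promoter_up, promoter_down)
  ctx <- ctx[ctx$gene_id %in% e$gene_id, , drop = FALSE]
  if (!is.null(enhancers)) {
    if (!"gene_id" %in% names(enhancers) || any(is.na(enhancers$gene_id)) ||
        any(!nzchar(enhancers$gene_id))) {
      abort_field("enhancers", "every enhancer interval needs a gene link")
    }
    enh <- dplyr::mutate(enhancers[enhancers$gene_id %in% e$gene_id, ],
                         context = "enhancer")
    ctx <- dplyr::bind_rows(ctx, enh[c("gene_id", "chrom", "context", "start", "end")])
  }
  if (nrow(ctx) == 0L || nrow(d) == 0L) {
    out <- tibble::tibble(gene_id = character(), deg_direction = character(),
                          lfc = double(), fragment_id = character(),
                          context = character(), dmf_diff = double(),
                          dmf_direction = character(), concordance = character(),
                          multi_dmf = logical())
    class(out) <- c("integration_tbl", class(out))
    return(out)
  }
  recs <- purrr::map_dfr(unique(ctx$chrom), function(ch) {
    cc <- ctx[ctx$chrom == ch, , drop = FALSE]
    dd <- d[d$chrom == ch, , drop = FALSE]
    if (nrow(dd) == 0L) return(NULL)
    ov <- IRanges::findOverlaps(ir(dd$start, dd$end), ir(cc$start, cc$end),
                                minoverlap = 1L)
    if (length(ov) == 0L) return(NULL)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    tibble::tibble(gene_id = cc$gene_id[si], fragment_id = dd$fragment_id[qi],
                   context = cc$context[si], dmf_diff = dd$diff[qi],
                   dmf_direction = dd$direction[qi])
  })
  if (nrow(recs) == 0L) {
    out <- recs
  } else {
    # a DMF may sit in two context intervals of the same gene; keep one row
    recs <- dplyr::distinct(recs, .data$gene_id, .data$fragment_id,
                            .data$context, .keep_all = TRUE)
    out <- dplyr::inner_join(recs,
                             tibble::tibble(gene_id = e$gene_id,
                                            deg_direction = e$direction,
                                            lfc = e$lfc),
                             by = "gene_id")
    out$concordance <- sprintf("%s-%s/%s", out$context, out$dmf_direction,
                               out$deg_direction)
    multi <- dplyr::summarise(dplyr::group_by(out, .data$gene_id),
                              k = dplyr::n_distinct(.data$fragment_id))
    out$multi_dmf <- out$gene_id %in% multi$gene_id[multi$k >= 2]
    out <- dplyr::relocate(out, "gene_id", "deg_direction", "lfc",
                           "fragment_id", "context")
  }
  class(out) <- c("integration_tbl", class(out))
  out
}

#' Concordance summary of an integration table
#'
#' @param records An `integration_tbl` from [integrate_dmf_deg()].
#' @return Tibble counting (gene, DMF) pairs per context, DMF direction and
#'   DEG direction, plus distinct gene counts.
#' @export
summarize_concordance <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, .data$context, .data$dmf_direction, .data$deg_direction),
    n_pairs = dplyr::n(), n_genes = dplyr::n_distinct(.data$gene_id),
    .groups = "drop")
}

#' Restrict and scale an expression matrix to a gene panel
#'
#' @inheritParams scale_expression
#' @param panel Character vector of panel gene ids (default the shipped
#'   viral-mimicry / immune panel, [viral_mimicry_panel]).
#' @return Scaled tibble restricted to the panel genes found; genes absent
#'   from the matrix are listed in the `missing_genes` attribute.
#' @export
panel_matrix <- function(expr, panel = viral_mimicry_panel,
                         mode = c("mean_centered_log2", "zscore"), eps = 1) {
  mode <- match.arg(mode)
  m <- as_expr_matrix(expr)
  present <- intersect(panel, rownames(m))
  if (length(present) == 0L) abort_field("panel", "no panel gene present in the expression matrix")
  out <- scale_expression(expr_tibble(m[present, , drop = FALSE]), mode = mode, eps = eps)
  attr(out, "missing_genes") <- setdiff(panel, present)
  out
}

#' Log2 fold change of background-subtracted flow-cytometry MFI
#'
#' Computes log2(((MFI antibody, treated) - (MFI isotype, treated)) /
#' ((MFI antibody, mock) - (MFI isotype, mock))), the standard summary of
#' a surface-marker shift between a treatment and its mock control.
#' Vectorised over replicate measurements.
#'
#' @param mfi_antibody_treated,mfi_isotype_treated Treated-condition MFIs.
#' @param mfi_antibody_mock,mfi_isotype_mock Mock-condition MFIs.
#' @return Numeric log2 fold change(s).
#' @examples
#' mfi_log2fc(200, 10, 100, 5)  # 1
#' @export
mfi_log2fc <- function(mfi_antibody_treated, mfi_isotype_treated,
                       mfi_antibody_mock, mfi_isotype_mock) {
  num <- mfi_antibody_treated - mfi_isotype_treated
  den <- mfi_antibody_mock - mfi_isotype_mock
  if (any(num <= 0) || any(den <= 0)) {
    rlang::abort("background-subtracted MFI differences must be positive; measurement unusable")
  }
  log2(num / den)
}

#' @export
write_integration_table <- function(records, path) {
  readr::write_tsv(tibble::as_tibble(records), path)
  invisible(path)
}
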