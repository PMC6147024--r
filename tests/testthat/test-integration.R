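test_that("gene contexts reproduce the promoter window and carve the body", {
  genes <- tibble::tibble(
    gene_id = c("plus", "minus"), chrom = "chr1", strand = c("+", "-"),
    tx_start = c(10000L, 2000L), tx_end = c(20000L, 10000L))
  ctx <- gene_contexts(genes, c(chr1 = 40000L))
  p <- ctx[ctx$gene_id == "plus", ]
  expect_equal(p$start[p$context == "promoter"], 5000L)
  expect_equal(p$end[p$context == "promoter"], 11000L)
  expect_equal(p$start[p$context == "body"], 11000L)
  expect_equal(p$end[p$context == "body"], 20000L)
  m <- ctx[ctx$gene_id == "minus", ]
  expect_equal(m$start[m$context == "promoter"], 9000L)
  expect_equal(m$end[m$context == "promoter"], 15000L)
  expect_equal(m$start[m$context == "body"], 2000L)
  expect_equal(m$end[m$context == "body"], 9000L)
})

make_dmfs <- function(chrom, start, end, diff) {
  tibble::tibble(fragment_id = sprintf("%s:%d-%d", chrom, start, end),
                 chrom = chrom, start = start, end = end,
                 diff = diff, is_dmf = TRUE,
                 direction = ifelse(diff < 0, "hypo", "hyper"))
}

make_degs <- function(gene_id, lfc) {
  tibble::tibble(gene_id = gene_id, lfc = lfc, is_deg = TRUE,
                 direction = ifelse(lfc >= 0, "up", "down"))
}

test_that("DMF-DEG integration attributes fragments to per-gene contexts", {
  genes <- tibble::tibble(
    gene_id = c("X", "Y"), chrom = "chr1", strand = "+",
    tx_start = c(30000L, 19000L), tx_end = c(40000L, 27000L))
  # one DMF inside X's promoter window [25000, 31000) that also lies in Y's body
  dmfs <- make_dmfs("chr1", c(26000L, 35000L, 100L),
                    c(26100L, 35100L, 200L), c(-0.4, -0.3, 0.5))
  degs <- make_degs(c("X", "Y"), c(3, -4))
  rec <- integrate_dmf_deg(dmfs, degs, genes)
  x_rec <- rec[rec$gene_id == "X", ]
  expect_setequal(x_rec$context, c("promoter", "body"))
  y_rec <- rec[rec$gene_id == "Y", ]
  expect_equal(y_rec$context[y_rec$fragment_id == "chr1:26000-26100"], "body")
  # the distant fragment is attributed to no gene
  expect_false("chr1:100-200" %in% rec$fragment_id)
  # concordance class for a body-hypo fragment of the down gene
  expect_true("body-hypo/down" %in% rec$concordance[rec$gene_id == "Y"])
  # X carries two DMFs -> flagged
  expect_true(all(rec$multi_dmf[rec$gene_id == "X"]))
  expect_false(any(rec$multi_dmf[rec$gene_id == "Y"] &
                     !rec$gene_id[rec$gene_id == "Y"] %in% "X"))
})

test_that("every integration record is confirmed by a per-base oracle", {
  set.seed(47)
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5), chrom = "chr1",
    strand = sample(c("+", "-"), 5, replace = TRUE),
    tx_start = seq(10000L, 90000L, by = 20000L),
    tx_end = seq(10000L, 90000L, by = 20000L) + sample(6000:12000, 5))
  starts <- sort(sample.int(110000L, 60))
  dmfs <- make_dmfs("chr1", starts, starts + 150L,
                    runif(60, -0.6, 0.6))
  degs <- make_degs(genes$gene_id, runif(5, -4, 4))
  rec <- integrate_dmf_deg(dmfs, degs, genes)
  ctx <- gene_contexts(genes, NULL)
  # positive check: each record overlaps its claimed context interval
  for (i in seq_len(nrow(rec))) {
    iv <- ctx[ctx$gene_id == rec$gene_id[i] & ctx$context == rec$context[i], ]
    d <- dmfs[dmfs$fragment_id == rec$fragment_id[i], ]
    expect_gt(base_overlap(d$start, d$end, iv$start, iv$end), 0)
  }
  # negative check: no overlapping (gene, fragment, context) triple is missed
  for (g in genes$gene_id) {
    for (cx in c("promoter", "body")) {
      iv <- ctx[ctx$gene_id == g & ctx$context == cx, ]
      for (j in seq_len(nrow(dmfs))) {
        ov <- base_overlap(dmfs$start[j], dmfs$end[j], iv$start, iv$end)
        claimed <- any(rec$gene_id == g & rec$context == cx &
                         rec$fragment_id == dmfs$fragment_id[j])
        expect_equal(claimed, ov > 0)
      }
    }
  }
})

test_that("enhancer intervals join through their gene links", {
  genes <- tibble::tibble(gene_id = "X", chrom = "chr1", strand = "+",
                          tx_start = 50000L, tx_end = 60000L)
  dmfs <- make_dmfs("chr1", 1000L, 1100L, -0.5)
  degs <- make_degs("X", 5)
  enh <- tibble::tibble(chrom = "chr1", start = 900L, end = 1200L, gene_id = "X")
  rec <- integrate_dmf_deg(dmfs, degs, genes, enhancers = enh)
  expect_equal(rec$context, "enhancer")
  expect_equal(rec$concordance, "enhancer-hypo/up")
  expect_error(integrate_dmf_deg(dmfs, degs, genes,
                                 enhancers = dplyr::mutate(enh, gene_id = NA)),
               "gene link")
})

test_that("DEGs without overlapping DMFs are absent from the records", {
  genes <- tibble::tibble(gene_id = "lonely", chrom = "chr2", strand = "+",
                          tx_start = 10000L, tx_end = 20000L)
  dmfs <- make_dmfs("chr1", 10500L, 10600L, -0.4)
  rec <- integrate_dmf_deg(dmfs, make_degs("lonely", 3), genes)
  expect_equal(nrow(rec), 0L)
  expect_s3_class(rec, "integration_tbl")
})

test_that("concordance summaries count pairs and genes", {
  genes <- tibble::tibble(gene_id = c("X", "Y"), chrom = "chr1", strand = "+",
                          tx_start = c(10000L, 50000L), tx_end = c(20000L, 60000L))
  dmfs <- make_dmfs("chr1", c(12000L, 13000L, 52000L),
                    c(12100L, 13100L, 52100L), c(-0.4, -0.3, 0.6))
  degs <- make_degs(c("X", "Y"), c(-3, 3))
  s <- summarize_concordance(integrate_dmf_deg(dmfs, degs, genes))
  body_hypo_down <- s[s$context == "body" & s$dmf_direction == "hypo" &
                        s$deg_direction == "down", ]
  expect_equal(body_hypo_down$n_pairs, 2L)
  expect_equal(body_hypo_down$n_genes, 1L)
})

test_that("panel matrices restrict, scale and report missing genes", {
  samples <- paste0("s", 1:4)
  m <- matrix(c(1, 3, 1, 3, 2, 2, 2, 2), 2, 4, byrow = TRUE,
              dimnames = list(c("IFI44", "OTHER"), samples))
  expr <- tibble::as_tibble(m, rownames = "gene_id")
  pm <- panel_matrix(expr, panel = c("IFI44", "IFI27"))
  expect_equal(pm$gene_id, "IFI44")
  expect_equal(attr(pm, "missing_genes"), "IFI27")
  expect_lt(abs(sum(pm[1, -1])), 1e-12)
  z <- suppressMessages(panel_matrix(expr, panel = "OTHER", mode = "zscore"))
  expect_true(all(unlist(z[1, -1]) == 0))
  expect_error(panel_matrix(expr, panel = "NOPE"), "panel")
})

test_that("MFI log2 fold change follows the background-subtracted formula", {
  expect_equal(mfi_log2fc(200, 10, 100, 5), 1)
  expect_equal(mfi_log2fc(390, 10, 100, 5), 2)
  expect_equal(mfi_log2fc(150, 20, 150, 20), 0)
  expect_error(mfi_log2fc(10, 20, 100, 5), "positive")
  # vectorised over replicates
  expect_equal(mfi_log2fc(c(200, 390), c(10, 10), c(100, 100), c(5, 5)), c(1, 2))
})
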