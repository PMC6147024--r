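small_config <- function(...) {
  args <- list(n_chrom = 1, chrom_length = 5e4, genes_per_chrom = 4,
               gene_length_range = c(2000, 4000), n_genes = 40, n_deg = 5,
               n_per_group = 3, seed = 101)
  over <- list(...)
  do.call(sim_config, utils::modifyList(args, over))
}

toy_fragments <- function(n = 4, n_cpg = 5L) {
  tibble::tibble(fragment_id = sprintf("f%d", seq_len(n)), chrom = "chr1",
                 start = (seq_len(n) - 1L) * 1000L,
                 end = (seq_len(n) - 1L) * 1000L + 100L,
                 length = 100L, n_cpg = n_cpg)
}

test_that("configuration validation names the offending field", {
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(dispersion = 1), "dispersion")
  expect_error(sim_config(chrom_length = 100), "chrom_length")
  expect_error(sim_config(repeat_density = c(L1 = 0.5, Alu = 0.5)), "repeat_density")
  expect_error(sim_config(repeat_density = c(NOTFAM = 0.1)), "repeat_density")
  expect_error(sim_config(coupling_rho = 1.2), "coupling_rho")
  expect_error(sim_config(n_deg = 50, n_genes = 10), "n_deg")
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(group_labels = "one"), "group_labels")
})

test_that("the same seed reproduces the bundle exactly", {
  cfg <- small_config()
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$genes, b2$genes)
  expect_identical(b1$calls, b2$calls)
  expect_identical(b1$expr, b2$expr)
  expect_identical(b1$truth$fragments, b2$truth$fragments)
  # a different seed changes the genome
  b3 <- simulate_bundle(small_config(seed = 102))
  expect_false(identical(b1$genome, b3$genome))
})

test_that("per-stage seed streams are split from the one user seed", {
  cfg <- small_config()
  s <- vapply(c("genome", "methylome", "counts", "expression"),
              function(st) methfrag:::stage_seed(cfg, st), numeric(1))
  expect_equal(length(unique(s)), 4L)
  expect_true(all(s >= 1 & s < 2^31))
  # calling stage_seed does not disturb the caller's RNG stream
  set.seed(9); before <- runif(3)
  set.seed(9); invisible(methfrag:::stage_seed(cfg, "counts")); after <- runif(3)
  expect_identical(before, after)
})

test_that("zero repeat density yields an empty, well-typed repeat table", {
  b <- simulate_bundle(small_config(repeat_density = c(L1 = 0)))
  expect_equal(nrow(b$repeats), 0L)
  expect_named(b$repeats, c("chrom", "start", "end", "family"))
  expect_true(all(lengths(b$fragments$repeat_families) == 0L))
})

test_that("planted proportions follow baseline + delta with clipping", {
  frags <- toy_fragments(3)
  cfg <- small_config(meth_frag_sd = 0,
                      baseline_meth = c(intergenic = 0.05, L1 = 0.6),
                      group_effect = c(intergenic = -0.2, L1 = -0.1))
  truth <- sim_methylome(frags, c("intergenic", "L1", "intergenic"), cfg)
  expect_equal(truth$fragments$p_A, c(0.05, 0.6, 0.05))
  # 0.05 - 0.2 clips to the 0.01 floor
  expect_equal(truth$fragments$p_B, c(0.01, 0.5, 0.01))

  flat <- sim_methylome(frags, rep("L1", 3),
                        small_config(group_effect = c(intergenic = 0, L1 = 0)))
  expect_equal(flat$fragments$p_A, flat$fragments$p_B)

  expect_error(sim_methylome(frags, c("intergenic", "NOPE", "intergenic"), cfg),
               "unlabeled")
  expect_error(sim_methylome(frags, "intergenic", cfg), "one entry per fragment")
})

test_that("sampled counts converge to the planted truth at high depth", {
  frags <- toy_fragments(6, n_cpg = 8L)
  cfg <- small_config(meth_frag_sd = 0.1, meth_sample_sd = 0,
                      dispersion = 0.001, coverage_mean = 1e4,
                      coverage_shape = 50, n_per_group = 3)
  truth <- sim_methylome(frags, rep(c("intergenic", "L1"), 3), cfg)
  calls <- sample_counts(truth, frags, cfg)
  fm <- quantify_fragments(calls, frags, sim_design(truth),
                           min_reads = 10, min_samples_per_group = 3)
  expect_equal(nrow(fm$meth), 6L)
  design <- sim_design(truth)
  for (g in c("IND", "CON")) {
    ids <- design$sample_id[design$group == g]
    est <- rowMeans(fm$meth[, ids, drop = FALSE])
    want <- if (g == "IND") truth$fragments$p_A else truth$fragments$p_B
    expect_lt(max(abs(est - want[match(rownames(fm$meth), truth$fragments$fragment_id)])),
              0.02)
  }
})

test_that("count totals match the coverage model and drop zero-depth CpGs", {
  frags <- toy_fragments(50, n_cpg = 4L)
  cfg <- small_config(coverage_mean = 3, coverage_shape = 1)
  truth <- sim_methylome(frags, rep("intergenic", 50), cfg)
  calls <- sample_counts(truth, frags, cfg)
  expect_true(all(calls$n_meth + calls$n_unmeth >= 1))
  expect_true(all(calls$n_meth >= 0))
  # mean depth near the negative-binomial mean
  expect_lt(abs(mean(calls$n_meth + calls$n_unmeth) / mean_trunc_nb(3, 1) - 1), 0.1)
  expect_error(sample_counts(truth, toy_fragments(3), cfg), "match the truth")
})

test_that("noiseless expression carries the planted fold changes exactly", {
  frags <- toy_fragments(20)
  cfg <- small_config(expr_sd = 0, coupling_rho = 0, meth_sample_sd = 0,
                      lfc_scale = 3, anchor_lfc = 6, panel_lfc = 2,
                      n_genes = 60, n_deg = 8)
  truth <- sim_methylome(frags, rep("intergenic", 20), cfg)
  ex <- sim_expression(truth, cfg)
  degs <- call_degs(ex$expr, sim_design(truth), eps = 0)
  planted <- ex$truth$expression$true_deg
  expect_equal(nrow(planted), 8L)
  got <- degs$lfc[match(planted$gene_id, degs$gene_id)]
  expect_equal(got, planted$lfc, tolerance = 1e-9)
  expect_equal(sort(unique(planted$lfc)), c(-3, 3))
  expect_equal(degs$lfc[degs$gene_id == "CD274"], 6, tolerance = 1e-9)
  panel_in <- intersect(ex$truth$expression$panel, degs$gene_id)
  expect_true(all(abs(degs$lfc[degs$gene_id %in% panel_in] - 2) < 1e-9))
})

test_that("the bundled genome produces fragments in every element class", {
  b <- simulate_bundle(sim_config(n_chrom = 1, chrom_length = 2e5,
                                  genes_per_chrom = 8,
                                  gene_length_range = c(4000, 9000), seed = 13))
  expect_setequal(unique(b$fragments$element_class),
                  c("promoter", "exon", "intron", "intergenic"))
  expect_true(any(lengths(b$fragments$repeat_families) > 0))
  # fragments and truth rows correspond 1:1
  expect_identical(b$truth$fragments$fragment_id, b$fragments$fragment_id)
  expect_true(all(b$fragments$length >= 40 & b$fragments$length <= 220))
})
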