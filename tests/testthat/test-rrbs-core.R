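test_that("digestion cuts one base into every CCGG and tiles the chromosome", {
  f <- mspi_digest(c(chr1 = "ACCGGTTCCGGA"), size_range = NULL)
  expect_equal(f$start, c(0L, 2L, 8L))
  expect_equal(f$end, c(2L, 8L, 12L))

  f2 <- mspi_digest(c(chr1 = "CCGGCCGG"), size_range = NULL)
  expect_equal(f2$start, c(0L, 1L, 5L))
  expect_equal(f2$end, c(1L, 5L, 8L))

  # no cut site: one fragment spanning the chromosome
  f3 <- mspi_digest(c(chr1 = "AAATTTGGG"), size_range = NULL)
  expect_equal(nrow(f3), 1L)
  expect_equal(c(f3$start, f3$end), c(0L, 9L))

  # N inside CCGG never matches
  f4 <- mspi_digest(c(chr1 = "AACCNGGAA"), size_range = NULL)
  expect_equal(nrow(f4), 1L)

  expect_error(mspi_digest(c(chr1 = "ACGT"), size_range = c(100, 40)), "size_range")
})

test_that("digestion equals a brute-force scanner on random sequences", {
  set.seed(42)
  for (i in 1:30) {
    s <- rand_seq(300, prob = c(0.2, 0.3, 0.3, 0.2))
    got <- mspi_digest(stats::setNames(s, "c"), size_range = NULL)
    ref <- brute_digest(s)
    expect_equal(got$start, ref$start)
    expect_equal(got$end, ref$end)
    expect_equal(sum(got$length), nchar(s))
    # every internal boundary sits 1 bp inside a CCGG
    for (b in got$start[-1]) {
      expect_equal(substr(s, b, b + 3), "CCGG")
    }
  }
})

test_that("size selection keeps only fragments inside the window", {
  set.seed(7)
  s <- rand_seq(5000)
  all <- mspi_digest(stats::setNames(s, "c"), size_range = NULL)
  sel <- mspi_digest(stats::setNames(s, "c"), size_range = c(40, 220))
  expect_true(all(sel$length >= 40 & sel$length <= 220))
  expect_equal(sel$fragment_id, all$fragment_id[all$length >= 40 & all$length <= 220])
})

test_that("bismark coverage dialect converts coordinates and validates", {
  tmp <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\t101\t101\t50.0\t5\t5", tmp)
  calls <- read_bismark_cov(tmp, "s1")
  expect_equal(calls$pos, 100L)
  expect_equal(calls$n_meth, 5L)
  expect_equal(calls$n_unmeth, 5L)

  writeLines("chr1\t101\t101\t60.0\t5\t5", tmp)
  expect_error(read_bismark_cov(tmp, "s1"), "inconsistent")

  # zero-coverage rows are dropped, with a count
  writeLines(c("chr1\t11\t11\t0\t0\t0", "chr1\t21\t21\t100\t4\t0"), tmp)
  calls <- read_bismark_cov(tmp, "s1")
  expect_equal(nrow(calls), 1L)
  expect_equal(attr(calls, "n_dropped_zero"), 1L)
})

test_that("coverage files round-trip through write and read", {
  calls <- tibble::tibble(chrom = "chr2", pos = c(0L, 10L, 999L),
                          sample_id = "s1",
                          n_meth = c(3L, 0L, 7L), n_unmeth = c(1L, 6L, 0L))
  tmp <- withr::local_tempfile(fileext = ".cov")
  write_bismark_cov(calls, tmp)
  back <- read_bismark_cov(tmp, "s1")
  expect_equal(back$pos, calls$pos)
  expect_equal(back$n_meth, calls$n_meth)
  expect_equal(back$n_unmeth, calls$n_unmeth)
})

test_that("fragment proportions pool read counts over CpGs", {
  design <- study_design(data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                                    group = c("A", "A", "B", "B")))
  frags <- tibble::tibble(fragment_id = "chr1:0-100", chrom = "chr1",
                          start = 0L, end = 100L, length = 100L, n_cpg = 2L)
  calls <- tidyr::crossing(pos = c(10L, 20L), sample_id = design$sample_id) |>
    dplyr::mutate(chrom = "chr1",
                  n_meth = ifelse(pos == 10L, 5L, 5L),
                  n_unmeth = 5L)
  fm <- quantify_fragments(calls, frags, design, min_reads = 10,
                           min_samples_per_group = 2)
  expect_equal(unname(fm$meth[1, ]), rep(0.5, 4))

  # pooled, not averaged: 9/10 and 0/10 -> 9/20
  calls2 <- dplyr::mutate(calls, n_meth = ifelse(pos == 10L, 9L, 0L),
                          n_unmeth = ifelse(pos == 10L, 1L, 10L))
  fm2 <- quantify_fragments(calls2, frags, design, min_reads = 10,
                            min_samples_per_group = 2)
  expect_equal(unname(fm2$meth[1, ]), rep(0.45, 4))
})

test_that("coverage standardisation masks cells and enforces the quorum", {
  design <- design_6v6()
  frags <- tibble::tibble(fragment_id = c("f1", "f2"), chrom = "chr1",
                          start = c(0L, 200L), end = c(100L, 300L),
                          length = 100L, n_cpg = 1L)
  calls <- tidyr::crossing(fragment = c("f1", "f2"),
                           sample_id = design$sample_id) |>
    dplyr::mutate(chrom = "chr1", pos = ifelse(fragment == "f1", 10L, 210L),
                  n_meth = 5L, n_unmeth = 5L)
  # one cell of f1 drops to 9 reads: masked but fragment retained
  calls$n_unmeth[calls$fragment == "f1" & calls$sample_id == "IND_1"] <- 4L
  # f2 loses coverage in 4 of 6 CON samples: quorum of 3 fails
  drop <- calls$fragment == "f2" & calls$sample_id %in% paste0("CON_", 1:4)
  calls$n_meth[drop] <- 1L
  calls$n_unmeth[drop] <- 2L
  fm <- suppressMessages(quantify_fragments(calls[, c("chrom", "pos", "sample_id", "n_meth", "n_unmeth")],
                                            frags, design))
  expect_equal(rownames(fm$meth), "f1")
  expect_false(fm$mask["f1", "IND_1"])
  expect_true(is.na(fm$meth["f1", "IND_1"]))
  expect_equal(fm$n_excluded_quorum, 1L)
})

test_that("quantification equals a per-read tally on a random small instance", {
  set.seed(99)
  design <- design_6v6()
  n_frag <- 8
  frags <- tibble::tibble(fragment_id = sprintf("f%d", 1:n_frag), chrom = "chr1",
                          start = (0:(n_frag - 1)) * 100L,
                          end = (0:(n_frag - 1)) * 100L + 80L,
                          length = 80L, n_cpg = 3L)
  calls <- tidyr::crossing(fr = 1:n_frag, off = c(5L, 25L, 60L),
                           sample_id = design$sample_id) |>
    dplyr::mutate(chrom = "chr1", pos = (fr - 1L) * 100L + off,
                  n_meth = rpois(dplyr::n(), 6), n_unmeth = rpois(dplyr::n(), 6))
  fm <- quantify_fragments(calls, frags, design, min_reads = 1,
                           min_samples_per_group = 1)
  for (i in 1:n_frag) {
    for (s in design$sample_id) {
      sub <- calls[calls$fr == i & calls$sample_id == s, ]
      expect_equal(fm$meth[sprintf("f%d", i), s],
                   sum(sub$n_meth) / sum(sub$n_meth + sub$n_unmeth))
    }
  }
  expect_true(all(fm$meth >= 0 & fm$meth <= 1, na.rm = TRUE))
})

test_that("fragments without CpGs are excluded with a count", {
  design <- design_6v6()
  frags <- tibble::tibble(fragment_id = c("f1", "f0"), chrom = "chr1",
                          start = c(0L, 200L), end = c(100L, 300L),
                          length = 100L, n_cpg = c(1L, 0L))
  calls <- tidyr::crossing(sample_id = design$sample_id) |>
    dplyr::mutate(chrom = "chr1", pos = 10L, n_meth = 10L, n_unmeth = 10L)
  fm <- quantify_fragments(calls, frags, design)
  expect_equal(fm$n_excluded_no_cpg, 1L)
  expect_equal(rownames(fm$meth), "f1")
})
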