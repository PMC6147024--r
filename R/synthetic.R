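# Synthetic study generator: genomes with CpG islands and repeat families,
# a 6-vs-6 two-group methylome in which group B is globally hypomethylated
# preferentially at intergenic, intronic and repeat fragments, beta-binomial
# bisulfite counts over a negative-binomial depth model, and an expression
# matrix whose regulator genes are rank-coupled to per-sample global
# methylation. Ground truth is retained for parameter-recovery tests.

clip01 <- function(x) pmin(pmax(x, 0.01), 0.99)

DEFAULT_BASELINE <- c(
  promoter = 0.15, exon = 0.55, intron = 0.63, intergenic = 0.66,
  L1 = 0.72, L2 = 0.75, Alu = 0.68, MIR = 0.65, ERV1 = 0.70, ERVK = 0.70,
  ERVL = 0.72, `ERVL-MaLR` = 0.70, satellite = 0.72)

DEFAULT_EFFECT <- c(
  promoter = 0, exon = 0, intron = -0.12, intergenic = -0.19,
  L1 = -0.19, L2 = -0.11, Alu = -0.13, MIR = -0.10, ERV1 = -0.19,
  ERVK = -0.15, ERVL = -0.14, `ERVL-MaLR` = -0.13, satellite = -0.15)

DEFAULT_REPEAT_DENSITY <- c(
  L1 = 0.06, L2 = 0.03, Alu = 0.08, MIR = 0.03, ERV1 = 0.03, ERVK = 0.02,
  ERVL = 0.02, `ERVL-MaLR` = 0.02, satellite = 0.02)

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: a 6-vs-6 two-group
#' design whose group B is globally hypomethylated, with per-class
#' baselines and deltas calibrated to the published element-wise medians
#' (intergenic 0.66 with a -0.19 delta, introns -0.12, L1 0.72 -> 0.53,
#' L2 0.75 -> 0.64, LTR family deltas between -0.13 and -0.19, promoters
#' hypomethylated in both groups, exons unchanged).
#'
#' @param n_chrom,chrom_length Number and length (bp) of chromosomes.
#' @param cpg_island_rate CpG islands per Mb beyond the one stamped at each
#'   gene TSS.
#' @param repeat_density Named fraction of the genome covered per repeat
#'   family; the sum must not exceed 0.9.
#' @param n_per_group Samples per group (default 6).
#' @param baseline_meth,group_effect Named per-class mean methylation of
#'   group A and delta (group B - group A); classes are the four genomic
#'   elements plus the repeat families.
#' @param dispersion Beta-binomial overdispersion phi in (0,1) (the
#'   intra-CpG read correlation).
#' @param coverage_mean,coverage_shape Negative-binomial per-CpG read depth
#'   (mean and size).
#' @param n_genes,n_deg Expression genes and planted DEGs among them.
#' @param lfc_scale Planted |log2 fold change| of the DEGs.
#' @param coupling_rho Target rank correlation between the DNMT3A-like
#'   regulator and per-sample global methylation; the UHRF2-like regulator
#'   and the CD274-like anchor get the opposite sign.
#' @param anchor_lfc Planted log2 up-shift of the anchor gene in group B.
#' @param panel_lfc Planted log2 up-shift of the viral-mimicry panel genes
#'   in group B.
#' @param meth_frag_sd Per-fragment noise (proportion scale) around the
#'   class baseline.
#' @param meth_sample_sd Per-sample logit-scale methylation offset,
#'   providing the within-group variation the regulator coupling acts on.
#' @param expr_sd Per-observation log2 expression noise.
#' @param genes_per_chrom,gene_length_range,island_length Genome layout.
#' @param size_range RRBS size-selection window used by the bundled
#'   pipeline.
#' @param group_labels Group names, reference first.
#' @param seed Integer seed; one seed drives split sub-streams per stage.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chrom = 2, chrom_length = 6e5, cpg_island_rate = 10,
                       repeat_density = DEFAULT_REPEAT_DENSITY,
                       n_per_group = 6,
                       baseline_meth = DEFAULT_BASELINE,
                       group_effect = DEFAULT_EFFECT,
                       dispersion = 0.05,
                       coverage_mean = 30, coverage_shape = 5,
                       n_genes = 120, n_deg = 20, lfc_scale = 3,
                       coupling_rho = 0.9, anchor_lfc = 6, panel_lfc = 2,
                       meth_frag_sd = 0.05, meth_sample_sd = 0.3,
                       expr_sd = 0.5,
                       genes_per_chrom = 20,
                       gene_length_range = c(5000, 20000),
                       island_length = 500,
                       size_range = c(40, 220),
                       group_labels = c("IND", "CON"),
                       seed = 1) {
  if (chrom_length < 1e4) abort_field("chrom_length", "must be at least 10 kb")
  if (any(repeat_density < 0 | repeat_density > 1)) {
    abort_field("repeat_density", "densities must lie in [0, 1]")
  }
  if (sum(repeat_density) > 0.9) abort_field("repeat_density", "densities must sum to at most 0.9")
  bad <- setdiff(names(repeat_density), REPEAT_FAMILIES)
  if (length(bad)) abort_field("repeat_density", paste("unknown families:", paste(bad, collapse = ", ")))
  if (dispersion <= 0 || dispersion >= 1) abort_field("dispersion", "phi must lie in (0, 1)")
  if (coverage_mean < 0) abort_field("coverage_mean", "must be non-negative")
  if (abs(coupling_rho) > 1) abort_field("coupling_rho", "must lie in [-1, 1]")
  if (n_deg > n_genes) abort_field("n_deg", "cannot exceed n_genes")
  if (any(baseline_meth < 0 | baseline_meth > 1)) abort_field("baseline_meth", "means must lie in [0, 1]")
  if (any(abs(group_effect) > 1)) abort_field("group_effect", "deltas must lie in [-1, 1]")
  if (n_per_group < 2) abort_field("n_per_group", "need at least 2 samples per group")
  if (length(group_labels) != 2L) abort_field("group_labels", "exactly two labels")
  cfg <- list(n_chrom = n_chrom, chrom_length = as.integer(chrom_length),
              cpg_island_rate = cpg_island_rate, repeat_density = repeat_density,
              n_per_group = n_per_group, baseline_meth = baseline_meth,
              group_effect = group_effect, dispersion = dispersion,
              coverage_mean = coverage_mean, coverage_shape = coverage_shape,
              n_genes = n_genes, n_deg = n_deg, lfc_scale = lfc_scale,
              coupling_rho = coupling_rho, anchor_lfc = anchor_lfc,
              panel_lfc = panel_lfc, meth_frag_sd = meth_frag_sd,
              meth_sample_sd = meth_sample_sd, expr_sd = expr_sd,
              genes_per_chrom = genes_per_chrom,
              gene_length_range = gene_length_range,
              island_length = island_length, size_range = size_range,
              group_labels = group_labels, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# split one user seed into independent per-stage streams
stage_seed <- function(config, stage) {
  stages <- c("genome", "methylome", "counts", "expression")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s[match(stage, stages)]
}

# gene identifier pool: anchor, regulators and panel first, then filler ids
gene_id_pool <- function(n) {
  ids <- unique(c("CD274", epigenetic_regulators, viral_mimicry_panel))
  if (n > length(ids)) ids <- c(ids, sprintf("G%04d", seq_len(n - length(ids))))
  ids[seq_len(min(n, length(ids)))]
}

REPEAT_LENGTH_RANGE <- list(
  L1 = c(1500, 4000), L2 = c(1000, 3000), Alu = c(250, 350), MIR = c(200, 300),
  ERV1 = c(500, 1500), ERVK = c(500, 1500), ERVL = c(500, 1500),
  `ERVL-MaLR` = c(400, 1200), satellite = c(500, 2000))

#' Generate a synthetic genome with gene models and repeat annotation
#'
#' Chromosomes are random uniform-base sequence (so CCGG occurs at the
#' background rate of 4^-4) with CG-rich CpG islands stamped at every gene
#' TSS and at extra random positions, so digestion yields fragments in all
#' element classes. Repeat intervals per family are placed without mutual
#' overlap until the requested genome fraction is covered.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (named character), `genes` (gene tibble),
#'   `repeats` (repeat tibble). Deterministic given the seed.
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "genome"))
  L <- config$chrom_length
  pool <- gene_id_pool(config$n_chrom * config$genes_per_chrom)
  next_gene <- 1L
  genomes <- list(); gene_rows <- list(); repeat_rows <- list()
  for (ci in seq_len(config$n_chrom)) {
    ch <- paste0("chr", ci)
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

    # gene placement without overlap
    occupied <- IRanges::IRanges()
    genes_here <- list()
    for (gi in seq_len(config$genes_per_chrom)) {
      if (next_gene > length(pool)) break
      glen <- round(stats::runif(1, config$gene_length_range[1], config$gene_length_range[2]))
      placed <- FALSE
      for (try in 1:200) {
        s <- sample.int(L - glen, 1) - 1L
        cand <- ir(s, s + glen)
        if (!any(IRanges::overlapsAny(cand, occupied))) {
          occupied <- c(occupied, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) next
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(3:8, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      while (sum(ex_len) > glen * 0.6) ex_len <- ex_len[-length(ex_len)]
      n_ex <- length(ex_len)
      gap_total <- glen - sum(ex_len)
      cuts <- sort(stats::runif(n_ex - 1))
      gaps <- round(diff(c(0, cuts, 1)) * gap_total)
      starts <- integer(n_ex); pos <- s
      for (k in seq_len(n_ex)) {
        pos <- pos + gaps[k]
        starts[k] <- pos
        pos <- pos + ex_len[k]
      }
      ends <- starts + ex_len
      starts[1] <- s
      keep <- starts < s + glen
      starts <- starts[keep]
      ends <- pmin(ends[keep], s + glen)
      gene_rows[[length(gene_rows) + 1L]] <- tibble::tibble(
        gene_id = pool[next_gene], chrom = ch, strand = strand,
        tx_start = s, tx_end = s + glen,
        exon_starts = list(as.integer(starts)), exon_ends = list(as.integer(ends)))
      next_gene <- next_gene + 1L

      # CpG island at the TSS
      tss <- if (strand == "+") s else s + glen
      bases <- stamp_island(bases, tss - config$island_length %/% 2,
                            config$island_length, L)
    }

    # extra islands to reach the requested rate
    n_extra <- max(0, round(config$cpg_island_rate * L / 1e6))
    if (n_extra > 0) {
      for (s in sample.int(L - config$island_length, n_extra) - 1L) {
        bases <- stamp_island(bases, s, config$island_length, L)
      }
    }

    # repeat families, mutually non-overlapping
    rep_occ <- IRanges::IRanges()
    for (fam in names(config$repeat_density)) {
      target <- config$repeat_density[[fam]] * L
      if (target <= 0) next
      lr <- REPEAT_LENGTH_RANGE[[fam]]
      covered <- 0; tries <- 0
      while (covered < target && tries < 50 * ceiling(target / mean(lr))) {
        tries <- tries + 1
        rlen <- round(stats::runif(1, lr[1], lr[2]))
        s <- sample.int(L - rlen, 1) - 1L
        cand <- ir(s, s + rlen)
        if (any(IRanges::overlapsAny(cand, rep_occ))) next
        rep_occ <- c(rep_occ, cand)
        repeat_rows[[length(repeat_rows) + 1L]] <- tibble::tibble(
          chrom = ch, start = s, end = s + rlen, family = fam)
        covered <- covered + rlen
      }
    }
    genomes[[ch]] <- paste(bases, collapse = "")
  }
  repeats <- if (length(repeat_rows)) {
    dplyr::arrange(dplyr::bind_rows(repeat_rows), .data$chrom, .data$start)
  } else {
    tibble::tibble(chrom = character(), start = integer(),
                   end = integer(), family = character())
  }
  list(genome = unlist(genomes),
       genes = dplyr::bind_rows(gene_rows),
       repeats = repeats)
}

# overwrite a window with CG-rich sequence carrying regular CCGG motifs
stamp_island <- function(bases, start, len, L) {
  start <- max(0L, min(as.integer(start), L - len))
  idx <- (start + 1L):(start + len)
  bases[idx] <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                       prob = c(0.15, 0.35, 0.35, 0.15))
  for (off in seq(1L, len - 4L, by = 60L)) {
    bases[start + off + 0:3] <- c("C", "C", "G", "G")
  }
  bases
}

# methylation label: covering repeat family if any, else element class
#' Methylation class label for classified fragments
#' @param fragments Output of [classify_fragments()].
#' @return Character vector of labels (repeat family when one covers the
#'   fragment, otherwise the element class).
#' @export
meth_label <- function(fragments) {
  stopifnot(all(c("element_class", "repeat_families") %in% names(fragments)))
  purrr::map2_chr(fragments$repeat_families, fragments$element_class,
                  function(fams, el) if (length(fams)) fams[[1]] else el)
}

#' Plant the two-group methylome truth
#'
#' Group A truth per fragment is the class baseline plus per-fragment
#' noise; group B adds the class delta; both are clipped to [0.01, 0.99].
#' Per-sample logit-scale offsets give each sample its own realized
#' methylome.
#'
#' @param fragments Fragment tibble.
#' @param labels Character vector of methylation class labels, one per
#'   fragment (see [meth_label()]); every label must have a baseline and
#'   delta in the config.
#' @param config A [sim_config()].
#' @return A `sim_truth` object.
#' @export
sim_methylome <- function(fragments, labels, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(labels) != nrow(fragments)) {
    rlang::abort("labels must have one entry per fragment")
  }
  unlabeled <- is.na(labels) | !labels %in% names(config$baseline_meth)
  if (any(unlabeled)) {
    rlang::abort(sprintf("unlabeled fragment(s): %s",
                         paste(utils::head(fragments$fragment_id[unlabeled], 3), collapse = ", ")))
  }
  set.seed(stage_seed(config, "methylome"))
  n <- nrow(fragments)
  p_a <- clip01(config$baseline_meth[labels] + stats::rnorm(n, 0, config$meth_frag_sd))
  p_b <- clip01(p_a + config$group_effect[labels])
  n_s <- 2L * config$n_per_group
  samples <- tibble::tibble(
    sample_id = paste0(rep(config$group_labels, each = config$n_per_group), "_",
                       rep(seq_len(config$n_per_group), 2)),
    group = rep(config$group_labels, each = config$n_per_group),
    logit_offset = stats::rnorm(n_s, 0, config$meth_sample_sd))
  structure(list(
    fragments = tibble::tibble(fragment_id = fragments$fragment_id,
                               label = unname(labels),
                               p_A = unname(p_a), p_B = unname(p_b)),
    samples = samples,
    config = config
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d fragments, %d samples", nrow(x$fragments), nrow(x$samples)))
  if (!is.null(x$expression)) {
    cat(sprintf("; %d genes (%d planted DEGs)", nrow(x$expression$baseline),
                nrow(x$expression$true_deg)))
  }
  cat("\n")
  invisible(x)
}

#' Study design implied by a simulation truth
#' @param truth A `sim_truth`.
#' @return A [study_design()].
#' @export
sim_design <- function(truth) {
  study_design(truth$samples[c("sample_id", "group")],
               levels = truth$config$group_labels)
}

# fragment x sample matrix of true per-sample proportions
true_sample_meth <- function(truth) {
  pg <- cbind(truth$fragments$p_A, truth$fragments$p_B)
  gi <- match(truth$samples$group, truth$config$group_labels)
  m <- stats::plogis(stats::qlogis(pg[, gi]) +
                       rep(truth$samples$logit_offset, each = nrow(pg)))
  dimnames(m) <- list(truth$fragments$fragment_id, truth$samples$sample_id)
  m
}

#' True per-sample global median methylation of a planted truth
#' @param truth A `sim_truth`.
#' @export
truth_global_median <- function(truth) {
  apply(true_sample_meth(truth), 2, stats::median)
}

#' True per-group median fragment methylation under the realized truth
#' @param truth A `sim_truth`.
#' @return Named length-2 vector (group A, group B).
#' @export
truth_group_median <- function(truth) {
  m <- true_sample_meth(truth)
  ga <- truth$samples$sample_id[truth$samples$group == truth$config$group_labels[1]]
  gb <- truth$samples$sample_id[truth$samples$group == truth$config$group_labels[2]]
  stats::setNames(c(stats::median(rowMeans(m[, ga, drop = FALSE])),
                    stats::median(rowMeans(m[, gb, drop = FALSE]))),
                  truth$config$group_labels)
}

#' Sample bisulfite read counts from a planted truth
#'
#' Per CpG and sample, total depth is negative-binomial
#' (mean `coverage_mean`, size `coverage_shape`) and the methylated count
#' is beta-binomial around the sample's true fragment proportion with
#' overdispersion `dispersion`. CpGs with zero depth produce no record.
#'
#' @param truth A `sim_truth` from [sim_methylome()].
#' @param fragments Fragment tibble matching the truth (same order).
#' @param config A [sim_config()].
#' @param genome Optional genome; when given, real CG positions inside each
#'   fragment are used, otherwise `n_cpg` evenly spaced positions.
#' @return Methylation-call tibble (chrom, pos, sample_id, n_meth,
#'   n_unmeth).
#' @export
sample_counts <- function(truth, fragments, config, genome = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (config$dispersion <= 0 || config$dispersion >= 1) {
    abort_field("dispersion", "phi must lie in (0, 1)")
  }
  if (!identical(fragments$fragment_id, truth$fragments$fragment_id)) {
    rlang::abort("fragments do not match the truth table")
  }
  set.seed(stage_seed(config, "counts"))
  cpg <- cpg_positions(fragments, genome)
  pmat <- true_sample_meth(truth)
  n_s <- nrow(truth$samples)
  n_c <- nrow(cpg)
  # long layout: all CpGs for sample 1, then sample 2, ...
  p <- as.vector(pmat[cpg$frag_row, ])
  depth <- stats::rnbinom(n_c * n_s, mu = config$coverage_mean,
                          size = config$coverage_shape)
  s0 <- (1 - config$dispersion) / config$dispersion
  pi_draw <- stats::rbeta(n_c * n_s, p * s0, (1 - p) * s0)
  n_meth <- stats::rbinom(n_c * n_s, depth, pi_draw)
  out <- tibble::tibble(
    chrom = rep(cpg$chrom, n_s),
    pos = rep(cpg$pos, n_s),
    sample_id = rep(truth$samples$sample_id, each = n_c),
    n_meth = n_meth,
    n_unmeth = depth - n_meth)
  out[depth > 0, , drop = FALSE]
}

# CpG positions per fragment: from the genome when available, otherwise
# n_cpg evenly spaced positions inside the fragment
cpg_positions <- function(fragments, genome = NULL) {
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    purrr::map_dfr(unique(fragments$chrom), function(ch) {
      cg <- pattern_starts0(genome[[ch]], "CG")
      fr <- fragments[fragments$chrom == ch, ]
      rows <- which(fragments$chrom == ch)
      idx <- match_fragment(rep(ch, length(cg)), cg, fr)
      keep <- !is.na(idx)
      tibble::tibble(chrom = ch, pos = cg[keep], frag_row = rows[idx[keep]])
    })
  } else {
    stopifnot("n_cpg" %in% names(fragments))
    k <- pmin(fragments$n_cpg, pmax(fragments$length - 1L, 1L))
    purrr::map_dfr(which(k > 0), function(i) {
      tibble::tibble(chrom = fragments$chrom[i],
                     pos = fragments$start[i] +
                       unique(floor(fragments$length[i] * seq_len(k[i]) / (k[i] + 1L))),
                     frag_row = i)
    })
  }
}

#' Generate the coupled expression matrix
#'
#' Log-normal FPKMs with planted group shifts of +/- `lfc_scale` on
#' `n_deg` genes, an anchor "CD274"-like gene up-shifted in the
#' hypomethylated group, an up-shifted viral-mimicry panel, and regulator
#' genes rank-coupled to per-sample global methylation: "DNMT3A" at
#' +`coupling_rho`, "UHRF2" and the anchor at the opposite sign.
#'
#' @param truth A `sim_truth` (supplies the per-sample methylation the
#'   coupling acts on).
#' @param config A [sim_config()].
#' @return List with `expr` (tibble gene_id + samples) and the updated
#'   `truth` carrying `expression` ground truth (planted DEGs, regulator
#'   correlations, anchor).
#' @export
sim_expression <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (abs(config$coupling_rho) > 1) abort_field("coupling_rho", "must lie in [-1, 1]")
  set.seed(stage_seed(config, "expression"))
  ids <- gene_id_pool(config$n_genes)
  n_g <- length(ids)
  samples <- truth$samples$sample_id
  n_s <- length(samples)
  is_b <- truth$samples$group == config$group_labels[2]

  mu <- stats::rnorm(n_g, 5, 1.5)
  shift <- stats::setNames(rep(0, n_g), ids)

  filler <- ids[grepl("^G\\d+$", ids)]
  n_deg <- min(config$n_deg, length(filler))
  deg_genes <- if (n_deg > 0) sample(filler, n_deg) else character()
  deg_sign <- rep(c(1, -1), length.out = n_deg)
  shift[deg_genes] <- deg_sign * config$lfc_scale

  panel_present <- intersect(viral_mimicry_panel, ids)
  shift[panel_present] <- shift[panel_present] + config$panel_lfc
  if ("CD274" %in% ids) shift["CD274"] <- config$anchor_lfc

  rho <- config$coupling_rho
  coupled <- c(DNMT3A = rho, UHRF2 = -rho, CD274 = -rho)
  coupled <- coupled[names(coupled) %in% ids & abs(coupled) > 0]

  g_s <- truth_global_median(truth)[samples]
  z_g <- stats::qnorm((rank(g_s) - 0.5) / n_s)

  lx <- matrix(rep(mu, n_s), n_g, n_s, dimnames = list(ids, samples))
  lx <- lx + outer(shift, as.numeric(is_b))
  for (g in names(coupled)) {
    r <- coupled[[g]]
    latent <- r * z_g + sqrt(1 - r^2) * stats::rnorm(n_s)
    lx[g, ] <- lx[g, ] + 2.5 * latent
  }
  lx <- lx + matrix(stats::rnorm(n_g * n_s, 0, config$expr_sd), n_g, n_s)
  expr <- expr_tibble(2^lx)

  truth$expression <- list(
    baseline = tibble::tibble(gene_id = ids, mu = mu),
    true_deg = tibble::tibble(gene_id = deg_genes, lfc = deg_sign * config$lfc_scale),
    true_regulator_rho = tibble::tibble(gene_id = names(coupled),
                                        rho = unname(coupled)),
    anchor = "CD274",
    panel = panel_present)
  list(expr = expr, truth = truth)
}

#' Simulate a complete synthetic input bundle
#'
#' Runs genome generation, digestion, classification, methylome planting,
#' count sampling and expression generation, and (optionally) writes the
#' whole bundle — genome FASTA, gene table, repeat BED, per-sample Bismark
#' coverage files, expression TSV, design TSV and truth tables — to a
#' directory.
#'
#' @param config A [sim_config()].
#' @param dir Output directory, or `NULL` to skip writing.
#' @return List: `genome`, `genes`, `repeats`, `fragments` (classified),
#'   `truth`, `calls`, `design`, `expr`, and `files` (named paths when
#'   written).
#' @export
simulate_bundle <- function(config = sim_config(), dir = NULL) {
  gen <- sim_genome(config)
  frags <- mspi_digest(gen$genome, config$size_range)
  lens <- stats::setNames(nchar(gen$genome), names(gen$genome))
  elements <- derive_elements(gen$genes, lens)
  frags <- classify_fragments(frags, elements, gen$repeats)
  labels <- meth_label(frags)
  truth <- sim_methylome(frags, labels, config)
  calls <- sample_counts(truth, frags, config, genome = gen$genome)
  design <- sim_design(truth)
  ex <- sim_expression(truth, config)
  truth <- ex$truth
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(gen$genome), fa)
    write_gene_table(gen$genes, file.path(dir, "genes.tsv"))
    write_repeat_bed(gen$repeats, file.path(dir, "repeats.bed"))
    write_design(design, file.path(dir, "design.tsv"))
    cov_files <- vapply(design$sample_id, function(s) {
      p <- file.path(dir, paste0(s, ".cov"))
      write_bismark_cov(calls[calls$sample_id == s, ], p)
      p
    }, character(1))
    write_expression(ex$expr, file.path(dir, "expression.tsv"))
    readr::write_tsv(truth$fragments, file.path(dir, "truth_fragments.tsv"))
    readr::write_tsv(truth$samples, file.path(dir, "truth_samples.tsv"))
    readr::write_tsv(truth$expression$true_deg, file.path(dir, "truth_deg.tsv"))
    files <- c(genome = fa, genes = file.path(dir, "genes.tsv"),
               repeats = file.path(dir, "repeats.bed"),
               design = file.path(dir, "design.tsv"),
               expression = file.path(dir, "expression.tsv"),
               cov_files)
  }
  list(genome = gen$genome, genes = gen$genes, repeats = gen$repeats,
       fragments = frags, truth = truth, calls = calls, design = design,
       expr = ex$expr, files = files)
}
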