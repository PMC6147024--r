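# Pipeline orchestration: a single validated run configuration, staged
# execution digest -> quantify -> annotate -> diffmeth -> diffexpr ->
# integrate, and a JSON run manifest recording every default that stands
# in for an unpublished study parameter.

#' Pipeline run configuration
#'
#' All inputs and thresholds of a full run. Unknown arguments are
#' rejected; the configuration is echoed verbatim into the run manifest.
#'
#' @param genome_fasta Reference genome FASTA.
#' @param gene_table Gene model TSV (see [read_gene_table()]).
#' @param repeat_bed Optional repeat BED (see [read_repeat_bed()]).
#' @param meth_dir Directory of Bismark coverage files named
#'   `<sample_id>.cov`.
#' @param expression_tsv FPKM matrix TSV (genes x samples).
#' @param design_tsv Sample design TSV (sample_id, group).
#' @param enhancer_bed Optional gene-linked enhancer BED.
#' @param outdir Output directory.
#' @param size_range RRBS size-selection window (bp).
#' @param min_reads,min_samples_per_group Fragment coverage
#'   standardisation.
#' @param alpha_dmf,delta_dmf DMF thresholds (FDR level, min |difference|).
#' @param alpha_deg,min_lfc,eps DEG thresholds and pseudocount.
#' @param promoter_up,promoter_down Promoter window (bp).
#' @param repeat_min_overlap Repeat-family assignment rule.
#' @param anchor_gene Anchor gene for the correlation analyses.
#' @param regulators Regulator panel for the correlogram.
#' @param seed Integer seed (recorded; the pipeline stages themselves are
#'   deterministic).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(genome_fasta, gene_table, meth_dir, expression_tsv,
                            design_tsv, repeat_bed = NULL, enhancer_bed = NULL,
                            outdir = "methfrag_out",
                            size_range = c(40, 220),
                            min_reads = 10, min_samples_per_group = 3,
                            alpha_dmf = 0.05, delta_dmf = 0.25,
                            alpha_deg = 0.05, min_lfc = 2, eps = 1,
                            promoter_up = 5000, promoter_down = 1000,
                            repeat_min_overlap = 0.5,
                            anchor_gene = "CD274",
                            regulators = epigenetic_regulators,
                            seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

require_input <- function(path, what) {
  if (is.null(path)) return(invisible(NULL))
  if (!file.exists(path)) {
    rlang::abort(sprintf("missing input: %s (%s)", what, path),
                 class = "methfrag_validation_error")
  }
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 class = "methfrag_stage_error", parent = e)
  })
}

#' Run the full fragment-methylation pipeline
#'
#' Executes digestion, fragment quantification, element/repeat annotation,
#' DMF calling, DEG calling, the correlation analyses and the DMF-DEG
#' integration, writing every stage table plus a JSON manifest to the
#' configured output directory. Re-running with an identical configuration
#' and inputs reproduces identical tables.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly alongside the stage results
#'   in `$results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  require_input(config$genome_fasta, "genome FASTA")
  require_input(config$gene_table, "gene table")
  require_input(config$expression_tsv, "expression matrix")
  require_input(config$design_tsv, "design table")
  require_input(config$repeat_bed, "repeat BED")
  require_input(config$enhancer_bed, "enhancer BED")
  if (!dir.exists(config$meth_dir)) {
    rlang::abort(sprintf("missing input: coverage directory (%s)", config$meth_dir),
                 class = "methfrag_validation_error")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  design <- run_stage("design", read_design(config$design_tsv))
  cov_paths <- stats::setNames(
    file.path(config$meth_dir, paste0(design$sample_id, ".cov")),
    design$sample_id)
  for (p in cov_paths) require_input(p, "coverage file")

  genome <- run_stage("digest", {
    g <- Biostrings::readDNAStringSet(config$genome_fasta)
    names(g) <- sub("\\s.*$", "", names(g))
    as_genome(g)
  })
  fragments <- run_stage("digest", mspi_digest(genome, config$size_range))
  genes <- run_stage("annotate", read_gene_table(config$gene_table))
  lens <- stats::setNames(nchar(genome), names(genome))
  elements <- run_stage("annotate",
                        derive_elements(genes, lens, config$promoter_up, config$promoter_down))
  repeats <- run_stage("annotate", {
    if (is.null(config$repeat_bed)) NULL else read_repeat_bed(config$repeat_bed)
  })
  fragments <- run_stage("annotate",
                         classify_fragments(fragments, elements, repeats,
                                            config$repeat_min_overlap))

  calls <- run_stage("quantify", read_meth_calls(cov_paths))
  fm <- run_stage("quantify",
                  quantify_fragments(calls, fragments, design,
                                     config$min_reads, config$min_samples_per_group))

  summary <- run_stage("diffmeth", global_summary(fm))
  dmfs <- run_stage("diffmeth", call_dmfs(fm, config$alpha_dmf, config$delta_dmf))

  expr <- run_stage("diffexpr", read_expression(config$expression_tsv))
  degs <- run_stage("diffexpr",
                    call_degs(expr, design, config$alpha_deg, config$min_lfc, config$eps))

  correlogram <- run_stage("integrate", {
    if (config$anchor_gene %in% expr$gene_id) {
      suppressWarnings(regulator_correlogram(
        expr, config$regulators, config$anchor_gene, summary$per_sample_median))
    } else NULL
  })
  enhancers <- if (is.null(config$enhancer_bed)) NULL else read_enhancer_bed(config$enhancer_bed)
  integration <- run_stage("integrate",
                           integrate_dmf_deg(dmfs, degs, genes, enhancers, lens,
                                             config$promoter_up, config$promoter_down))

  out <- function(f) file.path(config$outdir, f)
  write_fragment_bed(fm$fragments, out("fragments.bed"))
  write_meth_matrix(fm, out("fragment_methylation.tsv"))
  write_dmf_table(dmfs, out("dmf.tsv"))
  readr::write_tsv(degs, out("deg.tsv"))
  write_integration_table(integration, out("integration.tsv"))
  if (!is.null(correlogram)) {
    write_correlogram(correlogram, out("correlogram.tsv"), out("correlogram.json"))
  }
  jsonlite::write_json(
    list(group_median = as.list(summary$group_median),
         median_diff = summary$median_diff,
         wilcoxon = summary$wilcoxon,
         per_sample_median = as.list(summary$per_sample_median),
         elements = summary$elements),
    out("global_summary.json"), auto_unbox = TRUE, digits = NA)

  inputs <- purrr::compact(list(
    genome = config$genome_fasta, genes = config$gene_table,
    repeats = config$repeat_bed, expression = config$expression_tsv,
    design = config$design_tsv, enhancers = config$enhancer_bed))
  manifest <- list(
    config = config[setdiff(names(config), "regulators")],
    regulators = config$regulators,
    input_md5 = as.list(c(unlist(lapply(inputs, tools::md5sum)),
                          tools::md5sum(cov_paths))),
    counts = list(
      fragments_digested = nrow(fragments),
      fragments_quantified = nrow(fm$fragments),
      fragments_excluded_no_cpg = fm$n_excluded_no_cpg,
      fragments_excluded_quorum = fm$n_excluded_quorum,
      fragments_tested = nrow(dmfs),
      fragments_skipped_in_test = attr(dmfs, "n_skipped"),
      n_dmf = sum(dmfs$is_dmf),
      genes_tested = nrow(degs),
      genes_excluded_zero = attr(degs, "n_excluded_zero"),
      n_deg = sum(degs$is_deg),
      integration_records = nrow(integration)),
    version = as.character(utils::packageVersion("methfrag")),
    timestamp = format(Sys.time(), tz = "UTC"))
  class(manifest$config) <- NULL
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  manifest$results <- list(fm = fm, summary = summary, dmfs = dmfs,
                           degs = degs, integration = integration,
                           correlogram = correlogram)
  invisible(manifest)
}
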