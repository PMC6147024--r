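# Genomic-element derivation from gene models and fragment classification.
# Element classes: promoter (TSS -5 kb / +1 kb in transcription
# orientation), exon, intron, intergenic. Promoter bases are carved out of
# gene bodies so the four classes are disjoint.

REPEAT_FAMILIES <- c("L1", "L2", "Alu", "MIR", "ERV1", "ERVK", "ERVL",
                     "ERVL-MaLR", "satellite")

parse_int_list <- function(x) {
  if (is.list(x)) return(lapply(x, as.integer))
  lapply(strsplit(as.character(x), ","), function(v) as.integer(v[nzchar(v)]))
}

# normalise a gene table: exon_starts/exon_ends become integer list-columns
as_gene_table <- function(genes) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  if (!all(need %in% names(genes))) {
    abort_field("genes", paste("missing columns:", paste(setdiff(need, names(genes)), collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort_field("strand", "must be '+' or '-'")
  }
  g <- tibble::as_tibble(genes)
  if (!"exon_starts" %in% names(g)) {
    g$exon_starts <- as.list(g$tx_start)
    g$exon_ends <- as.list(g$tx_end)
  } else {
    g$exon_starts <- parse_int_list(g$exon_starts)
    g$exon_ends <- parse_int_list(g$exon_ends)
  }
  g
}

#' Read a tab-delimited gene table
#'
#' Columns: gene_id, chrom, strand, tx_start, tx_end, exon_starts,
#' exon_ends (comma-separated, 0-based half-open).
#' @param path Path to the TSV.
#' @return Gene tibble with exon list-columns.
#' @export
read_gene_table <- function(path) {
  as_gene_table(readr::read_tsv(path, show_col_types = FALSE,
                                col_types = readr::cols(
                                  exon_starts = readr::col_character(),
                                  exon_ends = readr::col_character(),
                                  .default = readr::col_guess())))
}

#' @export
write_gene_table <- function(genes, path) {
  g <- as_gene_table(genes)
  out <- tibble::tibble(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    tx_start = g$tx_start, tx_end = g$tx_end,
    exon_starts = purrr::map_chr(g$exon_starts, paste, collapse = ","),
    exon_ends = purrr::map_chr(g$exon_ends, paste, collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a RepeatMasker-style repeat BED
#'
#' BED with columns chrom, start, end, family (0-based half-open); family
#' labels must come from the controlled vocabulary
#' L1, L2, Alu, MIR, ERV1, ERVK, ERVL, ERVL-MaLR, satellite.
#' @param path Path to the BED file.
#' @return Repeat tibble.
#' @export
read_repeat_bed <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "family"),
                           colClasses = c("character", "integer", "integer", "character"))
  validate_repeats(tibble::as_tibble(tbl))
}

validate_repeats <- function(repeats) {
  if (is.null(repeats) || nrow(repeats) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), family = character()))
  }
  bad <- setdiff(unique(repeats$family), REPEAT_FAMILIES)
  if (length(bad)) abort_field("family", paste("unknown repeat families:", paste(bad, collapse = ", ")))
  if (any(repeats$start >= repeats$end) || any(repeats$start < 0)) {
    abort_field("repeats", "intervals must satisfy 0 <= start < end")
  }
  tibble::as_tibble(repeats)
}

#' @export
write_repeat_bed <- function(repeats, path) {
  utils::write.table(repeats[c("chrom", "start", "end", "family")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# strand-aware promoter window, clipped to [0, chrom_len)
promoter_window <- function(tx_start, tx_end, strand, chrom_len,
                            up = 5000, down = 1000) {
  tss <- ifelse(strand == "+", tx_start, tx_end)
  start <- ifelse(strand == "+", tss - up, tss - down)
  end <- ifelse(strand == "+", tss + down, tss + up)
  tibble::tibble(start = pmax(0L, as.integer(start)),
                 end = pmin(as.integer(chrom_len), as.integer(end)))
}

ir <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)  # 0-based -> IRanges
ir_tbl <- function(x) {
  tibble::tibble(start = BiocGenerics::start(x) - 1L, end = BiocGenerics::end(x))
}

#' Derive promoter / exon / intron / intergenic element intervals
#'
#' Promoter = TSS -`promoter_up` to +`promoter_down` in transcription
#' orientation (reflected on the minus strand), clipped to the chromosome;
#' exon = exonic bases outside promoters; intron = gene-span bases outside
#' exons and promoters; intergenic = the remainder. The four classes
#' partition the genome.
#'
#' @param genes Gene table (see [read_gene_table()]).
#' @param genome_lengths Named integer vector of chromosome lengths.
#' @param promoter_up,promoter_down Promoter window in bp (defaults 5000
#'   and 1000, the -5 kb/+1 kb convention).
#' @return An `element_map`: tibble of (chrom, start, end, element_class).
#' @export
derive_elements <- function(genes, genome_lengths,
                            promoter_up = 5000, promoter_down = 1000) {
  genes <- as_gene_table(genes)
  if (any(!genes$chrom %in% names(genome_lengths))) {
    abort_field("genes", "chromosome absent from genome_lengths")
  }
  if (any(genes$tx_start < 0 | genes$tx_end > genome_lengths[genes$chrom])) {
    abort_field("genes", "gene outside chromosome bounds")
  }
  out <- purrr::map_dfr(names(genome_lengths), function(ch) {
    L <- genome_lengths[[ch]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    chrom_ir <- ir(0L, L)
    if (nrow(g) == 0L) {
      return(tibble::tibble(chrom = ch, start = 0L, end = as.integer(L),
                            element_class = "intergenic"))
    }
    pw <- promoter_window(g$tx_start, g$tx_end, g$strand, L,
                          promoter_up, promoter_down)
    prom <- IRanges::reduce(ir(pw$start, pw$end))
    exon <- IRanges::reduce(ir(unlist(g$exon_starts), unlist(g$exon_ends)))
    span <- IRanges::reduce(ir(g$tx_start, g$tx_end))
    exon_el <- IRanges::setdiff(exon, prom)
    intron_el <- IRanges::setdiff(IRanges::setdiff(span, exon), prom)
    inter_el <- IRanges::setdiff(IRanges::setdiff(chrom_ir, span), prom)
    dplyr::bind_rows(
      dplyr::mutate(ir_tbl(prom), element_class = "promoter"),
      dplyr::mutate(ir_tbl(exon_el), element_class = "exon"),
      dplyr::mutate(ir_tbl(intron_el), element_class = "intron"),
      dplyr::mutate(ir_tbl(inter_el), element_class = "intergenic")
    ) |>
      dplyr::mutate(chrom = ch, .before = 1)
  })
  class(out) <- c("element_map", class(out))
  out
}

#' Classify fragments into element classes and repeat families
#'
#' Element class is assigned by >= 1 bp overlap under the precedence
#' promoter > exon > intron, defaulting to intergenic. Repeat families are
#' assigned independently: every family whose intervals cover at least
#' `repeat_min_overlap` of the fragment length is attached.
#'
#' @param fragments Fragment tibble (from [mspi_digest()]).
#' @param elements An `element_map` from [derive_elements()].
#' @param repeats Optional repeat tibble (see [read_repeat_bed()]).
#' @param repeat_min_overlap Minimum covered fraction for a repeat family
#'   label (default 0.5).
#' @return The fragment tibble with `element_class` (character) and
#'   `repeat_families` (list of character) columns added.
#' @export
classify_fragments <- function(fragments, elements, repeats = NULL,
                               repeat_min_overlap = 0.5) {
  repeats <- validate_repeats(repeats)
  frags <- fragments
  frags$element_class <- "intergenic"
  frags$repeat_families <- rep(list(character()), nrow(frags))
  for (ch in unique(frags$chrom)) {
    fi <- which(frags$chrom == ch)
    fr <- ir(frags$start[fi], frags$end[fi])
    cls <- rep("intergenic", length(fi))
    for (k in c("intron", "exon", "promoter")) {  # ascending precedence
      e <- elements[elements$chrom == ch & elements$element_class == k, ]
      if (nrow(e) == 0L) next
      hit <- IRanges::overlapsAny(fr, ir(e$start, e$end), minoverlap = 1L)
      cls[hit] <- k
    }
    frags$element_class[fi] <- cls
    rp <- repeats[repeats$chrom == ch, , drop = FALSE]
    if (nrow(rp)) {
      fam_lists <- vector("list", length(fi))
      for (fam in unique(rp$family)) {
        r <- rp[rp$family == fam, ]
        rir <- IRanges::reduce(ir(r$start, r$end))
        ov <- IRanges::findOverlaps(fr, rir)
        w <- BiocGenerics::width(IRanges::pintersect(
          fr[S4Vectors::queryHits(ov)], rir[S4Vectors::subjectHits(ov)]))
        covered <- rep(0, length(fi))
        if (length(w)) {
          sums <- tapply(w, S4Vectors::queryHits(ov), sum)
          covered[as.integer(names(sums))] <- as.numeric(sums)
        }
        frac <- covered / frags$length[fi]
        for (i in which(frac >= repeat_min_overlap)) {
          fam_lists[[i]] <- c(fam_lists[[i]], fam)
        }
      }
      frags$repeat_families[fi] <- lapply(fam_lists, function(x) x %||% character())
    }
  }
  frags
}

#' @export
write_element_bed <- function(elements, path) {
  utils::write.table(elements[c("chrom", "start", "end", "element_class")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
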