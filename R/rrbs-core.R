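# In-silico MspI digestion, Bismark-coverage ingestion and per-fragment
# methylation quantification. All internal coordinates are 0-based,
# half-open; only the Bismark dialect converts (1-based inclusive).

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome)) || any(names(genome) == "")) {
    rlang::abort("genome must be a named character vector or DNAStringSet")
  }
  if (anyDuplicated(names(genome))) rlang::abort("chromosome names must be unique")
  if (any(nchar(genome) == 0L)) rlang::abort("chromosome sequences must be non-empty")
  toupper(genome)
}

# 0-based start positions of a fixed pattern, including overlapping hits
pattern_starts0 <- function(seq, pattern) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq))
  BiocGenerics::start(m) - 1L
}

#' In-silico MspI digestion of a genome
#'
#' MspI cuts C^CGG; every CCGG occurrence therefore produces a cut one base
#' after the match start. Fragments are the intervals between consecutive
#' cuts, closed by the chromosome ends, and are then size-selected to the
#' library window. CCGG containing N never matches.
#'
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param size_range Length-2 numeric `c(min_bp, max_bp)` retained after
#'   digestion, or `NULL` to keep all fragments. The default 40-220 bp is a
#'   typical RRBS size-selection window.
#' @return A tibble with one row per retained fragment: `fragment_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `length`, and `n_cpg`,
#'   the number of CG dinucleotides starting inside the fragment.
#' @examples
#' mspi_digest(c(chr1 = "ACCGGTTCCGGA"), size_range = NULL)
#' @export
mspi_digest <- function(genome, size_range = c(40, 220)) {
  genome <- as_genome(genome)
  if (!is.null(size_range)) {
    if (length(size_range) != 2L || size_range[1] > size_range[2]) {
      abort_field("size_range", "must be c(min_bp, max_bp) with min_bp <= max_bp")
    }
  }
  frags <- purrr::map2_dfr(names(genome), unname(genome), function(chrom, seq) {
    L <- nchar(seq)
    cuts <- pattern_starts0(seq, "CCGG") + 1L   # cut offset +1 from match start
    bounds <- unique(c(0L, cuts, L))
    cg <- pattern_starts0(seq, "CG")
    start <- bounds[-length(bounds)]
    end <- bounds[-1]
    # CpG counted when its C lies within [start, end), matching the
    # assignment rule for per-CpG calls
    n_cpg <- if (length(cg)) {
      findInterval(end - 0.5, cg) - findInterval(start - 0.5, cg)
    } else rep(0L, length(start))
    tibble::tibble(chrom = chrom, start = start, end = end,
                   length = end - start, n_cpg = as.integer(n_cpg))
  })
  if (!is.null(size_range)) {
    frags <- dplyr::filter(frags, .data$length >= size_range[1],
                           .data$length <= size_range[2])
  }
  dplyr::mutate(frags,
                fragment_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end),
                .before = 1)
}

#' Read per-CpG methylation calls in Bismark coverage format
#'
#' Bismark coverage files are one sample each:
#' `chrom  start  end  %methylation  count_methylated  count_unmethylated`
#' with 1-based inclusive positions. Positions are converted to 0-based;
#' rows with zero total reads are dropped (their count is reported in the
#' `n_dropped_zero` attribute); a percentage inconsistent with the counts by
#' more than 0.5 points is an error.
#'
#' @param path Path to the coverage file.
#' @param sample_id Sample identifier attached to every record.
#' @return A tibble (`chrom`, `pos`, `sample_id`, `n_meth`, `n_unmeth`).
#' @export
read_bismark_cov <- function(path, sample_id) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "pct", "n_meth", "n_unmeth"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric", "integer", "integer"))
  if (any(is.na(tbl$start) | is.na(tbl$n_meth) | is.na(tbl$n_unmeth))) {
    bad <- which(is.na(tbl$start) | is.na(tbl$n_meth) | is.na(tbl$n_unmeth))[1]
    rlang::abort(sprintf("malformed coverage line %d in %s", bad, path))
  }
  if (any(tbl$n_meth < 0 | tbl$n_unmeth < 0)) {
    rlang::abort(sprintf("negative read count in %s", path))
  }
  total <- tbl$n_meth + tbl$n_unmeth
  zero <- total == 0L
  keep <- tbl[!zero, , drop = FALSE]
  expected <- 100 * keep$n_meth / (keep$n_meth + keep$n_unmeth)
  off <- which(abs(expected - keep$pct) > 0.5)
  if (length(off)) {
    rlang::abort(sprintf(
      "line %d of %s: %% methylation %.2f inconsistent with counts %d/%d",
      which(!zero)[off[1]], path, keep$pct[off[1]], keep$n_meth[off[1]], keep$n_unmeth[off[1]]))
  }
  out <- tibble::tibble(chrom = keep$chrom, pos = keep$start - 1L,
                        sample_id = sample_id,
                        n_meth = keep$n_meth, n_unmeth = keep$n_unmeth)
  if (anyDuplicated(out[c("chrom", "pos")])) {
    rlang::abort(sprintf("duplicate (chrom, pos) record in %s", path))
  }
  attr(out, "n_dropped_zero") <- sum(zero)
  out
}

#' Write one sample's calls as a Bismark coverage file
#'
#' @param calls Methylation-call tibble for a single sample (0-based `pos`).
#' @param path Output path.
#' @export
write_bismark_cov <- function(calls, path) {
  stopifnot(length(unique(calls$sample_id)) <= 1L)
  pct <- 100 * calls$n_meth / (calls$n_meth + calls$n_unmeth)
  df <- data.frame(chrom = calls$chrom, start = calls$pos + 1L, end = calls$pos + 1L,
                   pct = formatC(pct, format = "g", digits = 15),
                   n_meth = calls$n_meth, n_unmeth = calls$n_unmeth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a set of Bismark coverage files into one call table
#'
#' @param paths Named character vector, names are sample ids.
#' @return Combined methylation-call tibble.
#' @export
read_meth_calls <- function(paths) {
  stopifnot(!is.null(names(paths)))
  purrr::imap_dfr(paths, function(p, s) read_bismark_cov(p, s))
}

# assign call positions to fragments; returns integer index into frags or NA
match_fragment <- function(chrom, pos, frags) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    f <- which(frags$chrom == ch)
    if (!length(f)) next
    o <- order(frags$start[f])
    f <- f[o]
    j <- findInterval(pos[sel], frags$start[f])
    ok <- j >= 1L & pos[sel] < frags$end[f][pmax(j, 1L)]
    idx[sel][ok] <- f[j[ok]]
  }
  idx
}

#' Per-fragment methylation quantification with coverage standardisation
#'
#' Pools methylated and total read counts over every CpG of a fragment, per
#' sample, so the fragment proportion is read-weighted
#' (sum n_meth / sum total), not a mean of per-CpG proportions. A
#' fragment-sample cell is "covered" when its pooled read total reaches
#' `min_reads`; a fragment is retained only when covered in at least
#' `min_samples_per_group` samples in each group.
#'
#' @param calls Methylation-call tibble (see [read_bismark_cov()]).
#' @param fragments Fragment tibble from [mspi_digest()].
#' @param design A [study_design()].
#' @param min_reads Minimum pooled reads for a covered cell (default 10).
#' @param min_samples_per_group Coverage quorum per group (default 3).
#' @return An object of class `frag_meth`: the retained fragment table plus
#'   fragment-by-sample matrices `meth` (proportion, NA where not covered),
#'   `coverage` (pooled reads) and `mask` (covered cells).
#' @export
quantify_fragments <- function(calls, fragments, design,
                               min_reads = 10, min_samples_per_group = 3) {
  stopifnot(inherits(design, "study_design"))
  extra <- setdiff(unique(calls$sample_id), design$sample_id)
  if (length(extra)) {
    rlang::abort(sprintf("samples in calls not in design: %s",
                         paste(extra, collapse = ", ")))
  }
  n0 <- sum(fragments$n_cpg == 0L)
  frags <- dplyr::filter(fragments, .data$n_cpg > 0L)
  if (n0 > 0) rlang::inform(sprintf("excluded %d fragments without CpGs", n0))

  fidx <- match_fragment(calls$chrom, calls$pos, frags)
  dat <- calls[!is.na(fidx), ]
  dat$fragment <- fidx[!is.na(fidx)]

  samples <- design$sample_id
  nm_mat <- cov_mat <- matrix(0, nrow = nrow(frags), ncol = length(samples),
                              dimnames = list(frags$fragment_id, samples))
  agg <- dplyr::summarise(
    dplyr::group_by(dat, .data$fragment, .data$sample_id),
    nm = sum(.data$n_meth), tot = sum(.data$n_meth + .data$n_unmeth),
    .groups = "drop")
  ij <- cbind(agg$fragment, match(agg$sample_id, samples))
  nm_mat[ij] <- agg$nm
  cov_mat[ij] <- agg$tot

  mask <- cov_mat >= min_reads & cov_mat > 0
  meth <- ifelse(mask, nm_mat / cov_mat, NA_real_)

  gA <- group_samples(design, "A"); gB <- group_samples(design, "B")
  quorum <- rowSums(mask[, gA, drop = FALSE]) >= min_samples_per_group &
    rowSums(mask[, gB, drop = FALSE]) >= min_samples_per_group
  n_quorum_fail <- sum(!quorum)
  if (n_quorum_fail > 0) {
    rlang::inform(sprintf("excluded %d fragments failing the coverage quorum", n_quorum_fail))
  }
  structure(list(
    fragments = frags[quorum, , drop = FALSE],
    meth = meth[quorum, , drop = FALSE],
    coverage = cov_mat[quorum, , drop = FALSE],
    mask = mask[quorum, , drop = FALSE],
    design = design,
    params = list(min_reads = min_reads, min_samples_per_group = min_samples_per_group),
    n_excluded_no_cpg = n0,
    n_excluded_quorum = n_quorum_fail
  ), class = "frag_meth")
}

#' @export
print.frag_meth <- function(x, ...) {
  cat(sprintf("<frag_meth> %d fragments x %d samples (groups %s)\n",
              nrow(x$meth), ncol(x$meth),
              paste(design_groups(x$design), collapse = " vs ")))
  cat(sprintf("  covered cells: %.1f%%; min_reads=%d, quorum=%d/group\n",
              100 * mean(x$mask), x$params$min_reads, x$params$min_samples_per_group))
  invisible(x)
}

#' Tidy a fragment methylation matrix into long form
#'
#' @param x A `frag_meth` object.
#' @param ... Unused.
#' @return Long tibble: fragment_id, sample_id, group, methylation,
#'   coverage, covered.
#' @export
tidy.frag_meth <- function(x, ...) {
  long <- tibble::tibble(
    fragment_id = rep(rownames(x$meth), ncol(x$meth)),
    sample_id = rep(colnames(x$meth), each = nrow(x$meth)),
    methylation = as.vector(x$meth),
    coverage = as.vector(x$coverage),
    covered = as.vector(x$mask)
  )
  dplyr::left_join(long, tibble::tibble(sample_id = x$design$sample_id,
                                        group = x$design$group), by = "sample_id")
}

#' Write fragments as BED (score column = CpG count)
#' @export
write_fragment_bed <- function(fragments, path) {
  df <- data.frame(fragments$chrom, fragments$start, fragments$end,
                   fragments$fragment_id, fragments$n_cpg, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the fragment-by-sample methylation matrix as TSV
#' @export
write_meth_matrix <- function(fm, path) {
  m <- tibble::as_tibble(fm$meth, rownames = "fragment_id")
  readr::write_tsv(m, path)
  invisible(path)
}
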