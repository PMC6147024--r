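# shared fixtures and independent oracles used across the suite

# brute-force MspI scanner: walk the string, cut after the first C of each
# CCGG, return 0-based half-open fragments
brute_digest <- function(seq) {
  L <- nchar(seq)
  cuts <- integer()
  for (i in seq_len(max(L - 3, 0))) {
    if (substr(seq, i, i + 3) == "CCGG") cuts <- c(cuts, i)  # 0-based cut = (i-1)+1
  }
  bounds <- unique(c(0L, cuts, L))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

# random DNA sequence
rand_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob), collapse = "")
}

# build a frag_meth object directly from a methylation matrix (tests of the
# statistical layer that do not need the count machinery)
make_fm <- function(meth, design, coverage = NULL, mask = NULL) {
  n <- nrow(meth)
  if (is.null(rownames(meth))) rownames(meth) <- sprintf("frag%03d", seq_len(n))
  colnames(meth) <- design$sample_id
  if (is.null(coverage)) coverage <- matrix(50, n, ncol(meth), dimnames = dimnames(meth))
  if (is.null(mask)) mask <- !is.na(meth)
  frags <- tibble::tibble(fragment_id = rownames(meth), chrom = "chr1",
                          start = seq_len(n) * 1000L,
                          end = seq_len(n) * 1000L + 100L,
                          length = 100L, n_cpg = 2L)
  structure(list(fragments = frags, meth = meth, coverage = coverage,
                 mask = mask, design = design,
                 params = list(min_reads = 10, min_samples_per_group = 3),
                 n_excluded_no_cpg = 0L, n_excluded_quorum = 0L),
            class = "frag_meth")
}

design_6v6 <- function() {
  study_design(data.frame(
    sample_id = c(paste0("IND_", 1:6), paste0("CON_", 1:6)),
    group = rep(c("IND", "CON"), each = 6)))
}

# Benjamini-Hochberg step-up, written from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail P(X >= k) by direct enumeration
brute_hyper_tail <- function(k, A, U, S) {
  j <- k:min(A, S)
  sum(choose(A, j) * choose(U - A, S - j)) / choose(U, S)
}

# per-base interval membership oracle
base_overlap <- function(start, end, iv_start, iv_end) {
  if (length(iv_start) == 0L) return(0L)
  bases <- start:(end - 1L)
  sum(vapply(bases, function(b) any(b >= iv_start & b < iv_end), logical(1)))
}

# mean of a negative-binomial depth conditioned on being positive
mean_trunc_nb <- function(mu, size) {
  mu / (1 - stats::dnbinom(0, mu = mu, size = size))
}
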