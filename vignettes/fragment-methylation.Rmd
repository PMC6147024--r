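---
title: "Fragment-level RRBS differential methylation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-level RRBS differential methylation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methfrag)
```

## Scope

methfrag analyses reduced representation bisulfite sequencing (RRBS) data at
the level of MspI restriction fragments rather than individual CpGs, and
integrates the resulting differential methylation with a matched
transcriptome. This vignette documents the statistical model, the default
parameters, the synthetic-data generator the test suite relies on, and the
limitations of each choice.

## The fragment unit

RRBS libraries are built from an MspI digest, so the natural unit of
quantification is the fragment between consecutive `C^CGG` cut sites.
`mspi_digest()` locates every `CCGG` occurrence on the forward strand of the
reference and cuts after the first base (offset +1 from the match start);
chromosome ends close the terminal fragments. Coordinates are 0-based,
half-open internally; BED exports keep that convention and Bismark coverage
files are converted from their 1-based inclusive positions on the way in.
Size selection (default 40–220 bp) models the library's fragment window.

Assumptions: digestion is complete (no partial digests), only the forward
strand is scanned (`CCGG` is its own reverse complement, so cut *sites*
agree; the one-base cut-offset asymmetry between strands is ignored), and
`N` bases never match.

## Fragment quantification

For each sample, all CpG calls falling inside a fragment are pooled:
the fragment proportion is the read-weighted ratio
`sum(n_meth) / sum(n_meth + n_unmeth)`. A fragment is *covered* in a sample
when the pooled read count reaches `min_reads` (default 10), and enters the
analysis only when covered in at least `min_samples_per_group` (default 3)
samples of *each* group. Pooling trades CpG-level resolution for stable
proportions at modest depth, which is the appropriate regime for
fragment-level RRBS.

## Differential methylation

Per fragment, the two groups are compared with a one-way ANOVA on the
per-sample proportions (with two groups, F equals the squared pooled-variance
t statistic); p-values are Benjamini–Hochberg adjusted over all tested
fragments. A fragment is a differentially methylated fragment (DMF) when
q ≤ 0.05 **and** the absolute difference of group means is ≥ 0.25.
Differences are reported as group B minus group A (the first design level is
the reference), so `direction = "hypo"` means group B is lower. Fragments
with zero variance in both groups take p = 1 by convention; zero
within-group variance with a real between-group difference saturates at
F = ∞, p = 0. A coverage-weighted variant (`weighted = TRUE`) weights each
sample by its pooled read count.

The ANOVA on proportions is a normal approximation; it ignores the binomial
mean–variance relationship. At the default depth (≥10 pooled reads over
several CpGs) this is acceptable and is what the test suite calibrates: under
a beta-binomial null the raw p ≤ 0.05 fraction stays within 0.05 ± 0.02.

## Genomic context

Promoters are defined as −5 kb to +1 kb around the TSS, reflected on the
minus strand and clipped at chromosome ends. Element classes partition each
chromosome with precedence promoter > exon > intron > intergenic (promoter
windows are carved out of gene bodies). Repeat families (L1, L2, Alu, MIR,
ERV1, ERVK, ERVL, ERVL-MaLR, satellite) are assigned to a fragment when they
cover at least 50% of its bases. Both rules are exact interval arithmetic,
verified against per-base oracles in the tests.

## Expression and integration

Differential expression uses Welch's t test on `log2(FPKM + eps)` (default
`eps = 1`); the fold change is `log2((mean_B + eps)/(mean_A + eps))` on raw
group means. A gene is a DEG when q < 0.05 (strict) and |lfc| ≥ 2
(inclusive). This deliberately simple test fits the FPKM-matrix input; count
models (e.g. negative-binomial GLMs) are out of scope because raw counts are
not part of the data model.

Spearman correlations are computed as Pearson correlations of average ranks.
For n ≥ 10 the t approximation is used; for n < 10 the permutation null is
enumerated exactly. `regulator_correlogram()` correlates a panel of
epigenetic regulators, the anchor gene and the per-sample global methylation
median. Integration attributes each DMF to every gene whose promoter window,
gene body (the transcript span minus the promoter), or linked enhancer it
overlaps, and labels each (gene, fragment) pair with a concordance class
such as `body-hypo/up`. Over-representation uses the hypergeometric tail
`phyper(k − 1, ...)`.

## The synthetic-data generator

`sim_config()` / `simulate_bundle()` generate a complete study with known
ground truth:

* **Genome** — uniform random bases (so `CCGG` occurs at rate 4^−4 and mean
  fragment length ≈ 256 bp), CG-rich CpG islands stamped at every TSS and at
  extra random positions, non-overlapping gene models with exons, and
  non-overlapping repeat intervals per family at configurable genome
  fractions.
* **Methylome** — each fragment gets a class label (covering repeat family,
  else element class); group A truth is the class baseline plus N(0,
  `meth_frag_sd`) noise, group B adds the class delta, clipped to
  [0.01, 0.99]. Each sample additionally carries a logit-scale offset
  N(0, `meth_sample_sd`), giving samples their own realized methylomes —
  this within-group variation is what the regulator coupling acts on.
* **Counts** — per CpG and sample, depth is negative-binomial (mean 30,
  size 5) and methylated reads are beta-binomial with overdispersion
  `dispersion` (the intra-CpG read correlation; `a + b = (1 − φ)/φ`).
* **Expression** — log-normal FPKMs with planted ±`lfc_scale` shifts on
  filler genes, an up-shifted anchor gene and viral-mimicry panel in group
  B, and regulator genes coupled to per-sample global methylation through a
  Gaussian-rank latent variable: the DNMT3A-like regulator at
  +`coupling_rho`, the UHRF2-like regulator and the anchor at the opposite
  sign.

Default baselines and deltas are calibrated so the generated study shows the
qualitative signature the pipeline targets: strong hypomethylation of
intergenic, intronic and repeat fragments, near-zero change at promoters and
exons. One user seed is split into four independent per-stage streams
(genome, methylome, counts, expression), so e.g. regenerating counts with a
different dispersion keeps the same genome; the caller's RNG state is left
untouched.

The generator is the package's verification instrument: the test suite
recovers planted group medians (±0.02 of the realized truth), planted DMFs
(recall ≥ 0.9 at empirical FDR ≤ 0.1), planted DEGs, and planted regulator
correlations from it.

## Numerical choices

* BH adjustment, `phyper`, `pf`, `pt` and `wilcox.test` come from base
  R's stats; interval arithmetic uses IRanges; sequence matching uses
  Biostrings. Only the fragment-level logic itself is bespoke.
* All closed-form paths (F from sums of squares, exact Spearman permutation
  p, hypergeometric tails) are tested against brute-force enumerations.
* Pipelines are deterministic: rerunning an identical configuration
  reproduces bit-identical output tables, and the run manifest records
  input checksums and every threshold.

## Limitations

* Proportions, not counts, are tested; at very low coverage a beta-binomial
  likelihood test would be better calibrated than the ANOVA.
* Strand-specific methylation, partial digestion, bisulfite conversion
  failure and SNP-induced artefacts are not modelled.
* The expression layer assumes a precomputed FPKM matrix; no library-size
  normalisation or count-level inference is performed.
* The generator's genome is compositionally uniform outside CpG islands;
  it is designed for parameter recovery, not for mimicking real genome
  base composition.
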