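#' Keep only biallelic sites
#'
#' Retains variants at which exactly two alleles are observed. For panels
#' read from real data, the variant table may carry a comma-separated `alt`
#' field (multi-allelic records); such sites, and sites where only one
#' allele is actually observed in the calls, are removed. Variant order is
#' preserved.
#'
#' @param panel a [genotype_panel()].
#' @return The filtered panel; a warning (not an error) if nothing survives.
#' @export
filter_biallelic <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  multi <- grepl(",", panel$variants$alt, fixed = TRUE)
  alt <- colSums(panel$calls, na.rm = TRUE)
  total <- panel$ploidy * colSums(!is.na(panel$calls))
  two_observed <- alt > 0 & alt < total
  keep <- !multi & two_observed
  out <- recompute_variant_stats(subset_variants(panel, keep))
  if (n_variants(out) == 0) warning("no biallelic variants remain")
  out
}

#' Filter variants by missing-call count
#'
#' Removes variants whose number of missing genotypes exceeds
#' `max_missing_count`. A threshold of 0 keeps fully-called sites only (the
#' rule applied to subset matrices); the full-panel rule of keeping sites
#' called in at least `n - k` samples corresponds to `max_missing_count = k`.
#'
#' @param panel a [genotype_panel()].
#' @param max_missing_count maximum tolerated number of missing calls per
#'   variant (>= 0).
#' @return The filtered panel.
#' @export
filter_missing <- function(panel, max_missing_count) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(max_missing_count) != 1 || is.na(max_missing_count) ||
      max_missing_count < 0)
    stop("max_missing_count must be a single non-negative number")
  nm <- colSums(is.na(panel$calls))
  recompute_variant_stats(subset_variants(panel, nm <= max_missing_count))
}

#' Filter variants by minor allele frequency
#'
#' Removes variants with MAF strictly below `min_maf`; a site at exactly the
#' threshold is kept (the exclusion rule is MAF < threshold). MAF is
#' computed from non-missing calls only.
#'
#' @param panel a [genotype_panel()].
#' @param min_maf minimum MAF in [0, 0.5]; default 0.05.
#' @return The filtered panel.
#' @export
filter_maf <- function(panel, min_maf = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(min_maf) != 1 || is.na(min_maf) || min_maf < 0 || min_maf > 0.5)
    stop("min_maf must lie in [0, 0.5]")
  panel <- recompute_variant_stats(panel)
  keep <- !is.na(panel$variants$maf) & panel$variants$maf >= min_maf
  subset_variants(panel, keep)
}

#' Thin a panel to an exact variant count
#'
#' Keeps a uniform random subset of `m` variants (order preserved). Useful
#' for building calibration panels with an exact post-filter marker count.
#'
#' @param panel a [genotype_panel()].
#' @param m target variant count (<= current count).
#' @param seed optional seed.
#' @return The thinned panel.
#' @export
thin_variants <- function(panel, m, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (m > n_variants(panel))
    stop("cannot thin to ", m, " from ", n_variants(panel), " variants")
  keep <- with_seed(seed, sort(sample.int(n_variants(panel), m)))
  subset_variants(panel, keep)
}

#' Average pairwise nucleotide diversity
#'
#' Computes pi as the sum over sites of the per-site fraction of allele
#' pairs that differ, divided by the genome length (the whole-genome-window
#' convention). With `A` minor-allele copies among `N` non-missing alleles
#' at a site, the site term is `A(N-A) / (N(N-1)/2)`.
#'
#' @param panel a [genotype_panel()].
#' @param genome_length genome size in bp (> 0); defaults to the simulating
#'   config's genome length when the panel was produced by
#'   [simulate_panel()].
#' @return pi, a number in [0, 1].
#' @export
nucleotide_diversity <- function(panel, genome_length = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(genome_length)) {
    cfg <- attr(panel, "config")
    if (is.null(cfg)) stop("genome_length must be supplied")
    genome_length <- cfg$genome_length
  }
  if (genome_length <= 0) stop("genome_length must be > 0")
  alt <- colSums(panel$calls, na.rm = TRUE)
  total <- panel$ploidy * colSums(!is.na(panel$calls))
  ok <- total >= 2
  site_pi <- alt[ok] * (total[ok] - alt[ok]) /
    (total[ok] * (total[ok] - 1) / 2)
  sum(site_pi) / genome_length
}

#' Fraction of singleton variants
#'
#' A singleton is a variant whose minor allele is carried by exactly one
#' sample in the panel.
#'
#' @param panel a [genotype_panel()] with at least one variant.
#' @return Fraction in [0, 1].
#' @export
singleton_fraction <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (n_variants(panel) == 0)
    stop("singleton fraction is undefined for a panel with no variants")
  mean(minor_carrier_counts(panel) == 1L)
}

#' Recode copy-number calls as association markers
#'
#' Converts a samples x genes matrix of integer copy numbers into 1/2-coded
#' markers: code 1 for a single copy of the gene, code 2 for an amplified
#' gene (two or more copies). A copy number of 0 (gene absent) becomes a
#' missing call. Genes without variation among their non-missing codes are
#' dropped. The resulting markers are flagged `is_cnv` and can be appended
#' to a SNP panel with [bind_panels()]; internally the codes are stored as
#' haploid allele counts (code - 1), and [cnv_codes()] recovers the 1/2
#' coding.
#'
#' @param copy_numbers integer matrix (samples x genes) of copy numbers
#'   >= 0; column names are used as gene identifiers.
#' @param sample_ids optional sample identifiers (defaults to row names).
#' @return A haploid [genotype_panel()] of CNV markers.
#' @export
cnv_recode <- function(copy_numbers, sample_ids = NULL) {
  copy_numbers <- as.matrix(copy_numbers)
  if (any(copy_numbers < 0, na.rm = TRUE))
    stop("copy numbers must be >= 0")
  codes <- ifelse(copy_numbers >= 2, 2L, ifelse(copy_numbers == 1, 1L,
                                                NA_integer_))
  genes <- colnames(copy_numbers)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(copy_numbers)))
  keep <- apply(codes, 2, function(x) length(unique(x[!is.na(x)])) >= 2)
  codes <- codes[, keep, drop = FALSE]
  genes <- genes[keep]
  variants <- data.frame(
    chrom = "cnv", pos = seq_along(genes), id = genes,
    ref = "single_copy", alt = "amplified", is_cnv = TRUE,
    stringsAsFactors = FALSE)
  genotype_panel(codes - 1L, variants, sample_ids = sample_ids,
                 ploidy_mode = "haploid")
}

#' @rdname cnv_recode
#' @param panel a panel of CNV markers produced by [cnv_recode()].
#' @return For `cnv_codes`: the samples x markers matrix of 1/2 codes.
#' @export
cnv_codes <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"), all(panel$variants$is_cnv))
  panel$calls + 1L
}
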