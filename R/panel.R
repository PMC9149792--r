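#' Construct a genotype panel
#'
#' A `genotype_panel` is the central container of the package: a samples x
#' variants matrix of allele counts together with per-variant metadata.
#' Haploid panels store calls in \{0, 1\} (the count of the alternate allele
#' on the single haplotype); diploid panels store \{0, 1, 2\}. Missing
#' genotypes are `NA`. Variants are kept strictly sorted by (chrom, pos).
#'
#' @param calls integer matrix, samples in rows, variants in columns. `NA`
#'   marks a missing genotype.
#' @param variants data frame with one row per variant and at least columns
#'   `chrom`, `pos`, `ref`, `alt`. Columns `maf`, `n_missing` and `is_cnv`
#'   are (re)computed if absent.
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   row names of `calls` or `s1..sn`.
#' @param ploidy_mode `"haploid"` or `"diploid"`.
#'
#' @return An object of class `genotype_panel` with fields `calls`,
#'   `variants`, `sample_ids` and `ploidy`.
#' @seealso [simulate_panel()], [filter_biallelic()], [filter_missing()],
#'   [filter_maf()]
#' @export
genotype_panel <- function(calls, variants, sample_ids = NULL,
                           ploidy_mode = c("haploid", "diploid")) {
  ploidy_mode <- match.arg(ploidy_mode)
  ploidy <- if (ploidy_mode == "haploid") 1L else 2L
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(calls)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(calls)))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants) != ncol(calls))
    stop("variants table has ", nrow(variants), " rows but calls has ",
         ncol(calls), " columns")
  if (length(sample_ids) != nrow(calls))
    stop("sample_ids length does not match number of rows of calls")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample identifiers")
  for (col in c("chrom", "pos", "ref", "alt"))
    if (is.null(variants[[col]])) stop("variants table lacks column '", col, "'")
  if (is.null(variants$is_cnv)) variants$is_cnv <- FALSE
  ord <- order(variants$chrom, variants$pos)
  if (is.unsorted(ord)) {
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(variants) <- NULL
  dimnames(calls) <- NULL
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > ploidy))
    stop("calls must lie in [0, ", ploidy, "] for ", ploidy_mode, " panels")
  panel <- structure(
    list(calls = calls, variants = variants, sample_ids = sample_ids,
         ploidy = ploidy),
    class = "genotype_panel")
  recompute_variant_stats(panel)
}

#' Recompute per-variant MAF and missingness
#'
#' Fills the `maf` and `n_missing` columns of the variant table from the call
#' matrix. MAF is computed on non-missing calls only and folded to [0, 0.5].
#'
#' @param panel a [genotype_panel()].
#' @return The panel with refreshed variant statistics.
#' @export
recompute_variant_stats <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  nm <- colSums(is.na(panel$calls))
  n_called <- nrow(panel$calls) - nm
  alt <- colSums(panel$calls, na.rm = TRUE)
  total <- panel$ploidy * n_called
  p <- ifelse(total > 0, alt / total, NA_real_)
  panel$variants$maf <- pmin(p, 1 - p)
  panel$variants$n_missing <- as.integer(nm)
  panel
}

#' Number of samples and variants in a panel
#' @param panel a [genotype_panel()].
#' @return Integer count.
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' @rdname n_samples
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants (%s)\n",
              n_samples(x), n_variants(x),
              if (x$ploidy == 1L) "haploid" else "diploid"))
  if (n_variants(x)) {
    cat(sprintf("  MAF: median %.3f, range [%.3f, %.3f]\n",
                stats::median(x$variants$maf, na.rm = TRUE),
                min(x$variants$maf, na.rm = TRUE),
                max(x$variants$maf, na.rm = TRUE)))
    cat(sprintf("  missing calls: %d; CNV markers: %d\n",
                sum(x$variants$n_missing), sum(x$variants$is_cnv)))
  }
  invisible(x)
}

# Subset a panel by variant index (logical or integer), keeping order.
subset_variants <- function(panel, keep) {
  panel$calls <- panel$calls[, keep, drop = FALSE]
  panel$variants <- panel$variants[keep, , drop = FALSE]
  rownames(panel$variants) <- NULL
  panel
}

# Subset a panel by sample index; variant stats are refreshed.
subset_samples <- function(panel, keep) {
  panel$calls <- panel$calls[keep, , drop = FALSE]
  panel$sample_ids <- panel$sample_ids[keep]
  recompute_variant_stats(panel)
}

#' Append the variants of one panel to another
#'
#' Used to add CNV markers produced by [cnv_recode()] to a SNP panel. Sample
#' sets must match (same ids, same order after matching).
#'
#' @param panel,extra two [genotype_panel()] objects over the same samples
#'   and ploidy mode.
#' @return A combined panel, re-sorted by (chrom, pos).
#' @export
bind_panels <- function(panel, extra) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(extra, "genotype_panel"))
  if (panel$ploidy != extra$ploidy)
    stop("cannot bind panels with different ploidy modes")
  idx <- match(panel$sample_ids, extra$sample_ids)
  if (anyNA(idx))
    stop("sample sets differ: ",
         paste(utils::head(setdiff(panel$sample_ids, extra$sample_ids), 5),
               collapse = ", "))
  cols <- intersect(names(panel$variants), names(extra$variants))
  genotype_panel(
    cbind(panel$calls, extra$calls[idx, , drop = FALSE]),
    rbind(panel$variants[, cols, drop = FALSE],
          extra$variants[, cols, drop = FALSE]),
    sample_ids = panel$sample_ids,
    ploidy_mode = if (panel$ploidy == 1L) "haploid" else "diploid")
}
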