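#' Permutation-based family-wise significance threshold
#'
#' Shuffles the phenotype across samples `n_perm` times, re-runs the
#' genome-wide scan for each shuffle (reusing the unpermuted null model's
#' variance ratio), records the genome-wide minimum p-value of each, and
#' returns the `ceiling(fwer * n_perm)`-th smallest of these minima — the
#' fifth lowest of 100 at the defaults. Variants at or below this threshold
#' have a family-wise error rate of `fwer`.
#'
#' @param panel a filtered [genotype_panel()] (ignored when `context` is
#'   given).
#' @param phenotype numeric phenotype vector.
#' @param kinship optional [kinship_matrix()].
#' @param n_perm number of permutations (default 100).
#' @param fwer target family-wise error rate in (0, 1) (default 0.05).
#' @param null_fit optional [fit_null_reml()] of the unpermuted phenotype.
#' @param context optional [scan_context()] to reuse.
#' @param seed optional seed for the permutations.
#' @return The p-value threshold, with the vector of per-permutation
#'   minimum p-values attached as attribute `"minima"`.
#' @export
permutation_threshold <- function(panel = NULL, phenotype, kinship = NULL,
                                  n_perm = 100, fwer = 0.05,
                                  null_fit = NULL, context = NULL,
                                  seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (fwer <= 0 || fwer >= 1) stop("fwer must lie in (0, 1)")
  if (n_perm * fwer < 1)
    stop("n_perm * fwer < 1: the requested quantile of the permutation ",
         "minima is undefined; increase n_perm")
  if (is.null(context)) context <- scan_context(panel, kinship)
  if (is.null(null_fit))
    null_fit <- fit_null_reml(phenotype, context = context)
  minima <- with_seed(seed,
    perm_min_pvalues(context, phenotype, null_fit$delta, n_perm))
  k <- ceiling(fwer * n_perm)
  threshold <- sort(minima)[k]
  attr(threshold, "minima") <- minima
  threshold
}

#' Genomic inflation factor
#'
#' `lambda = median(observed statistics) / median of the chi-square
#' distribution with 1 d.f.` The denominator is computed analytically
#' (`qchisq(0.5, 1)`, approximately 0.4549; conventionally printed as
#' 0.456). Under a null model of no association with unlinked variants the
#' expectation is 1; values above 1 indicate inflated association
#' statistics, e.g. from unmodelled confounding.
#'
#' @param statistics per-variant 1-d.f. test statistics (finite, length
#'   >= 1), or an `association_result`.
#' @return lambda (> 0).
#' @export
genomic_inflation <- function(statistics) {
  if (inherits(statistics, "association_result"))
    statistics <- statistics$table$stat
  statistics <- statistics[is.finite(statistics)]
  if (length(statistics) == 0)
    stop("no finite statistics supplied")
  stats::median(statistics) / stats::qchisq(0.5, df = 1)
}

#' Confusion table of a simulation run
#'
#' Classifies every tested variant against the known causal set at a
#' p-value threshold (significant iff `p <= threshold`): TP = significant
#' causal, FN = causal not significant, FP = significant non-causal,
#' TN = the rest. Rates: TPR = TP/(TP+FN), TNR = TN/(TN+FP),
#' FPR = FP/(FP+TN), FNR = FN/(FN+TP). With `linkage_window` set (in bp),
#' significant non-causal variants within the window of any causal variant
#' are excluded from FP and TN and reported separately as
#' `n_linked_excluded`, since counting markers linked to the causal site as
#' false positives overstates the error.
#'
#' @param p_values per-variant p-values, or an `association_result`.
#' @param threshold significance threshold in (0, 1].
#' @param causal_ids indices (into `p_values`) of the causal variants.
#' @param linkage_window window in bp, or `NULL` (default: off).
#' @param variants data frame with `chrom` and `pos` (required when
#'   `linkage_window` is set; taken from the `association_result` if one
#'   was supplied).
#' @param lambda_gc optional genomic inflation factor to record.
#' @param run_id optional run identifier.
#' @return A `confusion_summary`: counts `tp`, `fp`, `tn`, `fn`, rates
#'   `tpr`, `tnr`, `fpr`, `fnr`, plus `threshold`, `lambda_gc`,
#'   `n_linked_excluded` and `run_id`.
#' @export
confusion_rates <- function(p_values, threshold, causal_ids,
                            linkage_window = NULL, variants = NULL,
                            lambda_gc = NA_real_, run_id = NA) {
  if (inherits(p_values, "association_result")) {
    if (is.null(variants)) variants <- p_values$table
    p_values <- p_values$table$p_value
  }
  if (length(threshold) != 1 || is.na(threshold) || threshold <= 0 ||
      threshold > 1)
    stop("threshold must lie in (0, 1]")
  m <- length(p_values)
  if (length(causal_ids) && (min(causal_ids) < 1 || max(causal_ids) > m))
    stop("causal_ids must index the tested variants")
  causal <- logical(m)
  causal[causal_ids] <- TRUE
  sig <- p_values <= threshold
  linked <- logical(m)
  if (!is.null(linkage_window)) {
    if (is.null(variants))
      stop("variants (chrom, pos) required when linkage_window is set")
    for (ci in causal_ids) {
      near <- variants$chrom == variants$chrom[ci] &
        abs(variants$pos - variants$pos[ci]) <= linkage_window
      linked <- linked | near
    }
    linked <- linked & !causal & sig
  }
  tp <- sum(sig & causal)
  fn <- sum(!sig & causal)
  fp <- sum(sig & !causal & !linked)
  tn <- sum(!sig & !causal & !linked)
  rate <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = rate(tp, fn), tnr = rate(tn, fp),
    fpr = rate(fp, tn), fnr = rate(fn, tp),
    threshold = as.numeric(threshold), lambda_gc = lambda_gc,
    n_linked_excluded = sum(linked), run_id = run_id),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "confusion_summary: TP %d FP %d TN %d FN %d | TPR %.3f FPR %.4g | threshold %.3g\n",
    x$tp, x$fp, x$tn, x$fn, x$tpr, x$fpr, x$threshold))
  invisible(x)
}

#' @export
as.data.frame.confusion_summary <- function(x, ...) {
  data.frame(run_id = x$run_id, threshold = x$threshold, tp = x$tp,
             fp = x$fp, tn = x$tn, fn = x$fn, tpr = x$tpr, fpr = x$fpr,
             fnr = x$fnr, tnr = x$tnr, lambda_gc = x$lambda_gc,
             n_linked_excluded = x$n_linked_excluded)
}
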