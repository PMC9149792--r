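#' Configuration of a simulation study
#'
#' Bundles every tunable of one scaled-down association-power study: the
#' panel (a preset name, a [population_config()], or a prebuilt
#' [genotype_panel()]), the trait architecture, and the evaluation
#' parameters. Defaults follow the reference study design (heritability
#' 0.8, 100 permutations, 5% family-wise error rate, MAF filter 5%), with
#' the run count scaled down to 100.
#'
#' @param preset a [panel_preset()] name, or `NULL`.
#' @param population a [population_config()], or `NULL`.
#' @param panel a prebuilt [genotype_panel()], or `NULL`. Exactly one of
#'   `preset`, `population`, `panel` must be given.
#' @param trait_type `"mendelian"` (1 causal variant) or `"complex"`
#'   (default 10).
#' @param n_causal number of causal variants; defaults to 1 or 10 by trait
#'   type.
#' @param h2 simulated heritability (default 0.8).
#' @param n_runs number of simulation runs (default 100).
#' @param n_perm permutations per run (default 100).
#' @param fwer family-wise error rate (default 0.05).
#' @param maf_min MAF filter applied to the panel and to causal-variant
#'   eligibility (default 0.05).
#' @param n_variants candidate sites when simulating from a preset
#'   (default 10000).
#' @param downsample_to optional sample count to downsample the panel to
#'   before the study.
#' @param seed master seed; per-run seeds are derived by a counter scheme
#'   so that runs are independent and individually replayable.
#' @return A `study_config` list.
#' @export
study_config <- function(preset = NULL, population = NULL, panel = NULL,
                         trait_type = c("complex", "mendelian"),
                         n_causal = NULL, h2 = 0.8, n_runs = 100,
                         n_perm = 100, fwer = 0.05, maf_min = 0.05,
                         n_variants = 10000, downsample_to = NULL,
                         seed = 1L) {
  trait_type <- match.arg(trait_type)
  if (sum(!is.null(preset), !is.null(population), !is.null(panel)) != 1)
    stop("give exactly one of preset, population, panel")
  if (is.null(n_causal))
    n_causal <- if (trait_type == "mendelian") 1L else 10L
  if (trait_type == "mendelian" && n_causal != 1)
    stop("a Mendelian trait has exactly 1 causal variant")
  if (n_runs < 1 || n_causal < 1) stop("n_runs and n_causal must be >= 1")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  structure(list(
    preset = preset, population = population, panel = panel,
    trait_type = trait_type, n_causal = as.integer(n_causal), h2 = h2,
    n_runs = as.integer(n_runs), n_perm = as.integer(n_perm), fwer = fwer,
    maf_min = maf_min, n_variants = as.integer(n_variants),
    downsample_to = downsample_to, seed = as.integer(seed)),
    class = "study_config")
}

# Materialize and filter the study panel.
build_study_panel <- function(config) {
  panel <- if (!is.null(config$panel)) {
    config$panel
  } else {
    pop <- if (!is.null(config$population)) config$population
           else panel_preset(config$preset, n_variants = config$n_variants)
    if (is.null(pop$seed)) pop$seed <- derive_seed(config$seed, 0L)
    simulate_panel(pop)
  }
  if (!is.null(config$downsample_to))
    panel <- downsample_panel(panel, config$downsample_to,
                              seed = derive_seed(config$seed, 999999L),
                              min_maf = 0)
  filter_maf(filter_missing(panel, max_missing_count = n_samples(panel)),
             config$maf_min)
}

#' Run a simulation study
#'
#' For each run: draw the causal set, simulate the trait at the target
#' heritability, fit the null mixed model, scan all variants, derive the
#' permutation threshold, and tabulate the confusion summary together with
#' the genomic inflation factor and the REML heritability estimate. The
#' expensive panel-level work (GRM, eigendecomposition, genotype rotation)
#' is done once and shared across runs. A failure in one run is logged and
#' skipped; it does not abort the study.
#'
#' @param config a [study_config()].
#' @param verbose emit one structured log line per run to stderr.
#' @return A `study_result`: `runs` (one row per run: threshold, counts,
#'   rates, lambda, h2 estimate), `aggregate` (medians and IQRs),
#'   `panel_summary`, and the config.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  panel <- with_seed(config$seed, build_study_panel(config))
  if (n_variants(panel) < config$n_causal)
    stop("panel has fewer variants than n_causal after filtering")
  ctx <- scan_context(panel)
  rows <- vector("list", config$n_runs)
  for (run in seq_len(config$n_runs)) {
    run_seed <- derive_seed(config$seed, run)
    row <- tryCatch(
      with_seed(run_seed, {
        causal <- sample_causal(panel, config$n_causal, config$maf_min)
        trait <- simulate_trait(panel, causal, config$h2)
        nf <- fit_null_reml(trait$phenotype, context = ctx)
        res <- association_scan(phenotype = trait$phenotype,
                                null_fit = nf, context = ctx)
        thr <- permutation_threshold(phenotype = trait$phenotype,
                                     n_perm = config$n_perm,
                                     fwer = config$fwer, null_fit = nf,
                                     context = ctx)
        lam <- genomic_inflation(res)
        cs <- confusion_rates(res, thr, causal, lambda_gc = lam,
                              run_id = run)
        cbind(as.data.frame(cs), h2_est = nf$h2_est,
              h2_realized = trait$h2_realized, seed = run_seed)
      }),
      error = function(e) {
        warning("run ", run, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (verbose && !is.null(row))
      message(sprintf(
        "run=%d threshold=%.3g tp=%d fp=%d tn=%d fn=%d lambda=%.3f h2=%.3f",
        run, row$threshold, row$tp, row$fp, row$tn, row$fn, row$lambda_gc,
        row$h2_est))
    rows[[run]] <- row
  }
  runs <- do.call(rbind, rows)
  agg_of <- function(x) c(median = stats::median(x, na.rm = TRUE),
                          q25 = unname(stats::quantile(x, 0.25, na.rm = TRUE)),
                          q75 = unname(stats::quantile(x, 0.75, na.rm = TRUE)))
  metrics <- c("tpr", "fpr", "fnr", "tnr", "lambda_gc", "h2_est",
               "threshold")
  aggregate <- as.data.frame(t(vapply(metrics, function(mname)
    agg_of(runs[[mname]]), numeric(3))))
  aggregate$metric <- metrics
  aggregate <- aggregate[, c("metric", "median", "q25", "q75")]
  rownames(aggregate) <- NULL
  structure(list(
    runs = runs, aggregate = aggregate,
    panel_summary = list(n_samples = n_samples(panel),
                         n_variants = n_variants(panel)),
    config = config),
    class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d runs on %d samples x %d variants (%s, k=%d, h2=%.2f)\n",
              nrow(x$runs), x$panel_summary$n_samples,
              x$panel_summary$n_variants, x$config$trait_type,
              x$config$n_causal, x$config$h2))
  print(x$aggregate, digits = 4)
  invisible(x)
}

#' Downsample a panel to fewer individuals
#'
#' Draws `n` individuals uniformly without replacement and re-filters the
#' variants: sites monomorphic in the reduced sample are removed, and the
#' MAF filter is re-applied if requested.
#'
#' @param panel a [genotype_panel()].
#' @param n target sample count (<= current count).
#' @param seed optional seed.
#' @param min_maf MAF filter to re-apply after downsampling (default 0:
#'   drop monomorphic sites only).
#' @return The reduced [genotype_panel()].
#' @export
downsample_panel <- function(panel, n, seed = NULL, min_maf = 0) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (n > n_samples(panel))
    stop("cannot downsample to ", n, " from ", n_samples(panel), " samples")
  keep <- with_seed(seed, sort(sample.int(n_samples(panel), n)))
  out <- subset_samples(panel, keep)
  poly <- !is.na(out$variants$maf) & out$variants$maf > 0
  out <- subset_variants(out, poly)
  if (min_maf > 0) out <- filter_maf(out, min_maf) else out
}

#' End-to-end association on user data
#'
#' Real-data mode: loads a genotype panel (VCF file, PLINK-style table
#' prefix, or an in-memory panel) and a phenotype table, applies the
#' standard filters (biallelic, missingness, MAF), fits the null mixed
#' model, scans every variant, derives the permutation threshold, and
#' returns the significant-variant table.
#'
#' @param panel a [genotype_panel()], a path to a VCF file, or a path
#'   prefix of a [write_panel_table()] pair.
#' @param phenotype a data frame with columns `sample_id` and `value`, or
#'   the path of such a tab-separated file.
#' @param max_missing_count missingness filter (default 0: fully-called
#'   sites only).
#' @param maf_min MAF filter (default 0.05).
#' @param n_perm,fwer permutation-threshold parameters.
#' @param seed optional seed for the permutations.
#' @return List with the `association_result`, the `threshold`, the
#'   `significant` sub-table (p <= threshold, sorted), the heritability
#'   estimate `h2_est`, and the filtered panel.
#' @export
associate_real <- function(panel, phenotype, max_missing_count = 0,
                           maf_min = 0.05, n_perm = 100, fwer = 0.05,
                           seed = NULL) {
  if (is.character(panel)) {
    panel <- if (grepl("\\.vcf(\\.gz)?$", panel)) read_vcf_panel(panel)
             else read_panel_table(panel)
  }
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.character(phenotype)) phenotype <- read_phenotypes(phenotype)
  idx <- match(panel$sample_ids, phenotype$sample_id)
  if (anyNA(idx)) {
    missing_ids <- panel$sample_ids[is.na(idx)]
    stop("no phenotype for sample(s): ",
         paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  y <- phenotype$value[idx]
  panel <- filter_maf(filter_missing(filter_biallelic(panel),
                                     max_missing_count), maf_min)
  ctx <- scan_context(panel)
  nf <- fit_null_reml(y, context = ctx)
  res <- association_scan(phenotype = y, null_fit = nf, context = ctx)
  thr <- permutation_threshold(phenotype = y, n_perm = n_perm, fwer = fwer,
                               null_fit = nf, context = ctx, seed = seed)
  sig <- res$table[res$table$p_value <= thr, ]
  sig <- sig[order(sig$p_value), ]
  rownames(sig) <- NULL
  list(result = res, threshold = as.numeric(thr), significant = sig,
       h2_est = nf$h2_est, panel = panel)
}
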