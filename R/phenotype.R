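#' Sample causal variants for a simulated trait
#'
#' Draws `k` distinct variant indices uniformly without replacement from the
#' variants whose MAF passes `min_maf` — one for a Mendelian trait, several
#' (typically 10) for a complex trait.
#'
#' @param panel a [genotype_panel()].
#' @param k number of causal variants.
#' @param min_maf minimum MAF for eligibility (default 0.05, matching the
#'   association matrix filter).
#' @param seed optional seed.
#' @return Integer vector of variant indices into the panel.
#' @export
sample_causal <- function(panel, k, min_maf = 0.05, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), k >= 1)
  eligible <- which(!is.na(panel$variants$maf) &
                      panel$variants$maf >= min_maf)
  if (length(eligible) < k)
    stop("only ", length(eligible), " variants with MAF >= ", min_maf,
         " but k = ", k)
  with_seed(seed, {
    if (length(eligible) == 1L) eligible else sort(sample(eligible, k))
  })
}

#' Simulate an additive quantitative trait
#'
#' Follows the standard additive simulation model for quantitative traits:
#' effect sizes `b_j` are i.i.d. standard normal; the genetic value of
#' sample i is `g_i = sum_j w_ij b_j` where `w` is the standardized
#' genotype, centered by the allele frequency and scaled by its binomial
#' standard deviation (`sqrt(p(1-p))` per haploid call, `sqrt(2p(1-p))` per
#' diploid call). Residuals are i.i.d. normal with variance
#' `Var(g) (1-h2) / h2`, where `Var(g)` is the realized sample variance of
#' the genetic values, so a finite panel hits the target heritability on
#' average. Missing causal genotypes are mean-imputed.
#'
#' @param panel a [genotype_panel()].
#' @param causal_ids variant indices from [sample_causal()].
#' @param h2 target heritability in [0, 1]. `h2 = 0` yields a pure-noise
#'   standard-normal trait (used for null calibration); `h2 = 1` yields the
#'   genetic value exactly.
#' @param seed optional seed.
#' @return A `trait_realization`: list with `phenotype`, `causal_ids`,
#'   `effects`, `genetic_values`, `h2_target` and `h2_realized`
#'   (empirical Var(g)/Var(y)).
#' @export
simulate_trait <- function(panel, causal_ids, h2, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  n <- n_samples(panel)
  with_seed(seed, {
    if (h2 == 0) {
      y <- stats::rnorm(n)
      tr <- list(phenotype = y, causal_ids = causal_ids,
                 effects = rep(0, length(causal_ids)),
                 genetic_values = rep(0, n),
                 h2_target = 0, h2_realized = 0)
      class(tr) <- "trait_realization"
      return(tr)
    }
    w <- standardize_genotypes(panel, causal_ids)
    b <- stats::rnorm(length(causal_ids))
    g <- drop(w %*% b)
    var_g <- stats::var(g)
    if (var_g == 0)
      stop("causal variants carry no genetic variance (monomorphic?)")
    e <- if (h2 == 1) rep(0, n)
         else stats::rnorm(n, sd = sqrt(var_g * (1 - h2) / h2))
    y <- g + e
    tr <- list(phenotype = y, causal_ids = causal_ids, effects = b,
               genetic_values = g, h2_target = h2,
               h2_realized = var_g / stats::var(y))
    class(tr) <- "trait_realization"
    tr
  })
}

#' @export
print.trait_realization <- function(x, ...) {
  cat(sprintf(
    "trait_realization: %d samples, %d causal variant(s), h2 target %.2f, realized %.3f\n",
    length(x$phenotype), length(x$causal_ids), x$h2_target, x$h2_realized))
  invisible(x)
}

# Standardized genotype matrix W (samples x selected variants): missing
# calls mean-imputed, columns centered at ploidy * p and scaled by
# sqrt(ploidy * p * (1 - p)) with p the alternate-allele frequency.
standardize_genotypes <- function(panel, idx = seq_len(n_variants(panel))) {
  x <- panel$calls[, idx, drop = FALSE]
  storage.mode(x) <- "double"
  ploidy <- panel$ploidy
  n_called <- colSums(!is.na(x))
  p <- colSums(x, na.rm = TRUE) / (ploidy * n_called)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic variant in standardization; filter the panel first")
  if (anyNA(x)) {
    mu <- ploidy * p
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- mu[na_idx[, 2]]
  }
  scale(x, center = ploidy * p, scale = sqrt(ploidy * p * (1 - p)))
}
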