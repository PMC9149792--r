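# Small in-code fixtures shared across test files.

# Build a panel directly from a call matrix (samples x variants).
make_panel <- function(calls, ploidy_mode = "haploid", chrom = NULL,
                       pos = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  variants <- data.frame(
    chrom = if (is.null(chrom)) rep("chr1", m) else chrom,
    pos = if (is.null(pos)) seq_len(m) * 100L else pos,
    id = paste0("v", seq_len(m)),
    ref = "A", alt = "T", is_cnv = FALSE, stringsAsFactors = FALSE)
  genotype_panel(calls, variants, ploidy_mode = ploidy_mode)
}

# A quick random haploid panel with frequencies bounded away from 0/1.
random_panel <- function(n, m, seed, missing_rate = 0) {
  withr::with_seed(seed, {
    p <- runif(m, 0.1, 0.5)
    calls <- matrix(rbinom(n * m, 1, rep(p, each = n)), nrow = n)
    if (missing_rate > 0)
      calls[matrix(runif(n * m) < missing_rate, nrow = n)] <- NA_integer_
    # ensure every site is polymorphic among non-missing calls
    for (j in seq_len(m)) {
      x <- calls[, j]
      if (all(x == 0L, na.rm = TRUE)) calls[1, j] <- 1L
      if (all(x == 1L, na.rm = TRUE)) calls[1, j] <- 0L
    }
    make_panel(calls)
  })
}

# Hand-written VCF with a mix of biallelic and multi-allelic records.
write_mixed_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0\t1\t0\t1",
    "chr1\t200\t.\tC\tG,T\t.\tPASS\t.\tGT\t0\t1\t2\t0",  # triallelic
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1\t1\t0\t.",
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t0\t0\t1\t1")
  writeLines(lines, path)
  path
}

# Dense-matrix restricted likelihood, written independently of the
# spectral implementation (Harville form, same constant convention).
dense_reml <- function(y, X, K, sigma_g2, delta) {
  V <- sigma_g2 * (K + delta * diag(nrow(K)))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  n <- length(y); p <- ncol(X)
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) -
            as.numeric(determinant(crossprod(X))$modulus) +
            drop(t(y) %*% P %*% y))
}

# An unstructured calibration panel with an exact post-filter marker count:
# default low-frequency-skewed spectrum with realistic singleton load,
# MAF-filtered at 5%, thinned to m markers.
calibration_panel <- function(n, m, seed) {
  cfg <- population_config(n_samples = n, n_variants = m * 4,
                           singleton_rate = 0.313, seed = seed)
  p <- filter_maf(simulate_panel(cfg), 0.05)
  thin_variants(p, m, seed = seed + 1L)
}

# Null-trait calibration runs shared by the family-wise-error and genomic
# inflation checks (computed once per session).
null_calibration_cache <- new.env(parent = emptyenv())
null_calibration_runs <- function() {
  if (!is.null(null_calibration_cache$runs))
    return(null_calibration_cache$runs)
  p <- calibration_panel(200, 5000, seed = 3001L)
  ctx <- scan_context(p)
  out <- withr::with_seed(3002, t(replicate(200, {
    y <- rnorm(200)
    nf <- fit_null_reml(y, context = ctx)
    res <- association_scan(phenotype = y, null_fit = nf, context = ctx)
    thr <- permutation_threshold(phenotype = y, n_perm = 100, fwer = 0.05,
                                 null_fit = nf, context = ctx)
    c(hit = min(res$table$p_value) <= thr,
      lambda = genomic_inflation(res))
  })))
  null_calibration_cache$runs <- out
  out
}

# Brute-force nucleotide diversity: loop over all sample pairs and sites,
# counting allele differences among non-missing haploid calls.
pairwise_pi_oracle <- function(calls, genome_length) {
  n <- nrow(calls)
  total <- 0
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]
    diff <- 0; pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (is.na(x[a]) || is.na(x[b])) next
      pairs <- pairs + 1
      if (x[a] != x[b]) diff <- diff + 1
    }
    if (pairs > 0) total <- total + diff / pairs
  }
  total / genome_length
}
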