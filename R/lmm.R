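#' Genomic relationship matrix
#'
#' Builds the kinship matrix `K = W W' / m` from the per-variant
#' standardized genotype matrix `W` (missing calls mean-imputed, columns
#' centered at `ploidy * p` and scaled by `sqrt(ploidy * p (1-p))`). Under
#' this scaling the mean diagonal entry is close to 1, so the genetic
#' variance component of the mixed model is on the phenotypic scale. The
#' panel must already be filtered: a monomorphic variant is an error.
#'
#' @param panel a filtered [genotype_panel()] with at least 2 variants.
#' @return A `kinship_matrix`: list with `matrix` (n x n, symmetric PSD)
#'   and `sample_ids`.
#' @export
compute_grm <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (n_variants(panel) < 2) stop("need at least 2 variants for a GRM")
  w <- standardize_genotypes(panel)
  k <- tcrossprod(w) / ncol(w)
  kinship_matrix(k, panel$sample_ids)
}

#' @rdname compute_grm
#' @param matrix an n x n symmetric positive semi-definite matrix.
#' @param sample_ids sample identifiers matching the matrix rows.
#' @export
kinship_matrix <- function(matrix, sample_ids = NULL) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("kinship matrix must be square")
  if (!all(is.finite(matrix))) stop("kinship matrix has non-finite entries")
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(1, max(abs(matrix))))
    stop("kinship matrix must be symmetric")
  matrix <- (matrix + t(matrix)) / 2
  if (is.null(sample_ids)) {
    sample_ids <- rownames(matrix)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(matrix)))
  }
  structure(list(matrix = matrix, sample_ids = sample_ids),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d samples, mean diagonal %.3f\n",
              nrow(x$matrix), mean(diag(x$matrix))))
  invisible(x)
}

#' Precomputed scan context for one panel
#'
#' The association engine works in the eigenbasis of the kinship matrix
#' (the single-spectral-decomposition trick): `K = U S U'`, after rotating
#' phenotype, covariates and genotypes by `U'` the mixed model becomes a
#' weighted least-squares problem with diagonal weights `1/(S_i + delta)`.
#' Building the context — the eigendecomposition and the rotated genotype
#' matrix — is the expensive step and depends only on the panel, so it can
#' be shared across traits, permutations and whole simulation studies.
#'
#' @param panel a filtered [genotype_panel()].
#' @param kinship optional precomputed [kinship_matrix()]; computed from the
#'   panel by [compute_grm()] when absent.
#' @param covariates optional n x c numeric matrix of fixed covariates; an
#'   intercept is always included.
#' @return A `scan_context` object.
#' @export
scan_context <- function(panel, kinship = NULL, covariates = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(kinship)) kinship <- compute_grm(panel)
  stopifnot(inherits(kinship, "kinship_matrix"))
  n <- n_samples(panel)
  if (nrow(kinship$matrix) != n)
    stop("kinship dimension does not match panel sample count")
  eig <- eigen(kinship$matrix, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values)))
    stop("kinship matrix is not positive semi-definite")
  s <- pmax(eig$values, 0)
  x <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) x <- cbind(x, as.matrix(covariates))
  structure(list(
    u = eig$vectors, s = s,
    x_rot = crossprod(eig$vectors, x),
    g_rot = crossprod(eig$vectors, standardize_genotypes(panel)),
    ldet_xtx = as.numeric(determinant(crossprod(x))$modulus),
    n = n, p = ncol(x), variants = panel$variants,
    sample_ids = panel$sample_ids),
    class = "scan_context")
}

# Profiled restricted log-likelihood at ratio delta = sigma_e^2 / sigma_g^2,
# evaluated on the spectral axis. Returns the loglik and the REML variance
# estimate sigma_g^2 = RSS_w / (n - p).
reml_profile <- function(delta, s, ty, tx, ldet_xtx) {
  n <- length(ty)
  p <- ncol(tx)
  w <- 1 / (s + delta)
  a <- crossprod(tx, tx * w)
  rhs <- crossprod(tx, ty * w)
  beta <- solve(a, rhs)
  r <- ty - tx %*% beta
  rss <- sum(w * r^2)
  sg2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * sg2) + sum(log(s + delta)) +
                  as.numeric(determinant(a)$modulus) - ldet_xtx + (n - p))
  list(loglik = ll, sigma_g2 = sg2, beta = beta)
}

#' Fit the null linear mixed model by REML
#'
#' Model: `y = X beta + g + e` with `g ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`. The restricted likelihood is profiled over
#' `delta = sigma_e^2 / sigma_g^2` and maximized by Brent search on
#' `log(delta)` in [-10, 10] (tolerance 1e-6); `beta` and `sigma_g^2` are
#' profiled out analytically on the spectral axis, so each evaluation is
#' O(n). An optimum at the search boundary is flagged, and the heritability
#' estimate `sigma_g^2 / (sigma_g^2 + sigma_e^2)` is clamped to [0, 1].
#'
#' @param phenotype numeric phenotype vector (finite, non-constant).
#' @param kinship a [kinship_matrix()] (ignored when `context` is given).
#' @param covariates optional fixed covariates (intercept always included).
#' @param context optional [scan_context()] carrying the cached
#'   eigendecomposition.
#' @return A `null_model_fit`: `sigma_g2`, `sigma_e2`, `delta`,
#'   `reml_loglik`, `h2_est`, `boundary` flag and the eigen cache.
#' @export
fit_null_reml <- function(phenotype, kinship = NULL, covariates = NULL,
                          context = NULL) {
  y <- as.numeric(phenotype)
  if (!all(is.finite(y))) stop("phenotype must be finite")
  if (length(y) < 3) stop("need at least 3 samples")
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  if (is.null(context)) {
    stopifnot(inherits(kinship, "kinship_matrix"))
    n <- length(y)
    if (nrow(kinship$matrix) != n)
      stop("kinship dimension does not match phenotype length")
    eig <- eigen(kinship$matrix, symmetric = TRUE)
    s <- pmax(eig$values, 0)
    u <- eig$vectors
    x <- cbind(intercept = rep(1, n))
    if (!is.null(covariates)) x <- cbind(x, as.matrix(covariates))
    tx <- crossprod(u, x)
    ldet_xtx <- as.numeric(determinant(crossprod(x))$modulus)
  } else {
    stopifnot(inherits(context, "scan_context"))
    if (length(y) != context$n)
      stop("phenotype length does not match scan context")
    u <- context$u; s <- context$s; tx <- context$x_rot
    ldet_xtx <- context$ldet_xtx
  }
  ty <- drop(crossprod(u, y))
  obj <- function(logd)
    -reml_profile(exp(logd), s, ty, tx, ldet_xtx)$loglik
  opt <- stats::optimize(obj, interval = c(-10, 10), tol = 1e-6)
  delta <- exp(opt$minimum)
  at_boundary <- opt$minimum < -10 + 1e-3 || opt$minimum > 10 - 1e-3
  prof <- reml_profile(delta, s, ty, tx, ldet_xtx)
  sigma_g2 <- prof$sigma_g2
  sigma_e2 <- delta * sigma_g2
  structure(list(
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
    reml_loglik = prof$loglik,
    h2_est = min(max(sigma_g2 / (sigma_g2 + sigma_e2), 0), 1),
    boundary = at_boundary,
    eigen_cache = list(values = s, vectors = u)),
    class = "null_model_fit")
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf(
    "null_model_fit: sigma_g2 %.4g, sigma_e2 %.4g, h2 %.3f, REML loglik %.3f%s\n",
    x$sigma_g2, x$sigma_e2, x$h2_est, x$reml_loglik,
    if (x$boundary) " (optimum at search boundary)" else ""))
  invisible(x)
}

#' Heritability from a fitted null model
#'
#' The genome-wide heritability estimate: the genetic variance of the null
#' model divided by its total variance (genetic plus residual).
#'
#' @param null_fit a [fit_null_reml()] result.
#' @return `sigma_g2 / (sigma_g2 + sigma_e2)`.
#' @export
estimate_h2 <- function(null_fit) {
  stopifnot(inherits(null_fit, "null_model_fit"))
  total <- null_fit$sigma_g2 + null_fit$sigma_e2
  if (total <= 0) stop("both variance components are zero")
  null_fit$sigma_g2 / total
}

# Core scan on the rotated axis for one (already rotated) phenotype.
# Returns per-variant Wald statistics; delta fixed from the null model
# ("population parameters previously determined" approximation).
rotated_scan_stats <- function(context, ty, delta) {
  w <- 1 / (context$s + delta)
  sw <- sqrt(w)
  xw <- context$x_rot * sw
  qr_x <- qr(xw)
  q <- qr.Q(qr_x)
  yw <- ty * sw
  yr <- yw - q %*% crossprod(q, yw)
  gw <- context$g_rot * sw
  gr <- gw - q %*% crossprod(q, gw)
  g2 <- colSums(gr^2)
  b2 <- drop(crossprod(gr, yr))
  yy <- sum(yr^2)
  df <- context$n - context$p - 1
  ok <- g2 > 1e-10 * max(g2, 1)
  stat <- rep(0, length(g2))
  rss <- pmax(yy - b2[ok]^2 / g2[ok], 0)
  stat[ok] <- (b2[ok]^2 / g2[ok]) / (rss / df)
  list(stat = stat, collinear = !ok)
}

#' Mixed-model association scan
#'
#' Tests each variant for association with the phenotype by generalized
#' least squares in the rotated (spectral) space, holding the variance
#' ratio `delta` fixed at the null-model REML estimate. Each variant yields
#' a 1-d.f. Wald statistic and a p-value from its asymptotic chi-square
#' null distribution. Variants collinear with the covariates after rotation
#' are flagged and assigned p = 1. The tested variant is not excluded from
#' the kinship matrix (the same marker set builds the GRM and is scanned),
#' which costs some power at the causal marker but mirrors the standard
#' single-GRM workflow.
#'
#' @param panel a filtered [genotype_panel()] (ignored when `context` is
#'   given).
#' @param phenotype numeric phenotype vector.
#' @param kinship optional [kinship_matrix()].
#' @param null_fit optional [fit_null_reml()] result to reuse.
#' @param context optional [scan_context()] to reuse.
#' @return An `association_result`: data frame `table` with columns
#'   `chrom`, `pos`, `id`, `index`, `stat`, `p_value`, `collinear`, plus
#'   the `null_fit`.
#' @export
association_scan <- function(panel = NULL, phenotype, kinship = NULL,
                             null_fit = NULL, context = NULL) {
  if (is.null(context)) context <- scan_context(panel, kinship)
  if (is.null(null_fit))
    null_fit <- fit_null_reml(phenotype, context = context)
  ty <- drop(crossprod(context$u, as.numeric(phenotype)))
  sc <- rotated_scan_stats(context, ty, null_fit$delta)
  p <- stats::pchisq(sc$stat, df = 1, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  p[sc$collinear] <- 1
  v <- context$variants
  structure(list(
    table = data.frame(
      chrom = v$chrom, pos = v$pos,
      id = if (is.null(v$id)) paste0(v$chrom, ":", v$pos) else v$id,
      index = seq_len(nrow(v)), stat = sc$stat, p_value = p,
      collinear = sc$collinear, stringsAsFactors = FALSE),
    null_fit = null_fit),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result: %d variants scanned, min p = %.3g\n",
              nrow(x$table), min(x$table$p_value)))
  print(x$null_fit)
  invisible(x)
}

#' Write an association result table
#'
#' Tab-separated output sorted by p-value, preceded by a commented
#' null-model summary block (variance components and heritability).
#'
#' @param result an [association_scan()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_association <- function(result, path) {
  stopifnot(inherits(result, "association_result"))
  nf <- result$null_fit
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sigma_g2=%.6g\tsigma_e2=%.6g\th2_est=%.6g",
                     nf$sigma_g2, nf$sigma_e2, nf$h2_est), con)
  tab <- result$table[order(result$table$p_value), ]
  utils::write.table(tab[, c("chrom", "pos", "id", "stat", "p_value")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Genome-wide minimum p-values for a batch of permuted phenotypes.
# Permutation destroys the genetic covariance, so delta is reused from the
# unpermuted null fit rather than refit per permutation.
perm_min_pvalues <- function(context, phenotype, delta, n_perm) {
  n <- context$n
  perm_idx <- replicate(n_perm, sample.int(n))
  ymat <- matrix(as.numeric(phenotype)[perm_idx], nrow = n)
  tymat <- crossprod(context$u, ymat)
  w <- 1 / (context$s + delta)
  sw <- sqrt(w)
  xw <- context$x_rot * sw
  q <- qr.Q(qr(xw))
  yw <- tymat * sw
  yr <- yw - q %*% crossprod(q, yw)
  gw <- context$g_rot * sw
  gr <- gw - q %*% crossprod(q, gw)
  g2 <- colSums(gr^2)
  ok <- g2 > 1e-10 * max(g2, 1)
  b2 <- crossprod(gr[, ok, drop = FALSE], yr)      # m_ok x n_perm
  yy <- colSums(yr^2)
  df <- n - context$p - 1
  stat <- sweep(b2^2, 1, g2[ok], "/")              # numerator ss
  rss <- pmax(sweep(-stat, 2, yy, "+"), 0)
  stat <- stat / (rss / df)
  max_stat <- apply(stat, 2, max)
  pmax(stats::pchisq(max_stat, df = 1, lower.tail = FALSE),
       .Machine$double.xmin)
}
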