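#' Configuration of a synthetic population panel
#'
#' Describes a population of haploid (or diploid) individuals genotyped at
#' biallelic sites. Site minor-allele frequencies are drawn from a Beta
#' distribution folded onto (0, 0.5], with an explicit extra mass of
#' singleton variants (minor allele carried by exactly one individual).
#' Population structure is modelled by Balding-Nichols frequency drift: each
#' clade c draws its own site frequency from
#' `Beta(p(1-F_c)/F_c, (1-p)(1-F_c)/F_c)`, so `F_c` (`clade_divergence`) is
#' the Wright fixation index of the clade relative to the ancestral pool.
#' An optional near-identical clonal subclade (`recent_clone_fraction`)
#' models a group of individuals sharing a very recent common ancestor: all
#' of its members carry the same haplotype, drawn once per site from a
#' heavily drifted frequency (`clone_divergence`). Sites fixed inside that
#' subclade and absent elsewhere then segregate at frequency
#' n_clone / n_samples in the panel, producing the characteristic excess of
#' variants with MAF close to 0.49 seen in clonal yeast subpopulations.
#'
#' @param n_samples number of individuals (>= 2).
#' @param n_variants number of candidate sites drawn; sites that come out
#'   monomorphic are discarded, so the realized panel can be slightly
#'   smaller.
#' @param genome_length genome size in bp; only used as the denominator of
#'   nucleotide diversity. Default is the approximate S. cerevisiae genome.
#' @param structure_model `"unstructured"` or `"clades"`.
#' @param n_clades number of clades (structure_model = "clades").
#' @param clade_proportions proportions of the non-clonal samples per clade;
#'   must sum to 1. Defaults to equal proportions.
#' @param clade_divergence per-clade drift F in [0, 1); recycled to
#'   `n_clades`.
#' @param recent_clone_fraction fraction of all samples placed in the
#'   near-identical clonal subclade (0 disables it).
#' @param clone_divergence drift F of the clonal subclade's founder
#'   haplotype relative to the ancestral pool.
#' @param singleton_rate fraction of sites forced to be singletons.
#' @param maf_spectrum list with `shape1`, `shape2`: Beta parameters of the
#'   ancestral allele-frequency distribution (folded to (0, 0.5]).
#' @param missing_rate probability that any one call is missing
#'   (missing-completely-at-random).
#' @param ploidy_mode `"haploid"` (default; clonal yeast isolates) or
#'   `"diploid"`.
#' @param seed optional integer seed; when set, [simulate_panel()] is fully
#'   reproducible and leaves the caller's RNG state untouched.
#'
#' @return A `population_config` list, validated.
#' @export
population_config <- function(n_samples,
                              n_variants,
                              genome_length = 12.07e6,
                              structure_model = c("unstructured", "clades"),
                              n_clades = 1L,
                              clade_proportions = NULL,
                              clade_divergence = 0.1,
                              recent_clone_fraction = 0,
                              clone_divergence = 0.8,
                              singleton_rate = 0,
                              maf_spectrum = list(shape1 = 0.5, shape2 = 5),
                              missing_rate = 0,
                              ploidy_mode = c("haploid", "diploid"),
                              seed = NULL) {
  structure_model <- match.arg(structure_model)
  ploidy_mode <- match.arg(ploidy_mode)
  if (n_samples < 2) stop("invalid config: n_samples must be >= 2")
  if (n_variants < 1) stop("invalid config: n_variants must be >= 1")
  if (genome_length <= 0) stop("invalid config: genome_length must be > 0")
  if (is.null(clade_proportions))
    clade_proportions <- rep(1 / n_clades, n_clades)
  if (length(clade_proportions) != n_clades)
    stop("invalid config: clade_proportions length must equal n_clades")
  if (abs(sum(clade_proportions) - 1) > 1e-8)
    stop("invalid config: clade_proportions must sum to 1")
  clade_divergence <- rep_len(clade_divergence, n_clades)
  fractions <- c(clade_divergence, recent_clone_fraction, clone_divergence,
                 singleton_rate, missing_rate)
  if (any(fractions < 0 | fractions > 1))
    stop("invalid config: all fractions/divergences must lie in [0, 1]")
  if (!is.list(maf_spectrum) || is.null(maf_spectrum$shape1) ||
      is.null(maf_spectrum$shape2) || maf_spectrum$shape1 <= 0 ||
      maf_spectrum$shape2 <= 0)
    stop("invalid config: maf_spectrum needs positive shape1, shape2")
  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    genome_length = genome_length, structure_model = structure_model,
    n_clades = as.integer(n_clades), clade_proportions = clade_proportions,
    clade_divergence = clade_divergence,
    recent_clone_fraction = recent_clone_fraction,
    clone_divergence = clone_divergence,
    singleton_rate = singleton_rate, maf_spectrum = maf_spectrum,
    missing_rate = missing_rate, ploidy_mode = ploidy_mode, seed = seed),
    class = "population_config")
}

# Expected vcftools-style per-site diversity contribution of one
# non-singleton candidate site, averaged over the frequency spectrum and
# the group structure. E[site pi] = 2 p (1 - p) for binomially sampled
# alleles; a within-clade pair at drift F shrinks to 2 p (1 - p) (1 - F),
# and the clonal subclade behaves as F = 1 (no within-group variation).
# Unaffected by discarding monomorphic realizations, which contribute 0.
expected_site_diversity <- function(config) {
  n <- config$n_samples
  ploidy <- if (config$ploidy_mode == "haploid") 1L else 2L
  N <- ploidy * n
  a <- config$maf_spectrum$shape1
  b <- config$maf_spectrum$shape2
  e_pq <- a * b / ((a + b) * (a + b + 1))  # E[p(1-p)] for Beta(a, b)
  groups <- group_sizes(config)
  f_g <- c(if (groups$n_clone > 0) 1, groups$divergence)
  n_g <- c(if (groups$n_clone > 0) groups$n_clone * ploidy,
           groups$clade_sizes * ploidy)
  pairs_within <- sum(n_g * (n_g - 1) / 2 * f_g)
  kappa <- 1 - pairs_within / (N * (N - 1) / 2)
  2 * e_pq * kappa
}

# Candidate-site outcome probabilities, by Monte Carlo over the frequency
# spectrum and drift (allele sampling enters analytically): `polymorphic`
# is the survival rate of a candidate, `single_carrier` the rate of
# naturally-realized singletons. Used to size the singleton top-up when
# calibrating preset genome lengths.
candidate_site_rates <- function(config, nsim = 20000) {
  ploidy <- if (config$ploidy_mode == "haploid") 1L else 2L
  groups <- group_sizes(config)
  with_seed(760437L, {
    p0 <- stats::rbeta(nsim, config$maf_spectrum$shape1,
                       config$maf_spectrum$shape2)
    p0 <- pmin(p0, 1 - p0)
    ng <- integer(0)
    pg <- NULL
    if (groups$n_clone > 0) {
      # the shared subclade haplotype behaves as a single individual
      ng <- c(ng, 1L)
      pg <- cbind(pg, bn_drift(p0, config$clone_divergence))
    }
    for (c_idx in seq_along(groups$clade_sizes)) {
      if (groups$clade_sizes[c_idx] == 0) next
      ng <- c(ng, groups$clade_sizes[c_idx])
      pg <- cbind(pg, bn_drift(p0, groups$divergence[c_idx]))
    }
    na <- ploidy * ng  # allele draws per group
    p_zero <- (1 - pg)^rep(na, each = nsim)
    p_ones <- pg^rep(na, each = nsim)
    all0 <- apply(p_zero, 1, prod)
    all1 <- apply(p_ones, 1, prod)
    # natural singleton (haploid): exactly one sample carries the minor
    # allele. A clone-block carrier is n_clone samples, so the block (the
    # first group, when present) is excluded as the contributing group.
    single <- NA_real_
    if (ploidy == 1L) {
      contrib <- if (groups$n_clone > 0 && length(na) > 1)
        seq_along(na)[-1] else seq_along(na)
      one_alt <- rowSums(vapply(contrib, function(j) {
        na[j] * pg[, j] * (1 - pg[, j])^(na[j] - 1) *
          all0 / pmax((1 - pg[, j])^na[j], 1e-300)
      }, numeric(nsim)))
      one_ref <- rowSums(vapply(contrib, function(j) {
        na[j] * (1 - pg[, j]) * pg[, j]^(na[j] - 1) *
          all1 / pmax(pg[, j]^na[j], 1e-300)
      }, numeric(nsim)))
      single <- mean(one_alt + one_ref)
    }
    list(polymorphic = 1 - mean(all0 + all1), single_carrier = single)
  })
}

# Partition samples into (clone subclade, clades 1..C); unstructured panels
# are a single clade with zero divergence.
group_sizes <- function(config) {
  n <- config$n_samples
  n_clone <- if (config$structure_model == "clades")
    round(config$recent_clone_fraction * n) else 0L
  n_rest <- n - n_clone
  if (config$structure_model == "clades") {
    sizes <- floor(config$clade_proportions * n_rest)
    rem <- n_rest - sum(sizes)
    if (rem > 0) {
      extra <- order(config$clade_proportions * n_rest - sizes,
                     decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    list(n_clone = as.integer(n_clone), clade_sizes = as.integer(sizes),
         divergence = config$clade_divergence)
  } else {
    list(n_clone = 0L, clade_sizes = as.integer(n), divergence = 0)
  }
}

#' Simulate a genotype panel
#'
#' Draws a [genotype_panel()] under a [population_config()]: ancestral site
#' frequencies from the folded Beta spectrum, per-clade Balding-Nichols
#' drift, a shared haplotype for the clonal subclade, explicit singletons,
#' and missing-completely-at-random calls. `n_variants` non-singleton
#' candidate sites are drawn and those monomorphic in the realized sample
#' are discarded; the singleton load is then adjusted to the target — extra
#' one-carrier variants are added, or excess naturally-realized singletons
#' dropped — so the realized singleton fraction equals `singleton_rate` up
#' to rounding. The realized variant count therefore differs somewhat from
#' `n_variants`.
#'
#' @param config a [population_config()].
#' @return A [genotype_panel()] with variant positions uniformly placed on a
#'   single contig of length `genome_length`. Members of the clonal
#'   subclade, if any, are recorded in the `"clone_samples"` attribute.
#' @examples
#' cfg <- population_config(n_samples = 20, n_variants = 200,
#'                          singleton_rate = 0.2, seed = 1)
#' simulate_panel(cfg)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "population_config"))
  if (!is.null(config$seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(config$seed)
  }
  n <- config$n_samples
  m <- config$n_variants
  ploidy <- if (config$ploidy_mode == "haploid") 1L else 2L

  # ancestral frequencies, folded to (0, 0.5]
  p0 <- stats::rbeta(m, config$maf_spectrum$shape1,
                     config$maf_spectrum$shape2)
  p0 <- pmin(p0, 1 - p0)
  p0 <- pmax(p0, 0.5 / (ploidy * n))  # guard against numerically-zero draws

  groups <- group_sizes(config)
  n_clone <- groups$n_clone
  calls <- matrix(0L, nrow = n, ncol = m)
  row0 <- 0L
  clone_rows <- if (n_clone > 0) seq_len(n_clone) else integer(0)
  if (n_clone > 0) {
    p_clone <- bn_drift(p0, config$clone_divergence)
    shared <- stats::rbinom(m, ploidy, p_clone)
    calls[clone_rows, ] <- matrix(shared, nrow = n_clone, ncol = m,
                                  byrow = TRUE)
    row0 <- n_clone
  }
  for (c_idx in seq_along(groups$clade_sizes)) {
    nc <- groups$clade_sizes[c_idx]
    if (nc == 0) next
    pc <- bn_drift(p0, groups$divergence[c_idx])
    rows <- row0 + seq_len(nc)
    calls[rows, ] <- matrix(
      stats::rbinom(nc * m, ploidy, rep(pc, each = nc)), nrow = nc)
    row0 <- row0 + nc
  }

  if (config$missing_rate > 0) {
    miss <- stats::runif(n * m) < config$missing_rate
    calls[matrix(miss, nrow = n)] <- NA_integer_
  }

  # keep realized-polymorphic candidates only
  ac <- colSums(calls, na.rm = TRUE)
  total <- ploidy * colSums(!is.na(calls))
  poly <- total > 0 & ac > 0 & ac < total
  calls <- calls[, poly, drop = FALSE]
  m_poly <- ncol(calls)
  if (m_poly == 0) warning("no polymorphic sites realized")

  # singleton top-up: add one-carrier variants until the realized fraction
  # reaches the configured rate (carrier calls are never set missing);
  # naturally-realized singletons among the candidates count toward it
  s <- config$singleton_rate
  is_nat_single <- if (m_poly > 0 && config$ploidy_mode == "haploid") {
    ac_p <- colSums(calls, na.rm = TRUE)
    tot_p <- colSums(!is.na(calls))
    pmin(ac_p, tot_p - ac_p) == 1L
  } else rep(FALSE, m_poly)
  natural <- sum(is_nat_single)
  # above target: drop excess natural singletons; below: top up
  excess <- if (s < 1) ceiling((natural - s * m_poly) / (1 - s)) else 0
  if (excess > 0) {
    drop_cols <- sample(which(is_nat_single), excess)
    calls <- calls[, -drop_cols, drop = FALSE]
    m_poly <- ncol(calls)
    natural <- natural - excess
  }
  n_single <- if (s > 0) max(0L, round((s * m_poly - natural) / (1 - s)))
              else 0L
  if (n_single > 0) {
    eligible <- setdiff(seq_len(n), clone_rows)
    if (length(eligible) == 0) eligible <- seq_len(n)
    singles <- matrix(0L, nrow = n, ncol = n_single)
    if (config$missing_rate > 0) {
      miss <- stats::runif(n * n_single) < config$missing_rate
      singles[matrix(miss, nrow = n)] <- NA_integer_
    }
    carriers <- sample(eligible, n_single, replace = TRUE)
    singles[cbind(carriers, seq_len(n_single))] <- 1L
    calls <- cbind(calls, singles)
    calls <- calls[, sample.int(ncol(calls)), drop = FALSE]
  }

  m_kept <- ncol(calls)
  pos <- sort(sample.int(as.integer(config$genome_length),
                         min(m_kept, as.integer(config$genome_length))))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m_kept, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  variants <- data.frame(
    chrom = "chrI", pos = pos, id = paste0("var", seq_len(m_kept)),
    ref = ref, alt = alt, is_cnv = FALSE, stringsAsFactors = FALSE)
  panel <- genotype_panel(calls, variants,
                          sample_ids = paste0("s", seq_len(n)),
                          ploidy_mode = config$ploidy_mode)
  attr(panel, "config") <- config
  attr(panel, "clone_samples") <- panel$sample_ids[clone_rows]
  panel
}

# Balding-Nichols drifted frequency: Beta(p(1-F)/F, (1-p)(1-F)/F); F -> 0
# degenerates to the ancestral frequency itself.
bn_drift <- function(p, f) {
  if (f < 1e-12) return(p)
  if (f > 1 - 1e-12) return(as.numeric(stats::runif(length(p)) < p))
  k <- (1 - f) / f
  stats::rbeta(length(p), p * k, (1 - p) * k)
}

#' Bundled population presets
#'
#' Six presets emulating the summary characteristics (sample size,
#' nucleotide diversity, singleton fraction, relatedness pattern) of the
#' yeast population panels commonly used for association-power studies: the
#' full 1011-isolate collection, a mixed-origin cluster, a mosaic cluster, a
#' highly clonal sake cluster, a sampled-diversity panel and a European wine
#' lineage. Marker counts are scaled down by `n_variants`; the genome length
#' is rescaled analytically so the preset's expected nucleotide diversity
#' matches its target at any marker count.
#'
#' @param name one of `"1011-like"`, `"mixed-like"`, `"mosaic3-like"`,
#'   `"sake-like"`, `"diversity-like"`, `"wine-like"`.
#' @param n_variants number of candidate sites to draw (default 10000).
#' @param seed optional seed stored in the config.
#' @return A [population_config()].
#' @export
panel_preset <- function(name = c("1011-like", "mixed-like", "mosaic3-like",
                                  "sake-like", "diversity-like", "wine-like"),
                         n_variants = 10000, seed = NULL) {
  name <- match.arg(name)
  par <- preset_table[[name]]
  cfg <- population_config(
    n_samples = par$n, n_variants = n_variants,
    genome_length = 1,  # placeholder, rescaled below
    structure_model = par$structure, n_clades = par$n_clades,
    clade_divergence = par$divergence,
    recent_clone_fraction = par$clone_fraction,
    clone_divergence = par$clone_divergence,
    singleton_rate = par$singleton_rate,
    maf_spectrum = list(shape1 = par$shape1, shape2 = par$shape2),
    missing_rate = 0, ploidy_mode = "haploid", seed = seed)
  # genome length sized so expected pi matches the target: candidate sites
  # contribute their expected site diversity, the expected singleton
  # top-up contributes 2/N each
  n_alleles <- par$n  # haploid
  s <- par$singleton_rate
  rates <- candidate_site_rates(cfg)
  topup <- max(0, (s * rates$polymorphic - rates$single_carrier) / (1 - s))
  pi_sum <- n_variants * (expected_site_diversity(cfg) +
                            topup * 2 / n_alleles)
  cfg$genome_length <- max(2 * n_variants, round(pi_sum / par$pi))
  cfg
}

# Target pi and singleton fractions follow published per-panel summaries;
# spectrum shapes and divergences were calibrated once against those same
# summaries (see the methods vignette).
preset_table <- list(
  "1011-like" = list(n = 1011L, pi = 0.0044, singleton_rate = 0.313,
                     structure = "clades", n_clades = 6L, divergence = 0.2,
                     clone_fraction = 0, clone_divergence = 0,
                     shape1 = 0.4, shape2 = 6),
  "mixed-like" = list(n = 71L, pi = 0.0032, singleton_rate = 0.028,
                      structure = "clades", n_clades = 1L, divergence = 0.05,
                      clone_fraction = 0, clone_divergence = 0,
                      shape1 = 1.5, shape2 = 2.5),
  "mosaic3-like" = list(n = 113L, pi = 0.0042, singleton_rate = 0.35,
                        structure = "clades", n_clades = 2L, divergence = 0.1,
                        clone_fraction = 0, clone_divergence = 0,
                        shape1 = 0.5, shape2 = 6),
  "sake-like" = list(n = 47L, pi = 0.0008, singleton_rate = 0.145,
                     structure = "clades", n_clades = 3L, divergence = 0.6,
                     clone_fraction = 0.49, clone_divergence = 0.9,
                     shape1 = 0.6, shape2 = 5),
  "diversity-like" = list(n = 133L, pi = 0.0049, singleton_rate = 0.542,
                          structure = "unstructured", n_clades = 1L,
                          divergence = 0, clone_fraction = 0,
                          clone_divergence = 0, shape1 = 0.5, shape2 = 5),
  "wine-like" = list(n = 323L, pi = 0.0012, singleton_rate = 0.125,
                     structure = "clades", n_clades = 1L, divergence = 0.15,
                     clone_fraction = 0, clone_divergence = 0,
                     shape1 = 0.6, shape2 = 2.5))
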