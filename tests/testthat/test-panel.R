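test_that("panel construction validates dimensions, codes and ordering", {
  calls <- rbind(c(0, 1, 0), c(1, 0, 1))
  v <- data.frame(chrom = "chr1", pos = c(300L, 100L, 200L),
                  ref = "A", alt = "T")
  p <- genotype_panel(calls, v)
  expect_equal(p$variants$pos, c(100L, 200L, 300L))  # re-sorted
  expect_equal(p$calls[, 3], c(0L, 1L))              # calls follow variants
  expect_error(genotype_panel(calls, v[1:2, ]), "rows")
  expect_error(genotype_panel(rbind(c(0, 2, 0), c(1, 0, 1)), v), "haploid")
  expect_silent(genotype_panel(rbind(c(0, 2, 0), c(1, 0, 1)), v,
                               ploidy_mode = "diploid"))
})

test_that("MAF and missingness are computed on non-missing calls and folded", {
  calls <- rbind(c(1, 1, NA), c(1, 0, 0), c(1, 1, 1), c(0, 1, 1))
  p <- make_panel(calls)
  # site 1: 3/4 alt -> folded 0.25; site 3: 2/3 among called
  expect_equal(p$variants$maf, c(0.25, 0.25, 1 / 3))
  expect_true(all(p$variants$maf <= 0.5))
  expect_equal(p$variants$n_missing, c(0L, 0L, 1L))
})

test_that("missingness filter applies the max-missing-count rule", {
  set.seed(41)
  p <- random_panel(40, 60, seed = 41, missing_rate = 0.05)
  nm <- colSums(is.na(p$calls))
  for (k in c(0, 3)) {
    kept <- filter_missing(p, k)
    expect_equal(n_variants(kept), sum(nm <= k))  # direct count oracle
  }
  full <- random_panel(10, 5, seed = 7)
  expect_identical(filter_missing(full, 0)$calls, full$calls)
  expect_error(filter_missing(p, -1), "non-negative")
  # the full-matrix rule: a site missing in 12 of 1011 samples fails
  # threshold 11, one missing in 11 passes
  big <- matrix(0L, nrow = 1011, ncol = 2)
  big[, 1] <- rep(c(0L, 1L), length.out = 1011)
  big[, 2] <- rep(c(0L, 1L), length.out = 1011)
  big[1:12, 1] <- NA_integer_
  big[1:11, 2] <- NA_integer_
  kept <- filter_missing(make_panel(big), 11)
  expect_equal(n_variants(kept), 1L)
})

test_that("MAF filter keeps the boundary and matches a recount oracle", {
  calls <- rbind(matrix(0L, 21, 3), matrix(1L, 4, 3))
  calls[25, 1] <- 0L; calls[c(24, 25), 2] <- 0L  # maf 3/25, 2/25, 4/25
  p <- make_panel(calls)
  kept <- filter_maf(p, 0.12)
  expect_equal(n_variants(kept), 2L)  # 0.12 boundary kept, 0.08 removed
  expect_identical(filter_maf(p, 0)$calls, p$calls)
  expect_error(filter_maf(p, 0.6), "0.5")
  sim <- random_panel(50, 200, seed = 11)
  ac <- colSums(sim$calls); maf <- pmin(ac, 50 - ac) / 50
  expect_equal(n_variants(filter_maf(sim, 0.05)), sum(maf >= 0.05))
})

test_that("filters are idempotent, commute, and compose by max threshold", {
  p <- random_panel(30, 150, seed = 5)
  a <- filter_maf(p, 0.1)
  expect_identical(filter_maf(a, 0.1)$calls, a$calls)
  ab <- filter_maf(filter_maf(p, 0.05), 0.2)
  expect_identical(ab$calls, filter_maf(p, 0.2)$calls)
  f1 <- filter_maf(filter_biallelic(p), 0.1)
  f2 <- filter_biallelic(filter_maf(p, 0.1))
  expect_identical(f1$calls, f2$calls)
})

test_that("biallelic filter keeps sites with exactly two observed alleles", {
  calls <- cbind(c(0, 1, 0, 1), c(0, 0, 0, 0), c(1, 1, 1, 1), c(0, 1, 1, 1))
  p <- make_panel(calls)
  kept <- filter_biallelic(p)
  expect_equal(n_variants(kept), 2L)  # monomorphic columns dropped
  allb <- random_panel(10, 20, seed = 2)
  expect_identical(filter_biallelic(allb)$calls, allb$calls)
})

test_that("nucleotide diversity matches definition and the all-pairs oracle", {
  # two haploids differing at 1 site, genome of 100 bp -> pi = 0.01
  p <- make_panel(rbind(c(0), c(1)))
  expect_equal(nucleotide_diversity(p, 100), 0.01)
  mono <- genotype_panel(rbind(c(0, 0), c(0, 0)),
                         data.frame(chrom = "c", pos = 1:2, ref = "A",
                                    alt = "T"))
  expect_equal(nucleotide_diversity(mono, 50), 0)
  expect_error(nucleotide_diversity(p, 0), "> 0")
  toy <- random_panel(5, 30, seed = 9, missing_rate = 0.1)
  expect_equal(nucleotide_diversity(toy, 1000),
               pairwise_pi_oracle(toy$calls, 1000))
})

test_that("singleton fraction counts single-carrier minor alleles", {
  # published full-panel census: 509011 singletons of 1625809 variants
  expect_equal(round(509011 / 1625809, 3), 0.313)
  p <- make_panel(diag(5))  # every variant private to one sample
  expect_equal(singleton_fraction(p), 1)
  sim <- random_panel(30, 100, seed = 13)
  carriers <- apply(sim$calls, 2, function(x) {
    ac <- sum(x); min(ac, 30 - ac)
  })
  expect_equal(singleton_fraction(sim), mean(carriers == 1))
  empty <- suppressWarnings(filter_maf(sim, 0.5))
  if (n_variants(empty) == 0) expect_error(singleton_fraction(empty))
})

test_that("CNV recode maps copies to 1/2 codes and drops invariant genes", {
  cn <- cbind(gA = c(1, 1, 3, 2), gB = c(1, 1, 1, 1), gC = c(0, 1, 2, 1))
  res <- cnv_recode(cn)
  expect_equal(n_variants(res), 2L)  # gB invariant, dropped
  expect_equal(unname(cnv_codes(res)[, res$variants$id == "gA"]),
               c(1L, 1L, 2L, 2L))
  expect_true(all(res$variants$is_cnv))
  # gC: copy 0 becomes missing
  expect_equal(res$variants$n_missing[res$variants$id == "gC"], 1L)
  set.seed(3)
  cn2 <- matrix(sample(0:4, 200, replace = TRUE), nrow = 10)
  res2 <- cnv_recode(cn2)
  oracle <- apply(cn2, 2, function(x) {
    codes <- ifelse(x >= 2, 2L, ifelse(x == 1, 1L, NA))
    length(unique(codes[!is.na(codes)])) >= 2
  })
  expect_equal(n_variants(res2), sum(oracle))
  expect_error(cnv_recode(matrix(-1)), ">= 0")
})

test_that("CNV markers can be appended to a SNP panel and scanned", {
  p <- random_panel(12, 10, seed = 21)
  cn <- matrix(sample(1:3, 24, replace = TRUE), nrow = 12)
  rownames(cn) <- p$sample_ids
  combined <- bind_panels(p, cnv_recode(cn, sample_ids = p$sample_ids))
  expect_equal(n_samples(combined), 12L)
  expect_true(any(combined$variants$is_cnv))
})
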