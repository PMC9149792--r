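test_that("study configs validate trait architecture", {
  expect_error(study_config(), "exactly one")
  expect_error(study_config(preset = "sake-like", trait_type = "mendelian",
                            n_causal = 5), "exactly 1")
  expect_error(study_config(preset = "sake-like", h2 = 1.5), "h2")
})

test_that("a study run is deterministic given config and seed", {
  cfg <- study_config(population = population_config(
    n_samples = 50, n_variants = 400, seed = NULL),
    trait_type = "complex", n_causal = 5, n_runs = 2, n_perm = 20,
    fwer = 0.1, seed = 99)
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_identical(r1$runs, r2$runs)
  expect_equal(nrow(r1$runs), 2)
  # count conservation holds row-wise and in aggregate
  m <- r1$panel_summary$n_variants
  expect_true(all(r1$runs$tp + r1$runs$fp + r1$runs$tn + r1$runs$fn == m))
})

test_that("well-powered Mendelian studies find the causal variant", {
  cfg <- study_config(population = population_config(
    n_samples = 400, n_variants = 800,
    maf_spectrum = list(shape1 = 1, shape2 = 2), seed = NULL),
    trait_type = "mendelian", n_runs = 10, n_perm = 50, seed = 3)
  res <- run_study(cfg)
  expect_gte(mean(res$runs$tp == 1), 0.9)  # causal hit in ~all runs
  # the polygenic term absorbs part of the single-SNP signal when the
  # marker set is small, so lambda sits at or below 1 under a real signal
  expect_lt(median(res$runs$lambda_gc), 1.2)
  expect_gt(median(res$runs$lambda_gc), 0.3)
})

test_that("downsampling keeps n samples and removes monomorphic sites", {
  p <- simulate_panel(population_config(n_samples = 323, n_variants = 2000,
                                        singleton_rate = 0.3, seed = 40))
  d <- downsample_panel(p, 47, seed = 41)
  expect_equal(n_samples(d), 47)
  ac <- colSums(d$calls)
  expect_true(all(ac > 0 & ac < 47))
  expect_true(all(d$sample_ids %in% p$sample_ids))
  # identity downsample only re-filters
  full <- downsample_panel(p, n_samples(p), seed = 42)
  expect_equal(n_samples(full), n_samples(p))
  expect_error(downsample_panel(p, 400), "cannot downsample")
  # survival recount oracle: kept variants = polymorphic after subsetting
  keep <- withr::with_seed(43, sort(sample(323, 60)))
  sub <- p$calls[keep, ]
  ac2 <- colSums(sub)
  d2 <- downsample_panel(p, 60, seed = 43)
  expect_equal(n_variants(d2), sum(ac2 > 0 & ac2 < 60))
})

test_that("real-data association flags id mismatches and finds planted hits", {
  p <- random_panel(80, 300, seed = 50)
  pheno <- data.frame(sample_id = p$sample_ids,
                      value = as.numeric(p$calls[, 100]) * 3 +
                        withr::with_seed(51, rnorm(80, sd = 0.3)))
  out <- associate_real(p, pheno, maf_min = 0.05, n_perm = 40,
                        fwer = 0.1, seed = 52)
  planted <- which(out$panel$variants$pos == p$variants$pos[100])
  expect_equal(out$significant$index[1], planted)
  bad <- pheno[-5, ]
  expect_error(associate_real(p, bad, seed = 1), p$sample_ids[5])
})

test_that("real-data association runs from files on disk", {
  p <- random_panel(40, 120, seed = 60)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_panel(p, f)
  pheno_file <- withr::local_tempfile(fileext = ".tsv")
  tr <- simulate_trait(p, 30L, 0.9, seed = 61)
  write_phenotypes(tr, p, pheno_file)
  out <- associate_real(f, pheno_file, maf_min = 0.05, n_perm = 40,
                        fwer = 0.1, seed = 62)
  expect_s3_class(out$result, "association_result")
  expect_true(out$threshold > 0 && out$threshold <= 1)
})

test_that("a planted CNV effect is detected among SNP markers", {
  p <- random_panel(100, 200, seed = 70)
  cn <- withr::with_seed(71, matrix(sample(1:3, 100 * 5, replace = TRUE),
                                    nrow = 100))
  colnames(cn) <- paste0("g", 1:5)
  cnv <- cnv_recode(cn, sample_ids = p$sample_ids)
  combined <- bind_panels(p, cnv)
  amplified <- as.numeric(cnv_codes(cnv)[, cnv$variants$id == "g2"] == 2)
  pheno <- data.frame(sample_id = p$sample_ids,
                      value = amplified * 2 +
                        withr::with_seed(72, rnorm(100, sd = 0.4)))
  out <- associate_real(combined, pheno, maf_min = 0.05, n_perm = 40,
                        fwer = 0.1, seed = 73)
  top <- out$significant[1, ]
  expect_true(top$id == "g2")
})

test_that("null phenotypes rarely produce significant hits", {
  p <- random_panel(60, 300, seed = 80)
  hits <- withr::with_seed(81, vapply(1:20, function(i) {
    pheno <- data.frame(sample_id = p$sample_ids, value = rnorm(60))
    nrow(associate_real(p, pheno, maf_min = 0.05, n_perm = 40,
                        fwer = 0.05)$significant) > 0
  }, logical(1)))
  expect_lte(mean(hits), 0.25)
})
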