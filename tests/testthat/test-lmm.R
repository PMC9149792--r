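test_that("GRM equals the explicit double-loop sum over variants", {
  p <- random_panel(5, 20, seed = 101)
  k <- compute_grm(p)
  # brute force: standardize each variant by hand, accumulate outer products
  n <- 5; m <- 20
  acc <- matrix(0, n, n)
  for (j in seq_len(m)) {
    x <- p$calls[, j]
    pj <- mean(x)
    w <- (x - pj) / sqrt(pj * (1 - pj))
    acc <- acc + outer(w, w)
  }
  expect_equal(k$matrix, acc / m, tolerance = 1e-12)
  expect_equal(mean(diag(k$matrix)), 1, tolerance = 1e-6)
})

test_that("duplicated samples share diagonal and off-diagonal GRM entries", {
  p <- random_panel(6, 40, seed = 103)
  calls <- rbind(p$calls, p$calls[1, ])  # sample 7 duplicates sample 1
  k <- compute_grm(make_panel(calls))$matrix
  expect_equal(k[1, 7], k[1, 1], tolerance = 1e-10)
  expect_equal(k[7, 7], k[1, 1], tolerance = 1e-10)
  # many independent variants: K approaches identity as n grows; sample
  # centering pins the off-diagonal mean at exactly -1/(n-1)
  big <- random_panel(100, 2000, seed = 104)
  kb <- compute_grm(big)$matrix
  expect_equal(mean(diag(kb)), 1, tolerance = 0.02)
  expect_equal(mean(kb[upper.tri(kb)]), -1 / 99, tolerance = 1e-3)
})

test_that("monomorphic variants are rejected by the GRM", {
  calls <- cbind(rep(0L, 6), rep(c(0L, 1L), 3), rep(c(1L, 0L), 3))
  expect_error(compute_grm(make_panel(calls)), "monomorphic")
})

test_that("spectral REML profile equals the dense-matrix likelihood", {
  set.seed(111)
  n <- 10
  p <- random_panel(n, 60, seed = 112)
  K <- compute_grm(p)$matrix
  y <- rnorm(n) + drop(chol(K + 0.5 * diag(n)) %*% rnorm(n))
  X <- matrix(1, n, 1)
  eig <- eigen(K, symmetric = TRUE)
  ty <- drop(crossprod(eig$vectors, y))
  tX <- crossprod(eig$vectors, X)
  for (delta in c(0.05, 0.3, 1, 5, 40)) {
    prof <- gwasim:::reml_profile(delta, pmax(eig$values, 0), ty, tX,
                                  as.numeric(determinant(crossprod(X))$modulus))
    # profile sigma_g2 out of the dense likelihood independently
    dense_opt <- optimize(function(lg)
      -dense_reml(y, X, K, exp(lg), delta), c(-10, 10), tol = 1e-9)
    expect_equal(prof$loglik, -dense_opt$objective, tolerance = 1e-5)
    expect_equal(prof$sigma_g2, exp(dense_opt$minimum), tolerance = 1e-3)
  }
})

test_that("REML optimizer lands on the dense grid-search optimum", {
  set.seed(121)
  n <- 12
  p <- random_panel(n, 80, seed = 122)
  kin <- compute_grm(p)
  y <- drop(chol(kin$matrix + 0.3 * diag(n)) %*% rnorm(n))
  fit <- fit_null_reml(y, kin)
  X <- matrix(1, n, 1)
  grid <- exp(seq(-10, 10, length.out = 400))
  dense <- vapply(grid, function(d) {
    optimize(function(lg) -dense_reml(y, X, kin$matrix, exp(lg), d),
             c(-12, 12), tol = 1e-9)$objective
  }, numeric(1))
  best <- grid[which.min(dense)]
  expect_equal(log(fit$delta), log(best), tolerance = 0.1)
  expect_equal(fit$reml_loglik, -min(dense), tolerance = 1e-4)
  expect_equal(fit$h2_est, 1 / (1 + fit$delta), tolerance = 1e-10)
})

test_that("null model errors on degenerate phenotypes", {
  p <- random_panel(10, 30, seed = 131)
  kin <- compute_grm(p)
  expect_error(fit_null_reml(rep(1, 10), kin), "zero variance")
  expect_error(fit_null_reml(c(1, NA, rep(0, 8)), kin), "finite")
})

test_that("scan reduces to per-variant OLS when K = I", {
  n <- 30
  p <- random_panel(n, 25, seed = 141)
  kin <- kinship_matrix(diag(n), p$sample_ids)
  ctx <- scan_context(p, kin)
  set.seed(142)
  y <- rnorm(n)
  res <- association_scan(phenotype = y, context = ctx)
  # with V proportional to I, GLS is OLS at any delta: t^2 from lm
  for (j in c(1, 7, 25)) {
    fit <- summary(lm(y ~ p$calls[, j]))
    tstat <- fit$coefficients[2, "t value"]
    expect_equal(res$table$stat[j], tstat^2, tolerance = 1e-8)
    expect_equal(res$table$p_value[j],
                 pchisq(tstat^2, 1, lower.tail = FALSE), tolerance = 1e-8)
  }
})

test_that("a phenotype copying one variant attains the scan minimum there", {
  p <- random_panel(40, 100, seed = 151)
  y <- as.numeric(p$calls[, 42])
  res <- association_scan(p, y)
  expect_equal(which.min(res$table$p_value), 42L)
  expect_true(all(res$table$p_value > 0 & res$table$p_value <= 1))
})

test_that("consistent sample relabeling leaves all p-values unchanged", {
  p <- random_panel(25, 60, seed = 161)
  set.seed(162)
  y <- rnorm(25) + p$calls[, 3]
  res1 <- association_scan(p, y)
  perm <- sample(25)
  p2 <- make_panel(p$calls[perm, ])
  res2 <- association_scan(p2, y[perm])
  expect_equal(res2$table$p_value, res1$table$p_value, tolerance = 1e-6)
})

test_that("heritability estimator follows the variance-ratio definition", {
  fake <- function(sg, se) structure(
    list(sigma_g2 = sg, sigma_e2 = se), class = "null_model_fit")
  expect_equal(estimate_h2(fake(4, 1)), 0.8)
  expect_equal(estimate_h2(fake(0, 2)), 0)
  expect_error(estimate_h2(fake(0, 0)), "zero")
})

test_that("REML recovers the simulated heritability on average", {
  p <- random_panel(200, 500, seed = 171)
  pf <- filter_maf(p, 0.05)
  ctx <- scan_context(pf)
  h2s <- withr::with_seed(172, replicate(40, {
    tr <- simulate_trait(pf, sample_causal(pf, 10, 0.05), 0.8)
    fit_null_reml(tr$phenotype, context = ctx)$h2_est
  }))
  expect_equal(mean(h2s), 0.8, tolerance = 0.08)
  null_h2 <- withr::with_seed(173, replicate(20, {
    fit_null_reml(rnorm(200), context = ctx)$h2_est
  }))
  expect_lt(mean(null_h2), 0.15)
})
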