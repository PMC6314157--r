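test_that("with unrelated subjects the LMM reduces to the OLS closed form", {
  set.seed(21)
  n <- 60
  eig <- eigen(diag(n), symmetric = TRUE)
  for (i in 1:100) {
    x <- rbinom(n, 2, runif(1, 0.1, 0.5))
    if (sd(x) == 0) next
    y <- 0.3 * x + rnorm(n)
    fit <- lmm_test(y, x, eig = eig)
    ref <- ols_ml(y, x)
    expect_equal(fit$beta, ref$beta, tolerance = 1e-6)
    expect_equal(fit$se, ref$se, tolerance = 1e-6)
    expect_lt(abs(fit$p_value - ref$p_value), 1e-5)
  }
})

test_that("degenerate predictors and bad inputs are handled", {
  y <- rnorm(10)
  expect_warning(fit <- lmm_test(y, rep(1, 10), diag(10)), "constant")
  expect_equal(fit$p_value, 1)
  expect_error(lmm_test(y, rnorm(9), diag(9)), "length")
  bad <- diag(10); bad[1, 1] <- -1
  expect_error(lmm_test(y, rbinom(10, 2, 0.4), bad), "semidefinite")
})

test_that("the LMM recovers simulated variance components on pedigrees", {
  peds <- generate_pedigree_set(4, size_range = c(20, 30),
                                generations_range = c(3, 4), seed = 2)
  A <- relationship_matrix_set(peds)
  tr <- simulate_traits(A, "H0", sigma_g2 = 1.5, sigma_e2 = 0.5,
                        n_traits = 40, seed = 5)
  eig <- eigen(A, symmetric = TRUE)
  set.seed(6)
  x <- rbinom(nrow(A), 2, 0.3)
  fits <- sapply(1:40, function(r) {
    f <- lmm_test(tr$values[, r], x, eig = eig)
    c(f$sigma_g2, f$sigma_e2)
  })
  expect_lt(abs(mean(fits[1, ]) - 1.5), 0.4)
  expect_lt(abs(mean(fits[2, ]) - 0.5), 0.4)
})

test_that("edge buffers drop exactly the flanking SNPs", {
  ids <- sprintf("s%05d", 1:8954)
  expect_length(exclude_buffer(ids, 500), 7954)
  expect_identical(exclude_buffer(ids, 0), ids)
  expect_identical(exclude_buffer(ids, 2)[1], ids[3])
  expect_error(exclude_buffer(ids[1:10], 5), "smaller")
})

test_that("rejection rates aggregate per SNP then per MAF bin", {
  res <- data.frame(snp_id = "s1", maf = 0.25, replicate = 1:4,
                    beta = 0, se = 1,
                    p_value = c(0.04, 0.2, 0.06, 0.01),
                    source = "true", model = "H0")
  out <- estimate_rates(res, alphas = 0.05)
  expect_equal(out$rate, 0.5)  # 2 of 4 below alpha

  res2 <- data.frame(snp_id = "s1", maf = 0.25, replicate = 1:3,
                     beta = 0, se = 1, p_value = rep(5e-4, 3),
                     source = "true", model = "Ha")
  out2 <- estimate_rates(res2)
  expect_true(all(out2$rate == 1))

  set.seed(9)
  resu <- data.frame(snp_id = rep(paste0("s", 1:20), each = 100),
                     maf = 0.3, replicate = 1, beta = 0, se = 1,
                     p_value = runif(2000), source = "true", model = "H0")
  outu <- estimate_rates(resu, alphas = 0.05)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / 2000)
  expect_gt(outu$rate, ci[1]); expect_lt(outu$rate, ci[2])
})

test_that("power rises with the SNP's additive variance", {
  peds <- generate_pedigree_set(3, generations_range = c(3, 4),
                                sizes = c(26, 26, 28), seed = 4)
  fx_pool <- generate_founder_pool(
    scenario_config(n_haplotypes = 300, n_snps = 40,
                    region_length_bp = 1e5, seed = 9))
  truth <- drop_haplotypes(peds, fx_pool, seed = 10)
  A <- relationship_matrix_set(peds)
  D <- true_dosage(truth)[rownames(A), ]
  maf <- colMeans(D) / 2
  snps <- names(maf)[maf >= 0.1 & maf <= 0.5][1:10]
  power <- sapply(c(0.005, 0.01, 0.02), function(va) {
    res <- run_association(D, A, snp_ids = snps, model = "Ha",
                           n_traits = 10, v_a = va, seed = 33)
    mean(res$p_value < 0.05)
  })
  expect_true(all(diff(power) >= 0))
  expect_gt(power[3], power[1])
})

test_that("power is driven by imputation accuracy of the dosages", {
  peds <- generate_pedigree_set(3, generations_range = c(3, 4),
                                sizes = c(26, 26, 28), seed = 14)
  pool <- generate_founder_pool(
    scenario_config(n_haplotypes = 300, n_snps = 40,
                    region_length_bp = 1e5, seed = 19))
  truth <- drop_haplotypes(peds, pool, seed = 20)
  A <- relationship_matrix_set(peds)
  D <- true_dosage(truth)[rownames(A), ]
  maf <- colMeans(D) / 2
  snps <- names(maf)[maf >= 0.15 & maf <= 0.5][1:8]
  run <- function(X) {
    res <- run_association(X, A, snp_ids = snps, model = "Ha",
                           trait_dosages = D, n_traits = 12, v_a = 0.05,
                           seed = 44, mafs = pmin(maf, 1 - maf))
    mean(res$p_value < 0.05)
  }
  p_true <- run(D)
  expect_equal(run(D + 0), p_true)        # perfect dosages: identical power
  set.seed(3)
  noisy <- pmin(pmax(D + matrix(rnorm(length(D), 0, 0.8), nrow(D)), 0), 2)
  expect_lt(run(noisy), p_true)           # degraded R2 costs power
})
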