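test_that("founder pools are deterministic and polarized to the minor allele", {
  cfg <- scenario_config(n_haplotypes = 300, n_snps = 150,
                         region_length_bp = 2e5, seed = 11)
  pool1 <- generate_founder_pool(cfg)
  pool2 <- generate_founder_pool(cfg)
  expect_identical(pool1, pool2)
  expect_true(!is.unsorted(pool1$positions_bp, strictly = TRUE))
  for (seed in 1:4) {
    cfg$seed <- seed
    maf <- pool_maf(generate_founder_pool(cfg))
    expect_true(all(maf > 0 & maf <= 0.5))
  }
  expect_error(generate_founder_pool(
    scenario_config(n_haplotypes = 1, n_snps = 10)))
})

test_that("realized MAF spectrum follows the configured bin weights", {
  spec <- pedimpute:::spectrum_presets("eur_like")
  cfg <- scenario_config(n_haplotypes = 2000, n_snps = 4000,
                         region_length_bp = 3e6, maf_spectrum = spec,
                         ld_strength = 0, seed = 5)
  maf <- pool_maf(generate_founder_pool(cfg))
  realized <- table(cut(maf, spec$breaks, include.lowest = TRUE,
                        right = FALSE)) / length(maf)
  expect_lt(max(abs(as.numeric(realized) - spec$probs)), 0.05)
})

test_that("independent sites show only sampling-noise LD", {
  cfg <- scenario_config(n_haplotypes = 500, n_snps = 200,
                         region_length_bp = 2e5, ld_strength = 0, seed = 2)
  pool <- generate_founder_pool(cfg)
  # null expectation of r^2 between independent binary sites is ~ 1/(H-1)
  expect_lt(abs(as.numeric(mean_window_ld(pool, 100)) - 1 / 499), 0.5 / 499)
})

test_that("window LD is monotone in ld_strength", {
  grid <- c(0, 8000, 30000)
  ld <- sapply(grid, function(lam) sapply(1:10, function(seed) {
    cfg <- scenario_config(n_haplotypes = 300, n_snps = 300,
                           region_length_bp = 2e5, ld_strength = lam,
                           seed = seed)
    as.numeric(mean_window_ld(generate_founder_pool(cfg), 100))
  }))
  expect_lt(stats::t.test(ld[, 2] - ld[, 1], alternative = "greater")$p.value,
            0.01)
  expect_lt(stats::t.test(ld[, 3] - ld[, 2], alternative = "greater")$p.value,
            0.01)
})

test_that("ancestry presets land on their window-LD targets", {
  # density-preserving sub-scale of the full presets (same SNPs/bp, fewer
  # sites and haplotypes)
  sub <- function(preset, S) {
    full <- scenario_config(preset = preset)
    scenario_config(preset = preset, n_snps = S, n_haplotypes = 2000,
                    region_length_bp = round(S / full$n_snps *
                                               full$region_length_bp))
  }
  for (tgt in list(c("eur_like", 0.032), c("afr_like", 0.02))) {
    vals <- sapply(1:3, function(seed) {
      cfg <- sub(tgt[1], 1500)
      cfg$seed <- seed
      as.numeric(mean_window_ld(generate_founder_pool(cfg), 100))
    })
    expect_lt(abs(mean(vals) - as.numeric(tgt[2])) / as.numeric(tgt[2]), 0.2)
  }
})

test_that("generated pedigrees honor size, depth and sibship constraints", {
  expect_error(generate_pedigree_set(1, size_range = c(2, 2),
                                     generations_range = c(3, 3)),
               "infeasible")
  trio <- generate_pedigree_set(1, size_range = c(3, 3),
                                generations_range = c(2, 2), seed = 1)[[1]]
  expect_equal(nrow(trio$members), 3)
  expect_length(founders(trio), 2)

  peds <- generate_pedigree_set(20, size_range = c(10, 174),
                                generations_range = c(3, 9),
                                sibship_range = c(1, 11), seed = 42)
  expect_length(peds, 20)
  for (ped in peds) {
    expect_silent(validate_pedigree(ped))
    expect_true(nrow(ped$members) >= 10 && nrow(ped$members) <= 174)
    expect_true(pedigree_generations(ped) >= 3 &&
                  pedigree_generations(ped) <= 9)
    sib <- table(paste(ped$members$father, ped$members$mother)[
      !is.na(ped$members$father)])
    expect_true(all(sib >= 1 & sib <= 11))
    expect_gte(pedigree_bits(ped), 0)
  }
  ids <- unlist(lapply(peds, function(p) p$members$id))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("exact pedigree sizes can be requested", {
  peds <- generate_pedigree_set(4, generations_range = c(3, 5),
                                sizes = c(12, 20, 9, 31), seed = 9)
  expect_identical(vapply(peds, function(p) nrow(p$members), integer(1)),
                   c(ped01 = 12L, ped02 = 20L, ped03 = 9L, ped04 = 31L))
})
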