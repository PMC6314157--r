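test_that("every imputer satisfies the posterior and dosage invariants", {
  fx <- small_dataset(seed = 21)
  ds <- apply_selection(fx$dataset, select_random(fx$peds, 0.25, seed = 4))
  for (res in list(impute_allele_frequency(ds),
                   impute_population_ld(ds),
                   impute_family_kinship(ds))) {
    expect_true(check_imputation_result(res))
    expect_identical(res$subjects, study_subjects(ds))
    expect_true(all(res$dosage >= 0 & res$dosage <= 2))
  }
})

test_that("allele-frequency baseline returns exact HWE posteriors", {
  h <- matrix(0L, 4, 3, dimnames = list(c("fa", "mo", "kid", "x"), NULL))
  truth <- make_truth(h, h)
  ped <- pedigree(c("fa", "mo", "kid", "x"), c(NA, NA, "fa", NA),
                  c(NA, NA, "mo", NA), "unknown", "p")
  ds <- mask_gwas_panel(truth, 1, seed = 1, peds = list(ped))
  ds$reference_ids <- c("fa", "mo")
  res <- impute_allele_frequency(ds, ref_mafs = c(0, 0.5, 0.25))
  free <- setdiff(truth$snp_ids, ds$gwas_snp_ids)
  s0 <- truth$snp_ids[1]
  if (s0 %in% free) {
    expect_equal(unname(res$p0["kid", s0]), 1)
    expect_equal(unname(res$dosage["kid", s0]), 0)
  }
  s2 <- truth$snp_ids[2]
  if (s2 %in% free) {
    expect_equal(unname(res$p1["kid", s2]), 0.5)
    expect_equal(unname(res$dosage["kid", s2]), 1)
    expect_equal(unname(res$p0["kid", s2]), 0.25)
  }
  expect_error(impute_allele_frequency(ds, ref_mafs = c(-0.1, 0.2, 0.2)),
               "0, 1")
})

test_that("kinship conditioning imputes trio genotypes in closed form", {
  # parents homozygous minor at site 2; site 1 is the (observed) panel site
  h1 <- rbind(fa = c(0L, 1L), mo = c(0L, 1L), kid = c(0L, 0L))
  h2 <- h1
  truth <- make_truth(h1, h2, positions_bp = c(1000, 2000))
  ds <- mask_gwas_panel(truth, 1, seed = 5, peds = list(trio_ped()))
  ds$gwas_snp_ids <- truth$snp_ids[1]
  ds$reference_ids <- c("fa", "mo")
  res <- impute_family_kinship(ds)
  target <- truth$snp_ids[2]
  expect_equal(unname(res$dosage["kid", target]), 2)

  # a subject with no sequenced relatives falls back to the prior mean 2p
  h1b <- rbind(fa = c(1L, 1L), mo = c(0L, 0L), kid = c(0L, 1L),
               fa2 = c(0L, 0L), mo2 = c(0L, 0L), kid2 = c(0L, 0L))
  truth2 <- make_truth(h1b, h1b, positions_bp = c(1000, 2000))
  peds2 <- list(trio_ped("t1"),
                pedigree(c("fa2", "mo2", "kid2"), c(NA, NA, "fa2"),
                         c(NA, NA, "mo2"), "unknown", "t2"))
  ds2 <- mask_gwas_panel(truth2, 1, seed = 5, peds = peds2)
  ds2$gwas_snp_ids <- truth2$snp_ids[1]
  ds2$reference_ids <- c("fa", "mo")
  res2 <- impute_family_kinship(ds2)
  tgt <- truth2$snp_ids[2]
  p <- mean(true_dosage(truth2)[c("fa", "mo"), tgt]) / 2
  expect_equal(unname(res2$dosage["kid2", tgt]), 2 * p)
})

test_that("with only unrelated founders the kinship imputer equals HWE", {
  ids <- paste0("f", 1:8)
  ped <- pedigree(ids, NA, NA, "unknown", "flat")
  set.seed(2)
  h1 <- matrix(rbinom(8 * 30, 1, 0.3), 8, 30, dimnames = list(ids, NULL))
  h2 <- matrix(rbinom(8 * 30, 1, 0.3), 8, 30, dimnames = list(ids, NULL))
  truth <- make_truth(h1, h2)
  ds <- mask_gwas_panel(truth, 3, seed = 1, peds = list(ped))
  ds$reference_ids <- ids[1:4]
  fam <- impute_family_kinship(ds)
  af <- impute_allele_frequency(ds)
  expect_equal(fam$dosage, af$dosage)
  expect_equal(fam$p1, af$p1)
})

test_that("LD imputation recovers a duplicated panel site", {
  set.seed(9)
  H <- 200; S <- 40
  hap <- matrix(rbinom(H * S, 1, 0.3), H, S)
  hap[, 25] <- hap[, 24]  # target 25 duplicates its panel neighbor 24
  pool <- make_pool(hap)
  peds <- generate_pedigree_set(2, size_range = c(10, 14),
                                generations_range = c(3, 3), seed = 2)
  truth <- drop_haplotypes(peds, pool, seed = 3)
  ds <- mask_gwas_panel(truth, 5, seed = 1, peds = peds, pool = pool)
  ds$gwas_snp_ids <- pool$snp_ids[c(5, 15, 24, 30, 38)]  # designed panel
  ds <- apply_selection(ds, select_random(peds, 0.3, seed = 4))
  res <- impute_population_ld(ds, k_flank = 3)
  subj <- study_subjects(ds)
  tgt <- pool$snp_ids[25]
  truthv <- true_dosage(truth)[subj, tgt]
  if (stats::sd(truthv) > 0)
    expect_equal(dosage_r2(truthv, res$dosage[subj, tgt]), 1)
})

test_that("without LD the population imputer carries no information", {
  # unrelated subjects, so no information can leak through shared descent
  ids <- sprintf("u%03d", 1:60)
  ped <- pedigree(ids, NA, NA, "unknown", "flat")
  cfg <- scenario_config(n_haplotypes = 400, n_snps = 80,
                         region_length_bp = 8e4, ld_strength = 0, seed = 31)
  pool <- generate_founder_pool(cfg)
  truth <- drop_haplotypes(list(ped), pool, seed = 32)
  ds <- mask_gwas_panel(truth, 15, seed = 33, peds = list(ped), pool = pool)
  ds$reference_ids <- ids[1:20]
  res <- impute_population_ld(ds)
  acc <- snp_accuracy(ds, res, n_buffer = 0)
  expect_lt(mean(acc$r2, na.rm = TRUE), 0.1)
})

test_that("family imputation beats LD imputation for rare variants when
           first-degree relatives are sequenced", {
  wins <- numeric(10)
  for (r in 1:10) {
    peds <- lapply(1:10, function(i)
      nuclear_ped(4, sprintf("fam%d", i), prefix = sprintf("f%d_", i)))
    # EUR-like marker density and LD, ~5% GWAS panel as in the emulated study
    cfg <- scenario_config(n_haplotypes = 400, n_snps = 250,
                           region_length_bp = 1.5e5,
                           maf_spectrum = maf_spectrum(), ld_strength = 15000,
                           seed = 100 + r)
    pool <- generate_founder_pool(cfg)
    truth <- drop_haplotypes(peds, pool, seed = 200 + r)
    ds <- mask_gwas_panel(truth, 12, seed = 300 + r, peds = peds, pool = pool)
    parents <- unname(unlist(lapply(peds, founders)))
    ds$reference_ids <- parents
    fam <- impute_family_kinship(ds)
    ld <- impute_population_ld(ds)
    subj <- study_subjects(ds)
    maf <- colMeans(true_dosage(truth)) / 2
    rare <- setdiff(names(maf)[maf > 0 & maf <= 0.05], ds$gwas_snp_ids)
    r2 <- function(res) {
      v <- vapply(rare, function(s)
        dosage_r2(true_dosage(truth)[subj, s], res$dosage[subj, s]),
        numeric(1))
      mean(v, na.rm = TRUE)
    }
    wins[r] <- r2(fam) - r2(ld)
  }
  expect_gt(mean(wins), 0)
  expect_gte(sum(wins > 0), 8)
})

test_that("LD imputation beats the HWE floor for common variants", {
  diffs <- numeric(5)
  for (r in 1:5) {
    fx <- small_dataset(seed = 40 + r, S = 100, H = 300, ld = 25000)
    ds <- apply_selection(fx$dataset,
                          select_random(fx$peds, 0.3, seed = r))
    ldres <- impute_population_ld(ds)
    af <- impute_allele_frequency(ds)
    acc_ld <- snp_accuracy(ds, ldres, n_buffer = 0)
    acc_af <- snp_accuracy(ds, af, n_buffer = 0)
    common <- acc_ld$maf >= 0.2
    diffs[r] <- mean(acc_ld$iqs[common], na.rm = TRUE) -
      mean(acc_af$iqs[common], na.rm = TRUE)
  }
  expect_gt(mean(diffs), 0)
})

test_that("the combiner obeys its limit identities and is idempotent", {
  fx <- small_dataset(seed = 51)
  ds <- apply_selection(fx$dataset, select_random(fx$peds, 0.25, seed = 1))
  fam <- impute_family_kinship(ds)
  pop <- impute_population_ld(ds)
  expect_equal(combine_ped_pop(fam, pop, tau = 0)$dosage, fam$dosage)
  expect_equal(combine_ped_pop(fam, pop, tau = 1.1)$dosage, pop$dosage)
  twice <- combine_ped_pop(fam, fam, tau = 0.8)
  expect_equal(twice$dosage, fam$dosage)
})

test_that("the combiner picks cells by family confidence (hand-checked 2x2)", {
  mk <- function(p0, p1, p2, lab)
    pedimpute:::new_imputation_result(
      matrix(p0, 2, 2), matrix(p1, 2, 2), matrix(p2, 2, 2),
      c("s1", "s2"), c("m1", "m2"), lab)
  fam <- mk(c(0.9, 0.5, 0.1, 0.85), c(0.05, 0.3, 0.1, 0.1),
            c(0.05, 0.2, 0.8, 0.05), "fam")
  pop <- mk(c(0.2, 0.6, 0.3, 0.1), c(0.6, 0.3, 0.4, 0.2),
            c(0.2, 0.1, 0.3, 0.7), "pop")
  out <- combine_ped_pop(fam, pop, tau = 0.8)
  # confident family cells: (s1,m1)=0.9, (s1,m2)=0.8(p2), (s2,m2)=0.85
  expect_equal(out$p0[1, 1], fam$p0[1, 1])
  expect_equal(out$p2[1, 2], fam$p2[1, 2])
  expect_equal(out$p0[2, 2], fam$p0[2, 2])
  expect_equal(out$p1[2, 1], pop$p1[2, 1])  # max fam posterior 0.5 < tau
  expect_equal(unname(attr(out, "provenance")),
               c(3L, 1L))
  other <- mk(c(1, 1, 1, 1), c(0, 0, 0, 0), c(0, 0, 0, 0), "o")
  other$snp_ids <- c("zz1", "zz2")
  expect_error(combine_ped_pop(fam, other), "grid")
})
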