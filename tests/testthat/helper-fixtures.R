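# Small pedigrees built in code -------------------------------------------

trio_ped <- function(ped_id = "trio") {
  pedigree(id = c("fa", "mo", "kid"),
           father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
           sex = c("male", "female", "unknown"), ped_id = ped_id)
}

nuclear_ped <- function(k = 3, ped_id = "nuc", prefix = "") {
  kids <- paste0(prefix, "kid", seq_len(k))
  fa <- paste0(prefix, "fa"); mo <- paste0(prefix, "mo")
  pedigree(id = c(fa, mo, kids),
           father = c(NA, NA, rep(fa, k)),
           mother = c(NA, NA, rep(mo, k)),
           sex = c("male", "female", rep("unknown", k)), ped_id = ped_id)
}

# grandparents -> two married sons -> one child each (first cousins c1, c2)
cousins_ped <- function() {
  pedigree(id = c("gf", "gm", "s1", "s2", "w1", "w2", "c1", "c2"),
           father = c(NA, NA, "gf", "gf", NA, NA, "s1", "s2"),
           mother = c(NA, NA, "gm", "gm", NA, NA, "w1", "w2"),
           sex = c("male", "female", "male", "male", "female", "female",
                   "unknown", "unknown"),
           ped_id = "cousins")
}

# full-sib mating: child of two full sibs is inbred (A diagonal 1.25)
sibmating_ped <- function() {
  pedigree(id = c("fa", "mo", "s1", "s2", "inb"),
           father = c(NA, NA, "fa", "fa", "s1"),
           mother = c(NA, NA, "mo", "mo", "s2"),
           sex = c("male", "female", "male", "female", "unknown"),
           ped_id = "sibmating")
}

# Hand-built truth/pool objects --------------------------------------------

make_pool <- function(hap, positions_bp = seq_len(ncol(hap)) * 1000,
                      label = "fixture") {
  structure(list(haplotypes = hap, positions_bp = as.numeric(positions_bp),
                 snp_ids = sprintf("snp%05d", seq_len(ncol(hap))),
                 region_label = label),
            class = "haplotype_pool")
}

make_truth <- function(h1, h2, positions_bp = seq_len(ncol(h1)) * 1000) {
  snp_ids <- sprintf("snp%05d", seq_len(ncol(h1)))
  colnames(h1) <- colnames(h2) <- snp_ids
  structure(list(h1 = h1, h2 = h2, subjects = rownames(h1),
                 snp_ids = snp_ids, positions_bp = as.numeric(positions_bp),
                 founder_rows = NULL),
            class = "phased_genotypes")
}

make_selection <- function(ids, ped_id = "fix", strategy = "manual") {
  structure(list(strategy = strategy, selected_ids = ids,
                 by_ped = stats::setNames(list(ids), ped_id),
                 fraction = NA_real_),
            class = "selection_result")
}

# a small ready-to-impute dataset on generated pedigrees
small_dataset <- function(seed = 1, n_peds = 2, size = c(10, 16), S = 120,
                          H = 400, n_panel = 20, ld = 20000) {
  peds <- generate_pedigree_set(n_peds, size_range = size,
                                generations_range = c(3, 4), seed = seed)
  cfg <- scenario_config(n_haplotypes = H, n_snps = S,
                         region_length_bp = S * 600, ld_strength = ld,
                         seed = seed + 1)
  pool <- generate_founder_pool(cfg)
  truth <- drop_haplotypes(peds, pool, seed = seed + 2)
  list(peds = peds, pool = pool,
       dataset = mask_gwas_panel(truth, n_panel, seed = seed + 3,
                                 peds = peds, pool = pool))
}

# Independent oracles -------------------------------------------------------

# Monte-Carlo twice-kinship: empirical expected allele sharing from
# single-locus founder-label drops (independent of the tabular recursion)
mc_twice_kinship <- function(ped, n_drops = 1e5, seed = 99) {
  set.seed(seed)
  m <- ped$members
  n <- nrow(m)
  fnd <- founders(ped)
  a1 <- a2 <- matrix(NA_integer_, n, n_drops, dimnames = list(m$id, NULL))
  a1[fnd, ] <- 2 * match(fnd, fnd) - 1
  a2[fnd, ] <- 2 * match(fnd, fnd)
  todo <- setdiff(m$id, fnd)
  while (length(todo) > 0) {
    for (id in todo) {
      i <- match(id, m$id)
      if (anyNA(a1[m$father[i], ]) || anyNA(a1[m$mother[i], ])) next
      pf <- stats::runif(n_drops) < 0.5
      pm <- stats::runif(n_drops) < 0.5
      a1[id, ] <- ifelse(pf, a1[m$father[i], ], a2[m$father[i], ])
      a2[id, ] <- ifelse(pm, a1[m$mother[i], ], a2[m$mother[i], ])
      todo <- setdiff(todo, id)
    }
  }
  K <- matrix(0, n, n, dimnames = list(m$id, m$id))
  for (i in seq_len(n)) for (j in i:n) {
    share <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
             (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
    K[i, j] <- K[j, i] <- 2 * mean(share) / 4
  }
  K
}

# textbook Cohen's kappa on hard calls (3 genotype classes)
cohen_kappa <- function(truth, calls) {
  lev <- 0:2
  tab <- table(factor(calls, lev), factor(truth, lev))
  N <- sum(tab)
  po <- sum(diag(tab)) / N
  pe <- sum(rowSums(tab) * colSums(tab)) / N^2
  (po - pe) / (1 - pe)
}

# closed-form OLS with ML residual variance and a normal Wald p-value
ols_ml <- function(y, x) {
  X <- cbind(1, x)
  xtx_inv <- solve(crossprod(X))
  beta <- xtx_inv %*% crossprod(X, y)
  r <- y - X %*% beta
  s2 <- sum(r^2) / length(y)
  se <- sqrt(s2 * xtx_inv[2, 2])
  z <- beta[2] / se
  list(beta = beta[2], se = se, p_value = 2 * stats::pnorm(-abs(z)))
}
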