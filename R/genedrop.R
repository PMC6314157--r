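#' Genetic map with a uniform recombination rate
#'
#' Genetic distance between adjacent sites is `(delta_bp / 1e6) * cm_per_mb`,
#' i.e. the default equates 1 cM with 1000 kb.
#'
#' @param positions_bp strictly increasing physical positions.
#' @param cm_per_mb map rate, centiMorgan per megabase (> 0).
#' @return a `genetic_map` list with `positions_bp`, `cm_per_mb`, `cm`.
#' @export
genetic_map <- function(positions_bp, cm_per_mb = 1) {
  stopifnot(cm_per_mb > 0, !is.unsorted(positions_bp, strictly = TRUE))
  structure(list(positions_bp = as.numeric(positions_bp),
                 cm_per_mb = cm_per_mb,
                 cm = as.numeric(positions_bp) / 1e6 * cm_per_mb),
            class = "genetic_map")
}

# Per-interval transmission switch probability: 1% per cM, linear in
# distance, clipped at 1/2 (no Haldane transform, no interference).
interval_theta <- function(map) pmin(0.5, 0.01 * diff(map$cm))

# One meiosis: a gamete that starts on a random parental haplotype and
# switches haplotype between adjacent sites with probability theta.
meiosis <- function(h1, h2, theta) {
  switches <- stats::runif(length(theta)) < theta
  state <- cumsum(c(stats::rbinom(1L, 1L, 0.5), switches)) %% 2L
  ifelse(state == 0L, h1, h2)
}

#' Simulate independent meioses of a phase-known double heterozygote
#'
#' Diagnostic for recombination-rate recovery: runs `n` independent
#' meioses of a synthetic parent that is heterozygous at every site with
#' fully known phase (haplotype 1 carries allele 0 everywhere, haplotype 2
#' allele 1), so the returned gamete entries are the parental-haplotype
#' origin at each site and a gamete whose values differ between two sites
#' is unambiguously recombinant between them. The expected recombinant
#' fraction between sites `d` cM apart is `min(0.5, 0.01 * d)`.
#'
#' @param n number of meioses.
#' @param positions_bp marker positions.
#' @param cm_per_mb map rate (default 1 cM per 1000 kb).
#' @param seed integer seed.
#' @return integer matrix `n x length(positions_bp)` of haplotype origins
#'   (0/1).
#' @export
simulate_meioses <- function(n, positions_bp, cm_per_mb = 1, seed = 1L) {
  map <- genetic_map(positions_bp, cm_per_mb)
  theta <- interval_theta(map)
  S <- length(positions_bp)
  h1 <- rep(0L, S)
  h2 <- rep(1L, S)
  set.seed(seed)
  t(vapply(seq_len(n), function(i) meiosis(h1, h2, theta), integer(S)))
}

#' Drop founder haplotypes through pedigrees
#'
#' Assigns each founder two haplotypes sampled without replacement from the
#' pool (a single draw across all pedigrees, so no pool haplotype is reused
#' within a replicate), then transmits haplotypes through every meiosis in
#' parent-first order. Each gamete starts from a random parental haplotype
#' and recombines between adjacent sites with probability
#' `min(0.5, 0.01 * d_cM)` - a rate of 1% per centiMorgan. The result is
#' Mendelian-consistent by construction.
#'
#' @param peds a `pedigree` or list of pedigrees (ids unique across the set).
#' @param pool a `haplotype_pool` with at least `2 * n_founders` haplotypes.
#' @param map a [genetic_map()] covering the pool's sites (defaults to the
#'   pool positions at 1 cM/Mb).
#' @param seed integer seed; output is deterministic given it.
#' @return a `phased_genotypes` object: matrices `h1`, `h2`
#'   (subjects x sites, 0/1 minor-allele indicators; `h1` is the paternal
#'   haplotype for nonfounders), `subjects`, `snp_ids`, `positions_bp`, and
#'   `founder_rows` (pool row indices used per founder).
#' @export
drop_haplotypes <- function(peds, pool, map = NULL, seed = 1L) {
  peds <- as_pedigree_list(peds)
  if (is.null(map)) map <- genetic_map(pool$positions_bp)
  stopifnot(length(map$positions_bp) == ncol(pool$haplotypes))
  set.seed(seed)
  theta <- interval_theta(map)
  all_ids <- unlist(lapply(peds, function(p) p$members$id), use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("subject ids must be unique across pedigrees")
  fnd <- unlist(lapply(peds, founders), use.names = FALSE)
  H <- nrow(pool$haplotypes)
  if (H < 2L * length(fnd))
    stop("pool has ", H, " haplotypes but ", 2L * length(fnd),
         " are needed for ", length(fnd), " founders")
  rows <- sample.int(H, 2L * length(fnd))
  founder_rows <- matrix(rows, ncol = 2L, byrow = TRUE,
                         dimnames = list(fnd, c("hap1", "hap2")))
  S <- ncol(pool$haplotypes)
  h1 <- h2 <- matrix(0L, length(all_ids), S,
                     dimnames = list(all_ids, pool$snp_ids))
  h1[fnd, ] <- pool$haplotypes[founder_rows[, 1L], , drop = FALSE]
  h2[fnd, ] <- pool$haplotypes[founder_rows[, 2L], , drop = FALSE]
  for (p in peds) {
    m <- p$members
    for (id in pedigree_order(p)) {
      i <- match(id, m$id)
      if (is.na(m$father[i])) next
      h1[id, ] <- meiosis(h1[m$father[i], ], h2[m$father[i], ], theta)
      h2[id, ] <- meiosis(h1[m$mother[i], ], h2[m$mother[i], ], theta)
    }
  }
  structure(list(h1 = h1, h2 = h2, subjects = all_ids,
                 snp_ids = pool$snp_ids,
                 positions_bp = map$positions_bp,
                 founder_rows = founder_rows),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("phased_genotypes: ", length(x$subjects), " subjects x ",
      length(x$snp_ids), " SNPs\n", sep = "")
  invisible(x)
}

#' Genotype dosages (minor-allele counts) from phased truth
#' @param truth a `phased_genotypes`.
#' @return subjects x SNPs integer matrix with entries 0/1/2.
#' @export
true_dosage <- function(truth) truth$h1 + truth$h2

#' Mask a sparse GWAS panel on a simulated dataset
#'
#' Selects `n_panel` SNPs uniformly at random to act as the sparse genotyping
#' array observed on every study subject. The truth is untouched; masking is
#' a view used by exporters, imputers and metrics.
#'
#' @param truth a `phased_genotypes`.
#' @param n_panel number of panel SNPs (must be < number of sites).
#' @param seed integer seed.
#' @param peds the pedigrees the truth was simulated on (carried along for
#'   imputers that need relationship structure).
#' @param pool optionally, the founder pool (carried along for exports and
#'   LD summaries).
#' @param replicate_index replicate number recorded in the dataset.
#' @return a `study_dataset`: list with `truth`, `peds`, `pool`,
#'   `gwas_snp_ids`, `reference_ids` (empty until a selection is applied),
#'   `replicate_index`, `seed`.
#' @export
mask_gwas_panel <- function(truth, n_panel, seed = 1L, peds = NULL,
                            pool = NULL, replicate_index = 1L) {
  S <- length(truth$snp_ids)
  if (n_panel >= S)
    stop("n_panel (", n_panel, ") must be smaller than the number of SNPs (",
         S, ")")
  set.seed(seed)
  panel <- sort(sample.int(S, n_panel))
  structure(list(truth = truth, peds = peds, pool = pool,
                 gwas_snp_ids = truth$snp_ids[panel],
                 reference_ids = character(0),
                 replicate_index = as.integer(replicate_index),
                 seed = as.integer(seed)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset (replicate ", x$replicate_index, "): ",
      length(x$truth$subjects), " subjects, ", length(x$truth$snp_ids),
      " SNPs (", length(x$gwas_snp_ids), " on GWAS panel), ",
      length(x$reference_ids), " reference subjects\n", sep = "")
  invisible(x)
}

#' Deterministic per-replicate seed streams
#'
#' Fans a base seed out into `n` rows of named sub-seeds so that any single
#' replicate (or stage within it) can be reproduced in isolation.
#'
#' @param base_seed integer.
#' @param n number of replicates.
#' @return integer matrix `n x 3` with columns `pool`, `drop`, `mask`.
#' @export
derive_seeds <- function(base_seed, n) {
  set.seed(base_seed)
  matrix(sample.int(.Machine$integer.max - 1L, 3L * n), nrow = n,
         dimnames = list(NULL, c("pool", "drop", "mask")))
}

#' Build replicate study datasets
#'
#' Each replicate draws an independent founder pool, an independent gene
#' drop, and an independent GWAS panel, with all seeds derived
#' deterministically from `base_seed` and the replicate index via
#' [derive_seeds()].
#'
#' @param peds list of pedigrees.
#' @param cfg a [scenario_config()]; its `seed` field is overridden per
#'   replicate.
#' @param n_replicates number of replicates (the emulated study used 100).
#' @param base_seed integer.
#' @param n_panel GWAS panel size (default 500 sites, ~5% of an EUR-like
#'   region).
#' @param cm_per_mb map rate for the gene drop.
#' @return list of `study_dataset` objects.
#' @export
make_replicates <- function(peds, cfg, n_replicates, base_seed = 1L,
                            n_panel = 500L, cm_per_mb = 1) {
  stopifnot(n_replicates >= 1)
  seeds <- derive_seeds(base_seed, n_replicates)
  lapply(seq_len(n_replicates), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- seeds[r, "pool"]
    pool <- generate_founder_pool(cfg_r)
    map <- genetic_map(pool$positions_bp, cm_per_mb)
    truth <- drop_haplotypes(peds, pool, map, seed = seeds[r, "drop"])
    mask_gwas_panel(truth, n_panel, seed = seeds[r, "mask"], peds = peds,
                    pool = pool, replicate_index = r)
  })
}
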