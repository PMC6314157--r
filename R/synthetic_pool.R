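#' Minor-allele-frequency spectrum specification
#'
#' A spectrum is a histogram over (0, 0.5]: bin `breaks` plus bin weights
#' `probs`. Target frequencies are drawn by sampling a bin by weight, then a
#' value inside the bin (log-uniform in the rarest bin, uniform elsewhere),
#' giving a rare-variant-heavy spectrum when the first bins carry most mass.
#'
#' The `"eur_like"` and `"afr_like"` presets reproduce the per-bin site
#' proportions of the European- and African-ancestry simulation scenarios
#' this package emulates (the AFR-like preset has more sites and a heavier
#' rare tail than the EUR-like one).
#'
#' @param breaks increasing numeric vector of bin edges spanning (0, 0.5].
#' @param probs bin weights (normalized internally).
#' @return a `maf_spectrum` list.
#' @export
maf_spectrum <- function(breaks = c(0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                         probs = c(0.30, 0.22, 0.13, 0.12, 0.09, 0.08, 0.06)) {
  stopifnot(length(probs) == length(breaks) - 1L, all(diff(breaks) > 0),
            breaks[1] >= 0, breaks[length(breaks)] <= 0.5, all(probs >= 0))
  structure(list(breaks = breaks, probs = probs / sum(probs)),
            class = "maf_spectrum")
}

# Bin weights implied by the emulated scenarios' per-bin site counts.
spectrum_presets <- function(name) {
  switch(name,
    eur_like = maf_spectrum(probs = c(2497.9, 1708.68, 955.46, 911.85,
                                      766.81, 652.04, 461.26)),
    afr_like = maf_spectrum(probs = c(2621.32, 3333.93, 1646.34, 1384.9,
                                      840.62, 582.29, 481.6)),
    stop("unknown maf spectrum preset '", name, "'"))
}

draw_target_mafs <- function(spec, n, maf_min) {
  bins <- sample.int(length(spec$probs), n, replace = TRUE, prob = spec$probs)
  lo <- pmax(spec$breaks[bins], maf_min)
  hi <- spec$breaks[bins + 1L]
  p <- numeric(n)
  rare <- bins == 1L  # log-uniform inside the rarest bin
  p[rare] <- exp(stats::runif(sum(rare), log(lo[rare]), log(hi[rare])))
  p[!rare] <- stats::runif(sum(!rare), lo[!rare], hi[!rare])
  p
}

#' Simulation scenario configuration
#'
#' Bundles every knob of the founder-pool generator. Two presets mirror the
#' emulated study scenarios: `"eur_like"` (8954 SNPs over a ~5.6 Mb region,
#' fewer and more common variants, stronger LD) and `"afr_like"` (11,891
#' SNPs, rare-heavy spectrum, weaker LD). Both use a pool of 20,000 founder
#' haplotypes. `ld_strength` is the correlation length (bp) of the latent
#' process that induces linkage disequilibrium; mean pairwise r-squared
#' within non-overlapping 100-SNP windows is monotone in it, and the preset
#' values are calibrated so the EUR-like pool lands near 0.032 and the
#' AFR-like pool near 0.02.
#'
#' @param preset `"eur_like"`, `"afr_like"`, or `NULL` for fully manual.
#' @param n_haplotypes number of founder haplotypes in the pool.
#' @param n_snps number of biallelic sites.
#' @param region_length_bp physical length of the simulated region.
#' @param region_start_bp coordinate offset of the first base (1-based).
#' @param maf_spectrum a [maf_spectrum()] (or preset name).
#' @param ld_strength latent correlation length in bp; 0 gives independent
#'   sites.
#' @param seed integer seed; the pool is a deterministic function of the
#'   config.
#' @param region_label label stored with the pool.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(preset = NULL,
                            n_haplotypes = 20000L,
                            n_snps = 9000L,
                            region_length_bp = 6e6,
                            region_start_bp = 26443384,
                            maf_spectrum = NULL,
                            ld_strength = 15000,
                            seed = 1L,
                            region_label = if (is.null(preset)) "custom" else preset) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("eur_like", "afr_like"))
    defaults <- switch(preset,
      eur_like = list(n_snps = 8954L, region_length_bp = 5606534,
                      maf_spectrum = spectrum_presets("eur_like"),
                      ld_strength = 15000),
      afr_like = list(n_snps = 11891L, region_length_bp = 5606534,
                      maf_spectrum = spectrum_presets("afr_like"),
                      ld_strength = 6000))
    call_args <- names(match.call())[-1]
    for (nm in names(defaults))
      if (!nm %in% call_args) assign(nm, defaults[[nm]])
  }
  if (is.null(maf_spectrum)) maf_spectrum <- maf_spectrum()
  if (is.character(maf_spectrum)) maf_spectrum <- spectrum_presets(maf_spectrum)
  cfg <- structure(list(n_haplotypes = as.integer(n_haplotypes),
                        n_snps = as.integer(n_snps),
                        region_length_bp = as.numeric(region_length_bp),
                        region_start_bp = as.numeric(region_start_bp),
                        maf_spectrum = maf_spectrum,
                        ld_strength = as.numeric(ld_strength),
                        seed = as.integer(seed),
                        region_label = region_label),
                   class = "scenario_config")
  stopifnot(cfg$n_haplotypes >= 2, cfg$n_snps >= 2, cfg$region_length_bp > 0,
            cfg$ld_strength >= 0)
  cfg
}

#' Generate a founder haplotype pool
#'
#' Produces an `H x S` binary matrix of founder haplotypes whose per-site
#' minor-allele frequencies follow the configured spectrum and whose linkage
#' disequilibrium decays with physical distance.
#'
#' Each haplotype is generated from a standard-normal latent AR(1) process
#' along the chromosome: the latent correlation between adjacent sites is
#' `exp(-d_bp / ld_strength)`, and the allele at a site is the minor allele
#' when the latent value falls below the quantile of that site's target
#' frequency. Marginals therefore match the target spectrum exactly in
#' expectation, while nearby sites are correlated with a strength that
#' decays geometrically in distance and is monotone in `ld_strength`;
#' `ld_strength = 0` yields independent sites. Columns that come out
#' monomorphic are redrawn from a polymorphism-conditioned binomial, and all
#' sites are polarized so the coded allele is the minor one (frequency in
#' (0, 0.5]).
#'
#' @param cfg a [scenario_config()].
#' @return a `haplotype_pool`: list with `haplotypes` (H x S integer matrix,
#'   1 = minor allele), `positions_bp`, `snp_ids`, `region_label`.
#' @export
generate_founder_pool <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  H <- cfg$n_haplotypes; S <- cfg$n_snps
  set.seed(cfg$seed)
  pos <- sort(sample.int(cfg$region_length_bp, S)) + cfg$region_start_bp - 1
  p <- draw_target_mafs(cfg$maf_spectrum, S, maf_min = 1 / H)
  thr <- stats::qnorm(p)
  hap <- matrix(0L, H, S)
  if (cfg$ld_strength > 0) {
    rho <- exp(-diff(pos) / cfg$ld_strength)
    z <- stats::rnorm(H)
    hap[, 1L] <- as.integer(z < thr[1L])
    for (s in 2L:S) {
      z <- rho[s - 1L] * z + sqrt(1 - rho[s - 1L]^2) * stats::rnorm(H)
      hap[, s] <- as.integer(z < thr[s])
    }
  } else {
    hap[] <- as.integer(stats::runif(H * S) < rep(p, each = H))
  }
  # polymorphism repair + minor-allele polarization
  cnt <- colSums(hap)
  for (s in which(cnt == 0L | cnt == H)) {
    k <- 0L
    while (k == 0L || k == H) k <- stats::rbinom(1L, H, p[s])
    hap[, s] <- 0L
    hap[sample.int(H, k), s] <- 1L
    cnt[s] <- k
  }
  flip <- cnt > H / 2
  hap[, flip] <- 1L - hap[, flip]
  structure(list(haplotypes = hap,
                 positions_bp = as.numeric(pos),
                 snp_ids = sprintf("snp%05d", seq_len(S)),
                 region_label = cfg$region_label),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("haplotype_pool '", x$region_label, "': ", nrow(x$haplotypes),
      " haplotypes x ", ncol(x$haplotypes), " SNPs, span ",
      round(diff(range(x$positions_bp)) / 1e6, 2), " Mb\n", sep = "")
  invisible(x)
}

#' Realized minor-allele frequencies of a pool
#' @param pool a `haplotype_pool`.
#' @return numeric vector of per-site frequencies of the coded (minor) allele.
#' @export
pool_maf <- function(pool) colMeans(pool$haplotypes)

#' Export a haplotype pool as matrix TSV and map TSV
#'
#' `write_pool_tsv` writes the haplotype matrix (rows = haplotypes, columns
#' named by SNP id); `write_map_tsv` writes a 2-column map (snp_id, bp).
#' @param pool a `haplotype_pool`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pool_tsv <- function(pool, path) {
  tab <- as.data.frame(pool$haplotypes)
  names(tab) <- pool$snp_ids
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_tsv
#' @export
write_map_tsv <- function(pool, path) {
  utils::write.table(data.frame(snp_id = pool$snp_ids,
                                bp = format(pool$positions_bp, scientific = FALSE, trim = TRUE)),
                     path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
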