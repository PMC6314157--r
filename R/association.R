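#' Mixed-model association test for one SNP and one trait
#'
#' Exact maximum-likelihood fit of the two-variance-component model
#' `y = a + b x + e`, `e ~ N(0, sigma_g2 * A + sigma_e2 * I)`, followed by
#' a Wald test of `b = 0` against the standard-normal reference.
#'
#' The relationship matrix is eigendecomposed once (pass `eig` to reuse it
#' across many tests); in the rotated basis the covariance is diagonal,
#' `sigma_g2 * (d_i + delta)` with `delta = sigma_e2 / sigma_g2`, and the
#' profile log-likelihood is maximized over `log(delta)` on [-10, 10] by
#' 1-D optimization, with generalized least squares for the fixed effects
#' at each candidate `delta`. The boundary profiles (all-genetic /
#' all-residual) are also evaluated so purely unstructured data fall back
#' to ordinary least squares exactly.
#'
#' @param y trait vector.
#' @param x genotype dosage vector (may be continuous; imputed dosages are
#'   tested directly, without quality filtering).
#' @param A relationship matrix (ignored when `eig` is given).
#' @param eig optional precomputed `eigen(A, symmetric = TRUE)`.
#' @return list with `beta`, `se`, `p_value`, `sigma_g2`, `sigma_e2`.
#'   A constant `x` gives `p_value = 1` with a warning.
#' @export
lmm_test <- function(y, x, A = NULL, eig = NULL) {
  if (length(y) != length(x)) stop("y and x have different lengths")
  if (stats::sd(x) == 0) {
    warning("constant genotype vector; returning p = 1")
    return(list(beta = 0, se = NA_real_, p_value = 1,
                sigma_g2 = NA_real_, sigma_e2 = NA_real_))
  }
  if (is.null(eig)) {
    if (is.null(A)) stop("supply A or its eigendecomposition")
    eig <- eigen(A, symmetric = TRUE)
  }
  if (min(eig$values) < -1e-6)
    stop("relationship matrix is not positive semidefinite")
  d <- pmax(eig$values, 0)
  n <- length(y)
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, cbind(1, x))
  profile <- function(log_delta) {
    w <- 1 / (d + exp(log_delta))
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    XtWy <- crossprod(XtW, yt)
    beta <- solve(XtWX, XtWy)
    r <- yt - Xt %*% beta
    s2 <- sum(w * r^2) / n
    ll <- -0.5 * (n * log(2 * pi * s2) - sum(log(w)) + n)
    list(ll = ll, beta = beta, s2 = s2, XtWX = XtWX)
  }
  opt <- stats::optimize(function(ld) profile(ld)$ll, c(-10, 10),
                         maximum = TRUE)
  cand <- opt$maximum
  # residual-only limit: compare against delta -> +inf (OLS)
  fit <- profile(cand)
  fit_ols <- profile(30)
  if (fit_ols$ll > fit$ll + 1e-9) { fit <- fit_ols; cand <- 30 }
  delta <- exp(cand)
  sigma_g2 <- fit$s2
  vb <- solve(fit$XtWX) * sigma_g2
  beta <- fit$beta[2]
  se <- sqrt(vb[2, 2])
  z <- beta / se
  list(beta = beta, se = se, p_value = 2 * stats::pnorm(-abs(z)),
       sigma_g2 = if (cand >= 30) 0 else sigma_g2,
       sigma_e2 = sigma_g2 * delta)
}

#' Drop edge-buffer SNPs from a scored set
#'
#' Removes the first and last `n_buffer` SNPs in position order, where
#' imputation lacks flanking markers. With 8954 sites and the default
#' 500-SNP buffers, 7954 sites are retained (10,891 of 11,891).
#'
#' @param snp_ids SNP ids ordered by position.
#' @param n_buffer SNPs to drop at each end (default 500).
#' @return the retained SNP ids.
#' @export
exclude_buffer <- function(snp_ids, n_buffer = 500L) {
  S <- length(snp_ids)
  if (n_buffer == 0) return(snp_ids)
  if (2L * n_buffer >= S)
    stop("2 * n_buffer (", 2L * n_buffer, ") must be smaller than the ",
         "number of SNPs (", S, ")")
  snp_ids[(n_buffer + 1L):(S - n_buffer)]
}

#' Run mixed-model association across SNPs and trait replicates
#'
#' Simulates `n_traits` traits per SNP under the requested model and tests
#' each trait against the SNP's dosages with [lmm_test()], reusing a single
#' eigendecomposition of `A`.
#'
#' @param dosages subjects x SNPs matrix (true genotypes or imputed
#'   dosages) entered as the tested predictor.
#' @param A relationship matrix for the same subjects.
#' @param snp_ids columns of `dosages` to test.
#' @param model `"H0"` (type-I error) or `"Ha"` (power).
#' @param trait_dosages genotype matrix used to *generate* the `"Ha"`
#'   traits (defaults to `dosages`). When evaluating imputed dosages, pass
#'   the true genotypes here so the simulated trait does not depend on
#'   imputation errors.
#' @param mafs per-SNP frequencies used for effect sizes under `"Ha"`
#'   (defaults to frequencies realized in `dosages`).
#' @param n_traits trait replicates per SNP.
#' @param sigma_g2,sigma_e2,v_a trait-model parameters.
#' @param seed integer seed.
#' @param genotype_source label recorded on each row.
#' @return data.frame with one row per (SNP, trait replicate):
#'   `snp_id`, `maf`, `replicate`, `beta`, `se`, `p_value`, `source`,
#'   `model`.
#' @export
run_association <- function(dosages, A, snp_ids = colnames(dosages),
                            model = c("H0", "Ha"), trait_dosages = dosages,
                            mafs = NULL, n_traits = 10L, sigma_g2 = 1,
                            sigma_e2 = 1, v_a = 0.01, seed = 1L,
                            genotype_source = "true") {
  model <- match.arg(model)
  stopifnot(identical(rownames(dosages), rownames(A)),
            identical(rownames(trait_dosages), rownames(A)))
  eig <- eigen(A, symmetric = TRUE)
  if (is.null(mafs)) {
    mafs <- colMeans(dosages[, snp_ids, drop = FALSE]) / 2
    mafs <- pmin(mafs, 1 - mafs)
  }
  seeds <- derive_seeds(seed, length(snp_ids))[, "drop"]
  out <- vector("list", length(snp_ids))
  for (i in seq_along(snp_ids)) {
    s <- snp_ids[i]
    x <- dosages[, s]
    tr <- simulate_traits(A, model = model,
                          X = if (model == "Ha") trait_dosages[, s],
                          maf = if (model == "Ha") max(mafs[s], 1e-6),
                          sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                          v_a = v_a, n_traits = n_traits, seed = seeds[i])
    fits <- lapply(seq_len(n_traits), function(r)
      suppressWarnings(lmm_test(tr$values[, r], x, eig = eig)))
    out[[i]] <- data.frame(snp_id = s, maf = unname(mafs[s]),
                           replicate = seq_len(n_traits),
                           beta = vapply(fits, `[[`, numeric(1), "beta"),
                           se = vapply(fits, `[[`, numeric(1), "se"),
                           p_value = vapply(fits, `[[`, numeric(1), "p_value"),
                           source = genotype_source, model = model,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Aggregate association results into per-bin rejection rates
#'
#' For each SNP, the rejection rate is the proportion of trait replicates
#' with `p < alpha`; rates are then averaged (unweighted) over SNPs within
#' each MAF bin, separately per alpha, genotype source and model. `H0`
#' rows are type-I error, `Ha` rows power.
#'
#' @param results data.frame from [run_association()] (rbind several for
#'   multiple sources/replicates).
#' @param alphas nominal significance levels.
#' @param binning a [maf_bins()].
#' @return a `rate_table` data.frame: `model`, `source`, `bin`, `alpha`,
#'   `rate`, `n_tests`, `n_snps`.
#' @export
estimate_rates <- function(results, alphas = c(0.05, 0.01, 0.001),
                           binning = maf_bins()) {
  results$bin <- bin_of(results$maf, binning)
  if (anyNA(results$bin))
    message(sum(is.na(results$bin)), " tests outside (0, 0.5] omitted")
  groups <- split(results, list(results$model, results$source,
                                results$bin), drop = TRUE, sep = "\r")
  rows <- lapply(groups, function(d) {
    per_snp <- split(d$p_value, d$snp_id)
    do.call(rbind, lapply(alphas, function(a)
      data.frame(model = d$model[1], source = d$source[1],
                 bin = as.character(d$bin[1]), alpha = a,
                 rate = mean(vapply(per_snp, function(p) mean(p < a),
                                    numeric(1))),
                 n_tests = nrow(d), n_snps = length(per_snp),
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$model, out$source, out$bin, -out$alpha), ]
}

#' Write a rate table as TSV
#' @param rates data.frame from [estimate_rates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_tsv <- function(rates, path) {
  utils::write.table(rates, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
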