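#' Per-SNP additive effect size
#'
#' `beta_j = sqrt(v_a / (2 * MAF_j * (1 - MAF_j)))`, the effect size that
#' gives SNP `j` an additive variance contribution of `v_a` under
#' Hardy-Weinberg genotype frequencies, since Var(X_j) = 2 MAF (1 - MAF)
#' for a 0/1/2-coded genotype. Rarer SNPs get larger effects at fixed
#' `v_a`.
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @param v_a additive variance of the SNP (default 0.01).
#' @return effect size on the trait scale.
#' @export
effect_size <- function(maf, v_a = 0.01) {
  stopifnot(v_a >= 0)
  if (any(maf <= 0) || any(maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  sqrt(v_a / (2 * maf * (1 - maf)))
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`. The default components
#' (1, 1) give total variance 2 and heritability 0.5.
#'
#' @param sigma_g2 polygenic variance.
#' @param sigma_e2 residual variance.
#' @return heritability in [0, 1].
#' @export
heritability <- function(sigma_g2 = 1, sigma_e2 = 1) {
  stopifnot(sigma_g2 >= 0, sigma_e2 >= 0)
  if (sigma_g2 + sigma_e2 == 0) stop("total variance is zero")
  sigma_g2 / (sigma_g2 + sigma_e2)
}

# symmetric factor L with L %*% t(L) = Sigma; Cholesky with an
# eigenvalue-clipped fallback for semidefinite matrices
sigma_factor <- function(Sigma) {
  L <- tryCatch(t(chol(Sigma)), error = function(e) NULL)
  if (is.null(L)) {
    warning("Cholesky failed; using eigenvalue-clipped factorization")
    e <- eigen(Sigma, symmetric = TRUE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(Sigma))
  }
  L
}

#' Simulate quantitative traits with pedigree-structured covariance
#'
#' Draws trait replicates under the null model `Y = e` or the alternative
#' model `Y = beta_j X_j + e`, with
#' `e ~ N(0, sigma_g2 * A + sigma_e2 * I)` where `A` is the additive
#' relationship matrix (twice the kinship coefficients). The default
#' components (1, 1) set the total variance of a non-inbred subject to 2
#' and the heritability to 0.5. Under the alternative, `beta_j` comes from
#' [effect_size()] at the supplied SNP frequency.
#'
#' @param A relationship matrix (positive semidefinite), subjects in rows.
#' @param model `"H0"` or `"Ha"`.
#' @param X genotype vector (0/1/2 minor-allele copies) for `"Ha"`.
#' @param maf the SNP's minor allele frequency used for the effect size;
#'   defaults to the frequency realized in `X`.
#' @param sigma_g2,sigma_e2 polygenic and residual variances.
#' @param v_a additive variance of the tested SNP (default 0.01).
#' @param n_traits number of trait replicates (the emulated study used 10
#'   per SNP per dataset).
#' @param seed integer seed.
#' @return a `trait_replicates` object: `values` (subjects x n_traits
#'   matrix), `model`, `beta`, and the variance components.
#' @export
simulate_traits <- function(A, model = c("H0", "Ha"), X = NULL, maf = NULL,
                            sigma_g2 = 1, sigma_e2 = 1, v_a = 0.01,
                            n_traits = 10L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(sigma_g2 >= 0, sigma_e2 >= 0, n_traits >= 1)
  n <- nrow(A)
  Sigma <- sigma_g2 * A + sigma_e2 * diag(n)
  L <- sigma_factor(Sigma)
  set.seed(seed)
  eps <- L %*% matrix(stats::rnorm(n * n_traits), n, n_traits)
  beta <- 0
  if (model == "Ha") {
    if (is.null(X) || length(X) != n)
      stop("model Ha needs a genotype vector X of length nrow(A)")
    if (is.null(maf)) {
      maf <- mean(X) / 2
      maf <- min(maf, 1 - maf)
    }
    beta <- effect_size(maf, v_a)
    eps <- eps + beta * X
  }
  rownames(eps) <- rownames(A)
  structure(list(values = eps, model = model, beta = beta,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, v_a = v_a,
                 seed = as.integer(seed)),
            class = "trait_replicates")
}

#' @export
print.trait_replicates <- function(x, ...) {
  cat("trait_replicates (", x$model, "): ", nrow(x$values), " subjects x ",
      ncol(x$values), " replicates; sigma_g2=", x$sigma_g2, ", sigma_e2=",
      x$sigma_e2, ", h2=", heritability(x$sigma_g2, x$sigma_e2), "\n",
      sep = "")
  invisible(x)
}

#' Write trait replicates as TSV with a JSON parameter sidecar
#'
#' @param traits a `trait_replicates`.
#' @param path output TSV path; parameters go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_traits_tsv <- function(traits, path) {
  tab <- data.frame(subject_id = rownames(traits$values), traits$values)
  names(tab)[-1] <- paste0("trait_", seq_len(ncol(traits$values)))
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  pars <- traits[c("model", "beta", "sigma_g2", "sigma_e2", "v_a", "seed")]
  jsonlite::write_json(pars, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
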