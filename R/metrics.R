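#' Squared Pearson correlation between true and imputed dosages
#'
#' The per-SNP accuracy metric computed between the imputed and true
#' dosages of the imputation-target (non-reference) subjects. Invariant to
#' affine rescaling, so the minor-allele count scale (0-2) and the
#' minor-allele fraction scale (0-1) give identical values. Undefined
#' (`NA`) when either vector is constant - notably for the
#' allele-frequency baseline, whose prediction has zero variance.
#'
#' @param true_dosages,imputed_dosages numeric vectors of equal length.
#' @return squared correlation in [0, 1], or `NA` if undefined.
#' @export
dosage_r2 <- function(true_dosages, imputed_dosages) {
  if (length(true_dosages) != length(imputed_dosages))
    stop("dosage vectors have different lengths")
  if (stats::sd(true_dosages) == 0 || stats::sd(imputed_dosages) == 0)
    return(NA_real_)
  stats::cor(true_dosages, imputed_dosages)^2
}

#' Imputation quality score (chance-corrected agreement)
#'
#' A kappa-type statistic between imputed genotype probabilities and true
#' genotypes. A fractional 3x3 contingency table is built by adding each
#' subject's posterior triple to the column of its true genotype:
#' `n[j, k] = sum_i P_i(imputed = j) * 1[true_i = k]`. Then with
#' `Po = sum_j n[j, j] / N` (observed agreement) and
#' `Pc = sum_j row_j * col_j / N^2` (agreement expected by chance),
#' `IQS = (Po - Pc) / (1 - Pc)`. The upper bound is 1 (attained only by
#' perfect hard calls on a polymorphic site); the score can be negative,
#' and is undefined (`NA`) when `Pc = 1` (monomorphic agreement). With
#' degenerate (0/1) posteriors it reduces to Cohen's kappa.
#'
#' @param true_genotypes integer vector with values in 0, 1, 2.
#' @param posteriors matrix `n x 3` (columns P0, P1, P2) or a list with
#'   elements `p0`, `p1`, `p2` of per-subject probabilities.
#' @param best_guess if `TRUE`, posteriors are collapsed to hard calls
#'   (ties toward the smaller genotype) before tabulation.
#' @return IQS value (<= 1, possibly negative) or `NA`.
#' @export
iqs <- function(true_genotypes, posteriors, best_guess = FALSE) {
  P <- as_posterior_matrix(posteriors, length(true_genotypes))
  if (best_guess) {
    hard <- best_guess_calls(P)
    P <- cbind(hard == 0, hard == 1, hard == 2) * 1
  }
  N <- length(true_genotypes)
  tab <- vapply(0:2, function(k)
    colSums(P[true_genotypes == k, , drop = FALSE]), numeric(3))
  po <- sum(diag(tab)) / N
  pc <- sum(rowSums(tab) * colSums(tab)) / N^2
  if (abs(1 - pc) < 1e-12) return(NA_real_)
  (po - pc) / (1 - pc)
}

as_posterior_matrix <- function(posteriors, n) {
  P <- if (is.list(posteriors) && !is.data.frame(posteriors))
    cbind(posteriors$p0, posteriors$p1, posteriors$p2)
  else as.matrix(posteriors)
  if (nrow(P) != n || ncol(P) != 3)
    stop("posteriors must be an n x 3 probability matrix")
  if (any(P < -1e-6) || any(abs(rowSums(P) - 1) > 1e-4))
    stop("invalid genotype posteriors (not a probability simplex)")
  P
}

best_guess_calls <- function(P) max.col(P, ties.method = "first") - 1L

#' Concordance rate of best-guess calls
#'
#' Fraction of best-guess genotype calls (highest posterior, ties toward
#' the smaller genotype index) equal to the truth. Reported for
#' completeness only: it overestimates accuracy for rare variants, where
#' always calling the major homozygote is already nearly always correct,
#' and it is excluded from headline summaries.
#'
#' @inheritParams iqs
#' @return concordance in [0, 1].
#' @export
concordance_rate <- function(true_genotypes, posteriors) {
  if (length(true_genotypes) == 0) stop("empty genotype vector")
  P <- as_posterior_matrix(posteriors, length(true_genotypes))
  mean(best_guess_calls(P) == true_genotypes)
}

#' Default minor-allele-frequency bins
#'
#' The seven bins partitioning (0, 0.5]:
#' (0,0.01), [0.01,0.05), [0.05,0.1), [0.1,0.2), [0.2,0.3), [0.3,0.4),
#' [0.4,0.5].
#'
#' @param breaks bin edges.
#' @return a `maf_binning` list with `breaks` and `labels`.
#' @export
maf_bins <- function(breaks = c(0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  k <- length(breaks) - 1L
  labels <- paste0(ifelse(seq_len(k) == 1L, "(", "["),
                   breaks[-length(breaks)], ",", breaks[-1],
                   ifelse(seq_len(k) == k, "]", ")"))
  structure(list(breaks = breaks, labels = labels), class = "maf_binning")
}

bin_of <- function(maf, binning) {
  cut(maf, breaks = binning$breaks, labels = binning$labels,
      include.lowest = TRUE, right = FALSE)
}

#' Per-SNP imputation accuracy records
#'
#' Computes dosage R-squared, IQS and concordance for every scored SNP of
#' a dataset, over the non-reference subjects only. GWAS-panel SNPs are
#' always excluded (they are observed, not imputed); by default an edge
#' buffer of `n_buffer` SNPs at each end of the region is excluded as well,
#' where imputation lacks flanking information. Undefined metrics are kept
#' as `NA`, never coerced to 0.
#'
#' @param dataset a `study_dataset`.
#' @param result an `imputation_result` covering the study subjects.
#' @param true_mafs per-SNP true frequencies used for binning (defaults to
#'   the realized frequency among all pedigree members).
#' @param n_buffer edge-buffer size in SNPs (0 disables; default 500).
#' @return data.frame with columns `snp_id`, `maf`, `r2`, `iqs`, `cr`, `n`.
#' @export
snp_accuracy <- function(dataset, result, true_mafs = NULL, n_buffer = 500L) {
  subj <- study_subjects(dataset)
  stopifnot(all(subj %in% result$subjects))
  snps <- dataset$truth$snp_ids
  scored <- setdiff(if (n_buffer > 0) exclude_buffer(snps, n_buffer) else snps,
                    dataset$gwas_snp_ids)
  D <- true_dosage(dataset$truth)[subj, , drop = FALSE]
  if (is.null(true_mafs)) {
    true_mafs <- colMeans(true_dosage(dataset$truth)) / 2
    true_mafs <- pmin(true_mafs, 1 - true_mafs)
  }
  rec <- lapply(scored, function(s) {
    g <- D[, s]
    post <- cbind(result$p0[subj, s], result$p1[subj, s], result$p2[subj, s])
    data.frame(snp_id = s, maf = unname(true_mafs[s]),
               r2 = dosage_r2(g, result$dosage[subj, s]),
               iqs = iqs(g, post),
               cr = concordance_rate(g, post),
               n = length(subj), stringsAsFactors = FALSE)
  })
  do.call(rbind, rec)
}

#' Summarize per-SNP accuracy by MAF bin
#'
#' Mean of the defined values of each metric per bin; SNPs with undefined
#' metrics are counted per bin (`n_undef_*`), not averaged in as zeros.
#'
#' @param records data.frame from [snp_accuracy()] (or rbind of several
#'   replicates).
#' @param binning a [maf_bins()].
#' @return data.frame with one row per non-empty bin.
#' @export
summarize_by_bin <- function(records, binning = maf_bins()) {
  records$bin <- bin_of(records$maf, binning)
  out <- lapply(split(records, records$bin, drop = TRUE), function(d) {
    data.frame(bin = as.character(d$bin[1]),
               n_snps = nrow(d),
               mean_r2 = mean(d$r2, na.rm = TRUE),
               mean_iqs = mean(d$iqs, na.rm = TRUE),
               mean_cr = mean(d$cr, na.rm = TRUE),
               n_undef_r2 = sum(is.na(d$r2)),
               n_undef_iqs = sum(is.na(d$iqs)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[c("mean_r2", "mean_iqs", "mean_cr")][
    sapply(out[c("mean_r2", "mean_iqs", "mean_cr")], is.nan)] <- NA
  out
}

#' Mean pairwise LD within non-overlapping SNP windows
#'
#' Splits the sites into consecutive non-overlapping windows of `window`
#' SNPs (a trailing partial window is dropped), computes the mean pairwise
#' squared correlation between allele indicators over all site pairs within
#' each window, and averages across windows. Pairs involving a monomorphic
#' site are skipped. For independent sites the null expectation is
#' approximately `1 / (H - 1)` for `H` haplotypes.
#'
#' @param pool a `haplotype_pool` (or 0/1 matrix, haplotypes x sites).
#' @param window window size in SNPs (default 100).
#' @return mean window r-squared; the per-window means are attached as the
#'   `per_window` attribute.
#' @export
mean_window_ld <- function(pool, window = 100L) {
  hap <- if (inherits(pool, "haplotype_pool")) pool$haplotypes else pool
  S <- ncol(hap)
  if (window > S) stop("window (", window, ") exceeds the number of sites (",
                       S, ")")
  n_win <- S %/% window
  per_window <- vapply(seq_len(n_win), function(w) {
    cols <- ((w - 1L) * window + 1L):(w * window)
    sub <- hap[, cols, drop = FALSE]
    poly <- apply(sub, 2L, stats::sd) > 0
    sub <- sub[, poly, drop = FALSE]
    if (ncol(sub) < 2L) return(NA_real_)
    r2 <- stats::cor(sub)^2
    mean(r2[upper.tri(r2)])
  }, numeric(1))
  structure(mean(per_window, na.rm = TRUE), per_window = per_window)
}

#' Write per-SNP accuracy and per-bin summaries as TSV
#' @param records,summary data.frames from [snp_accuracy()] /
#'   [summarize_by_bin()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_tsv <- function(records, path) {
  utils::write.table(records, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_accuracy_tsv
#' @export
write_bin_summary_tsv <- function(summary, path) {
  utils::write.table(summary, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Effective sample-size factor implied by imputation accuracy
#'
#' For association testing on imputed dosages, the squared correlation
#' between imputed and true dosages acts as an effective-sample-size
#' multiplier: matching the power obtained with perfect genotypes requires
#' `1 / r2` times as many subjects (an accuracy of 0.8 costs a factor
#' 1.25).
#'
#' @param r2 dosage r-squared in (0, 1].
#' @return the sample-size inflation factor `1 / r2`.
#' @export
effective_sample_factor <- function(r2) {
  stopifnot(all(r2 > 0), all(r2 <= 1))
  1 / r2
}
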