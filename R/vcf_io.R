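# VCF 4.2 export/import. Sites are synthetic biallelic SNPs; by convention
# the exported REF is the major allele ("A") and ALT the minor allele ("C"),
# so dosages count ALT = minor alleles. Import harmonizes swapped alleles.

vcf_header <- function(chrom, format_lines) {
  c("##fileformat=VCFv4.2",
    "##source=pedimpute",
    paste0("##contig=<ID=", chrom, ">"),
    format_lines)
}

vcf_fixed_cols <- function(truthish, keep) {
  data.frame(CHROM = "22",
             POS = format(truthish$positions_bp[keep], scientific = FALSE,
                          trim = TRUE),
             ID = truthish$snp_ids[keep],
             REF = "A", ALT = "C", QUAL = ".", FILTER = ".", INFO = ".",
             stringsAsFactors = FALSE)
}

write_vcf_body <- function(path, header, fixed, format_str, geno) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(geno)), collapse = "\t"), con)
  body <- cbind(as.matrix(fixed), FORMAT = format_str, geno)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Export phased truth genotypes as VCF 4.2
#'
#' Writes phased GT fields (`h1|h2`) for the requested subjects and sites.
#' REF is the major allele, ALT the minor allele, so allele 1 counts minor
#' alleles.
#'
#' @param truth a `phased_genotypes`.
#' @param path output path.
#' @param subjects subject ids to write (default all).
#' @param snp_ids sites to write (default all).
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path, subjects = truth$subjects,
                            snp_ids = truth$snp_ids) {
  keep <- match(snp_ids, truth$snp_ids)
  if (anyNA(keep)) stop("unknown snp ids requested")
  gt <- matrix(paste0(t(truth$h1[subjects, keep, drop = FALSE]), "|",
                      t(truth$h2[subjects, keep, drop = FALSE])),
               nrow = length(keep), dimnames = list(NULL, subjects))
  hdr <- vcf_header("22",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">')
  write_vcf_body(path, hdr, vcf_fixed_cols(truth, keep), "GT", gt)
}

#' Export an imputation result as VCF 4.2 with DS and GP fields
#'
#' @param result an `imputation_result`.
#' @param truth the `phased_genotypes` the result refers to (for positions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imputation_vcf <- function(result, truth, path) {
  keep <- match(result$snp_ids, truth$snp_ids)
  if (anyNA(keep)) stop("result covers snp ids absent from the truth")
  fmt <- function(x) formatC(x, digits = 4, format = "g")
  cell <- paste0(fmt(t(result$dosage)), ":",
                 fmt(t(result$p0)), ",", fmt(t(result$p1)), ",",
                 fmt(t(result$p2)))
  geno <- matrix(cell, nrow = length(result$snp_ids),
                 dimnames = list(NULL, result$subjects))
  hdr <- vcf_header("22", c(
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated minor-allele dosage">',
    '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype posterior probabilities">'))
  write_vcf_body(path, hdr, vcf_fixed_cols(truth, keep), "DS:GP", geno)
}

#' Import an external imputation result from VCF
#'
#' Reads a VCF with `GP` and/or `DS` FORMAT fields (the output format of
#' common population- and family-based imputation tools). `GP` is used when
#' present (renormalized); otherwise `DS` is converted to genotype
#' probabilities via the dosage-to-posterior mapping. When a `dataset` (or
#' `phased_genotypes` truth) is supplied, allele polarization is harmonized
#' to the truth's minor allele: sites whose REF/ALT are swapped relative to
#' the export convention have dosages flipped `d -> 2 - d` and posterior
#' order reversed; any other allele mismatch is an error naming the site.
#'
#' @param vcf_path path to a VCF file.
#' @param dataset optional `study_dataset` or `phased_genotypes` used to
#'   harmonize alleles and order sites.
#' @param method_label label stored on the result.
#' @return an `imputation_result`.
#' @export
import_external_result <- function(vcf_path, dataset = NULL,
                                   method_label = "external") {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix  # always a matrix, also for single-variant files
  ids <- fix[, "ID"]
  fmt <- v@gt[, "FORMAT"]
  has_gp <- all(grepl("GP", fmt)); has_ds <- all(grepl("DS", fmt))
  if (!has_gp && !has_ds)
    stop("VCF '", vcf_path, "' carries neither GP nor DS FORMAT fields")
  flip <- rep(FALSE, nrow(fix))
  if (!is.null(dataset)) {
    truth <- if (inherits(dataset, "study_dataset")) dataset$truth else dataset
    keep <- match(ids, truth$snp_ids)
    if (anyNA(keep))
      stop("VCF site '", ids[is.na(keep)][1], "' not found in the truth")
    swapped <- fix[, "REF"] == "C" & fix[, "ALT"] == "A"
    ok <- (fix[, "REF"] == "A" & fix[, "ALT"] == "C") | swapped
    if (!all(ok))
      stop("allele mismatch at site '", ids[!ok][1], "': REF/ALT ",
           fix[!ok, "REF"][1], "/", fix[!ok, "ALT"][1])
    flip <- swapped
  }
  subjects <- colnames(v@gt)[-1L]
  n <- length(subjects); S <- nrow(fix)
  if (has_gp) {
    gp <- vcfR::extract.gt(v, element = "GP")
    parts <- lapply(1:3, function(k)
      t(matrix(as.numeric(vapply(strsplit(as.vector(gp), ","), `[`,
                                 character(1), k)),
               nrow = S, dimnames = list(ids, subjects))))
    tot <- parts[[1]] + parts[[2]] + parts[[3]]
    p0 <- parts[[1]] / tot; p1 <- parts[[2]] / tot; p2 <- parts[[3]] / tot
    if (any(flip)) {
      tmp <- p0[, flip]; p0[, flip] <- p2[, flip]; p2[, flip] <- tmp
    }
    new_imputation_result(p0, p1, p2, subjects, ids, method_label)
  } else {
    ds <- t(matrix(as.numeric(vcfR::extract.gt(v, element = "DS")),
                   nrow = S, dimnames = list(ids, subjects)))
    ds[, flip] <- 2 - ds[, flip]
    post <- dosage_to_posterior(ds)
    new_imputation_result(post$p0, post$p1, post$p2, subjects, ids,
                          method_label, dosage = ds)
  }
}
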