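#' Read and validate an experiment configuration
#'
#' The configuration is a YAML file (or an equivalent named list) driving
#' [run_pipeline()]: scenario preset and overrides, pedigree-set
#' parameters, replicate count, GWAS panel size, selection strategy and
#' fraction, imputer list, metric and association options, output
#' directory and a mandatory `base_seed`.
#'
#' @param config path to a YAML file, or a named list.
#' @return a validated `experiment_config` list with defaults filled in.
#' @export
read_experiment_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    scenario = "eur_like",
    scenario_overrides = list(),
    pedigrees = list(n = 2L, size_range = c(10L, 30L),
                     generations_range = c(3L, 5L),
                     sibship_range = c(1L, 11L)),
    n_replicates = 1L,
    n_panel = 500L,
    cm_per_mb = 1,
    selection = list(strategy = "random", fraction = 0.2),
    imputers = c("allele_frequency", "population_ld", "family_kinship",
                 "ped_pop"),
    metrics = list(n_buffer = 500L),
    association = list(enabled = FALSE, n_snps = 10L, n_traits = 2L,
                       models = c("H0", "Ha"),
                       alphas = c(0.05, 0.01, 0.001),
                       sigma_g2 = 1, sigma_e2 = 1, v_a = 0.01),
    output_dir = NULL,
    base_seed = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      miss <- setdiff(names(defaults[[nm]]), names(config[[nm]]))
      config[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  if (is.null(config$base_seed)) stop("config must set base_seed")
  known_strategies <- c("random", "max_unrelated", "generation_units",
                        "founder_coverage")
  if (!config$selection$strategy %in% known_strategies)
    stop("unknown selection strategy '", config$selection$strategy, "'")
  known_imputers <- c("allele_frequency", "population_ld", "family_kinship",
                      "ped_pop")
  bad <- setdiff(config$imputers, known_imputers)
  if (length(bad)) stop("unknown imputer(s): ", paste(bad, collapse = ", "))
  if ("ped_pop" %in% config$imputers &&
      !all(c("family_kinship", "population_ld") %in% config$imputers))
    stop("imputer 'ped_pop' needs both 'family_kinship' and 'population_ld'")
  structure(config, class = "experiment_config")
}

select_by_strategy <- function(strategy, peds, fraction, seed) {
  switch(strategy,
         random = select_random(peds, fraction, seed = seed),
         max_unrelated = select_max_unrelated(peds, fraction),
         generation_units = select_generation_units(peds, fraction),
         founder_coverage = select_founder_coverage(peds, fraction,
                                                    seed = seed),
         stop("unknown selection strategy '", strategy, "'"))
}

run_imputers <- function(dataset, imputers) {
  out <- list()
  for (im in setdiff(imputers, "ped_pop"))
    out[[im]] <- switch(im,
      allele_frequency = impute_allele_frequency(dataset),
      population_ld = impute_population_ld(dataset),
      family_kinship = impute_family_kinship(dataset))
  if ("ped_pop" %in% imputers)
    out$ped_pop <- combine_ped_pop(out$family_kinship, out$population_ld)
  out
}

#' Run the full simulation-imputation-evaluation pipeline
#'
#' Orchestrates, from one configuration: pedigree generation, replicate
#' simulation (founder pool, gene drop, GWAS-panel masking), reference
#' selection, the configured imputers, per-SNP accuracy scoring with MAF
#' binning, optional mixed-model association (type-I error and power on
#' true genotypes and on each imputer's dosages), and TSV/JSON reporting.
#' Every stage's seed derives deterministically from `base_seed`, so a
#' rerun with the same configuration reproduces all outputs.
#'
#' @param config an `experiment_config`, a YAML path, or a named list.
#' @return invisibly, a list with `peds`, `selection`, `accuracy`
#'   (per-SNP records across replicates), `bin_summary` (per imputer),
#'   `rates` (when association is enabled), and `manifest`. When
#'   `output_dir` is set, the tables, the manifest and the config are also
#'   written there, each output stamped with the config hash.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "experiment_config"))
    config <- read_experiment_config(config)
  stage <- "setup"
  on_fail <- function(e) stop("pipeline failed at stage '", stage, "': ",
                              conditionMessage(e), call. = FALSE)
  tryCatch({
    outdir <- config$output_dir
    if (!is.null(outdir) && !dir.exists(outdir))
      dir.create(outdir, recursive = TRUE)
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA)
    # hash the scientific configuration only, not where it is written
    hash_cfg <- unclass(config)
    hash_cfg$output_dir <- NULL
    hash_file <- tempfile()
    writeLines(jsonlite::toJSON(hash_cfg, auto_unbox = TRUE, digits = NA),
               hash_file)
    config_hash <- unname(tools::md5sum(hash_file)); unlink(hash_file)
    seeds <- derive_seeds(config$base_seed, 4L)
    scen <- do.call(scenario_config,
                    c(list(preset = config$scenario),
                      config$scenario_overrides))

    stage <- "pedigrees"
    pd <- config$pedigrees
    peds <- generate_pedigree_set(pd$n, size_range = pd$size_range,
                                  generations_range = pd$generations_range,
                                  sibship_range = pd$sibship_range,
                                  seed = seeds[1, "pool"],
                                  sizes = pd$sizes)
    stage <- "selection"
    sel <- select_by_strategy(config$selection$strategy, peds,
                              config$selection$fraction,
                              seed = seeds[1, "mask"])
    stage <- "simulate"
    datasets <- make_replicates(peds, scen, config$n_replicates,
                                base_seed = seeds[1, "drop"],
                                n_panel = config$n_panel,
                                cm_per_mb = config$cm_per_mb)
    stage <- "impute+score"
    accuracy <- list()
    imp_last <- NULL
    for (r in seq_along(datasets)) {
      ds <- apply_selection(datasets[[r]], sel)
      imps <- run_imputers(ds, config$imputers)
      imp_last <- imps
      datasets[[r]] <- ds
      for (im in names(imps)) {
        rec <- snp_accuracy(ds, imps[[im]],
                            n_buffer = config$metrics$n_buffer)
        rec$replicate <- r
        rec$method <- im
        accuracy[[paste(im, r)]] <- rec
      }
    }
    accuracy <- do.call(rbind, accuracy)
    rownames(accuracy) <- NULL
    bin_summary <- lapply(split(accuracy, accuracy$method), summarize_by_bin)

    rates <- NULL
    if (isTRUE(config$association$enabled)) {
      stage <- "association"
      as_cfg <- config$association
      ds <- datasets[[1]]
      subj <- study_subjects(ds)
      A <- relationship_matrix_set(peds)[subj, subj]
      Dtrue <- true_dosage(ds$truth)[subj, , drop = FALSE]
      scored <- setdiff(exclude_buffer(ds$truth$snp_ids,
                                       config$metrics$n_buffer),
                        ds$gwas_snp_ids)
      poly <- scored[apply(Dtrue[, scored, drop = FALSE], 2, stats::sd) > 0]
      set.seed(seeds[2, "pool"])
      test_snps <- sort(sample(poly, min(as_cfg$n_snps, length(poly))))
      results <- list()
      sources <- c(list(true = Dtrue),
                   lapply(imp_last, function(x) x$dosage[subj, , drop = FALSE]))
      mafs <- colMeans(Dtrue) / 2; mafs <- pmin(mafs, 1 - mafs)
      for (src in names(sources)) for (mod in as_cfg$models)
        results[[paste(src, mod)]] <-
          run_association(sources[[src]], A, snp_ids = test_snps,
                          model = mod, trait_dosages = Dtrue, mafs = mafs,
                          n_traits = as_cfg$n_traits,
                          sigma_g2 = as_cfg$sigma_g2,
                          sigma_e2 = as_cfg$sigma_e2, v_a = as_cfg$v_a,
                          seed = seeds[2, "drop"], genotype_source = src)
      rates <- estimate_rates(do.call(rbind, results),
                              alphas = as_cfg$alphas)
    }

    stage <- "report"
    manifest <- list(config = unclass(config), config_hash = config_hash,
                     seeds = as.data.frame(seeds),
                     n_subjects = sum(vapply(peds, function(p)
                       nrow(p$members), integer(1))),
                     n_reference = length(sel$selected_ids),
                     r_version = as.character(getRversion()))
    if (!is.null(outdir)) {
      writeLines(cfg_json, file.path(outdir, "config.json"))
      stamp_write <- function(tab, name) {
        path <- file.path(outdir, name)
        con <- file(path, "w")
        writeLines(paste0("# config_hash: ", config_hash), con)
        close(con)
        suppressWarnings(
          utils::write.table(tab, path, quote = FALSE, sep = "\t",
                             row.names = FALSE, append = TRUE))
        path
      }
      files <- c(stamp_write(accuracy, "accuracy_per_snp.tsv"),
                 unlist(lapply(names(bin_summary), function(im)
                   stamp_write(bin_summary[[im]],
                               paste0("bin_summary_", im, ".tsv")))))
      if (!is.null(rates))
        files <- c(files, stamp_write(rates, "rate_table.tsv"))
      manifest$files <- lapply(stats::setNames(files, basename(files)),
                               function(f) unname(tools::md5sum(f)))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(list(peds = peds, selection = sel, datasets = datasets,
                   accuracy = accuracy, bin_summary = bin_summary,
                   rates = rates, manifest = manifest))
  }, error = on_fail)
}

#' Export a dataset for external imputation tools
#'
#' Writes the file set an external phasing/imputation tool consumes:
#' a full-sites phased VCF for the reference subjects, a panel-sites VCF
#' for the study subjects, the pedigree structures as a LINKAGE/PED file,
#' the SNP map as TSV, and the GWAS panel id list.
#'
#' @param dataset a `study_dataset` with a selection applied.
#' @param selection the `selection_result` (used when the dataset has no
#'   reference subjects yet).
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
export_for_external_tools <- function(dataset, selection = NULL, outdir) {
  if (!is.null(selection)) dataset <- apply_selection(dataset, selection)
  if (length(dataset$reference_ids) == 0)
    stop("dataset has no reference subjects")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  truth <- dataset$truth
  paths <- c(reference_vcf = file.path(outdir, "reference_full.vcf"),
             study_vcf = file.path(outdir, "study_panel.vcf"),
             ped = file.path(outdir, "pedigrees.ped"),
             map = file.path(outdir, "snp_map.tsv"),
             panel = file.path(outdir, "gwas_panel.txt"))
  write_truth_vcf(truth, paths["reference_vcf"],
                  subjects = dataset$reference_ids)
  write_truth_vcf(truth, paths["study_vcf"],
                  subjects = study_subjects(dataset),
                  snp_ids = dataset$gwas_snp_ids)
  if (!is.null(dataset$peds)) write_ped(dataset$peds, paths["ped"])
  utils::write.table(data.frame(snp_id = truth$snp_ids,
                                bp = format(truth$positions_bp,
                                            scientific = FALSE, trim = TRUE)),
                     paths["map"], quote = FALSE, sep = "\t",
                     row.names = FALSE)
  writeLines(dataset$gwas_snp_ids, paths["panel"])
  invisible(paths)
}
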