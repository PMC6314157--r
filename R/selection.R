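#' Per-pedigree sequencing quotas
#'
#' Splits a global sequencing fraction into per-pedigree subject counts:
#' each pedigree gets `floor(fraction * size)` subjects, and the remainder
#' needed to reach the global total `round(fraction * N_total)` (round half
#' up) is distributed by largest fractional remainder, ties broken by
#' pedigree order. With 20 pedigrees totaling 1200 subjects and fraction
#' 0.2 this yields exactly 240 selected subjects.
#'
#' @param peds list of pedigrees.
#' @param fraction proportion in (0, 1).
#' @return named integer vector of per-pedigree quotas.
#' @export
selection_quotas <- function(peds, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  peds <- as_pedigree_list(peds)
  sizes <- vapply(peds, function(p) nrow(p$members), integer(1))
  raw <- fraction * sizes
  base <- floor(raw + 1e-9)
  total <- floor(fraction * sum(sizes) + 0.5)
  extra <- total - sum(base)
  if (extra > 0) {
    top <- order(-(raw - base), seq_along(raw))[seq_len(extra)]
    base[top] <- base[top] + 1
  }
  if (any(base == 0))
    warning("selection quota is 0 for pedigree(s) ",
            paste(names(peds)[base == 0], collapse = ", "))
  stats::setNames(as.integer(base), names(peds))
}

new_selection <- function(strategy, by_ped, fraction) {
  structure(list(strategy = strategy,
                 selected_ids = unlist(by_ped, use.names = FALSE),
                 by_ped = by_ped,
                 fraction = fraction),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result ('", x$strategy, "'): ", length(x$selected_ids),
      " subjects from ", length(x$by_ped), " pedigrees (fraction ",
      x$fraction, ")\n", sep = "")
  invisible(x)
}

#' Random selection of reference subjects
#'
#' Selects the per-pedigree quota (see [selection_quotas()]) uniformly at
#' random within each pedigree.
#'
#' @param peds list of pedigrees.
#' @param fraction proportion of subjects to sequence (the emulated study
#'   used 0.2).
#' @param seed integer seed.
#' @return a `selection_result`.
#' @export
select_random <- function(peds, fraction, seed = 1L) {
  peds <- as_pedigree_list(peds)
  q <- selection_quotas(peds, fraction)
  set.seed(seed)
  by_ped <- lapply(names(peds), function(nm) {
    ids <- peds[[nm]]$members$id
    sort(ids[sample.int(length(ids), q[nm])])
  })
  names(by_ped) <- names(peds)
  new_selection("random", by_ped, fraction)
}

#' Maximally unrelated selection (PRIMUS-style surrogate)
#'
#' Greedy selection of subjects whose pairwise relationship (twice the
#' kinship coefficient) does not exceed `kinship_threshold`, considering
#' candidates in order of increasing total relatedness (ties by subject
#' id). If fewer compatible subjects exist than the quota, the quota is
#' filled with the lowest-total-relatedness remaining subjects. This is a
#' transparent surrogate for tools that force a maximally unrelated set; it
#' is deterministic.
#'
#' @param peds list of pedigrees.
#' @param fraction proportion to sequence.
#' @param kinship_threshold maximum tolerated pairwise relationship
#'   (default 0: strictly unrelated).
#' @return a `selection_result`.
#' @export
select_max_unrelated <- function(peds, fraction, kinship_threshold = 0) {
  peds <- as_pedigree_list(peds)
  q <- selection_quotas(peds, fraction)
  by_ped <- lapply(names(peds), function(nm) {
    A <- relationship_matrix(peds[[nm]])
    ids <- rownames(A)
    total_rel <- rowSums(A) - diag(A)
    ord <- ids[order(total_rel, ids)]
    sel <- character(0)
    for (id in ord) {
      if (length(sel) >= q[nm]) break
      if (length(sel) == 0 || max(A[id, sel]) <= kinship_threshold)
        sel <- c(sel, id)
    }
    if (length(sel) < q[nm]) {
      rest <- setdiff(ord, sel)
      sel <- c(sel, rest[seq_len(q[nm] - length(sel))])
    }
    sort(sel)
  })
  names(by_ped) <- names(peds)
  new_selection("max_unrelated", by_ped, fraction)
}

# parent couples of a pedigree with reproduction generation and offspring count
pedigree_couples <- function(ped) {
  m <- ped$members
  gen <- subject_generations(ped)
  kids <- m[!is.na(m$father), ]
  if (nrow(kids) == 0)
    return(data.frame(father = character(0), mother = character(0),
                      gen = integer(0), n_offspring = integer(0)))
  key <- paste(kids$father, kids$mother, sep = "\r")
  tab <- table(key)
  fa <- sub("\r.*", "", names(tab)); mo <- sub(".*\r", "", names(tab))
  data.frame(father = fa, mother = mo,
             gen = pmax(gen[fa], gen[mo]),
             n_offspring = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Generation-unit selection (ExomePicks-style surrogate)
#'
#' Ranks parent couples from the oldest to the youngest generation, within
#' a generation by descending number of offspring, then by father id, and
#' selects whole couples until the per-pedigree quota is met (the last
#' couple may be truncated). If quotas remain after all couples, remaining
#' subjects are added oldest-generation first, ties by id. Deterministic.
#'
#' @inheritParams select_max_unrelated
#' @return a `selection_result`.
#' @export
select_generation_units <- function(peds, fraction) {
  peds <- as_pedigree_list(peds)
  q <- selection_quotas(peds, fraction)
  by_ped <- lapply(names(peds), function(nm) {
    ped <- peds[[nm]]
    cpl <- pedigree_couples(ped)
    cpl <- cpl[order(cpl$gen, -cpl$n_offspring, cpl$father), , drop = FALSE]
    ordered <- unique(as.vector(t(as.matrix(cpl[, c("father", "mother")]))))
    gen <- subject_generations(ped)
    rest <- setdiff(ped$members$id, ordered)
    ordered <- c(ordered, rest[order(gen[rest], rest)])
    sort(ordered[seq_len(q[nm])])
  })
  names(by_ped) <- names(peds)
  new_selection("generation_units", by_ped, fraction)
}

# Monte-Carlo drop of founder allele labels through one pedigree:
# returns for each subject two (n_drops-long) label vectors.
drop_founder_labels <- function(ped, n_drops) {
  m <- ped$members
  fnd <- founders(ped)
  lab <- matrix(seq_len(2L * length(fnd)), ncol = 2L, byrow = TRUE,
                dimnames = list(fnd, NULL))
  L1 <- L2 <- matrix(0L, nrow(m), n_drops, dimnames = list(m$id, NULL))
  L1[fnd, ] <- lab[, 1L]
  L2[fnd, ] <- lab[, 2L]
  for (id in pedigree_order(ped)) {
    i <- match(id, m$id)
    if (is.na(m$father[i])) next
    pick <- stats::runif(n_drops) < 0.5
    L1[id, ] <- ifelse(pick, L1[m$father[i], ], L2[m$father[i], ])
    pick <- stats::runif(n_drops) < 0.5
    L2[id, ] <- ifelse(pick, L1[m$mother[i], ], L2[m$mother[i], ])
  }
  list(L1 = L1, L2 = L2, n_labels = 2L * length(fnd))
}

#' Founder-genome-coverage selection (GIGI-Pick-style surrogate)
#'
#' Greedy forward selection maximizing the expected fraction of founder
#' genome copies observed in at least one selected subject, estimated by
#' Monte-Carlo gene drops of founder allele labels at a single unlinked
#' locus. The objective is monotone, so adding a subject never decreases
#' coverage. This is a simplified surrogate for inheritance-vector-based
#' selection tools; ties are broken by subject id and the result is
#' deterministic given the seed.
#'
#' @inheritParams select_max_unrelated
#' @param n_mc_drops number of Monte-Carlo label drops (>= 100).
#' @param seed integer seed.
#' @return a `selection_result`.
#' @export
select_founder_coverage <- function(peds, fraction, n_mc_drops = 1000L,
                                    seed = 1L) {
  stopifnot(n_mc_drops >= 100)
  peds <- as_pedigree_list(peds)
  q <- selection_quotas(peds, fraction)
  set.seed(seed)
  by_ped <- lapply(names(peds), function(nm) {
    ped <- peds[[nm]]
    dr <- drop_founder_labels(ped, n_mc_drops)
    ids <- ped$members$id
    covered <- matrix(FALSE, dr$n_labels, n_mc_drops)
    sel <- character(0)
    cand <- sort(ids)
    for (step in seq_len(q[nm])) {
      gain <- vapply(cand, function(id) {
        i1 <- cbind(dr$L1[id, ], seq_len(n_mc_drops))
        i2 <- cbind(dr$L2[id, ], seq_len(n_mc_drops))
        sum(!covered[i1]) + sum(!covered[i2] & !(dr$L1[id, ] == dr$L2[id, ]))
      }, numeric(1))
      best <- cand[which.max(gain)]  # first max = lexicographically smallest
      covered[cbind(dr$L1[best, ], seq_len(n_mc_drops))] <- TRUE
      covered[cbind(dr$L2[best, ], seq_len(n_mc_drops))] <- TRUE
      sel <- c(sel, best)
      cand <- setdiff(cand, best)
    }
    sort(sel)
  })
  names(by_ped) <- names(peds)
  new_selection("founder_coverage", by_ped, fraction)
}

#' Expected founder-genome coverage of a subject set
#'
#' Monte-Carlo estimate of the fraction of founder genome copies carried by
#' at least one subject in `subject_ids`, the objective maximized by
#' [select_founder_coverage()].
#'
#' @param ped a `pedigree`.
#' @param subject_ids subjects assumed sequenced.
#' @param n_mc_drops number of label drops.
#' @param seed integer seed.
#' @return scalar in [0, 1].
#' @export
founder_coverage <- function(ped, subject_ids, n_mc_drops = 1000L, seed = 1L) {
  set.seed(seed)
  dr <- drop_founder_labels(ped, n_mc_drops)
  if (length(subject_ids) == 0) return(0)
  per_drop <- vapply(seq_len(n_mc_drops), function(r) {
    length(unique(c(dr$L1[subject_ids, r], dr$L2[subject_ids, r])))
  }, numeric(1))
  mean(per_drop) / dr$n_labels
}

#' Attach a selection to a study dataset
#'
#' Records the selected subjects as the dataset's reference panel
#' (the subjects whose full sequence is observed).
#'
#' @param dataset a `study_dataset`.
#' @param selection a `selection_result`.
#' @return the updated `study_dataset`.
#' @export
apply_selection <- function(dataset, selection) {
  stopifnot(inherits(dataset, "study_dataset"),
            inherits(selection, "selection_result"))
  missing <- setdiff(selection$selected_ids, dataset$truth$subjects)
  if (length(missing) > 0)
    stop("selected subjects not in dataset: ",
         paste(utils::head(missing, 3), collapse = ", "))
  dataset$reference_ids <- selection$selected_ids
  dataset
}

#' Write a selection as id list and TSV
#'
#' `write_selection_ids` writes one subject id per line;
#' `write_selection_tsv` writes (pedigree_id, subject_id, strategy).
#' @param selection a `selection_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_ids <- function(selection, path) {
  writeLines(selection$selected_ids, path)
  invisible(path)
}

#' @rdname write_selection_ids
#' @export
write_selection_tsv <- function(selection, path) {
  tab <- do.call(rbind, lapply(names(selection$by_ped), function(nm)
    data.frame(pedigree_id = nm, subject_id = selection$by_ped[[nm]],
               strategy = selection$strategy, stringsAsFactors = FALSE)))
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
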