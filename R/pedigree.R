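#' Construct a pedigree object
#'
#' A pedigree is an ordered collection of subjects, each with either both
#' parents present in the same pedigree (a nonfounder) or neither (a founder).
#' The parent-child graph must be acyclic and subject ids unique.
#'
#' @param id character vector of subject ids.
#' @param father,mother character vectors of parent ids; `NA` (or `"0"`) marks
#'   a missing parent. A subject must have both parents or neither.
#' @param sex character vector, one of `"male"`, `"female"`, `"unknown"`.
#'   Parsed and stored but not used for transmission: the simulation model is
#'   autosomal with a single uniform genetic map.
#' @param ped_id scalar pedigree identifier.
#' @return An object of class `pedigree`: a list with elements `ped_id` and
#'   `members` (a data.frame with columns `id`, `father`, `mother`, `sex`).
#' @examples
#' trio <- pedigree(id = c("F", "M", "C"),
#'                  father = c(NA, NA, "F"),
#'                  mother = c(NA, NA, "M"),
#'                  sex = c("male", "female", "unknown"))
#' founders(trio)
#' pedigree_bits(trio)
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", ped_id = "ped1") {
  n <- length(id)
  miss <- function(x) is.na(x) | x == "0" | x == ""
  father <- rep_len(as.character(father), n)
  mother <- rep_len(as.character(mother), n)
  father[miss(father)] <- NA_character_
  mother[miss(mother)] <- NA_character_
  sex <- rep_len(as.character(sex), n)
  members <- data.frame(id = as.character(id), father = father,
                        mother = mother, sex = sex,
                        stringsAsFactors = FALSE)
  ped <- structure(list(ped_id = as.character(ped_id)[1], members = members),
                   class = "pedigree")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree invariants
#'
#' Checks that subject ids are unique, that every subject has both parents in
#' the pedigree or neither, that named parents exist, and that the
#' parent-child graph is acyclic.
#'
#' @param ped a `pedigree`.
#' @return `ped`, invisibly. Signals an error naming the offending subject on
#'   the first violated invariant.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  m <- ped$members
  if (anyDuplicated(m$id))
    stop("duplicated subject id '", m$id[duplicated(m$id)][1],
         "' in pedigree ", ped$ped_id)
  one_parent <- xor(is.na(m$father), is.na(m$mother))
  if (any(one_parent))
    stop("one parent missing for subject '", m$id[one_parent][1],
         "' in pedigree ", ped$ped_id,
         " (subjects must have both parents or neither)")
  for (col in c("father", "mother")) {
    bad <- !is.na(m[[col]]) & !(m[[col]] %in% m$id)
    if (any(bad))
      stop("unknown ", col, " '", m[[col]][bad][1], "' for subject '",
           m$id[bad][1], "' in pedigree ", ped$ped_id)
  }
  self <- !is.na(m$father) & (m$father == m$id | m$mother == m$id)
  if (any(self))
    stop("subject '", m$id[self][1], "' is its own parent in pedigree ",
         ped$ped_id)
  ord <- tryCatch(pedigree_order(ped), error = function(e)
    stop("pedigree ", ped$ped_id, " contains a cycle: ", conditionMessage(e)))
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree '", x$ped_id, "': ", nrow(x$members), " subjects (",
      length(founders(x)), " founders, ", length(nonfounders(x)),
      " nonfounders), ", pedigree_generations(x), " generations, ",
      pedigree_bits(x), " bits\n", sep = "")
  invisible(x)
}

#' Founder and nonfounder ids
#'
#' Founders have no parents in the pedigree; nonfounders have both.
#' @param ped a `pedigree`.
#' @return character vector of subject ids.
#' @export
founders <- function(ped) ped$members$id[is.na(ped$members$father)]

#' @rdname founders
#' @export
nonfounders <- function(ped) ped$members$id[!is.na(ped$members$father)]

# Topological order: every subject after both of its parents.
# Errors if no such order exists (cycle).
pedigree_order <- function(ped) {
  m <- ped$members
  placed <- is.na(m$father)
  ord <- m$id[placed]
  while (length(ord) < nrow(m)) {
    ready <- !placed & (m$father %in% ord) & (m$mother %in% ord)
    if (!any(ready)) stop("no parent-first ordering exists (subjects ",
                          paste(m$id[!placed], collapse = ", "), ")")
    ord <- c(ord, m$id[ready])
    placed <- placed | ready
  }
  ord
}

#' Generation number of each subject
#'
#' Founders are generation 1; a nonfounder is one generation below its
#' deepest parent.
#'
#' @param ped a `pedigree`.
#' @return named integer vector of generation numbers, in member order.
#' @export
subject_generations <- function(ped) {
  m <- ped$members
  gen <- stats::setNames(rep(NA_integer_, nrow(m)), m$id)
  for (id in pedigree_order(ped)) {
    i <- match(id, m$id)
    gen[id] <- if (is.na(m$father[i])) 1L
               else max(gen[m$father[i]], gen[m$mother[i]]) + 1L
  }
  gen[m$id]
}

#' @rdname subject_generations
#' @return `pedigree_generations`: the number of generations (depth).
#' @export
pedigree_generations <- function(ped) max(subject_generations(ped))

#' Lander-Green bit complexity of a pedigree
#'
#' Computes `2 * n - f`, where `n` is the number of nonfounders and `f` the
#' number of founders. This quantity governs the memory requirement of exact
#' multipoint pedigree-likelihood algorithms; a trio is 0 bits.
#'
#' @param ped a `pedigree`.
#' @return integer bit count.
#' @export
pedigree_bits <- function(ped) {
  2L * length(nonfounders(ped)) - length(founders(ped))
}

#' Read pedigrees from a 6-column LINKAGE/PED file
#'
#' The file is whitespace-delimited with columns family id, subject id,
#' father, mother, sex (1 = male, 2 = female, other = unknown) and phenotype.
#' `"0"` marks a missing parent. The phenotype column is ignored: traits live
#' in their own files.
#'
#' @param path file path.
#' @return a named list of validated `pedigree` objects, one per family id,
#'   member order preserved.
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed PED line ", which(nf < 6)[1], " in '", path,
         "': expected 6 whitespace-delimited columns, found ", nf[nf < 6][1])
  tab <- as.data.frame(do.call(rbind, lapply(fields, `[`, 1:6)),
                       stringsAsFactors = FALSE)
  names(tab) <- c("fam", "id", "father", "mother", "sex", "pheno")
  sex <- c("1" = "male", "2" = "female")[tab$sex]
  sex[is.na(sex)] <- "unknown"
  peds <- lapply(split(seq_len(nrow(tab)), factor(tab$fam, unique(tab$fam))),
                 function(i) pedigree(id = tab$id[i], father = tab$father[i],
                                      mother = tab$mother[i], sex = sex[i],
                                      ped_id = tab$fam[i][1]))
  peds
}

#' Write pedigrees to a 6-column LINKAGE/PED file
#'
#' @param peds a `pedigree` or list of pedigrees.
#' @param path output file path.
#' @return `path`, invisibly. The phenotype column is written as 0.
#' @export
write_ped <- function(peds, path) {
  peds <- as_pedigree_list(peds)
  rows <- lapply(peds, function(p) {
    m <- p$members
    data.frame(fam = p$ped_id, id = m$id,
               father = ifelse(is.na(m$father), "0", m$father),
               mother = ifelse(is.na(m$mother), "0", m$mother),
               sex = c(male = 1L, female = 2L)[m$sex],
               pheno = 0L, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$sex[is.na(tab$sex)] <- 0L
  utils::write.table(tab, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_pedigree_list <- function(peds) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  stopifnot(all(vapply(peds, inherits, logical(1), "pedigree")))
  if (is.null(names(peds)))
    names(peds) <- vapply(peds, `[[`, character(1), "ped_id")
  peds
}

#' Additive (numerator) relationship matrix of a pedigree
#'
#' Entries are twice the kinship coefficient between pairs of subjects,
#' computed by the standard tabular recursion in parent-first order:
#' `A[i,i] = 1 + A[father(i), mother(i)] / 2` and
#' `A[i,j] = (A[j, father(i)] + A[j, mother(i)]) / 2` for nonfounder `i`
#' processed after `j`. Founders are taken to be unrelated and non-inbred
#' (diagonal 1, mutual 0), matching a simulation in which founders draw
#' independent haplotypes.
#'
#' @param ped a `pedigree`.
#' @return symmetric matrix with subject ids as dimnames, in member order.
#' @export
relationship_matrix <- function(ped) {
  m <- ped$members
  ids <- m$id
  A <- matrix(0, nrow(m), nrow(m), dimnames = list(ids, ids))
  done <- character(0)
  for (id in pedigree_order(ped)) {
    i <- match(id, ids)
    fa <- m$father[i]; mo <- m$mother[i]
    if (is.na(fa)) {
      A[i, i] <- 1
    } else {
      A[i, i] <- 1 + A[fa, mo] / 2
      for (j in match(done, ids))
        A[i, j] <- A[j, i] <- (A[j, fa] + A[j, mo]) / 2
    }
    done <- c(done, id)
  }
  A
}

#' Block-diagonal relationship matrix for a set of pedigrees
#'
#' Subjects in different pedigrees are unrelated. Subject ids must be unique
#' across the whole set.
#'
#' @param peds list of `pedigree` objects.
#' @return symmetric block-diagonal matrix, subjects in pedigree order.
#' @export
relationship_matrix_set <- function(peds) {
  peds <- as_pedigree_list(peds)
  ids <- unlist(lapply(peds, function(p) p$members$id), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("subject ids must be unique across pedigrees; duplicated: '",
         ids[duplicated(ids)][1], "'")
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (p in peds) {
    Ap <- relationship_matrix(p)
    A[rownames(Ap), colnames(Ap)] <- Ap
  }
  A
}

#' Export a relationship matrix as TSV
#'
#' Writes the matrix with a header row and a leading column of subject ids.
#' @param A relationship matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relationship_tsv <- function(A, path) {
  tab <- data.frame(subject_id = rownames(A), A, check.names = FALSE)
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
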