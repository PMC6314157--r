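#' Generate random extended pedigrees
#'
#' Builds pedigrees top-down so that structural invariants hold by
#' construction: a founding couple starts the pedigree, a "spine" of
#' descendants guarantees the requested generation depth, and the pedigree
#' is then grown by adding children to existing couples or marrying founder
#' spouses into childless descendants until the target size is reached.
#' Every nonfounder therefore has both parents in the pedigree, and every
#' marry-in spouse is a founder.
#'
#' Defaults emulate the demography of the emulated study's 20 real extended
#' pedigrees: sizes 10-174, 3-9 generations, sibships of 1-11 with most
#' sibships small.
#'
#' @param n_pedigrees number of pedigrees.
#' @param size_range integer range of pedigree sizes (subjects).
#' @param generations_range integer range of generation depths.
#' @param sibship_range integer range of children per couple.
#' @param seed integer seed.
#' @param sizes optional integer vector of exact sizes (length
#'   `n_pedigrees`), overriding random draws from `size_range`.
#' @param ped_prefix prefix for pedigree and subject ids; subject ids are
#'   unique across the whole set.
#' @return list of validated `pedigree` objects.
#' @export
generate_pedigree_set <- function(n_pedigrees,
                                  size_range = c(10L, 174L),
                                  generations_range = c(3L, 9L),
                                  sibship_range = c(1L, 11L),
                                  seed = 1L,
                                  sizes = NULL,
                                  ped_prefix = "ped") {
  stopifnot(n_pedigrees >= 1, length(size_range) == 2, length(generations_range) == 2,
            length(sibship_range) == 2, sibship_range[1] >= 1,
            generations_range[1] >= 2)
  size_range <- as.integer(sort(size_range))
  generations_range <- as.integer(sort(generations_range))
  if (2L * generations_range[1] - 1L > size_range[2])
    stop("infeasible ranges: ", generations_range[1], " generations need at least ",
         2L * generations_range[1] - 1L, " subjects, but max size is ", size_range[2])
  if (!is.null(sizes)) {
    stopifnot(length(sizes) == n_pedigrees)
    sizes <- as.integer(sizes)
    if (any(sizes < 2L * generations_range[1] - 1L))
      stop("infeasible sizes for the requested generation range")
  }
  set.seed(seed)
  peds <- vector("list", n_pedigrees)
  for (k in seq_len(n_pedigrees)) {
    lo_N <- max(size_range[1], 2L * generations_range[1] - 1L)
    N <- if (is.null(sizes)) {
      lo_N + sample.int(size_range[2] - lo_N + 1L, 1L) - 1L
    } else sizes[k]
    gmax_feasible <- min(generations_range[2], (N + 1L) %/% 2L)
    G <- generations_range[1] +
      sample.int(gmax_feasible - generations_range[1] + 1L, 1L) - 1L
    peds[[k]] <- build_pedigree(N, G, sibship_range,
                                ped_id = sprintf("%s%02d", ped_prefix, k))
  }
  names(peds) <- vapply(peds, `[[`, character(1), "ped_id")
  peds
}

# Grow one pedigree of exactly N subjects and depth exactly G.
build_pedigree <- function(N, G, sibship_range, ped_id) {
  sib_max <- sibship_range[2]
  nxt <- 0L
  new_id <- function() { nxt <<- nxt + 1L; sprintf("%s_i%03d", ped_id, nxt) }
  id <- fa <- mo <- sex <- character(0)
  add <- function(i, f, m, s) {
    id <<- c(id, i); fa <<- c(fa, f); mo <<- c(mo, m); sex <<- c(sex, s)
  }
  # couples: father id, mother id, descent depth of the deeper partner,
  # current number of children
  cpl <- data.frame(fa = character(0), mo = character(0),
                    gen = integer(0), kids = integer(0),
                    stringsAsFactors = FALSE)
  f1 <- new_id(); m1 <- new_id()
  add(f1, NA, NA, "male"); add(m1, NA, NA, "female")
  cpl[1L, ] <- list(f1, m1, 1L, 0L)
  # spine guaranteeing depth G
  prev <- 1L
  for (g in 2L:G) {
    child <- new_id()
    csex <- sample(c("male", "female"), 1L)
    add(child, cpl$fa[prev], cpl$mo[prev], csex)
    cpl$kids[prev] <- cpl$kids[prev] + 1L
    if (g < G) {
      sp <- new_id()
      add(sp, NA, NA, if (csex == "male") "female" else "male")
      cpl[nrow(cpl) + 1L, ] <- list(if (csex == "male") child else sp,
                                    if (csex == "male") sp else child,
                                    g, 0L)
      prev <- nrow(cpl)
    }
  }
  # childless nonfounders available for marry-in
  leaves <- function() {
    parents <- c(cpl$fa, cpl$mo)
    cand <- setdiff(id[!is.na(fa)], parents)
    gens <- descent_depth(id, fa, mo)
    cand[gens[match(cand, id)] < G]
  }
  # growth moves: +1 = child to an open couple; +2 = founder spouse onto a
  # childless descendant plus their first child (so no couple stays
  # childless and bits = 2n - f stays nonnegative)
  while (length(id) < N) {
    need <- N - length(id)
    open <- which(cpl$kids < sib_max & cpl$gen < G)
    lv <- leaves()
    grow_couple <- need >= 2L && length(lv) > 0L &&
      (length(open) == 0L || stats::runif(1) < 0.35)
    if (grow_couple) {
      child <- sample(lv, 1L)
      csex <- sex[match(child, id)]
      sp <- new_id()
      add(sp, NA, NA, if (csex == "male") "female" else "male")
      g <- descent_depth(id, fa, mo)[match(child, id)]
      i <- nrow(cpl) + 1L
      cpl[i, ] <- list(if (csex == "male") child else sp,
                       if (csex == "male") sp else child, g, 1L)
      add(new_id(), cpl$fa[i], cpl$mo[i], sample(c("male", "female"), 1L))
    } else if (length(open) > 0L) {
      i <- if (length(open) == 1L) open else sample(open, 1L)
      add(new_id(), cpl$fa[i], cpl$mo[i], sample(c("male", "female"), 1L))
      cpl$kids[i] <- cpl$kids[i] + 1L
    } else {
      stop("cannot grow pedigree ", ped_id, " to size ", N,
           " under sibship limit ", sib_max)
    }
  }
  pedigree(id = id, father = fa, mother = mo, sex = sex, ped_id = ped_id)
}

# depth along descent lines (founders 1), on raw vectors for speed
descent_depth <- function(id, fa, mo) {
  g <- stats::setNames(ifelse(is.na(fa), 1L, NA_integer_), id)
  while (anyNA(g)) {
    ready <- is.na(g) & !is.na(g[fa]) & !is.na(g[mo])
    if (!any(ready)) stop("unreachable subjects in pedigree")
    g[ready] <- pmax(g[fa[ready]], g[mo[ready]]) + 1L
  }
  unname(g[id])
}
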