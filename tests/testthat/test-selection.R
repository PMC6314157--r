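test_that("quotas reconcile per-pedigree rounding with the global total", {
  peds <- generate_pedigree_set(6, generations_range = c(3, 4),
                                sizes = c(11, 13, 17, 19, 23, 12), seed = 2)
  q <- selection_quotas(peds, 0.2)
  expect_equal(sum(q), round(0.2 * 95))
  expect_true(all(q >= floor(0.2 * c(11, 13, 17, 19, 23, 12))))
  expect_equal(sum(selection_quotas(list(trio_ped()), 0.5)), 2)  # round(1.5)
  expect_warning(selection_quotas(list(trio_ped(), nuclear_ped(8)), 0.1),
                 "quota is 0")
})

test_that("random selection is deterministic and meets the quotas", {
  peds <- generate_pedigree_set(3, size_range = c(10, 20),
                                generations_range = c(3, 4), seed = 5)
  s1 <- select_random(peds, 0.2, seed = 9)
  s2 <- select_random(peds, 0.2, seed = 9)
  expect_identical(s1, s2)
  q <- selection_quotas(peds, 0.2)
  expect_equal(lengths(s1$by_ped), q, ignore_attr = TRUE)
  expect_true(all(unlist(Map(`%in%`, s1$by_ped,
                             lapply(peds, function(p) p$members$id)))))
})

test_that("max-unrelated picks founders in a trio (exhaustive-search oracle)", {
  ped <- trio_ped()
  A <- relationship_matrix(ped)
  ids <- rownames(A)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  best <- pairs[vapply(pairs, function(p) A[p[1], p[2]] == 0, logical(1))]
  expect_length(best, 1)  # the founder couple is the only unrelated pair
  sel <- select_max_unrelated(list(ped), 0.67)
  expect_setequal(sel$selected_ids, best[[1]])
})

test_that("max-unrelated finds a compatible set whenever one exists", {
  for (seed in 1:4) {
    ped <- generate_pedigree_set(1, size_range = c(8, 12),
                                 generations_range = c(3, 4),
                                 seed = seed)[[1]]
    A <- relationship_matrix(ped)
    q <- selection_quotas(list(ped), 0.25)[[1]]
    sel <- select_max_unrelated(list(ped), 0.25)$selected_ids
    # brute force: does any quota-sized subset have all pairs unrelated?
    sets <- utils::combn(rownames(A), q, simplify = FALSE)
    feasible <- any(vapply(sets, function(s)
      max(A[s, s] - diag(diag(A[s, s]))) <= 0, logical(1)))
    if (feasible)
      expect_lte(max(A[sel, sel] - diag(diag(A[sel, sel]))), 0)
    expect_length(sel, q)
  }
})

test_that("generation units go oldest-first, larger sibships first", {
  # gf/gm (gen 1) -> s1 couple with 3 kids, s2 couple with 1 kid
  ped <- pedigree(
    id = c("gf", "gm", "s1", "s2", "w1", "w2", "a1", "a2", "a3", "b1"),
    father = c(NA, NA, "gf", "gf", NA, NA, "s1", "s1", "s1", "s2"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "w1", "w1", "w1", "w2"),
    sex = c("male", "female", "male", "male", "female", "female",
            "unknown", "unknown", "unknown", "unknown"),
    ped_id = "units")
  sel2 <- select_generation_units(list(ped), 0.2)   # quota 2
  expect_setequal(sel2$selected_ids, c("gf", "gm"))
  sel4 <- select_generation_units(list(ped), 0.4)   # quota 4
  expect_setequal(sel4$selected_ids, c("gf", "gm", "s1", "w1"))
  all_sel <- select_generation_units(list(ped), 0.99)
  expect_setequal(all_sel$selected_ids, ped$members$id)
})

test_that("founder-coverage selection recovers the parents of a sibship", {
  ped <- nuclear_ped(4)
  sel <- select_founder_coverage(list(ped), 0.34, seed = 3)  # quota 2
  expect_setequal(sel$selected_ids, c("fa", "mo"))
  expect_equal(founder_coverage(ped, c("fa", "mo")), 1)
  expect_equal(founder_coverage(ped, character(0)), 0)
})

test_that("founder coverage is a monotone set function", {
  ped <- generate_pedigree_set(1, size_range = c(10, 12),
                               generations_range = c(3, 4), seed = 6)[[1]]
  ids <- ped$members$id
  set.seed(1)
  for (i in 1:5) {
    base <- sample(ids, 3)
    extra <- sample(setdiff(ids, base), 1)
    expect_gte(founder_coverage(ped, c(base, extra), seed = 42),
               founder_coverage(ped, base, seed = 42))
  }
})

test_that("all strategies select identical per-pedigree counts", {
  peds <- generate_pedigree_set(3, size_range = c(10, 22),
                                generations_range = c(3, 4), seed = 11)
  sels <- list(select_random(peds, 0.2, seed = 1),
               select_max_unrelated(peds, 0.2),
               select_generation_units(peds, 0.2),
               select_founder_coverage(peds, 0.2, n_mc_drops = 200, seed = 1))
  counts <- lapply(sels, function(s) lengths(s$by_ped))
  for (i in 2:4) expect_identical(counts[[i]], counts[[1]])
})

test_that("selections export as id list and TSV", {
  peds <- list(trio_ped())
  sel <- select_random(peds, 0.67, seed = 1)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_selection_ids(sel, f1)
  expect_identical(readLines(f1), sel$selected_ids)
  write_selection_tsv(sel, f2)
  tab <- utils::read.delim(f2)
  expect_identical(tab$subject_id, sel$selected_ids)
  expect_true(all(tab$strategy == "random"))
})
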