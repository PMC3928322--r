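mk_coll <- function(sets) {
  goforge:::new_geneset_collection(
    sets, setNames(names(sets), names(sets)), "biological_process"
  )
}

test_that("identical collections have no unique sets", {
  coll <- mk_coll(list(
    "GO:0000001" = sprintf("G%02d", 1:10),
    "GO:0000002" = sprintf("G%02d", 5:20)
  ))
  cmp <- classify_sets(coll, coll, sprintf("G%02d", 1:30))
  expect_equal(unique(cmp$status), "common")
  expect_equal(nrow(cmp), 2L)
})

test_that("sets crossing the size window become unique to one collection", {
  u <- sprintf("G%03d", 1:200)
  # augmentation lifts a 6-gene set to 7 -> unique to A
  small_b <- mk_coll(list("GO:0000001" = u[1:6]))
  small_a <- mk_coll(list("GO:0000001" = u[1:7]))
  cmp <- classify_sets(small_a, small_b, u)
  expect_equal(cmp$status, "unique_to_a")
  expect_equal(cmp$size_a, 7L)
  expect_equal(cmp$size_b, 6L)

  # growth past the maximum disqualifies -> unique to B
  big_b <- mk_coll(list("GO:0000002" = u[1:150]))
  big_a <- mk_coll(list("GO:0000002" = u[1:151]))
  cmp2 <- classify_sets(big_a, big_b, u)
  expect_equal(cmp2$status, "unique_to_b")

  # failing bounds in both -> not reported
  tiny <- mk_coll(list("GO:0000003" = u[1:3]))
  expect_equal(nrow(classify_sets(tiny, tiny, u)), 0L)

  # a term absent from one collection has effective size 0 there
  only_a <- mk_coll(list("GO:0000004" = u[1:10]))
  none <- mk_coll(list())
  cmp3 <- classify_sets(only_a, none, u)
  expect_equal(cmp3$status, "unique_to_a")
  expect_equal(cmp3$size_b, 0L)
})

test_that("classification is stable under relabeling A and B", {
  withr::with_seed(81, {
    u <- sprintf("G%03d", 1:120)
    sets_a <- lapply(setNames(1:20, sprintf("GO:%07d", 1:20)), function(i) sample(u, sample(3:40, 1)))
    sets_b <- lapply(setNames(1:20, sprintf("GO:%07d", 1:20)), function(i) sample(u, sample(3:40, 1)))
    ab <- classify_sets(mk_coll(sets_a), mk_coll(sets_b), u)
    ba <- classify_sets(mk_coll(sets_b), mk_coll(sets_a), u)
    swap <- c(common = "common", unique_to_a = "unique_to_b", unique_to_b = "unique_to_a")
    expect_equal(
      dplyr::arrange(tibble::tibble(term_id = ab$term_id, status = unname(swap[ab$status])), term_id),
      dplyr::arrange(tibble::tibble(term_id = ba$term_id, status = ba$status), term_id)
    )
    # partitions are disjoint by construction: one status per term
    expect_equal(anyDuplicated(ab$term_id), 0L)
  })
})

test_that("tallies use strict inequality and half-up percentage rounding", {
  expect_equal(significance_tally(14, 406)$percent, 3.45)
  expect_equal(significance_tally(0, 64)$percent, 0)
  expect_equal(significance_tally(40, 47, digits = 1)$percent, 85.1)
  expect_true(is.na(significance_tally(0, 0)$percent))

  res <- tibble::tibble(p_value = c(0.049, 0.05, 0.051))
  tl <- tally_significance(res, alpha = 0.05)
  expect_equal(tl$significant, 1L) # p == alpha does not count
  expect_equal(tl$total, 3L)

  # order invariance
  shuffled <- res[c(3, 1, 2), ]
  expect_equal(tally_significance(shuffled, 0.05), tl)
})

test_that("round_half_up resolves ties away from zero at any precision", {
  expect_equal(round_half_up(3.125, 2), 3.13)
  expect_equal(round_half_up(31.25, 1), 31.3)
  expect_equal(round_half_up(68.75, 1), 68.8)
  expect_equal(round_half_up(-3.125, 2), -3.13)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("one-sided Fisher matches hypergeometric enumeration", {
  expect_equal(fisher_one_sided(0, 10, 0, 10, "a_greater"), 1)
  expect_equal(fisher_one_sided(1, 2, 1, 2, "a_greater"), 5 / 6)
  expect_error(fisher_one_sided(0, 0, 1, 5), "zero-total")
  expect_error(fisher_one_sided(3, 2, 1, 5))

  withr::with_seed(82, {
    for (i in 1:40) {
      total_a <- sample(1:60, 1)
      total_b <- sample(1:60, 1)
      sig_a <- sample(0:total_a, 1)
      sig_b <- sample(0:total_b, 1)
      dir <- sample(c("a_greater", "b_greater"), 1)
      expect_equal(
        fisher_one_sided(sig_a, total_a, sig_b, total_b, dir),
        enum_fisher(sig_a, total_a, sig_b, total_b, dir),
        tolerance = 1e-9
      )
    }
  })
})

test_that("newly significant/insignificant accounting follows the absence rule", {
  res <- function(terms, ps) tibble::tibble(term_id = terms, p_value = ps)
  a <- res(c("t1", "t2", "t3", "t4", "t5"), c(0.01, 0.02, 0.03, 0.5, 0.9))
  b <- res(c("t1", "t2", "t3", "t4", "t6"), c(0.5, 0.6, 0.7, 0.01, 0.02))
  out <- newly_significant(a, b, 0.05)
  expect_setequal(out$newly_significant, c("t1", "t2", "t3"))
  expect_setequal(out$newly_insignificant, c("t4", "t6"))
  expect_equal(length(intersect(out$newly_significant, out$newly_insignificant)), 0L)

  same <- newly_significant(a, a, 0.05)
  expect_equal(same$newly_significant, character())
  expect_equal(same$newly_insignificant, character())

  # a term unique to A with p < alpha is newly significant
  extra <- res("t9", 0.001)
  out2 <- newly_significant(dplyr::bind_rows(a, extra), b, 0.05)
  expect_true("t9" %in% out2$newly_significant)
})

test_that("the assembled report equals an independently scripted recomputation", {
  fx <- withr::with_seed(83, {
    u <- sprintf("G%03d", 1:150)
    sets_a <- lapply(setNames(1:30, sprintf("GO:%07d", 1:30)), function(i) sample(u, sample(4:30, 1)))
    sets_b <- lapply(sets_a, function(g) g[-seq_len(min(3, length(g) - 1))])
    res_a <- tibble::tibble(
      term_id = names(sets_a), p_value = runif(30)
    )
    res_b <- tibble::tibble(
      term_id = names(sets_b), p_value = runif(30)
    )
    list(u = u, ca = mk_coll(sets_a), cb = mk_coll(sets_b), ra = res_a, rb = res_b)
  })
  cmp <- classify_sets(fx$ca, fx$cb, fx$u, min_size = 7, max_size = 20)
  rep <- compare_collections(cmp, fx$ra, fx$rb, alpha = 0.2)

  # recompute everything with plain base R over the raw pieces
  eff <- function(sets, t) length(intersect(toupper(sets[[t]]), fx$u))
  terms <- union(names(fx$ca$sets), names(fx$cb$sets))
  in_a <- vapply(terms, function(t) {
    s <- eff(fx$ca$sets, t); s >= 7 && s <= 20
  }, logical(1))
  in_b <- vapply(terms, function(t) {
    s <- eff(fx$cb$sets, t); s >= 7 && s <= 20
  }, logical(1))
  ua <- terms[in_a & !in_b]
  ub <- terms[!in_a & in_b]
  expect_setequal(rep$comparison$term_id[rep$comparison$status == "unique_to_a"], ua)
  expect_setequal(rep$comparison$term_id[rep$comparison$status == "unique_to_b"], ub)

  pa <- fx$ra$p_value[match(ua, fx$ra$term_id)]
  pb <- fx$rb$p_value[match(ub, fx$rb$term_id)]
  expect_equal(rep$tally_a$significant, sum(pa < 0.2))
  expect_equal(rep$tally_b$significant, sum(pb < 0.2))
  expect_equal(
    rep$fisher_greater_a,
    enum_fisher(sum(pa < 0.2), length(pa), sum(pb < 0.2), length(pb), "a_greater"),
    tolerance = 1e-9
  )
  sig_a <- fx$ra$term_id[fx$ra$p_value < 0.2]
  sig_b <- fx$rb$term_id[fx$rb$p_value < 0.2]
  expect_setequal(rep$newly_significant, setdiff(sig_a, sig_b))
  expect_setequal(rep$newly_insignificant, setdiff(sig_b, sig_a))

  # tidy/glance expose the same numbers
  td <- tidy(rep)
  expect_equal(td$value[td$metric == "n_newly_significant"], length(setdiff(sig_a, sig_b)))
  expect_equal(glance(rep)$fisher_greater_a, rep$fisher_greater_a)
})

test_that("an empty comparison yields an empty report with undefined percents", {
  empty <- mk_coll(list())
  cmp <- classify_sets(empty, empty, character())
  rep <- compare_collections(cmp, tibble::tibble(term_id = character(), p_value = double()),
    tibble::tibble(term_id = character(), p_value = double())
  )
  expect_equal(nrow(rep$comparison), 0L)
  expect_true(is.na(rep$tally_a$percent))
  expect_true(is.na(rep$fisher_greater_a))
})
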