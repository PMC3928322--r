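test_that("signal-to-noise matches direct formula evaluation on a tiny fixture", {
  mat <- rbind(
    up = c(1, 2, 5, 6),
    flat = c(3, 3, 3, 3)
  )
  ds <- expression_dataset(mat, c(0, 0, 1, 1))
  rl <- rank_by_signal_to_noise(ds)

  s2n <- function(x0, x1) {
    m0 <- mean(x0); m1 <- mean(x1)
    s0 <- max(sd(x0), 0.2 * abs(m0), 0.2)
    s1 <- max(sd(x1), 0.2 * abs(m1), 0.2)
    (m1 - m0) / (s1 + s0)
  }
  expect_equal(rl$score[rl$gene == "UP"], s2n(c(1, 2), c(5, 6)))
  expect_equal(rl$score[rl$gene == "FLAT"], 0) # equal class means
  expect_equal(rl$gene, c("UP", "FLAT")) # sorted descending
})

test_that("ranking is invariant to permuting samples within classes", {
  withr::with_seed(61, {
    mat <- matrix(rnorm(200), nrow = 20,
      dimnames = list(sprintf("g%02d", 1:20), NULL)
    )
    labels <- rep(c(0, 1), each = 5)
    rl1 <- rank_by_signal_to_noise(expression_dataset(mat, labels))
    perm <- c(sample(1:5), sample(6:10))
    rl2 <- rank_by_signal_to_noise(expression_dataset(mat[, perm], labels[perm]))
    expect_equal(rl1, rl2)
  })
})

test_that("a class with fewer than 2 samples is an error", {
  mat <- matrix(1:6, nrow = 2, dimnames = list(c("a", "b"), NULL))
  expect_error(
    rank_by_signal_to_noise(expression_dataset(mat, c(0, 1, 1))),
    "at least 2 samples"
  )
})

test_that("duplicate symbols collapse to the row with the largest mean", {
  mat <- rbind(c(1, 1), c(10, 10), c(5, 5))
  rownames(mat) <- c("dup", "dup", "other")
  ds <- expression_dataset(mat, c(0, 1))
  expect_equal(unname(ds$matrix["DUP", ]), c(10, 10))
})

test_that("the log-max-p statistic evaluates and sorts as specified", {
  genes <- c(both = 1, a_only = 1, none = 1)
  p_a <- c(both = 0.001, a_only = 0.002, none = 1)
  p_b <- c(both = 0.01, a_only = 0.9, none = 1)
  rl <- preranked_statistic(p_a, p_b)
  expect_equal(rl$score[rl$gene == "BOTH"], log10(0.01)) # -2
  expect_equal(rl$score[rl$gene == "NONE"], 0)
  # most extreme negative scores last
  expect_equal(rl$gene[nrow(rl)], "BOTH")

  expect_error(preranked_statistic(c(g = 0), c(g = 0.5)), "0, 1")
  expect_error(preranked_statistic(c(g = 0.5), c(h = 0.5)), "same genes")
})

test_that("log-max-p ranking order is invariant to the log base", {
  withr::with_seed(62, {
    genes <- sprintf("g%02d", 1:30)
    p_a <- setNames(runif(30, 1e-6, 1), genes)
    p_b <- setNames(runif(30, 1e-6, 1), genes)
    rl10 <- preranked_statistic(p_a, p_b)
    natural <- sort(log(pmax(p_a, p_b)), decreasing = TRUE)
    expect_equal(rl10$gene, toupper(names(natural)))
  })
})

test_that("enrichment score equals the brute-force running sum", {
  # degenerate cases pinned analytically
  rl <- goforge:::new_ranked_list(sprintf("g%02d", 1:10), 10:1)
  expect_equal(enrichment_score(rl, "g01", weight = 0), 1)
  expect_equal(enrichment_score(rl, sprintf("g%02d", 1:10), weight = 0), 1)

  withr::with_seed(63, {
    for (i in 1:100) {
      n <- 10
      scores <- sort(round(rnorm(n), 2), decreasing = TRUE)
      k <- sample(1:9, 1)
      hit_idx <- sort(sample(n, k))
      hit <- seq_len(n) %in% hit_idx
      w <- sample(c(0, 0.5, 1, 2), 1)
      rl <- goforge:::new_ranked_list(sprintf("g%02d", 1:n), scores)
      set_genes <- rl$gene[hit_idx]
      expect_equal(enrichment_score(rl, set_genes, weight = w), brute_es(rl$score, hit, w))
    }
  })
  expect_error(enrichment_score(rl, "absent"), "no genes")
})

test_that("enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(64, {
    for (i in 1:20) {
      n <- 50
      scores <- sort(rnorm(n), decreasing = TRUE)
      idx <- sort(sample(n, 8))
      rl <- goforge:::new_ranked_list(sprintf("g%02d", 1:n), scores)
      ours <- enrichment_score(rl, rl$gene[idx], weight = 1)
      theirs <- fgsea::calcGseaStat(setNames(scores, rl$gene), idx, gseaParam = 1)
      expect_equal(ours, theirs, tolerance = 1e-8)
    }
  })
})

test_that("ES stays in [-1, 1] and negation reverses it at weight 0", {
  withr::with_seed(65, {
    for (i in 1:30) {
      n <- 40
      scores <- sort(rnorm(n), decreasing = TRUE)
      idx <- sort(sample(n, 6))
      rl <- goforge:::new_ranked_list(sprintf("g%02d", 1:n), scores)
      es <- enrichment_score(rl, rl$gene[idx], weight = 0)
      expect_gte(es, -1)
      expect_lte(es, 1)
      flipped <- goforge:::new_ranked_list(rl$gene[n:1], rev(-rl$score))
      es_flip <- enrichment_score(flipped, rl$gene[idx], weight = 0)
      # reversing the negated list mirrors the running sum, so |ES| is
      # preserved exactly; the sign flips unless the positive and negative
      # extrema tie in magnitude (possible on the weight-0 rational grid),
      # in which case each direction reports its first-reached extremum
      expect_equal(abs(es_flip), abs(es), tolerance = 1e-12)
      hit <- seq_len(n) %in% idx
      run <- cumsum(ifelse(hit, 1 / length(idx), -1 / (n - length(idx))))
      tied <- abs(max(run) + min(run)) < 1e-9
      if (!tied) {
        expect_equal(es_flip, -es, tolerance = 1e-12)
      }
    }
  })
})

make_null_run <- function(n_genes = 120, n_sets = 15, seed = 71) {
  withr::with_seed(seed, {
    mat <- matrix(rnorm(n_genes * 12), nrow = n_genes,
      dimnames = list(sprintf("g%03d", 1:n_genes), NULL)
    )
    sets <- lapply(setNames(1:n_sets, sprintf("GO:%07d", 1:n_sets)), function(i) {
      sample(rownames(mat), sample(8:20, 1))
    })
    coll <- goforge:::new_geneset_collection(
      sets, setNames(sprintf("set %d", 1:n_sets), names(sets)), "biological_process"
    )
    list(ds = expression_dataset(mat, rep(c(0, 1), each = 6)), coll = coll)
  })
}

test_that("run_gsea is deterministic and independent of set iteration order", {
  fx <- make_null_run()
  r1 <- run_gsea(fx$coll, fx$ds, mode = "phenotype", n_permutations = 50, seed = 9)
  r2 <- run_gsea(fx$coll, fx$ds, mode = "phenotype", n_permutations = 50, seed = 9)
  expect_identical(r1, r2)

  perm <- withr::with_seed(2, sample(length(fx$coll$sets)))
  shuffled <- goforge:::new_geneset_collection(
    fx$coll$sets[perm], fx$coll$names[perm], "biological_process"
  )
  r3 <- run_gsea(shuffled, fx$ds, mode = "phenotype", n_permutations = 50, seed = 9)
  expect_identical(
    dplyr::arrange(tibble::as_tibble(r1), term_id),
    dplyr::arrange(tibble::as_tibble(r3), term_id)
  )

  # gene mode too
  rl <- rank_by_signal_to_noise(fx$ds)
  g1 <- run_gsea(fx$coll, rl, mode = "gene", n_permutations = 50, seed = 9)
  g3 <- run_gsea(shuffled, rl, mode = "gene", n_permutations = 50, seed = 9)
  expect_identical(
    dplyr::arrange(tibble::as_tibble(g1), term_id),
    dplyr::arrange(tibble::as_tibble(g3), term_id)
  )
})

test_that("with a single permutation all p-values are 0.5 or 1", {
  fx <- make_null_run(seed = 72)
  res <- run_gsea(fx$coll, fx$ds, mode = "phenotype", n_permutations = 1, seed = 3)
  expect_true(all(res$p_value %in% c(0.5, 1)))
  expect_true(all(res$es >= -1 & res$es <= 1))
  expect_error(run_gsea(fx$coll, fx$ds, n_permutations = 0), "n_permutations")
})

test_that("a planted up-shifted set attains the minimum p-value", {
  sim <- simulate_ontology(n_terms = 40, seed = 73)
  recs <- random_records(150,
    seed = 74, symbols = sprintf("gene%03d", 1:80),
    terms = sim$onto$terms$term_id
  )
  coll <- build_collection(recs, sim$onto, quiet = TRUE)
  sizes <- lengths(coll$sets)
  planted <- names(coll$sets)[which(sizes >= 10 & sizes <= 30)[1]]
  expr <- simulate_expression(coll,
    planted_terms = planted, effect_size = 1,
    n_background = 50, seed = 75
  )
  res <- run_gsea(coll, expr$dataset,
    mode = "phenotype",
    n_permutations = 200, seed = 76
  )
  expect_equal(
    res$p_value[res$term_id == planted],
    min(res$p_value)
  )
  expect_gt(res$es[res$term_id == planted], 0)
})
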