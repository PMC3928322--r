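# Self-contained GSEA-style enrichment: signal-to-noise ranking, the
# log-max-p pre-ranked statistic, the weighted running-sum enrichment score,
# and phenotype- or gene-permutation nulls.

#' Construct a two-class expression dataset
#'
#' Wraps a genes-by-samples matrix with per-sample class labels. Duplicate
#' gene symbols are collapsed by keeping, for each symbol, the row with the
#' largest mean expression.
#'
#' @param matrix numeric matrix, genes in rows (rownames are symbols),
#'   samples in columns.
#' @param labels per-sample class in `{0, 1}` (or a two-level factor).
#' @return an `expression_dataset` (list with `genes`, `matrix`, `labels`).
#' @export
expression_dataset <- function(matrix, labels) {
  if (is.null(rownames(matrix))) {
    abort("matrix must have gene symbols as rownames")
  }
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (length(labels) != ncol(matrix) || !all(labels %in% c(0L, 1L))) {
    abort("labels must be one 0/1 value per sample column")
  }
  genes <- .norm_symbol(rownames(matrix))
  if (anyDuplicated(genes)) {
    means <- rowMeans(matrix)
    keep <- tapply(seq_along(genes), genes, function(ix) ix[which.max(means[ix])])
    matrix <- matrix[as.integer(keep), , drop = FALSE]
    genes <- genes[as.integer(keep)]
  }
  rownames(matrix) <- genes
  structure(
    list(genes = genes, matrix = matrix, labels = labels),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d samples (%d / %d per class)\n",
    length(x$genes), ncol(x$matrix), sum(x$labels == 0L), sum(x$labels == 1L)
  ))
  invisible(x)
}

new_ranked_list <- function(genes, scores) {
  ord <- order(-scores, genes)
  structure(
    tibble(gene = genes[ord], score = scores[ord]),
    class = c("ranked_list", class(tibble()))
  )
}

# signal-to-noise scores for one or many 0/1 label columns.
# X: genes x samples; L: samples x P indicator matrix of class-1 membership.
# Each class sd is floored at max(0.2 * |class mean|, 0.2).
.s2n <- function(X, L) {
  L <- as.matrix(L)
  n1 <- sum(L[, 1L])
  n0 <- nrow(L) - n1
  if (n1 < 2L || n0 < 2L) {
    abort("signal-to-noise ranking needs at least 2 samples in each class")
  }
  M1 <- (X %*% L) / n1
  M0 <- (X %*% (1 - L)) / n0
  X2 <- X * X
  V1 <- ((X2 %*% L) - n1 * M1 * M1) / (n1 - 1)
  V0 <- ((X2 %*% (1 - L)) - n0 * M0 * M0) / (n0 - 1)
  S1 <- pmax(sqrt(pmax(V1, 0)), 0.2 * abs(M1), 0.2)
  S0 <- pmax(sqrt(pmax(V0, 0)), 0.2 * abs(M0), 0.2)
  (M1 - M0) / (S1 + S0)
}

#' Rank genes by signal-to-noise ratio
#'
#' The default two-class ranking metric: per gene,
#' `(mean1 - mean0) / (sd1 + sd0)`, with each class standard deviation floored
#' at `max(0.2 * |class mean|, 0.2)` so low-variance genes cannot dominate.
#' Ties are broken by gene symbol (ascending) for determinism.
#'
#' @param dataset an [expression_dataset()] with at least 2 samples per class.
#' @return a `ranked_list` tibble (`gene`, `score`), scores non-increasing.
#' @export
rank_by_signal_to_noise <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  s <- .s2n(dataset$matrix, matrix(dataset$labels, ncol = 1L))[, 1L]
  new_ranked_list(dataset$genes, unname(s))
}

#' Log-max-p pre-ranked statistic
#'
#' Combines two per-gene p-value vectors (two independent comparisons of the
#' same genes) into one ranking statistic: the log of the per-gene maximum
#' p-value, `log10(max(p_a, p_b))`. Genes significant in *both* comparisons
#' get the most extreme negative scores and, in the default descending order,
#' land at the bottom of the ranked list.
#'
#' @param p_a,p_b named numeric vectors of p-values in (0, 1] covering the
#'   same genes.
#' @param decreasing sort direction; default `TRUE` (most extreme negative
#'   scores last).
#' @return a `ranked_list` tibble.
#' @export
preranked_statistic <- function(p_a, p_b, decreasing = TRUE) {
  if (is.null(names(p_a)) || is.null(names(p_b))) {
    abort("p_a and p_b must be named by gene")
  }
  if (!setequal(names(p_a), names(p_b))) {
    abort("p_a and p_b must cover the same genes")
  }
  p_b <- p_b[names(p_a)]
  if (any(p_a <= 0) || any(p_b <= 0) || any(p_a > 1) || any(p_b > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  score <- log10(pmax(p_a, p_b))
  if (!decreasing) score <- -score
  rl <- new_ranked_list(.norm_symbol(names(p_a)), unname(score))
  if (!decreasing) rl$score <- -rl$score
  rl
}

# ES from hit ranks in O(k): the running sum moves only at hits, and its
# extrema occur immediately before or after a hit.
# s_sorted: full score vector sorted as ranked; ranks: sorted hit positions.
.es_fast <- function(s_sorted, ranks, weight) {
  N <- length(s_sorted)
  k <- length(ranks)
  w <- abs(s_sorted[ranks])^weight
  nr <- sum(w)
  if (nr == 0) {
    w <- rep(1, k)
    nr <- k
  }
  phit <- cumsum(w) / nr
  if (N == k) {
    return(1)
  }
  miss_unit <- 1 / (N - k)
  i <- seq_len(k)
  after <- phit - (ranks - i) * miss_unit
  before <- c(0, phit[-k]) - (ranks - i) * miss_unit
  # interleave in list-position order so magnitude ties (exact or at float
  # precision) resolve to the extremum reached first, matching the explicit
  # running-sum walk
  cand <- as.vector(rbind(before, after))
  m <- max(abs(cand))
  cand[which(abs(cand) >= m - 1e-9 * max(1, m))[1L]]
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list top to bottom keeping a running sum: genes in the set
#' ("hits") increment it by `|score|^weight` normalized by the total over
#' hits; genes outside decrement it by `1/(N - k)`. The enrichment score is
#' the maximum-magnitude deviation from zero, a signed value in `[-1, 1]`.
#' `weight = 1` (default) is the weighted form; `weight = 0` recovers the
#' classic Kolmogorov–Smirnov statistic.
#'
#' @param ranked a `ranked_list`.
#' @param set_genes character vector of gene symbols.
#' @param weight non-negative exponent on `|score|`; default 1.
#' @return the enrichment score.
#' @export
enrichment_score <- function(ranked, set_genes, weight = 1) {
  stopifnot(weight >= 0)
  hits <- which(.norm_symbol(ranked$gene) %in% .norm_symbol(set_genes))
  if (!length(hits)) {
    abort("gene set has no genes in the ranked list")
  }
  .es_fast(ranked$score, hits, weight)
}

#' Run a GSEA-style enrichment analysis
#'
#' Applies the effective-size filter to the collection, computes the observed
#' enrichment score for every surviving set, and assesses it against a
#' permutation null:
#'
#' * `mode = "phenotype"`: sample class labels are permuted and the
#'   signal-to-noise ranking recomputed per permutation (requires an
#'   [expression_dataset()]);
#' * `mode = "gene"`: set membership is permuted over the ranked universe
#'   (requires a `ranked_list`, e.g. from [preranked_statistic()]).
#'
#' The p-value compares enrichment magnitudes: with `b` of the `n`
#' permutations reaching `|ES|` at least as large as observed,
#' `p = (b + 1) / (n + 1)`. Adding one to numerator and denominator keeps
#' p-values strictly positive, and because the observed score is exchangeable
#' with the permuted ones under the null, p-values are uniform on the
#' `1/(n+1)` grid. The ES sign still reports the direction of enrichment.
#'
#' All randomness derives from `seed`. Phenotype permutations are drawn once
#' before iterating over sets, and gene permutations use a per-term seed
#' derived from the term accession, so results do not depend on set iteration
#' order; reruns with the same seed are bit-identical.
#'
#' @param collection a `geneset_collection`.
#' @param data an `expression_dataset` (phenotype mode) or `ranked_list`
#'   (gene mode).
#' @param mode `"phenotype"` or `"gene"`.
#' @param min_size,max_size inclusive effective-size bounds (defaults 7, 150).
#' @param n_permutations number of permutations (default 1000).
#' @param seed integer seed.
#' @param weight ES weight exponent; default 1.
#' @return a `gsea_results` tibble: `term_id`, `name`, `effective_size`,
#'   `es`, `p_value`, `n_permutations`, `seed`.
#' @export
run_gsea <- function(collection, data, mode = c("phenotype", "gene"),
                     min_size = 7, max_size = 150,
                     n_permutations = 1000, seed = 1, weight = 1) {
  mode <- match.arg(mode)
  if (n_permutations < 1) {
    abort("n_permutations must be >= 1")
  }
  seed <- as.integer(seed)

  if (mode == "phenotype") {
    stopifnot(inherits(data, "expression_dataset"))
    universe <- data$genes
  } else {
    stopifnot(inherits(data, "ranked_list"))
    universe <- data$gene
  }
  coll <- size_filter(collection, universe, min_size, max_size)
  terms <- names(coll$sets)
  if (!length(terms)) {
    return(structure(
      tibble(
        term_id = character(), name = character(),
        effective_size = integer(), es = double(), p_value = double(),
        n_permutations = integer(), seed = integer()
      ),
      class = c("gsea_results", class(tibble()))
    ))
  }
  set_idx <- lapply(coll$sets, function(g) {
    which(.norm_symbol(universe) %in% .norm_symbol(g))
  })

  if (mode == "phenotype") {
    res <- .gsea_phenotype(data, set_idx, n_permutations, seed, weight)
  } else {
    res <- .gsea_gene(data, set_idx, n_permutations, seed, weight)
  }

  structure(
    tibble(
      term_id = terms,
      name = unname(coll$names[terms]),
      effective_size = lengths(set_idx),
      es = res$es,
      p_value = res$p,
      n_permutations = as.integer(n_permutations),
      seed = seed
    ),
    class = c("gsea_results", class(tibble()))
  )
}

.perm_p <- function(es_obs, es_null) {
  b <- sum(abs(es_null) >= abs(es_obs))
  (b + 1) / (length(es_null) + 1)
}

.gsea_phenotype <- function(dataset, set_idx, n_perm, seed, weight) {
  X <- dataset$matrix
  labels <- dataset$labels
  genes <- dataset$genes
  n_sets <- length(set_idx)

  obs_scores <- .s2n(X, matrix(labels, ncol = 1L))[, 1L]
  obs_ord <- order(-obs_scores, genes)
  obs_sorted <- obs_scores[obs_ord]
  pos <- integer(length(genes))
  pos[obs_ord] <- seq_along(genes)
  es_obs <- vapply(set_idx, function(ix) {
    .es_fast(obs_sorted, sort(pos[ix]), weight)
  }, double(1))

  L <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(j) sample(labels), integer(length(labels)))
  })
  scores <- .s2n(X, L)

  es_null <- matrix(0, nrow = n_sets, ncol = n_perm)
  for (j in seq_len(n_perm)) {
    s <- scores[, j]
    ord <- order(-s)
    s_sorted <- s[ord]
    pos[ord] <- seq_along(s)
    for (i in seq_len(n_sets)) {
      es_null[i, j] <- .es_fast(s_sorted, sort(pos[set_idx[[i]]]), weight)
    }
  }
  p <- vapply(seq_len(n_sets), function(i) .perm_p(es_obs[i], es_null[i, ]), double(1))
  list(es = es_obs, p = p)
}

.gsea_gene <- function(ranked, set_idx, n_perm, seed, weight) {
  s_sorted <- ranked$score
  N <- length(s_sorted)
  terms <- names(set_idx)

  es_obs <- vapply(set_idx, function(ix) .es_fast(s_sorted, sort(ix), weight), double(1))
  p <- vapply(seq_along(set_idx), function(i) {
    k <- length(set_idx[[i]])
    term_seed <- .string_seed(terms[[i]], seed)
    es_null <- withr::with_seed(term_seed, {
      vapply(seq_len(n_perm), function(j) {
        .es_fast(s_sorted, sort(sample.int(N, k)), weight)
      }, double(1))
    })
    .perm_p(es_obs[[i]], es_null)
  }, double(1))
  list(es = es_obs, p = p)
}

#' Glance at GSEA results
#'
#' @param x a `gsea_results` tibble.
#' @param alpha significance threshold for the summary count.
#' @param ... unused.
#' @return one-row tibble: set count, minimum p, count below `alpha`.
#' @method glance gsea_results
#' @export
glance.gsea_results <- function(x, alpha = 0.05, ...) {
  tibble(
    n_sets = nrow(x),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_,
    n_significant = sum(x$p_value < alpha)
  )
}

#' Plot the p-value spectrum of a GSEA run
#'
#' Histogram of per-set permutation p-values with the significance threshold
#' marked; a flat profile is what a null dataset should show.
#'
#' @param object a `gsea_results` tibble.
#' @param alpha threshold to mark (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gsea_results
#' @export
autoplot.gsea_results <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05), fill = "grey35") +
    ggplot2::geom_vline(xintercept = alpha, linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "permutation p-value", y = "gene sets",
      title = "Enrichment p-value spectrum"
    )
}
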