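# Comparative framework: unique/common partitioning by effective size,
# significance tallies, one-sided Fisher tests, newly-significant accounting.

#' Partition gene sets into unique/common by effective size
#'
#' For every term present in either collection, computes the effective size
#' under both (0 if absent) and assigns the term to exactly one of:
#' `common` (meets the bounds under both collections), `unique_to_a` /
#' `unique_to_b` (meets them under only one), or `excluded` (fails both —
#' these are dropped from the returned table). This captures how augmenting an
#' annotation corpus moves sets across the analysis size window: sets that
#' grow past the minimum become unique to the augmented collection, while sets
#' that outgrow the maximum are disqualified and become unique to the
#' baseline.
#'
#' @param coll_a,coll_b `geneset_collection`s (a: augmented, b: baseline, by
#'   convention).
#' @param universe gene symbols of the expression dataset.
#' @param min_size,max_size inclusive effective-size bounds (defaults 7, 150).
#' @return a `collection_comparison` tibble: `term_id`, `size_a`, `size_b`,
#'   `status` in `{common, unique_to_a, unique_to_b}`; bounds and universe are
#'   attached as attributes.
#' @export
classify_sets <- function(coll_a, coll_b, universe, min_size = 7, max_size = 150) {
  if (min_size > max_size) {
    abort("min_size must be <= max_size")
  }
  u <- .norm_symbol(universe)
  terms <- as.character(union(names(coll_a$sets), names(coll_b$sets)))
  eff <- function(coll, t) {
    g <- coll$sets[[t]]
    if (is.null(g)) 0L else length(intersect(.norm_symbol(g), u))
  }
  size_a <- vapply(terms, function(t) eff(coll_a, t), integer(1))
  size_b <- vapply(terms, function(t) eff(coll_b, t), integer(1))
  in_a <- size_a >= min_size & size_a <= max_size
  in_b <- size_b >= min_size & size_b <= max_size
  status <- dplyr::case_when(
    in_a & in_b ~ "common",
    in_a & !in_b ~ "unique_to_a",
    !in_a & in_b ~ "unique_to_b",
    TRUE ~ "excluded"
  )
  out <- tibble(
    term_id = terms, size_a = unname(size_a), size_b = unname(size_b),
    status = status
  ) %>%
    filter(.data$status != "excluded") %>%
    arrange(.data$term_id)
  structure(
    out,
    class = c("collection_comparison", class(tibble())),
    bounds = c(min_size, max_size),
    universe = u
  )
}

#' Significance tally with reproducible percentage rounding
#'
#' Counts results strictly below the significance threshold and expresses them
#' as a percentage rounded half-up at a configurable number of decimals, the
#' convention needed to reproduce published summary tables digit-for-digit.
#' `significance_tally()` is the count-level constructor;
#' `tally_significance()` tallies a result table.
#'
#' @param significant number of significant results.
#' @param total number of results considered.
#' @param digits decimal places for the percentage (2 for detailed tables,
#'   1 for compact ones).
#' @return a `significance_tally`: list with `total`, `significant`,
#'   `percent` (`NA` when `total` is 0).
#' @export
significance_tally <- function(significant, total, digits = 2) {
  stopifnot(significant >= 0, significant <= total)
  structure(
    list(
      total = as.integer(total),
      significant = as.integer(significant),
      percent = if (total > 0) round_half_up(100 * significant / total, digits) else NA_real_
    ),
    class = "significance_tally"
  )
}

#' @rdname significance_tally
#' @param results a `gsea_results` tibble (or any data frame with a `p_value`
#'   column).
#' @param alpha significance threshold; strict comparison (`p < alpha`), so a
#'   p-value exactly equal to `alpha` does not count.
#' @export
tally_significance <- function(results, alpha = 0.05, digits = 2) {
  stopifnot(alpha > 0, alpha < 1)
  significance_tally(sum(results$p_value < alpha), nrow(results), digits = digits)
}

#' @export
print.significance_tally <- function(x, ...) {
  cat(sprintf(
    "<significance_tally> %d / %d significant (%s%%)\n",
    x$significant, x$total,
    if (is.na(x$percent)) "-" else format(x$percent)
  ))
  invisible(x)
}

#' One-sided Fisher's exact test on two significance proportions
#'
#' Exact hypergeometric tail probability for the 2x2 table
#' `[[sig_a, total_a - sig_a], [sig_b, total_b - sig_b]]`, testing whether the
#' significant fraction is larger in the stated direction.
#'
#' @param sig_a,total_a significant and total counts for collection A.
#' @param sig_b,total_b significant and total counts for collection B.
#' @param direction `"a_greater"` (is A's fraction larger?) or `"b_greater"`.
#' @return the one-sided p-value.
#' @export
fisher_one_sided <- function(sig_a, total_a, sig_b, total_b,
                             direction = c("a_greater", "b_greater")) {
  direction <- match.arg(direction)
  stopifnot(sig_a >= 0, sig_b >= 0, sig_a <= total_a, sig_b <= total_b)
  if (total_a == 0 || total_b == 0) {
    abort("fisher_one_sided: zero-total margin")
  }
  tab <- matrix(c(sig_a, total_a - sig_a, sig_b, total_b - sig_b),
    nrow = 2, byrow = TRUE
  )
  alternative <- if (direction == "a_greater") "greater" else "less"
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Terms crossing the significance threshold in only one analysis
#'
#' A term absent from an analysis counts as not significant there, so a term
#' unique to A with `p < alpha` is newly significant. Counts run over the
#' union of terms considered in either analysis.
#'
#' @param results_a,results_b `gsea_results` tibbles keyed by `term_id`.
#' @param alpha significance threshold (strict).
#' @return list with character vectors `newly_significant` (significant in A
#'   only) and `newly_insignificant` (significant in B only).
#' @export
newly_significant <- function(results_a, results_b, alpha = 0.05) {
  sig_a <- results_a$term_id[results_a$p_value < alpha]
  sig_b <- results_b$term_id[results_b$p_value < alpha]
  list(
    newly_significant = sort(setdiff(sig_a, sig_b)),
    newly_insignificant = sort(setdiff(sig_b, sig_a))
  )
}

#' Assemble a full collection-comparison report
#'
#' Combines the size-window partition with the two enrichment analyses:
#' significance tallies over the unique-to-A and unique-to-B subsets, both
#' one-sided Fisher tests on those tallies, and the newly significant /
#' insignificant term lists over all considered terms.
#'
#' @param comparison a `collection_comparison` from [classify_sets()].
#' @param results_a,results_b `gsea_results` for collections A and B.
#' @param alpha significance threshold (strict; default 0.05).
#' @param digits decimal places for tally percentages.
#' @return a `comparison_report` (list): `comparison`, `tally_a`, `tally_b`,
#'   `fisher_greater_a`, `fisher_greater_b`, `newly_significant`,
#'   `newly_insignificant`, `alpha`.
#' @export
compare_collections <- function(comparison, results_a, results_b,
                                alpha = 0.05, digits = 2) {
  unique_a <- comparison$term_id[comparison$status == "unique_to_a"]
  unique_b <- comparison$term_id[comparison$status == "unique_to_b"]
  tally_a <- tally_significance(
    results_a %>% filter(.data$term_id %in% unique_a), alpha, digits
  )
  tally_b <- tally_significance(
    results_b %>% filter(.data$term_id %in% unique_b), alpha, digits
  )
  fishers <- if (tally_a$total > 0 && tally_b$total > 0) {
    list(
      a = fisher_one_sided(
        tally_a$significant, tally_a$total,
        tally_b$significant, tally_b$total, "a_greater"
      ),
      b = fisher_one_sided(
        tally_a$significant, tally_a$total,
        tally_b$significant, tally_b$total, "b_greater"
      )
    )
  } else {
    list(a = NA_real_, b = NA_real_)
  }
  newly <- newly_significant(results_a, results_b, alpha)
  structure(
    list(
      comparison = comparison,
      tally_a = tally_a,
      tally_b = tally_b,
      fisher_greater_a = fishers$a,
      fisher_greater_b = fishers$b,
      newly_significant = newly$newly_significant,
      newly_insignificant = newly$newly_insignificant,
      alpha = alpha
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  s <- table(factor(x$comparison$status,
    levels = c("common", "unique_to_a", "unique_to_b")
  ))
  cat("<comparison_report>\n")
  cat(sprintf(
    "  sets in bounds: %d common, %d unique to A, %d unique to B\n",
    s[["common"]], s[["unique_to_a"]], s[["unique_to_b"]]
  ))
  cat(sprintf(
    "  unique-set significance (p < %g): A %d/%d (%s%%), B %d/%d (%s%%)\n",
    x$alpha,
    x$tally_a$significant, x$tally_a$total, format(x$tally_a$percent),
    x$tally_b$significant, x$tally_b$total, format(x$tally_b$percent)
  ))
  cat(sprintf(
    "  one-sided Fisher: A greater p = %s, B greater p = %s\n",
    format(x$fisher_greater_a, digits = 3), format(x$fisher_greater_b, digits = 3)
  ))
  cat(sprintf(
    "  newly significant: %d, newly insignificant: %d\n",
    length(x$newly_significant), length(x$newly_insignificant)
  ))
  invisible(x)
}

#' Tidy a comparison report
#'
#' @param x a `comparison_report`.
#' @param ... unused.
#' @return tibble with one row per reported quantity (`metric`, `value`).
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) {
  s <- table(factor(x$comparison$status,
    levels = c("common", "unique_to_a", "unique_to_b")
  ))
  tibble(
    metric = c(
      "n_common", "n_unique_to_a", "n_unique_to_b",
      "sig_unique_a", "total_unique_a", "percent_unique_a",
      "sig_unique_b", "total_unique_b", "percent_unique_b",
      "fisher_greater_a", "fisher_greater_b",
      "n_newly_significant", "n_newly_insignificant"
    ),
    value = c(
      s[["common"]], s[["unique_to_a"]], s[["unique_to_b"]],
      x$tally_a$significant, x$tally_a$total, x$tally_a$percent,
      x$tally_b$significant, x$tally_b$total, x$tally_b$percent,
      x$fisher_greater_a, x$fisher_greater_b,
      length(x$newly_significant), length(x$newly_insignificant)
    )
  )
}

#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  tibble(
    n_considered = nrow(x$comparison),
    n_newly_significant = length(x$newly_significant),
    n_newly_insignificant = length(x$newly_insignificant),
    fisher_greater_a = x$fisher_greater_a,
    fisher_greater_b = x$fisher_greater_b,
    alpha = x$alpha
  )
}

#' Plot a comparison report
#'
#' Bar chart of the size-window partition, with the unique subsets split by
#' significance at the report's threshold.
#'
#' @param object a `comparison_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  td <- tidy(object)
  v <- setNames(td$value, td$metric)
  df <- tibble(
    partition = factor(
      c("common", "unique to A", "unique to A", "unique to B", "unique to B"),
      levels = c("common", "unique to A", "unique to B")
    ),
    significance = c(
      "all", "significant", "not significant", "significant", "not significant"
    ),
    n = c(
      v[["n_common"]],
      v[["sig_unique_a"]], v[["total_unique_a"]] - v[["sig_unique_a"]],
      v[["sig_unique_b"]], v[["total_unique_b"]] - v[["sig_unique_b"]]
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$partition, y = .data$n, fill = .data$significance)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "gene sets",
      title = sprintf("Gene-set availability and significance (p < %g)", object$alpha)
    )
}

#' Write a comparison report to TSV and JSON
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if needed); writes
#'   `comparison.tsv` (the partition), `report.tsv` (tidied metrics) and
#'   `report.json`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(as_tibble(report$comparison), file.path(dir, "comparison.tsv"))
  readr::write_tsv(tidy(report), file.path(dir, "report.tsv"))
  jsonlite::write_json(
    list(
      tally_a = unclass(report$tally_a),
      tally_b = unclass(report$tally_b),
      fisher_greater_a = report$fisher_greater_a,
      fisher_greater_b = report$fisher_greater_b,
      newly_significant = report$newly_significant,
      newly_insignificant = report$newly_insignificant,
      alpha = report$alpha
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
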