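# End-to-end pipeline: transfer -> merge/consolidate -> build -> enrich ->
# compare, with all intermediates written for provenance.

#' Build a validated pipeline configuration
#'
#' Collects every input path and tuning parameter for [run_pipeline()] in one
#' validated list; the effective configuration is serialized next to the
#' outputs for provenance.
#'
#' @param obo,mouse_gaf,human_gaf,orthologs,id_map input file paths (`id_map`
#'   may be `NULL` when human symbols are already filled in).
#' @param expression,classes expression matrix and CLS-style class file (two
#'   class mode), or
#' @param ranked a two-column ranked-list file (pre-ranked mode; exactly one
#'   of the two input styles must be given).
#' @param out_dir output directory.
#' @param dev_root developmental subtree root accession.
#' @param namespace GO namespace for the collections.
#' @param min_size,max_size inclusive effective-size bounds.
#' @param alpha significance threshold.
#' @param n_permutations permutations per enrichment run.
#' @param seed integer seed for all randomness.
#' @param weight enrichment-score weight exponent.
#' @param digits decimal places for tally percentages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(obo, mouse_gaf, human_gaf, orthologs,
                            id_map = NULL,
                            expression = NULL, classes = NULL, ranked = NULL,
                            out_dir = tempfile("goforge_run_"),
                            dev_root = "GO:0032502",
                            namespace = "biological_process",
                            min_size = 7, max_size = 150,
                            alpha = 0.05, n_permutations = 1000,
                            seed = 1, weight = 1, digits = 2) {
  two_class <- !is.null(expression) && !is.null(classes)
  if (two_class == !is.null(ranked)) {
    abort("provide either expression+classes or ranked, not both/neither")
  }
  for (p in c(obo, mouse_gaf, human_gaf, orthologs, id_map, expression, classes, ranked)) {
    .assert_file_exists(p)
  }
  stopifnot(min_size <= max_size, alpha > 0, alpha < 1, n_permutations >= 1)
  structure(
    list(
      obo = obo, mouse_gaf = mouse_gaf, human_gaf = human_gaf,
      orthologs = orthologs, id_map = id_map,
      expression = expression, classes = classes, ranked = ranked,
      out_dir = out_dir, dev_root = dev_root, namespace = namespace,
      min_size = min_size, max_size = max_size, alpha = alpha,
      n_permutations = n_permutations, seed = as.integer(seed),
      weight = weight, digits = digits
    ),
    class = "pipeline_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full annotation-augmentation and comparison pipeline
#'
#' Executes, in order: ortholog transfer of mouse developmental annotations;
#' merge and consolidation with the human corpus; construction of the
#' baseline (human-only) and augmented (human + transferred) gene-set
#' collections; enrichment analysis of the expression input against both
#' collections; and the comparative report (unique/common partition, tallies,
#' Fisher tests, newly significant terms). Every intermediate artifact and
#' the effective configuration are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return a list: `report` (a `comparison_report`), `results_a` /
#'   `results_b` (`gsea_results` for augmented/baseline), `collections`, and
#'   `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))

  cfg_json <- file.path(config$out_dir, "config.json")
  cfg <- unclass(config)
  jsonlite::write_json(
    cfg[!vapply(cfg, is.null, logical(1))],
    cfg_json,
    auto_unbox = TRUE, digits = NA
  )

  onto <- .stage("parse ontology", parse_obo(config$obo))
  say("parsed ontology: %d terms", nrow(onto$terms))

  mouse <- .stage("read mouse GAF", read_gaf(config$mouse_gaf))
  orth <- .stage("load orthologs", read_ortholog_table(config$orthologs, quiet = quiet))
  transferred <- .stage(
    "ortholog transfer",
    transfer_annotations(mouse, orth, onto, dev_root = config$dev_root)
  )
  say("transferred %d human records from %d mouse records", nrow(transferred), nrow(mouse))
  transferred_path <- file.path(config$out_dir, "transferred.gaf")
  write_gaf(transferred, transferred_path)

  human <- .stage("read human GAF", read_gaf(config$human_gaf))
  if (!is.null(config$id_map)) {
    human <- .stage(
      "map symbols",
      map_symbols(human, read_id_map(config$id_map), quiet = quiet)
    )
  }
  baseline_records <- consolidate(human)
  merged <- .stage("merge/consolidate", consolidate(bind_rows(human, transferred)))
  merged_path <- file.path(config$out_dir, "merged.gaf")
  write_gaf(merged, merged_path)
  say("merged corpus: %d unique annotations (baseline %d)", nrow(merged), nrow(baseline_records))

  coll_b <- .stage(
    "build baseline collection",
    build_collection(baseline_records, onto, config$namespace, quiet = quiet)
  )
  coll_a <- .stage(
    "build augmented collection",
    build_collection(merged, onto, config$namespace, quiet = quiet)
  )
  baseline_gmt <- file.path(config$out_dir, "baseline.gmt")
  augmented_gmt <- file.path(config$out_dir, "augmented.gmt")
  write_gmt(coll_b, baseline_gmt)
  write_gmt(coll_a, augmented_gmt)
  say("collections: augmented %d sets, baseline %d sets", length(coll_a), length(coll_b))

  if (!is.null(config$expression)) {
    data <- .stage("read expression", read_expression(config$expression, config$classes))
    mode <- "phenotype"
    universe <- data$genes
  } else {
    data <- .stage("read ranked list", read_ranked(config$ranked))
    mode <- "gene"
    universe <- data$gene
  }

  gsea <- function(coll) {
    run_gsea(coll, data,
      mode = mode, min_size = config$min_size, max_size = config$max_size,
      n_permutations = config$n_permutations, seed = config$seed,
      weight = config$weight
    )
  }
  results_a <- .stage("enrichment (augmented)", gsea(coll_a))
  results_b <- .stage("enrichment (baseline)", gsea(coll_b))
  readr::write_tsv(as_tibble(results_a), file.path(config$out_dir, "results_augmented.tsv"))
  readr::write_tsv(as_tibble(results_b), file.path(config$out_dir, "results_baseline.tsv"))

  comparison <- .stage(
    "classify",
    classify_sets(coll_a, coll_b, universe, config$min_size, config$max_size)
  )
  report <- .stage(
    "compare",
    compare_collections(comparison, results_a, results_b,
      alpha = config$alpha, digits = config$digits
    )
  )
  write_report(report, config$out_dir)

  list(
    report = report,
    results_a = results_a, results_b = results_b,
    collections = list(augmented = coll_a, baseline = coll_b),
    paths = c(
      config = cfg_json, transferred = transferred_path, merged = merged_path,
      baseline_gmt = baseline_gmt, augmented_gmt = augmented_gmt,
      out_dir = config$out_dir
    )
  )
}

#' One-command demo on generated fixtures
#'
#' Simulates an ontology, an annotation corpus and a planted two-class
#' expression dataset, writes them to disk, and runs the full pipeline on the
#' files — exercising every parser and stage end to end with no downloads.
#' A gene set of the augmented collection is planted as differentially
#' expressed, so a sensible run reports it among the most significant sets.
#'
#' @param seed integer seed driving every generator and the enrichment
#'   permutations.
#' @param out_dir output directory (a fresh temporary directory by default).
#' @param n_terms ontology size.
#' @param n_permutations permutations per enrichment run.
#' @param effect_size planted effect size in noise-sd units.
#' @param quiet suppress progress messages.
#' @return the [run_pipeline()] result, with the simulation `truth` attached.
#' @export
run_demo <- function(seed = 7, out_dir = tempfile("goforge_demo_"),
                     n_terms = 60, n_permutations = 200,
                     effect_size = 1, quiet = FALSE) {
  sim <- simulate_ontology(n_terms = n_terms, seed = seed)
  corpus <- simulate_corpus(sim, seed = seed + 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_corpus(sim, corpus, out_dir)

  # choose the planted set from the augmented collection, deterministically
  transferred <- transfer_annotations(
    read_gaf(paths[["mouse_gaf"]]),
    ortholog_map(corpus$orthologs, quiet = TRUE),
    sim$onto,
    dev_root = corpus$dev_root
  )
  human <- map_symbols(read_gaf(paths[["human_gaf"]]), corpus$id_map, quiet = TRUE)
  merged <- consolidate(bind_rows(human, transferred))
  coll <- build_collection(merged, sim$onto, quiet = TRUE)
  sizes <- lengths(coll$sets)
  candidates <- names(coll$sets)[sizes >= 10 & sizes <= 40]
  planted <- if (length(candidates)) candidates[[1L]] else names(coll$sets)[which.min(abs(sizes - 20))]

  expr <- simulate_expression(coll,
    planted_terms = planted, effect_size = effect_size,
    n_background = 100, seed = seed + 2L
  )
  expr_path <- file.path(out_dir, "expression.tsv")
  cls_path <- file.path(out_dir, "classes.cls")
  write_expression(expr$dataset, expr_path, cls_path)
  readr::write_tsv(expr$truth, file.path(out_dir, "planted_truth.tsv"))

  config <- pipeline_config(
    obo = paths[["obo"]], mouse_gaf = paths[["mouse_gaf"]],
    human_gaf = paths[["human_gaf"]], orthologs = paths[["orthologs"]],
    id_map = paths[["id_map"]],
    expression = expr_path, classes = cls_path,
    out_dir = file.path(out_dir, "run"),
    n_permutations = n_permutations, seed = seed
  )
  out <- run_pipeline(config, quiet = quiet)
  out$truth <- expr$truth
  out$transfer_truth <- corpus$truth
  out
}
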