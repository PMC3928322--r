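# Seeded generators for every input format: ontology, annotation corpora,
# ortholog tables, expression matrices. Each generator is a pure function of
# its arguments (seed included) and emits ground-truth sidecars computed from
# its own bookkeeping, independently of the package's query machinery, so
# end-to-end tests can assert exact equality.

#' Simulate a GO-like ontology DAG
#'
#' Generates an acyclic is_a/part_of DAG with a single designated
#' developmental root whose subtree covers roughly `dev_fraction` of the
#' terms. Acyclicity holds by construction: each term draws parents only from
#' earlier-indexed terms, developmental terms only from earlier developmental
#' terms (so subtree membership is exact bookkeeping, not a traversal).
#' Edge types are assigned is_a/part_of at 70/30.
#'
#' @param n_terms number of terms (>= 3).
#' @param max_parents maximum parents per term.
#' @param dev_fraction target fraction of terms inside the developmental
#'   subtree.
#' @param namespace namespace for all generated terms.
#' @param seed integer seed.
#' @return list with `onto` (a `go_ontology`), `dev_root` (accession,
#'   GO:0032502), and `dev_terms` (the subtree membership set by
#'   construction, including the root).
#' @export
simulate_ontology <- function(n_terms = 50, max_parents = 3, dev_fraction = 0.5,
                              namespace = "biological_process", seed = 1) {
  stopifnot(n_terms >= 3, max_parents >= 1, dev_fraction >= 0, dev_fraction <= 1)
  dev_root <- "GO:0032502"
  withr::with_seed(seed, {
    ids <- sprintf("GO:%07d", seq_len(n_terms))
    ids[2] <- dev_root
    is_dev <- logical(n_terms)
    is_dev[2] <- TRUE

    edges <- list(tibble(child = dev_root, parent = ids[1], relation = "is_a"))
    for (i in 3:n_terms) {
      is_dev[i] <- stats::runif(1) < dev_fraction
      pool <- if (is_dev[i]) ids[seq_len(i - 1)][is_dev[seq_len(i - 1)]] else ids[c(1, which(!is_dev[seq_len(i - 1)]))]
      pool <- unique(pool)
      k <- sample.int(min(max_parents, length(pool)), 1)
      parents <- sample(pool, k)
      rel <- ifelse(stats::runif(k) < 0.7, "is_a", "part_of")
      edges[[length(edges) + 1]] <- tibble(child = ids[i], parent = parents, relation = rel)
    }
    edges <- bind_rows(edges)

    terms <- tibble(
      term_id = ids,
      name = sprintf("simulated term %03d", seq_len(n_terms)),
      namespace = namespace,
      is_obsolete = FALSE
    )
    onto <- structure(
      list(
        terms = terms,
        edges = edges,
        parents = .adjacency(edges$child, edges$parent, ids),
        children = .adjacency(edges$parent, edges$child, ids),
        alt_map = character()
      ),
      class = "go_ontology"
    )
    .check_acyclic(onto)
    list(onto = onto, dev_root = dev_root, dev_terms = ids[is_dev])
  })
}

#' Simulate an annotation corpus with a transfer ground truth
#'
#' Generates a mouse GAF concentrated in the developmental subtree, a human
#' baseline GAF with UniProt-style accessions, a strictly one-to-one ortholog
#' table covering `ortholog_fraction` of the mouse genes, an
#' accession-to-symbol mapping table, and — crucially — the exact set of
#' (human symbol, term) pairs a correct transfer must produce. The ground
#' truth is derived from the generator's own bookkeeping (which terms were
#' drawn from the developmental pool, which genes it mapped, which evidence
#' codes it assigned), never from the package's ontology queries.
#'
#' @param sim output of [simulate_ontology()].
#' @param n_mouse_genes,n_human_genes gene pool sizes.
#' @param n_mouse_annotations,n_human_annotations GAF line counts.
#' @param ortholog_fraction fraction of mouse genes with a human ortholog.
#' @param evidence_mix named probability vector over evidence codes for mouse
#'   annotations (must sum to 1).
#' @param not_fraction fraction of annotations carrying a NOT qualifier.
#' @param dev_concentration probability a mouse annotation targets a
#'   developmental-subtree term. Mouse molecular developmental annotation is
#'   substantially richer than human, which is the premise that makes
#'   cross-species transfer worthwhile; the human corpus therefore
#'   concentrates on developmental terms at the lower
#'   `human_dev_concentration`.
#' @param human_dev_concentration probability a human annotation targets a
#'   developmental-subtree term.
#' @param seed integer seed.
#' @return list of tibbles: `mouse_gaf`, `human_gaf`, `orthologs`, `id_map`,
#'   `truth` (columns `symbol`, `term_id`), plus `dev_root`.
#' @export
simulate_corpus <- function(sim,
                            n_mouse_genes = 150, n_human_genes = 200,
                            n_mouse_annotations = 1000,
                            n_human_annotations = 1000,
                            ortholog_fraction = 0.8,
                            evidence_mix = c(
                              IDA = 0.30, IMP = 0.20, IGI = 0.10,
                              IEA = 0.15, ISS = 0.15, TAS = 0.10
                            ),
                            not_fraction = 0.05,
                            dev_concentration = 0.7,
                            human_dev_concentration = 0.3,
                            seed = 1) {
  stopifnot(abs(sum(evidence_mix) - 1) < 1e-8)
  unknown <- setdiff(names(evidence_mix), GO_EVIDENCE_CODES)
  if (length(unknown)) {
    abort(sprintf("evidence_mix contains unknown code(s): %s", paste(unknown, collapse = ", ")))
  }
  onto <- sim$onto
  dev_terms <- sim$dev_terms
  nondev_terms <- setdiff(onto$terms$term_id, dev_terms)

  withr::with_seed(seed, {
    mouse_genes <- sprintf("Mgene%04d", seq_len(n_mouse_genes))
    human_genes <- sprintf("HGENE%04d", seq_len(n_human_genes))
    n_mapped <- floor(ortholog_fraction * n_mouse_genes)
    mapped_mouse <- sort(sample(mouse_genes, n_mapped))
    mapped_human <- sample(human_genes, n_mapped)
    orthologs <- tibble(mouse_symbol = mapped_mouse, human_symbol = mapped_human)

    draw_terms <- function(n, concentration = dev_concentration) {
      from_dev <- stats::runif(n) < concentration
      out <- character(n)
      if (length(dev_terms)) out[from_dev] <- sample(dev_terms, sum(from_dev), replace = TRUE)
      pool <- if (length(nondev_terms)) nondev_terms else dev_terms
      out[!from_dev | !nzchar(out)] <- sample(pool, sum(!from_dev | !nzchar(out)), replace = TRUE)
      out
    }

    m_gene <- sample(mouse_genes, n_mouse_annotations, replace = TRUE)
    m_term <- draw_terms(n_mouse_annotations)
    m_evid <- sample(names(evidence_mix), n_mouse_annotations,
      replace = TRUE, prob = evidence_mix
    )
    m_not <- stats::runif(n_mouse_annotations) < not_fraction
    mouse_gaf <- annotation_prototype() %>%
      bind_rows(tibble(
        db = "MGI",
        object_id = sprintf("MGI:%07d", match(m_gene, mouse_genes)),
        symbol = m_gene,
        qualifiers = lapply(m_not, function(q) if (q) "NOT" else character()),
        term_id = m_term,
        references = sprintf("PMID:%07d", sample.int(9999999, n_mouse_annotations, replace = TRUE)),
        evidence_code = m_evid,
        with_from = "",
        aspect = "P",
        object_name = "", synonym = "", object_type = "gene",
        taxon = "taxon:10090",
        date = "20130410",
        assigned_by = "MGI",
        annotation_extension = "", gene_product_form_id = "",
        provenance = "BASELINE",
        provenances = list("BASELINE")
      ))

    h_gene <- sample(human_genes, n_human_annotations, replace = TRUE)
    h_acc <- sprintf("P%05d", match(h_gene, human_genes))
    h_term <- draw_terms(n_human_annotations, human_dev_concentration)
    h_evid <- sample(names(evidence_mix), n_human_annotations,
      replace = TRUE, prob = evidence_mix
    )
    h_not <- stats::runif(n_human_annotations) < not_fraction
    human_gaf <- annotation_prototype() %>%
      bind_rows(tibble(
        db = "UniProtKB",
        object_id = h_acc,
        symbol = h_acc, # symbols are derived from accessions via the id map
        qualifiers = lapply(h_not, function(q) if (q) "NOT" else character()),
        term_id = h_term,
        references = sprintf("PMID:%07d", sample.int(9999999, n_human_annotations, replace = TRUE)),
        evidence_code = h_evid,
        with_from = "",
        aspect = "P",
        object_name = "", synonym = "", object_type = "protein",
        taxon = "taxon:9606",
        date = "20130410",
        assigned_by = "UniProt",
        annotation_extension = "", gene_product_form_id = "",
        provenance = "BASELINE",
        provenances = list("BASELINE")
      ))

    id_map <- tibble(
      object_id = sprintf("P%05d", seq_len(n_human_genes)),
      symbol = human_genes
    )

    # ground truth from generator bookkeeping: experimental evidence, not
    # NOT-qualified, developmental term, mapped gene
    eligible <- m_evid %in% c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP") &
      !m_not & m_term %in% dev_terms & m_gene %in% mapped_mouse
    truth <- tibble(
      symbol = .norm_symbol(orthologs$human_symbol[match(m_gene[eligible], orthologs$mouse_symbol)]),
      term_id = m_term[eligible]
    ) %>%
      distinct() %>%
      arrange(.data$symbol, .data$term_id)

    list(
      mouse_gaf = mouse_gaf, human_gaf = human_gaf,
      orthologs = orthologs, id_map = id_map,
      truth = truth, dev_root = sim$dev_root
    )
  })
}

#' Write a simulated corpus to disk
#'
#' Writes `ontology.obo`, `mouse.gaf`, `human.gaf`, `orthologs.tsv`,
#' `id_map.tsv` and `truth.tsv` into `dir`, the on-disk forms consumed by the
#' corresponding readers.
#'
#' @param sim output of [simulate_ontology()].
#' @param corpus output of [simulate_corpus()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_corpus <- function(sim, corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    obo = file.path(dir, "ontology.obo"),
    mouse_gaf = file.path(dir, "mouse.gaf"),
    human_gaf = file.path(dir, "human.gaf"),
    orthologs = file.path(dir, "orthologs.tsv"),
    id_map = file.path(dir, "id_map.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_obo(sim$onto, paths[["obo"]])
  write_gaf(corpus$mouse_gaf, paths[["mouse_gaf"]])
  write_gaf(corpus$human_gaf, paths[["human_gaf"]])
  readr::write_tsv(corpus$orthologs, paths[["orthologs"]], col_names = FALSE)
  readr::write_tsv(corpus$id_map, paths[["id_map"]], col_names = FALSE)
  readr::write_tsv(corpus$truth, paths[["truth"]])
  invisible(paths)
}

#' Simulate a two-class expression dataset with planted gene sets
#'
#' Emulates the two-class microarray structure of a differential expression
#' study: a genes-by-samples matrix of Gaussian noise in which the member
#' genes of each planted gene set have their class-1 mean shifted by
#' `effect_size` standard deviations.
#'
#' @param collection a `geneset_collection`; the gene universe is the union
#'   of its member genes plus `n_background` extra background genes.
#' @param planted_terms term accessions of the sets to shift (must exist in
#'   `collection`).
#' @param effect_size mean shift in units of `noise_sd`.
#' @param n_per_class samples per class.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_background extra genes belonging to no set.
#' @param seed integer seed.
#' @return list with `dataset` (an `expression_dataset`) and `truth`
#'   (tibble `term_id`, `effect_size`).
#' @export
simulate_expression <- function(collection, planted_terms = character(),
                                effect_size = 1, n_per_class = 10,
                                noise_sd = 1, n_background = 0, seed = 1) {
  missing <- setdiff(planted_terms, names(collection$sets))
  if (length(missing)) {
    abort(sprintf("planted term(s) not in collection: %s", paste(missing, collapse = ", ")))
  }
  genes <- sort(unique(c(
    unlist(collection$sets, use.names = FALSE),
    if (n_background > 0) sprintf("BGGENE%04d", seq_len(n_background))
  )))
  n_samples <- 2L * n_per_class
  labels <- rep(c(0L, 1L), each = n_per_class)
  planted_genes <- unique(unlist(collection$sets[planted_terms], use.names = FALSE))
  withr::with_seed(seed, {
    mat <- matrix(rnorm(length(genes) * n_samples, sd = noise_sd),
      nrow = length(genes),
      dimnames = list(genes, sprintf("sample%02d", seq_len(n_samples)))
    )
    mat[genes %in% planted_genes, labels == 1L] <-
      mat[genes %in% planted_genes, labels == 1L] + effect_size * noise_sd
    list(
      dataset = expression_dataset(mat, labels),
      truth = tibble(
        term_id = planted_terms,
        effect_size = rep(effect_size, length(planted_terms))
      )
    )
  })
}
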