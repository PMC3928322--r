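# One-to-one ortholog map and cross-species annotation transfer.

#' Load a mouse-to-human ortholog table
#'
#' Reads a two-column tab-delimited table (mouse symbol, human symbol) and
#' enforces a strictly one-to-one mapping. In strict mode (default), every row
#' participating in a one-to-many or many-to-one relationship is excluded and
#' the exclusion count reported; with `strict = FALSE` any ambiguity is an
#' error instead. Exact duplicate rows are deduplicated silently in either
#' mode.
#'
#' @param path tab-delimited file, columns mouse symbol then human symbol, no
#'   header.
#' @param strict drop ambiguous rows (`TRUE`, default) or error on them.
#' @param quiet suppress the exclusion-count message.
#' @return an `ortholog_map`: a tibble with columns `mouse_symbol`,
#'   `human_symbol`, injective in both directions; the number of excluded rows
#'   is attached as `attr(, "n_excluded")`.
#' @export
read_ortholog_table <- function(path, strict = TRUE, quiet = FALSE) {
  .assert_file_exists(path)
  tbl <- readr::read_tsv(path,
    col_names = c("mouse_symbol", "human_symbol"),
    col_types = "cc", progress = FALSE
  )
  ortholog_map(tbl, strict = strict, quiet = quiet)
}

#' @rdname read_ortholog_table
#' @param pairs tibble or data frame with columns `mouse_symbol`,
#'   `human_symbol`.
#' @export
ortholog_map <- function(pairs, strict = TRUE, quiet = FALSE) {
  stopifnot(all(c("mouse_symbol", "human_symbol") %in% names(pairs)))
  pairs <- as_tibble(pairs) %>%
    select("mouse_symbol", "human_symbol") %>%
    distinct()
  dup_mouse <- pairs$mouse_symbol[duplicated(pairs$mouse_symbol)]
  dup_human <- pairs$human_symbol[duplicated(pairs$human_symbol)]
  ambiguous <- pairs$mouse_symbol %in% dup_mouse | pairs$human_symbol %in% dup_human
  if (any(ambiguous) && !strict) {
    abort(sprintf("%d ambiguous ortholog row(s); use strict = TRUE to exclude them", sum(ambiguous)))
  }
  kept <- pairs[!ambiguous, ]
  if (!quiet && any(ambiguous)) {
    inform(sprintf(
      "read_ortholog_table: excluded %d row(s) in one-to-many/many-to-one relationships",
      sum(ambiguous)
    ))
  }
  structure(kept, class = c("ortholog_map", class(kept)), n_excluded = sum(ambiguous))
}

#' Transfer mouse developmental annotations to human genes
#'
#' Maps mouse GO annotations onto their human one-to-one orthologs under four
#' gates, each motivated by keeping only well-supported, development-specific
#' biology:
#'
#' 1. the evidence code passes `policy` (default [transfer_policy()]:
#'    experimental codes only);
#' 2. the annotated term lies in the developmental subtree — `dev_root` or any
#'    of its is_a/part_of descendants;
#' 3. the mouse symbol has a human ortholog in `map`;
#' 4. the record is not NOT-qualified (negative findings are never transferred
#'    across species).
#'
#' Surviving records keep their original GO term and mouse evidence code, get
#' the human symbol, carry provenance `ORTHOLOG`, and record the mouse
#' reference in the with/from column. The output is consolidated (one record
#' per human gene–term pair).
#'
#' @param mouse_records annotation tibble (e.g. from [read_gaf()] on an
#'   MGI-style GAF).
#' @param map an `ortholog_map`.
#' @param onto a `go_ontology`.
#' @param dev_root accession of the developmental subtree root (default
#'   GO:0032502, "developmental process").
#' @param policy evidence policy gating transfer; default [transfer_policy()].
#' @param taxon if non-`NULL` (default `"10090"`, mouse), records whose taxon
#'   column is non-empty and does not contain this taxon id are dropped.
#' @return consolidated annotation tibble of transferred human records.
#' @export
transfer_annotations <- function(mouse_records, map, onto,
                                 dev_root = "GO:0032502",
                                 policy = transfer_policy(),
                                 taxon = "10090") {
  stopifnot(inherits(map, "ortholog_map"))
  if (!dev_root %in% onto$terms$term_id && !dev_root %in% names(onto$alt_map)) {
    abort(sprintf("developmental root %s is not in the ontology", dev_root))
  }
  subtree <- dev_subtree(onto, dev_root)

  rec <- filter_evidence(mouse_records, policy)
  rec <- rec[!.has_not(rec$qualifiers), , drop = FALSE]
  if (!is.null(taxon) && nrow(rec)) {
    ok <- !nzchar(rec$taxon) | grepl(taxon, rec$taxon, fixed = TRUE)
    rec <- rec[ok, , drop = FALSE]
  }
  # resolve alt_ids before the subtree test
  if (nrow(rec) && length(onto$alt_map)) {
    hit <- match(rec$term_id, names(onto$alt_map))
    rec$term_id[!is.na(hit)] <- unname(onto$alt_map[hit[!is.na(hit)]])
  }
  rec <- rec[rec$term_id %in% subtree, , drop = FALSE]

  hit <- match(rec$symbol, map$mouse_symbol)
  rec <- rec[!is.na(hit), , drop = FALSE]
  human <- map$human_symbol[hit[!is.na(hit)]]

  if (!nrow(rec)) {
    return(annotation_prototype())
  }
  out <- rec %>%
    mutate(
      with_from = .data$references,
      symbol = .norm_symbol(human),
      object_id = .norm_symbol(human),
      taxon = "taxon:9606",
      assigned_by = "goforge-ortholog-transfer",
      provenance = "ORTHOLOG",
      provenances = list("ORTHOLOG")
    )
  consolidate(out)
}
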