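# GAF 2.0 reading, writing, filtering, consolidation, symbol mapping.

PROVENANCE_LEVELS <- c("BASELINE", "CURATED_ELIGIBLE", "CURATED_GONE", "ORTHOLOG")

GAF_COLUMNS <- c(
  "db", "object_id", "symbol", "qualifier", "term_id", "references",
  "evidence_code", "with_from", "aspect", "object_name", "synonym",
  "object_type", "taxon", "date", "assigned_by", "annotation_extension",
  "gene_product_form_id"
)

.sidecar_re <- "^!goforge-provenance:\\s*(\\d+)\\s+(\\S+)\\s*$"

# empty annotation tibble with the full column prototype
annotation_prototype <- function() {
  proto <- as.list(setNames(rep(list(character()), length(GAF_COLUMNS)), GAF_COLUMNS))
  proto$qualifier <- NULL
  tibble(
    db = character(), object_id = character(), symbol = character(),
    qualifiers = list(), term_id = character(), references = character(),
    evidence_code = character(), with_from = character(), aspect = character(),
    object_name = character(), synonym = character(), object_type = character(),
    taxon = character(), date = character(), assigned_by = character(),
    annotation_extension = character(), gene_product_form_id = character(),
    provenance = character(), provenances = list()
  )
}

#' Read a GAF 2.0 annotation file
#'
#' One [tibble][tibble::tibble] row per data line, with the 17 GAF 2.0 columns
#' plus a provenance tag. The qualifier column is split on `|` into a
#' list-column `qualifiers` (so `NOT|contributes_to` becomes
#' `c("NOT", "contributes_to")`). Lines beginning with `!` are comments;
#' a `!goforge-provenance:` comment block written by [write_gaf()] is honoured
#' so provenance survives a round trip.
#'
#' Records with an evidence code outside the known GO set are retained with a
#' warning — they stay visible to corpus audits but are rejected by every
#' [evidence_policy()].
#'
#' @param path path to a GAF 2.0 file (tab-delimited, 17 columns).
#' @param provenance default provenance for records without a sidecar tag; one
#'   of `r paste(PROVENANCE_LEVELS, collapse = ", ")`.
#' @return annotation tibble.
#' @export
read_gaf <- function(path, provenance = "BASELINE") {
  .assert_file_exists(path)
  provenance <- match.arg(provenance, PROVENANCE_LEVELS)
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "!")
  data_lines <- lines[!is_comment & nzchar(lines)]
  if (!length(data_lines)) {
    return(annotation_prototype())
  }

  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  # strsplit drops trailing empty columns (extension / gene-product form are
  # routinely empty); pad 15- and 16-field lines back out to 17
  pad <- n_fields %in% c(15L, 16L)
  fields[pad] <- lapply(fields[pad], function(x) c(x, rep("", 17L - length(x))))
  n_fields <- lengths(fields)
  if (any(n_fields != 17L)) {
    bad <- which(!is_comment & nzchar(lines))[which(n_fields != 17L)[1L]]
    abort(sprintf("GAF parse error at line %d: expected 17 columns, got %d",
      bad, n_fields[n_fields != 17L][1L]
    ))
  }

  mat <- do.call(rbind, fields)
  colnames(mat) <- GAF_COLUMNS
  rec <- as_tibble(mat)
  rec <- rec %>%
    mutate(
      qualifiers = lapply(strsplit(.data$qualifier, "|", fixed = TRUE), function(q) q[nzchar(q)]),
      provenances = list(provenance),
      provenance = provenance
    ) %>%
    select(-"qualifier") %>%
    select(all_of(names(annotation_prototype())))

  # provenance sidecar: "!goforge-provenance: <record index> <P1|P2|...>"
  side <- lines[grepl(.sidecar_re, lines)]
  if (length(side)) {
    idx <- as.integer(sub(.sidecar_re, "\\1", side))
    provs <- strsplit(sub(.sidecar_re, "\\2", side), "|", fixed = TRUE)
    ok <- idx >= 1L & idx <= nrow(rec)
    rec$provenances[idx[ok]] <- provs[ok]
    rec$provenance[idx[ok]] <- vapply(provs[ok], function(p) p[[1L]], "")
  }

  bad_terms <- !is_go_accession(rec$term_id)
  if (any(bad_terms)) {
    abort(sprintf("invalid GO accession in GAF column 5: %s", rec$term_id[bad_terms][1L]))
  }
  unknown <- setdiff(unique(rec$evidence_code), GO_EVIDENCE_CODES)
  if (length(unknown)) {
    warn(sprintf("unknown evidence code(s) retained: %s", paste(unknown, collapse = ", ")))
  }
  rec
}

#' Write annotations to a GAF 2.0 file
#'
#' Inverse of [read_gaf()]: `read_gaf(write_gaf(records))` reproduces the
#' records field-for-field. Provenance, which has no GAF column, is stored in a
#' trailing comment block of `!goforge-provenance:` lines keyed by record
#' index.
#'
#' @param records annotation tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(records, path) {
  lines <- "!gaf-version: 2.0"
  if (nrow(records)) {
    qual <- vapply(records$qualifiers, paste, "", collapse = "|")
    body <- records %>%
      mutate(qualifier = qual) %>%
      select(all_of(GAF_COLUMNS))
    lines <- c(lines, do.call(paste, c(as.list(body), sep = "\t")))
    provs <- vapply(records$provenances, paste, "", collapse = "|")
    lines <- c(lines, sprintf("!goforge-provenance: %d %s", seq_len(nrow(records)), provs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Filter annotations by an evidence-code policy
#'
#' Keeps exactly the records whose evidence code is whitelisted and not in any
#' expanded blacklist family; input order is preserved. Idempotent.
#'
#' @param records annotation tibble.
#' @param policy an [evidence_policy()].
#' @return filtered annotation tibble.
#' @export
filter_evidence <- function(records, policy) {
  stopifnot(inherits(policy, "evidence_policy"))
  records %>%
    filter(
      .data$evidence_code %in% policy$whitelist,
      !.data$evidence_code %in% policy$blacklist
    )
}

.has_not <- function(qualifiers) {
  vapply(qualifiers, function(q) "NOT" %in% q, logical(1))
}

#' Consolidate duplicate annotations across sources
#'
#' Annotations appearing in more than one source (e.g. curated and
#' ortholog-derived) collapse to a single record. The uniqueness key is
#' `(symbol, term_id, NOT-status)` — gene-set semantics depend only on
#' gene–term pairs and their sign, not on references or dates. The surviving
#' record keeps the first occurrence's fields; its `provenances` list-column
#' becomes the sorted union over the group and `provenance` its first element.
#'
#' @param records annotation tibble.
#' @return consolidated annotation tibble; `nrow()` equals the number of
#'   distinct `(symbol, term_id, NOT-status)` triples.
#' @export
consolidate <- function(records) {
  if (!nrow(records)) {
    return(records)
  }
  records %>%
    mutate(.not = .has_not(.data$qualifiers)) %>%
    group_by(.data$symbol, .data$term_id, .data$.not) %>%
    mutate(.merged_prov = list(sort(unique(unlist(.data$provenances))))) %>%
    slice(1L) %>%
    ungroup() %>%
    mutate(
      provenances = .data$.merged_prov,
      provenance = vapply(.data$.merged_prov, function(p) p[[1L]], "")
    ) %>%
    select(-".not", -".merged_prov")
}

#' Read a two-column accession-to-symbol mapping table
#'
#' @param path tab-delimited file with accession and symbol columns (no
#'   header).
#' @return tibble with columns `object_id`, `symbol`.
#' @export
read_id_map <- function(path) {
  .assert_file_exists(path)
  readr::read_tsv(path,
    col_names = c("object_id", "symbol"),
    col_types = "cc", progress = FALSE
  )
}

#' Overwrite gene symbols from an accession-to-symbol map
#'
#' Records whose `object_id` appears in the map get their `symbol` replaced;
#' the rest pass through untouched and are reported via the `"unmapped"`
#' attribute and a message. Applying the same map twice equals applying it
#' once.
#'
#' @param records annotation tibble.
#' @param id_map tibble with columns `object_id`, `symbol` (see
#'   [read_id_map()]).
#' @param quiet suppress the unmapped-count message.
#' @return annotation tibble with updated symbols; unmapped records (original
#'   form) attached as `attr(, "unmapped")`.
#' @export
map_symbols <- function(records, id_map, quiet = FALSE) {
  stopifnot(all(c("object_id", "symbol") %in% names(id_map)))
  hit <- match(records$object_id, id_map$object_id)
  out <- records
  out$symbol[!is.na(hit)] <- id_map$symbol[hit[!is.na(hit)]]
  unmapped <- records[is.na(hit), ]
  if (!quiet && nrow(unmapped)) {
    inform(sprintf("map_symbols: %d of %d records had no mapping", nrow(unmapped), nrow(records)))
  }
  attr(out, "unmapped") <- unmapped
  out
}
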