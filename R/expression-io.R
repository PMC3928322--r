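# On-disk forms for expression input: tab-delimited matrix + CLS-style class
# file, and two-column ranked lists.

#' Read / write a two-class expression dataset
#'
#' The matrix file is tab-delimited with a header row of sample ids and gene
#' symbols in the first column. The class file is CLS-style: a counts line
#' (`n_samples n_classes 1`) followed by a line of space-separated 0/1 labels.
#'
#' @param expr_path matrix file path.
#' @param cls_path class file path.
#' @return `read_expression()`: an [expression_dataset()].
#' @export
read_expression <- function(expr_path, cls_path) {
  .assert_file_exists(expr_path)
  .assert_file_exists(cls_path)
  tbl <- utils::read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(mat) <- tbl[[1]]
  cls <- readLines(cls_path, warn = FALSE)
  cls <- cls[!startsWith(cls, "#") & nzchar(cls)]
  if (length(cls) < 2) {
    abort("class file must have a counts line and a label line")
  }
  labels <- as.integer(strsplit(trimws(cls[[2]]), "\\s+")[[1]])
  expression_dataset(mat, labels)
}

#' @rdname read_expression
#' @param dataset an `expression_dataset`.
#' @return `write_expression()`: the paths, invisibly.
#' @export
write_expression <- function(dataset, expr_path, cls_path) {
  df <- data.frame(gene = dataset$genes, dataset$matrix, check.names = FALSE)
  utils::write.table(df, expr_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(c(
    sprintf("%d 2 1", length(dataset$labels)),
    paste(dataset$labels, collapse = " ")
  ), cls_path)
  invisible(c(expr_path, cls_path))
}

#' Read / write a ranked gene list
#'
#' Two-column tab-delimited file: gene symbol, ranking score.
#'
#' @param path file path.
#' @return `read_ranked()`: a `ranked_list`.
#' @export
read_ranked <- function(path) {
  .assert_file_exists(path)
  tbl <- readr::read_tsv(path, col_names = c("gene", "score"), col_types = "cd", progress = FALSE)
  new_ranked_list(.norm_symbol(tbl$gene), tbl$score)
}

#' @rdname read_ranked
#' @param ranked a `ranked_list`.
#' @export
write_ranked <- function(ranked, path) {
  readr::write_tsv(as_tibble(ranked), path, col_names = FALSE)
  invisible(path)
}
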