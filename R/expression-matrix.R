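#' Construct an expression matrix
#'
#' The package's central data structure is a plain numeric matrix with genes
#' as rows and samples as columns, carrying gene identifiers as rownames and
#' sample identifiers as colnames. Values are assumed to be on a log scale
#' and already normalized upstream (e.g. RMA); the package performs no
#' normalization itself.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique gene identifiers (rownames).
#' @param sample_ids character vector of unique sample identifiers (colnames).
#' @return A validated numeric matrix with dimnames set.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2, byrow = TRUE),
#'                        gene_ids = c("g1", "g2", "g3"),
#'                        sample_ids = c("s1", "s2"))
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  validate_expression_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the invariants every pipeline stage relies on: a numeric matrix,
#' unique non-missing gene and sample identifiers, and no missing or
#' non-finite values.
#'
#' @param x candidate matrix.
#' @param what label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must carry gene ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1L]
    stop(what, ": duplicate gene ID '", dup, "'", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- colnames(x)[duplicated(colnames(x))][1L]
    stop(what, ": duplicate sample ID '", dup, "'", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(what, ": non-finite value at gene '", rownames(x)[bad[1L]],
         "', sample '", colnames(x)[bad[2L]], "'", call. = FALSE)
  }
  invisible(x)
}

#' Restrict an expression matrix to a gene list
#'
#' Subsets the matrix to the listed genes, in list order — the analogue of
#' restricting a compendium to a curated metabolic gene set before ICA.
#' Listed genes absent from the matrix are reported with a warning and
#' dropped.
#'
#' @param matrix expression matrix (see [expression_matrix()]).
#' @param gene_list character vector of gene ids, non-empty.
#' @return The row-subset expression matrix, rows in `gene_list` order.
#' @export
select_genes <- function(matrix, gene_list) {
  validate_expression_matrix(matrix)
  gene_list <- as.character(gene_list)
  if (length(gene_list) == 0L) {
    stop("gene_list must be non-empty", call. = FALSE)
  }
  gene_list <- unique(gene_list)
  missing <- setdiff(gene_list, rownames(matrix))
  if (length(missing) == length(gene_list)) {
    stop("empty selection: none of the listed genes are in the matrix",
         call. = FALSE)
  }
  if (length(missing) > 0L) {
    warning("gene list entries absent from matrix: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- gene_list[gene_list %in% rownames(matrix)]
  matrix[keep, , drop = FALSE]
}
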