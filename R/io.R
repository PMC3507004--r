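#' Read a genes-by-samples expression TSV
#'
#' Parses the flat tab-separated layout used by pre-processed expression
#' compendia: a header row whose first cell names the ID column followed by
#' one sample ID per column, then one row per gene (gene ID, then one numeric
#' value per sample). Lines starting with `#` are treated as comments (the
#' package's own writers emit a provenance comment line).
#'
#' @param path path to the TSV file.
#' @param impute how to handle missing cells: `"reject"` (default) errors on
#'   any missing/non-numeric value; `"row-mean"` replaces missing values with
#'   the gene's row mean.
#' @return An expression matrix (numeric matrix with gene/sample dimnames).
#' @seealso [write_expression_tsv()]
#' @export
read_expression_tsv <- function(path, impute = c("reject", "row-mean")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("format error: expected a header row and at least one gene row in ",
         path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  if (n_col < 2L) {
    stop("format error: header must name the ID column and at least one sample",
         call. = FALSE)
  }
  sample_ids <- header[-1L]
  rows <- fields[-1L]
  widths <- lengths(rows)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1L]
    stop("format error: ragged row ", bad + 1L, " has ", widths[bad],
         " fields, expected ", n_col, call. = FALSE)
  }
  gene_ids <- vapply(rows, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop("format error: duplicate gene ID '", dup, "'", call. = FALSE)
  }
  raw <- vapply(rows, function(r) r[-1L], character(n_col - 1L))
  raw <- matrix(raw, nrow = n_col - 1L) # columns = genes
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(values) & !(raw %in% c("NA", "nan", "NaN", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("format error: non-numeric cell '", raw[bad[1L, 1L], bad[1L, 2L]],
         "' at row ", bad[1L, 2L] + 1L, ", column ", bad[1L, 1L] + 1L,
         call. = FALSE)
  }
  values <- t(values) # genes x samples
  dimnames(values) <- list(gene_ids, sample_ids)
  if (anyNA(values)) {
    if (impute == "reject") {
      miss <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", gene_ids[miss[1L]], "', sample '",
           sample_ids[miss[2L]], "' (use impute = \"row-mean\" to impute)",
           call. = FALSE)
    }
    for (i in seq_len(nrow(values))) {
      na_j <- is.na(values[i, ])
      if (any(na_j)) {
        if (all(na_j)) {
          stop("cannot impute gene '", gene_ids[i], "': all values missing",
               call. = FALSE)
        }
        values[i, na_j] <- mean(values[i, !na_j])
      }
    }
  }
  validate_expression_matrix(values)
  values
}

#' Write an expression matrix as TSV
#'
#' Values are serialized with `%.17g` so a read/write round trip is
#' bit-exact. An optional `#`-prefixed provenance comment can be prepended;
#' [read_expression_tsv()] skips such lines.
#'
#' @param matrix expression matrix.
#' @param path output path.
#' @param id_column name of the first header cell.
#' @param comment optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path, id_column = "gene_id",
                                 comment = NULL) {
  validate_expression_matrix(matrix)
  header <- paste(c(id_column, colnames(matrix)), collapse = "\t")
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], sprintf("%.17g", matrix[i, ])),
          collapse = "\t")
  }, character(1L))
  lines <- c(if (!is.null(comment)) paste0("# ", comment), header, body)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a gene list (one ID per line, '#' comments allowed)
#'
#' @param path path to the list file.
#' @return Character vector of gene ids in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Export a clustered signature matrix in Cluster 3.0 CDT/GTR dialect
#'
#' Writes `<path_stem>.cdt` (the signature table with gene rows reordered by
#' dendrogram leaf order and a GID column linking rows to tree nodes) and
#' `<path_stem>.gtr` (one merge per line: node id, two child ids, similarity
#' at the merge), the file pair Java TreeView loads.
#'
#' @param signature numeric matrix with gene ids as rownames (typically the
#'   gene signature matrix S).
#' @param dendrogram a dendrogram from [hca()] over the same genes.
#' @param path_stem output path without extension.
#' @return Invisibly, a list with the `cdt` and `gtr` paths.
#' @export
write_cdt_gtr <- function(signature, dendrogram, path_stem) {
  stopifnot(inherits(dendrogram, "gene_dendrogram"))
  genes <- rownames(signature)
  if (is.null(genes) || !setequal(genes, dendrogram$leaves) ||
      length(genes) != length(dendrogram$leaves)) {
    stop("consistency error: dendrogram leaves and signature rows differ",
         call. = FALSE)
  }
  n <- length(genes)
  gid <- paste0("GENE", seq_len(n) - 1L, "X")
  names(gid) <- dendrogram$leaves # leaf i (input order) -> GENEiX

  merges <- dendrogram$merges
  node_name <- function(id) {
    # leaves are 1..n, internal nodes n+1 .. 2n-1
    ifelse(id <= n, gid[dendrogram$leaves[id]],
           paste0("NODE", id - n, "X"))
  }
  gtr <- vapply(seq_len(nrow(merges)), function(i) {
    paste(c(paste0("NODE", i, "X"),
            node_name(merges$left[i]),
            node_name(merges$right[i]),
            sprintf("%.6g", merges$similarity[i])),
          collapse = "\t")
  }, character(1L))
  gtr_path <- paste0(path_stem, ".gtr")
  writeLines(gtr, gtr_path, useBytes = TRUE)

  ord <- dendrogram$leaf_order
  cols <- colnames(signature)
  if (is.null(cols)) cols <- paste0("IC", seq_len(ncol(signature)))
  cdt_header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", cols),
                      collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "",
                     rep("1", length(cols))), collapse = "\t")
  leaf_ids <- dendrogram$leaves[ord]
  body <- vapply(seq_along(ord), function(r) {
    g <- leaf_ids[r]
    paste(c(gid[g], g, g, "1", sprintf("%.6g", signature[g, ])),
          collapse = "\t")
  }, character(1L))
  cdt_path <- paste0(path_stem, ".cdt")
  writeLines(c(cdt_header, eweight, body), cdt_path, useBytes = TRUE)
  invisible(list(cdt = cdt_path, gtr = gtr_path))
}

#' Write a flat cluster assignment as TSV
#'
#' @param assignment a cluster assignment from [cut_tree()].
#' @param path output path.
#' @param comment optional comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(assignment, path, comment = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  lines <- c(if (!is.null(comment)) paste0("# ", comment),
             "gene_id\tcluster",
             paste(names(assignment$labels), assignment$labels, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
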