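#' Pearson product-moment correlation
#'
#' Thin validated wrapper used by the guide-gene screen: requires at least 3
#' paired observations and nonzero variance in both vectors.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Sample Pearson correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate input: constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Guide-gene coexpression screen
#'
#' For every non-guide gene, computes the Pearson correlation with each guide
#' gene across all samples and counts guides with `r > threshold` (strict,
#' positive correlations only). A gene passes when it links to at least
#' `min_links` guides — the classic candidate-nomination rule for extending a
#' pathway gene set from known members. A two-sided t-approximation p-value
#' is reported per link for information only; filtering is by `r` alone, with
#' no multiple-testing correction.
#'
#' @param matrix expression matrix (genes x samples, >= 3 samples).
#' @param guides character vector of guide gene ids, all present in `matrix`.
#' @param threshold correlation cutoff (default 0.525), strict inequality.
#' @param min_links minimum number of passing guide links (default 2).
#' @return A `screen_result` tibble, one row per candidate (non-guide) gene,
#'   sorted by (`n_links_passing` desc, `best_r` desc, `gene_id` asc), with
#'   columns `gene_id`, `n_links_passing`, `passes`, `best_guide`, `best_r`,
#'   and `links` (list column: tibble of guide/r/p_value per candidate).
#'   Attributes `threshold`, `min_links` and `guides` record the screen.
#' @examples
#' sim <- generate_expression(synthetic_spec(n_genes = 100, n_samples = 50,
#'                                           modules = c(a = 6)))
#' members <- dplyr::filter(sim$truth$module_of_gene, module == "a")$gene_id
#' screen_candidates(sim$matrix, guides = members[1:3])
#' @export
screen_candidates <- function(matrix, guides, threshold = 0.525,
                              min_links = 2L) {
  validate_expression_matrix(matrix)
  guides <- as.character(guides)
  absent <- setdiff(guides, rownames(matrix))
  if (length(absent) > 0L) {
    stop("guide gene(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  candidates <- setdiff(rownames(matrix), guides)
  if (length(candidates) == 0L) {
    stop("no non-guide genes to screen", call. = FALSE)
  }
  n <- ncol(matrix)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)

  r_mat <- stats::cor(t(matrix[candidates, , drop = FALSE]),
                      t(matrix[guides, , drop = FALSE]))
  # two-sided p from the t transform of r (information only)
  tstat <- r_mat * sqrt((n - 2) / pmax(1 - r_mat^2, .Machine$double.eps))
  p_mat <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)

  n_pass <- unname(rowSums(r_mat > threshold))
  best_j <- apply(r_mat, 1L, which.max)
  result <- tibble::tibble(
    gene_id = candidates,
    n_links_passing = as.integer(n_pass),
    passes = n_pass >= min_links,
    best_guide = guides[best_j],
    best_r = r_mat[cbind(seq_along(candidates), best_j)],
    links = lapply(seq_along(candidates), function(i) {
      tibble::tibble(guide = guides, r = unname(r_mat[i, ]),
                     p_value = unname(p_mat[i, ]))
    })
  )
  result <- dplyr::arrange(result, dplyr::desc(.data$n_links_passing),
                           dplyr::desc(.data$best_r), .data$gene_id)
  attr(result, "threshold") <- threshold
  attr(result, "min_links") <- as.integer(min_links)
  attr(result, "guides") <- guides
  class(result) <- c("screen_result", class(result))
  result
}

#' Write a screen result as TSV
#'
#' One row per candidate: `gene_id`, `n_links_passing`, `passes`,
#' `best_guide`, `best_r`, and all links serialized as `guide:r;...`.
#'
#' @param screen a [screen_candidates()] result.
#' @param path output path.
#' @param comment optional comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path, comment = NULL) {
  stopifnot(inherits(screen, "screen_result"))
  link_str <- vapply(screen$links, function(l) {
    paste(sprintf("%s:%.6g", l$guide, l$r), collapse = ";")
  }, character(1L))
  lines <- c(if (!is.null(comment)) paste0("# ", comment),
             "gene_id\tn_links_passing\tpasses\tbest_guide\tbest_r\tlinks",
             sprintf("%s\t%d\t%s\t%s\t%.17g\t%s",
                     screen$gene_id, screen$n_links_passing,
                     ifelse(screen$passes, "TRUE", "FALSE"),
                     screen$best_guide, screen$best_r, link_str))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
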