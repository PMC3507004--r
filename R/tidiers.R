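#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fastICA decomposition
#'
#' @param x an `ica_decomposition`.
#' @param matrix which factor to tidy: `"S"` (gene signatures, default) or
#'   `"A"` (mixing matrix).
#' @param ... unused.
#' @return Long tibble: `gene_id`/`sample_id`, `component`, `value`.
#' @export
tidy.ica_decomposition <- function(x, matrix = c("S", "A"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "S") {
    tibble::as_tibble(x$S, rownames = "gene_id") |>
      tidyr::pivot_longer(-"gene_id", names_to = "component",
                          values_to = "value")
  } else {
    tibble::as_tibble(t(x$A), rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "component",
                          values_to = "value")
  }
}

#' One-row summary of a fastICA decomposition
#'
#' @param x an `ica_decomposition`.
#' @param ... unused.
#' @return Tibble: `k`, `n_genes`, `n_samples`, `contrast`, `alpha`,
#'   `converged`, `iterations`, `tolerance_achieved`, `seed`.
#' @export
glance.ica_decomposition <- function(x, ...) {
  tibble::tibble(k = x$k, n_genes = nrow(x$S), n_samples = ncol(x$A),
                 contrast = x$contrast, alpha = x$alpha,
                 converged = x$converged, iterations = x$iterations,
                 tolerance_achieved = x$tolerance_achieved, seed = x$seed)
}

#' Tidy a dendrogram's merge records
#'
#' @param x a `gene_dendrogram`.
#' @param ... unused.
#' @return The merge tibble: `node`, `left`, `right`, `distance`,
#'   `similarity`.
#' @export
tidy.gene_dendrogram <- function(x, ...) x$merges

#' Tidy a flat cluster assignment
#'
#' @param x a `cluster_assignment`.
#' @param ... unused.
#' @return Tibble: `gene_id`, `cluster`.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble::tibble(gene_id = names(x$labels), cluster = unname(x$labels))
}

#' Tidy a screen result into one row per candidate-guide link
#'
#' @param x a `screen_result`.
#' @param ... unused.
#' @return Tibble: `gene_id`, `guide`, `r`, `p_value`, `passes_link`
#'   (whether this link clears the threshold).
#' @export
tidy.screen_result <- function(x, ...) {
  threshold <- attr(x, "threshold")
  tibble::tibble(gene_id = x$gene_id, links = x$links) |>
    tidyr::unnest("links") |>
    dplyr::mutate(passes_link = .data$r > threshold)
}

#' One-row summary of a screen result
#'
#' @param x a `screen_result`.
#' @param ... unused.
#' @return Tibble: `n_candidates`, `n_passing`, `threshold`, `min_links`,
#'   `n_guides`.
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x), n_passing = sum(x$passes),
                 threshold = attr(x, "threshold"),
                 min_links = attr(x, "min_links"),
                 n_guides = length(attr(x, "guides")))
}

#' Tidy a recovery report (one row per planted module)
#'
#' @param x a `recovery_report`.
#' @param ... unused.
#' @return The per-module tibble with `k` and `ari` columns prepended.
#' @export
tidy.recovery_report <- function(x, ...) {
  dplyr::mutate(x$per_module, k = x$k, ari = x$ari, .before = 1L)
}

#' One-row summary of a recovery report
#'
#' @param x a `recovery_report`.
#' @param ... unused.
#' @return Tibble: `k`, `ari`, `mean_jaccard`, `min_jaccard`, `n_modules`.
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(k = x$k, ari = x$ari,
                 mean_jaccard = mean(x$per_module$jaccard),
                 min_jaccard = min(x$per_module$jaccard),
                 n_modules = nrow(x$per_module))
}

#' Tidy an IC-number sweep (one row per k and module)
#'
#' @param x an `ic_sweep`.
#' @param ... unused.
#' @return Row-bound [tidy.recovery_report()] tibbles.
#' @export
tidy.ic_sweep <- function(x, ...) {
  purrr::map_dfr(x$reports, tidy)
}

#' Per-k summary of an IC-number sweep
#'
#' @param x an `ic_sweep`.
#' @param ... unused.
#' @return Row-bound [glance.recovery_report()] tibbles, one row per k.
#' @export
glance.ic_sweep <- function(x, ...) {
  purrr::map_dfr(x$reports, glance)
}
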