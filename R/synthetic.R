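#' Specify a synthetic expression matrix with planted modules
#'
#' Describes the generative world the test suite exercises: a large
#' background gene set plus a few small co-regulated modules, each driven by
#' one sparse, super-Gaussian latent activation signal across samples — the
#' statistical situation in which pathway modules are identifiable by ICA
#' (pathway genes are induced together in a minority of conditions).
#'
#' @param n_genes total number of genes (rows).
#' @param n_samples number of samples (columns).
#' @param modules named integer vector of module sizes, e.g.
#'   `c(anthocyanin = 8, modification = 6, flavonol = 10)`.
#' @param source_distribution latent activation distribution: `"laplace"`
#'   (unit-variance Laplace) or `"sparse-spike"` (zero except in a ~10% of
#'   samples, unit variance). Both are super-Gaussian (excess kurtosis 3 and
#'   27 respectively), as ICA identifiability requires.
#' @param loading_strength loading of a module gene on its module's source;
#'   with unit-variance sources this is the signal standard deviation.
#' @param cross_loading fraction (0..1) of `loading_strength` that a
#'   dual-membership gene puts on its second module.
#' @param dual_genes list of 2-element character vectors naming module pairs;
#'   each entry plants one extra gene loading on both modules (primary label
#'   = first module).
#' @param noise_sd standard deviation of the i.i.d. Gaussian measurement
#'   noise added to every entry (>= 0).
#' @param baseline_sd standard deviation of background-gene variation.
#' @param seed integer RNG seed; identical spec => identical matrix.
#' @return A `synthetic_spec` list, validated.
#' @export
synthetic_spec <- function(n_genes = 1000L,
                           n_samples = 200L,
                           modules = c(anthocyanin = 8L, modification = 6L,
                                       flavonol = 10L),
                           source_distribution = c("laplace", "sparse-spike"),
                           loading_strength = 1.0,
                           cross_loading = 0.0,
                           dual_genes = list(),
                           noise_sd = 0.3,
                           baseline_sd = 0.1,
                           seed = 7L) {
  source_distribution <- match.arg(source_distribution)
  spec <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    modules = modules, source_distribution = source_distribution,
    loading_strength = loading_strength, cross_loading = cross_loading,
    dual_genes = dual_genes, noise_sd = noise_sd, baseline_sd = baseline_sd,
    seed = as.integer(seed)
  )
  if (spec$n_genes < 1L || spec$n_samples < 1L) {
    stop("n_genes and n_samples must be positive", call. = FALSE)
  }
  if (is.null(names(modules)) || anyDuplicated(names(modules))) {
    stop("modules must be a named vector with unique module names",
         call. = FALSE)
  }
  n_planted <- sum(modules) + length(dual_genes)
  if (n_planted > spec$n_genes) {
    stop("spec error: module member counts (", n_planted,
         ") exceed n_genes (", spec$n_genes, ")", call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (spec$cross_loading < 0 || spec$cross_loading > 1) {
    stop("cross_loading must lie in [0, 1]", call. = FALSE)
  }
  for (d in dual_genes) {
    if (length(d) != 2L || !all(d %in% names(modules))) {
      stop("each dual_genes entry must name two planted modules",
           call. = FALSE)
    }
  }
  structure(spec, class = "synthetic_spec")
}

# unit-variance super-Gaussian draws
draw_source <- function(n, distribution) {
  switch(distribution,
    "laplace" = {
      u <- stats::runif(n) - 0.5
      -sign(u) * log(1 - 2 * abs(u)) / sqrt(2) # Laplace(0, 1/sqrt(2)), var 1
    },
    "sparse-spike" = {
      p <- 0.1
      on <- stats::rbinom(n, 1L, p)
      on * stats::rnorm(n) / sqrt(p)
    },
    stop("unknown source distribution: ", distribution, call. = FALSE)
  )
}

#' Generate an expression matrix with planted module structure
#'
#' Simulates `X = loadings %*% sources + noise`: each module's member genes
#' load `loading_strength` on that module's latent source, background genes
#' load on nothing and vary independently with `baseline_sd`, dual-membership
#' genes load on two sources (the second scaled by `cross_loading`), and
#' i.i.d. Gaussian noise of sd `noise_sd` is added throughout. Gene row order
#' is shuffled under the seed so module members do not sit at contiguous
#' indices. Noise is drawn after all signal randomness, so raising `noise_sd`
#' with a fixed seed perturbs the same signal realization.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{matrix}{the genes x samples expression matrix;}
#'     \item{truth}{a `synthetic_truth` object: `module_of_gene` (tibble
#'       gene_id/module, background rows labelled `"background"`),
#'       `sources` (modules x samples latent activations), `loadings`
#'       (genes x modules), and `dual_genes` (tibble gene_id/primary/
#'       secondary).}
#'   }
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- spec$n_genes
  n <- spec$n_samples
  mods <- spec$modules
  k <- length(mods)

  sources <- matrix(0, k, n,
                    dimnames = list(names(mods), sprintf("S%04d", seq_len(n))))
  for (j in seq_len(k)) {
    sources[j, ] <- draw_source(n, spec$source_distribution)
  }

  loadings <- matrix(0, m, k)
  module_of_gene <- rep("background", m)
  idx <- 1L
  for (j in seq_len(k)) {
    members <- idx:(idx + mods[[j]] - 1L)
    loadings[members, j] <- spec$loading_strength
    module_of_gene[members] <- names(mods)[j]
    idx <- idx + mods[[j]]
  }
  dual_rows <- integer(0)
  dual_info <- list()
  for (d in spec$dual_genes) {
    loadings[idx, match(d[1L], names(mods))] <- spec$loading_strength
    loadings[idx, match(d[2L], names(mods))] <-
      spec$loading_strength * spec$cross_loading
    module_of_gene[idx] <- d[1L]
    dual_rows <- c(dual_rows, idx)
    dual_info[[length(dual_info) + 1L]] <-
      list(row = idx, primary = d[1L], secondary = d[2L])
    idx <- idx + 1L
  }

  x <- loadings %*% sources
  background <- module_of_gene == "background"
  if (spec$baseline_sd > 0 && any(background)) {
    x[background, ] <- x[background, , drop = FALSE] +
      matrix(stats::rnorm(sum(background) * n, sd = spec$baseline_sd),
             sum(background), n)
  }
  # row shuffle before noise so the noise stream is tied to final gene ids
  perm <- sample.int(m)
  x <- x[perm, , drop = FALSE]
  loadings <- loadings[perm, , drop = FALSE]
  module_of_gene <- module_of_gene[perm]

  if (spec$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(m * n, sd = spec$noise_sd), m, n)
  }

  gene_ids <- sprintf("G%04d", seq_len(m))
  dimnames(x) <- list(gene_ids, colnames(sources))
  dimnames(loadings) <- list(gene_ids, names(mods))

  dual_tbl <- tibble::tibble(
    gene_id = gene_ids[match(vapply(dual_info, function(d) as.integer(d$row),
                                    integer(1L)), perm)],
    primary = vapply(dual_info, `[[`, character(1L), "primary"),
    secondary = vapply(dual_info, `[[`, character(1L), "secondary")
  )

  truth <- structure(
    list(
      module_of_gene = tibble::tibble(gene_id = gene_ids,
                                      module = module_of_gene),
      sources = sources,
      loadings = loadings,
      dual_genes = dual_tbl,
      spec = spec
    ),
    class = "synthetic_truth"
  )
  list(matrix = x, truth = truth)
}

#' Sample excess kurtosis
#'
#' Fourth standardized sample moment minus 3; the non-Gaussianity check used
#' to confirm that latent activation signals are super-Gaussian (positive
#' excess kurtosis), the property fastICA's contrast exploits.
#'
#' @param values numeric vector, length >= 4, non-constant.
#' @return Sample excess kurtosis (0 for a Gaussian, 3 for Laplace, -2 for a
#'   symmetric two-point distribution).
#' @export
excess_kurtosis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L) {
    stop("need at least 4 values", call. = FALSE)
  }
  v <- stats::var(values) * (length(values) - 1) / length(values)
  if (v <= 0) {
    stop("degenerate input: constant vector has no kurtosis", call. = FALSE)
  }
  m <- mean(values)
  mean((values - m)^4) / v^2 - 3
}

#' Write the planted truth labels as TSV
#'
#' @param truth a `synthetic_truth` from [generate_expression()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  lines <- c("gene_id\tmodule",
             paste(truth$module_of_gene$gene_id,
                   truth$module_of_gene$module, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read planted truth labels from TSV
#'
#' @param path path to a truth TSV written by [write_truth_tsv()].
#' @return A minimal `synthetic_truth` holding only `module_of_gene`.
#' @export
read_truth_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), module = readr::col_character()
  ), comment = "#", progress = FALSE)
  structure(list(module_of_gene = tibble::as_tibble(tbl),
                 sources = NULL, loadings = NULL,
                 dual_genes = tibble::tibble(gene_id = character(0),
                                             primary = character(0),
                                             secondary = character(0)),
                 spec = NULL),
            class = "synthetic_truth")
}
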