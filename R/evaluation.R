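# coerce assignment/truth into aligned label vectors over the same genes
aligned_labels <- function(assignment, truth, foreground_only = FALSE) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(truth, "synthetic_truth"))
  genes_a <- names(assignment$labels)
  genes_t <- truth$module_of_gene$gene_id
  if (!setequal(genes_a, genes_t)) {
    diff <- c(setdiff(genes_a, genes_t), setdiff(genes_t, genes_a))
    stop("gene universe mismatch; symmetric difference: ",
         paste(utils::head(diff, 10L), collapse = ", "),
         if (length(diff) > 10L) ", ...", call. = FALSE)
  }
  modules <- truth$module_of_gene$module[match(genes_a, genes_t)]
  keep <- rep(TRUE, length(genes_a))
  if (foreground_only) keep <- modules != "background"
  list(genes = genes_a[keep],
       clusters = unname(assignment$labels[keep]),
       modules = modules[keep])
}

#' Adjusted Rand index between a clustering and the planted truth
#'
#' Chance-corrected pair-counting agreement between the flat cluster
#' assignment and the planted module labels (background genes count as one
#' module of their own unless `foreground_only = TRUE`). 1 means identical
#' partitions; values near 0 mean chance-level agreement.
#'
#' @param assignment a [cut_tree()] result.
#' @param truth a `synthetic_truth` (or anything with a
#'   `module_of_gene` tibble over the same genes).
#' @param foreground_only drop background genes before scoring.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(assignment, truth, foreground_only = FALSE) {
  al <- aligned_labels(assignment, truth, foreground_only)
  ari_from_labels(al$clusters, al$modules)
}

# permutation-model ARI from two label vectors
ari_from_labels <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    # only reachable when both partitions are all-together or both are
    # all-singletons, i.e. identical degenerate partitions
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Per-module best-match Jaccard indices
#'
#' For each planted module, the Jaccard index against the cluster maximizing
#' it (ties broken towards the smaller cluster label).
#'
#' @inheritParams adjusted_rand_index
#' @return Tibble: `module`, `best_match_cluster`, `jaccard`, `module_size`,
#'   `cluster_size`.
#' @export
module_jaccard <- function(assignment, truth) {
  al <- aligned_labels(assignment, truth)
  modules <- setdiff(unique(al$modules), "background")
  purrr::map_dfr(modules, function(mod) {
    mod_set <- al$genes[al$modules == mod]
    labs <- sort(unique(al$clusters))
    jac <- vapply(labs, function(cl) {
      cl_set <- al$genes[al$clusters == cl]
      length(intersect(mod_set, cl_set)) / length(union(mod_set, cl_set))
    }, numeric(1L))
    best <- labs[which.max(jac)] # which.max takes the first (smallest label)
    tibble::tibble(module = mod, best_match_cluster = best,
                   jaccard = max(jac), module_size = length(mod_set),
                   cluster_size = sum(al$clusters == best))
  })
}

# planted module whose gene set best matches a given cluster; background is
# not a candidate (it would win on size alone whenever clusters are large)
best_module_of_cluster <- function(al, cluster_label) {
  cl_set <- al$genes[al$clusters == cluster_label]
  mods <- sort(setdiff(unique(al$modules), "background"))
  jac <- vapply(mods, function(mod) {
    mod_set <- al$genes[al$modules == mod]
    length(intersect(mod_set, cl_set)) / length(union(mod_set, cl_set))
  }, numeric(1L))
  mods[which.max(jac)]
}

#' Score module recovery of a clustering against planted truth
#'
#' Bundles the adjusted Rand index, per-module best-match Jaccard indices,
#' and — for planted dual-membership genes — the module best matching the
#' cluster the gene landed in.
#'
#' @inheritParams adjusted_rand_index
#' @param k the number of independent components that produced the
#'   clustering (recorded in the report).
#' @return A `recovery_report`: `k`, `ari`, `per_module` (tibble),
#'   `dual_gene_assignments` (tibble: gene_id, cluster, assigned_module).
#' @export
score_recovery <- function(assignment, truth, k = NA_integer_,
                           foreground_only = FALSE) {
  al <- aligned_labels(assignment, truth)
  ari <- adjusted_rand_index(assignment, truth, foreground_only)
  per_module <- module_jaccard(assignment, truth)
  duals <- truth$dual_genes
  if (is.null(duals)) {
    duals <- tibble::tibble(gene_id = character(0), primary = character(0),
                            secondary = character(0))
  }
  dual_assign <- purrr::map_dfr(duals$gene_id, function(g) {
    cl <- al$clusters[match(g, al$genes)]
    tibble::tibble(gene_id = g, cluster = cl,
                   assigned_module = best_module_of_cluster(al, cl))
  })
  structure(list(k = as.integer(k), ari = ari, per_module = per_module,
                 dual_gene_assignments = dual_assign),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("module recovery (k = ", x$k, "): ARI = ", signif(x$ari, 4), "\n",
      sep = "")
  print(x$per_module)
  if (nrow(x$dual_gene_assignments) > 0L) {
    cat("dual-membership gene assignments:\n")
    print(x$dual_gene_assignments)
  }
  invisible(x)
}

#' Sensitivity of module recovery to the number of independent components
#'
#' Runs the full decomposition-clustering-scoring chain for each requested
#' number of components k: [fastica()] on the matrix, [hca()] of the gene
#' signature matrix with uncentered correlation and average linkage,
#' [cut_tree()] into `n_clusters`, and [score_recovery()] against the
#' planted truth. Dual-membership gene assignments are tabulated per k so a
#' membership shift across k — the signature of a gene acting in two
#' pathways — is visible in one table.
#'
#' @param matrix expression matrix.
#' @param truth planted truth from [generate_expression()].
#' @param k_values integer vector of component numbers to try.
#' @param n_clusters flat cluster count for the cut (default: number of
#'   planted modules + 1, leaving one cluster for background).
#' @param seed seed for every fastICA initialization.
#' @param contrast a [contrast_function()].
#' @param foreground_only passed to [score_recovery()].
#' @return An `ic_sweep` object: list of `recovery_report`s (one per k), with
#'   [tidy()]/[glance()] methods and an `autoplot()`.
#' @export
ic_sweep <- function(matrix, truth, k_values, n_clusters = NULL, seed,
                     contrast = contrast_function("logcosh", 1.0),
                     foreground_only = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(n_clusters)) {
    mods <- setdiff(unique(truth$module_of_gene$module), "background")
    n_clusters <- length(mods) + 1L
  }
  reports <- purrr::map(as.integer(k_values), function(k) {
    dec <- fastica(matrix, k = k, contrast = contrast, seed = seed)
    dend <- hca(dec$S, similarity = "uncentered")
    assign <- cut_tree(dend, n_clusters = n_clusters)
    score_recovery(assign, truth, k = k, foreground_only = foreground_only)
  })
  structure(list(reports = reports, k_values = as.integer(k_values),
                 n_clusters = as.integer(n_clusters), seed = as.integer(seed)),
            class = "ic_sweep")
}

#' Dual-membership gene assignments across an IC-number sweep
#'
#' @param sweep an [ic_sweep()] result.
#' @return Tibble: `k`, `gene_id`, `cluster`, `assigned_module`.
#' @export
dual_gene_assignments <- function(sweep) {
  stopifnot(inherits(sweep, "ic_sweep"))
  purrr::map_dfr(sweep$reports, function(rep) {
    if (nrow(rep$dual_gene_assignments) == 0L) return(tibble::tibble())
    dplyr::mutate(rep$dual_gene_assignments, k = rep$k, .before = 1L)
  })
}

#' @export
print.ic_sweep <- function(x, ...) {
  cat("IC-number sweep over k = {", paste(x$k_values, collapse = ", "),
      "}, cut at ", x$n_clusters, " clusters\n", sep = "")
  print(glance(x))
  duals <- dual_gene_assignments(x)
  if (nrow(duals) > 0L) {
    cat("dual-membership gene assignments by k:\n")
    print(duals)
  }
  invisible(x)
}
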