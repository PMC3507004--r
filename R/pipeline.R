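# deterministic polynomial hash of the serialized config (provenance only)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[setdiff(names(config), "out_dir")]),
                           collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Assemble a pipeline configuration
#'
#' Every field has a default except the input: give either `matrix_path` (an
#' expression TSV to analyse) or `simulate` (a [synthetic_spec()] to
#' generate). `guides` may be a character vector of guide gene ids or a path
#' to a gene-list file; when simulating and `guides = NULL`, the first
#' planted module's first three members are used.
#'
#' @param matrix_path path to an expression TSV, or `NULL` when simulating.
#' @param simulate a [synthetic_spec()], or `NULL` when reading a matrix.
#' @param gene_list optional path to a gene subset list applied after
#'   loading.
#' @param guides guide genes for the coexpression screen (vector or path).
#' @param out_dir output directory (created if absent).
#' @param k number of independent components.
#' @param contrast,alpha contrast function name and logcosh scale.
#' @param max_iter,tol fastICA iteration controls.
#' @param similarity clustering similarity (`"uncentered"` or `"pearson"`).
#' @param cut_k,cut_sim flat-cut rule: cluster count or similarity threshold
#'   (exactly one; `cut_k = NULL` with `cut_sim = NULL` defaults to planted
#'   modules + 1 when simulating, else `k`).
#' @param threshold,min_links screen rule (defaults 0.525 and 2).
#' @param seed integer seed controlling simulation and fastICA init.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_path = NULL, simulate = NULL,
                            gene_list = NULL, guides = NULL,
                            out_dir = "icaclust-out",
                            k = 8L, contrast = "logcosh", alpha = 1.0,
                            max_iter = 200L, tol = 1e-4,
                            similarity = "uncentered",
                            cut_k = NULL, cut_sim = NULL,
                            threshold = 0.525, min_links = 2L, seed = 7L) {
  if (is.null(matrix_path) == is.null(simulate)) {
    stop("give exactly one of matrix_path or simulate", call. = FALSE)
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "synthetic_spec"))
  structure(list(matrix_path = matrix_path, simulate = simulate,
                 gene_list = gene_list, guides = guides, out_dir = out_dir,
                 k = as.integer(k), contrast = contrast, alpha = alpha,
                 max_iter = as.integer(max_iter), tol = tol,
                 similarity = similarity, cut_k = cut_k, cut_sim = cut_sim,
                 threshold = threshold, min_links = as.integer(min_links),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Built-in demonstration configuration
#'
#' The default synthetic world: 1000 genes x 200 samples with planted
#' modules of 8, 6 and 10 genes, k = 3 components, cut at 4 clusters, and
#' the first module's first three members as screen guides.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(out_dir = tempfile("icaclust-demo-"), seed = 7L) {
  pipeline_config(simulate = synthetic_spec(seed = seed),
                  out_dir = out_dir, k = 3L, cut_k = 4L, seed = seed)
}

#' Run the full analysis pipeline
#'
#' Chains the stages end to end: load or simulate the expression matrix,
#' optionally restrict to a gene list, decompose with [fastica()], cluster
#' the gene signature matrix with [hca()] and [cut_tree()], screen
#' candidates against the guide genes with [screen_candidates()], and — when
#' planted truth is available — score recovery with [score_recovery()].
#' Writes all artifacts under `config$out_dir`; identical config and seed
#' give byte-identical files. Every TSV written carries a `#` provenance
#' header with package version, config hash and seed.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`matrix`, `truth`,
#'   `decomposition`, `dendrogram`, `assignment`, `screen`, `recovery`) and
#'   `paths` of all files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("icaclust %s config=%s seed=%d",
                   as.character(utils::packageVersion("icaclust")),
                   config_hash(unclass(config)), config$seed)
  out <- function(name) file.path(config$out_dir, name)
  paths <- list()

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- generate_expression(config$simulate)
    mat <- sim$matrix
    truth <- sim$truth
    write_expression_tsv(mat, out("matrix.tsv"), comment = stamp)
    write_truth_tsv(truth, out("truth.tsv"))
    paths$matrix <- out("matrix.tsv")
    paths$truth <- out("truth.tsv")
  } else {
    mat <- read_expression_tsv(config$matrix_path)
  }
  if (!is.null(config$gene_list)) {
    mat <- select_genes(mat, read_gene_list(config$gene_list))
  }

  dec <- fastica(mat, k = config$k,
                 contrast = contrast_function(config$contrast, config$alpha),
                 max_iter = config$max_iter, tol = config$tol,
                 seed = config$seed)
  write_expression_tsv(dec$S, out("S.tsv"), id_column = "gene_id",
                       comment = stamp)
  write_expression_tsv(dec$A, out("A.tsv"), id_column = "component",
                       comment = stamp)
  paths$S <- out("S.tsv")
  paths$A <- out("A.tsv")

  dend <- hca(dec$S, similarity = config$similarity)
  cut_k <- config$cut_k
  if (is.null(cut_k) && is.null(config$cut_sim)) {
    cut_k <- if (!is.null(truth)) {
      length(setdiff(unique(truth$module_of_gene$module), "background")) + 1L
    } else {
      config$k
    }
  }
  assign <- cut_tree(dend, n_clusters = cut_k,
                     min_similarity = config$cut_sim)
  write_cdt_gtr(dec$S, dend, out("signatures"))
  write_cluster_tsv(assign, out("clusters.tsv"), comment = stamp)
  paths$cdt <- out("signatures.cdt")
  paths$gtr <- out("signatures.gtr")
  paths$clusters <- out("clusters.tsv")

  guides <- config$guides
  if (is.null(guides) && !is.null(truth)) {
    first_mod <- names(config$simulate$modules)[1L]
    members <- truth$module_of_gene$gene_id[
      truth$module_of_gene$module == first_mod]
    guides <- sort(members)[seq_len(min(3L, length(members)))]
  }
  if (is.character(guides) && length(guides) == 1L && file.exists(guides)) {
    guides <- read_gene_list(guides)
  }
  screen <- NULL
  if (!is.null(guides)) {
    screen <- screen_candidates(mat, guides, threshold = config$threshold,
                                min_links = config$min_links)
    write_screen_tsv(screen, out("screen.tsv"), comment = stamp)
    paths$screen <- out("screen.tsv")
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- score_recovery(assign, truth, k = config$k)
    rec_tbl <- tidy(recovery)
    readr::write_tsv(rec_tbl, out("recovery.tsv"))
    paths$recovery <- out("recovery.tsv")
  }

  cfg <- unclass(config)
  cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  jsonlite::write_json(cfg, out("config.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  paths$config <- out("config.json")

  invisible(list(matrix = mat, truth = truth, decomposition = dec,
                 dendrogram = dend, assignment = assign, screen = screen,
                 recovery = recovery, paths = paths))
}
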