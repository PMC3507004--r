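#' Uncentered correlation (cosine similarity)
#'
#' The Cluster 3.0 "correlation (uncentered)" metric:
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))` — the cosine of the angle between
#' the two vectors, with no mean-centering. Equals the Pearson correlation
#' whenever both vectors have zero mean.
#'
#' @param x,y numeric vectors of equal length with nonzero norm.
#' @return Similarity in \[-1, 1\].
#' @examples
#' uncentered_correlation(c(1, 2), c(2, 1)) # 0.8
#' @export
uncentered_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  nx <- sum(x^2)
  ny <- sum(y^2)
  if (nx == 0 || ny == 0) {
    stop("degenerate input: zero-norm vector", call. = FALSE)
  }
  sum(x * y) / sqrt(nx * ny)
}

# full similarity matrix for hca(); rows of `signature` are genes
similarity_matrix <- function(signature, similarity) {
  if (similarity == "pearson") {
    signature <- signature - rowMeans(signature)
  }
  norms <- sqrt(rowSums(signature^2))
  zero <- which(norms == 0)
  if (length(zero) > 0L) {
    stop("degenerate input: zero-norm signature for gene '",
         rownames(signature)[zero[1L]], "'", call. = FALSE)
  }
  s <- tcrossprod(signature / norms)
  pmin(pmax(s, -1), 1)
}

#' Hierarchical cluster analysis of gene signatures
#'
#' Agglomerative average-linkage (UPGMA) clustering of the rows of a
#' signature matrix (typically the gene signature matrix S), on distance
#' `1 - similarity` with similarity either the uncentered correlation
#' (Cluster 3.0's metric, the default) or the Pearson correlation. Merge
#' records store `similarity = 1 - merge distance`. Ties between candidate
#' merges at equal distance are broken by the lexicographically smallest
#' `(min_node_id, max_node_id)` pair, so results are deterministic across
#' platforms. Rows are clustered as-is, with no re-standardization.
#'
#' @param signature numeric matrix with gene ids as rownames, >= 2 rows.
#' @param similarity `"uncentered"` (default) or `"pearson"`.
#' @param linkage only `"average"` is supported.
#' @return A `gene_dendrogram`: `leaves` (gene ids in input order), `merges`
#'   (tibble: node, left, right, similarity, distance — leaves are nodes
#'   `1..n`, internal nodes `n+1..2n-1` in merge order), `leaf_order`
#'   (left-to-right display permutation of `leaves`).
#' @export
hca <- function(signature, similarity = c("uncentered", "pearson"),
                linkage = "average") {
  similarity <- match.arg(similarity)
  linkage <- match.arg(linkage, "average")
  signature <- as.matrix(signature)
  n <- nrow(signature)
  if (n < 2L) stop("need at least 2 genes to cluster", call. = FALSE)
  if (is.null(rownames(signature))) {
    stop("signature matrix must have gene ids as rownames", call. = FALSE)
  }

  d <- 1 - similarity_matrix(signature, similarity)
  diag(d) <- Inf

  # slot i holds current cluster; node id, size, member leaves tracked per slot
  node_id <- seq_len(n)
  size <- rep(1L, n)
  members <- as.list(seq_len(n)) # leaf indices, left-to-right order
  active <- rep(TRUE, n)
  d[!active, ] <- Inf

  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    mval <- min(d)
    cand <- which(d == mval, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # tie-break on (min node id, max node id)
    a <- pmin(node_id[cand[, 1L]], node_id[cand[, 2L]])
    b <- pmax(node_id[cand[, 1L]], node_id[cand[, 2L]])
    pick <- order(a, b)[1L]
    i <- cand[pick, 1L]
    j <- cand[pick, 2L]

    new_id <- n + step
    merges[[step]] <- c(node = new_id,
                        left = min(node_id[i], node_id[j]),
                        right = max(node_id[i], node_id[j]),
                        distance = mval)

    # UPGMA update: average over all cross pairs, weighted by sizes
    ni <- size[i]
    nj <- size[j]
    new_row <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
    # keep left/right child order by node id for deterministic leaf order
    if (node_id[i] <= node_id[j]) {
      members[[i]] <- c(members[[i]], members[[j]])
    } else {
      members[[i]] <- c(members[[j]], members[[i]])
    }
    d[i, ] <- new_row
    d[, i] <- new_row
    d[i, i] <- Inf
    d[j, ] <- Inf
    d[, j] <- Inf
    node_id[i] <- new_id
    size[i] <- ni + nj
    active[j] <- FALSE
  }

  merges <- do.call(rbind, merges)
  merges <- tibble::tibble(node = as.integer(merges[, "node"]),
                           left = as.integer(merges[, "left"]),
                           right = as.integer(merges[, "right"]),
                           distance = unname(merges[, "distance"]),
                           similarity = unname(1 - merges[, "distance"]))
  structure(list(leaves = rownames(signature),
                 merges = merges,
                 leaf_order = members[[which(active)[1L]]]),
            class = "gene_dendrogram")
}

#' @export
print.gene_dendrogram <- function(x, ...) {
  cat("gene dendrogram: ", length(x$leaves), " leaves, ",
      nrow(x$merges), " merges (similarity ",
      signif(max(x$merges$similarity), 3), " .. ",
      signif(min(x$merges$similarity), 3), ")\n", sep = "")
  invisible(x)
}

#' Cut a dendrogram into flat clusters
#'
#' Either undo the last `n_clusters - 1` merges (fixed cluster count) or keep
#' only merges at `similarity >= min_similarity` (similarity threshold).
#' Exactly one criterion must be given. Cluster labels are contiguous
#' integers numbered by first appearance in leaf display order.
#'
#' @param dendrogram a [hca()] result.
#' @param n_clusters desired number of clusters (1..n leaves).
#' @param min_similarity keep merges at or above this similarity, in \[-1, 1\].
#' @return A `cluster_assignment`: `labels` (named integer vector,
#'   gene id -> cluster), `n_clusters`.
#' @export
cut_tree <- function(dendrogram, n_clusters = NULL, min_similarity = NULL) {
  stopifnot(inherits(dendrogram, "gene_dendrogram"))
  if (is.null(n_clusters) == is.null(min_similarity)) {
    stop("give exactly one of n_clusters or min_similarity", call. = FALSE)
  }
  n <- length(dendrogram$leaves)
  merges <- dendrogram$merges
  if (!is.null(n_clusters)) {
    n_clusters <- as.integer(n_clusters)
    if (n_clusters < 1L || n_clusters > n) {
      stop("n_clusters must lie in 1..", n, call. = FALSE)
    }
    keep <- seq_len(n - n_clusters)
  } else {
    if (min_similarity < -1 || min_similarity > 1) {
      stop("min_similarity must lie in [-1, 1]", call. = FALSE)
    }
    keep <- which(merges$similarity >= min_similarity)
  }

  # union-find over node ids 1..2n-1
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in keep) {
    parent[find(merges$left[r])] <- merges$node[r]
    parent[find(merges$right[r])] <- merges$node[r]
  }
  root <- vapply(seq_len(n), find, integer(1L))

  # contiguous labels in leaf display order
  ord <- dendrogram$leaf_order
  labels <- integer(n)
  next_label <- 0L
  seen <- integer(0)
  for (leaf in ord) {
    r <- root[leaf]
    hit <- match(r, seen)
    if (is.na(hit)) {
      next_label <- next_label + 1L
      seen <- c(seen, r)
      hit <- next_label
    }
    labels[leaf] <- hit
  }
  names(labels) <- dendrogram$leaves
  structure(list(labels = labels, n_clusters = next_label),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster assignment: ", length(x$labels), " genes in ",
      x$n_clusters, " clusters\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}
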