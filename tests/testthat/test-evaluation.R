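# build a cluster_assignment and synthetic_truth from bare label vectors
make_assignment <- function(labels, genes = sprintf("g%02d", seq_along(labels))) {
  names(labels) <- genes
  structure(list(labels = labels, n_clusters = length(unique(labels))),
            class = "cluster_assignment")
}

make_truth <- function(modules, genes = sprintf("g%02d", seq_along(modules))) {
  structure(list(module_of_gene = tibble::tibble(gene_id = genes,
                                                 module = modules),
                 dual_genes = tibble::tibble(gene_id = character(0),
                                             primary = character(0),
                                             secondary = character(0))),
            class = "synthetic_truth")
}

test_that("ARI anchors: identical partitions and degenerate pairs", {
  a <- make_assignment(c(1, 1, 2, 2, 3))
  t_same <- make_truth(c("x", "x", "y", "y", "z"))
  expect_equal(adjusted_rand_index(a, t_same), 1)
  # all-singletons vs all-together: chance correction forces 0
  singles <- make_assignment(1:6)
  together <- make_truth(rep("m", 6))
  expect_equal(adjusted_rand_index(singles, together), 0)
})

test_that("ARI on the {{2,1},{1,2}} contingency table matches pair counting", {
  # 6 items: clusters (1,1,1,2,2,2), modules (x,x,y,x,y,y)
  labels <- c(1, 1, 1, 2, 2, 2)
  modules <- c("x", "x", "y", "x", "y", "y")
  a <- make_assignment(labels)
  t6 <- make_truth(modules)
  expect_equal(adjusted_rand_index(a, t6), ari_oracle(labels, modules))
})

test_that("ARI agrees with the brute-force pair oracle on partition pairs", {
  # exhaustive over all label-vector pairs for 4 items (up to 4 blocks),
  # then random partitions for 5..8 items
  grid4 <- expand.grid(rep(list(1:4), 4))
  set.seed(99)
  pick <- sample(nrow(grid4), 40)
  for (i in pick) {
    for (j in sample(nrow(grid4), 3)) {
      a <- unlist(grid4[i, ])
      b <- unlist(grid4[j, ])
      expect_equal(
        adjusted_rand_index(make_assignment(a),
                            make_truth(paste0("m", b))),
        ari_oracle(a, b), tolerance = 1e-12)
    }
  }
  for (n in 5:8) {
    for (rep in 1:25) {
      a <- random_partition(n, kmax = 4, seed = n * 100 + rep)
      b <- random_partition(n, kmax = 3, seed = n * 100 + rep + 5000)
      expect_equal(
        adjusted_rand_index(make_assignment(a),
                            make_truth(paste0("m", b))),
        ari_oracle(a, b), tolerance = 1e-12)
    }
  }
})

test_that("ARI is symmetric and invariant to label permutation", {
  set.seed(5)
  a <- sample(1:3, 30, replace = TRUE)
  b <- sample(1:4, 30, replace = TRUE)
  ari_ab <- adjusted_rand_index(make_assignment(a), make_truth(paste0("m", b)))
  ari_ba <- adjusted_rand_index(make_assignment(b), make_truth(paste0("m", a)))
  expect_equal(ari_ab, ari_ba, tolerance = 1e-12)
  relabeled <- c(3, 1, 2)[a]
  expect_equal(adjusted_rand_index(make_assignment(relabeled),
                                   make_truth(paste0("m", b))),
               ari_ab, tolerance = 1e-12)
})

test_that("universe mismatch errors list the symmetric difference", {
  a <- make_assignment(c(1, 2), genes = c("g1", "g2"))
  t2 <- make_truth(c("x", "y"), genes = c("g1", "g3"))
  expect_error(adjusted_rand_index(a, t2), "g2.*g3|g3.*g2")
})

test_that("module Jaccard: perfect recovery, partial overlap, random null", {
  truth <- make_truth(c(rep("mod", 8), rep("background", 12)))
  perfect <- make_assignment(c(rep(1, 8), rep(2, 12)))
  mj <- module_jaccard(perfect, truth)
  expect_equal(mj$jaccard, 1)

  # module of 8 with 6 members in a best cluster of size 6 -> 6/8
  partial <- make_assignment(c(rep(1, 6), 2, 2, rep(2, 12)))
  mj2 <- module_jaccard(partial, truth)
  expect_equal(mj2$jaccard, 0.75)

  # randomized labels on 1000 genes, 4 clusters: Jaccard stays tiny
  big_truth <- make_truth(c(rep("mod", 8), rep("background", 992)),
                          genes = sprintf("g%04d", 1:1000))
  jac <- vapply(1:100, function(seed) {
    set.seed(seed)
    asg <- make_assignment(sample(1:4, 1000, replace = TRUE),
                           genes = sprintf("g%04d", 1:1000))
    module_jaccard(asg, big_truth)$jaccard
  }, numeric(1))
  expect_lt(stats::quantile(jac, 0.99), 0.1)
})

test_that("noise-free planted modules are recovered exactly at ARI 1", {
  # all genes belong to a module (a truly noise-free background would have
  # zero-norm signature rows, which the clustering rejects by contract)
  # k is capped at 2: with every gene in a module and equal loadings, column
  # centering removes one dimension from the module subspace
  spec <- synthetic_spec(n_genes = 18, n_samples = 40,
                         modules = c(a = 6, b = 6, c = 6),
                         noise_sd = 1e-8, baseline_sd = 0, seed = 3)
  sim <- generate_expression(spec)
  dec <- suppressWarnings(fastica(sim$matrix, k = 2, seed = 1))
  asg <- cut_tree(hca(dec$S), n_clusters = 3)
  expect_equal(adjusted_rand_index(asg, sim$truth), 1)
})

test_that("ic_sweep is deterministic end to end and tabulates dual genes", {
  spec <- synthetic_spec(n_genes = 150, n_samples = 60,
                         modules = c(a = 6, b = 6),
                         dual_genes = list(c("a", "b")), cross_loading = 0.8,
                         seed = 4)
  sim <- generate_expression(spec)
  s1 <- suppressWarnings(ic_sweep(sim$matrix, sim$truth, k_values = c(2, 3),
                                  n_clusters = 3, seed = 2))
  s2 <- suppressWarnings(ic_sweep(sim$matrix, sim$truth, k_values = c(2, 3),
                                  n_clusters = 3, seed = 2))
  expect_identical(tidy(s1), tidy(s2))
  duals <- dual_gene_assignments(s1)
  expect_identical(nrow(duals), 2L)
  expect_identical(duals$k, c(2L, 3L))
  expect_true(all(duals$assigned_module %in% c("a", "b")))
  expect_identical(unique(duals$gene_id), sim$truth$dual_genes$gene_id)
})
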