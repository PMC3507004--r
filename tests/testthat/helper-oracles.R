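# Independent oracles and tiny fixture builders. Everything here is kept
# deliberately naive (double loops, explicit set bookkeeping) so it shares no
# code path with the package implementation it checks.

tiny_matrix <- function(values, genes, samples) {
  expression_matrix(matrix(values, length(genes), length(samples),
                           byrow = TRUE),
                    gene_ids = genes, sample_ids = samples)
}

random_matrix <- function(m, n, seed) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(m * n), m, n),
                    gene_ids = sprintf("g%03d", seq_len(m)),
                    sample_ids = sprintf("s%03d", seq_len(n)))
}

# --- exhaustive UPGMA oracle --------------------------------------------
# Clusters kept as explicit member sets; the inter-cluster distance is
# recomputed every step as the arithmetic mean over ALL member pairs of the
# original distance matrix. Tie-break: smallest (min node id, max node id).
upgma_oracle <- function(d0) {
  n <- nrow(d0)
  clusters <- lapply(seq_len(n), function(i) i)   # member leaf sets
  ids <- seq_len(n)                               # node ids
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        tot <- 0
        for (x in clusters[[a]]) for (y in clusters[[b]]) tot <- tot + d0[x, y]
        dist_ab <- tot / (length(clusters[[a]]) * length(clusters[[b]]))
        key <- c(dist_ab, min(ids[a], ids[b]), max(ids[a], ids[b]))
        if (is.null(best) ||
            dist_ab < best$key[1] - 1e-15 ||
            (abs(dist_ab - best$key[1]) <= 1e-15 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(a = a, b = b, key = key, dist = dist_ab)
        }
      }
    }
    new_id <- n + length(merges) + 1L
    merges[[length(merges) + 1L]] <- c(
      node = new_id,
      left = min(ids[best$a], ids[best$b]),
      right = max(ids[best$a], ids[best$b]),
      distance = best$dist
    )
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    ids[best$a] <- new_id
    clusters[[best$b]] <- NULL
    ids <- ids[-best$b]
  }
  do.call(rbind, merges)
}

# --- brute-force ARI oracle ---------------------------------------------
# Enumerates every unordered item pair and classifies it into the four
# agreement cells; ARI from the pair-count closed form.
ari_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa) n10 <- n10 + 1
      else if (sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1) # identical degenerate partitions
  2 * (n11 * n00 - n10 * n01) / denom
}

# random set partition of n items into at most kmax blocks
random_partition <- function(n, kmax, seed) {
  set.seed(seed)
  sample.int(kmax, n, replace = TRUE)
}

# --- hand-rolled Pearson for the screen oracle --------------------------
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# --- rotation-scan ICA oracle -------------------------------------------
# On 2-d whitened data, scan the rotation angle on a 0.001-rad grid and
# return the angle maximizing the sum of squared excess kurtoses of the two
# rotated coordinates.
kurtosis_rotation_scan <- function(z, step = 0.001) {
  stopifnot(nrow(z) == 2L)
  kurt <- function(v) {
    vv <- mean((v - mean(v))^2)
    mean((v - mean(v))^4) / vv^2 - 3
  }
  thetas <- seq(0, pi - step, by = step)
  obj <- vapply(thetas, function(th) {
    y1 <- cos(th) * z[1, ] + sin(th) * z[2, ]
    y2 <- -sin(th) * z[1, ] + cos(th) * z[2, ]
    kurt(y1)^2 + kurt(y2)^2
  }, numeric(1L))
  thetas[which.max(obj)]
}

# angular distance modulo pi/2 (component permutation and sign both fold
# the rotation angle into a quarter turn)
angle_dist_mod90 <- function(a, b) {
  d <- abs(a - b) %% (pi / 2)
  min(d, pi / 2 - d)
}

# best |correlation| assignment between recovered and planted source pairs
match_abs_cor <- function(S, truth) {
  cc <- abs(stats::cor(S, truth))
  # 2x2: direct or swapped
  max(min(cc[1, 1], cc[2, 2]), min(cc[1, 2], cc[2, 1]))
}

demo_world <- function(seed = 7, dual = FALSE) {
  spec <- if (dual) {
    synthetic_spec(dual_genes = list(c("anthocyanin", "flavonol")),
                   cross_loading = 0.8, seed = seed)
  } else {
    synthetic_spec(seed = seed)
  }
  generate_expression(spec)
}
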