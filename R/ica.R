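#' Contrast (non-Gaussianity) functions for fastICA
#'
#' The fixed-point iteration maximizes a proxy for negentropy through a
#' nonlinearity g and its derivative. Two standard choices are provided:
#' `logcosh` (g(u) = tanh(alpha u), robust general-purpose) and `exp`
#' (g(u) = u exp(-u^2/2), suited to very spiky sources).
#'
#' @param name `"logcosh"` or `"exp"`.
#' @param alpha scale of the logcosh nonlinearity, in \[1, 2\].
#' @return A `contrast_function` list with elements `name`, `alpha`, `g`
#'   (vectorized nonlinearity) and `dg` (its derivative).
#' @export
contrast_function <- function(name = c("logcosh", "exp"), alpha = 1.0) {
  name <- match.arg(name)
  if (alpha < 1 || alpha > 2) stop("alpha must lie in [1, 2]", call. = FALSE)
  fns <- switch(name,
    logcosh = list(
      g = function(u) tanh(alpha * u),
      dg = function(u) alpha * (1 - tanh(alpha * u)^2)
    ),
    exp = list(
      g = function(u) u * exp(-u^2 / 2),
      dg = function(u) (1 - u^2) * exp(-u^2 / 2)
    )
  )
  structure(list(name = name, alpha = alpha, g = fns$g, dg = fns$dg),
            class = "contrast_function")
}

#' Center and whiten an expression matrix for ICA
#'
#' Genes are treated as observations of an n_samples-dimensional variable.
#' Sample (column) means are removed, the sample covariance across columns is
#' eigendecomposed, and the data are projected onto the top-k eigenvectors
#' scaled to unit variance, so the whitened data have identity covariance.
#' Eigenvalues below `1e-12` times the largest count as numerically zero for
#' rank detection.
#'
#' @param matrix expression matrix (genes x samples).
#' @param k number of retained components; must not exceed the numerical rank.
#' @return A list: `z` (k x n_genes whitened data, covariance = I), `K`
#'   (k x n_samples whitening transform), `means` (column means, length
#'   n_samples), `eigenvalues` (all covariance eigenvalues, decreasing).
#' @export
center_and_whiten <- function(matrix, k) {
  validate_expression_matrix(matrix)
  m <- nrow(matrix)
  n <- ncol(matrix)
  k <- as.integer(k)
  if (k < 1L || k > min(m, n)) {
    stop("k must lie in 1..min(n_genes, n_samples)", call. = FALSE)
  }
  means <- colMeans(matrix)
  xc <- sweep(matrix, 2L, means)
  cv <- crossprod(xc) / m # n x n sample covariance (divisor m: whitening scale)
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > 1e-12 * max(eg$values, 0))
  if (k > rank) {
    stop("rank deficiency: requested k = ", k,
         " exceeds numerical rank ", rank, call. = FALSE)
  }
  K <- diag(1 / sqrt(eg$values[seq_len(k)]), k, k) %*%
    t(eg$vectors[, seq_len(k), drop = FALSE]) # k x n
  z <- K %*% t(xc) # k x m, cov = I
  list(z = z, K = K, means = means, eigenvalues = eg$values)
}

# symmetric decorrelation: W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors) %*% W
}

#' fastICA decomposition of an expression matrix (X = SA)
#'
#' From-scratch symmetric (parallel) fixed-point fastICA. The genes x samples
#' matrix X is modelled as X = SA: S (genes x k) is the gene signature
#' matrix whose column j scores every gene on independent component j, and A
#' (k x samples) is the latent mixing matrix giving each component's
#' activation across samples. Genes are the observations; the k component
#' patterns over genes are the statistically independent variables sought by
#' maximizing non-Gaussianity.
#'
#' The iteration starts from a seeded standard-normal unmixing matrix,
#' orthonormalizes it, and repeats the fastICA update with symmetric
#' decorrelation until the unmixing rotation stabilizes (`tol` on
#' `max |1 - |diag(W_new W_old^T)||`) or `max_iter` is reached. Columns of S
#' are scaled to unit sample variance, and each column's sign is flipped so
#' its largest-magnitude entry is positive (a deterministic resolution of
#' ICA's sign indeterminacy, so downstream clustering is reproducible).
#'
#' @param matrix expression matrix (genes x samples).
#' @param k number of independent components (default 8).
#' @param contrast a [contrast_function()].
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance on the unmixing rotation.
#' @param seed integer seed for the random initial unmixing matrix.
#' @return An `ica_decomposition`: `S` (genes x k, unit-variance columns),
#'   `A` (k x samples), `W` (k x k orthonormal unmixing), `K` (k x samples
#'   whitening transform), `means`, `k`, `converged`, `iterations`,
#'   `tolerance_achieved`, `seed`. Non-convergence yields a warning, not an
#'   error.
#' @examples
#' sim <- generate_expression(synthetic_spec(n_genes = 200, n_samples = 60,
#'                                           modules = c(a = 6, b = 6)))
#' dec <- fastica(sim$matrix, k = 2, seed = 1)
#' dim(dec$S)
#' @export
fastica <- function(matrix, k = 8L,
                    contrast = contrast_function("logcosh", 1.0),
                    max_iter = 200L, tol = 1e-4, seed) {
  stopifnot(inherits(contrast, "contrast_function"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  wh <- center_and_whiten(matrix, k)
  z <- wh$z # k x m
  m <- ncol(z)
  k <- as.integer(k)

  set.seed(as.integer(seed))
  W <- base::matrix(stats::rnorm(k * k), k, k)
  W <- sym_decorrelate(W)

  converged <- FALSE
  achieved <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    u <- W %*% z # k x m projections
    gu <- contrast$g(u)
    W1 <- gu %*% t(z) / m - diag(rowMeans(contrast$dg(u)), k) %*% W
    W1 <- sym_decorrelate(W1)
    achieved <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (achieved < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("fastICA did not converge in ", max_iter,
            " iterations (criterion ", signif(achieved, 3), ")",
            call. = FALSE)
  }

  y <- W %*% z # k x m raw sources over genes
  sds <- apply(y, 1L, stats::sd)
  S <- t(y / sds) # m x k, unit sample variance columns
  # sign convention: largest-magnitude element of each column positive
  for (j in seq_len(k)) {
    peak <- which.max(abs(S[, j]))
    if (S[peak, j] < 0) S[, j] <- -S[, j]
  }
  rownames(S) <- rownames(matrix)
  colnames(S) <- paste0("IC", seq_len(k))

  xc <- sweep(matrix, 2L, wh$means)
  A <- qr.solve(S, xc) # k x n least squares: S A = rank-k projection of xc
  rownames(A) <- colnames(S)
  colnames(A) <- colnames(matrix)

  structure(list(S = S, A = A, W = W, K = wh$K, means = wh$means,
                 eigenvalues = wh$eigenvalues, k = k,
                 contrast = contrast$name, alpha = contrast$alpha,
                 converged = converged, iterations = iter,
                 tolerance_achieved = achieved, seed = as.integer(seed)),
            class = "ica_decomposition")
}

#' Reconstruct the expression matrix from a decomposition
#'
#' Returns `S %*% A` plus the restored sample means — the rank-k principal
#' subspace projection of the input.
#'
#' @param decomposition an `ica_decomposition` from [fastica()].
#' @return Numeric matrix, genes x samples.
#' @export
reconstruct <- function(decomposition) {
  stopifnot(inherits(decomposition, "ica_decomposition"))
  x <- decomposition$S %*% decomposition$A
  sweep(x, 2L, decomposition$means, `+`)
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat("fastICA decomposition: ", nrow(x$S), " genes x ", ncol(x$A),
      " samples, k = ", x$k, "\n", sep = "")
  cat("  contrast: ", x$contrast, " (alpha = ", x$alpha, "), seed ", x$seed,
      "\n", sep = "")
  cat("  ", if (x$converged) "converged" else "NOT converged", " in ",
      x$iterations, " iterations (criterion ",
      signif(x$tolerance_achieved, 3), ")\n", sep = "")
  invisible(x)
}
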