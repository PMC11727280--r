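#' First canonical correlation between two omics blocks
#'
#' The association between two genes is measured by the first canonical
#' correlation between their omics blocks: the square root of the largest
#' eigenvalue of \code{S11^-1 S12 S22^-1 S21}, where \code{Sab} are the
#' within/between-block covariance blocks.  A small ridge is added to each
#' within-block covariance to guard against collinear omics.
#'
#' @param block_i,block_j numeric matrices with the same number of rows
#'   (samples) and one column per omics.
#' @param ridge ridge added to the diagonal of each within-block covariance.
#' @return Scalar in \code{[0, 1]}.
#' @export
canonical_correlation <- function(block_i, block_j, ridge = 1e-8) {
  block_i <- as.matrix(block_i); block_j <- as.matrix(block_j)
  n <- nrow(block_i)
  stopifnot(nrow(block_j) == n, n > max(ncol(block_i), ncol(block_j)))
  A <- scale(block_i, center = TRUE, scale = FALSE)
  B <- scale(block_j, center = TRUE, scale = FALSE)
  if (any(colSums(A^2) < .Machine$double.eps * n) ||
      any(colSums(B^2) < .Machine$double.eps * n))
    warning("degenerate (zero-variance) column in a gene block")
  S11 <- crossprod(A) / (n - 1) + ridge * diag(ncol(A))
  S22 <- crossprod(B) / (n - 1) + ridge * diag(ncol(B))
  S12 <- crossprod(A, B) / (n - 1)
  M <- solve(S11, S12 %*% solve(S22, t(S12)))
  lam <- max(Re(eigen(M, only.values = TRUE)$values))
  sqrt(min(1, max(0, lam)))
}

#' Gene-by-gene canonical correlation matrix
#'
#' Computes the G x G matrix of pairwise first canonical correlations between
#' all gene blocks.  Each block is whitened once by the Cholesky factor of its
#' (ridge-regularised) covariance, after which the canonical correlations of a
#' pair are the singular values of the n0 x n0 cross-covariance of the
#' whitened blocks -- the same quantity as \code{\link{canonical_correlation}}
#' but computed in O(G^2 n0^3) after an O(n p) pass.
#'
#' @param X n x p data matrix.
#' @param structure an \code{\link{omics_structure}}.
#' @param ridge ridge for the within-block covariances.
#' @return Symmetric G x G matrix with unit diagonal, entries in \code{[0,1]},
#'   of class \code{"gene_association"}.
#' @export
gene_association_matrix <- function(X, structure, ridge = 1e-8) {
  stopifnot(inherits(structure, "omics_structure"),
            ncol(X) == structure$p, nrow(X) > structure$n0)
  n <- nrow(X); G <- structure$G; n0 <- structure$n0
  Y <- scale(X, center = TRUE, scale = FALSE)
  for (g in seq_len(G)) {
    cols <- structure$columns_of_gene[[g]]
    Sg <- crossprod(Y[, cols, drop = FALSE]) / (n - 1) + ridge * diag(n0)
    Y[, cols] <- Y[, cols, drop = FALSE] %*% backsolve(chol(Sg), diag(n0))
  }
  Mfull <- crossprod(Y) / (n - 1)
  A <- diag(1, G)
  for (i in seq_len(G - 1L)) {
    ci <- structure$columns_of_gene[[i]]
    for (j in (i + 1L):G) {
      Bij <- Mfull[ci, structure$columns_of_gene[[j]], drop = FALSE]
      lam <- max(eigen(tcrossprod(Bij), symmetric = TRUE,
                       only.values = TRUE)$values)
      A[i, j] <- A[j, i] <- sqrt(min(1, max(0, lam)))
    }
  }
  class(A) <- c("gene_association", class(A))
  A
}

#' Cluster genes from a gene association matrix
#'
#' Follows the WGCNA convention: the association matrix is soft-thresholded to
#' an adjacency \code{a^power}, converted to the dissimilarity
#' \code{1 - adjacency}, and genes are grouped by average-linkage hierarchical
#' clustering.  Unless \code{k} is supplied, the tree is cut at the largest
#' gap in the merge-height sequence.
#'
#' @param assoc G x G gene association matrix (see
#'   \code{\link{gene_association_matrix}}).
#' @param power soft-threshold exponent (default 6).
#' @param k optional forced number of clusters.
#' @return List of class \code{"gene_clustering"}: \code{labels} (per-gene
#'   cluster index), \code{n_clusters}, \code{power}, \code{k_forced},
#'   \code{hclust} (the dendrogram).
#' @export
cluster_genes <- function(assoc, power = 6, k = NULL) {
  A <- unclass(assoc)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  G <- nrow(A)
  diss <- 1 - A^power
  diag(diss) <- 0
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  if (is.null(k)) {
    h <- hc$height
    k <- if (G <= 2L) G else G - which.max(diff(h)) # cut at largest height gap
  }
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = as.integer(labels), n_clusters = length(unique(labels)),
                 power = power, k_forced = k, hclust = hc),
            class = "gene_clustering")
}

#' @export
print.gene_clustering <- function(x, ...) {
  cat(sprintf("Gene clustering: %d genes in %d clusters (power = %g)\n",
              length(x$labels), x$n_clusters, x$power))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (Hubert-Arabie form): 1 for identical partitions, expected value 0 under
#' random partitioning, and possibly negative.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial and identical
  (sum_ij - expected) / (maxi - expected)
}
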