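#' Tri-level hierarchical structure of a multi-omics design matrix
#'
#' A design matrix with tri-level structure has its \code{p} columns organised
#' as \code{G} genes of \code{n0} consecutive omics columns each, and the genes
#' partitioned into \code{C} disjoint clusters.  Gene \code{g} occupies columns
#' \code{(g-1)*n0 + 1, ..., g*n0}; cluster membership is a label per gene, so
#' clusters need not be contiguous runs of genes (they are after
#' \code{\link{build_structure}}, but not after label perturbation).
#'
#' @param cluster_of_gene integer vector of length \code{G}; cluster label of
#'   each gene.  Labels are relabelled to consecutive integers \code{1..C}.
#' @param n0 number of omics measurements per gene.
#' @return An object of class \code{"omics_structure"}: a list with elements
#'   \code{p}, \code{G}, \code{C}, \code{n0}, \code{Hc} (genes per cluster),
#'   \code{cluster_of_gene}, \code{genes_of_cluster} (list),
#'   \code{columns_of_gene} (list of length-\code{n0} column index vectors),
#'   \code{cluster_of_col}, \code{gene_of_col}, \code{type_of_col} (omics type
#'   \code{1..n0} of each column), and \code{alpha} (per-cluster cumulative
#'   column offsets, \code{NULL} when clusters are not contiguous).
#' @export
omics_structure <- function(cluster_of_gene, n0 = 3L) {
  cluster_of_gene <- as.integer(cluster_of_gene)
  n0 <- as.integer(n0)
  stopifnot(length(cluster_of_gene) >= 1L, n0 >= 1L,
            all(is.finite(cluster_of_gene)))
  ## relabel clusters to 1..C keeping numeric order of the original labels
  labs <- sort(unique(cluster_of_gene))
  cluster_of_gene <- match(cluster_of_gene, labs)
  G <- length(cluster_of_gene)
  C <- length(labs)
  p <- G * n0
  Hc <- tabulate(cluster_of_gene, nbins = C)
  genes_of_cluster <- split(seq_len(G), cluster_of_gene)
  names(genes_of_cluster) <- NULL
  columns_of_gene <- lapply(seq_len(G), function(g) ((g - 1L) * n0 + 1L):(g * n0))
  gene_of_col <- rep(seq_len(G), each = n0)
  cluster_of_col <- cluster_of_gene[gene_of_col]
  type_of_col <- rep(seq_len(n0), times = G)
  ## alpha offsets are defined when each cluster is one contiguous block of
  ## genes in increasing cluster order (the canonical layout)
  contiguous <- !is.unsorted(cluster_of_gene)
  alpha <- if (contiguous) c(0L, cumsum(Hc * n0))[seq_len(C)] else NULL
  structure(list(p = p, G = G, C = C, n0 = n0, Hc = Hc,
                 cluster_of_gene = cluster_of_gene,
                 genes_of_cluster = genes_of_cluster,
                 columns_of_gene = columns_of_gene,
                 gene_of_col = gene_of_col,
                 cluster_of_col = cluster_of_col,
                 type_of_col = type_of_col,
                 alpha = alpha),
            class = "omics_structure")
}

#' Build the canonical simulation-design structure
#'
#' Builds an \code{\link{omics_structure}} with \code{dims[k]} clusters of
#' gene-size 5, 10, 20 and 40 respectively, laid out contiguously (all size-5
#' clusters first, then size-10, and so on).
#'
#' @param dims length-4 integer vector: number of clusters containing 5, 10,
#'   20 and 40 genes.
#' @param n0 omics per gene.
#' @return An \code{omics_structure}.
#' @examples
#' s <- build_structure(c(10, 5, 4, 3), n0 = 3)  # p = 900, G = 300, C = 22
#' @export
build_structure <- function(dims, n0 = 3L) {
  stopifnot(length(dims) == 4L, all(dims >= 0), sum(dims) >= 1)
  sizes <- rep(c(5L, 10L, 20L, 40L), times = as.integer(dims))
  omics_structure(rep(seq_along(sizes), times = sizes), n0 = n0)
}

#' Column offset of a gene within the canonical layout
#'
#' Returns the offset \code{kappa = alpha_c + n0*(h-1)} such that gene \code{h}
#' of cluster \code{c} occupies columns \code{kappa + 1, ..., kappa + n0}.
#' Only defined for contiguous (canonical) layouts.
#'
#' @param structure an \code{omics_structure} with non-\code{NULL} \code{alpha}.
#' @param c,h cluster index and within-cluster gene index.
#' @export
kappa_offset <- function(structure, c, h) {
  stopifnot(inherits(structure, "omics_structure"), !is.null(structure$alpha))
  structure$alpha[c] + structure$n0 * (h - 1L)
}

#' @export
print.omics_structure <- function(x, ...) {
  cat("Tri-level omics structure\n")
  cat(sprintf("  p = %d covariates, G = %d genes (n0 = %d omics each), C = %d clusters\n",
              x$p, x$G, x$n0, x$C))
  sz <- table(x$Hc)
  cat("  cluster sizes (genes): ",
      paste(sprintf("%s x %s", sz, names(sz)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Replace cluster labels of a structure
#'
#' Returns a new structure with the same gene/omics layout but new per-gene
#' cluster labels (e.g. perturbed labels from
#' \code{\link{permute_cluster_labels}} or labels estimated by
#' \code{\link{cluster_genes}}).
#'
#' @param structure an \code{omics_structure}.
#' @param labels integer vector of length \code{structure$G}.
#' @export
relabel_structure <- function(structure, labels) {
  stopifnot(inherits(structure, "omics_structure"),
            length(labels) == structure$G)
  omics_structure(labels, n0 = structure$n0)
}
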