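#' Block-diagonal weight matrix for joint screening
#'
#' Builds the gene-block weight matrix W(beta) used by the quadratic surrogate
#' of the log-likelihood.  For gene h of cluster c the raw block is the
#' negative Hessian sub-block of the logistic log-likelihood restricted to the
#' gene's n0 columns; the block entering W is that raw block scaled by
#' \code{q2[c] * n0}.  Only the G small blocks are materialised.  With
#' \code{diagonal = TRUE} each block is reduced to its diagonal (the JSD
#' variant, which ignores within-gene correlation).
#'
#' @param X,y design matrix and binary outcome.
#' @param beta,beta0 evaluation point.
#' @param structure an \code{\link{omics_structure}}.
#' @param q2 per-cluster gene retention caps (used in the block scale).
#' @param diagonal reduce each gene block to its diagonal.
#' @param scale_wc apply the \code{q2[c] * n0} cluster scale factor (the
#'   stated form of W; disabling it is offered for sensitivity checks only --
#'   it cannot change within-cluster gene rankings).
#' @return Object of class \code{"block_weights"}: \code{blocks} (list of G
#'   raw n0 x n0 matrices), \code{scale} (per-gene scale factors),
#'   \code{structure}, \code{q2}.
#' @export
build_block_W <- function(X, y, beta, beta0, structure, q2,
                          diagonal = FALSE, scale_wc = TRUE) {
  stopifnot(inherits(structure, "omics_structure"),
            length(q2) == structure$C)
  eta <- beta0 + linear_predictor(X, beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  G <- structure$G; n0 <- structure$n0
  blocks <- vector("list", G)
  for (g in seq_len(G)) {
    Xg <- X[, structure$columns_of_gene[[g]], drop = FALSE]
    B <- crossprod(Xg, w * Xg)
    if (diagonal && n0 > 1L) B <- diag(diag(B), n0)
    blocks[[g]] <- B
  }
  scale <- if (scale_wc) (q2[structure$cluster_of_gene] * n0) else rep(1, G)
  structure(list(blocks = blocks, scale = scale, structure = structure,
                 q2 = q2, diagonal = diagonal),
            class = "block_weights")
}

## invert a small symmetric PSD block, adding the ridge
## 1e-8 * trace/n0 when its condition number exceeds 1e12
solve_block <- function(B, v) {
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values
  if (min(lam) <= 0 || max(lam) / min(lam) > 1e12) {
    lam <- lam + 1e-8 * sum(diag(B)) / nrow(B) + 1e-300
    if (min(lam) <= 0) stop("singular weight block after ridge")
  }
  e$vectors %*% ((crossprod(e$vectors, v)) / lam)
}

#' Closed-form maximiser of the quadratic surrogate
#'
#' The surrogate \code{g(w | beta) = l(beta) + (w - beta)' l'(beta) -
#' (u/2) (w - beta)' W(beta) (w - beta)} is maximised, block by block, at
#' \code{w = beta + (1/u) W^{-1} l'(beta)}.
#'
#' @param beta current coefficient vector (length p).
#' @param grad score vector \code{l'(beta)} (length p).
#' @param W a \code{\link{build_block_W}} object.
#' @param u surrogate curvature constant.
#' @return The unconstrained maximiser \code{omega_hat} (length p).
#' @export
surrogate_argmax <- function(beta, grad, W, u) {
  st <- W$structure
  omega <- numeric(st$p)
  for (g in seq_len(st$G)) {
    cols <- st$columns_of_gene[[g]]
    omega[cols] <- beta[cols] +
      solve_block(W$blocks[[g]], grad[cols]) / (u * W$scale[g])
  }
  omega
}

#' Gene- and cluster-level screening scores
#'
#' \code{gene_scores} returns the per-gene weighted squared sums
#' \code{r_ch = omega_ch' W_ch omega_ch} computed with the raw (unscaled) gene
#' blocks; the per-cluster scale constant cannot alter within-cluster
#' rankings.  \code{cluster_scores} returns
#' \code{R_c = omega_c' W_c omega_c = q2[c] * n0 * sum_h r_ch}, using the
#' scaled cluster blocks.
#'
#' @param omega_hat surrogate maximiser (length p).
#' @param W a \code{\link{build_block_W}} object.
#' @return \code{gene_scores}: length-G vector; \code{cluster_scores}:
#'   length-C vector.
#' @export
gene_scores <- function(omega_hat, W) {
  st <- W$structure
  vapply(seq_len(st$G), function(g) {
    v <- omega_hat[st$columns_of_gene[[g]]]
    as.numeric(crossprod(v, W$blocks[[g]] %*% v))
  }, numeric(1))
}

#' @rdname gene_scores
#' @export
cluster_scores <- function(omega_hat, W) {
  st <- W$structure
  r <- gene_scores(omega_hat, W) * W$scale
  as.numeric(rowsum(r, st$cluster_of_gene)[, 1])
}

#' Apply the cluster- and gene-level cardinality constraints
#'
#' Implements the two-level hard-thresholding step: within each cluster keep
#' the \code{q2[c]} genes with the largest scores \code{r_ch} and zero the
#' rest of \code{omega_hat}; recompute the cluster scores \code{R_c} on the
#' masked vector; keep the \code{q1} top clusters and zero all genes outside
#' them.  Ties are broken by ascending index.  The surviving support satisfies
#' both cardinality constraints, and on block-diagonal W this masking attains
#' the constrained maximum of the surrogate.
#'
#' @param omega_hat surrogate maximiser (length p).
#' @param W a \code{\link{build_block_W}} object.
#' @param q1 maximum number of clusters retained.
#' @return List: \code{genes} (retained gene indices), \code{clusters}
#'   (retained cluster indices), \code{omega} (masked omega_hat),
#'   \code{gene_scores}, \code{cluster_scores} (on the gene-masked vector).
#' @export
constrained_select <- function(omega_hat, W, q1) {
  st <- W$structure
  q2 <- W$q2
  stopifnot(q1 >= 1, q1 <= st$C)
  r <- gene_scores(omega_hat, W)
  keep_genes <- logical(st$G)
  for (c in seq_len(st$C)) {
    genes <- st$genes_of_cluster[[c]]
    ord <- genes[order(-r[genes], genes)]
    keep_genes[ord[seq_len(min(q2[c], length(genes)))]] <- TRUE
  }
  omega <- omega_hat
  omega[!keep_genes[st$gene_of_col]] <- 0
  Rc <- cluster_scores(omega, W)
  keep_cl <- order(-Rc, seq_len(st$C))[seq_len(q1)]
  keep_genes <- keep_genes & (st$cluster_of_gene %in% keep_cl)
  omega[!keep_genes[st$gene_of_col]] <- 0
  list(genes = which(keep_genes), clusters = sort(keep_cl), omega = omega,
       gene_scores = r, cluster_scores = Rc)
}

#' Joint screening with a block-diagonal weight matrix (JSBD)
#'
#' Screens genes in a tri-level logistic model under cardinality constraints:
#' at most \code{q1} clusters and at most \code{q2[c]} genes per cluster.
#' Starting from beta = 0, each iteration (i) maximises the block-diagonal
#' quadratic surrogate of the log-likelihood in closed form, (ii) keeps the
#' top genes within each cluster and then the top clusters by their weighted
#' squared-sum scores, and (iii) re-maximises the exact log-likelihood over
#' the retained columns.  Iteration stops when the relative change
#' \code{||beta_new - beta|| / ||beta||} falls below \code{tol} (the absolute
#' change is used while \code{||beta|| < 1e-12}) or after \code{max_iter}
#' iterations, in which case the best-log-likelihood iterate is returned with
#' \code{converged = FALSE}.  For \code{u} at least as large as the curvature
#' ratio \code{tau(k)} the log-likelihood trace is non-decreasing.
#'
#' @param X n x p numeric design matrix (genes in consecutive n0-column
#'   blocks).
#' @param y binary 0/1 outcome.
#' @param clusters an \code{\link{omics_structure}}, or a per-gene cluster
#'   label vector (in which case \code{n0} is inferred from \code{ncol(X)}).
#' @param q1 maximum clusters retained (default 8).
#' @param q2 per-cluster gene caps; default \code{max(1, ceiling(0.1 * Hc))}
#'   (10\% of the cluster size).  A scalar is recycled.
#' @param u surrogate curvature constant (default 1e5).
#' @param tol relative-change convergence threshold (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @param method \code{"jsbd"} (full n0 x n0 gene blocks) or \code{"jsd"}
#'   (blocks reduced to their diagonals, ignoring within-gene correlation).
#' @param scale_wc apply the \code{q2[c] * n0} cluster scale in W.
#' @param compute_tau also record the per-iteration curvature-ratio bound
#'   \code{tau(k)} (forms dense p x p matrices; small problems only).
#' @return Object of class \code{"jsbd"}; see Details.  Key elements:
#'   \code{beta}, \code{beta0}, \code{retained_genes},
#'   \code{retained_clusters}, \code{retained_genes_by_cluster},
#'   \code{gene_scores}, \code{cluster_scores}, \code{loglik_trace},
#'   \code{tau_trace}, \code{iterations}, \code{converged}.
#' @export
jsbd <- function(X, y, clusters, q1 = 8L, q2 = NULL, u = 1e5, tol = 1e-6,
                 max_iter = 100L, method = c("jsbd", "jsd"),
                 scale_wc = TRUE, compute_tau = FALSE) {
  method <- match.arg(method)
  check_binary(y)
  X <- as.matrix(X)
  st <- if (inherits(clusters, "omics_structure")) clusters
        else {
          G <- length(clusters)
          if (ncol(X) %% G != 0)
            stop("ncol(X) is not a multiple of the number of genes")
          omics_structure(clusters, n0 = ncol(X) %/% G)
        }
  stopifnot(ncol(X) == st$p, nrow(X) == length(y))
  if (is.null(q2)) q2 <- pmax(1L, ceiling(0.1 * st$Hc))
  q2 <- rep_len(as.integer(q2), st$C)
  stopifnot(all(q2 >= 1), all(q2 <= st$Hc), q1 >= 1, q1 <= st$C, u > 0)

  fit <- refit(X, y, integer(0))
  beta <- fit$beta; beta0 <- fit$beta0
  ll_trace <- fit$loglik
  tau_trace <- numeric(0)
  sel <- NULL
  best <- list(ll = fit$loglik, beta = beta, beta0 = beta0, sel = NULL,
               fit = fit)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    grad <- gradient(X, y, beta, beta0)
    W <- build_block_W(X, y, beta, beta0, st, q2,
                       diagonal = (method == "jsd"), scale_wc = scale_wc)
    if (compute_tau) tau_trace <- c(tau_trace, tau_bound(X, W))
    omega <- surrogate_argmax(beta, grad, W, u)
    sel <- constrained_select(omega, W, q1)
    cols <- unlist(st$columns_of_gene[sel$genes], use.names = FALSE)
    fit <- refit(X, y, cols)
    ll_trace <- c(ll_trace, fit$loglik)
    if (fit$loglik >= best$ll) {
      best <- list(ll = fit$loglik, beta = fit$beta, beta0 = fit$beta0,
                   sel = sel, fit = fit)
    }
    num <- sqrt(sum((fit$beta - beta)^2))
    den <- sqrt(sum(beta^2))
    delta <- if (den < 1e-12) num else num / den
    beta <- fit$beta; beta0 <- fit$beta0
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && !is.null(best$sel)) {
    beta <- best$beta; beta0 <- best$beta0; sel <- best$sel
  }
  genes_by_cluster <- split(sel$genes, st$cluster_of_gene[sel$genes])
  res <- list(beta = beta, beta0 = beta0,
              retained_genes = sel$genes,
              retained_clusters = sel$clusters,
              retained_genes_by_cluster = genes_by_cluster,
              retained_columns = unlist(st$columns_of_gene[sel$genes],
                                        use.names = FALSE),
              gene_scores = sel$gene_scores,
              cluster_scores = sel$cluster_scores,
              loglik_trace = ll_trace, tau_trace = tau_trace,
              iterations = iter, converged = converged,
              structure = st,
              config = list(q1 = q1, q2 = q2, u = u, tol = tol,
                            max_iter = max_iter, method = method,
                            scale_wc = scale_wc),
              xnames = colnames(X), call = match.call())
  class(res) <- "jsbd"
  res
}

#' Curvature-ratio bound for the surrogate constant
#'
#' Upper bound on \code{tau(k) = sup_beta lambda_max(W^{-1/2} (-l''(beta))
#' W^{-1/2})} at the current W, using the logistic curvature bound
#' \code{-l''(beta) <= X'X / 4}.  Forms dense p x p matrices; intended as a
#' diagnostic on small problems to verify \code{u >= tau(k)} (the ascent
#' condition).
#'
#' @param X design matrix.
#' @param W a \code{\link{build_block_W}} object.
#' @return Scalar bound on \code{tau(k)}.
#' @export
tau_bound <- function(X, W) {
  st <- W$structure
  Wd <- matrix(0, st$p, st$p)
  for (g in seq_len(st$G)) {
    cols <- st$columns_of_gene[[g]]
    Wd[cols, cols] <- W$blocks[[g]] * W$scale[g]
  }
  e <- eigen(Wd, symmetric = TRUE)
  lam <- pmax(e$values, 1e-300)
  Whalf_inv <- e$vectors %*% (t(e$vectors) / sqrt(lam))
  H <- crossprod(X) / 4
  max(eigen(Whalf_inv %*% H %*% Whalf_inv, symmetric = TRUE,
            only.values = TRUE)$values)
}

#' @export
print.jsbd <- function(x, ...) {
  cat(sprintf("Joint screening (%s): retained %d genes in %d clusters\n",
              toupper(x$config$method), length(x$retained_genes),
              length(x$retained_clusters)))
  cat(sprintf("  %d iterations, converged: %s, log-likelihood %.4f\n",
              x$iterations, x$converged, x$loglik_trace[length(x$loglik_trace)]))
  invisible(x)
}

#' @export
summary.jsbd <- function(object, ...) {
  st <- object$structure
  tab <- data.frame(gene = object$retained_genes,
                    cluster = st$cluster_of_gene[object$retained_genes],
                    score = object$gene_scores[object$retained_genes])
  tab <- tab[order(-tab$score), ]
  rownames(tab) <- NULL
  out <- list(config = object$config, retained = tab,
              cluster_scores = object$cluster_scores[object$retained_clusters],
              retained_clusters = object$retained_clusters,
              loglik = object$loglik_trace[length(object$loglik_trace)],
              iterations = object$iterations, converged = object$converged)
  class(out) <- "summary.jsbd"
  out
}

#' @export
print.summary.jsbd <- function(x, ...) {
  cat(sprintf("Joint screening (%s), q1 = %d, u = %g\n",
              toupper(x$config$method), x$config$q1, x$config$u))
  cat(sprintf("  converged in %d iterations; final log-likelihood %.4f\n",
              x$iterations, x$loglik))
  cat("Retained genes (by score):\n")
  print(utils::head(x$retained, 20))
  if (nrow(x$retained) > 20) cat("  ...\n")
  invisible(x)
}

#' @export
coef.jsbd <- function(object, ...) {
  nm <- if (!is.null(object$xnames)) object$xnames
        else paste0("x", seq_along(object$beta))
  stats::setNames(c(object$beta0, object$beta), c("(Intercept)", nm))
}

#' @export
predict.jsbd <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- object$beta0 + linear_predictor(as.matrix(newdata), object$beta)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
plot.jsbd <- function(x, ...) {
  graphics::plot(seq_along(x$loglik_trace) - 1L, x$loglik_trace, type = "b",
       xlab = "iteration", ylab = "log-likelihood",
       main = sprintf("%s screening ascent", toupper(x$config$method)), ...)
  invisible(x)
}
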