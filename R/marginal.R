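#' Omics-level marginal screening (OMS)
#'
#' Fits a univariable logistic regression for every omics column and ranks
#' columns by the Wald p-value of the slope; the \code{k} smallest-p columns
#' are retained.  All p single-covariate Newton fits are run simultaneously
#' through vectorised column-wise updates.  Non-convergent fits are assigned
#' p-value 1 and flagged.  Ties are broken by ascending column index.
#'
#' @param X n x p design matrix.
#' @param y binary 0/1 outcome.
#' @param k number of omics columns to retain.
#' @param max_iter Newton cap per column.
#' @return List: \code{retained} (column indices, ranked), \code{p_values}
#'   (length p), \code{converged} (logical length p).
#' @export
oms_screen <- function(X, y, k, max_iter = 30L) {
  check_binary(y)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(k >= 1, k <= p)
  ybar <- mean(y)
  b0 <- rep(stats::qlogis(min(max(ybar, 1e-6), 1 - 1e-6)), p)
  b1 <- numeric(p)
  active <- rep(TRUE, p)
  converged <- rep(FALSE, p)
  se2 <- rep(NA_real_, p)
  for (it in seq_len(max_iter)) {
    Eta <- X * rep(b1, each = n) + rep(b0, each = n)
    Eta <- pmin(pmax(Eta, -30), 30)
    Mu <- stats::plogis(Eta)
    Wt <- Mu * (1 - Mu)
    R <- y - Mu                        # y recycles down columns
    g0 <- colSums(R); g1 <- colSums(X * R)
    h00 <- colSums(Wt); h01 <- colSums(X * Wt); h11 <- colSums(X * X * Wt)
    det <- h00 * h11 - h01^2
    det[det <= 0] <- NA_real_
    db0 <- (h11 * g0 - h01 * g1) / det
    db1 <- (h00 * g1 - h01 * g0) / det
    db0[!active | !is.finite(db0)] <- 0
    db1[!active | !is.finite(db1)] <- 0
    b0 <- b0 + db0; b1 <- b1 + db1
    done <- active & (pmax(abs(db0), abs(db1)) < 1e-8)
    converged[done] <- TRUE
    se2[active] <- (h00 / det)[active]
    active <- active & !done
    if (!any(active)) break
  }
  z <- b1 / sqrt(se2)
  pv <- 2 * stats::pnorm(-abs(z))
  pv[!converged | !is.finite(pv)] <- 1
  ord <- order(pv, seq_len(p))
  list(retained = ord[seq_len(k)], p_values = pv, converged = converged,
       coefficients = b1)
}

#' Gene-level marginal screening (GMS)
#'
#' Fits, for every gene, a logistic regression on the gene's n0 omics columns
#' and ranks genes by the likelihood-ratio test p-value of the n0 slope
#' coefficients against the intercept-only model; the \code{k} smallest-p
#' genes are retained.  Ties are broken by ascending gene index.
#'
#' @param X n x p design matrix.
#' @param y binary 0/1 outcome.
#' @param structure an \code{\link{omics_structure}}.
#' @param k number of genes to retain.
#' @return List: \code{retained} (gene indices, ranked), \code{p_values}
#'   (length G).
#' @export
gms_screen <- function(X, y, structure, k) {
  check_binary(y)
  stopifnot(inherits(structure, "omics_structure"), k >= 1, k <= structure$G)
  X <- as.matrix(X)
  null_fit <- refit(X, y, integer(0))
  pv <- vapply(seq_len(structure$G), function(g) {
    cols <- structure$columns_of_gene[[g]]
    f <- refit(X, y, cols)
    if (!f$converged) return(1)
    stat <- 2 * (f$loglik - null_fit$loglik)
    stats::pchisq(max(stat, 0), df = length(cols), lower.tail = FALSE)
  }, numeric(1))
  ord <- order(pv, seq_len(structure$G))
  list(retained = ord[seq_len(k)], p_values = pv)
}

#' Gene retention metrics of a screening result
#'
#' Compares a retained gene set with the true non-zero genes:
#' \code{all_retained} is 1 when every true gene survived screening and
#' \code{proportion} is the fraction of true genes that survived.  For
#' omics-level screening (OMS), a gene counts as retained when at least one
#' of its omics is retained (set \code{all_omics = TRUE} to require all of
#' them instead).
#'
#' @param retained retained gene indices, or for \code{omics = TRUE} retained
#'   omics column indices.
#' @param true_genes true non-zero gene indices.
#' @param structure required when \code{omics = TRUE}, to map columns to
#'   genes.
#' @param omics interpret \code{retained} as omics column indices.
#' @param all_omics with \code{omics = TRUE}, require all of a gene's omics.
#' @return List: \code{all_retained} (0/1), \code{proportion}.
#' @export
retention_metrics <- function(retained, true_genes, structure = NULL,
                              omics = FALSE, all_omics = FALSE) {
  if (omics) {
    stopifnot(inherits(structure, "omics_structure"))
    genes <- structure$gene_of_col[retained]
    retained <- if (all_omics) {
      cnt <- table(genes)
      as.integer(names(cnt)[cnt == structure$n0])
    } else unique(genes)
  }
  hit <- true_genes %in% retained
  list(all_retained = as.integer(all(hit)),
       proportion = mean(hit))
}
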