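#' Group-bridge penalized logistic regression
#'
#' Fits the group-bridge penalized logistic regression
#' \deqn{L(\beta) = -l(\beta) + \lambda \sum_c |A_c|^{1/2}
#'   \big(\sum_{j \in A_c} |\beta_j|\big)^{1/2},}
#' which selects at both the group (cluster) and individual (omics) level.
#' After screening, gene clusters are the groups and all omics of genes in a
#' cluster are the individual variables.
#'
#' The bridge exponent 1/2 is handled by the standard variational
#' reformulation: writing \eqn{a^{1/2} = \min_{\theta>0} \{ \theta^{-1/2} a/2
#' + \theta^{1/2}/2 \}}, the fit alternates a closed-form update of the
#' per-group scale \eqn{\theta_c = \sum_{j \in A_c} |\beta_j|} with a weighted
#' L1-penalized logistic step (solved by \pkg{glmnet} with per-coefficient
#' penalty factors).  The intercept is unpenalized.  Initialisation is the
#' ridge-safeguarded maximum-likelihood fit, so the fit is deterministic.
#' The penalized objective is non-increasing over iterations.
#'
#' @param X n x d design matrix of the retained variables (d < n).
#' @param y binary 0/1 outcome.
#' @param groups length-d integer vector of group (cluster) memberships.
#' @param lambda penalty level (single non-negative value).
#' @param max_iter outer alternation cap.
#' @param tol relative convergence threshold on the objective.
#' @param init optional initial coefficient list \code{list(beta, beta0)}.
#' @return List: \code{beta}, \code{beta0}, \code{objective} (final),
#'   \code{objective_trace}, \code{converged}, \code{iterations}.
#' @export
group_bridge_fit <- function(X, y, groups, lambda, max_iter = 100L,
                             tol = 1e-7, init = NULL) {
  check_binary(y)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(length(groups) == d, d < n, lambda >= 0)
  groups <- match(groups, sort(unique(groups)))
  gsize <- tabulate(groups)
  cc <- sqrt(gsize)[groups]              # per-coefficient group constant
  penalty <- function(beta) {
    a <- rowsum(abs(beta), groups)[, 1]
    lambda * sum(sqrt(tabulate(groups)) * sqrt(a))
  }
  objective <- function(beta, beta0)
    -loglik(X, y, beta, beta0) + penalty(beta)

  if (is.null(init)) {
    f <- ridge_mle(X, y)
    beta <- f$beta; beta0 <- f$beta0
  } else { beta <- init$beta; beta0 <- init$beta0 }
  if (lambda == 0) {
    f <- ridge_mle(X, y)
    return(list(beta = f$beta, beta0 = f$beta0,
                objective = objective(f$beta, f$beta0),
                objective_trace = objective(f$beta, f$beta0),
                converged = TRUE, iterations = 0L))
  }
  obj <- objective(beta, beta0)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a <- rowsum(abs(beta), groups)[, 1]          # theta_c update
    live <- a[groups] > 1e-12
    if (!any(live)) { beta[] <- 0; beta0 <- stats::qlogis(mean(y)) }
    else {
      w <- rep(Inf, d)
      w[live] <- lambda * cc[live] / (2 * sqrt(a[groups][live]))
      sol <- weighted_l1_logistic(X, y, w, beta, beta0)
      ## keep the previous iterate if the inner solver failed to improve the
      ## majorizing surrogate (e.g. solver hit its iteration cap)
      if (isTRUE(objective(sol$beta, sol$beta0) <= obj + 1e-10)) {
        beta <- sol$beta; beta0 <- sol$beta0
      }
    }
    obj_new <- objective(beta, beta0)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) < tol * (abs(obj) + 1)) { converged <- TRUE; break }
    obj <- obj_new
  }
  list(beta = beta, beta0 = beta0, objective = trace[length(trace)],
       objective_trace = trace, converged = converged, iterations = it)
}

## logistic MLE with a tiny ridge safeguard (deterministic initialiser)
ridge_mle <- function(X, y, ridge = 1e-6, max_iter = 100L) {
  n <- nrow(X); d <- ncol(X)
  Z <- cbind(1, X)
  theta <- c(stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)), numeric(d))
  pen <- c(0, rep(ridge, d))
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(as.numeric(Z %*% theta), -30), 30)
    mu <- stats::plogis(eta)
    g <- as.numeric(crossprod(Z, y - mu)) - pen * theta
    H <- crossprod(Z, (mu * (1 - mu)) * Z) + diag(pen + 1e-12, d + 1)
    step <- solve(H, g)
    theta <- theta + step
    if (max(abs(step)) < 1e-10) break
  }
  list(beta = theta[-1], beta0 = theta[1])
}

## Weighted L1-penalized logistic regression: minimise -l(beta) + sum w_j |beta_j|.
## Coefficients with infinite weight are excluded.  Solved with glmnet when at
## least two penalized columns remain, else by an exact 1-d profile search.
weighted_l1_logistic <- function(X, y, w, beta_init, beta0_init) {
  d <- ncol(X); n <- nrow(X)
  keep <- which(is.finite(w))
  beta <- numeric(d)
  if (length(keep) == 0L)
    return(list(beta = beta, beta0 = stats::qlogis(mean(y))))
  if (length(keep) == 1L) {
    j <- keep
    prof <- function(b1) {
      f <- profile_intercept(X[, j], y, b1)
      -f$loglik + w[j] * abs(b1)
    }
    opt <- stats::optimize(prof, interval = c(-50, 50), tol = 1e-9)
    b1 <- opt$minimum
    if (prof(0) <= opt$objective) b1 <- 0   # kink at zero can beat the interior
    beta[j] <- b1
    return(list(beta = beta, beta0 = profile_intercept(X[, j], y, b1)$beta0))
  }
  Xk <- X[, keep, drop = FALSE]
  wk <- w[keep]
  lam <- sum(wk) / (n * length(keep))      # glmnet rescales pf to sum to nvars
  fit <- suppressWarnings(
    glmnet::glmnet(Xk, y, family = "binomial", lambda = lam,
                   penalty.factor = wk, standardize = FALSE,
                   thresh = 1e-11, maxit = 10^6))
  if (fit$jerr != 0 && length(fit$lambda) < 1L)
    return(list(beta = numeric(d) * NA, beta0 = NA_real_))
  beta[keep] <- as.numeric(fit$beta[, 1])
  list(beta = beta, beta0 = as.numeric(fit$a0[1]))
}

## intercept-profiled single-covariate logistic log-likelihood at fixed slope
profile_intercept <- function(x, y, b1) {
  off <- b1 * x
  b0 <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  for (it in 1:50) {
    eta <- pmin(pmax(b0 + off, -30), 30)
    mu <- stats::plogis(eta)
    g <- sum(y - mu); h <- sum(mu * (1 - mu))
    step <- g / max(h, 1e-12)
    b0 <- b0 + step
    if (abs(step) < 1e-12) break
  }
  eta <- pmin(pmax(b0 + off, -30), 30)
  list(beta0 = b0, loglik = sum(y * eta - log1pexp(eta)))
}

#' BIC of a fitted sparse logistic model
#'
#' \code{BIC = -2 l(beta_hat) + df log(n)} with \code{df} the number of
#' non-zero coefficients plus one for the intercept.
#'
#' @param X,y data.
#' @param beta,beta0 fitted coefficients.
#' @return Scalar BIC.
#' @export
bic_logistic <- function(X, y, beta, beta0) {
  df <- sum(beta != 0) + 1
  -2 * loglik(X, y, beta, beta0) + df * log(nrow(as.matrix(X)))
}

#' Group-bridge fit with BIC-tuned penalty
#'
#' Fits \code{\link{group_bridge_fit}} over a grid of penalty levels and
#' selects the one minimising the BIC.  When \code{lambda} is \code{NULL} the
#' grid is \code{nlambda} log-spaced values from \code{lambda_max} (the
#' smallest penalty producing the all-zero model, located by bisection) down
#' to \code{lambda_min_ratio * lambda_max}.  Grid ties go to the larger
#' (sparser) penalty.
#'
#' @param X n x d matrix of retained variables.
#' @param y binary 0/1 outcome.
#' @param groups length-d group membership vector (clusters).
#' @param lambda optional user grid (or a single value).
#' @param nlambda,lambda_min_ratio grid shape.
#' @param structure optional \code{\link{omics_structure}} of the \emph{full}
#'   design together with \code{columns}, the indices of the retained columns
#'   in that design, to report selected genes.
#' @param columns see \code{structure}.
#' @return Object of class \code{"group_bridge"}: \code{beta}, \code{beta0}
#'   (at the selected penalty), \code{lambda}, \code{selected_lambda},
#'   \code{bic}, \code{beta_path} (d x nlambda), \code{selected_omics}
#'   (indices into \code{1..d}), \code{selected_genes} (when structure
#'   given), \code{groups}.
#' @export
group_bridge <- function(X, y, groups, lambda = NULL, nlambda = 50L,
                         lambda_min_ratio = 1e-3, structure = NULL,
                         columns = NULL) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (is.null(lambda)) {
    lmax <- lambda_max_bisect(X, y, groups)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  path <- matrix(0, d, length(lambda))
  b0s <- numeric(length(lambda))
  bics <- numeric(length(lambda))
  ## every fit starts from the same ridge MLE: the all-zero model is a fixed
  ## point of the alternation, so warm starts down the path would stick there
  init <- ridge_mle(X, y)
  for (i in seq_along(lambda)) {
    f <- group_bridge_fit(X, y, groups, lambda[i], init = init)
    path[, i] <- f$beta; b0s[i] <- f$beta0
    bics[i] <- bic_logistic(X, y, f$beta, f$beta0)
  }
  best <- which(bics == min(bics))[1]  # grid is decreasing: first = largest lambda
  beta <- path[, best]
  sel_omics <- which(beta != 0)
  sel_genes <- NULL
  if (!is.null(structure)) {
    full_beta <- numeric(structure$p)
    full_beta[if (is.null(columns)) seq_len(d) else columns] <- beta
    sel_genes <- selected_genes_from_omics(full_beta, structure)
  }
  res <- list(beta = beta, beta0 = b0s[best], lambda = lambda,
              selected_lambda = lambda[best], bic = bics,
              beta_path = path, beta0_path = b0s,
              selected_omics = sel_omics, selected_genes = sel_genes,
              groups = groups, xnames = colnames(X), call = match.call())
  class(res) <- "group_bridge"
  res
}

## smallest lambda whose group-bridge fit is the all-zero model
lambda_max_bisect <- function(X, y, groups, tol = 0.01) {
  is_null_at <- function(l)
    all(group_bridge_fit(X, y, groups, l, max_iter = 50L)$beta == 0)
  hi <- 1
  while (!is_null_at(hi)) { hi <- hi * 4; if (hi > 1e8) return(hi) }
  lo <- hi / 4
  while (is_null_at(lo) && lo > 1e-8) { hi <- lo; lo <- lo / 4 }
  while ((hi - lo) / hi > tol) {
    mid <- sqrt(lo * hi)
    if (is_null_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Map non-zero omics coefficients to selected genes
#'
#' A gene is selected when at least one of its omics has a non-zero
#' coefficient.
#'
#' @param beta full-length (p) coefficient vector.
#' @param structure an \code{\link{omics_structure}}.
#' @return Sorted integer vector of selected gene indices.
#' @export
selected_genes_from_omics <- function(beta, structure) {
  stopifnot(length(beta) == structure$p)
  sort(unique(structure$gene_of_col[beta != 0]))
}

#' @export
print.group_bridge <- function(x, ...) {
  cat(sprintf("Group-bridge logistic fit: %d variables in %d groups\n",
              length(x$beta), length(unique(x$groups))))
  cat(sprintf("  lambda grid of %d, selected lambda = %.4g (BIC = %.2f)\n",
              length(x$lambda), x$selected_lambda, min(x$bic)))
  cat(sprintf("  %d non-zero omics", length(x$selected_omics)))
  if (!is.null(x$selected_genes))
    cat(sprintf(" in %d genes", length(x$selected_genes)))
  cat("\n")
  invisible(x)
}

#' @export
coef.group_bridge <- function(object, ...) {
  nm <- if (!is.null(object$xnames)) object$xnames
        else paste0("x", seq_along(object$beta))
  stats::setNames(c(object$beta0, object$beta), c("(Intercept)", nm))
}

#' @export
predict.group_bridge <- function(object, newdata,
                                 type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- object$beta0 + as.numeric(as.matrix(newdata) %*% object$beta)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
plot.group_bridge <- function(x, ...) {
  graphics::matplot(log(x$lambda), t(x$beta_path), type = "l", lty = 1,
                    xlab = "log(lambda)", ylab = "coefficient",
                    main = "Group-bridge path", ...)
  graphics::abline(v = log(x$selected_lambda), lty = 2)
  invisible(x)
}
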