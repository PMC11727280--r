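## Logistic-family plumbing used by the screening algorithms.  Only the
## logistic (binomial, logit link) family is implemented; the screening core
## is written against these three primitives so other exponential families
## would slot in here.

## numerically stable log(1 + exp(eta))
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

check_binary <- function(y) {
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1 for the logistic family")
}

#' Logistic log-likelihood, score and Hessian blocks
#'
#' Exact quantities for the logistic regression model
#' \code{logit P(y=1|x) = beta0 + x' beta}.  \code{hessian_block} returns the
#' requested square sub-matrix of the Hessian \code{l''(beta)} (with respect
#' to the slope coefficients only) without ever forming the p x p Hessian.
#'
#' @param X n x p design matrix (no intercept column).
#' @param y binary 0/1 outcome vector.
#' @param beta length-p coefficient vector.
#' @param beta0 intercept.
#' @param columns integer vector of column indices for the Hessian sub-block.
#' @return \code{loglik}: scalar; \code{gradient}: length-p score vector;
#'   \code{hessian_block}: the (columns x columns) block of \code{l''(beta)}
#'   (negative semidefinite).
#' @export
loglik <- function(X, y, beta, beta0 = 0) {
  check_binary(y)
  eta <- beta0 + linear_predictor(X, beta)
  sum(y * eta - log1pexp(eta))
}

#' @rdname loglik
#' @export
gradient <- function(X, y, beta, beta0 = 0) {
  check_binary(y)
  eta <- beta0 + linear_predictor(X, beta)
  as.numeric(crossprod(X, y - stats::plogis(eta)))
}

#' @rdname loglik
#' @export
hessian_block <- function(X, y, beta, beta0 = 0, columns) {
  check_binary(y)
  eta <- beta0 + linear_predictor(X, beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  Xc <- X[, columns, drop = FALSE]
  -crossprod(Xc, w * Xc)
}

## X %*% beta exploiting sparsity of beta
linear_predictor <- function(X, beta) {
  nz <- which(beta != 0)
  if (length(nz) == 0) return(numeric(nrow(X)))
  as.numeric(X[, nz, drop = FALSE] %*% beta[nz])
}

#' Safeguarded logistic maximum likelihood over a column subset
#'
#' Newton (IRLS) maximisation of the logistic log-likelihood restricted to the
#' given columns, with all other coefficients fixed at zero and an unpenalised
#' intercept.  Safeguards against separation at small n: at most
#' \code{max_iter} Newton steps, step halving whenever a step would decrease
#' the log-likelihood, and the linear predictor is bounded at \code{eta_cap}
#' in absolute value when evaluating likelihood and weights.  Rank-deficient
#' designs (e.g. duplicated columns) are resolved deterministically by a small
#' ridge on the Newton system, and flagged.
#'
#' @param X,y design matrix and binary outcome.
#' @param columns integer vector of retained column indices (possibly empty).
#' @param max_iter Newton step cap (default 50).
#' @param tol convergence threshold on the log-likelihood change.
#' @param eta_cap bound on the absolute linear predictor.
#' @return List: \code{beta} (full-length p vector, zeros off \code{columns}),
#'   \code{beta0}, \code{loglik}, \code{converged}, \code{iterations},
#'   \code{ridged} (TRUE when the Newton system needed regularisation).
#' @export
refit <- function(X, y, columns, max_iter = 50L, tol = 1e-10, eta_cap = 30) {
  check_binary(y)
  n <- nrow(X); p <- ncol(X)
  columns <- sort(unique(as.integer(columns)))
  stopifnot(length(columns) < n)
  ybar <- mean(y)
  beta <- numeric(p)
  if (ybar == 0 || ybar == 1) {
    ## degenerate outcome: intercept at the capped MLE
    b0 <- ifelse(ybar == 1, eta_cap, -eta_cap)
    return(list(beta = beta, beta0 = b0,
                loglik = loglik(X, y, beta, b0),
                converged = TRUE, iterations = 0L, ridged = FALSE))
  }
  b0 <- stats::qlogis(ybar)
  if (length(columns) == 0L) {
    return(list(beta = beta, beta0 = b0, loglik = loglik(X, y, beta, b0),
                converged = TRUE, iterations = 0L, ridged = FALSE))
  }
  Z <- cbind(1, X[, columns, drop = FALSE])
  d <- ncol(Z)
  theta <- c(b0, numeric(d - 1L))
  ll_of <- function(th) {
    eta <- pmin(pmax(as.numeric(Z %*% th), -eta_cap), eta_cap)
    sum(y * eta - log1pexp(eta))
  }
  ll <- ll_of(theta)
  ridged <- FALSE
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- pmin(pmax(as.numeric(Z %*% theta), -eta_cap), eta_cap)
    mu <- stats::plogis(eta)
    g <- as.numeric(crossprod(Z, y - mu))
    H <- crossprod(Z, (mu * (1 - mu)) * Z)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      ridged <- TRUE
      H <- H + (1e-8 * sum(diag(H)) / d + 1e-12) * diag(d)
      step <- solve(H, g)
    }
    ## step halving on log-likelihood decrease
    ll_new <- ll_of(theta + step)
    halvings <- 0L
    while (ll_new < ll && halvings < 30L) {
      step <- step / 2
      ll_new <- ll_of(theta + step)
      halvings <- halvings + 1L
    }
    theta <- theta + step
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  beta[columns] <- theta[-1L]
  list(beta = beta, beta0 = theta[1L], loglik = ll,
       converged = converged, iterations = iter, ridged = ridged)
}
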