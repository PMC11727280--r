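#' End-to-end tri-level variable selection
#'
#' Runs the full three-stage pipeline on a multi-omics design: (1) cluster
#' genes by canonical correlation (skipped when labels are supplied), (2)
#' joint screening (JSBD) of clusters and genes, (3) group-bridge penalized
#' logistic regression on the retained columns, with gene clusters as groups,
#' tuned by BIC.
#'
#' @param X n x p design matrix, genes in consecutive \code{n0}-column blocks.
#' @param y binary 0/1 outcome.
#' @param n0 omics per gene.
#' @param labels optional per-gene cluster labels; when \code{NULL} the
#'   clustering stage estimates them.
#' @param q1 maximum clusters retained by screening.
#' @param q2 per-cluster gene caps (default: 10\% of cluster size rule).
#' @param u,tol,max_iter,method screening controls (see \code{\link{jsbd}}).
#' @param power,k clustering controls (see \code{\link{cluster_genes}}).
#' @param nlambda,lambda_min_ratio group-bridge grid controls.
#' @return Object of class \code{"trilevel_pipeline"}: \code{clustering}
#'   (labels used and the \code{gene_clustering} object when estimated),
#'   \code{screening} (the \code{\link{jsbd}} fit), \code{fit} (the
#'   \code{\link{group_bridge}} fit), \code{selected_genes},
#'   \code{selected_omics} (column indices in the full design).
#' @export
run_pipeline <- function(X, y, n0 = 3L, labels = NULL, q1 = 8L, q2 = NULL,
                         u = 1e5, tol = 1e-6, max_iter = 100L,
                         method = "jsbd", power = 6, k = NULL,
                         nlambda = 50L, lambda_min_ratio = 1e-3) {
  X <- as.matrix(X)
  G <- ncol(X) %/% n0
  stopifnot(ncol(X) == G * n0)
  clustering <- NULL
  if (is.null(labels)) {
    base_st <- omics_structure(seq_len(G), n0 = n0)
    assoc <- gene_association_matrix(X, base_st)
    clustering <- cluster_genes(assoc, power = power, k = k)
    labels <- clustering$labels
  }
  st <- omics_structure(labels, n0 = n0)
  screen <- jsbd(X, y, st, q1 = q1, q2 = q2, u = u, tol = tol,
                 max_iter = max_iter, method = method)
  cols <- screen$retained_columns
  groups <- st$cluster_of_col[cols]
  fit <- group_bridge(X[, cols, drop = FALSE], y, groups,
                      nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                      structure = st, columns = cols)
  res <- list(clustering = list(labels = labels, result = clustering),
              screening = screen, fit = fit,
              selected_genes = fit$selected_genes,
              selected_omics = cols[fit$selected_omics],
              structure = st, call = match.call())
  class(res) <- "trilevel_pipeline"
  res
}

#' @export
print.trilevel_pipeline <- function(x, ...) {
  cat("Tri-level variable selection pipeline\n")
  cat(sprintf("  clustering: %d clusters (%s)\n",
              x$structure$C,
              if (is.null(x$clustering$result)) "supplied" else "estimated"))
  cat(sprintf("  screening:  %d genes retained in %d clusters\n",
              length(x$screening$retained_genes),
              length(x$screening$retained_clusters)))
  cat(sprintf("  selection:  %d omics in %d genes (lambda = %.4g)\n",
              length(x$selected_omics), length(x$selected_genes),
              x$fit$selected_lambda))
  invisible(x)
}

#' Monte-Carlo screening study
#'
#' Replicates the screening comparison: for each replicate a dataset is
#' simulated from \code{scenario}, cluster labels are optionally perturbed,
#' JSBD is run, and the competitors are run size-matched to it --- GMS retains
#' as many genes as JSBD did and OMS retains \code{n0} times as many omics.
#' Per method the proportion of replicates retaining \emph{all} true non-zero
#' genes, and the mean and SD over replicates of the fraction retained, are
#' reported.  Replicates are independently seeded from the master seed, so
#' results do not depend on evaluation order.
#'
#' @param scenario a \code{\link{simulation_scenario}}.
#' @param methods subset of \code{c("jsbd", "jsd", "oms", "gms")}.
#' @param reps number of replicates.
#' @param seed master seed.
#' @param perturb_fraction fraction of gene cluster labels randomly moved to a
#'   wrong cluster before screening (0 = perfect clustering).
#' @param q1,u,tol screening controls; \code{q2} follows the 10\%-of-cluster
#'   rule on whichever labels are used.
#' @return Object of class \code{"screening_study"}: \code{summary}
#'   (data.frame with one row per method: \code{prop_all_retained},
#'   \code{mean_prop_retained}, \code{sd_prop_retained}), \code{per_replicate}
#'   (matrix of retained fractions), \code{ari} (mean realised ARI of the
#'   perturbed labels vs truth, \code{NA} when unperturbed), \code{reps},
#'   \code{seed}, \code{failed} (count of failed replicates, excluded).
#' @export
simulation_study <- function(scenario, methods = c("jsbd", "jsd", "oms", "gms"),
                             reps = 200L, seed = 1L, perturb_fraction = 0,
                             q1 = 8L, u = 1e5, tol = 1e-6) {
  methods <- match.arg(methods, c("jsbd", "jsd", "oms", "gms"),
                       several.ok = TRUE)
  stopifnot(reps >= 1)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  prop <- matrix(NA_real_, reps, length(methods),
                 dimnames = list(NULL, methods))
  allr <- prop
  aris <- rep(NA_real_, reps)
  failed <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch(
      run_study_replicate(scenario, methods, rep_seeds[r], perturb_fraction,
                          q1, u, tol),
      error = function(e) e)
    if (inherits(res, "error")) { failed <- failed + 1L; next }
    prop[r, ] <- res$prop
    allr[r, ] <- res$all
    aris[r] <- res$ari
  }
  ok <- stats::complete.cases(prop)
  summary <- data.frame(
    method = methods,
    prop_all_retained = colMeans(allr[ok, , drop = FALSE]),
    mean_prop_retained = colMeans(prop[ok, , drop = FALSE]),
    sd_prop_retained = apply(prop[ok, , drop = FALSE], 2, stats::sd),
    row.names = NULL)
  structure(list(summary = summary, per_replicate = prop,
                 all_retained = allr,
                 ari = if (perturb_fraction > 0) mean(aris[ok]) else NA_real_,
                 reps = reps, seed = seed, failed = failed,
                 perturb_fraction = perturb_fraction, scenario = scenario),
            class = "screening_study")
}

run_study_replicate <- function(scenario, methods, rep_seed, perturb_fraction,
                                q1, u, tol) {
  dat <- simulate_dataset(scenario, seed = rep_seed)
  st <- dat$structure
  if (perturb_fraction > 0) {
    labels <- permute_cluster_labels(st$cluster_of_gene, perturb_fraction,
                                     seed = dat$seeds[3])
    ari <- adjusted_rand_index(labels, st$cluster_of_gene)
    st <- relabel_structure(st, labels)
  } else ari <- NA_real_
  truth <- dat$true_nonzero_genes
  out_all <- out_prop <- stats::setNames(numeric(length(methods)), methods)
  n_jsbd <- NA_integer_
  js_fit <- NULL
  if (any(c("jsbd", "oms", "gms") %in% methods)) {
    js_fit <- jsbd(dat$X, dat$y, st, q1 = q1, u = u, tol = tol)
    n_jsbd <- length(js_fit$retained_genes)
  }
  n_kept <- stats::setNames(rep(NA_integer_, length(methods)), methods)
  for (m in methods) {
    retained <- switch(m,
      jsbd = js_fit$retained_genes,
      jsd = jsbd(dat$X, dat$y, st, q1 = q1, u = u, tol = tol,
                 method = "jsd")$retained_genes,
      gms = gms_screen(dat$X, dat$y, st, k = n_jsbd)$retained,
      oms = NULL)
    met <- if (m == "oms") {
      oms <- oms_screen(dat$X, dat$y, k = st$n0 * n_jsbd)
      n_kept[m] <- length(oms$retained)
      retention_metrics(oms$retained, truth, structure = st, omics = TRUE)
    } else {
      n_kept[m] <- length(retained)
      retention_metrics(retained, truth)
    }
    out_all[m] <- met$all_retained
    out_prop[m] <- met$proportion
  }
  list(all = out_all, prop = out_prop, ari = ari, n_retained = n_kept)
}

#' @export
print.screening_study <- function(x, ...) {
  cat(sprintf("Screening study: %d replicates (%d failed), seed %d\n",
              x$reps, x$failed, x$seed))
  if (x$perturb_fraction > 0)
    cat(sprintf("  imperfect clustering: %.0f%% of labels moved, mean ARI %.3f\n",
                100 * x$perturb_fraction, x$ari))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Area under the ROC curve
#'
#' Wrapper around \pkg{pROC} returning the AUC of predicted scores for a
#' binary outcome.
#'
#' @param y binary 0/1 outcome.
#' @param score numeric predictions (higher = more likely 1).
#' @return Scalar AUC.
#' @export
auc_score <- function(y, score) {
  as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Repeated cross-validated AUC of the tri-level pipeline
#'
#' Stratified k-fold cross-validation, repeated: within each training fold
#' the full pipeline (screening then group bridge; clustering labels are
#' supplied or estimated once per fold) is refit, and the AUC of the held-out
#' fold's predicted probabilities is recorded, along with the number of genes
#' selected.
#'
#' @param X,y data.
#' @param n0 omics per gene.
#' @param labels optional per-gene cluster labels (recommended: estimate once
#'   on the full data or supply known labels).
#' @param folds,repeats cross-validation design (default 5 x 20).
#' @param seed seed for the fold draws.
#' @param ... passed to \code{\link{run_pipeline}}.
#' @return Object of class \code{"cv_report"}: \code{mean_auc}, \code{sd_auc},
#'   \code{mean_genes}, \code{sd_genes}, \code{auc} (per fold x repeat),
#'   \code{n_genes}.
#' @export
cv_auc <- function(X, y, n0 = 3L, labels = NULL, folds = 5L, repeats = 20L,
                   seed = 1L, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, folds >= 2)
  set.seed(as.integer(seed))
  aucs <- ngenes <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      pl <- run_pipeline(X[tr, , drop = FALSE], y[tr], n0 = n0,
                         labels = labels, ...)
      prob <- predict(pl$fit, X[!tr, pl$screening$retained_columns,
                                drop = FALSE], type = "response")
      aucs <- c(aucs, auc_score(y[!tr], prob))
      ngenes <- c(ngenes, length(pl$selected_genes))
    }
  }
  structure(list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
                 mean_genes = mean(ngenes), sd_genes = stats::sd(ngenes),
                 auc = aucs, n_genes = ngenes,
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_report")
}

## stratified fold assignment: both classes spread across folds
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation repeated %d times\n",
              x$folds, x$repeats))
  cat(sprintf("  mean AUC %.3f (SD %.3f); mean genes selected %.2f (SD %.2f)\n",
              x$mean_auc, x$sd_auc, x$mean_genes, x$sd_genes))
  invisible(x)
}
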