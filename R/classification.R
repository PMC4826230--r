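#' Classifier configuration
#'
#' Settings of the multivariate panel evaluation: panel sizes of the
#' stepwise-forward filter, the repeated stratified cross-validation
#' design, the RBF support vector machine hyperparameters, and the
#' permutation-null size.
#'
#' @param panel_sizes Integer vector of marker-panel sizes (default 5, 10,
#'   50).
#' @param n_repetitions Independent repetitions of the cross-validation
#'   (default 10).
#' @param n_folds Folds per repetition (default 10, stratified).
#' @param cost Soft-margin cost C of the SVM (default 1).
#' @param gamma RBF kernel width; `NULL` (default) uses
#'   `1 / (n_features * var(training values))`.
#' @param n_permutations Random-label refits of the whole procedure
#'   (default 10).
#' @param preselect If `TRUE`, select features once on the full dataset
#'   before cross-validation (the optimistic protocol); the default
#'   `FALSE` re-selects inside every training fold, which is unbiased.
#' @param seed Integer seed.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(panel_sizes = c(5L, 10L, 50L),
                              n_repetitions = 10L, n_folds = 10L,
                              cost = 1, gamma = NULL,
                              n_permutations = 10L, preselect = FALSE,
                              seed = 1L) {
  stopifnot(all(panel_sizes >= 1), n_repetitions >= 1, n_folds >= 2,
            cost > 0, is.null(gamma) || gamma > 0, n_permutations >= 0)
  structure(list(panel_sizes = as.integer(panel_sizes),
                 n_repetitions = as.integer(n_repetitions),
                 n_folds = as.integer(n_folds), cost = cost, gamma = gamma,
                 n_permutations = as.integer(n_permutations),
                 preselect = isTRUE(preselect), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Stepwise-forward filter selection of a marker panel
#'
#' Ranks markers by the significance of their two-group Welch t-test
#' (ascending p) and returns the top `k` in rank order. Ties are broken by
#' `|AUC - 0.5|` descending, then by assay id. Always computed on training
#' data only when used inside cross-validation.
#'
#' @param x Samples x markers numeric matrix of training values.
#' @param y Training labels (two classes).
#' @param k Panel size.
#' @param positive Label treated as the positive class.
#' @return Character vector of `k` marker names in selection order.
#' @export
forward_filter_select <- function(x, y, k, positive = y[1]) {
  if (k > ncol(x))
    stop(sprintf("panel size %d exceeds the %d available markers", k, ncol(x)),
         call. = FALSE)
  r <- rank_markers(x, y, positive)
  ord <- order(r$p, -abs(r$auc - 0.5), colnames(x))
  colnames(x)[ord][seq_len(k)]
}

## Vectorised per-marker Welch p and AUC on a samples x markers matrix.
rank_markers <- function(x, y, positive) {
  pos <- y == positive
  if (!any(pos) || all(pos)) stop("training data has a single class", call. = FALSE)
  tt <- row_t_stats(t(x[pos, , drop = FALSE]), t(x[!pos, , drop = FALSE]))
  n1 <- sum(pos); n2 <- sum(!pos)
  aucs <- apply(x, 2, function(v) {
    r <- rank(v)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  })
  list(p = tt$p, auc = aucs)
}

## ---- RBF C-SVM via the soft-margin dual QP (quadprog) ----------------

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

## y must be +/-1. Solves max 1'a - a'Qa/2 s.t. y'a = 0, 0 <= a <= C.
svm_rbf_fit <- function(x, y, cost = 1, gamma = NULL) {
  x <- as.matrix(x)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(x))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1
  }
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  Q <- (y %o% y) * K
  diag(Q) <- diag(Q) + 1e-8          # keep the QP strictly convex
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Q, rep(1, n), A, b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  coef <- alpha * y
  f_no_b <- as.vector(K %*% coef)
  margin <- alpha > 1e-6 * cost & alpha < cost * (1 - 1e-6)
  rho <- if (any(margin)) mean(y[margin] - f_no_b[margin])
         else mean(y[alpha > 1e-6 * cost] - f_no_b[alpha > 1e-6 * cost])
  list(x = x, coef = coef, b = rho, gamma = gamma, cost = cost)
}

svm_rbf_decision <- function(fit, newx) {
  as.vector(rbf_kernel(as.matrix(newx), fit$x, fit$gamma) %*% fit$coef) + fit$b
}

## ---- repeated stratified cross-validation ----------------------------

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated cross-validated SVM evaluation of marker panels
#'
#' For every configured panel size, runs `n_repetitions` independent
#' rounds of stratified `n_folds`-fold cross-validation of an RBF-kernel
#' SVM. Within every training fold a panel of `k` markers is selected by
#' [forward_filter_select()] (no information from the held-out fold is
#' used) and the classifier is trained on the selected markers only; the
#' held-out samples are then predicted once per repetition. Per
#' repetition, pooled fold predictions yield accuracy, sensitivity and
#' specificity (percent; positive class = first contrast group, the
#' disease group) and the AUC of the pooled decision values. Reported
#' metrics are means over repetitions with 95% CI `mean +/- 1.96 * SD` of
#' the repetition-level values. Deterministic given `config$seed`.
#'
#' @param delta A `delta_ct` / `curated_ct` object or assay x sample
#'   matrix.
#' @param groups Sample annotation (`sample_id`, `group`).
#' @param contrast Length-2 character vector `(positive, other)`.
#' @param config A `classifier_config`.
#' @return Object of class `classification_result`: per panel size a list
#'   with `metrics` (data frame: metric, mean, ci_lo, ci_hi), `per_rep`
#'   (repetition-level metric matrix), and `selection_freq` (named vector,
#'   fraction of training folds selecting each marker); plus the config
#'   and contrast.
#' @export
cross_validate <- function(delta, groups, contrast, config = classifier_config()) {
  values <- marker_values(delta)
  g <- groups$group[match(colnames(values), groups$sample_id)]
  keep <- g %in% contrast
  if (!all(contrast %in% g))
    stop("both contrast groups must be present", call. = FALSE)
  x <- t(values[, keep, drop = FALSE])
  y <- g[keep]
  if (any(config$panel_sizes > ncol(x)))
    stop(sprintf("panel size %d exceeds the %d available markers",
                 max(config$panel_sizes), ncol(x)), call. = FALSE)
  set.seed(config$seed)
  folds <- replicate(config$n_repetitions,
                     stratified_folds(y, config$n_folds))
  res <- cv_engine(x, y, positive = contrast[1], folds = folds,
                   config = config)
  structure(c(res, list(config = config, contrast = contrast,
                        positive = contrast[1])),
            class = "classification_result")
}

## Shared CV engine: folds is an n_samples x n_repetitions matrix so the
## observed run and every permutation reuse identical fold structure.
cv_engine <- function(x, y, positive, folds, config) {
  n_rep <- ncol(folds)
  pos <- y == positive
  per_size <- list()
  for (k in config$panel_sizes) {
    metrics <- matrix(NA_real_, n_rep, 4,
                      dimnames = list(NULL, c("accuracy", "sensitivity",
                                              "specificity", "auc")))
    sel_count <- stats::setNames(numeric(ncol(x)), colnames(x))
    n_folds_run <- 0L
    presel <- if (config$preselect)
      forward_filter_select(x, y, k, positive) else NULL
    for (r in seq_len(n_rep)) {
      fold <- folds[, r]
      pred <- character(length(y))
      dec <- numeric(length(y))
      for (f in sort(unique(fold))) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2 || min(table(y[tr])) < 2)
          stop("a training fold has fewer than two samples of a class; reduce n_folds",
               call. = FALSE)
        sel <- if (is.null(presel))
          forward_filter_select(x[tr, , drop = FALSE], y[tr], k, positive)
        else presel
        sel_count[sel] <- sel_count[sel] + 1
        n_folds_run <- n_folds_run + 1L
        yt <- ifelse(y[tr] == positive, 1, -1)
        fit <- svm_rbf_fit(x[tr, sel, drop = FALSE], yt,
                           cost = config$cost, gamma = config$gamma)
        d <- svm_rbf_decision(fit, x[!tr, sel, drop = FALSE])
        dec[!tr] <- d
        pred[!tr] <- ifelse(d >= 0, positive, "negative")
      }
      hit <- pred == ifelse(pos, positive, "negative")
      metrics[r, "accuracy"] <- 100 * mean(hit)
      metrics[r, "sensitivity"] <- 100 * mean(hit[pos])
      metrics[r, "specificity"] <- 100 * mean(hit[!pos])
      rr <- rank(dec)
      metrics[r, "auc"] <- (sum(rr[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
        (sum(pos) * sum(!pos))
    }
    mu <- colMeans(metrics)
    sdv <- apply(metrics, 2, stats::sd)
    per_size[[as.character(k)]] <- list(
      metrics = data.frame(metric = colnames(metrics), mean = mu,
                           ci_lo = mu - 1.96 * sdv, ci_hi = mu + 1.96 * sdv,
                           row.names = NULL),
      per_rep = metrics,
      selection_freq = sort(sel_count / n_folds_run, decreasing = TRUE))
  }
  list(panels = per_size)
}

#' Permutation null of the cross-validated classifier
#'
#' Repeats the entire cross-validation procedure of [cross_validate()] —
#' including within-fold feature selection — `n_permutations` times with
#' the class labels randomly permuted once per permutation, and reports
#' the null distribution of the repetition-averaged metrics together with
#' the empirical p-value of the observed accuracy
#' (`(1 + #{null >= observed}) / (n_permutations + 1)`).
#'
#' @inheritParams cross_validate
#' @param observed Optional `classification_result` from
#'   [cross_validate()] on the unpermuted labels; computed when missing.
#' @return Object of class `permutation_null`: per panel size a data
#'   frame `null` (per-permutation mean metrics), the observed mean
#'   accuracy, and `p_empirical`.
#' @export
permutation_null <- function(delta, groups, contrast,
                             config = classifier_config(), observed = NULL) {
  if (config$n_permutations < 1)
    stop("n_permutations must be >= 1", call. = FALSE)
  if (is.null(observed))
    observed <- cross_validate(delta, groups, contrast, config)
  values <- marker_values(delta)
  g <- groups$group[match(colnames(values), groups$sample_id)]
  keep <- g %in% contrast
  x <- t(values[, keep, drop = FALSE])
  y <- g[keep]
  set.seed(config$seed + 1L)
  out <- list()
  for (k in as.character(config$panel_sizes))
    out[[k]] <- matrix(NA_real_, config$n_permutations, 4,
                       dimnames = list(NULL, c("accuracy", "sensitivity",
                                               "specificity", "auc")))
  for (p in seq_len(config$n_permutations)) {
    yp <- sample(y)
    folds <- replicate(config$n_repetitions,
                       stratified_folds(yp, config$n_folds))
    res <- cv_engine(x, yp, positive = contrast[1], folds = folds, config = config)
    for (k in names(res$panels))
      out[[k]][p, ] <- colMeans(res$panels[[k]]$per_rep)
  }
  panels <- lapply(stats::setNames(nm = names(out)), function(k) {
    obs_acc <- mean(observed$panels[[k]]$per_rep[, "accuracy"])
    list(null = as.data.frame(out[[k]]),
         observed_accuracy = obs_acc,
         p_empirical = (1 + sum(out[[k]][, "accuracy"] >= obs_acc)) /
           (config$n_permutations + 1))
  })
  structure(list(panels = panels, config = config, contrast = contrast),
            class = "permutation_null")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("RBF-SVM repeated CV (%d x %d-fold), contrast %s vs %s (positive = %s)\n",
              x$config$n_repetitions, x$config$n_folds, x$contrast[1],
              x$contrast[2], x$positive))
  for (k in names(x$panels)) {
    m <- x$panels[[k]]$metrics
    cat(sprintf("  k = %s: ", k))
    cat(paste(sprintf("%s %.1f [%.1f, %.1f]", m$metric, m$mean, m$ci_lo,
                      m$ci_hi), collapse = "; "), "\n")
  }
  invisible(x)
}
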