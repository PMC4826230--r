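#' Coefficient of variation of a set of Ct values
#'
#' Sample SD divided by sample mean, either directly on the Ct (cycle)
#' scale or after linearizing each value to relative abundance via
#' \eqn{2^{-Ct}}. On the linearized scale the CV is invariant to scaling
#' all abundances by a positive constant (i.e. to a global Ct offset).
#'
#' @param values Numeric vector of Ct values (>= 2 values).
#' @param scale `"ct"` (default) or `"linear"` (transform to `2^-ct`
#'   first).
#' @return Non-negative numeric CV.
#' @export
coefficient_of_variation <- function(values, scale = c("ct", "linear")) {
  scale <- match.arg(scale)
  if (length(values) < 2 || anyNA(values))
    stop("need >= 2 non-missing values", call. = FALSE)
  if (scale == "linear") values <- 2^-values
  m <- mean(values)
  if (m == 0) stop("undefined CV: mean is zero", call. = FALSE)
  stats::sd(values) / m
}

#' Model-based (NormFinder-style) stability of candidate reference genes
#'
#' Re-implements the variance-decomposition stability measure of Andersen
#' et al. (2004) on log-scale data (Ct values are already log2). Candidate
#' values are first sample-centered by subtracting each sample's mean over
#' the candidate set (removing shared loading effects), then gene-centered.
#' For each candidate and group the method estimates the intragroup
#' variance (corrected for the noise the centering mixes in from the other
#' candidates) and the intergroup bias; the bias is shrunk toward zero in
#' proportion to its sampling uncertainty, and the stability value is the
#' average over groups of `|shrunken bias| + sqrt(intragroup variance /
#' group size)` — intergroup bias plus intragroup variation. Lower is
#' more stable. With `groups = NULL` the measure degrades to the overall
#' SD of the sample-centered values.
#'
#' @param curated A `curated_ct` object (or a bare assay x sample matrix).
#' @param groups Sample annotation data frame with `sample_id` and
#'   `group`, or `NULL` for the ungrouped estimator. Grouped mode needs
#'   >= 2 groups with >= 2 samples each (and >= 3 candidates for the
#'   variance correction).
#' @param candidates Character vector of candidate control assay ids
#'   (>= 2).
#' @return Named numeric vector of stability values, one per candidate.
#' @export
normfinder_stability <- function(curated, groups, candidates) {
  values <- if (inherits(curated, "curated_ct")) curated$values else curated
  missing_c <- setdiff(candidates, rownames(values))
  if (length(missing_c))
    stop(sprintf("candidate(s) not in matrix: %s",
                 paste(missing_c, collapse = ", ")), call. = FALSE)
  if (length(candidates) < 2) stop("need >= 2 candidates", call. = FALSE)
  m <- values[candidates, , drop = FALSE]
  z <- sweep(m, 2, colMeans(m))          # sample-center over candidate set
  z <- z - rowMeans(z)                   # gene-center

  if (is.null(groups)) {
    return(apply(z, 1, stats::sd))
  }
  g <- groups$group[match(colnames(m), groups$sample_id)]
  if (anyNA(g)) stop("samples missing from group annotation", call. = FALSE)
  glev <- unique(g)
  sizes <- table(factor(g, levels = glev))
  if (length(glev) < 2) stop("grouped estimator needs >= 2 groups", call. = FALSE)
  if (any(sizes < 2))
    stop("grouped estimator needs >= 2 samples per group", call. = FALSE)
  n <- length(candidates)
  if (n < 3) stop("grouped estimator needs >= 3 candidates", call. = FALSE)

  d <- sapply(glev, function(gg) rowMeans(z[, g == gg, drop = FALSE]))
  s2 <- sapply(glev, function(gg) apply(z[, g == gg, drop = FALSE], 1, stats::var))

  ## intragroup variance, corrected for the candidate-mean subtraction:
  ## Var(z_i) = sigma_i^2 (1 - 2/n) + sum_k sigma_k^2 / n^2
  sig2 <- sweep(s2, 2, colSums(s2) / (n * (n - 1))) / (1 - 2 / n)
  sig2 <- pmax(sig2, 0)

  ## intergroup variance of the group biases, method-of-moments
  G <- length(glev)
  sampling <- sweep(sig2, 2, as.numeric(sizes), `/`)
  gamma2 <- max(0, sum(d^2) / ((n - 1) * (G - 1)) - mean(sampling))

  shrink <- gamma2 / (gamma2 + sampling)
  shrink[!is.finite(shrink)] <- 0       # gamma2 = 0 and zero sampling var
  d_tilde <- d * shrink
  rho <- rowMeans(abs(d_tilde) + sqrt(sampling))
  names(rho) <- candidates
  rho
}

#' Evaluate and rank candidate endogenous controls
#'
#' Summarises every candidate control by mean and SD of its final Ct, the
#' CV on the Ct and linearized (`2^-Ct`) scales, and the model-based
#' NormFinder-style stability, with a rank per criterion. When a
#' screening-study statistics table is supplied, each candidate is
#' additionally scored by concordance with the screening platform: the
#' validation AUC of every panel assay (disease vs control) is computed on
#' the delta-Ct values normalized by that candidate and correlated
#' (Pearson) with the screening AUCs; a `none` row reports the same
#' correlation for raw, unnormalized Ct values.
#'
#' @param curated A `curated_ct` object.
#' @param groups Sample annotation (`sample_id`, `group`).
#' @param candidates Character vector of candidate control ids present in
#'   the curated matrix.
#' @param screening Optional `screening_stats` table (`assay_id`,
#'   `screen_auc`).
#' @param contrast Length-2 character vector naming the (positive, other)
#'   groups of the concordance AUCs; default first and last group level
#'   in annotation order.
#' @return Object of class `control_stability`: a data frame with one row
#'   per candidate (plus `none` when screening is given) and columns
#'   `mean_ct`, `sd_ct`, `cv_ct`, `cv_linear`, `stability`, the
#'   corresponding ranks, and `screen_cor` / `screen_cor_p`.
#' @export
rank_controls <- function(curated, groups, candidates, screening = NULL,
                          contrast = NULL) {
  values <- curated$values
  missing_c <- setdiff(candidates, rownames(values))
  if (length(missing_c))
    stop(sprintf("candidate(s) not in curated matrix: %s",
                 paste(missing_c, collapse = ", ")), call. = FALSE)

  rep_row <- function(f) vapply(candidates, function(a) f(values[a, ]), 0)
  out <- data.frame(
    control = candidates,
    mean_ct = rep_row(mean),
    sd_ct = rep_row(stats::sd),
    cv_ct = vapply(candidates, function(a)
      coefficient_of_variation(values[a, ], "ct"), 0),
    cv_linear = vapply(candidates, function(a)
      coefficient_of_variation(values[a, ], "linear"), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$stability <- if (length(candidates) >= 3 && !is.null(groups))
    unname(normfinder_stability(curated, groups, candidates))
  else unname(normfinder_stability(curated, NULL, candidates))
  ## ties.method "first" keeps every rank column a permutation of 1..n
  out$rank_sd <- rank(out$sd_ct, ties.method = "first")
  out$rank_cv_ct <- rank(out$cv_ct, ties.method = "first")
  out$rank_cv_linear <- rank(out$cv_linear, ties.method = "first")
  out$rank_stability <- rank(out$stability, ties.method = "first")

  if (!is.null(screening)) {
    if (is.null(contrast)) {
      glev <- unique(groups$group[match(colnames(values), groups$sample_id)])
      contrast <- c(glev[1], glev[length(glev)])
    }
    panel <- setdiff(rownames(values), candidates)
    scr <- screening[match(panel, screening$assay_id), ]
    keep <- !is.na(scr$screen_auc)
    val_auc_for <- function(mat) {
      vapply(panel[keep], function(a)
        auc(mat[a, ], groups$group[match(colnames(mat), groups$sample_id)],
            positive = contrast[1], other = contrast[2]), 0)
    }
    cors <- lapply(c(list(none = curated$values),
                     stats::setNames(lapply(candidates, function(ref)
                       delta_ct(curated, ref)$values), candidates)),
                   function(mat) {
        ct <- stats::cor.test(val_auc_for(mat), scr$screen_auc[keep])
        c(ct$estimate, ct$p.value)
    })
    out$screen_cor <- vapply(candidates, function(a) cors[[a]][1], 0)
    out$screen_cor_p <- vapply(candidates, function(a) cors[[a]][2], 0)
    none <- data.frame(control = "none", mean_ct = NA, sd_ct = NA,
                       cv_ct = NA, cv_linear = NA, stability = NA,
                       rank_sd = NA, rank_cv_ct = NA, rank_cv_linear = NA,
                       rank_stability = NA,
                       screen_cor = cors$none[1], screen_cor_p = cors$none[2],
                       stringsAsFactors = FALSE)
    out <- rbind(out, none)
  }
  class(out) <- c("control_stability", "data.frame")
  out
}

#' Normalize a curated Ct matrix to delta-Ct values
#'
#' Subtracts the reference control's Ct from every assay within each
#' sample: `dCt(a, s) = Ct(a, s) - Ct(reference, s)`. Higher delta-Ct
#' means lower expression relative to the reference. The reference row is
#' removed from the result. Per-sample global shifts (loading, efficiency)
#' cancel exactly.
#'
#' @param curated A `curated_ct` object.
#' @param reference Assay id of the endogenous control to normalize by.
#' @return Object of class `delta_ct`: `values` (assay x sample delta-Ct
#'   matrix) and `reference`.
#' @export
delta_ct <- function(curated, reference) {
  values <- curated$values
  if (!reference %in% rownames(values)) {
    extra <- if (reference %in% curated$dropped_assays$assay_id)
      " (dropped during curation)" else ""
    stop(sprintf("reference assay '%s' not in curated matrix%s",
                 reference, extra), call. = FALSE)
  }
  ref <- values[reference, ]
  out <- sweep(values[setdiff(rownames(values), reference), , drop = FALSE],
               2, ref)
  structure(list(values = out, reference = reference), class = "delta_ct")
}

#' @export
print.control_stability <- function(x, ...) {
  cat("Endogenous-control stability report\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
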