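#' Mann-Whitney area under the ROC curve
#'
#' Probability that a randomly drawn sample of the positive group has a
#' larger value than a randomly drawn sample of the other group, ties
#' counted one half: `AUC = U / (n1 * n2)` with U the Mann-Whitney
#' statistic. On delta-Ct values with the disease group positive, an AUC
#' below 0.5 therefore means lower delta-Ct — i.e. higher expression — in
#' the disease group. `auc(A) + auc(B) = 1` for the two orientations.
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Group label per sample.
#' @param positive Label of the positive group (by convention the
#'   first-named group of a contrast).
#' @param other Label of the comparison group; defaults to all remaining
#'   samples.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(values, labels, positive, other = NULL) {
  if (is.null(other)) {
    keep <- rep(TRUE, length(values))
  } else {
    keep <- labels %in% c(positive, other)
  }
  x <- values[keep & labels == positive]
  y <- values[keep & labels != positive]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups of the contrast must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u / (length(x) * length(y))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment: with the p-values sorted ascending,
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )` capped at 1, reported in the
#' original order. Ties receive identical q-values.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * pvals[o]))
  q[order(o)]
}

#' Per-assay two-group marker statistics
#'
#' For every assay of a (delta-)Ct matrix, compares the two groups of the
#' contrast with a two-sided Welch t-test and a two-sided Wilcoxon
#' rank-sum test (normal approximation with continuity correction, which
#' accommodates tied imputed values), adjusts each p-value family across
#' all assays by [bh_adjust()], and reports the Mann-Whitney AUC with the
#' first-named group of the contrast as positive. The Student
#' (equal-variance) t-test p-value is included for reference.
#'
#' @param delta A `delta_ct` or `curated_ct` object, or an assay x sample
#'   matrix.
#' @param groups Sample annotation (`sample_id`, `group`).
#' @param contrast Length-2 character vector `(A, B)`; A is the positive
#'   group.
#' @return Object of class `marker_stats`: data frame with `assay_id`,
#'   `mean_A`, `mean_B`, `p_t` (Welch), `p_t_student`, `p_w`, `q_t`,
#'   `q_w`, `auc`, `direction` (`up_in_<A>` when AUC < 0.5, i.e. higher
#'   expression in A; `down_in_<A>` when AUC > 0.5; `NA` at exactly 0.5)
#'   plus attributes `contrast` and `positive`.
#' @export
two_group_stats <- function(delta, groups, contrast) {
  values <- marker_values(delta)
  g <- groups$group[match(colnames(values), groups$sample_id)]
  for (gg in contrast) if (!gg %in% g)
    stop(sprintf("contrast group '%s' absent from data", gg), call. = FALSE)
  a <- values[, g == contrast[1], drop = FALSE]
  b <- values[, g == contrast[2], drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("both contrast groups need >= 2 samples", call. = FALSE)

  welch <- row_t_stats(a, b, var_equal = FALSE)
  student <- row_t_stats(a, b, var_equal = TRUE)
  p_w <- vapply(seq_len(nrow(values)), function(i)
    stats::wilcox.test(a[i, ], b[i, ], exact = FALSE, correct = TRUE)$p.value, 0)
  aucs <- vapply(seq_len(nrow(values)), function(i) {
    r <- rank(c(a[i, ], b[i, ]))
    (sum(r[seq_len(ncol(a))]) - ncol(a) * (ncol(a) + 1) / 2) /
      (ncol(a) * ncol(b))
  }, 0)

  out <- data.frame(
    assay_id = rownames(values),
    mean_A = rowMeans(a), mean_B = rowMeans(b),
    p_t = welch$p, p_t_student = student$p, p_w = p_w,
    q_t = bh_adjust(welch$p), q_w = bh_adjust(p_w),
    auc = aucs,
    direction = ifelse(aucs < 0.5, paste0("up_in_", contrast[1]),
                       ifelse(aucs > 0.5, paste0("down_in_", contrast[1]),
                              NA_character_)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- contrast
  attr(out, "positive") <- contrast[1]
  class(out) <- c("marker_stats", "data.frame")
  out
}

## Vectorised row-wise two-sample t-tests (two-sided).
row_t_stats <- function(a, b, var_equal = FALSE) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 1, 0)
  list(t = t, df = df, p = p)
}

#' Per-assay one-way ANOVA across three (or more) groups
#'
#' Fixed-effects one-way analysis of variance per assay, with BH
#' adjustment across assays, plus the group with the highest mean
#' (delta-)Ct, i.e. the lowest relative expression.
#'
#' @inheritParams two_group_stats
#' @return Data frame with `assay_id`, `f`, `p`, `q`, `highest_mean_group`.
#' @export
anova_three_group <- function(delta, groups) {
  values <- marker_values(delta)
  g <- factor(groups$group[match(colnames(values), groups$sample_id)])
  if (nlevels(g) < 3) stop("ANOVA comparison needs >= 3 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs >= 2 samples", call. = FALSE)

  n <- ncol(values)
  k <- nlevels(g)
  gm <- t(apply(values, 1, function(v) tapply(v, g, mean)))
  sizes <- as.numeric(table(g))
  grand <- rowMeans(values)
  ss_between <- rowSums(sweep(gm, 1, grand)^2 %*% diag(sizes))
  ss_total <- rowSums((values - grand)^2)
  ss_within <- ss_total - ss_between
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  zero <- ss_within == 0 & ss_between == 0
  p[zero] <- 1
  data.frame(assay_id = rownames(values), f = f, p = p, q = bh_adjust(p),
             highest_mean_group = levels(g)[max.col(gm)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Venn partition of significant markers across two contrasts
#'
#' Splits the significant assays of each contrast by direction of
#' regulation in the positive group and computes all pairwise overlaps
#' between the four sets, including discordant-direction overlaps (up in
#' one contrast, down in the other).
#'
#' @param statsA,statsB `marker_stats` tables for the two contrasts over
#'   the same assay universe.
#' @param alpha Significance level (default 0.05).
#' @param use_adjusted Use BH q-values (`TRUE`) or raw p-values of the
#'   base t-test.
#' @return Object of class `venn_partition`: list with `sets` (named list
#'   of the four assay-id sets `up_A`, `down_A`, `up_B`, `down_B`),
#'   `counts`, and `overlaps` (data frame of all pairwise intersections).
#' @export
venn_partition <- function(statsA, statsB, alpha = 0.05, use_adjusted = TRUE) {
  pcol <- if (use_adjusted) "q_t" else "p_t"
  sig_sets <- function(st, tag) {
    sig <- st[[pcol]] < alpha
    list(up = st$assay_id[sig & st$auc < 0.5],
         down = st$assay_id[sig & st$auc > 0.5])
  }
  sa <- sig_sets(statsA); sb <- sig_sets(statsB)
  sets <- list(up_A = sa$up, down_A = sa$down, up_B = sb$up, down_B = sb$down)
  nm <- names(sets)
  pairs <- utils::combn(nm, 2)
  overlaps <- data.frame(
    set1 = pairs[1, ], set2 = pairs[2, ],
    n = apply(pairs, 2, function(p) length(intersect(sets[[p[1]]], sets[[p[2]]]))),
    stringsAsFactors = FALSE
  )
  overlaps$members <- apply(pairs, 2, function(p)
    paste(intersect(sets[[p[1]]], sets[[p[2]]]), collapse = ","))
  structure(list(sets = sets, counts = lengths(sets), overlaps = overlaps,
                 alpha = alpha, use_adjusted = use_adjusted),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition (alpha = %g, %s p-values)\n", x$alpha,
              if (x$use_adjusted) "adjusted" else "raw"))
  print(x$counts)
  print(x$overlaps[, c("set1", "set2", "n")], row.names = FALSE)
  invisible(x)
}

## Accept delta_ct, curated_ct or a bare matrix.
marker_values <- function(delta) {
  if (inherits(delta, "delta_ct") || inherits(delta, "curated_ct"))
    delta$values
  else as.matrix(delta)
}
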