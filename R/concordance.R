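#' Match screening assay identifiers to validation assays
#'
#' Joins a screening statistics table onto the validation assay universe
#' by exact identifier, optionally after translating old identifiers
#' through a user-supplied mapping table (e.g. miRBase v12 names to v21
#' names). Unmatched identifiers are logged, never silently dropped.
#'
#' @param screen `screening_stats` table with `assay_id` (and optionally
#'   `old_id`).
#' @param validation_ids Character vector of validation assay ids.
#' @param mapping Optional data frame with columns `old_id`, `new_id`.
#' @param allow_many_to_one Permit several screening rows to map onto one
#'   validation assay (default `FALSE`: such collisions are an error).
#' @return List with `matched` (screening rows whose mapped id is present,
#'   with a `matched_id` column) and `unmatched` (character vector of
#'   screening ids without a partner).
#' @export
match_identifiers <- function(screen, validation_ids, mapping = NULL,
                              allow_many_to_one = FALSE) {
  ids <- screen$assay_id
  mapped <- ids
  if (!is.null(mapping)) {
    stopifnot(all(c("old_id", "new_id") %in% names(mapping)))
    hit <- match(ids, mapping$old_id)
    mapped[!is.na(hit)] <- mapping$new_id[hit[!is.na(hit)]]
  }
  present <- mapped %in% validation_ids
  dup <- duplicated(mapped[present])
  if (any(dup) && !allow_many_to_one)
    stop(sprintf("several screening assays map to validation assay(s) %s; set allow_many_to_one = TRUE to permit",
                 paste(unique(mapped[present][dup]), collapse = ", ")),
         call. = FALSE)
  matched <- screen[present, , drop = FALSE]
  matched$matched_id <- mapped[present]
  list(matched = matched, unmatched = ids[!present])
}

#' Directional concordance between screening and validation platforms
#'
#' Restricts to assays significant in the screening study at unadjusted
#' `p < alpha`, and calls an assay concordant when its validation AUC
#' deviates from 0.5 in the same direction as its screening AUC. Assays
#' with either AUC exactly 0.5 have no direction: they are excluded from
#' both numerator and denominator and counted separately. Significance of
#' the concordance fraction against chance is reported as a two-sided
#' exact binomial test of `n_concordant` successes in `n_determinate`
#' trials versus 0.5; a 2x2 Fisher exact test (significant in validation x
#' concordant) is emitted alongside for comparison.
#'
#' @param screen `screening_stats` table (columns `assay_id`,
#'   `screen_auc`, `screen_p`).
#' @param valid `marker_stats` table from [two_group_stats()] for the same
#'   contrast orientation.
#' @param alpha Screening significance level (default 0.05, unadjusted).
#' @return Object of class `concordance_report`: list with `n_matched`,
#'   `n_significant`, `n_indeterminate`, `n_concordant`,
#'   `percent_concordant` (of determinate significant assays, `NA` when
#'   none), `binom_p`, `fisher_p`, `discordant` (data frame of discordant
#'   assays with both directions).
#' @export
directional_concordance <- function(screen, valid, alpha = 0.05) {
  i <- match(valid$assay_id, screen$assay_id)
  keep <- !is.na(i)
  v <- valid[keep, , drop = FALSE]
  s <- screen[i[keep], , drop = FALSE]
  n_matched <- nrow(v)
  sig <- s$screen_p < alpha
  vs <- v[sig, , drop = FALSE]; ss <- s[sig, , drop = FALSE]
  n_sig <- nrow(vs)
  if (n_sig == 0) {
    return(structure(list(n_matched = n_matched, n_significant = 0L,
                          n_indeterminate = 0L, n_concordant = 0L,
                          percent_concordant = NA_real_, binom_p = NA_real_,
                          fisher_p = NA_real_,
                          discordant = data.frame(), alpha = alpha,
                          note = "no screening-significant assays"),
                     class = "concordance_report"))
  }
  dir_s <- sign(ss$screen_auc - 0.5)
  dir_v <- sign(vs$auc - 0.5)
  det <- dir_s != 0 & dir_v != 0
  conc <- det & (dir_s == dir_v)
  n_det <- sum(det)
  n_conc <- sum(conc)
  pct <- if (n_det > 0) 100 * n_conc / n_det else NA_real_
  binom_p <- if (n_det > 0)
    stats::binom.test(n_conc, n_det, 0.5)$p.value else NA_real_
  valid_sig <- vs$p_t < alpha
  fisher_p <- if (n_det > 1 && length(unique(valid_sig[det])) > 0) {
    tab <- table(factor(valid_sig[det], levels = c(FALSE, TRUE)),
                 factor(conc[det], levels = c(FALSE, TRUE)))
    stats::fisher.test(tab)$p.value
  } else NA_real_
  discordant <- data.frame(
    assay_id = vs$assay_id[det & !conc],
    screen_auc = ss$screen_auc[det & !conc],
    valid_auc = vs$auc[det & !conc],
    stringsAsFactors = FALSE
  )
  structure(list(n_matched = n_matched, n_significant = n_sig,
                 n_indeterminate = n_sig - n_det, n_concordant = n_conc,
                 percent_concordant = pct, binom_p = binom_p,
                 fisher_p = fisher_p, discordant = discordant,
                 alpha = alpha, note = NULL),
            class = "concordance_report")
}

#' Correlation of screening and validation AUC vectors
#'
#' Pearson correlation of the matched per-assay AUCs of the two platforms
#' with the standard t-based p-value, plus the paired values for
#' scatter-plotting.
#'
#' @inheritParams directional_concordance
#' @return List with `r`, `p`, `n`, and `pairs` (data frame `assay_id`,
#'   `screen_auc`, `valid_auc`).
#' @export
auc_correlation <- function(screen, valid) {
  i <- match(valid$assay_id, screen$assay_id)
  keep <- !is.na(i)
  pairs <- data.frame(assay_id = valid$assay_id[keep],
                      screen_auc = screen$screen_auc[i[keep]],
                      valid_auc = valid$auc[keep],
                      stringsAsFactors = FALSE)
  if (nrow(pairs) < 3) stop("need >= 3 matched AUC pairs", call. = FALSE)
  if (stats::sd(pairs$screen_auc) == 0 || stats::sd(pairs$valid_auc) == 0)
    stop("undefined correlation: zero variance in an AUC vector", call. = FALSE)
  ct <- stats::cor.test(pairs$screen_auc, pairs$valid_auc)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs),
       pairs = pairs)
}

#' Compare two sample subsets measured on the same panel
#'
#' Quantifies agreement between two disjoint sample subsets (e.g. the two
#' RNA extraction kits) on assay-level summaries computed independently in
#' each: the Pearson correlation of per-assay mean Ct, and — when both
#' subsets contain both contrast groups — the correlation of per-assay
#' AUCs for the contrast.
#'
#' @param curatedA,curatedB `curated_ct` objects for the two subsets.
#' @param groupsA,groupsB Sample annotations for each subset.
#' @param contrast Length-2 character vector `(positive, other)`.
#' @return List with `ct_cor` (`r`, `p`, `n`) and `auc_cor` (`r`, `p`,
#'   `n`, or `NULL` with a warning when a contrast group is missing in a
#'   subset).
#' @export
subset_comparison <- function(curatedA, curatedB, groupsA, groupsB, contrast) {
  shared <- intersect(rownames(curatedA$values), rownames(curatedB$values))
  if (length(shared) < 3) stop("need >= 3 shared assays", call. = FALSE)
  ma <- curatedA$values[shared, , drop = FALSE]
  mb <- curatedB$values[shared, , drop = FALSE]
  ct <- stats::cor.test(rowMeans(ma), rowMeans(mb))
  res <- list(ct_cor = list(r = unname(ct$estimate), p = ct$p.value,
                            n = length(shared)))
  ga <- groupsA$group[match(colnames(ma), groupsA$sample_id)]
  gb <- groupsB$group[match(colnames(mb), groupsB$sample_id)]
  if (all(contrast %in% ga) && all(contrast %in% gb)) {
    auc_of <- function(m, g) vapply(seq_len(nrow(m)), function(i)
      auc(m[i, ], g, positive = contrast[1], other = contrast[2]), 0)
    aa <- auc_of(ma, ga); ab <- auc_of(mb, gb)
    at <- stats::cor.test(aa, ab)
    res$auc_cor <- list(r = unname(at$estimate), p = at$p.value,
                        n = length(shared))
  } else {
    warning("a contrast group is missing in a subset; AUC comparison skipped")
    res$auc_cor <- NULL
  }
  res
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: %d matched, %d screening-significant (alpha = %g)\n",
              x$n_matched, x$n_significant, x$alpha))
  if (!is.na(x$percent_concordant))
    cat(sprintf("  %d/%d concordant (%.1f%%), %d without direction\n  exact binomial p = %.3g vs chance; Fisher 2x2 p = %.3g\n",
                x$n_concordant, x$n_significant - x$n_indeterminate,
                x$percent_concordant, x$n_indeterminate, x$binom_p,
                x$fisher_p))
  else cat("  no determinate screening-significant assays\n")
  invisible(x)
}
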