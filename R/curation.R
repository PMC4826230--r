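#' Filter a single well against the detection and quality criteria
#'
#' A well passes when it amplified (Ct present), its Ct lies inside the
#' linear range of detection (`ct <= ct_limit`) and its amplification-curve
#' quality score reaches the threshold (`quality >= quality_min`). Both
#' boundaries are inclusive for passing: a score that "fails the 0.65
#' threshold" is strictly below it.
#'
#' @param ct Ct value in cycles, `NA` for failed amplification.
#' @param quality Quality score in `[0, 1]`.
#' @param ct_limit Upper end of the linear range of detection (default 25
#'   cycles).
#' @param quality_min Minimum acceptable quality score (default 0.65).
#' @return List with `pass` (logical) and `reason` (`NA` when passing,
#'   otherwise one of `"no_amplification"`, `"out_of_range"`,
#'   `"low_quality"`).
#' @export
filter_replicate <- function(ct, quality, ct_limit = 25, quality_min = 0.65) {
  stopifnot(is.finite(ct_limit), is.finite(quality_min))
  r <- well_filter_reason(ct, quality, ct_limit, quality_min)
  list(pass = is.na(r), reason = r)
}

## Vectorised filter: NA reason = pass. Failure precedence follows the
## curation order: no amplification, then range, then quality.
well_filter_reason <- function(ct, quality, ct_limit, quality_min) {
  if (any(!is.na(quality) & (quality < 0 | quality > 1)))
    stop("quality score outside [0, 1]", call. = FALSE)
  if (any(!is.na(ct) & ct <= 0))
    stop("non-positive Ct value", call. = FALSE)
  reason <- rep(NA_character_, length(ct))
  reason[!is.na(ct) & !is.na(quality) & quality < quality_min] <- "low_quality"
  reason[!is.na(ct) & ct > ct_limit] <- "out_of_range"
  reason[is.na(ct)] <- "no_amplification"
  reason
}

#' Merge the triplicate measurements of one sample x assay cell
#'
#' The final measurement is the median of the replicates that pass
#' [filter_replicate()]; with two survivors this is their midpoint, and
#' with no survivors the cell is `NA`.
#'
#' @param wells Data frame of replicate rows for a single sample x assay
#'   pair, with columns `ct` and `quality` (and, if present, consistent
#'   `sample_id` / `assay_id`).
#' @inheritParams filter_replicate
#' @return Single numeric Ct, or `NA` when no replicate passes.
#' @export
merge_replicates <- function(wells, ct_limit = 25, quality_min = 0.65) {
  for (col in c("sample_id", "assay_id")) {
    if (col %in% names(wells) && length(unique(wells[[col]])) > 1)
      stop(sprintf("merge_replicates(): mixed %s in one cell", col), call. = FALSE)
  }
  reason <- well_filter_reason(wells$ct, wells$quality, ct_limit, quality_min)
  ok <- wells$ct[is.na(reason)]
  if (length(ok) == 0) NA_real_ else stats::median(ok)
}

#' Curate a raw well table into a final Ct matrix
#'
#' Applies the full curation protocol: each replicate is filtered by
#' detection range and quality score, surviving replicates are merged to
#' their median per sample x assay, assays with more than `na_limit`
#' missing cells are dropped, and the remaining missing cells are replaced
#' by the assay's global average (arithmetic mean of its observed merged
#' Ct values across all samples, groups pooled).
#'
#' @param wells Long-format well table with columns `sample_id`,
#'   `assay_id`, `replicate`, `ct`, `quality`.
#' @param na_limit Maximum tolerated number of missing cells per assay
#'   (default 10); assays exceeding it are omitted.
#' @inheritParams filter_replicate
#' @return Object of class `curated_ct`:
#' \describe{
#'   \item{values}{assay x sample matrix of final Ct values, no `NA`s.}
#'   \item{na_mask}{logical matrix marking cells that were `NA` before
#'     imputation.}
#'   \item{n_replicates}{matrix of surviving replicate counts per cell.}
#'   \item{dropped_assays}{data frame of omitted assays with their NA
#'     counts.}
#'   \item{params}{thresholds used.}
#' }
#' @export
curate_matrix <- function(wells, na_limit = 10, ct_limit = 25,
                          quality_min = 0.65) {
  stopifnot(na_limit >= 0)
  req <- c("sample_id", "assay_id", "ct", "quality")
  if (!all(req %in% names(wells)))
    stop("wells table needs columns sample_id, assay_id, ct, quality",
         call. = FALSE)
  assays <- unique(wells$assay_id)
  samples <- unique(wells$sample_id)
  if (length(samples) < 1) stop("no samples in well table", call. = FALSE)

  reason <- well_filter_reason(wells$ct, wells$quality, ct_limit, quality_min)
  pass <- is.na(reason)
  ai <- match(wells$assay_id, assays)
  si <- match(wells$sample_id, samples)
  cell <- (si - 1L) * length(assays) + ai

  dims <- c(length(assays), length(samples))
  n_rep <- matrix(0L, dims[1], dims[2], dimnames = list(assays, samples))
  tab <- tabulate(cell[pass], nbins = prod(dims))
  n_rep[] <- tab

  values <- matrix(NA_real_, dims[1], dims[2], dimnames = list(assays, samples))
  med <- tapply(wells$ct[pass], cell[pass], stats::median)
  values[as.integer(names(med))] <- med

  na_mask <- is.na(values)
  n_na <- rowSums(na_mask)
  drop <- n_na > na_limit
  dropped <- data.frame(assay_id = assays[drop], n_na = unname(n_na[drop]),
                        reason = rep("exceeds_na_limit", sum(drop)),
                        row.names = NULL, stringsAsFactors = FALSE)

  values <- values[!drop, , drop = FALSE]
  na_mask <- na_mask[!drop, , drop = FALSE]
  n_rep <- n_rep[!drop, , drop = FALSE]

  all_na <- rowSums(!na_mask) == 0
  if (any(all_na))
    stop(sprintf("assay(s) %s have no observed value to impute from",
                 paste(rownames(values)[all_na], collapse = ", ")),
         call. = FALSE)
  if (any(na_mask)) {
    means <- rowSums(values, na.rm = TRUE) / rowSums(!na_mask)
    idx <- which(na_mask, arr.ind = TRUE)
    values[na_mask] <- means[idx[, 1]]
  }

  structure(list(values = values, na_mask = na_mask, n_replicates = n_rep,
                 dropped_assays = dropped,
                 params = list(na_limit = na_limit, ct_limit = ct_limit,
                               quality_min = quality_min)),
            class = "curated_ct")
}

#' Assays reliably detected after curation
#'
#' Returns the target assays that survived curation, excluding the
#' endogenous controls — the "expressed panel" carried into all downstream
#' comparisons.
#'
#' @param curated A `curated_ct` object.
#' @param controls Character vector of endogenous-control assay ids to
#'   exclude.
#' @return Character vector of retained assay ids.
#' @export
expressed_panel <- function(curated, controls = character()) {
  setdiff(rownames(curated$values), controls)
}

#' @export
print.curated_ct <- function(x, ...) {
  cat(sprintf("Curated Ct matrix: %d assays x %d samples (%d assays dropped, %d cells imputed)\n",
              nrow(x$values), ncol(x$values), nrow(x$dropped_assays),
              sum(x$na_mask)))
  invisible(x)
}
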