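## Tab-separated I/O. One convention throughout: header row, tab
## delimiter, literal "NA" as the missing-value sentinel (never an empty
## field).

#' Write a table as TSV
#'
#' @param x Data frame (or matrix; row names become a leading column named
#'   by `rownames_as`).
#' @param path Output file.
#' @param rownames_as Column name for matrix row names.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, rownames_as = NULL) {
  if (is.matrix(x)) {
    df <- data.frame(rn = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- if (is.null(rownames_as)) "id" else rownames_as
    x <- df
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a long-format well table
#'
#' Expects columns `sample_id`, `assay_id`, `replicate`, `ct`, `quality`.
#' @param path TSV file.
#' @return Data frame of raw wells.
#' @export
read_wells <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "assay_id", "replicate", "ct", "quality")
  if (!all(req %in% names(x)))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(req, names(x)), collapse = ", ")), call. = FALSE)
  x
}

#' Read a sample annotation table (`sample_id`, `group`, ...)
#' @param path TSV file.
#' @return Data frame.
#' @export
read_samples <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(x)))
    stop(sprintf("%s: needs columns sample_id and group", path), call. = FALSE)
  x
}

#' Read a screening-study statistics table
#'
#' Expects `assay_id`, `screen_auc`, `screen_p` (and optionally `old_id`).
#' @param path TSV file.
#' @return `screening_stats` data frame.
#' @export
read_screening <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("assay_id", "screen_auc", "screen_p") %in% names(x)))
    stop(sprintf("%s: needs assay_id, screen_auc, screen_p", path),
         call. = FALSE)
  class(x) <- c("screening_stats", "data.frame")
  x
}

#' Read an identifier mapping table (`old_id`, `new_id`)
#' @param path TSV file.
#' @return Data frame.
#' @export
read_mapping <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("old_id", "new_id") %in% names(x)))
    stop(sprintf("%s: needs columns old_id and new_id", path), call. = FALSE)
  x
}
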