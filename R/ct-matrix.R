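#' Construct a Ct matrix
#'
#' A \code{ct_matrix} holds RT-qPCR threshold-cycle (Ct) values for a set of
#' samples (rows) by miRNA targets (columns), together with a right-censoring
#' flag per cell: a target that never amplified within the instrument's cycle
#' limit is "undetected" and its Ct is stored at the limit (default 40
#' cycles) with \code{censored = TRUE}. Storing censored values at the limit
#' rather than as missing keeps every downstream delta-Ct computable and is
#' the conservative qPCR convention for detection-limit data.
#'
#' @param ct numeric matrix of Ct values with sample ids as rownames and
#'   miRNA names as colnames.
#' @param censored logical matrix of the same dimensions; \code{TRUE} marks a
#'   cell undetected within \code{cycle_limit}. Defaults to all-\code{FALSE}.
#' @param cycle_limit maximum qPCR cycle number (cycles); Ct values at the
#'   limit with \code{censored = TRUE} encode non-detection.
#' @return an object of class \code{ct_matrix}: a list with elements
#'   \code{ct}, \code{censored}, \code{cycle_limit}, \code{sample_ids},
#'   \code{mirna_ids}.
#' @export
ct_matrix <- function(ct, censored = NULL, cycle_limit = 40) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop2("`ct` must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop2("`ct` must carry sample ids as rownames and miRNA names as colnames")
  if (is.null(censored))
    censored <- matrix(FALSE, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  x <- structure(
    list(ct = ct, censored = censored, cycle_limit = cycle_limit,
         sample_ids = rownames(ct), mirna_ids = colnames(ct)),
    class = "ct_matrix")
  validate_ct_matrix(x)
}

validate_ct_matrix <- function(x) {
  ct <- x$ct; cen <- x$censored
  if (!identical(dim(ct), dim(cen)))
    stop2("`ct` and `censored` must have identical dimensions")
  if (!is.logical(cen) || anyNA(cen))
    stop2("`censored` must be logical with no missing values")
  if (anyNA(ct))
    stop2("`ct` must not contain missing values; encode non-detection via `censored`")
  if (anyDuplicated(x$sample_ids))
    stop2("duplicate sample ids: ",
          paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "))
  if (anyDuplicated(x$mirna_ids))
    stop2("duplicate miRNA names: ",
          paste(unique(x$mirna_ids[duplicated(x$mirna_ids)]), collapse = ", "))
  if (any(ct[cen] != x$cycle_limit))
    stop2("censored cells must store ct equal to the cycle limit (",
          x$cycle_limit, ")")
  det <- ct[!cen]
  if (length(det) && (any(det <= 0) || any(det > x$cycle_limit)))
    stop2("detected Ct values must lie in (0, ", x$cycle_limit, "]")
  x
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d samples x %d miRNAs (cycle limit %g)\n",
              length(x$sample_ids), length(x$mirna_ids), x$cycle_limit))
  cat(sprintf("  censored cells: %d (%.1f%%)\n", sum(x$censored),
              100 * mean(x$censored)))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Subset a Ct matrix by samples and/or miRNAs
#'
#' @param x a \code{ct_matrix}.
#' @param i,j sample / miRNA index (integer, logical, or name).
#' @param ... ignored.
#' @return a \code{ct_matrix}.
#' @export
`[.ct_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$mirna_ids)
  ct_matrix(x$ct[i, j, drop = FALSE], x$censored[i, j, drop = FALSE],
            cycle_limit = x$cycle_limit)
}

delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a Ct table from delimited text
#'
#' Expects the first column to hold sample ids and the remaining columns one
#' miRNA each (use \code{transpose = TRUE} for miRNAs-in-rows exports).
#' Cells equal to an "undetected" token (or empty) are right-censored at the
#' cycle limit; numeric Ct values above the limit are clamped to it and also
#' marked censored, with a message. The delimiter is chosen from the file
#' extension: tab for \code{.tsv}/\code{.txt}, comma otherwise.
#'
#' @param path file path.
#' @param cycle_limit maximum cycle number (cycles, default 40).
#' @param undetected_token character value(s) marking non-detection (the
#'   empty string is always accepted); default \code{"Undetermined"}.
#' @param transpose set \code{TRUE} if rows are miRNAs and columns samples.
#' @return a \code{ct_matrix}.
#' @export
read_ct_table <- function(path, cycle_limit = 40,
                          undetected_token = "Undetermined",
                          transpose = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop2("Ct table needs an id column plus >= 1 value column")
  hdr <- names(df)[-1L]  # data.frame subsetting would silently dedupe these
  if (anyDuplicated(hdr))
    stop2("duplicate miRNA names in header: ",
          paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  ids <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  rownames(raw) <- ids
  if (transpose) raw <- t(raw)

  tokens <- c(undetected_token, "")
  cen <- matrix(trimws(raw) %in% tokens, nrow(raw), ncol(raw),
                dimnames = dimnames(raw))
  ct <- suppressWarnings(array(as.numeric(raw), dim(raw), dimnames(raw)))
  bad <- !cen & is.na(ct)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop2(sprintf("non-numeric cell '%s' at sample '%s', miRNA '%s'",
                  raw[bad][1L], rownames(raw)[w[1L]], colnames(raw)[w[2L]]))
  }
  over <- !cen & ct > cycle_limit
  if (any(over)) {
    message(sum(over), " Ct value(s) above the cycle limit ", cycle_limit,
            " clamped and marked censored")
    cen[over] <- TRUE
  }
  ct[cen] <- cycle_limit
  ct_matrix(ct, cen, cycle_limit = cycle_limit)
}

#' Write a Ct table as delimited text
#'
#' Inverse of \code{\link{read_ct_table}}: samples in rows, censored cells
#' written as the undetected token.
#'
#' @param x a \code{ct_matrix}.
#' @param path output file path (\code{.tsv}/\code{.txt} write tabs,
#'   anything else commas).
#' @param undetected_token string written for censored cells.
#' @return \code{path}, invisibly.
#' @export
write_ct_table <- function(x, path, undetected_token = "Undetermined") {
  out <- matrix(format(x$ct, trim = TRUE, digits = 15),
                nrow(x$ct), ncol(x$ct), dimnames = dimnames(x$ct))
  out[x$censored] <- undetected_token
  df <- data.frame(sample_id = x$sample_ids, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Drop miRNAs undetected in every sample
#'
#' The pre-screening detection filter: a miRNA censored at the cycle limit in
#' all samples carries no information and is removed; miRNAs detected in at
#' least one sample are kept in their original column order. Idempotent.
#'
#' @param x a \code{ct_matrix}.
#' @return a \code{ct_matrix} with the same samples and the detectable
#'   miRNAs only.
#' @export
filter_globally_undetected <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  keep <- colSums(!x$censored) > 0L
  if (!any(keep)) stop2("no miRNA is detected in any sample")
  x[, keep]
}

#' Aggregate replicate RT-qPCR reactions
#'
#' Combines per-replicate Ct matrices (e.g. two independent RT reactions each
#' followed by one qPCR) cell-wise: the mean of the detected replicate Ct
#' values; a cell is censored only when every replicate is censored, in which
#' case the Ct stays at the cycle limit.
#'
#' @param matrices list of \code{ct_matrix} objects over identical samples
#'   and miRNAs (same order).
#' @return a single \code{ct_matrix}.
#' @export
aggregate_replicates <- function(matrices) {
  if (!length(matrices)) stop2("need at least one replicate matrix")
  ref <- matrices[[1L]]
  for (m in matrices) {
    stopifnot(inherits(m, "ct_matrix"))
    if (!identical(m$sample_ids, ref$sample_ids) ||
        !identical(m$mirna_ids, ref$mirna_ids) ||
        m$cycle_limit != ref$cycle_limit)
      stop2("replicate matrices must share samples, miRNAs and cycle limit")
  }
  n_det <- Reduce(`+`, lapply(matrices, function(m) !m$censored))
  sum_det <- Reduce(`+`, lapply(matrices, function(m) m$ct * !m$censored))
  cen <- n_det == 0L
  ct <- ifelse(cen, ref$cycle_limit, sum_det / pmax(n_det, 1L))
  dimnames(ct) <- dimnames(ref$ct)
  ct_matrix(ct, cen, cycle_limit = ref$cycle_limit)
}

#' Read a cohort metadata table
#'
#' CSV with header \code{sample_id,group,split,...}; \code{group} must be
#' cancer/control and \code{split} train/test for every sample. Optional
#' demographic columns (age, sex, smoker, stage, histology) pass through.
#'
#' @param path CSV file path.
#' @return data.frame with one row per sample.
#' @export
read_cohort_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_metadata(df)
}

validate_cohort_metadata <- function(df) {
  need <- c("sample_id", "group", "split")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop2("duplicate sample_id in metadata")
  if (anyNA(df$group) || !all(df$group %in% c("cancer", "control")))
    stop2("`group` must be 'cancer' or 'control' for every sample")
  if (anyNA(df$split) || !all(df$split %in% c("train", "test")))
    stop2("`split` must be 'train' or 'test' for every sample")
  if (is.character(df$smoker)) df$smoker <- df$smoker %in% c("TRUE", "true", "1", "yes")
  df
}

# Match metadata rows to a ct/diffpair sample id vector, erroring on gaps.
meta_for_samples <- function(meta, sample_ids) {
  idx <- match(sample_ids, meta$sample_id)
  if (anyNA(idx))
    stop2("samples missing from metadata: ",
          paste(utils::head(sample_ids[is.na(idx)], 5L), collapse = ", "))
  meta[idx, , drop = FALSE]
}
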