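#' Enumerate all unordered miRNA pairs
#'
#' Every unordered pair of targets, each emitted once in canonical
#' orientation: the member that comes first in the input column order is
#' \code{mirna_a}. Ordering is lexicographic by column index, so the pair
#' list is reproducible from the input file alone and stable under renaming.
#' For m targets this yields m(m-1)/2 pairs (181 miRNAs -> 16290 pairs).
#'
#' @param mirna_ids character vector of at least two unique miRNA names.
#' @return data.frame with columns \code{mirna_a}, \code{mirna_b}.
#' @export
enumerate_pairs <- function(mirna_ids) {
  if (anyDuplicated(mirna_ids)) stop2("miRNA names must be unique")
  m <- length(mirna_ids)
  if (m < 2L) stop2("need at least two miRNAs to form pairs")
  idx <- utils::combn(m, 2L)
  data.frame(mirna_a = mirna_ids[idx[1L, ]], mirna_b = mirna_ids[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Compute the per-sample delta-Ct diffpair matrix
#'
#' For each sample and each unordered pair (a, b) the diffpair value is
#' \code{Ct(a) - Ct(b)} within that sample. Because any per-sample global
#' offset (serum input, extraction efficiency) adds the same constant to both
#' Ct values, it cancels exactly: the diffpair matrix needs no external
#' normalizer. A pair is flagged \code{any_censored} for a sample when either
#' member was undetected there (its stored Ct sits at the cycle limit).
#'
#' @param x a \code{ct_matrix} with >= 2 miRNAs.
#' @return an object of class \code{diffpair_matrix}: list with
#'   \code{sample_ids}, \code{pairs} (data.frame \code{mirna_a},
#'   \code{mirna_b}), \code{delta_ct} (samples x pairs), and
#'   \code{any_censored} (logical, same shape). Pair columns are named
#'   \code{"a|b"}.
#' @export
compute_diffpairs <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  pairs <- enumerate_pairs(x$mirna_ids)
  ia <- match(pairs$mirna_a, x$mirna_ids)
  ib <- match(pairs$mirna_b, x$mirna_ids)
  delta <- x$ct[, ia, drop = FALSE] - x$ct[, ib, drop = FALSE]
  cen <- x$censored[, ia, drop = FALSE] | x$censored[, ib, drop = FALSE]
  lab <- pair_label(pairs$mirna_a, pairs$mirna_b)
  colnames(delta) <- colnames(cen) <- lab
  structure(
    list(sample_ids = x$sample_ids, pairs = pairs, delta_ct = delta,
         any_censored = cen),
    class = "diffpair_matrix")
}

pair_label <- function(a, b) paste(a, b, sep = "|")

#' @export
print.diffpair_matrix <- function(x, ...) {
  cat(sprintf("diffpair_matrix: %d samples x %d pairs\n",
              length(x$sample_ids), nrow(x$pairs)))
  invisible(x)
}

#' @export
dim.diffpair_matrix <- function(x) dim(x$delta_ct)

#' Write a diffpair matrix as CSV
#'
#' @param x a \code{diffpair_matrix}.
#' @param path output CSV path.
#' @param format \code{"wide"} (samples x \code{a|b} columns) or
#'   \code{"long"} (\code{sample_id,mirna_a,mirna_b,delta_ct,any_censored}).
#' @return \code{path}, invisibly.
#' @export
write_diffpairs <- function(x, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(sample_id = x$sample_ids, x$delta_ct,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    np <- nrow(x$pairs); ns <- length(x$sample_ids)
    df <- data.frame(
      sample_id = rep(x$sample_ids, times = np),
      mirna_a = rep(x$pairs$mirna_a, each = ns),
      mirna_b = rep(x$pairs$mirna_b, each = ns),
      delta_ct = as.vector(x$delta_ct),
      any_censored = as.vector(x$any_censored),
      stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Column of the diffpair matrix for a (possibly flipped) pair. Returns the
# column index and +1/-1 for whether the stored orientation matches.
find_pair <- function(dp, mirna_a, mirna_b) {
  lab <- pair_label(mirna_a, mirna_b)
  j <- match(lab, colnames(dp$delta_ct))
  if (!is.na(j)) return(list(col = j, sign = 1))
  j <- match(pair_label(mirna_b, mirna_a), colnames(dp$delta_ct))
  if (!is.na(j)) return(list(col = j, sign = -1))
  stop2("pair (", mirna_a, ", ", mirna_b, ") not present in diffpair matrix")
}
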