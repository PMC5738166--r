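#' Fold change over the time-zero baseline
#'
#' @param values numeric vector of normalized expression over the time
#'   course; the first element is the time-0 baseline.
#' @param pseudocount added to numerator and denominator so zero baselines
#'   stay finite (default 1 normalized unit).
#' @return fold changes for the post-baseline time points.
#' @examples
#' fold_change(c(10, 25), pseudocount = 0)  # 2.5
#' @export
fold_change <- function(values, pseudocount = 1) {
  stopifnot(length(values) >= 2L, all(values >= 0))
  (values[-1] + pseudocount) / (values[1] + pseudocount)
}

#' Call light-induced features across replicate datasets
#'
#' A feature is induced when its maximum fold change over the time course
#' strictly exceeds \code{threshold} in every dataset.
#'
#' @param datasets named list of matrices (features x time points, first
#'   column time 0, shared rownames = feature ids).
#' @param threshold fold-change threshold (default 2).
#' @param pseudocount see [fold_change()].
#' @param require_all if \code{FALSE}, one passing dataset suffices.
#' @return character vector of induced feature ids.
#' @export
call_induced <- function(datasets, threshold = 2, pseudocount = 1,
                         require_all = TRUE) {
  stopifnot(length(datasets) >= 1L)
  ids <- rownames(datasets[[1]])
  pass <- sapply(datasets, function(m) {
    stopifnot(identical(rownames(m), ids))
    apply(m, 1, function(v) max(fold_change(v, pseudocount)) > threshold)
  })
  pass <- matrix(pass, nrow = length(ids))
  hit <- if (require_all) rowSums(pass) == length(datasets) else
    rowSums(pass) > 0
  ids[hit]
}

#' Classify induction timing
#'
#' Early responders peak at the first post-baseline time point (30 min);
#' everything else is late. The peak is the argmax of expression over the
#' course, ties broken toward the earlier time point.
#'
#' @param mat matrix features x time points (first column time 0), e.g. the
#'   mean of the replicate datasets.
#' @param induced ids to classify (default: all rows).
#' @param times numeric time labels of the columns.
#' @return data.frame feature_id, peak_time, timing ("early"/"late").
#' @export
classify_timing <- function(mat, induced = rownames(mat),
                            times = c(0, 30, 60, 120)) {
  stopifnot(ncol(mat) == length(times))
  m <- mat[induced, , drop = FALSE]
  post <- m[, -1, drop = FALSE]
  peak_idx <- apply(post, 1, which.max)   # which.max takes the first tie
  peak <- times[-1][peak_idx]
  data.frame(feature_id = induced,
             peak_time = peak,
             timing = ifelse(peak == times[2], "early", "late"),
             stringsAsFactors = FALSE)
}

#' Sense co-induction of induced antisense transcripts
#'
#' @param induced_antisense induced antisense feature ids.
#' @param induced_sense induced sense gene ids.
#' @param pairing named character vector: antisense id -> sense partner id.
#' @param digits decimal places of the percentage (default 0).
#' @return list with \code{n_antisense}, \code{n_coinduced} and
#'   \code{pct_coinduced}.
#' @examples
#' p <- setNames(paste0("g", 1:3), paste0("as", 1:3))
#' sense_antisense_concordance(c("as1", "as2"), "g1", p)
#' @export
sense_antisense_concordance <- function(induced_antisense, induced_sense,
                                        pairing, digits = 0) {
  n <- length(induced_antisense)
  co <- sum(pairing[induced_antisense] %in% induced_sense)
  list(n_antisense = n, n_coinduced = co,
       pct_coinduced = if (n > 0) percent_of(co, n, digits) else NA_real_)
}
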