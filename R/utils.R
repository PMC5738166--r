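#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages: halves are rounded
#' away from zero rather than to even (the base \code{round} rule).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a total, rounded as printed
#'
#' @param n numerator count.
#' @param total denominator count.
#' @param digits decimal places kept (0 for whole percentages).
#' @return numeric percentage on the 0-100 scale.
#' @examples
#' percent_of(8956, 9730)      # 92
#' percent_of(26, 1056, 1)     # 2.5
#' @export
percent_of <- function(n, total, digits = 0) {
  stopifnot(total > 0)
  round_half_up(100 * n / total, digits)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# data.frame -> GRanges without requiring seqinfo
df_to_gr <- function(df, strand = NULL) {
  s <- if (is.null(strand)) "*" else strand
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end),
                         strand = s)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
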