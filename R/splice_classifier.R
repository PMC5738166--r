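#' Load splice junctions
#'
#' Reads a junction file: either a TSV with columns chrom, donor, acceptor,
#' strand, reads, or a BED6-like file whose name (or score) column carries
#' the supporting spliced-read count and whose interval spans the intron
#' (donor = first intronic base, acceptor = last, 1-based internally).
#' Junctions with intron length outside \code{[min_len, max_len]} are
#' rejected; the rejected count is kept as attribute \code{n_rejected}.
#'
#' @param path junction file, or a data.frame already in the TSV layout.
#' @param min_len,max_len intron length bounds in bp (defaults 50 and
#'   500,000).
#' @return data.frame chrom, donor, acceptor, strand, reads with attribute
#'   \code{n_rejected}.
#' @export
load_junctions <- function(path, min_len = 50L, max_len = 500000L) {
  if (is.data.frame(path)) {
    df <- path
  } else {
    if (!file.exists(path)) stopf("junction file not found: %s", path)
    first <- readLines(path, n = 1L)
    ncol1 <- length(strsplit(first, "\t")[[1]])
    raw <- tryCatch(
      utils::read.table(path, sep = "\t", header = grepl("chrom", first),
                        stringsAsFactors = FALSE),
      error = function(e) stopf("malformed junction file %s: %s",
                                path, conditionMessage(e)))
    if (ncol1 >= 6 && !grepl("chrom", first)) {   # BED6: 0-based half-open
      reads <- suppressWarnings(as.numeric(raw[[4]]))
      if (anyNA(reads)) reads <- as.numeric(raw[[5]])
      df <- data.frame(chrom = raw[[1]], donor = raw[[2]] + 1L,
                       acceptor = raw[[3]], strand = raw[[6]],
                       reads = reads, stringsAsFactors = FALSE)
    } else {
      names(raw) <- c("chrom", "donor", "acceptor", "strand", "reads")
      df <- raw
    }
  }
  need <- c("chrom", "donor", "acceptor", "strand", "reads")
  if (!all(need %in% names(df))) {
    stopf("junctions need columns: %s", paste(need, collapse = ", "))
  }
  bad <- which(df$acceptor <= df$donor | df$reads < 0)
  if (length(bad)) stopf("invalid junction at line %d", bad[1])
  len <- df$acceptor - df$donor + 1L
  keep <- len >= min_len & len <= max_len
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!keep)
  out
}

# exact-match index of each junction against the annotated intron table
# (chrom + donor + acceptor; strand must agree unless the junction strand is
# unknown "*"/".")
match_annotated <- function(junctions, introns) {
  if (nrow(introns) == 0L) return(rep(NA_integer_, nrow(junctions)))
  key_j <- paste(junctions$chrom, junctions$donor, junctions$acceptor)
  key_i <- paste(introns$chrom, introns$start, introns$end)
  m <- match(key_j, key_i)
  known <- junctions$strand %in% c("+", "-")
  bad <- !is.na(m) & known & introns$strand[m] != junctions$strand
  m[bad] <- NA_integer_
  m
}

#' Read-count cutoff from annotated introns
#'
#' The filter applied to non-annotated junctions: the 25\% quantile
#' (linear interpolation between order statistics, R's default type 7) of
#' the read counts of junctions that exactly match an annotated intron.
#'
#' @param junctions junction data.frame.
#' @param introns annotated introns (from \code{gene_models$introns}).
#' @param probs quantile level (default 0.25).
#' @return the cutoff value.
#' @export
annotated_coverage_cutoff <- function(junctions, introns, probs = 0.25) {
  m <- match_annotated(junctions, introns)
  v <- junctions$reads[!is.na(m)]
  if (!length(v)) stopf("no junction matches an annotated intron")
  unname(stats::quantile(v, probs = probs, type = 7))
}

#' Classify junctions against annotated introns
#'
#' Classes, in precedence order, each junction compared against all
#' annotated introns:
#' \describe{
#'   \item{perfect}{both splice sites exactly match one annotated intron.}
#'   \item{filtered}{non-annotated junction with read support below the
#'     cutoff (ties at the cutoff are kept).}
#'   \item{alternative}{shares exactly the donor or the acceptor with an
#'     annotated intron (an alternative splice isoform).}
#'   \item{weak}{both ends within \code{weak_tol} bp of one annotated
#'     intron, neither end exact.}
#'   \item{novel}{everything else.}
#' }
#'
#' @param junctions junction data.frame.
#' @param introns annotated introns.
#' @param cutoff read-count cutoff from [annotated_coverage_cutoff()].
#' @param weak_tol tolerance (bp) of the weak-match class (default 10).
#' @return junctions with a \code{cls} factor column.
#' @export
classify_junctions <- function(junctions, introns, cutoff,
                               weak_tol = 10L) {
  n <- nrow(junctions)
  cls <- character(n)
  exact <- !is.na(match_annotated(junctions, introns))
  for (i in seq_len(n)) {
    if (exact[i]) { cls[i] <- "perfect"; next }
    if (junctions$reads[i] < cutoff) { cls[i] <- "filtered"; next }
    ii <- introns[introns$chrom == junctions$chrom[i], , drop = FALSE]
    if (nrow(ii) &&
        any(ii$start == junctions$donor[i] | ii$end == junctions$acceptor[i])) {
      cls[i] <- "alternative"
      next
    }
    if (nrow(ii) &&
        any(abs(ii$start - junctions$donor[i]) <= weak_tol &
            abs(ii$end - junctions$acceptor[i]) <= weak_tol)) {
      cls[i] <- "weak"
      next
    }
    cls[i] <- "novel"
  }
  junctions$cls <- factor(cls, levels = c("perfect", "weak", "alternative",
                                          "novel", "filtered"))
  junctions
}

#' Count well-supported junctions inside feature intervals
#'
#' @param junctions junction data.frame.
#' @param features data.frame with chrom/start/end (e.g. the lincRNA or
#'   antisense catalog).
#' @param min_reads minimum spliced-read support (default 10).
#' @return list with \code{n} (junctions with \code{reads >= min_reads}
#'   whose intron lies fully inside some feature) and \code{feature_hit}
#'   (logical per feature: contains at least one such junction).
#' @export
junctions_in_features <- function(junctions, features, min_reads = 10) {
  jj <- junctions[junctions$reads >= min_reads, , drop = FALSE]
  if (nrow(jj) == 0L || nrow(features) == 0L) {
    return(list(n = 0L, feature_hit = rep(FALSE, nrow(features))))
  }
  jr <- GenomicRanges::GRanges(jj$chrom, IRanges::IRanges(jj$donor, jj$acceptor))
  fr <- df_to_gr(features)
  hits <- GenomicRanges::findOverlaps(jr, fr, type = "within")
  list(n = length(unique(S4Vectors::queryHits(hits))),
       feature_hit = seq_along(fr) %in% S4Vectors::subjectHits(hits))
}

#' Spliced-fraction report per feature class
#'
#' @param counts named list; each element \code{list(spliced =, total =)}.
#' @param digits decimal places of the percentage (default 1).
#' @return data.frame class, n_spliced, n_unspliced, total, pct_spliced.
#' @examples
#' splice_fraction_report(list(antisense = list(spliced = 26, total = 1056)))
#' @export
splice_fraction_report <- function(counts, digits = 1) {
  do.call(rbind, lapply(names(counts), function(k) {
    sp <- counts[[k]]$spliced; tot <- counts[[k]]$total
    data.frame(class = k, n_spliced = sp, n_unspliced = tot - sp,
               total = tot,
               pct_spliced = if (tot > 0) percent_of(sp, tot, digits) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
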