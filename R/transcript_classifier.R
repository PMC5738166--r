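#' Classify transcription units against the gene annotation
#'
#' A unit overlapping an annotated gene by at least 1 bp is a coding unit.
#' A non-overlapping unit at least \code{min_distance} bp from the nearest
#' gene is a lincRNA candidate; non-overlapping units closer than that are
#' discarded (kept in the table with status \code{"discarded"}), since their
#' signal may belong to the neighboring gene.
#'
#' @param units unit data.frame from [call_units()].
#' @param genes a \code{gene_models} object.
#' @param min_distance minimum gap (bp) to the nearest gene for a lincRNA
#'   candidate; the gap between adjacent intervals is 0.
#' @return units with added \code{status}
#'   (coding/linc_candidate/discarded) and \code{distance_to_gene} columns.
#' @export
classify_units <- function(units, genes, min_distance = 500L) {
  stopifnot(inherits(genes, "gene_models"))
  if (nrow(units) == 0L) {
    units$status <- character(0)
    units$distance_to_gene <- integer(0)
    return(units)
  }
  ug <- df_to_gr(units)
  gg <- df_to_gr(genes$genes)
  ov <- IRanges::overlapsAny(ug, gg)
  d <- GenomicRanges::distanceToNearest(ug, gg)
  dist <- rep(NA_integer_, nrow(units))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  units$status <- ifelse(ov, "coding",
                         ifelse(!is.na(dist) & dist >= min_distance,
                                "linc_candidate", "discarded"))
  # a chromosome without genes has no neighbor: intergenic by any margin
  units$status[!ov & is.na(dist)] <- "linc_candidate"
  units$distance_to_gene <- ifelse(ov, 0L, dist)
  units
}

#' Merge nearby lincRNA segments
#'
#' Candidate lincRNA segments separated by less than \code{max_gap} bp are
#' merged into one spanning interval (transitively); raw counts are summed
#' and re-normalized to the merged length. Motivated by the short spacing of
#' the genome: merging below 100 bp cannot bridge distinct genes, which are
#' almost always further apart.
#'
#' @param candidates lincRNA-candidate unit rows (same chromosome mix fine).
#' @param grid bin grid (for library totals during re-normalization).
#' @param max_gap gaps strictly smaller than this are merged.
#' @return merged candidate data.frame.
#' @export
merge_linc_segments <- function(candidates, grid, max_gap = 100L) {
  if (nrow(candidates) == 0L) return(candidates)
  raw_cols <- grep("^raw_", names(candidates), value = TRUE)
  out <- do.call(rbind, lapply(split(candidates, candidates$chrom), function(cc) {
    cc <- cc[order(cc$start), , drop = FALSE]
    gap_prev <- c(Inf, cc$start[-1] - cc$end[-nrow(cc)] - 1L)
    grp <- cumsum(gap_prev >= max_gap)
    mg <- lapply(split(cc, grp), function(s) {
      m <- s[1, , drop = FALSE]
      m$start <- min(s$start); m$end <- max(s$end)
      m$n_bins <- sum(s$n_bins)
      m$mean_logodds <- sum(s$mean_logodds * s$n_bins) / sum(s$n_bins)
      for (rc in raw_cols) m[[rc]] <- sum(s[[rc]])
      m
    })
    do.call(rbind, mg)
  }))
  rownames(out) <- NULL
  out <- out[order(match(out$chrom, unique(candidates$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$unit_id <- sprintf("LINC%05d", seq_len(nrow(out)))
  renormalize_units(out, grid)
}

#' Polysome coding threshold
#'
#' The coding filter of the lincRNA catalog: the median length-normalized
#' polysome coverage of the detected coding units. Intergenic candidates
#' above it are flagged as polysome-positive (possibly translated). The
#' median of an even-sized set is the mean of the central pair.
#'
#' @param coding_units coding unit rows carrying \code{norm_<polysome_lib>}.
#' @param polysome_lib polysome library id (default \code{"polysome"}).
#' @return the threshold value.
#' @export
polysome_threshold <- function(coding_units, polysome_lib = "polysome") {
  if (nrow(coding_units) == 0L) stopf("no coding units: threshold undefined")
  v <- coding_units[[paste0("norm_", polysome_lib)]]
  if (is.null(v)) stopf("missing norm_%s column", polysome_lib)
  stats::median(v)
}

#' Split lincRNA candidates on the polysome threshold
#'
#' @param candidates merged lincRNA candidates.
#' @param threshold value from [polysome_threshold()].
#' @param polysome_lib polysome library id.
#' @return list with data.frames \code{linc_confident} (value <= threshold;
#'   ties stay noncoding) and \code{polysome_positive} (value > threshold).
#' @export
apply_polysome_filter <- function(candidates, threshold,
                                  polysome_lib = "polysome") {
  v <- candidates[[paste0("norm_", polysome_lib)]]
  if (is.null(v) && nrow(candidates) > 0L) {
    stopf("missing norm_%s column", polysome_lib)
  }
  pos <- !is.null(v) & v > threshold
  list(linc_confident = candidates[!pos, , drop = FALSE],
       polysome_positive = candidates[pos, , drop = FALSE])
}

#' Assemble the final lincRNA catalog
#'
#' Polysome-positive candidates are rescued into the catalog when an
#' external coding-potential assessment flags them as noncoding; flagged
#' (possibly coding) records are reported separately. The final catalog is
#' the confident set plus the rescued set.
#'
#' @param linc_confident confident lincRNA data.frame.
#' @param polysome_positive polysome-positive candidate data.frame.
#' @param coding_potential_flags logical vector aligned to
#'   \code{polysome_positive} rows (TRUE = predicted coding), or a named
#'   vector keyed by unit_id.
#' @return list with \code{final} (all lincRNAs, with \code{status} column
#'   \code{linc_confident}/\code{linc_recovered}), \code{possibly_coding},
#'   and the counts \code{n_confident}, \code{n_polysome_positive},
#'   \code{n_recovered}, \code{n_possibly_coding}, \code{n_final}.
#' @export
assemble_final_catalog <- function(linc_confident, polysome_positive,
                                   coding_potential_flags) {
  np <- nrow(polysome_positive)
  f <- coding_potential_flags
  if (!is.null(names(f))) f <- f[polysome_positive$unit_id]
  if (length(f) != np || anyNA(f)) {
    miss <- if (length(f) == np) polysome_positive$unit_id[is.na(f)] else "(length mismatch)"
    stopf("missing coding-potential flag for: %s", paste(miss, collapse = ", "))
  }
  f <- as.logical(f)
  conf <- linc_confident
  if (nrow(conf)) conf$status <- "linc_confident"
  rec <- polysome_positive[!f, , drop = FALSE]
  if (nrow(rec)) rec$status <- "linc_recovered"
  pc <- polysome_positive[f, , drop = FALSE]
  if (nrow(pc)) pc$status <- "possibly_coding"
  final <- rbind(conf, rec)
  list(final = final,
       possibly_coding = pc,
       n_confident = nrow(linc_confident),
       n_polysome_positive = np,
       n_recovered = nrow(rec),
       n_possibly_coding = nrow(pc),
       n_final = nrow(final))
}

#' Summarize a feature catalog
#'
#' @param features data.frame with chrom/start/end and optional
#'   \code{norm_<lib>} columns.
#' @return list with \code{n}, \code{median_length}, \code{median_distance}
#'   (median gap between neighboring features on a chromosome; NA with < 2
#'   features on every chromosome) and \code{median_norm} (named vector of
#'   per-library median normalized coverage).
#' @export
catalog_summary <- function(features) {
  len <- features$end - features$start + 1L
  gaps <- unlist(lapply(split(features, features$chrom), function(cc) {
    if (nrow(cc) < 2L) return(numeric(0))
    cc <- cc[order(cc$start), , drop = FALSE]
    cc$start[-1] - cc$end[-nrow(cc)] - 1L
  }))
  norm_cols <- grep("^norm_", names(features), value = TRUE)
  list(n = nrow(features),
       median_length = if (length(len)) stats::median(len) else NA_real_,
       median_distance = if (length(gaps)) stats::median(gaps) else NA_real_,
       median_norm = vapply(features[norm_cols], stats::median, numeric(1)))
}

#' Gene detection report
#'
#' How many annotated genes are recovered by the unit caller: a gene counts
#' as detected when a coding unit overlaps it.
#'
#' @param genes a \code{gene_models} object.
#' @param coding_units coding unit rows.
#' @return list with \code{n_annotated}, \code{n_detected},
#'   \code{n_undetected} and \code{pct_detected} (whole percent).
#' @export
detection_report <- function(genes, coding_units) {
  gg <- df_to_gr(genes$genes)
  det <- if (nrow(coding_units)) {
    sum(IRanges::overlapsAny(gg, df_to_gr(coding_units)))
  } else 0L
  n <- nrow(genes$genes)
  list(n_annotated = n, n_detected = det, n_undetected = n - det,
       pct_detected = percent_of(det, n))
}
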