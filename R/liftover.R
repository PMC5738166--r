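#' Assembly map between two genome versions
#'
#' Describes, per chromosome, how coordinates transform between two
#' assembly versions: unchanged, whole-chromosome reverse complement, or
#' reverse complement of one internal segment.
#'
#' @param chrom chromosome names.
#' @param op per-chromosome operation: \code{"identity"},
#'   \code{"revcomp_whole"} or \code{"revcomp_segment"}.
#' @param length chromosome length (bp), required for
#'   \code{revcomp_whole}.
#' @param seg_start,seg_end 1-based inclusive bounds of the
#'   reverse-complemented segment, required for \code{revcomp_segment}.
#' @return data.frame of class \code{assembly_map}.
#' @export
assembly_map <- function(chrom, op, length = NA_integer_,
                         seg_start = NA_integer_, seg_end = NA_integer_) {
  df <- data.frame(chrom = chrom, op = op, length = length,
                   seg_start = seg_start, seg_end = seg_end,
                   stringsAsFactors = FALSE)
  if (!all(df$op %in% c("identity", "revcomp_whole", "revcomp_segment"))) {
    stopf("unknown liftover operation")
  }
  if (anyDuplicated(df$chrom)) stopf("one operation per chromosome")
  w <- df$op == "revcomp_whole"
  if (any(w & is.na(df$length))) stopf("revcomp_whole needs chromosome length")
  s <- df$op == "revcomp_segment"
  if (any(s & (is.na(df$seg_start) | is.na(df$seg_end)))) {
    stopf("revcomp_segment needs segment bounds")
  }
  if (any(s & !is.na(df$seg_start) & df$seg_start > df$seg_end)) {
    stopf("segment start > end")
  }
  class(df) <- c("assembly_map", "data.frame")
  df
}

#' Default map between the two successive assemblies of this genome
#'
#' Chromosomes 1-5 are identical between the versions; chromosome 6 has the
#' segment 1,847,027-2,788,223 reverse complemented; chromosome 7
#' (4,255,303 bp) is reverse complemented as a whole.
#'
#' @return an \code{assembly_map}.
#' @export
nc10_to_nc12_map <- function() {
  assembly_map(
    chrom = as.character(1:7),
    op = c(rep("identity", 5), "revcomp_segment", "revcomp_whole"),
    length = c(rep(NA_integer_, 6), 4255303L),
    seg_start = c(rep(NA_integer_, 5), 1847027L, NA_integer_),
    seg_end = c(rep(NA_integer_, 5), 2788223L, NA_integer_))
}

#' Convert intervals between assembly versions
#'
#' Identity chromosomes pass through. A whole reverse complement maps
#' \code{(start, end)} to \code{(L - end + 1, L - start + 1)}. A segment
#' reverse complement maps intervals inside the segment \code{[a, b]} to
#' \code{(a + b - end, a + b - start)} and leaves intervals outside
#' unchanged; an interval straddling a segment boundary has no defined
#' image and errors. Both reverse-complement operations flip the strand;
#' lengths are always preserved.
#'
#' @param iv data.frame with chrom, start, end (1-based inclusive) and
#'   optionally strand.
#' @param map an \code{assembly_map}.
#' @return converted data.frame, same columns.
#' @examples
#' m <- nc10_to_nc12_map()
#' convert_intervals(data.frame(chrom = "6", start = 2116400, end = 2116700), m)
#' @export
convert_intervals <- function(iv, map) {
  stopifnot(inherits(map, "assembly_map"))
  if (any(iv$start > iv$end)) stopf("interval start > end")
  mi <- match(iv$chrom, map$chrom)
  if (anyNA(mi)) {
    stopf("chromosome(s) not in map: %s",
          paste(unique(iv$chrom[is.na(mi)]), collapse = ", "))
  }
  out <- iv
  has_strand <- "strand" %in% names(iv)
  for (i in seq_len(nrow(iv))) {
    m <- map[mi[i], ]
    s <- iv$start[i]; e <- iv$end[i]
    flip <- FALSE
    if (m$op == "revcomp_whole") {
      if (e > m$length) stopf("interval beyond chromosome %s length", m$chrom)
      out$start[i] <- m$length - e + 1L
      out$end[i] <- m$length - s + 1L
      flip <- TRUE
    } else if (m$op == "revcomp_segment") {
      inside <- s >= m$seg_start & e <= m$seg_end
      outside <- e < m$seg_start | s > m$seg_end
      if (inside) {
        out$start[i] <- m$seg_start + m$seg_end - e
        out$end[i] <- m$seg_start + m$seg_end - s
        flip <- TRUE
      } else if (!outside) {
        stopf("interval %s:%d-%d straddles the reverse-complemented segment",
              iv$chrom[i], s, e)
      }
    }
    if (flip && has_strand && out$strand[i] %in% c("+", "-")) {
      out$strand[i] <- ifelse(iv$strand[i] == "+", "-", "+")
    }
  }
  out
}

#' Invert an assembly map
#'
#' Reverse complementation of a whole chromosome or of a fixed segment is
#' an involution, so the map is its own inverse;
#' \code{convert_intervals(convert_intervals(iv, m), invert_map(m))}
#' restores \code{iv}.
#'
#' @param map an \code{assembly_map}.
#' @return the inverse \code{assembly_map}.
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "assembly_map"))
  map
}
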