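#' Call transcription units per strand
#'
#' Runs the full bin-level pipeline (label, fit, score, segment) separately
#' for each strand of a strand-specific library, the per-strand analogue of
#' the unstranded caller. Eligible bins must both exceed the log-odds cutoff
#' and carry at least \code{min_reads} raw reads in the 50 bp bin.
#'
#' @param grid a \code{bin_grid} whose \code{rna_lib} (and optionally
#'   \code{pol_lib}) libraries are stranded.
#' @param genes \code{gene_models}; per-strand labels are built from genes
#'   on the matching strand.
#' @param rna_lib stranded RNA-seq library id.
#' @param pol_lib RNAPII library id (stranded or unstranded).
#' @param cutoff log-odds threshold.
#' @param min_reads minimum raw reads per bin (default 10).
#' @param seed training-subsample seed.
#' @param ... further arguments to [fit_transcription_model()].
#' @return list with elements \code{"+"} and \code{"-"}: unit data.frames,
#'   plus attribute \code{models} holding the two fits.
#' @export
call_stranded_units <- function(grid, genes, rna_lib = "ssrna",
                                pol_lib = "pol", cutoff = 1.5,
                                min_reads = 10, seed = 1L, ...) {
  e <- grid$counts[[rna_lib]]
  if (is.null(e)) stopf("no counts for library '%s'", rna_lib)
  if (!e$stranded) stopf("library '%s' is not stranded", rna_lib)
  models <- list()
  out <- lapply(c("+", "-"), function(s) {
    labels <- label_bins(grid, genes, strand = s)
    m <- fit_transcription_model(grid, labels, rna_lib = rna_lib,
                                 pol_lib = pol_lib, strand = s,
                                 cutoff = cutoff, seed = seed, ...)
    models[[s]] <<- m
    call_units(grid, predict(m, grid), cutoff = cutoff, strand = s,
               min_reads = min_reads, min_reads_lib = rna_lib)
  })
  names(out) <- c("+", "-")
  attr(out, "models") <- models
  out
}

opposite <- function(s) ifelse(s == "+", "-", "+")

#' Pair antisense units with their sense genes
#'
#' An antisense unit is a called unit overlapping an annotated gene on the
#' opposite strand. A pair is retained only when the gene itself is
#' expressed, i.e. overlapped by an above-cutoff unit on its own strand.
#' Antisense fragments overlapping the same gene are merged and scored as a
#' single antisense transcript whose span runs from the first to the last
#' fragment.
#'
#' @param stranded_units list from [call_stranded_units()].
#' @param genes \code{gene_models}.
#' @param rna_lib library whose normalized coverage fills the sense and
#'   antisense levels.
#' @return data.frame, one row per sense gene with an antisense partner:
#'   gene_id, chrom, start, end (antisense span), strand (antisense),
#'   n_fragments, antisense_level, sense_level, and a \code{fragments}
#'   list-column of the member fragment rows.
#' @export
pair_sense_antisense <- function(stranded_units, genes, rna_lib = "ssrna") {
  g <- genes$genes
  gg <- df_to_gr(g)
  res <- lapply(c("+", "-"), function(gs) {
    gi <- which(g$strand == gs)
    if (!length(gi)) return(NULL)
    sense_units <- stranded_units[[gs]]
    anti_units <- stranded_units[[opposite(gs)]]
    expressed <- if (nrow(sense_units)) {
      IRanges::overlapsAny(gg[gi], df_to_gr(sense_units))
    } else rep(FALSE, length(gi))
    if (nrow(anti_units) == 0L) return(NULL)
    hits <- GenomicRanges::findOverlaps(gg[gi], df_to_gr(anti_units))
    if (!length(hits)) return(NULL)
    per_gene <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    rows <- lapply(names(per_gene), function(q) {
      qi <- as.integer(q)
      if (!expressed[qi]) return(NULL)     # no sense expression: not a pair
      gene <- g[gi[qi], ]
      fr <- anti_units[per_gene[[q]], , drop = FALSE]
      nc <- paste0("norm_", rna_lib)
      sense_lvl <- {
        su <- sense_units[IRanges::overlapsAny(df_to_gr(sense_units),
                                               gg[gi][qi]), , drop = FALSE]
        if (nrow(su)) max(su[[nc]]) else 0
      }
      data.frame(gene_id = gene$gene_id, chrom = gene$chrom,
                 start = min(fr$start), end = max(fr$end),
                 strand = opposite(gs),
                 gene_start = gene$start, gene_end = gene$end,
                 gene_strand = gs,
                 n_fragments = nrow(fr),
                 antisense_level = max(fr[[nc]]),
                 sense_level = sense_lvl,
                 fragments = I(list(fr)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), gene_start = integer(),
                      gene_end = integer(), gene_strand = character(),
                      n_fragments = integer(), antisense_level = numeric(),
                      sense_level = numeric(), stringsAsFactors = FALSE)
    out$fragments <- list()
  }
  rownames(out) <- NULL
  out
}

#' Drop antisense calls explainable by a neighboring gene
#'
#' An apparent antisense signal lying on the same strand as, and close to
#' (or overlapping), a different annotated gene is more parsimoniously that
#' gene's own transcription. A call is removed when its antisense span
#' overlaps or lies within less than \code{min_gap} bp of an annotated gene
#' (other than the sense partner) on the antisense strand.
#'
#' @param calls data.frame from [pair_sense_antisense()].
#' @param genes \code{gene_models}.
#' @param min_gap distance threshold in bp (default 500).
#' @return filtered calls.
#' @export
filter_by_neighbor_distance <- function(calls, genes, min_gap = 500L) {
  if (nrow(calls) == 0L) return(calls)
  g <- genes$genes
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    nb <- g[g$strand == cl$strand & g$chrom == cl$chrom &
              g$gene_id != cl$gene_id, , drop = FALSE]
    if (!nrow(nb)) return(TRUE)
    gap <- ifelse(nb$start > cl$end, nb$start - cl$end - 1L,
                  ifelse(cl$start > nb$end, cl$start - nb$end - 1L, 0L))
    overlap <- nb$start <= cl$end & nb$end >= cl$start
    all(!overlap & gap >= min_gap)
  }, logical(1))
  calls[keep, , drop = FALSE]
}

#' Detect genes with antisense but no sense expression
#'
#' From gene-level stranded read counts in two or more datasets
#' (total-count normalized), reports genes whose average sense coverage is
#' below 1 read per 50 bp bin and average antisense coverage above 1 read
#' per 50 bp bin in every dataset. Genes overlapping another annotated gene
#' are removed, since their strand assignment is ambiguous.
#'
#' @param gene_counts data.frame with columns gene_id, dataset, sense,
#'   antisense (normalized read counts per gene and dataset).
#' @param genes \code{gene_models}.
#' @param datasets dataset ids that must all pass (default: all present).
#' @return data.frame gene_id, sense_avg, antisense_avg (means over
#'   datasets of per-50bp-bin averages), datasets_passed.
#' @export
detect_antisense_only <- function(gene_counts, genes,
                                  datasets = unique(gene_counts$dataset)) {
  g <- genes$genes
  len <- g$end - g$start + 1L
  names(len) <- g$gene_id
  gc <- gene_counts[gene_counts$dataset %in% datasets, , drop = FALSE]
  gc$nbins <- len[gc$gene_id] / 50
  gc$sense_avg <- gc$sense / gc$nbins
  gc$anti_avg <- gc$antisense / gc$nbins
  pass <- tapply(gc$sense_avg < 1 & gc$anti_avg > 1, gc$gene_id, all)
  nds <- tapply(gc$dataset, gc$gene_id, function(d) length(unique(d)))
  ids <- names(pass)[pass & nds[names(pass)] == length(datasets)]
  # remove genes overlapping another gene
  gg <- df_to_gr(g)
  novl <- GenomicRanges::countOverlaps(gg, gg) == 1L
  ok <- g$gene_id[novl]
  ids <- ids[ids %in% ok]
  out <- data.frame(
    gene_id = ids,
    sense_avg = as.numeric(tapply(gc$sense_avg, gc$gene_id, mean)[ids]),
    antisense_avg = as.numeric(tapply(gc$anti_avg, gc$gene_id, mean)[ids]),
    datasets_passed = I(rep(list(datasets), length(ids))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize the antisense catalog
#'
#' @param paired calls from [pair_sense_antisense()] (after filtering).
#' @param antisense_only calls from [detect_antisense_only()].
#' @return list with \code{n_paired}, \code{n_antisense_only},
#'   \code{n_total}, \code{median_antisense_length},
#'   \code{median_sense_length} and \code{level_correlation} (Pearson r of
#'   sense vs antisense levels over pairs; NA with < 3 pairs).
#' @export
antisense_summary <- function(paired, antisense_only) {
  np <- nrow(paired); no <- nrow(antisense_only)
  list(
    n_paired = np,
    n_antisense_only = no,
    n_total = np + no,
    median_antisense_length =
      if (np) stats::median(paired$end - paired$start + 1L) else NA_real_,
    median_sense_length =
      if (np && "gene_start" %in% names(paired)) {
        stats::median(paired$gene_end - paired$gene_start + 1L)
      } else NA_real_,
    level_correlation =
      if (np >= 3 && all(c("sense_level", "antisense_level") %in%
                           names(paired))) {
        stats::cor(paired$sense_level, paired$antisense_level)
      } else NA_real_)
}

#' Antisense 5' start offsets to sense TSS and TTS
#'
#' The antisense 5' start is the boundary that is 5' on the antisense
#' strand (the higher coordinate for antisense to a plus-strand gene).
#' Offsets are signed in the sense gene's orientation: positive means the
#' antisense start lies downstream of the landmark.
#'
#' @param calls data.frame from [pair_sense_antisense()].
#' @return data.frame gene_id, offset_tss, offset_tts (bp).
#' @export
tss_offset_profile <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(gene_id = character(), offset_tss = numeric(),
                      offset_tts = numeric(), stringsAsFactors = FALSE))
  }
  plus <- calls$gene_strand == "+"
  as5 <- ifelse(plus, calls$end, calls$start)
  tss <- ifelse(plus, calls$gene_start, calls$gene_end)
  tts <- ifelse(plus, calls$gene_end, calls$gene_start)
  sgn <- ifelse(plus, 1, -1)
  data.frame(gene_id = calls$gene_id,
             offset_tss = sgn * (as5 - tss),
             offset_tts = sgn * (as5 - tts),
             stringsAsFactors = FALSE)
}
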