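#' Read gene models from GFF3 or BED12
#'
#' Parses an annotation file into a \code{gene_models} object: a gene table,
#' an exon table and the derived intron table (the gaps between consecutive
#' exons of each gene). Coordinates are 1-based inclusive throughout the
#' package; BED input is converted on read.
#'
#' @param path path to a GFF3 (\code{.gff}/\code{.gff3}) or BED12
#'   (\code{.bed}) file. GFF3 files must carry \code{gene} records and
#'   \code{exon} records whose \code{Parent} (or \code{ID} prefix) names the
#'   gene.
#' @return an object of class \code{gene_models}: list with data.frames
#'   \code{genes} (gene_id, chrom, start, end, strand), \code{exons}
#'   (gene_id, start, end) and \code{introns} (gene_id, chrom, start, end,
#'   strand).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    typ <- as.character(gr$type)
    gg <- gr[typ == "gene"]
    ee <- gr[typ == "exon"]
    if (length(gg) == 0L) stopf("no gene records in %s", path)
    genes <- data.frame(
      gene_id = as.character(gg$ID),
      chrom = as.character(GenomicRanges::seqnames(gg)),
      start = GenomicRanges::start(gg),
      end = GenomicRanges::end(gg),
      strand = as.character(GenomicRanges::strand(gg)),
      stringsAsFactors = FALSE)
    parent <- as.character(S4Vectors::unstrsplit(ee$Parent, ","))
    exons <- data.frame(
      gene_id = parent,
      start = GenomicRanges::start(ee),
      end = GenomicRanges::end(ee),
      stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    genes <- data.frame(
      gene_id = as.character(gr$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    if (!is.null(gr$blocks)) {
      bl <- gr$blocks
      n <- S4Vectors::elementNROWS(bl)
      ubl <- unlist(bl)
      exons <- data.frame(
        gene_id = rep(genes$gene_id, n),
        start = rep(genes$start, n) + IRanges::start(ubl) - 1L,
        end = rep(genes$start, n) + IRanges::end(ubl) - 1L,
        stringsAsFactors = FALSE)
    } else {
      exons <- data.frame(gene_id = genes$gene_id,
                          start = genes$start, end = genes$end,
                          stringsAsFactors = FALSE)
    }
  } else {
    stopf("unsupported annotation format: .%s", ext)
  }
  gene_models(genes, exons)
}

#' Construct gene models from tables
#'
#' @param genes data.frame with columns gene_id, chrom, start, end, strand.
#' @param exons data.frame with columns gene_id, start, end; defaults to one
#'   exon spanning each gene.
#' @return a \code{gene_models} object (see [read_annotation()]).
#' @export
gene_models <- function(genes, exons = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stopf("genes table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(genes$start > genes$end)) stopf("gene with start > end")
  if (any(genes$start < 1L)) stopf("non-positive gene coordinate")
  if (anyDuplicated(genes$gene_id)) stopf("duplicated gene_id")
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
  }
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  # validate exons against their gene span
  idx <- match(exons$gene_id, genes$gene_id)
  if (anyNA(idx)) stopf("exon with unknown gene_id")
  bad <- exons$start < genes$start[idx] | exons$end > genes$end[idx]
  if (any(bad)) {
    stopf("exon outside gene span for gene %s", exons$gene_id[which(bad)[1]])
  }
  introns <- derive_introns(genes, exons)
  structure(list(genes = genes, exons = exons, introns = introns),
            class = "gene_models")
}

# introns = gaps between consecutive exons, per gene
derive_introns <- function(genes, exons) {
  sp <- split(seq_len(nrow(exons)), exons$gene_id)
  out <- lapply(names(sp), function(g) {
    i <- sp[[g]]
    if (length(i) < 2L) return(NULL)
    s <- exons$start[i]; e <- exons$end[i]
    o <- order(s)
    s <- s[o]; e <- e[o]
    if (any(s[-1] <= e[-length(e)])) stopf("overlapping exons in gene %s", g)
    data.frame(gene_id = g, start = e[-length(e)] + 1L, end = s[-1] - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  idx <- match(out$gene_id, genes$gene_id)
  out$chrom <- genes$chrom[idx]
  out$strand <- genes$strand[idx]
  rownames(out) <- NULL
  out[, c("gene_id", "chrom", "start", "end", "strand")]
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons, %d introns on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), nrow(x$introns),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with chromosome name and length in bp.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' Partition a genome into fixed-width bins
#'
#' Tiles every chromosome with non-overlapping windows of \code{width} bp
#' (default 50 bp, the unit of all downstream detection); the last bin of a
#' chromosome is truncated at its end.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param width bin width in bp.
#' @return an object of class \code{bin_grid}: list with \code{bin_width},
#'   \code{chrom_sizes}, \code{bins} (data.frame chrom/start/end, 1-based
#'   inclusive) and an initially empty \code{counts} list keyed by library.
#' @examples
#' g <- build_bin_grid(c(chrA = 120), width = 50)
#' g$bins  # (1,50), (51,100), (101,120)
#' @export
build_bin_grid <- function(chrom_sizes, width = 50L) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stopf("bin width must be >= 1")
  if (length(chrom_sizes) == 0L || any(chrom_sizes < 1L)) {
    stopf("chromosome sizes must be >= 1")
  }
  if (is.null(names(chrom_sizes))) stopf("chrom_sizes must be named")
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    L <- as.integer(chrom_sizes[[ch]])
    n <- ceiling(L / width)
    s <- (seq_len(n) - 1L) * width + 1L
    data.frame(chrom = ch, start = s, end = pmin(s + width - 1L, L),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  structure(list(bin_width = width,
                 chrom_sizes = chrom_sizes,
                 bins = bins,
                 counts = list()),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins of %d bp over %d chromosome(s); %d track(s)\n",
              nrow(x$bins), x$bin_width, length(x$chrom_sizes),
              length(x$counts)))
  invisible(x)
}

n_bins <- function(grid) nrow(grid$bins)

# index of the bin containing base `pos` of chromosome `chrom` in the
# concatenated bin table
bin_index <- function(grid, chrom, pos) {
  per <- ceiling(grid$chrom_sizes / grid$bin_width)
  off <- c(0L, cumsum(per))[match(chrom, names(grid$chrom_sizes))]
  off + (as.integer(pos) - 1L) %/% grid$bin_width + 1L
}

#' Construct a coverage track of read placements
#'
#' A track is a set of read placements: intervals with a multiplicity. Each
#' placement is later assigned to exactly one bin, the one containing its
#' 5'-most mapped base (\code{start} on the plus or unknown strand,
#' \code{end} on the minus strand), so no read is counted twice across a bin
#' boundary.
#'
#' @param placements data.frame with columns chrom, start, end (1-based
#'   inclusive), count (reads placed there) and, for stranded tracks, strand
#'   in \code{+}/\code{-}.
#' @param library_id track label used as the key in the bin grid.
#' @param stranded logical; strand-specific ops require \code{TRUE}.
#' @return object of class \code{coverage_track}.
#' @export
coverage_track <- function(placements, library_id, stranded = FALSE) {
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(placements))) {
    stopf("placements must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(placements$count < 0)) stopf("negative placement count")
  if (stranded) {
    if (!"strand" %in% names(placements) ||
        !all(placements$strand %in% c("+", "-"))) {
      stopf("stranded track needs strand column with +/- only")
    }
  } else if (!"strand" %in% names(placements)) {
    placements$strand <- rep("*", nrow(placements))
  }
  structure(list(library_id = library_id,
                 stranded = stranded,
                 placements = placements,
                 total_reads = sum(placements$count)),
            class = "coverage_track")
}

#' Read a 4-column bedGraph as a coverage track
#'
#' Each bedGraph interval (0-based half-open on disk) is taken as
#' \code{value} read placements on that interval.
#'
#' @param path bedGraph file.
#' @param library_id track label.
#' @param strand \code{NULL} for an unstranded track, else \code{"+"} or
#'   \code{"-"} assigning the whole file to one strand.
#' @return a \code{coverage_track}; stranded when \code{strand} is given.
#' @export
read_bedgraph <- function(path, library_id, strand = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start0", "end", "value"))
  pl <- data.frame(chrom = df$chrom, start = df$start0 + 1L, end = df$end,
                   count = df$value, stringsAsFactors = FALSE)
  if (!is.null(strand)) pl$strand <- strand
  coverage_track(pl, library_id, stranded = !is.null(strand))
}

#' Merge two single-strand tracks into one stranded track
#' @param plus,minus \code{coverage_track}s carrying \code{+} and \code{-}
#'   placements.
#' @param library_id label of the combined track.
#' @return stranded \code{coverage_track}.
#' @export
combine_strand_tracks <- function(plus, minus, library_id) {
  coverage_track(rbind(plus$placements, minus$placements), library_id,
                 stranded = TRUE)
}

#' Aggregate a coverage track onto the bin grid
#'
#' Assigns every placement to the bin holding its 5'-most base and sums
#' multiplicities. Stranded tracks fill one array per strand.
#'
#' @param grid a \code{bin_grid}.
#' @param track a \code{coverage_track}.
#' @return the grid with \code{counts[[library_id]]} filled: list with
#'   \code{stranded}, \code{total_reads} and either \code{counts} (numeric
#'   vector) or \code{counts$`+`}/\code{counts$`-`}.
#' @export
aggregate_counts <- function(grid, track) {
  stopifnot(inherits(grid, "bin_grid"), inherits(track, "coverage_track"))
  pl <- track$placements
  unknown <- setdiff(unique(pl$chrom), names(grid$chrom_sizes))
  if (length(unknown)) {
    stopf("track chromosomes not in grid: %s", paste(unknown, collapse = ", "))
  }
  pos5 <- ifelse(pl$strand == "-", pl$end, pl$start)
  if (any(pos5 < 1L | pos5 > grid$chrom_sizes[pl$chrom])) {
    stopf("placement outside chromosome bounds")
  }
  idx <- bin_index(grid, pl$chrom, pos5)
  nb <- n_bins(grid)
  sum_to <- function(i, w) {
    v <- numeric(nb)
    if (length(i)) {
      t <- tapply(w, i, sum)
      v[as.integer(names(t))] <- as.numeric(t)
    }
    v
  }
  entry <- list(stranded = track$stranded, total_reads = track$total_reads)
  if (track$stranded) {
    p <- pl$strand == "+"
    entry$counts <- list("+" = sum_to(idx[p], pl$count[p]),
                         "-" = sum_to(idx[!p], pl$count[!p]))
  } else {
    entry$counts <- sum_to(idx, pl$count)
  }
  grid$counts[[track$library_id]] <- entry
  grid
}

# fetch one per-bin count vector; strand NULL for unstranded libraries
grid_counts <- function(grid, library_id, strand = NULL) {
  e <- grid$counts[[library_id]]
  if (is.null(e)) stopf("no counts for library '%s'", library_id)
  if (e$stranded) {
    if (is.null(strand)) stopf("library '%s' is stranded; give strand", library_id)
    e$counts[[strand]]
  } else {
    if (!is.null(strand)) stopf("library '%s' is unstranded", library_id)
    e$counts
  }
}

grid_total <- function(grid, library_id) grid$counts[[library_id]]$total_reads

# like grid_counts, but the strand argument is applied only when the library
# is actually stranded (covariate pairs may mix stranded RNA with unstranded
# ChIP tracks)
lib_counts <- function(grid, library_id, strand = NULL) {
  e <- grid$counts[[library_id]]
  if (is.null(e)) stopf("no counts for library '%s'", library_id)
  grid_counts(grid, library_id, if (e$stranded) strand else NULL)
}

#' Normalize counts between libraries and by feature length
#'
#' Counts are scaled to counts-per-million of the library total and divided
#' by the feature length in kilobases, so values are comparable across
#' libraries and across features of different length.
#'
#' @param counts per-feature read counts.
#' @param total library total read count (> 0).
#' @param length_bp per-feature length in bp (> 0).
#' @param scale library-size scale constant (default 1e6).
#' @return normalized values, \code{(counts/total) * scale / (length_bp/1000)}.
#' @examples
#' normalize_counts(100, 1e6, 1000)  # 100
#' @export
normalize_counts <- function(counts, total, length_bp, scale = 1e6) {
  if (any(total <= 0)) stopf("library total must be > 0")
  if (any(length_bp <= 0)) stopf("feature length must be > 0")
  (counts / total) * scale / (length_bp / 1000)
}

#' Write intervals as BED6
#'
#' Converts from the package's 1-based inclusive coordinates to BED's
#' 0-based half-open convention.
#'
#' @param df data.frame with chrom, start, end and optionally name, score,
#'   strand columns.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_bed6 <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else
    if ("unit_id" %in% names(df)) df$unit_id else
      if ("gene_id" %in% names(df)) df$gene_id else "."
  score <- if ("score" %in% names(df)) df$score else
    if ("mean_logodds" %in% names(df)) round(df$mean_logodds, 4) else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  out <- data.frame(df$chrom, df$start - 1L, df$end, name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
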