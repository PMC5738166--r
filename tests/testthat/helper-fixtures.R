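# shared fixtures, built in code

# three genes on two chromosomes; g1 has one intron
make_genes <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chrA", "chrA", "chrB"),
    start = c(1001L, 5001L, 2001L),
    end = c(2000L, 6000L, 3000L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3"),
    start = c(1001L, 1501L, 5001L, 2001L),
    end = c(1300L, 2000L, 6000L, 3000L),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

# a bin grid with count vectors injected directly (no track aggregation);
# each entry of `libs` is a numeric vector (unstranded) or list(`+`,`-`)
manual_grid <- function(chrom_sizes, width = 50L, libs = list()) {
  g <- build_bin_grid(chrom_sizes, width)
  nb <- nrow(g$bins)
  for (nm in names(libs)) {
    v <- libs[[nm]]
    if (is.list(v)) {
      stopifnot(length(v[["+"]]) == nb, length(v[["-"]]) == nb)
      g$counts[[nm]] <- list(stranded = TRUE,
                             total_reads = sum(unlist(v)),
                             counts = v)
    } else {
      stopifnot(length(v) == nb)
      g$counts[[nm]] <- list(stranded = FALSE, total_reads = sum(v),
                             counts = v)
    }
  }
  g
}

# scaled-down simulation for module tests; any default may be overridden
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, chrom_length = 150000, n_coding = 24,
         n_linc = 6, n_antisense = 6, n_antisense_only = 2),
    list(...))
  do.call(sim_config, args)
}

# dummy interval rows for count-fixture arithmetic
dummy_features <- function(n, chrom = "chr1", len = 500L, gap = 1000L,
                           prefix = "f") {
  if (n == 0L) {
    return(data.frame(unit_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- seq(1L, by = len + gap, length.out = n)
  data.frame(unit_id = sprintf("%s%05d", prefix, seq_len(n)),
             chrom = chrom, start = start, end = start + len - 1L,
             stringsAsFactors = FALSE)
}
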