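mk_units <- function(rows) {
  if (is.null(rows)) {
    return(data.frame(unit_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_bins = integer(),
                      mean_logodds = numeric(), raw_ssrna = numeric(),
                      norm_ssrna = numeric(), stringsAsFactors = FALSE))
  }
  rows$n_bins <- (rows$end - rows$start + 1L) %/% 50L
  rows$mean_logodds <- 2
  if (is.null(rows$raw_ssrna)) rows$raw_ssrna <- 100
  if (is.null(rows$norm_ssrna)) rows$norm_ssrna <- 10
  rows$unit_id <- sprintf("u%03d", seq_len(nrow(rows)))
  rows
}

one_gene <- function(strand = "+") {
  gene_models(data.frame(gene_id = "g1", chrom = "c", start = 1001L,
                         end = 3000L, strand = strand,
                         stringsAsFactors = FALSE))
}

test_that("sense/antisense pairing requires an expressed sense partner", {
  genes <- one_gene("+")
  sense <- mk_units(data.frame(chrom = "c", start = 1001L, end = 2500L,
                               strand = "+", stringsAsFactors = FALSE))
  anti <- mk_units(data.frame(chrom = "c", start = 2201L, end = 2500L,
                              strand = "-", stringsAsFactors = FALSE))
  calls <- pair_sense_antisense(list("+" = sense, "-" = anti), genes,
                                rna_lib = "ssrna")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gene_id, "g1")
  expect_equal(calls$strand, "-")

  # sense below cutoff (no sense unit): no pair
  none <- pair_sense_antisense(list("+" = mk_units(NULL), "-" = anti),
                               genes, rna_lib = "ssrna")
  expect_equal(nrow(none), 0L)

  # two antisense fragments over one gene merge into a single call
  anti2 <- mk_units(data.frame(chrom = "c", start = c(1201L, 2201L),
                               end = c(1400L, 2500L), strand = "-",
                               stringsAsFactors = FALSE))
  merged <- pair_sense_antisense(list("+" = sense, "-" = anti2), genes,
                                 rna_lib = "ssrna")
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_fragments, 2L)
  expect_equal(c(merged$start, merged$end), c(1201L, 2500L))
})

test_that("neighbor-distance filter removes signal explainable by another gene", {
  genes <- gene_models(data.frame(
    gene_id = c("g1", "near", "far"),
    chrom = "c",
    start = c(1001L, 3201L, 20001L),
    end = c(3000L, 4000L, 21000L),
    strand = c("+", "-", "-"),
    stringsAsFactors = FALSE))
  call <- data.frame(gene_id = "g1", chrom = "c", start = 2501L, end = 3000L,
                     strand = "-", gene_start = 1001L, gene_end = 3000L,
                     gene_strand = "+", n_fragments = 1L,
                     antisense_level = 5, sense_level = 8,
                     stringsAsFactors = FALSE)
  # "near" is on the antisense strand 200 bp away -> removed
  expect_equal(nrow(filter_by_neighbor_distance(call, genes, 500)), 0L)
  # with the neighbor 2 kb away the call survives
  genes2 <- gene_models(data.frame(
    gene_id = c("g1", "far"), chrom = "c",
    start = c(1001L, 5001L), end = c(3000L, 6000L),
    strand = c("+", "-"), stringsAsFactors = FALSE))
  expect_equal(nrow(filter_by_neighbor_distance(call, genes2, 500)), 1L)
  # overlapping convergent gene -> removed
  genes3 <- gene_models(data.frame(
    gene_id = c("g1", "conv"), chrom = "c",
    start = c(1001L, 2800L), end = c(3000L, 3800L),
    strand = c("+", "-"), stringsAsFactors = FALSE))
  expect_equal(nrow(filter_by_neighbor_distance(call, genes3, 500)), 0L)
  # neighbors on the sense strand do not trigger the filter
  genes4 <- gene_models(data.frame(
    gene_id = c("g1", "same"), chrom = "c",
    start = c(1001L, 3201L), end = c(3000L, 4000L),
    strand = c("+", "+"), stringsAsFactors = FALSE))
  expect_equal(nrow(filter_by_neighbor_distance(call, genes4, 500)), 1L)
})

test_that("antisense-only genes need sense < 1 and antisense > 1 in every dataset", {
  genes <- gene_models(data.frame(
    gene_id = c("a", "b", "c"), chrom = "c",
    start = c(1L, 10001L, 20001L), end = c(5000L, 15000L, 25000L),
    strand = "+", stringsAsFactors = FALSE))
  # gene length 5000 -> 100 bins; avg = counts / 100
  gc <- rbind(
    data.frame(gene_id = "a", dataset = "d1", sense = 40, antisense = 310),
    data.frame(gene_id = "a", dataset = "d2", sense = 40, antisense = 310),
    data.frame(gene_id = "b", dataset = "d1", sense = 40, antisense = 310),
    data.frame(gene_id = "b", dataset = "d2", sense = 150, antisense = 310),
    data.frame(gene_id = "c", dataset = "d1", sense = 40, antisense = 50),
    data.frame(gene_id = "c", dataset = "d2", sense = 40, antisense = 50))
  out <- detect_antisense_only(gc, genes)
  expect_equal(out$gene_id, "a")
  expect_equal(out$sense_avg, 0.4)
  expect_equal(out$antisense_avg, 3.1)

  # a passing gene overlapping another gene is removed
  genes_ov <- gene_models(data.frame(
    gene_id = c("a", "ov"), chrom = "c",
    start = c(1L, 4001L), end = c(5000L, 9000L),
    strand = c("+", "-"), stringsAsFactors = FALSE))
  expect_equal(nrow(detect_antisense_only(gc[gc$gene_id == "a", ], genes_ov)),
               0L)
})

test_that("antisense summary adds paired and antisense-only sets", {
  paired <- dummy_features(826, len = 251L, prefix = "as")
  paired$gene_id <- paste0("g", seq_len(826))
  paired$sense_level <- runif(826)
  paired$antisense_level <- runif(826)
  only <- data.frame(gene_id = paste0("o", 1:230), stringsAsFactors = FALSE)
  s <- antisense_summary(paired, only)
  expect_equal(s$n_total, 1056L)
  expect_equal(s$median_antisense_length, 251)
  empty <- antisense_summary(paired[0, ], only[0, , drop = FALSE])
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$median_antisense_length))
})

test_that("antisense 5' offsets are signed in sense orientation", {
  call <- function(s, e, gs) data.frame(
    gene_id = "g", chrom = "c", start = s, end = e,
    strand = ifelse(gs == "+", "-", "+"),
    gene_start = 1000L, gene_end = 2000L, gene_strand = gs,
    stringsAsFactors = FALSE)
  # + gene: antisense 5' is the higher coordinate; TTS = gene end
  o <- tss_offset_profile(call(1800L, 2000L, "+"))
  expect_equal(o$offset_tts, 0)
  expect_equal(o$offset_tss, 1000)
  # antisense ending downstream of the TTS -> positive offset
  o2 <- tss_offset_profile(call(1900L, 2100L, "+"))
  expect_equal(o2$offset_tts, 100)
  # - gene: antisense 5' is the lower coordinate; TTS = gene start
  o3 <- tss_offset_profile(call(1000L, 1400L, "-"))
  expect_equal(o3$offset_tts, 0)
  expect_equal(o3$offset_tss, 1000)
  # downstream for a minus gene means smaller coordinate
  o4 <- tss_offset_profile(call(900L, 1300L, "-"))
  expect_equal(o4$offset_tts, 100)
})

test_that("per-strand calls respect the read floor and mirror under strand swap", {
  cfg <- tiny_config()
  sim <- simulate_genome(cfg, seed = 5)
  grid <- simulate_coverage(sim, seed = 5)
  st <- call_stranded_units(grid, sim$genes, rna_lib = "ssrna_dark", seed = 5)
  expect_true(nrow(st[["+"]]) > 0 && nrow(st[["-"]]) > 0)
  # every member bin of every unit carries >= 10 raw reads
  for (s in c("+", "-")) {
    cnt <- grid_counts(grid, "ssrna_dark", s)
    u <- st[[s]]
    for (i in seq_len(nrow(u))) {
      idx <- which(grid$bins$chrom == u$chrom[i] &
                     grid$bins$start >= u$start[i] &
                     grid$bins$end <= u$end[i])
      expect_true(all(cnt[idx] >= 10))
    }
  }
  expect_error(call_stranded_units(grid, sim$genes, rna_lib = "rna"),
               "not stranded")

  # swapping every strand label yields mirror-identical calls
  calls <- filter_by_neighbor_distance(
    pair_sense_antisense(st, sim$genes, "ssrna_dark"), sim$genes)
  grid_sw <- grid
  for (lib in names(grid_sw$counts)) {
    e <- grid_sw$counts[[lib]]
    if (e$stranded) {
      grid_sw$counts[[lib]]$counts <- list("+" = e$counts[["-"]],
                                           "-" = e$counts[["+"]])
    }
  }
  g <- sim$genes$genes
  g$strand <- ifelse(g$strand == "+", "-", "+")
  genes_sw <- gene_models(g, sim$genes$exons)
  st_sw <- call_stranded_units(grid_sw, genes_sw, rna_lib = "ssrna_dark",
                               seed = 5)
  calls_sw <- filter_by_neighbor_distance(
    pair_sense_antisense(st_sw, genes_sw, "ssrna_dark"), genes_sw)
  o1 <- calls[order(calls$gene_id), ]
  o2 <- calls_sw[order(calls_sw$gene_id), ]
  expect_equal(o1$gene_id, o2$gene_id)
  expect_equal(o1$start, o2$start)
  expect_equal(o1$end, o2$end)
  expect_equal(o1$strand, ifelse(o2$strand == "+", "-", "+"))
})
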