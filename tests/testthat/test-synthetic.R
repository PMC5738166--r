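test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_config()
  s1 <- simulate_genome(cfg, seed = 4)
  s2 <- simulate_genome(cfg, seed = 4)
  expect_identical(s1$truth$features, s2$truth$features)
  expect_identical(s1$genes$exons, s2$genes$exons)
  g1 <- simulate_coverage(s1, seed = 4)
  g2 <- simulate_coverage(s2, seed = 4)
  expect_identical(g1$counts, g2$counts)
  expect_identical(simulate_junctions(s1, seed = 4),
                   simulate_junctions(s2, seed = 4))
  expect_identical(simulate_timecourse(s1, seed = 4),
                   simulate_timecourse(s2, seed = 4))
  s3 <- simulate_genome(cfg, seed = 5)
  expect_false(identical(s1$truth$features, s3$truth$features))
})

test_that("planted feature classes and geometry honour the config", {
  cfg <- tiny_config()
  sim <- simulate_genome(cfg, seed = 8)
  tf <- sim$truth$features
  expect_equal(sum(tf$class == "coding"), cfg$n_coding)
  expect_equal(sum(tf$class == "linc"), cfg$n_linc)
  expect_equal(sum(tf$class == "antisense"), cfg$n_antisense)
  expect_equal(sum(tf$class == "antisense_only"), cfg$n_antisense_only)
  # lincs are >= 500 bp from every gene
  lt <- tf[tf$class == "linc", ]
  g <- sim$genes$genes
  for (i in seq_len(nrow(lt))) {
    same <- g[g$chrom == lt$chrom[i], ]
    gaps <- pmax(same$start - lt$end[i], lt$start[i] - same$end, 0) - 1
    expect_true(all(gaps >= 500))
  }
  # antisense lie inside their host on the opposite strand
  at <- tf[tf$class %in% c("antisense", "antisense_only"), ]
  host <- tf[match(at$host_gene, tf$feature_id), ]
  expect_true(all(at$start >= host$start & at$end <= host$end))
  expect_true(all(at$strand != host$strand))
  # antisense-only hosts are silent; paired hosts are expressed
  expect_true(all(host$expression[at$class == "antisense_only"] == 0))
  expect_true(all(host$expression[at$class == "antisense"] > 0))
  # a config without lincs yields only the other classes
  s0 <- simulate_genome(tiny_config(n_linc = 0), seed = 8)
  expect_false("linc" %in% s0$truth$features$class)
})

test_that("planted length medians match the configured medians within 10%", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 1500000,
                    n_coding = 300, n_linc = 150, n_antisense = 60,
                    n_antisense_only = 0)
  sim <- simulate_genome(cfg, seed = 17)
  tf <- sim$truth$features
  med <- function(cl) median(tf$end[tf$class == cl] - tf$start[tf$class == cl] + 1)
  expect_equal(med("coding"), cfg$coding_len_median, tolerance = 0.1)
  expect_equal(med("linc"), cfg$linc_len_median, tolerance = 0.1)
  expect_equal(med("antisense"), cfg$as_len_median, tolerance = 0.1)
})

test_that("coverage means follow background plus planted signal", {
  # single expressed gene, no background: signal confined to the feature
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 30000, n_coding = 1,
                    n_linc = 0, n_antisense = 0, n_antisense_only = 0,
                    frac_silent = 0, background_mean = 0,
                    stranded_background_mean = 0)
  sim <- simulate_genome(cfg, seed = 2)
  tf <- sim$truth$features
  grid <- simulate_coverage(sim, seed = 2)
  rna <- grid_counts(grid, "rna")
  outside <- grid$bins$end < tf$start | grid$bins$start > tf$end
  expect_true(all(rna[outside] == 0))
  expect_true(any(rna[!outside] > 0))

  # Monte-Carlo mean of an interior bin approaches background + level
  cfg2 <- sim_config(n_chromosomes = 1, chrom_length = 30000, n_coding = 1,
                     n_linc = 0, n_antisense = 0, n_antisense_only = 0,
                     frac_silent = 0)
  sim2 <- simulate_genome(cfg2, seed = 2)
  f <- sim2$truth$features[1, ]
  bins2 <- build_bin_grid(sim2$chrom_sizes, 50)$bins
  bin_idx <- which(bins2$start >= f$start + 50 & bins2$end <= f$end - 50)[1]
  reps <- vapply(1:200, function(k) {
    grid_counts(simulate_coverage(sim2, seed = 1000 + k), "rna")[bin_idx]
  }, numeric(1))
  mu <- cfg2$background_mean + f$expression
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - mu), 4 * se + 0.5)

  # the unstranded library mean matches the sum of strand means over genes
  grid2 <- simulate_coverage(sim2, seed = 3)
  over <- build_bin_grid(sim2$chrom_sizes, 50)$bins$start >= f$start &
    build_bin_grid(sim2$chrom_sizes, 50)$bins$end <= f$end
  un <- mean(grid_counts(grid2, "rna")[over])
  st <- mean(grid_counts(grid2, "ssrna_dark", "+")[over] +
               grid_counts(grid2, "ssrna_dark", "-")[over])
  expect_equal(un, st, tolerance = 0.25)
})

test_that("polysome signal is restricted to coding features", {
  cfg <- tiny_config()
  sim <- simulate_genome(cfg, seed = 21)
  grid <- simulate_coverage(sim, seed = 21)
  tf <- sim$truth$features
  lt <- tf[tf$class == "linc", ]
  poly <- grid_counts(grid, "polysome")
  bins <- grid$bins
  over_linc <- rep(FALSE, nrow(bins))
  for (i in seq_len(nrow(lt))) {
    over_linc <- over_linc | (bins$chrom == lt$chrom[i] &
                                bins$start >= lt$start[i] &
                                bins$end <= lt$end[i])
  }
  # only the low polysome background over lincRNAs
  expect_lt(mean(poly[over_linc]), 2)
  cod <- tf[tf$class == "coding" & tf$expression > 0, ][1, ]
  over_cod <- bins$chrom == cod$chrom & bins$start >= cod$start &
    bins$end <= cod$end
  expect_gt(mean(poly[over_cod]), 5)
})

test_that("junction support reflects planted introns with sub-threshold decoys", {
  cfg <- tiny_config(intron_freq = c(coding = 0.9, linc = 0.5,
                                     antisense = 0.5))
  sim <- simulate_genome(cfg, seed = 6)
  jx <- simulate_junctions(sim, seed = 6)
  intr <- sim$truth$introns
  tf <- sim$truth$features
  expressed <- tf$feature_id[tf$expression > 0]
  n_real <- sum(intr$feature_id %in% expressed)
  expect_equal(nrow(jx), n_real + cfg$n_decoy_junctions)
  expect_true(all(jx$acceptor - jx$donor + 1 >= 50))
  # decoys sit below the annotated 25% quantile
  ann_key <- paste(intr$chrom, intr$start, intr$end)
  is_ann_coding <- intr$feature_id %in% sim$genes$genes$gene_id
  jx_key <- paste(jx$chrom, jx$donor, jx$acceptor)
  matched <- jx$reads[jx_key %in% ann_key[is_ann_coding]]
  decoys <- jx$reads[!jx_key %in% ann_key]
  expect_true(all(decoys < quantile(matched, 0.25)))
})

test_that("recovery metrics behave at the extremes", {
  truth <- data.frame(chrom = "c", start = c(100L, 1000L),
                      end = c(400L, 1500L), class = "linc",
                      stringsAsFactors = FALSE)
  perfect <- truth
  m <- recovery_metrics(perfect, truth)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$bin_recall, 1)
  none <- recovery_metrics(perfect[0, ], truth)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  shifted <- transform(truth, start = start + 2000L, end = end + 2000L)
  ms <- recovery_metrics(shifted, truth)
  expect_equal(ms$recall, 0)
  expect_equal(ms$precision, 0)
  # reciprocal rule: a call covering just over half of one truth feature
  # recovers it (151/301 > 0.5 on the truth side, 151/151 on the call side)
  half <- data.frame(chrom = "c", start = 100L, end = 250L, class = "linc",
                     stringsAsFactors = FALSE)
  mh <- recovery_metrics(half, truth)
  expect_equal(mh$recall, 0.5)
  expect_equal(mh$precision, 1)
  # a call covering less than half of the truth does not
  third <- data.frame(chrom = "c", start = 100L, end = 180L, class = "linc",
                      stringsAsFactors = FALSE)
  expect_equal(recovery_metrics(third, truth)$recall, 0)
})

test_that("infeasible packing errors with advice", {
  expect_error(simulate_genome(sim_config(n_chromosomes = 1,
                                          chrom_length = 20000,
                                          n_coding = 50), seed = 1),
               "increase chrom_length")
})
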