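test_that("bin labels mark exon overlap, matching a per-base oracle", {
  genes <- make_genes()
  grid <- build_bin_grid(c(chrA = 10000, chrB = 5000), 50)
  lab <- label_bins(grid, genes)
  # bin fully inside an exon of g1
  expect_equal(lab[bin_of <- 22], 1L)          # bin (1051,1100) in exon 1
  expect_equal(lab[1], 0L)                     # gene desert
  # per-base oracle
  exonic <- list(chrA = rep(FALSE, 10000), chrB = rep(FALSE, 5000))
  g <- genes$genes
  for (i in seq_len(nrow(genes$exons))) {
    e <- genes$exons[i, ]
    ch <- g$chrom[g$gene_id == e$gene_id]
    exonic[[ch]][e$start:e$end] <- TRUE
  }
  oracle <- unlist(lapply(names(exonic), function(ch) {
    b <- grid$bins[grid$bins$chrom == ch, ]
    vapply(seq_len(nrow(b)), function(k) {
      as.integer(any(exonic[[ch]][b$start[k]:b$end[k]]))
    }, integer(1))
  }))
  expect_equal(lab, oracle)

  # strand-restricted labels only see genes on that strand
  labp <- label_bins(grid, genes, strand = "+")
  labm <- label_bins(grid, genes, strand = "-")
  expect_equal(pmax(labp, labm), lab)          # per-strand union = unstranded
  expect_equal(sum(labm[grid$bins$chrom == "chrB"]), 0L)  # g3 is on +
})

# closed-form saturated 2x2 logistic oracle: with a binary covariate,
# beta0 = logit(p at x=0), beta1 = logit(p at x=1) - logit(p at x=0)
logit2x2 <- function(n0, k0, n1, k1) {
  c(log(k0 / (n0 - k0)), log(k1 / (n1 - k1)) - log(k0 / (n0 - k0)))
}

test_that("logistic fit reproduces the closed-form 2x2 log-odds", {
  # 1/10 positives at x=0, 9/10 at x=1; a constant second covariate is
  # aliased out by glm and reported NA
  x <- rep(c(0, 1), each = 10)
  grid <- manual_grid(c(c1 = 1000), 50,
                      libs = list(rna = x, pol = rep(1, 20)))
  labels <- c(1L, rep(0L, 9), rep(1L, 9), 0L)
  fit <- fit_transcription_model(grid, labels, transform = "identity",
                                 train_fraction = 1)
  expected <- logit2x2(10, 1, 10, 9)
  expect_equal(unname(coef(fit)[1]), expected[1], tolerance = 1e-6)
  expect_equal(unname(coef(fit)[2]), expected[2], tolerance = 1e-6)
  expect_equal(unname(coef(fit)[1]), log(1 / 9), tolerance = 1e-6)
  expect_equal(unname(coef(fit)[2]), 2 * log(9), tolerance = 1e-6)

  # random saturated designs agree with the closed form to 1e-6
  set.seed(21)
  for (rep in 1:5) {
    n0 <- sample(10:40, 1); n1 <- sample(10:40, 1)
    k0 <- sample(seq_len(n0 - 1), 1); k1 <- sample(seq_len(n1 - 1), 1)
    xr <- c(rep(0, n0), rep(1, n1))
    nb <- length(xr)
    gr <- manual_grid(c(c1 = nb * 50), 50,
                      libs = list(rna = xr, pol = rep(1, nb)))
    y <- c(rep(1L, k0), rep(0L, n0 - k0), rep(1L, k1), rep(0L, n1 - k1))
    f <- fit_transcription_model(gr, y, transform = "identity",
                                 train_fraction = 1)
    expect_equal(unname(coef(f)[1:2]), logit2x2(n0, k0, n1, k1),
                 tolerance = 1e-6)
  }
})

test_that("swapping the two covariate tracks swaps their coefficients", {
  set.seed(31)
  nb <- 2000
  a <- rpois(nb, 3); b <- rpois(nb, 5)
  y <- rbinom(nb, 1, plogis(-2 + 0.4 * a + 0.2 * b))
  g1 <- manual_grid(c(c1 = nb * 50), 50, libs = list(rna = a, pol = b))
  g2 <- manual_grid(c(c1 = nb * 50), 50, libs = list(rna = b, pol = a))
  f1 <- fit_transcription_model(g1, y, transform = "identity",
                                train_fraction = 1)
  f2 <- fit_transcription_model(g2, y, transform = "identity",
                                train_fraction = 1)
  expect_equal(unname(coef(f1)[c(1, 3, 2)]), unname(coef(f2)),
               tolerance = 1e-8)
})

test_that("coefficients vanish when labels are independent of covariates", {
  set.seed(55)
  nb <- 10000
  rna <- rnbinom(nb, mu = 4, size = 5)
  pol <- rnbinom(nb, mu = 4, size = 5)
  y <- sample(rep(c(0L, 1L), c(7000, 3000)))   # permuted: no association
  grid <- manual_grid(c(c1 = nb * 50), 50, libs = list(rna = rna, pol = pol))
  fit <- fit_transcription_model(grid, y, transform = "identity", seed = 2)
  z <- coef(fit)[2:3] / fit$se[2:3]
  expect_true(all(abs(z) < 4))
})

test_that("single-class training set errors; train_fraction validated", {
  grid <- manual_grid(c(c1 = 500), 50,
                      libs = list(rna = rep(1, 10), pol = rep(1, 10)))
  expect_error(fit_transcription_model(grid, rep(0L, 10)), "single class")
  expect_error(fit_transcription_model(grid, rep(c(0L, 1L), 5),
                                       train_fraction = 0), "train_fraction")
})

test_that("scores are the linear predictor, matching a per-bin loop", {
  expect_equal(score_bins(c(-5, 0.01, 0.01), 400, 300), 2.0)
  expect_equal(score_bins(c(-1.3, 2, 3), 0, 0), -1.3)
  set.seed(8)
  beta <- rnorm(3)
  x1 <- rnorm(100); x2 <- rnorm(100)
  loop <- vapply(1:100, function(i) beta[1] + beta[2] * x1[i] + beta[3] * x2[i],
                 numeric(1))
  expect_identical(score_bins(beta, x1, x2), loop)
})

test_that("simulated labels follow the fitted probabilities", {
  nb <- 4000
  set.seed(3)
  rna <- rnbinom(nb, mu = 6, size = 10)
  grid <- manual_grid(c(c1 = nb * 50), 50,
                      libs = list(rna = rna, pol = rep(1, nb)))
  y <- rbinom(nb, 1, plogis(-2 + 0.5 * rna))
  fit <- fit_transcription_model(grid, y, transform = "identity",
                                 train_fraction = 1)
  sims <- simulate(fit, nsim = 5, seed = 4, grid = grid)
  p <- plogis(predict(fit, grid))
  expect_equal(mean(sims), mean(p), tolerance = 0.02)
})

test_that("unit calling merges maximal super-threshold runs", {
  nb <- 10
  grid <- manual_grid(c(c1 = nb * 50), 50,
                      libs = list(rna = rep(2, nb), pol = rep(1, nb)))
  sc <- c(0, 0, 2, 2, 2, 0, 0, 2, 0, 0)
  units <- call_units(grid, sc, cutoff = 1.5)
  expect_equal(nrow(units), 2L)
  expect_equal(units$start, c(101L, 351L))
  expect_equal(units$end, c(250L, 400L))
  expect_equal(units$n_bins, c(3L, 1L))
  expect_equal(nrow(call_units(grid, rep(0, nb))), 0L)
  # ties at the cutoff are sub-threshold
  expect_equal(nrow(call_units(grid, rep(1.5, nb), cutoff = 1.5)), 0L)
})

test_that("units partition the super-threshold bins and shrink with the cutoff", {
  set.seed(12)
  sizes <- c(cA = 5000, cB = 3000)
  grid <- manual_grid(sizes, 50, libs = list(
    rna = rpois(160, 4), pol = rpois(160, 2)))
  sc <- rnorm(160, 0, 2)
  units <- call_units(grid, sc, cutoff = 1)
  # partition: every super-threshold bin in exactly one unit
  covered <- rep(0L, 160)
  for (i in seq_len(nrow(units))) {
    idx <- which(grid$bins$chrom == units$chrom[i] &
                   grid$bins$start >= units$start[i] &
                   grid$bins$end <= units$end[i])
    covered[idx] <- covered[idx] + 1L
  }
  expect_true(all(covered[sc > 1] == 1L))
  expect_true(all(covered[sc <= 1] == 0L))
  # sorted and disjoint within chromosome
  for (ch in unique(units$chrom)) {
    u <- units[units$chrom == ch, ]
    if (nrow(u) > 1) expect_true(all(u$start[-1] > u$end[-nrow(u)]))
  }
  # monotonicity: raising the cutoff never increases covered bases
  widths <- vapply(c(-1, 0, 0.5, 1, 2, 3), function(ct) {
    u <- call_units(grid, sc, cutoff = ct)
    sum(u$end - u$start + 1)
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
  # unit counts equal the sum over member bins, length-normalized
  u1 <- units[1, ]
  idx <- which(grid$bins$chrom == u1$chrom & grid$bins$start >= u1$start &
                 grid$bins$end <= u1$end)
  raw <- sum(grid_counts(grid, "rna")[idx])
  expect_equal(u1$raw_rna, raw)
  expect_equal(u1$norm_rna,
               normalize_counts(raw, grid_total(grid, "rna"),
                                u1$end - u1$start + 1))
})

test_that("minimum read filter gates bin eligibility", {
  nb <- 6
  grid <- manual_grid(c(c1 = nb * 50), 50, libs = list(
    ss = list("+" = c(15, 8, 15, 15, 0, 0), "-" = rep(0, nb))))
  sc <- c(2, 2, 2, 2, 2, 0)
  units <- call_units(grid, sc, cutoff = 1.5, strand = "+",
                      min_reads = 10, min_reads_lib = "ss")
  # bin 2 (8 reads) breaks the run despite its score
  expect_equal(nrow(units), 2L)
  expect_equal(units$n_bins, c(1L, 2L))
  expect_error(call_units(grid, sc, min_reads = 10), "min_reads_lib")
})
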