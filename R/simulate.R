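#' Configuration of the synthetic genome and coverage generator
#'
#' Defaults describe a compact fungal-style test genome sequenced deeply, as
#' pooled libraries are: a ~2 Mb, 4-chromosome genome carrying 200
#' multi-exon coding genes (length median 1782 bp, 80\% intron-containing,
#' intron length median 69 bp), 40 planted intergenic noncoding transcripts
#' (median 551 bp, rarely spliced) and 30 planted antisense transcripts
#' (median 251 bp) whose 5' starts are biased toward the 3' ends of their
#' sense genes, plus hosts that express only an antisense RNA. Counts are
#' drawn per 50 bp bin from a negative binomial around the planted means;
#' polysome signal is restricted to coding features. Coding expression spans
#' orders of magnitude (lognormal, sdlog 1), which anchors the logistic
#' classifier's decision boundary near the detection floor; planted
#' noncoding features spread broadly above a floor that keeps every one of
#' them separable from background (see the package vignette for the
#' calibration rationale). Strand-specific libraries carry a lower
#' per-strand background than the pooled unstranded ones, as directional
#' protocols do.
#'
#' @param n_chromosomes,chrom_length genome shape (bp per chromosome).
#' @param n_coding,n_linc,n_antisense,n_antisense_only feature counts;
#'   antisense-only hosts are coding genes with silenced sense expression.
#' @param frac_silent fraction of additional coding genes left unexpressed.
#' @param coding_len_median,linc_len_median,as_len_median,len_sdlog length
#'   distributions (lognormal, bp).
#' @param coding_expr_median,linc_expr_median,as_expr_median expression
#'   levels: mean reads per fully covered 50 bp bin (lognormal medians).
#' @param coding_expr_sdlog,nc_expr_sdlog lognormal spread of expression for
#'   coding and noncoding features.
#' @param nc_expr_min,as_expr_min lower truncation of noncoding expression;
#'   the antisense floor is slightly higher because a 5-bin feature
#'   tolerates no fragmentation at 50 bp resolution.
#' @param background_mean,stranded_background_mean background mean reads
#'   per bin for unstranded tracks and per strand for stranded tracks.
#' @param nb_size negative-binomial dispersion (size) of all count draws;
#'   bin-level dispersion is mild because feature-to-feature variability is
#'   modeled separately by the expression distributions.
#' @param pol_factor,polysome_factor track means as multiples of feature
#'   expression (RNAPII over all transcribed features; polysome over coding
#'   only).
#' @param intron_freq named vector of per-class intron probabilities.
#' @param intron_len_median,intron_len_sdlog intron length distribution.
#' @param as_tss_sd jitter (bp, normal) of the antisense 5' start around
#'   the sense TTS.
#' @param frac_induced fraction of linc and antisense features induced by
#'   light; \code{frac_sense_coinduced} fraction of induced antisense whose
#'   sense partner is also induced; \code{frac_early} induced features
#'   peaking at 30 min.
#' @param induced_fold_range uniform range of planted fold changes.
#' @param n_decoy_junctions unannotated low-support junctions added to the
#'   junction file.
#' @param bin_width bin width used by the coverage tracks.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_chromosomes = 4, chrom_length = 500000,
                       n_coding = 200, n_linc = 40, n_antisense = 30,
                       n_antisense_only = 10, frac_silent = 0.05,
                       coding_len_median = 1782, linc_len_median = 551,
                       as_len_median = 251, len_sdlog = 0.4,
                       coding_expr_median = 60, linc_expr_median = 50,
                       as_expr_median = 60, as_expr_min = 50,
                       coding_expr_sdlog = 1.0,
                       nc_expr_sdlog = 0.6, nc_expr_min = 40,
                       background_mean = 0.5, stranded_background_mean = 0.25,
                       nb_size = 50, pol_factor = 0.5, polysome_factor = 0.8,
                       intron_freq = c(coding = 0.8, linc = 0.016,
                                       antisense = 0.025),
                       intron_len_median = 69, intron_len_sdlog = 0.25,
                       as_tss_sd = 100,
                       frac_induced = 0.3, frac_sense_coinduced = 0.35,
                       frac_early = 0.58,
                       induced_fold_range = c(3, 8),
                       n_decoy_junctions = 30,
                       bin_width = 50) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length >= 10000,
            all(unlist(cfg[grep("^n_", names(cfg))]) >= 0),
            cfg$nb_size > 0, all(cfg$intron_freq >= 0 & cfg$intron_freq <= 1))
  class(cfg) <- "sim_config"
  cfg
}

rlnorm_median <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# lognormal truncated below: noncoding expression has a broad spread (so its
# per-bin density never dominates the coding mixture anywhere) but a hard
# floor keeping every planted feature detectable
rlnorm_trunc <- function(n, median, sdlog, lower) {
  p0 <- stats::plnorm(lower, meanlog = log(median), sdlog = sdlog)
  u <- stats::runif(n, p0, 1)
  stats::qlnorm(u, meanlog = log(median), sdlog = sdlog)
}

# split feature counts across chromosomes as evenly as possible
split_counts <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

#' Simulate a genome with planted truth
#'
#' Places coding genes and intergenic noncoding features along each
#' chromosome with at least 600 bp between neighboring features (so the
#' 500 bp intergenic rule is unambiguous), gives coding genes exon/intron
#' structure, plants antisense transcripts inside host genes with their 5'
#' starts jittered around the sense TTS, and assigns expression levels,
#' light-induction flags and peak times.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; the same seed reproduces the genome exactly.
#' @return list of class \code{sim_genome}: \code{genes} (a
#'   \code{gene_models} of the coding annotation), \code{chrom_sizes},
#'   \code{truth} (list with \code{features} and \code{introns}
#'   data.frames) and the echoed \code{config}.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                                 chroms)
  ncod <- split_counts(cfg$n_coding, cfg$n_chromosomes)
  nlin <- split_counts(cfg$n_linc, cfg$n_chromosomes)
  feats <- list(); k <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    n_items <- ncod[ci] + nlin[ci]
    cls <- sample(c(rep("coding", ncod[ci]), rep("linc", nlin[ci])))
    lens <- ifelse(cls == "coding",
                   pmax(300, round(rlnorm_median(n_items, cfg$coding_len_median,
                                                 cfg$len_sdlog))),
                   pmax(200, round(rlnorm_median(n_items, cfg$linc_len_median,
                                                 cfg$len_sdlog))))
    gaps <- round(stats::runif(n_items, 600, 2500))
    if (sum(lens) + sum(gaps) > cfg$chrom_length) {
      stopf("features do not fit on %s; increase chrom_length", chroms[ci])
    }
    cursor <- 1L
    for (j in seq_len(n_items)) {
      cursor <- cursor + gaps[j]
      k <- k + 1L
      feats[[k]] <- data.frame(
        feature_id = NA_character_, class = cls[j], chrom = chroms[ci],
        start = cursor, end = cursor + lens[j] - 1L,
        strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE)
      cursor <- cursor + lens[j]
    }
  }
  features <- do.call(rbind, feats)
  ic <- features$class == "coding"
  features$feature_id[ic] <- sprintf("G%04d", seq_len(sum(ic)))
  features$feature_id[!ic] <- sprintf("L%04d", seq_len(sum(!ic)))

  # expression levels; silenced genes include the antisense-only hosts
  features$expression <- NA_real_
  features$expression[ic] <- rlnorm_median(sum(ic), cfg$coding_expr_median,
                                           cfg$coding_expr_sdlog)
  features$expression[!ic] <- rlnorm_trunc(sum(!ic), cfg$linc_expr_median,
                                           cfg$nc_expr_sdlog, cfg$nc_expr_min)
  gene_ids <- features$feature_id[ic]
  n_sil <- round(cfg$frac_silent * length(gene_ids))
  silent <- sample(gene_ids, min(length(gene_ids),
                                 n_sil + cfg$n_antisense_only))
  ao_hosts <- silent[seq_len(min(cfg$n_antisense_only, length(silent)))]
  features$expression[features$feature_id %in% silent] <- 0

  # antisense transcripts: hosts inside expressed genes; 5' start near TTS
  # paired antisense is only defined over expressed sense partners, so hosts
  # are drawn from genes clearly above the stranded detection floor
  host_pool <- setdiff(gene_ids[features$expression[ic] >= 50], silent)
  hosts <- c(sample(host_pool, min(cfg$n_antisense, length(host_pool))),
             ao_hosts)
  as_rows <- lapply(seq_along(hosts), function(i) {
    g <- features[features$feature_id == hosts[i], ]
    len <- max(150, round(rlnorm_median(1, cfg$as_len_median,
                                        cfg$len_sdlog * 0.75)))
    len <- min(len, g$end - g$start + 1L)
    jit <- round(stats::rnorm(1, 0, cfg$as_tss_sd))
    if (g$strand == "+") {           # antisense on -, 5' = higher coordinate
      a5 <- min(g$end + jit, g$end)
      a5 <- max(a5, g$start + len - 1L)
      st <- a5 - len + 1L; en <- a5; s <- "-"
    } else {                          # antisense on +, 5' = lower coordinate
      a5 <- max(g$start - jit, g$start)
      a5 <- min(a5, g$end - len + 1L)
      st <- a5; en <- a5 + len - 1L; s <- "+"
    }
    data.frame(feature_id = sprintf("AS%04d", i),
               class = if (hosts[i] %in% ao_hosts) "antisense_only"
                       else "antisense",
               chrom = g$chrom, start = st, end = en, strand = s,
               expression = rlnorm_trunc(1, cfg$as_expr_median,
                                         cfg$nc_expr_sdlog, cfg$as_expr_min),
               stringsAsFactors = FALSE)
  })
  features$host_gene <- NA_character_
  if (length(hosts)) {
    as_df <- do.call(rbind, as_rows)
    as_df$host_gene <- hosts
    features <- rbind(features, as_df[, names(features)])
  }

  # light induction
  nc_idx <- which(features$class %in% c("linc", "antisense", "antisense_only"))
  features$induced <- FALSE
  features$peak_time <- NA_real_
  features$fold <- NA_real_
  ind <- nc_idx[stats::runif(length(nc_idx)) < cfg$frac_induced]
  features$induced[ind] <- TRUE
  features$peak_time[ind] <- ifelse(stats::runif(length(ind)) < cfg$frac_early,
                                    30, sample(c(60, 120), length(ind),
                                               replace = TRUE))
  features$fold[ind] <- stats::runif(length(ind), cfg$induced_fold_range[1],
                                     cfg$induced_fold_range[2])
  # co-induced sense partners of induced antisense
  as_ind <- features$feature_id[features$induced &
                                  features$class %in% c("antisense",
                                                        "antisense_only")]
  hosts_ind <- features$host_gene[match(as_ind, features$feature_id)]
  co <- hosts_ind[stats::runif(length(hosts_ind)) < cfg$frac_sense_coinduced]
  gi <- match(co, features$feature_id)
  gi <- gi[features$expression[gi] > 0]
  features$induced[gi] <- TRUE
  features$peak_time[gi] <- 30
  features$fold[gi] <- stats::runif(length(gi), cfg$induced_fold_range[1],
                                    cfg$induced_fold_range[2])

  # intron structure
  introns <- list(); exons <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    p <- cfg$intron_freq[[switch(f$class, coding = "coding",
                                 linc = "linc", "antisense")]]
    len <- f$end - f$start + 1L
    n_int <- 0L
    if (stats::runif(1) < p) n_int <- sample(1:2, 1L, prob = c(0.7, 0.3))
    ilens <- round(rlnorm_median(n_int, cfg$intron_len_median,
                                 cfg$intron_len_sdlog))
    ilens <- pmax(50L, pmin(ilens, len %/% 4L))
    if (n_int > 0 && len - sum(ilens) < 50L * (n_int + 1L)) n_int <- 0L
    if (n_int == 0L) {
      if (f$class == "coding") {
        exons[[length(exons) + 1L]] <-
          data.frame(gene_id = f$feature_id, start = f$start, end = f$end,
                     stringsAsFactors = FALSE)
      }
      next
    }
    exonic <- len - sum(ilens)
    cut_pool <- seq(50L, exonic - 50L)
    cuts <- sort(cut_pool[sample.int(length(cut_pool), n_int)])
    ex_st <- f$start; pieces <- diff(c(0L, cuts, exonic))
    ex <- data.frame(gene_id = f$feature_id, start = integer(n_int + 1L),
                     end = integer(n_int + 1L), stringsAsFactors = FALSE)
    intr <- data.frame(feature_id = f$feature_id, chrom = f$chrom,
                       start = integer(n_int), end = integer(n_int),
                       strand = f$strand, stringsAsFactors = FALSE)
    for (q in seq_len(n_int + 1L)) {
      ex$start[q] <- ex_st
      ex$end[q] <- ex_st + pieces[q] - 1L
      ex_st <- ex$end[q] + 1L
      if (q <= n_int) {
        intr$start[q] <- ex_st
        intr$end[q] <- ex_st + ilens[q] - 1L
        ex_st <- intr$end[q] + 1L
      }
    }
    introns[[length(introns) + 1L]] <- intr
    if (f$class == "coding") exons[[length(exons) + 1L]] <- ex
  }
  exons <- do.call(rbind, exons)
  introns <- if (length(introns)) do.call(rbind, introns) else
    data.frame(feature_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  rownames(features) <- rownames(introns) <- NULL

  gtab <- features[features$class == "coding",
                   c("feature_id", "chrom", "start", "end", "strand")]
  names(gtab)[1] <- "gene_id"
  rownames(gtab) <- NULL
  structure(list(genes = gene_models(gtab, exons),
                 chrom_sizes = chrom_sizes,
                 truth = list(features = features, introns = introns),
                 config = cfg),
            class = "sim_genome")
}

#' Write gene models as GFF3
#' @param genes a \code{gene_models}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_gff3 <- function(genes, path) {
  g <- genes$genes
  ex <- genes$exons
  ex$chrom <- g$chrom[match(ex$gene_id, g$gene_id)]
  ex$strand <- g$strand[match(ex$gene_id, g$gene_id)]
  lines <- c("##gff-version 3",
             sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, g$start, g$end, g$strand, g$gene_id),
             sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                     ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id))
  writeLines(lines, path)
  invisible(path)
}

# per-bin expected signal of a feature set on one chromosome's bins
add_feature_means <- function(mu, bins, feats, weight = 1) {
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    if (f$expression <= 0) next
    idx <- which(bins$chrom == f$chrom & bins$end >= f$start &
                   bins$start <= f$end)
    if (!length(idx)) next
    ov <- pmin(bins$end[idx], f$end) - pmax(bins$start[idx], f$start) + 1L
    mu[idx] <- mu[idx] + weight * f$expression * ov /
      (bins$end[idx] - bins$start[idx] + 1L)
  }
  mu
}

nb_draw <- function(mu, size) stats::rnbinom(length(mu), mu = mu, size = size)

#' Simulate coverage tracks onto a bin grid
#'
#' Generates the five library types of the pipeline, per bin, as negative
#' binomial draws around background-plus-signal means: pooled unstranded
#' RNA-seq (\code{rna}; all transcribed features), RNAPII ChIP-seq
#' (\code{pol}; correlated with expression), polysome RNA-seq
#' (\code{polysome}; coding features only), and two strand-specific
#' RNA-seq datasets (\code{ssrna_dark}, \code{ssrna_light}; induced
#' features scaled by their planted fold in the light track).
#'
#' @param sim a \code{sim_genome}.
#' @param seed RNG seed.
#' @return a \code{bin_grid} with all five libraries aggregated.
#' @export
simulate_coverage <- function(sim, seed = 1L) {
  stopifnot(inherits(sim, "sim_genome"))
  cfg <- sim$config
  grid <- build_bin_grid(sim$chrom_sizes, cfg$bin_width)
  bins <- grid$bins
  tf <- sim$truth$features
  with_seed(seed + 1000L, {
    zero <- numeric(nrow(bins))
    mu_sig <- add_feature_means(zero, bins, tf)
    mu_cod <- add_feature_means(zero, bins, tf[tf$class == "coding", ])
    tracks <- list()
    tracks$rna <- nb_draw(cfg$background_mean + mu_sig, cfg$nb_size)
    tracks$pol <- nb_draw(cfg$background_mean +
                            cfg$pol_factor * mu_sig, cfg$nb_size)
    tracks$polysome <- nb_draw(0.2 + cfg$polysome_factor * mu_cod,
                               cfg$nb_size)
    light_scale <- ifelse(tf$induced, tf$fold, 1)
    for (ds in c("ssrna_dark", "ssrna_light")) {
      tfs <- tf
      if (ds == "ssrna_light") tfs$expression <- tfs$expression * light_scale
      mu_p <- add_feature_means(zero, bins, tfs[tfs$strand == "+", ])
      mu_m <- add_feature_means(zero, bins, tfs[tfs$strand == "-", ])
      tracks[[ds]] <- list(
        "+" = nb_draw(cfg$stranded_background_mean + mu_p, cfg$nb_size),
        "-" = nb_draw(cfg$stranded_background_mean + mu_m, cfg$nb_size))
    }
  })
  for (lib in names(tracks)) {
    tr <- tracks[[lib]]
    if (is.list(tr)) {
      pl <- rbind(
        data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   count = tr[["+"]], strand = "+", stringsAsFactors = FALSE),
        data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   count = tr[["-"]], strand = "-", stringsAsFactors = FALSE))
      pl <- pl[pl$count > 0, , drop = FALSE]
      grid <- aggregate_counts(grid, coverage_track(pl, lib, stranded = TRUE))
    } else {
      pl <- data.frame(chrom = bins$chrom, start = bins$start,
                       end = bins$end, count = tr, stringsAsFactors = FALSE)
      pl <- pl[pl$count > 0, , drop = FALSE]
      grid <- aggregate_counts(grid, coverage_track(pl, lib))
    }
  }
  grid
}

#' Simulate a splice-junction file
#'
#' One junction per planted intron of an expressed feature, with read
#' support drawn around the feature's expression level, plus unannotated
#' decoy junctions whose support is below the 25\% quantile of the
#' annotated-matching junction supports by construction.
#'
#' @param sim a \code{sim_genome}.
#' @param seed RNG seed.
#' @return junction data.frame (chrom, donor, acceptor, strand, reads).
#' @export
simulate_junctions <- function(sim, seed = 1L) {
  cfg <- sim$config
  tf <- sim$truth$features
  intr <- sim$truth$introns
  with_seed(seed + 2000L, {
    expr <- tf$expression[match(intr$feature_id, tf$feature_id)]
    keep <- expr > 0
    intr <- intr[keep, , drop = FALSE]
    expr <- expr[keep]
    reads <- pmax(1, stats::rnbinom(nrow(intr), mu = expr, size = cfg$nb_size))
    jx <- data.frame(chrom = intr$chrom, donor = intr$start,
                     acceptor = intr$end, strand = intr$strand,
                     reads = reads, stringsAsFactors = FALSE)
    n_dec <- cfg$n_decoy_junctions
    if (n_dec > 0 && nrow(jx) > 0) {
      ann <- intr$feature_id %in% sim$genes$genes$gene_id
      q25 <- stats::quantile(jx$reads[ann], 0.25, type = 7)
      cap <- max(1, ceiling(q25) - 1)
      chroms <- sample(names(sim$chrom_sizes), n_dec, replace = TRUE)
      donor <- round(stats::runif(n_dec, 1000,
                                  sim$chrom_sizes[chroms] - 1000))
      dlen <- pmax(50, round(rlnorm_median(n_dec, 100, 0.3)))
      dec <- data.frame(chrom = chroms, donor = donor,
                        acceptor = donor + dlen - 1L,
                        strand = sample(c("+", "-"), n_dec, replace = TRUE),
                        reads = sample.int(cap, n_dec, replace = TRUE),
                        stringsAsFactors = FALSE)
      jx <- rbind(jx, dec)
    }
    rownames(jx) <- NULL
    jx
  })
}

#' Simulate light-induction time courses
#'
#' Two replicate datasets of normalized expression at 0, 30, 60 and 120
#' minutes for every planted noncoding feature and every expressed coding
#' gene. Induced features rise to \code{baseline * fold} at their planted
#' peak time with a rise-and-fall shape; all values carry lognormal
#' measurement noise.
#'
#' @param sim a \code{sim_genome}.
#' @param seed RNG seed.
#' @param noise_sdlog lognormal noise on every value.
#' @return list with \code{datasets} (two feature x time matrices),
#'   \code{times} and \code{pairing} (antisense id -> host gene id).
#' @export
simulate_timecourse <- function(sim, seed = 1L, noise_sdlog = 0.1) {
  tf <- sim$truth$features
  keep <- tf$class != "coding" | tf$expression > 0
  tf <- tf[keep, , drop = FALSE]
  times <- c(0, 30, 60, 120)
  shape <- function(peak, fold) {
    # multiplicative profile over times; max exactly at the planted peak
    prof <- rep(1, length(times))
    if (!is.na(peak)) {
      pi <- match(peak, times)
      prof[pi] <- fold
      others <- setdiff(seq_along(times)[-1], pi)
      prof[others] <- 1 + (fold - 1) * 0.3
    }
    prof
  }
  base <- pmax(tf$expression, 2)
  mk <- function(sd_seed) {
    with_seed(sd_seed, {
      m <- t(vapply(seq_len(nrow(tf)), function(i) {
        mu <- base[i] * (if (tf$induced[i]) shape(tf$peak_time[i], tf$fold[i])
                         else rep(1, length(times)))
        mu * stats::rlnorm(length(times), 0, noise_sdlog)
      }, numeric(length(times))))
      rownames(m) <- tf$feature_id
      colnames(m) <- paste0("t", times)
      m
    })
  }
  as_rows <- tf$class %in% c("antisense", "antisense_only")
  pairing <- stats::setNames(tf$host_gene[as_rows], tf$feature_id[as_rows])
  list(datasets = list(ds1 = mk(seed + 3000L), ds2 = mk(seed + 4000L)),
       times = times, pairing = pairing)
}

#' Precision and recall of calls against planted truth
#'
#' A truth feature is recovered when a called feature of the same class
#' overlaps it reciprocally by at least \code{min_reciprocal} of each
#' length; a called feature is correct when it recovers some truth
#' feature. Bin-level metrics compare the sets of covered fixed-width bins.
#'
#' @param called data.frame chrom/start/end/class.
#' @param truth data.frame chrom/start/end/class.
#' @param classes classes to evaluate (default: classes present in truth).
#' @param min_reciprocal reciprocal-overlap fraction (default 0.5).
#' @param bin_width bin width of the bin-level metrics.
#' @return data.frame per class: n_truth, n_called, recall, precision,
#'   bin_recall, bin_precision (NA where undefined).
#' @export
recovery_metrics <- function(called, truth,
                             classes = unique(truth$class),
                             min_reciprocal = 0.5, bin_width = 50) {
  one <- function(cl) {
    tr <- truth[truth$class == cl, , drop = FALSE]
    ca <- called[called$class == cl, , drop = FALSE]
    nt <- nrow(tr); nc <- nrow(ca)
    if (nt == 0L && nc == 0L) {
      return(data.frame(class = cl, n_truth = 0L, n_called = 0L,
                        recall = NA_real_, precision = NA_real_,
                        bin_recall = NA_real_, bin_precision = NA_real_))
    }
    rec <- prec <- NA_real_
    t_hit <- logical(nt); c_hit <- logical(nc)
    if (nt && nc) {
      tg <- df_to_gr(tr); cg <- df_to_gr(ca)
      h <- GenomicRanges::findOverlaps(tg, cg)
      if (length(h)) {
        qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
        ov <- pmin(tr$end[qi], ca$end[si]) - pmax(tr$start[qi], ca$start[si]) + 1
        good <- ov >= min_reciprocal * (tr$end[qi] - tr$start[qi] + 1) &
          ov >= min_reciprocal * (ca$end[si] - ca$start[si] + 1)
        t_hit[unique(qi[good])] <- TRUE
        c_hit[unique(si[good])] <- TRUE
      }
    }
    if (nt) rec <- mean(t_hit)
    if (nc) prec <- mean(c_hit)
    bin_key <- function(df) {
      unlist(lapply(seq_len(nrow(df)), function(i) {
        paste(df$chrom[i],
              seq((df$start[i] - 1) %/% bin_width, (df$end[i] - 1) %/% bin_width))
      }))
    }
    tb <- unique(bin_key(tr)); cb <- unique(bin_key(ca))
    data.frame(class = cl, n_truth = nt, n_called = nc,
               recall = rec, precision = prec,
               bin_recall = if (length(tb)) mean(tb %in% cb) else NA_real_,
               bin_precision = if (length(cb)) mean(cb %in% tb) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(classes, one))
  rownames(out) <- NULL
  out
}
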