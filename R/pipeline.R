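#' Pipeline configuration
#'
#' Collects every threshold of the annotation pipeline with its default:
#' 50 bp bins, log-odds cutoff 1.5, 60\% training fraction, 500 bp
#' intergenic distance, 100 bp lincRNA merge gap, 10 reads minimum per
#' stranded bin, the sense<1 / antisense>1 per-bin coverage rule, 2-fold
#' induction threshold, the 25\% junction quantile and 10 spliced reads
#' for junction-in-feature counting.
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param seed master seed for simulation and model training.
#' @param bin_width,cutoff,train_fraction,intergenic_distance,merge_gap
#'   core thresholds.
#' @param min_stranded_reads,fold_threshold,junction_quantile,min_spliced_reads
#'   remaining thresholds.
#' @param transform covariate transform of the logistic model.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1L,
                            bin_width = 50, cutoff = 1.5,
                            train_fraction = 0.6,
                            intergenic_distance = 500, merge_gap = 100,
                            min_stranded_reads = 10, fold_threshold = 2,
                            junction_quantile = 0.25,
                            min_spliced_reads = 10,
                            transform = "log1p_cpm") {
  cfg <- as.list(environment())
  stopifnot(bin_width > 0, train_fraction > 0, intergenic_distance > 0,
            merge_gap > 0, fold_threshold > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full annotation pipeline on synthetic data
#'
#' Stages, in order: simulate genome and coverage; build the bin grid; fit
#' the logistic transcription classifier; call units; classify into coding
#' and lincRNA with merging and the polysome filter; call stranded
#' antisense transcripts and antisense-only genes; classify splice
#' junctions; call light-induced features. Every output table is written
#' under \code{out_dir} and listed in a manifest together with the echoed
#' configuration; a rerun with the same config reproduces the files
#' byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return list with the in-memory results of every stage and
#'   \code{manifest} (data.frame file, md5).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("nct_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  sim <- simulate_genome(config$sim, seed = seed)
  genes <- sim$genes
  if (nrow(genes$genes) == 0L) stopf("classify stage: annotation is empty")
  grid <- simulate_coverage(sim, seed = seed)

  labels <- label_bins(grid, genes)
  model <- fit_transcription_model(grid, labels, rna_lib = "rna",
                                   pol_lib = "pol", cutoff = config$cutoff,
                                   train_fraction = config$train_fraction,
                                   transform = config$transform, seed = seed)
  scores <- predict(model, grid)
  units <- call_units(grid, scores, cutoff = config$cutoff)

  units <- classify_units(units, genes,
                          min_distance = config$intergenic_distance)
  coding <- units[units$status == "coding", , drop = FALSE]
  cand <- merge_linc_segments(units[units$status == "linc_candidate", ,
                                    drop = FALSE],
                              grid, max_gap = config$merge_gap)
  thr <- polysome_threshold(coding)
  filt <- apply_polysome_filter(cand, thr)
  # coding potential is an external per-record input; with none supplied no
  # polysome-positive candidate is flagged as coding
  flags <- rep(FALSE, nrow(filt$polysome_positive))
  catalog <- assemble_final_catalog(filt$linc_confident,
                                    filt$polysome_positive, flags)

  stranded <- call_stranded_units(grid, genes, rna_lib = "ssrna_dark",
                                  pol_lib = "pol", cutoff = config$cutoff,
                                  min_reads = config$min_stranded_reads,
                                  seed = seed,
                                  train_fraction = config$train_fraction,
                                  transform = config$transform)
  paired <- pair_sense_antisense(stranded, genes, rna_lib = "ssrna_dark")
  paired <- filter_by_neighbor_distance(paired, genes,
                                        min_gap = config$intergenic_distance)
  gc1 <- gene_strand_counts(grid, genes, "ssrna_dark")
  gc2 <- gene_strand_counts(grid, genes, "ssrna_light")
  gc1$dataset <- "dark"; gc2$dataset <- "light"
  as_only <- detect_antisense_only(rbind(gc1, gc2), genes)
  as_only <- as_only[!as_only$gene_id %in% paired$gene_id, , drop = FALSE]
  as_sum <- antisense_summary(paired, as_only)

  jx <- load_junctions(simulate_junctions(sim, seed = seed))
  jcut <- annotated_coverage_cutoff(jx, genes$introns,
                                    probs = config$junction_quantile)
  jx <- classify_junctions(jx, genes$introns, jcut)
  linc_hits <- junctions_in_features(jx, catalog$final,
                                     min_reads = config$min_spliced_reads)
  as_hits <- junctions_in_features(jx, paired,
                                   min_reads = config$min_spliced_reads)
  splice_rep <- splice_fraction_report(list(
    lincRNA = list(spliced = sum(linc_hits$feature_hit),
                   total = nrow(catalog$final)),
    antisense = list(spliced = sum(as_hits$feature_hit),
                     total = nrow(paired))))

  tc <- simulate_timecourse(sim, seed = seed)
  induced <- call_induced(tc$datasets, threshold = config$fold_threshold)
  mean_mat <- (tc$datasets[[1]] + tc$datasets[[2]]) / 2
  timing <- classify_timing(mean_mat, induced)
  as_ids <- names(tc$pairing)
  conc <- sense_antisense_concordance(intersect(induced, as_ids),
                                      setdiff(induced, as_ids), tc$pairing)

  files <- c(units = "units.bed", linc = "linc_catalog.tsv",
             linc_bed = "linc_catalog.bed", antisense = "antisense.tsv",
             antisense_only = "antisense_only.tsv",
             junctions = "junctions.tsv", splice = "splice_report.tsv",
             light = "light_induction.tsv", summary = "summary.json",
             config = "config.json")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  write_bed6(units, paths["units"])
  write_tsv(catalog$final, paths["linc"])
  write_bed6(catalog$final, paths["linc_bed"])
  write_tsv(paired, paths["antisense"])
  write_tsv(as_only, paths["antisense_only"])
  write_tsv(jx, paths["junctions"])
  write_tsv(splice_rep, paths["splice"])
  write_tsv(timing, paths["light"])
  summary_obj <- list(
    n_units = nrow(units),
    detection = detection_report(genes, coding),
    polysome_threshold = thr,
    linc = catalog[c("n_confident", "n_polysome_positive", "n_recovered",
                     "n_possibly_coding", "n_final")],
    antisense = as_sum[c("n_paired", "n_antisense_only", "n_total")],
    junction_cutoff = jcut,
    junction_classes = as.list(table(jx$cls)),
    n_induced = length(induced),
    concordance = conc)
  jsonlite::write_json(summary_obj, paths["summary"], auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  cfg_echo <- config
  cfg_echo$sim <- unclass(cfg_echo$sim)
  jsonlite::write_json(unclass(cfg_echo), paths["config"], auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  manifest <- data.frame(file = unname(files),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  list(sim = sim, grid = grid, model = model, units = units,
       coding = coding, catalog = catalog, polysome_threshold = thr,
       antisense = paired, antisense_only = as_only,
       antisense_summary = as_sum, junctions = jx,
       junction_cutoff = jcut, splice_report = splice_rep,
       induced = induced, timing = timing, concordance = conc,
       manifest = manifest, out_dir = out_dir)
}

#' Gene-level stranded read counts
#'
#' Sums a stranded library's bin counts over each gene's span, split into
#' the gene's own (sense) strand and the opposite (antisense) strand.
#'
#' @param grid bin grid with the stranded library aggregated.
#' @param genes \code{gene_models}.
#' @param lib stranded library id.
#' @return data.frame gene_id, sense, antisense.
#' @export
gene_strand_counts <- function(grid, genes, lib) {
  e <- grid$counts[[lib]]
  if (is.null(e) || !e$stranded) stopf("'%s' must be a stranded library", lib)
  g <- genes$genes
  bg <- df_to_gr(grid$bins)
  hits <- GenomicRanges::findOverlaps(df_to_gr(g), bg)
  cp <- e$counts[["+"]]; cm <- e$counts[["-"]]
  sense <- anti <- numeric(nrow(g))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  for (i in seq_len(nrow(g))) {
    b <- si[qi == i]
    if (g$strand[i] == "+") {
      sense[i] <- sum(cp[b]); anti[i] <- sum(cm[b])
    } else {
      sense[i] <- sum(cm[b]); anti[i] <- sum(cp[b])
    }
  }
  data.frame(gene_id = g$gene_id, sense = sense, antisense = anti,
             stringsAsFactors = FALSE)
}
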