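#' Label bins by exon overlap
#'
#' Builds the binary response of the transcription classifier: a bin is
#' labeled 1 when it overlaps an annotated exon by at least 1 bp (optionally
#' restricted to genes on one strand), 0 otherwise.
#'
#' @param grid a \code{bin_grid}.
#' @param genes a \code{gene_models} object.
#' @param strand \code{NULL} to use all genes, or \code{"+"}/\code{"-"} to
#'   label against genes of one strand only (per-strand fits).
#' @return integer vector of 0/1 labels, one per bin.
#' @export
label_bins <- function(grid, genes, strand = NULL) {
  stopifnot(inherits(grid, "bin_grid"), inherits(genes, "gene_models"))
  g <- genes$genes
  ex <- genes$exons
  ex$chrom <- g$chrom[match(ex$gene_id, g$gene_id)]
  if (!is.null(strand)) {
    keep <- g$gene_id[g$strand == strand]
    ex <- ex[ex$gene_id %in% keep, , drop = FALSE]
  }
  lab <- integer(n_bins(grid))
  if (nrow(ex)) {
    hit <- IRanges::overlapsAny(df_to_gr(grid$bins), df_to_gr(ex))
    lab[hit] <- 1L
  }
  lab
}

# covariate transforms, applied to raw bin counts; cpm variants divide by the
# library total first
transform_counts <- function(x, total, transform) {
  switch(transform,
         identity = x,
         log1p = log1p(x),
         log1p_cpm = log1p(x / total * 1e6),
         stopf("unknown covariate transform '%s'", transform))
}

#' Fit the bin-level logistic transcription classifier
#'
#' Models the probability that a 50 bp bin is transcribed ("coding
#' indication") as a Bernoulli GLM on two covariates, the bin's RNA-seq and
#' RNAPII ChIP-seq coverage:
#' \deqn{logit(\pi_i) = \beta_0 + \beta_1 t(x_{i,rna}) + \beta_2 t(x_{i,pol})}
#' where \eqn{t} is a configurable covariate transform. The model is fitted
#' by \code{stats::glm} on a seeded random subsample of the bins (60\% of the
#' genome by default). Bins whose fitted log-odds exceed the cutoff
#' (ln-ratio 1.5 by default) are declared transcribed downstream.
#'
#' @param grid a \code{bin_grid} carrying the two covariate libraries.
#' @param labels 0/1 response per bin, from [label_bins()].
#' @param rna_lib,pol_lib library ids of the RNA-seq and RNAPII tracks.
#' @param strand strand to read from stranded covariate libraries
#'   (\code{NULL} for unstranded libraries).
#' @param cutoff log-odds call threshold (strict \code{>}).
#' @param train_fraction fraction of bins in the training subsample.
#' @param transform covariate transform: \code{"log1p_cpm"} (default,
#'   \code{ln(1 + counts-per-million)}), \code{"log1p"} or
#'   \code{"identity"}.
#' @param seed seed of the training subsample.
#' @return object of class \code{unit_logit} with coefficients, cutoff,
#'   transform, training indices and a \code{separation} flag set when the
#'   fit hit perfect separation (probabilities pinned at 0/1).
#' @seealso [score_bins()], [call_units()]
#' @export
fit_transcription_model <- function(grid, labels, rna_lib = "rna",
                                    pol_lib = "pol", strand = NULL,
                                    cutoff = 1.5, train_fraction = 0.6,
                                    transform = "log1p_cpm", seed = 1L) {
  stopifnot(inherits(grid, "bin_grid"))
  if (length(labels) != n_bins(grid)) stopf("labels length != bin count")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0/1")
  if (train_fraction <= 0 || train_fraction > 1) {
    stopf("train_fraction must be in (0, 1]")
  }
  x1 <- transform_counts(lib_counts(grid, rna_lib, strand),
                         grid_total(grid, rna_lib), transform)
  x2 <- transform_counts(lib_counts(grid, pol_lib, strand),
                         grid_total(grid, pol_lib), transform)
  nb <- length(labels)
  train <- with_seed(seed, sort(sample.int(nb, round(train_fraction * nb))))
  y <- labels[train]
  if (length(unique(y)) < 2L) stopf("training subsample has a single class")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x1[train] + x2[train], family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::setNames(stats::coef(fit), c("beta0", "beta1", "beta2"))
  aliased <- is.na(cf)
  cf[aliased] <- 0          # aliased covariate contributes nothing, as in predict.glm
  structure(list(coefficients = cf,
                 aliased = aliased,
                 cutoff = cutoff,
                 transform = transform,
                 train_fraction = train_fraction,
                 seed = seed,
                 trials_per_bin = 1L,
                 rna_lib = rna_lib, pol_lib = pol_lib, strand = strand,
                 separation = separation,
                 converged = fit$converged,
                 n_train = length(train),
                 train_index = train,
                 se = {
                   s <- rep(NA_real_, 3)
                   s[!aliased] <- summary(fit)$coefficients[, "Std. Error"]
                   stats::setNames(s, names(cf))
                 },
                 null_deviance = fit$null.deviance,
                 deviance = fit$deviance),
            class = "unit_logit")
}

#' @export
print.unit_logit <- function(x, ...) {
  b <- x$coefficients
  cat("Bin-level logistic transcription classifier\n")
  cat(sprintf("  logit(p) = %.4f + %.4f * t(rna) + %.4f * t(pol),  t = %s\n",
              b[1], b[2], b[3], x$transform))
  cat(sprintf("  cutoff (log-odds) %.2f; trained on %d bins (%.0f%%), seed %d\n",
              x$cutoff, x$n_train, 100 * x$train_fraction, x$seed))
  if (x$separation) cat("  warning: perfect separation during fit\n")
  invisible(x)
}

#' @export
coef.unit_logit <- function(object, ...) object$coefficients

#' @export
summary.unit_logit <- function(object, ...) {
  out <- data.frame(estimate = object$coefficients,
                    std_error = as.numeric(object$se))
  out$z <- out$estimate / out$std_error
  cat(sprintf("unit_logit: deviance %.1f (null %.1f), %d training bins\n",
              object$deviance, object$null_deviance, object$n_train))
  print(out)
  invisible(out)
}

#' Score bins under a fitted transcription model
#'
#' @param object a fitted \code{unit_logit}.
#' @param grid a \code{bin_grid} with the model's covariate libraries.
#' @param strand override the strand the covariates are read from (defaults
#'   to the strand the model was fitted on).
#' @param ... unused.
#' @return per-bin linear predictor (log-odds of transcription).
#' @export
predict.unit_logit <- function(object, grid, strand = object$strand, ...) {
  x1 <- transform_counts(lib_counts(grid, object$rna_lib, strand),
                         grid_total(grid, object$rna_lib), object$transform)
  x2 <- transform_counts(lib_counts(grid, object$pol_lib, strand),
                         grid_total(grid, object$pol_lib), object$transform)
  b <- object$coefficients
  unname(b[1] + b[2] * x1 + b[3] * x2)
}

#' Per-bin log-odds from explicit coefficients
#'
#' Functional form of [predict.unit_logit()] for already-transformed
#' covariates: \code{beta0 + beta1 * x_rna + beta2 * x_pol}.
#'
#' @param beta length-3 coefficient vector (intercept, rna, pol).
#' @param x_rna,x_pol transformed covariate vectors.
#' @return log-odds vector.
#' @export
score_bins <- function(beta, x_rna, x_pol) {
  stopifnot(length(beta) == 3L, length(x_rna) == length(x_pol))
  unname(beta[1] + beta[2] * x_rna + beta[3] * x_pol)
}

#' Simulate bin labels from the fitted model
#'
#' Draws Bernoulli responses at the model's fitted probabilities for the
#' supplied covariates; used for parameter-recovery checks.
#'
#' @param object a \code{unit_logit}.
#' @param nsim number of label vectors.
#' @param seed RNG seed.
#' @param grid bin grid providing covariates.
#' @param ... unused.
#' @return matrix of 0/1 draws, one column per simulation.
#' @export
simulate.unit_logit <- function(object, nsim = 1, seed = 1L, grid, ...) {
  eta <- predict(object, grid)
  p <- stats::plogis(eta)
  with_seed(seed, {
    matrix(stats::rbinom(length(p) * nsim, size = object$trials_per_bin, p),
           ncol = nsim)
  })
}

#' Merge super-threshold bins into transcription units
#'
#' Maximal runs of consecutive bins (within one chromosome, and one strand
#' for stranded calls) whose score strictly exceeds the cutoff become one
#' transcription unit. Optionally a bin must also carry a minimum raw read
#' count to be eligible (the strand-specific antisense rule: at least 10
#' reads per 50 bp bin). Unit counts are the sums over member bins,
#' length-normalized with [normalize_counts()].
#'
#' @param grid a \code{bin_grid}.
#' @param scores per-bin log-odds.
#' @param cutoff log-odds threshold; ties are sub-threshold.
#' @param strand strand label stored on the units (\code{"."} for
#'   unstranded calls) and used to read stranded count libraries.
#' @param min_reads minimum raw reads per bin in \code{min_reads_lib}
#'   (0 disables the filter).
#' @param min_reads_lib library whose raw counts gate eligibility.
#' @param count_libs libraries to attach as per-unit raw and normalized
#'   counts (default: all libraries on the grid).
#' @return data.frame of units: unit_id, chrom, start, end, strand, n_bins,
#'   mean_logodds, plus \code{raw_<lib>} and \code{norm_<lib>} columns.
#' @export
call_units <- function(grid, scores, cutoff = 1.5, strand = ".",
                       min_reads = 0, min_reads_lib = NULL,
                       count_libs = names(grid$counts)) {
  stopifnot(inherits(grid, "bin_grid"))
  if (length(scores) != n_bins(grid)) stopf("scores length != bin count")
  above <- scores > cutoff
  if (min_reads > 0) {
    if (is.null(min_reads_lib)) stopf("min_reads set but min_reads_lib missing")
    s <- if (strand %in% c("+", "-")) strand else NULL
    raw <- grid_counts(grid, min_reads_lib,
                       if (grid$counts[[min_reads_lib]]$stranded) s else NULL)
    above <- above & raw >= min_reads
  }
  bins <- grid$bins
  # runs must not cross chromosome boundaries
  chrom_id <- match(bins$chrom, names(grid$chrom_sizes))
  r <- rle(ifelse(above, chrom_id, 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L
  starts <- starts[keep]; ends <- ends[keep]
  units <- data.frame(
    unit_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), n_bins = integer(0),
    mean_logodds = numeric(0), stringsAsFactors = FALSE)
  if (length(starts)) {
    units <- data.frame(
      unit_id = sprintf("TU%s%05d", if (strand == ".") "" else
        ifelse(strand == "+", "p", "m"), seq_along(starts)),
      chrom = bins$chrom[starts],
      start = bins$start[starts],
      end = bins$end[ends],
      strand = strand,
      n_bins = ends - starts + 1L,
      mean_logodds = vapply(seq_along(starts), function(k) {
        mean(scores[starts[k]:ends[k]])
      }, numeric(1)),
      stringsAsFactors = FALSE)
    for (lib in count_libs) {
      e <- grid$counts[[lib]]
      s <- if (e$stranded) {
        if (!strand %in% c("+", "-")) next
        strand
      } else NULL
      cnt <- grid_counts(grid, lib, s)
      cs <- c(0, cumsum(cnt))
      raw <- cs[ends + 1L] - cs[starts]
      units[[paste0("raw_", lib)]] <- raw
      units[[paste0("norm_", lib)]] <-
        normalize_counts(raw, e$total_reads, units$end - units$start + 1L)
    }
  }
  units
}

#' Re-derive the normalized count columns of a unit table
#' @param units unit data.frame with \code{raw_<lib>} columns.
#' @param grid bin grid supplying library totals.
#' @return units with \code{norm_<lib>} recomputed from the raw sums.
#' @keywords internal
renormalize_units <- function(units, grid) {
  libs <- sub("^raw_", "", grep("^raw_", names(units), value = TRUE))
  len <- units$end - units$start + 1L
  for (lib in libs) {
    units[[paste0("norm_", lib)]] <-
      normalize_counts(units[[paste0("raw_", lib)]], grid_total(grid, lib), len)
  }
  units
}
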