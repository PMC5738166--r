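#' Rank features by an index track
#'
#' Sorts features ascending by the index track (e.g. RNAPII ChIP-seq reads
#' per exon) and reorders every other track by the same permutation, the
#' substrate of index-profile plots. Ties keep their original order.
#'
#' @param index_values numeric vector ranked on.
#' @param tracks data.frame or matrix of companion tracks, rows aligned to
#'   \code{index_values}.
#' @return object of class \code{index_profile}: list with \code{order}
#'   (the permutation), \code{index} (sorted values) and \code{tracks}
#'   (reordered).
#' @export
rank_index <- function(index_values, tracks) {
  tracks <- as.data.frame(tracks)
  if (nrow(tracks) != length(index_values)) {
    stopf("tracks rows (%d) != index length (%d)", nrow(tracks),
          length(index_values))
  }
  o <- order(index_values)               # stable for numeric input
  structure(list(order = o,
                 index = index_values[o],
                 tracks = tracks[o, , drop = FALSE]),
            class = "index_profile")
}

#' Centered run-window average
#'
#' Moving mean with an odd, centered window; at the edges the window is
#' truncated to the available neighbors (no padding).
#'
#' @param values numeric vector.
#' @param window odd window width (1 = identity).
#' @return smoothed vector, same length.
#' @examples
#' run_window_average(c(0, 0, 3, 0, 0), 3)  # 0 1 1 1 0
#' @export
run_window_average <- function(values, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stopf("window must be a positive odd integer")
  }
  n <- length(values)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(values))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# total variation: sum of absolute successive differences
sad <- function(x) sum(abs(diff(x)))

#' Select a smoothing window from the sum-of-absolute-differences curve
#'
#' For every candidate window the values are smoothed and the total
#' variation SAD(w) of the smoothed series is computed. Smoothing a noisy
#' ranked profile drops SAD steeply at first, then the curve flattens once
#' noise is suppressed; the chosen window is the smallest candidate at
#' which the relative decrease to the next candidate falls below
#' \code{tol} (an elbow rule). A zero-SAD candidate is chosen outright.
#'
#' @param values numeric vector (typically a ranked track).
#' @param windows increasing odd candidate widths (at least 2).
#' @param tol relative-decrease tolerance (default 0.05).
#' @return list with \code{window} (chosen) and \code{sad_curve}
#'   (data.frame window, sad).
#' @export
select_window <- function(values, windows, tol = 0.05) {
  windows <- sort(unique(as.integer(windows)))
  if (length(windows) < 2L) stopf("need at least 2 candidate windows")
  s <- vapply(windows, function(w) sad(run_window_average(values, w)),
              numeric(1))
  curve <- data.frame(window = windows, sad = s)
  chosen <- windows[length(windows)]
  for (k in seq_len(length(windows) - 1L)) {
    if (s[k] == 0 || (s[k] - s[k + 1L]) / s[k] < tol) {
      chosen <- windows[k]
      break
    }
  }
  list(window = chosen, sad_curve = curve)
}

#' Smoothed profile of every track in an index profile
#'
#' @param profile an \code{index_profile} from [rank_index()].
#' @param windows candidate windows passed to [select_window()]; the window
#'   is selected on the index track and applied to all tracks.
#' @param tol elbow tolerance.
#' @return list with \code{window}, \code{sad_curve} and \code{smoothed}
#'   (data.frame of smoothed tracks in ranked order).
#' @export
profile_tracks <- function(profile, windows = c(1, 5, 11, 21, 51, 101),
                           tol = 0.05) {
  stopifnot(inherits(profile, "index_profile"))
  sel <- select_window(profile$index, windows, tol)
  sm <- as.data.frame(lapply(profile$tracks, run_window_average,
                             window = sel$window))
  list(window = sel$window, sad_curve = sel$sad_curve, smoothed = sm)
}
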