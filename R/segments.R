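# lag-1 autocorrelation of a numeric vector (mean-subtracted, lag-0
# normalised); NA when the window has no variance
.lag1_ac <- function(v) {
  z <- v - mean(v)
  den <- sum(z^2)
  if (den == 0) return(NA_real_)
  sum(z[-length(z)] * z[-1]) / den
}

#' Sliding-window oscillation labels
#'
#' Moves a window of \code{window} samples across a trajectory and computes
#' the velocity autocorrelation at lag 1 inside each window (velocities are
#' consecutive-frame differences; the autocorrelation is mean-subtracted
#' within the window).  Positive lag-1 velocity autocorrelation marks
#' processive back-and-forth (oscillatory) motion and labels the window's
#' centre point \code{"oscillatory"}; otherwise the point is labelled
#' \code{"regular"} (elastic, spring-like motion has negative lag-1 velocity
#' autocorrelation at every relaxation time).  Points within half a window
#' of either end are \code{"undetermined"}.
#'
#' @param traj a \code{"par_trajectory"} or numeric position vector
#'   (uniform sampling).
#' @param window sliding-window size in samples (default 12).
#' @param plasmid plasmid column for multi-plasmid trajectories.
#' @return Character vector of per-timepoint labels, one per sample:
#'   \code{"oscillatory"}, \code{"regular"} or \code{"undetermined"}.
#' @export
sliding_window_labels <- function(traj, window = 12, plasmid = 1) {
  x <- if (inherits(traj, "par_trajectory")) traj$positions[, plasmid]
       else as.numeric(traj)
  x <- x[!is.na(x)]
  n <- length(x)
  labels <- rep("undetermined", n)
  if (window < 3) stop("'window' must be at least 3")
  if (n < window) return(labels)
  v <- diff(x)
  centre_off <- window %/% 2          # centre of an even window: index w/2
  for (i in seq_len(n - window + 1)) {
    ac1 <- .lag1_ac(v[i:(i + window - 2)])
    if (is.na(ac1)) next
    labels[i + centre_off] <- if (ac1 > 0) "oscillatory" else "regular"
  }
  labels
}

#' Segments from per-timepoint labels
#'
#' Maximal runs of at least \code{min_run} identical non-undetermined
#' labels become segments; shorter runs are relabelled undetermined.
#'
#' @param labels character labels from
#'   \code{\link{sliding_window_labels}}.
#' @param min_run minimum run length to form a segment (default 6).
#' @return An object of class \code{"segment_labels"}: list with the
#'   filtered per-timepoint \code{labels} and a \code{segments} data frame
#'   (\code{start}, \code{end}, \code{label}, 1-based inclusive indices).
#' @export
segments_from_labels <- function(labels, min_run = 6) {
  r <- rle(labels)
  keep <- r$values != "undetermined" & r$lengths >= min_run
  r$values[r$values != "undetermined" & r$lengths < min_run] <- "undetermined"
  filtered <- inverse.rle(r)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[keep], end = ends[keep],
                    label = r$values[keep], stringsAsFactors = FALSE)
  out <- list(labels = filtered, segments = seg, min_run = min_run)
  class(out) <- "segment_labels"
  out
}

#' @export
print.segment_labels <- function(x, ...) {
  cat(sprintf("%d timepoints: %d oscillatory, %d regular, %d undetermined; %d segment(s)\n",
              length(x$labels), sum(x$labels == "oscillatory"),
              sum(x$labels == "regular"), sum(x$labels == "undetermined"),
              nrow(x$segments)))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

#' Classify a trajectory into oscillatory / regular segments
#'
#' Convenience wrapper: \code{\link{sliding_window_labels}} followed by
#' \code{\link{segments_from_labels}}.
#'
#' @param traj a \code{"par_trajectory"} or numeric position vector.
#' @param window sliding-window size (default 12 samples).
#' @param min_run minimum run length for a segment (default 6).
#' @param plasmid plasmid column.
#' @return A \code{"segment_labels"} object.
#' @export
classify_segments <- function(traj, window = 12, min_run = 6, plasmid = 1) {
  segments_from_labels(sliding_window_labels(traj, window, plasmid), min_run)
}

#' Oscillatory fraction by cell length
#'
#' Pools segment-classified timepoints from many trajectories, bins them by
#' the cell length at each timepoint, and reports per bin the fraction of
#' segment timepoints that are oscillatory.  Timepoints outside any segment
#' (undetermined) do not enter the denominator; empty bins give \code{NA}.
#'
#' @param trajs list of \code{"par_trajectory"} objects carrying
#'   \code{cell_lengths} (per-sample cell length in um).
#' @param length_bins numeric vector of bin breaks covering the lengths.
#' @param window,min_run classifier settings, see
#'   \code{\link{classify_segments}}.
#' @return Data frame with \code{bin_lo}, \code{bin_hi}, \code{bin_mid},
#'   \code{n_points} (segment timepoints in the bin) and
#'   \code{frac_oscillatory}.
#' @export
oscillatory_fraction_by_length <- function(trajs, length_bins, window = 12,
                                           min_run = 6) {
  stopifnot(length(length_bins) >= 2)
  pts <- do.call(rbind, lapply(trajs, function(tr) {
    stopifnot(inherits(tr, "par_trajectory"))
    if (is.null(tr$cell_lengths))
      stop("each trajectory must carry per-sample cell lengths")
    do.call(rbind, lapply(seq_len(ncol(tr$positions)), function(j) {
      lab <- classify_segments(tr$positions[, j], window, min_run)$labels
      data.frame(label = lab, len = tr$cell_lengths,
                 stringsAsFactors = FALSE)
    }))
  }))
  pts <- pts[pts$label != "undetermined", ]
  idx <- findInterval(pts$len, length_bins, rightmost.closed = TRUE)
  nb <- length(length_bins) - 1
  out <- data.frame(bin_lo = length_bins[-length(length_bins)],
                    bin_hi = length_bins[-1])
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  out$n_points <- vapply(seq_len(nb), function(b) sum(idx == b), 0L)
  out$frac_oscillatory <- vapply(seq_len(nb), function(b) {
    sel <- idx == b
    if (!any(sel)) return(NA_real_)
    mean(pts$label[sel] == "oscillatory")
  }, 0)
  out
}
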