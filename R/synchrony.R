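#' Bin spike trains into counts
#'
#' Divides the trial into `floor(duration / bin_width_s)` half-open bins
#' `[k*w, (k+1)*w)`; spikes at or beyond the last full bin are discarded
#' (their number is reported via a message and stored in the result).
#'
#' @param x A [trial_recording()] or a spike data frame (then `duration`
#'   is required).
#' @param bin_width_s Bin width in seconds (default 0.1).
#' @param duration,channels Only used when `x` is a bare data frame.
#' @return A `binned_counts` object: integer matrix `counts`
#'   (channels x bins, rownames = channel ids, including declared silent
#'   channels), plus `bin_width_s`, `duration_s`, `n_discarded`.
#' @export
bin_spikes <- function(x, bin_width_s = 0.1, duration = NULL,
                       channels = NULL) {
  rec <- as_trial_recording(x, duration, channels)
  if (!is.numeric(bin_width_s) || bin_width_s <= 0) {
    abort("bin_width_s must be positive.",
          class = "spikesync_validation_error")
  }
  if (bin_width_s > rec$duration) {
    abort("bin_width_s must not exceed the trial duration.",
          class = "spikesync_validation_error")
  }
  # small tolerance so durations that are exact bin multiples up to
  # floating-point error keep their last bin
  n_bins <- floor(rec$duration / bin_width_s + 1e-9)
  t_max <- n_bins * bin_width_s
  keep <- rec$spikes$time_s < t_max
  n_discarded <- sum(!keep)
  if (n_discarded > 0) {
    inform(sprintf("bin_spikes: discarded %d spike(s) at t >= %g s (past the last full bin).",
                   n_discarded, t_max))
  }
  sp <- rec$spikes[keep, ]
  counts <- matrix(0L, nrow = length(rec$channels), ncol = n_bins,
                   dimnames = list(rec$channels, NULL))
  if (nrow(sp) > 0) {
    bin <- floor(sp$time_s / bin_width_s) + 1L
    tab <- table(factor(sp$channel, levels = rec$channels),
                 factor(bin, levels = seq_len(n_bins)))
    counts <- matrix(as.integer(tab), nrow = length(rec$channels),
                     dimnames = list(rec$channels, NULL))
  }
  structure(
    list(counts = counts, channels = rec$channels,
         bin_width_s = bin_width_s, duration_s = rec$duration,
         n_discarded = n_discarded),
    class = "binned_counts"
  )
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> %d channels x %d bins (w = %g s)\n",
              nrow(x$counts), ncol(x$counts), x$bin_width_s))
  invisible(x)
}

#' @export
#' @method tidy binned_counts
tidy.binned_counts <- function(x, ...) {
  tibble(channel = rep(rownames(x$counts), ncol(x$counts)),
         bin = rep(seq_len(ncol(x$counts)), each = nrow(x$counts)),
         count = as.integer(x$counts)) %>%
    arrange(.data$channel, .data$bin)
}

#' Active channels of a recording
#'
#' A channel is active when its mean firing rate (spike count / duration)
#' is at least `min_rate_hz`; the boundary is inclusive.
#'
#' @param x A [trial_recording()] or spike data frame.
#' @param min_rate_hz Activity threshold, Hz (default 0.1).
#' @param duration,channels Only used for bare data frames.
#' @return Character vector of active channel ids (sorted).
#' @export
active_channels <- function(x, min_rate_hz = 0.1, duration = NULL,
                            channels = NULL) {
  rec <- as_trial_recording(x, duration, channels)
  if (min_rate_hz < 0) {
    abort("min_rate_hz must be >= 0.",
          class = "spikesync_validation_error")
  }
  counts <- table(factor(rec$spikes$channel, levels = rec$channels))
  rates <- as.double(counts) / rec$duration
  sort(rec$channels[rates >= min_rate_hz])
}

#' Pairwise Pearson synchrony matrix
#'
#' Sample Pearson correlation of binned spike counts for every pair of the
#' selected (active) channels. Zero-variance channels yield undefined
#' coefficients, which are recorded as `NA` (with a warning) rather than
#' silently zero. The diagonal is 1 by convention.
#'
#' @param binned A [bin_spikes()] result.
#' @param active_ids Channels to include (default: all binned channels).
#' @param min_rate_hz Recorded in the result for provenance.
#' @return A `synchrony_matrix`: symmetric numeric matrix with attributes
#'   `bin_width_s`, `min_rate_hz`.
#' @export
pearson_matrix <- function(binned, active_ids = NULL, min_rate_hz = NA) {
  stopifnot(inherits(binned, "binned_counts"))
  active_ids <- active_ids %||% rownames(binned$counts)
  if (length(active_ids) < 2) {
    abort("need at least 2 active channels for a synchrony matrix.",
          class = "spikesync_analysis_error")
  }
  if (ncol(binned$counts) < 2) {
    abort("need at least 2 bins for a synchrony matrix.",
          class = "spikesync_analysis_error")
  }
  missing_ch <- setdiff(active_ids, rownames(binned$counts))
  if (length(missing_ch) > 0) {
    abort(sprintf("channels not in binned counts: %s",
                  paste(missing_ch, collapse = ", ")),
          class = "spikesync_validation_error")
  }
  m <- binned$counts[active_ids, , drop = FALSE]
  zero_var <- apply(m, 1, function(r) stats::var(as.double(r)) == 0)
  r <- suppressWarnings(cor(t(m)))
  if (any(zero_var)) {
    warn(sprintf(
      "%d zero-variance channel(s) (%s): correlations recorded as NA.",
      sum(zero_var), paste(active_ids[zero_var], collapse = ", ")),
      class = "spikesync_zero_variance_warning")
    r[zero_var, ] <- NA_real_
    r[, zero_var] <- NA_real_
  }
  diag(r) <- 1
  structure(r, class = c("synchrony_matrix", "matrix"),
            bin_width_s = binned$bin_width_s, min_rate_hz = min_rate_hz)
}

#' One-step synchrony matrix from a recording
#'
#' Convenience wrapper: bin, filter active channels, correlate.
#'
#' @inheritParams bin_spikes
#' @inheritParams active_channels
#' @return A `synchrony_matrix` over active channels.
#' @export
synchrony_matrix <- function(x, bin_width_s = 0.1, min_rate_hz = 0.1,
                             duration = NULL, channels = NULL) {
  rec <- as_trial_recording(x, duration, channels)
  act <- active_channels(rec, min_rate_hz)
  pearson_matrix(bin_spikes(rec, bin_width_s), act,
                 min_rate_hz = min_rate_hz)
}

#' @export
#' @method tidy synchrony_matrix
tidy.synchrony_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
         r = unclass(x)[idx]) %>%
    arrange(.data$from, .data$to)
}

#' Threshold a synchrony matrix into a functional graph
#'
#' An (undirected, weighted) functional connection joins every unordered
#' pair of active channels whose Pearson coefficient is at least
#' `threshold`; undefined (`NA`) pairs never become edges, and negative
#' correlations are not functional connections.
#'
#' @param matrix A `synchrony_matrix`.
#' @param threshold Edge threshold in (-1, 1], default 0.3.
#' @return A `functional_graph`: tibble of edges (`from`, `to`, `weight`)
#'   with attributes `nodes` (all active channels, including isolated
#'   ones) and `threshold`.
#' @export
functional_edges <- function(matrix, threshold = 0.3) {
  stopifnot(inherits(matrix, "synchrony_matrix"))
  if (threshold <= -1 || threshold > 1) {
    abort("threshold must lie in (-1, 1].",
          class = "spikesync_validation_error")
  }
  pairs <- tidy.synchrony_matrix(matrix)
  edges <- filter(pairs, !is.na(.data$r), .data$r >= threshold) %>%
    rename(weight = "r")
  structure(edges, class = c("functional_graph", class(edges)),
            nodes = rownames(matrix), threshold = threshold,
            bin_width_s = attr(matrix, "bin_width_s"))
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> %d nodes, %d edges (r >= %g)\n",
              length(attr(x, "nodes")), nrow(x), attr(x, "threshold")))
  NextMethod()
}

#' Mean pairwise synchrony
#'
#' Mean of all defined off-diagonal Pearson coefficients over active-node
#' pairs (not only pairs forming edges).
#'
#' @param matrix A `synchrony_matrix`.
#' @return A single number.
#' @export
mean_synchrony <- function(matrix) {
  stopifnot(inherits(matrix, "synchrony_matrix"))
  vals <- unclass(matrix)[upper.tri(matrix)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    abort("no defined off-diagonal pairs in the synchrony matrix.",
          class = "spikesync_analysis_error")
  }
  mean(vals)
}

#' Network synchronization activity index
#'
#' The product of the total number of functional connections and their
#' average synchrony coefficient; 0 for an edgeless graph.
#'
#' @param graph A [functional_edges()] result.
#' @return A single nonnegative number.
#' @export
sync_activity_index <- function(graph) {
  stopifnot(inherits(graph, "functional_graph"))
  if (nrow(graph) == 0) return(0)
  nrow(graph) * mean(graph$weight)
}
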