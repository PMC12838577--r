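#' Inter-spike intervals of one train
#'
#' @param times Numeric vector of sorted spike times (seconds), or a
#'   [trial_recording()] plus `channel`.
#' @param channel Channel id when `times` is a recording.
#' @return Numeric vector of consecutive differences (length
#'   `max(0, n - 1)`, all positive).
#' @export
isi <- function(times, channel = NULL) {
  if (inherits(times, "trial_recording")) {
    times <- spike_times(times, channel)
  }
  if (length(times) < 2) return(double())
  diff(times)
}

default_isi_edges <- function(n_bins = 50, lo = 0.001, hi = 10) {
  10^seq(log10(lo), log10(hi), length.out = n_bins + 1)
}

#' Joint ISI distribution
#'
#' For every channel with at least 3 spikes, forms all consecutive
#' interval pairs (ISI_k, ISI_k+1) and pools them across channels into a
#' 2D histogram on log10-spaced bin edges (default 1 ms to 10 s, 50 bins
#' per axis, bins half-open `[e_k, e_k+1)` with the last bin closed).
#' Pairs with either interval outside the edges are counted and reported,
#' not binned.
#'
#' @param x A [trial_recording()] or spike data frame.
#' @param bin_edges Increasing vector of bin edges in seconds.
#' @param duration,channels For bare data frames.
#' @return A `joint_isi` object: `counts` (bins x bins integer matrix,
#'   first axis = ISI_k), `bin_edges`, `n_pairs` (in-range),
#'   `n_out_of_range`.
#' @export
joint_isi_hist <- function(x, bin_edges = default_isi_edges(),
                           duration = NULL, channels = NULL) {
  rec <- as_trial_recording(x, duration, channels)
  pairs <- consecutive_isi_pairs(rec)
  if (nrow(pairs) == 0) {
    abort("joint ISI distribution needs at least one channel with >= 3 spikes.",
          class = "spikesync_analysis_error")
  }
  nb <- length(bin_edges) - 1
  bx <- findInterval(pairs$isi1, bin_edges, rightmost.closed = TRUE)
  by <- findInterval(pairs$isi2, bin_edges, rightmost.closed = TRUE)
  ok <- bx >= 1 & bx <= nb & by >= 1 & by <= nb
  n_out <- sum(!ok)
  if (n_out > 0) {
    inform(sprintf("joint_isi_hist: %d pair(s) outside the bin range.",
                   n_out))
  }
  counts <- matrix(0L, nb, nb)
  if (any(ok)) {
    tab <- table(factor(bx[ok], levels = seq_len(nb)),
                 factor(by[ok], levels = seq_len(nb)))
    counts <- matrix(as.integer(tab), nb, nb)
  }
  structure(
    list(counts = counts, bin_edges = bin_edges, n_pairs = sum(ok),
         n_out_of_range = n_out),
    class = "joint_isi"
  )
}

#' @export
print.joint_isi <- function(x, ...) {
  cat(sprintf("<joint_isi> %d consecutive-ISI pairs over %d x %d log-spaced bins\n",
              x$n_pairs, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
#' @method tidy joint_isi
tidy.joint_isi <- function(x, ...) {
  nb <- nrow(x$counts)
  mid <- sqrt(x$bin_edges[-1] * x$bin_edges[-(nb + 1)])
  tibble(isi1_s = rep(mid, nb), isi2_s = rep(mid, each = nb),
         count = as.integer(x$counts))
}

consecutive_isi_pairs <- function(rec) {
  per_channel <- split(rec$spikes$time_s, rec$spikes$channel)
  rows <- lapply(names(per_channel), function(ch) {
    iv <- isi(per_channel[[ch]])
    if (length(iv) < 2) return(NULL)
    tibble(channel = ch, isi1 = iv[-length(iv)], isi2 = iv[-1])
  })
  bind_rows(rows)
}

#' Short-interval firing metrics
#'
#' Counts joint-ISI pairs confined to a short window: by default a pair
#' qualifies when both consecutive intervals are at most `window_s`
#' (50 ms), tying the count to the joint ISI distribution's lower-left
#' block. `mode = "isi"` instead counts single intervals
#' `<= window_s` (proportion of all intervals).
#'
#' @param x A [trial_recording()] or spike data frame.
#' @param window_s Window length in seconds (default 0.05).
#' @param mode `"pair"` (default) or `"isi"`.
#' @param duration,channels For bare data frames.
#' @return Tibble with `count`, `total` and `proportion`.
#' @export
short_interval_metrics <- function(x, window_s = 0.05,
                                   mode = c("pair", "isi"),
                                   duration = NULL, channels = NULL) {
  mode <- match.arg(mode)
  rec <- as_trial_recording(x, duration, channels)
  if (mode == "pair") {
    pairs <- consecutive_isi_pairs(rec)
    if (nrow(pairs) == 0) {
      abort("no consecutive-ISI pairs: need a channel with >= 3 spikes.",
            class = "spikesync_analysis_error")
    }
    count <- sum(pairs$isi1 <= window_s & pairs$isi2 <= window_s)
    total <- nrow(pairs)
  } else {
    ivs <- unlist(lapply(split(rec$spikes$time_s, rec$spikes$channel), isi))
    if (length(ivs) == 0) {
      abort("no inter-spike intervals: need a channel with >= 2 spikes.",
            class = "spikesync_analysis_error")
    }
    count <- sum(ivs <= window_s)
    total <- length(ivs)
  }
  tibble(count = count, total = total, proportion = count / total,
         window_s = window_s, mode = mode)
}

#' Per-channel firing rates and network mean firing rate
#'
#' Rates are spike count over duration; the network mean firing rate (MFR)
#' averages over all declared channels, silent ones included.
#'
#' @param x A [trial_recording()] or spike data frame.
#' @param duration,channels For bare data frames.
#' @return Tibble (`channel`, `n_spikes`, `rate_hz`) with the MFR stored
#'   as attribute `mfr`; see [mean_firing_rate()].
#' @export
firing_rate <- function(x, duration = NULL, channels = NULL) {
  rec <- as_trial_recording(x, duration, channels)
  counts <- table(factor(rec$spikes$channel, levels = rec$channels))
  out <- tibble(channel = rec$channels,
                n_spikes = as.integer(counts),
                rate_hz = as.double(counts) / rec$duration)
  structure(out, mfr = mean(out$rate_hz))
}

#' @rdname firing_rate
#' @return `mean_firing_rate()`: the MFR as a single number.
#' @export
mean_firing_rate <- function(x, duration = NULL, channels = NULL) {
  attr(firing_rate(x, duration, channels), "mfr")
}

#' Fixed-threshold burst detection
#'
#' A burst is a maximal run of consecutive spikes whose inter-spike
#' intervals are all at most `max_isi_s` and whose length is at least
#' `min_spikes`.
#'
#' @param x Sorted spike-time vector, or a [trial_recording()] (all
#'   channels are scanned).
#' @param max_isi_s Maximum intra-burst ISI, seconds (default 0.1).
#' @param min_spikes Minimum spikes per burst (default 3).
#' @param channel Restrict to one channel when `x` is a recording.
#' @return Tibble (`channel`, `start_s`, `end_s`, `n_spikes`), one row per
#'   burst, ordered within channel; bursts never overlap.
#' @export
detect_bursts <- function(x, max_isi_s = 0.1, min_spikes = 3,
                          channel = NULL) {
  if (max_isi_s <= 0 || min_spikes <= 0) {
    abort("burst parameters must be positive.",
          class = "spikesync_validation_error")
  }
  if (inherits(x, "trial_recording")) {
    chs <- if (is.null(channel)) unique(x$spikes$channel) else channel
    out <- lapply(chs, function(ch) {
      b <- burst_runs(spike_times(x, ch), max_isi_s, min_spikes)
      if (nrow(b) > 0) mutate(b, channel = ch, .before = 1) else NULL
    })
    res <- bind_rows(out)
    if (nrow(res) == 0) {
      res <- tibble(channel = character(), start_s = double(),
                    end_s = double(), n_spikes = integer())
    }
    return(res)
  }
  mutate(burst_runs(x, max_isi_s, min_spikes),
         channel = NA_character_, .before = 1)
}

burst_runs <- function(times, max_isi_s, min_spikes) {
  empty <- tibble(start_s = double(), end_s = double(),
                  n_spikes = integer())
  n <- length(times)
  if (n < min_spikes) return(empty)
  short <- diff(times) <= max_isi_s
  r <- rle(short)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths + 1) >= min_spikes
  if (!any(keep)) return(empty)
  tibble(start_s = times[starts[keep]],
         end_s = times[ends[keep] + 1],
         n_spikes = as.integer(r$lengths[keep] + 1))
}

#' Burst spike rate
#'
#' Fraction of all spikes (across channels) that fall inside a detected
#' burst.
#'
#' @inheritParams detect_bursts
#' @param x A [trial_recording()] or spike data frame.
#' @param duration,channels For bare data frames.
#' @return Number in `[0, 1]`.
#' @export
burst_spike_rate <- function(x, max_isi_s = 0.1, min_spikes = 3,
                             duration = NULL, channels = NULL) {
  rec <- as_trial_recording(x, duration, channels)
  total <- nrow(rec$spikes)
  if (total == 0) {
    abort("burst spike rate is undefined for a recording with no spikes.",
          class = "spikesync_analysis_error")
  }
  bursts <- detect_bursts(rec, max_isi_s, min_spikes)
  if (nrow(bursts) == 0) return(0)
  in_burst <- sum(bursts$n_spikes)
  in_burst / total
}

#' Baseline mean-firing-rate recovery check
#'
#' Confirms restoration of the network's baseline firing state: passes
#' when the post-recording MFR is within `tolerance_fraction` of the
#' baseline MFR (boundary inclusive).
#'
#' @param baseline,post [trial_recording()]s (or spike data frames with
#'   matching `duration` supplied via attributes).
#' @param tolerance_fraction Allowed relative deviation (default 0.2).
#' @return One-row tibble: `mfr_baseline`, `mfr_post`, `ratio`
#'   (post/baseline), `tolerance_fraction`, `pass`.
#' @export
mfr_recovery_check <- function(baseline, post, tolerance_fraction = 0.2) {
  mfr_b <- mean_firing_rate(baseline)
  mfr_p <- mean_firing_rate(post)
  if (mfr_b == 0) {
    abort("baseline MFR is zero; recovery ratio is undefined.",
          class = "spikesync_analysis_error")
  }
  tibble(mfr_baseline = mfr_b, mfr_post = mfr_p, ratio = mfr_p / mfr_b,
         tolerance_fraction = tolerance_fraction,
         pass = abs(mfr_p - mfr_b) <= tolerance_fraction * mfr_b)
}
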