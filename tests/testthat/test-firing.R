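test_that("inter-spike intervals telescope correctly", {
  expect_equal(isi(c(0.1, 0.2, 0.4)), c(0.1, 0.2))
  expect_equal(isi(0.5), double())
  expect_equal(isi(double()), double())
  set.seed(2)
  for (i in 1:10) {
    tt <- sort(runif(sample(2:30, 1), 0, 10))
    iv <- isi(tt)
    expect_true(all(iv > 0) || any(duplicated(tt)))
    expect_equal(sum(iv), max(tt) - min(tt))
  }
})

test_that("joint ISI histogram pools consecutive pairs across channels", {
  reg <- tibble::tibble(channel = "c1", time_s = (0:99) * 0.01)
  h <- joint_isi_hist(reg, duration = 2)
  expect_equal(h$n_pairs, 98L)
  expect_equal(sum(h$counts > 0), 1)  # a single cell holds every pair
  expect_equal(max(h$counts), 98L)

  two <- dplyr::bind_rows(reg, dplyr::mutate(reg, channel = "c2"))
  h2 <- joint_isi_hist(two, duration = 2)
  expect_equal(h2$n_pairs, 196L)
  expect_equal(max(h2$counts), 196L)

  sparse <- tibble::tibble(channel = "c1", time_s = c(0.1, 0.2))
  expect_error(joint_isi_hist(sparse, duration = 1),
               class = "spikesync_analysis_error")
})

test_that("joint ISI counts satisfy the per-channel counting identity", {
  set.seed(5)
  for (i in 1:15) {
    rec <- random_recording(n_channels = 5, duration = 20)
    wide <- 10^seq(-5, 3, length.out = 30)  # spans all possible intervals
    h <- joint_isi_hist(rec, bin_edges = wide)
    n_per <- table(rec$spikes$channel)
    expect_equal(h$n_pairs + h$n_out_of_range,
                 sum(pmax(0, as.integer(n_per) - 2)))
    expect_equal(h$n_out_of_range, 0L)
    expect_equal(sum(h$counts), h$n_pairs)
  }
})

test_that("short-interval metrics count doubly-short consecutive pairs", {
  reg <- tibble::tibble(channel = "c1", time_s = (0:50) * 0.01)
  m <- short_interval_metrics(reg, duration = 1)
  expect_equal(m$proportion, 1)

  slow <- tibble::tibble(channel = "c1", time_s = 0:9)
  m2 <- short_interval_metrics(slow, duration = 10)
  expect_equal(m2$proportion, 0)

  # alternating 10 ms / 500 ms intervals: no two consecutive short ISIs
  tt <- cumsum(rep(c(0.01, 0.5), 10))
  alt <- tibble::tibble(channel = "c1", time_s = c(0, tt))
  m3 <- short_interval_metrics(alt, duration = 12)
  expect_equal(m3$count, 0L)
  expect_gt(m3$total, 0)

  # the single-interval reading is available as a mode
  m4 <- short_interval_metrics(alt, duration = 12, mode = "isi")
  expect_equal(m4$proportion, 0.5)
})

test_that("firing rates average over all declared channels", {
  rec <- trial_recording(
    tibble::tibble(channel = "a", time_s = seq(0, 179, length.out = 180)),
    duration = 180, channels = c("a", "b"))
  fr <- firing_rate(rec)
  expect_equal(fr$rate_hz[fr$channel == "a"], 1)
  expect_equal(fr$rate_hz[fr$channel == "b"], 0)
  expect_equal(mean_firing_rate(rec), 0.5)

  set.seed(6)
  for (i in 1:10) {
    r <- random_recording(4, duration = 15)
    expect_equal(mean_firing_rate(r),
                 nrow(r$spikes) / (length(r$channels) * r$duration))
  }
})

test_that("burst detection finds maximal qualifying runs", {
  b <- detect_bursts(c(0, 0.01, 0.02, 0.03))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 4L)
  expect_equal(b$start_s, 0)
  expect_equal(b$end_s, 0.03)

  expect_equal(nrow(detect_bursts(0:10 * 1.0)), 0)

  b3 <- detect_bursts(c(0, 0.05, 0.3, 0.35, 0.40, 2.0))
  expect_equal(nrow(b3), 1)  # the first 2-spike run is below min_spikes
  expect_equal(b3$start_s, 0.3)
  expect_equal(b3$end_s, 0.40)
  expect_equal(b3$n_spikes, 3L)

  # bursts are ordered and non-overlapping
  set.seed(9)
  for (i in 1:10) {
    tt <- sort(runif(60, 0, 5))
    bb <- detect_bursts(tt, max_isi_s = 0.05)
    if (nrow(bb) > 1) {
      expect_true(all(diff(bb$start_s) > 0))
      expect_true(all(bb$start_s[-1] > bb$end_s[-nrow(bb)]))
    }
    expect_true(all(bb$n_spikes >= 3))
  }
})

test_that("burst spike rate is a proportion with expected monotonicity", {
  tt <- c(0, 0.01, 0.02, 0.03, 1, 2, 3, 4, 5, 6)  # 4 of 10 in one burst
  rec <- tibble::tibble(channel = "c1", time_s = tt)
  expect_equal(burst_spike_rate(rec, duration = 7), 0.4)
  expect_equal(burst_spike_rate(
    tibble::tibble(channel = "c1", time_s = 0:9 * 1.0), duration = 10), 0)
  expect_equal(burst_spike_rate(
    tibble::tibble(channel = "c1", time_s = 0:9 * 0.01), duration = 1), 1)
  expect_error(burst_spike_rate(
    tibble::tibble(channel = character(), time_s = double()), duration = 1),
    class = "spikesync_analysis_error")

  set.seed(10)
  rec2 <- random_recording(3, duration = 10, max_rate = 8)
  # non-increasing in min_spikes, non-decreasing in max_isi
  r_by_min <- sapply(2:6, function(m) {
    burst_spike_rate(rec2, min_spikes = m)
  })
  expect_true(all(diff(r_by_min) <= 1e-12))
  r_by_isi <- sapply(c(0.02, 0.05, 0.1, 0.3, 1), function(w) {
    burst_spike_rate(rec2, max_isi_s = w)
  })
  expect_true(all(diff(r_by_isi) >= -1e-12))
})

test_that("MFR recovery check compares against a relative tolerance", {
  base <- trial_recording(
    tibble::tibble(channel = "a", time_s = seq(0.5, 9.5, length.out = 10)),
    duration = 10)
  near <- trial_recording(
    tibble::tibble(channel = "a", time_s = seq(0.5, 9.5, length.out = 11)),
    duration = 10)
  far <- trial_recording(
    tibble::tibble(channel = "a", time_s = seq(0.1, 9.9, length.out = 15)),
    duration = 10)
  at_bound <- trial_recording(
    tibble::tibble(channel = "a", time_s = seq(0.1, 9.9, length.out = 12)),
    duration = 10)
  expect_true(mfr_recovery_check(base, near)$pass)
  expect_false(mfr_recovery_check(base, far)$pass)
  expect_true(mfr_recovery_check(base, at_bound)$pass)  # boundary inclusive

  silent <- trial_recording(
    tibble::tibble(channel = "a", time_s = double()),
    duration = 10, channels = "a")
  expect_error(mfr_recovery_check(silent, base),
               class = "spikesync_analysis_error")
})
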