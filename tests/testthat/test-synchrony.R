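test_that("spikes land in half-open bins and trailing spikes are dropped", {
  rec <- trial_recording(
    data.frame(channel = "c1", time_s = c(0.05, 0.15, 0.15001)),
    duration = 0.3)
  b <- bin_spikes(rec, 0.1)
  expect_equal(as.integer(b$counts["c1", ]), c(1L, 2L, 0L))

  silent <- trial_recording(
    data.frame(channel = "c1", time_s = 0.01),
    duration = 1, channels = c("c1", "c2"))
  b2 <- bin_spikes(silent, 0.25)
  expect_equal(sum(b2$counts["c2", ]), 0L)
  expect_equal(ncol(b2$counts), 4)

  # a spike past the last full bin is discarded and counted
  rec3 <- trial_recording(
    data.frame(channel = "c1", time_s = c(0.1, 0.65)), duration = 0.7)
  expect_message(b3 <- bin_spikes(rec3, 0.2), "discarded 1")
  expect_equal(b3$n_discarded, 1L)
  expect_equal(sum(b3$counts), 1L)

  expect_error(bin_spikes(rec, -0.1), class = "spikesync_validation_error")
})

test_that("binned counts conserve the number of in-range spikes", {
  set.seed(8)
  for (i in 1:20) {
    rec <- random_recording(n_channels = 4, duration = runif(1, 3, 12))
    w <- runif(1, 0.05, 1)
    n_bins <- floor(rec$duration / w)
    b <- suppressMessages(bin_spikes(rec, w))
    expect_equal(sum(b$counts), sum(rec$spikes$time_s < n_bins * w))
  }
})

test_that("activity threshold is rate-based and boundary inclusive", {
  rec <- trial_recording(
    data.frame(channel = rep("a", 18), time_s = seq(0, 170, length.out = 18)),
    duration = 180, channels = c("a", "b"))
  expect_equal(active_channels(rec, 0.1), "a")      # 18/180 = 0.1 exactly
  expect_equal(active_channels(rec, 0.11), character(0))
  expect_equal(active_channels(rec, 0), c("a", "b"))
})

test_that("pearson matrix matches hand-computed coefficients", {
  counts <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1),
                  d = c(1, 0, 1, 0), e = c(1, 0, 0, 1))
  binned <- structure(list(counts = counts, channels = rownames(counts),
                           bin_width_s = 1, duration_s = 4,
                           n_discarded = 0L),
                      class = "binned_counts")
  r <- pearson_matrix(binned)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["d", "e"], 0)  # covariance terms cancel exactly
  expect_true(isSymmetric(unclass(r)))
  expect_equal(unname(diag(unclass(r))), rep(1, 5))
  expect_true(all(abs(unclass(r)) <= 1 + 1e-12))
})

test_that("zero-variance channels become missing entries, never zero", {
  counts <- rbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(3, 1, 2))
  binned <- structure(list(counts = counts, channels = rownames(counts),
                           bin_width_s = 1, duration_s = 3,
                           n_discarded = 0L),
                      class = "binned_counts")
  expect_warning(r <- pearson_matrix(binned),
                 class = "spikesync_zero_variance_warning")
  expect_true(is.na(r["a", "b"]))
  expect_equal(r["b", "b"], 1)
  expect_false(is.na(r["a", "c"]))

  expect_error(pearson_matrix(binned, active_ids = "a"),
               class = "spikesync_analysis_error")
})

test_that("functional edges match a brute-force threshold count", {
  m <- random_sync_matrix(3)
  m[upper.tri(m)] <- 0.9
  m[lower.tri(m)] <- 0.9
  expect_equal(nrow(functional_edges(m, 0.3)), 3)
  expect_equal(nrow(functional_edges(m, 1.0)), 0)

  set.seed(13)
  for (i in 1:20) {
    m <- random_sync_matrix(10)
    thr <- runif(1, -0.5, 0.9)
    g <- functional_edges(m, thr)
    brute <- 0
    for (a in 1:9) for (b in (a + 1):10) {
      if (!is.na(m[a, b]) && m[a, b] >= thr) brute <- brute + 1
    }
    expect_equal(nrow(g), brute)
    expect_true(all(g$weight >= thr))
    expect_true(all(g$from != g$to))
    # raising the threshold never adds edges
    expect_lte(nrow(functional_edges(m, min(1, thr + 0.2))), nrow(g))
  }
})

test_that("NA pairs never become edges", {
  m <- random_sync_matrix(4)
  m[1, 2] <- m[2, 1] <- NA_real_
  g <- functional_edges(m, -0.99)
  expect_equal(nrow(g), 5)
})

test_that("mean synchrony averages all defined active pairs", {
  m <- random_sync_matrix(3)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- 0.6
  expect_equal(mean_synchrony(m), 0.4)

  set.seed(14)
  for (i in 1:10) {
    m <- random_sync_matrix(8)
    expect_equal(mean_synchrony(m), mean(m[upper.tri(m)]))
  }

  m2 <- random_sync_matrix(2)
  m2[1, 2] <- m2[2, 1] <- NA_real_
  expect_error(mean_synchrony(m2), class = "spikesync_analysis_error")
})

test_that("activity index is edge count times mean edge weight", {
  m <- random_sync_matrix(6)
  g <- functional_edges(m, 0.3)
  expect_equal(sync_activity_index(g),
               nrow(g) * mean(g$weight))
  g0 <- functional_edges(m, 1.0)
  expect_equal(sync_activity_index(g0), 0)

  ten <- random_sync_matrix(5)
  ten[upper.tri(ten)] <- 0.5
  ten[lower.tri(ten)] <- 0.5
  expect_equal(sync_activity_index(functional_edges(ten, 0.3)), 5)
})

test_that("mean synchrony increases with the within-community coupling", {
  sweep_a <- c(2, 6, 10, 14, 18)
  means <- sapply(seq_along(sweep_a), function(i) {
    vals <- sapply(1:8, function(s) {
      gt <- generate_ground_truth(20, 2, a_within = sweep_a[i],
                                  a_global = 0)
      rec <- simulate_trial(gt, seed = 400 + 10 * i + s, duration_s = 60)
      mean_synchrony(synchrony_matrix(rec))
    })
    mean(vals)
  })
  expect_gt(cor(sweep_a, means, method = "spearman"), 0.9)
})
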