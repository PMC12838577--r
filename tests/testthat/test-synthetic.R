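test_that("ground-truth communities are contiguous, near-equal blocks", {
  gt <- generate_ground_truth(60, 4)
  expect_equal(unname(table(gt$community_of)), rep(15L, 4),
               ignore_attr = TRUE)
  expect_equal(length(gt$channels), 60)

  gt5 <- generate_ground_truth(5, 5)
  expect_equal(sort(as.integer(table(gt5$community_of))), rep(1L, 5))

  gt7 <- generate_ground_truth(7, 3)
  expect_equal(sort(as.integer(table(gt7$community_of)), decreasing = TRUE),
               c(3L, 2L, 2L))
  # contiguity: labels are non-decreasing along the channel order
  expect_true(all(diff(gt7$community_of) >= 0))

  expect_error(generate_ground_truth(3, 4),
               class = "spikesync_validation_error")
})

test_that("stimulus effect follows the gain model and control identity", {
  e0 <- stimulus_effect(0, 0)
  expect_equal(unclass(e0), list(rate_mult = 1, sync_mult = 1,
                                 burst_mult = 1))

  expect_equal(stimulus_effect(40, 100)$rate_mult, 1.5)
  expect_equal(stimulus_effect(40, 1000)$rate_mult, 1.1)
  expect_equal(stimulus_effect(40, 10000)$rate_mult, 0.7)
  expect_equal(stimulus_effect(7.8, 100)$rate_mult, 0.7)
  expect_equal(stimulus_effect(7.8, 10000)$rate_mult, 0.7)

  gaps <- sapply(c(100, 1000, 10000), function(n) {
    abs(stimulus_effect(40, n)$rate_mult - stimulus_effect(7.8, n)$rate_mult)
  })
  expect_equal(gaps, c(0.8, 0.4, 0.0))

  expect_error(stimulus_effect(40, 0), class = "spikesync_validation_error")
  expect_error(stimulus_effect(0, 100), class = "spikesync_validation_error")
  expect_error(stimulus_effect(13, 100), class = "spikesync_validation_error")
})

test_that("the 40 vs 7.8 Hz effect gap is non-increasing in pulse count", {
  set.seed(21)
  n_grid <- sort(unique(round(10^runif(40, 2, 5))))
  for (mult in c("rate_mult", "sync_mult", "burst_mult")) {
    gap <- sapply(n_grid, function(n) {
      abs(stimulus_effect(40, n)[[mult]] - stimulus_effect(7.8, n)[[mult]])
    })
    expect_true(all(diff(gap) <= 1e-12))
  }
  # clamping keeps the guarantee even for gains where the raw 40 Hz curve
  # would cross below the 7.8 Hz level
  params <- stimulus_effect_params()
  params$rate <- list(g40 = 0.5, c40 = 1.2, floor40 = 0.1, g78 = 0.3)
  gap <- sapply(n_grid, function(n) {
    abs(stimulus_effect(40, n, params)$rate_mult -
          stimulus_effect(7.8, n, params)$rate_mult)
  })
  expect_true(all(diff(gap) <= 1e-12))
})

test_that("simulation is deterministic given the seed", {
  gt <- generate_ground_truth(10, 2)
  a <- simulate_trial(gt, seed = 99, duration_s = 20)
  b <- simulate_trial(gt, seed = 99, duration_s = 20)
  c <- simulate_trial(gt, seed = 100, duration_s = 20)
  expect_identical(a$spikes, b$spikes)
  expect_false(isTRUE(all.equal(a$spikes, c$spikes)))
})

test_that("uncoupled channels realize the analytic Poisson rate", {
  gt <- generate_ground_truth(60, 4, base_rate_hz = 1, a_within = 0,
                              a_global = 0)
  rec <- simulate_trial(gt, seed = 5, duration_s = 180)
  # total count ~ Poisson(60 * 180); within 3 SD
  lambda <- 60 * 180
  expect_lt(abs(nrow(rec$spikes) - lambda), 3 * sqrt(lambda))
  # and pairwise synchrony vanishes on average
  sm <- synchrony_matrix(rec, bin_width_s = 0.1)
  expect_lt(abs(mean(unclass(sm)[upper.tri(sm)])), 0.02)
})

test_that("sub-millisecond trials are almost surely silent", {
  gt <- generate_ground_truth(5, 1)
  rec <- simulate_trial(gt, seed = 1, duration_s = 0.001)
  expect_lte(nrow(rec$spikes), 1)
  expect_equal(length(rec$channels), 5)
})

test_that("planted communities raise within- over between-community synchrony", {
  gt <- generate_ground_truth()
  within <- outer(gt$community_of, gt$community_of, "==")
  hits <- 0
  n_runs <- 40
  for (s in seq_len(n_runs)) {
    rec <- simulate_trial(gt, seed = 1000 + s)
    r <- unclass(synchrony_matrix(rec))
    ut <- upper.tri(r)
    if (mean(r[ut & within], na.rm = TRUE) >
        mean(r[ut & !within], na.rm = TRUE)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("disrupt/stabilize series follow the protocol order", {
  gt <- generate_ground_truth(20, 4)
  series <- generate_disrupt_stabilize_series(gt, seeds = 1:8,
                                              duration_s = 30)
  expect_length(series, 8)
  expect_equal(purrr::map_chr(series, ~ .x$condition$paradigm),
               c("control", rep("disrupt", 3), rep("stabilize", 3),
                 "control"),
               ignore_attr = TRUE)
  expect_error(generate_disrupt_stabilize_series(gt, seeds = 1:5),
               class = "spikesync_validation_error")
})

test_that("rhythmic series covers control plus the frequency/pulse grid", {
  gt <- generate_ground_truth(12, 3)
  recs <- generate_rhythmic_series(gt, duration_s = 10, seed = 2)
  expect_length(recs, 7)
  expect_equal(recs[[1]]$condition$paradigm, "control")
  conds <- purrr::map(recs[-1], "condition")
  expect_setequal(purrr::map_dbl(conds, "frequency_hz"),
                  c(40, 40, 40, 7.8, 7.8, 7.8))
  expect_setequal(unique(purrr::map_dbl(conds, "n_pulses")),
                  c(100, 1000, 10000))
})
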