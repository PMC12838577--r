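#' Analysis configuration
#'
#' One object holding every tunable of the trial-series workflows; it is
#' hashed and the hash is embedded in all written outputs, so results from
#' different configurations are detectable.
#'
#' @param bin_width_s Spike-count bin width, seconds.
#' @param min_rate_hz Active-channel threshold, Hz.
#' @param edge_threshold Functional-edge Pearson threshold.
#' @param gamma Louvain resolution.
#' @param seed Base seed for partitioning (per-trial seeds derive from it).
#' @param burst_max_isi_s,burst_min_spikes Burst-detection parameters.
#' @param isi_bin_edges Joint-ISI histogram bin edges, seconds.
#' @param short_window_s Short-interval window, seconds.
#' @param short_mode `"pair"` or `"isi"` (see [short_interval_metrics()]).
#' @return A list of class `analysis_config` with a `hash` field.
#' @export
analysis_config <- function(bin_width_s = 0.1, min_rate_hz = 0.1,
                            edge_threshold = 0.3, gamma = 1, seed = 1L,
                            burst_max_isi_s = 0.1, burst_min_spikes = 3,
                            isi_bin_edges = default_isi_edges(),
                            short_window_s = 0.05,
                            short_mode = c("pair", "isi")) {
  short_mode <- match.arg(short_mode)
  cfg <- list(bin_width_s = bin_width_s, min_rate_hz = min_rate_hz,
              edge_threshold = edge_threshold, gamma = gamma,
              seed = as.integer(seed), burst_max_isi_s = burst_max_isi_s,
              burst_min_spikes = burst_min_spikes,
              isi_bin_edges = isi_bin_edges,
              short_window_s = short_window_s, short_mode = short_mode)
  cfg$hash <- hash(cfg)
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(
    "<analysis_config> bin %g s, min rate %g Hz, edge r >= %g, gamma %g, seed %d [%s]\n",
    x$bin_width_s, x$min_rate_hz, x$edge_threshold, x$gamma, x$seed,
    substr(x$hash, 1, 8)))
  invisible(x)
}

resolve_trials <- function(trials, dir = ".") {
  if (is.data.frame(trials)) {
    return(load_manifest_trials(trials, dir))
  }
  stopifnot(is.list(trials),
            all(vapply(trials, inherits, logical(1), "trial_recording")))
  ids <- map_chr(trials, function(r) r$trial_id %||% NA_character_)
  if (anyNA(ids)) {
    ids <- ifelse(is.na(ids), sprintf("trial%02d", seq_along(trials)), ids)
    trials <- map2(trials, ids, function(r, id) { r$trial_id <- id; r })
  }
  setNames(trials, ids)
}

# Synchrony matrix -> graph -> partition -> sequence for one trial.
# An edgeless graph cannot be partitioned by modularity; every active node
# then forms its own community (logged via the `note` field).
analyse_trial_connectivity <- function(rec, config, node_order, seed) {
  act <- active_channels(rec, config$min_rate_hz)
  sm <- synchrony_matrix(rec, config$bin_width_s, config$min_rate_hz)
  graph <- functional_edges(sm, config$edge_threshold)
  note <- NA_character_
  if (nrow(graph) > 0) {
    part <- louvain(graph, gamma = config$gamma, seed = seed)
  } else {
    part <- tibble(node = attr(graph, "nodes"),
                   community = seq_along(attr(graph, "nodes")))
    note <- "edgeless graph: singleton communities, Q undefined"
  }
  seq_sym <- affiliation_sequence(part, node_order)
  list(
    active = act, matrix = sm, graph = graph, partition = part,
    sequence = seq_sym,
    row = tibble(
      trial_id = rec$trial_id,
      paradigm = rec$condition$paradigm,
      frequency_hz = rec$condition$frequency_hz,
      n_pulses = rec$condition$n_pulses,
      n_active = length(act),
      n_edges = nrow(graph),
      mean_edge_weight = if (nrow(graph) > 0) mean(graph$weight) else NA_real_,
      mean_synchrony = mean_synchrony(sm),
      activity_index = sync_activity_index(graph),
      modularity = attr(part, "modularity") %||% NA_real_,
      n_communities = length(unique(part$community)),
      sequence = paste(seq_sym, collapse = ""),
      note = note))
}

#' Connectivity-series workflow
#'
#' Runs the full functional-connectivity pipeline over an ordered series
#' of trials: active-channel filtering, binned-count Pearson synchrony,
#' edge thresholding, Louvain partitioning, canonical affiliation
#' sequences, and Levenshtein network similarity of each trial to its
#' immediate predecessor (the first trial has none). The summary reports
#' per-paradigm means of edge count, mean synchrony and similarity.
#'
#' @param trials Ordered list of [trial_recording()]s, or a manifest
#'   tibble ([read_manifest()]) whose spike tables are then loaded.
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; per-trial artifacts (synchrony
#'   matrices, edge lists, partitions) and the summary CSVs are written
#'   there, each carrying the config hash.
#' @param dir Base directory for manifest paths.
#' @return A `connectivity_report`: list with `trials` (per-trial tibble,
#'   including `similarity_to_prev`), `summary` (per-paradigm tibble),
#'   `config`.
#' @export
run_connectivity_series <- function(trials, config = analysis_config(),
                                    out_dir = NULL, dir = ".") {
  recs <- resolve_trials(trials, dir)
  if (length(recs) < 2) {
    abort("a connectivity series needs at least 2 trials.",
          class = "spikesync_validation_error")
  }
  node_order <- sort(unique(unlist(map(recs, "channels"))))
  # one partition seed for every trial: identical graphs then partition
  # identically, so identical trials always reach similarity 1
  results <- imap(unname(recs), function(rec, i) {
    analyse_trial_connectivity(rec, config, node_order, config$seed)
  })
  rows <- list_rbind(map(results, "row"))
  sims <- c(NA_real_, map_dbl(seq_len(length(results) - 1), function(i) {
    network_similarity(results[[i + 1]]$sequence, results[[i]]$sequence)
  }))
  rows$similarity_to_prev <- sims
  summary <- rows %>%
    group_by(.data$paradigm) %>%
    summarise(n_trials = n(),
              mean_n_edges = mean(.data$n_edges),
              mean_edge_weight = mean(.data$mean_edge_weight, na.rm = TRUE),
              mean_synchrony = mean(.data$mean_synchrony),
              mean_similarity = mean(.data$similarity_to_prev, na.rm = TRUE),
              .groups = "drop")
  report <- structure(
    list(trials = rows, summary = summary, config = config,
         details = results),
    class = "connectivity_report")
  if (!is.null(out_dir)) write_connectivity_report(report, out_dir)
  report
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat(sprintf("<connectivity_report> %d trials [config %s]\n",
              nrow(x$trials), substr(x$config$hash, 1, 8)))
  print(x$summary)
  invisible(x)
}

#' @export
#' @method tidy connectivity_report
tidy.connectivity_report <- function(x, ...) x$trials

#' @export
#' @method glance connectivity_report
glance.connectivity_report <- function(x, ...) x$summary

write_connectivity_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- report$config$hash
  readr::write_csv(mutate(report$trials, config_hash = h),
                   file.path(out_dir, "trials.csv"))
  readr::write_csv(mutate(report$summary, config_hash = h),
                   file.path(out_dir, "summary.csv"))
  for (i in seq_along(report$details)) {
    d <- report$details[[i]]
    id <- report$trials$trial_id[[i]]
    readr::write_csv(mutate(as_tibble(d$graph), config_hash = h),
                     file.path(out_dir, sprintf("%s_edges.csv", id)))
    readr::write_csv(mutate(as_tibble(d$partition), config_hash = h),
                     file.path(out_dir, sprintf("%s_partition.csv", id)))
    sm <- as.data.frame(unclass(d$matrix))
    sm <- cbind(channel = rownames(d$matrix), sm)
    readr::write_csv(sm, file.path(out_dir, sprintf("%s_synchrony.csv", id)))
  }
  invisible(out_dir)
}

#' Rhythmic-stimulation workflow
#'
#' Computes per-trial firing-pattern and synchrony metrics (MFR, joint-ISI
#' short-interval count/proportion, burst spike rate, mean synchrony,
#' network synchronization activity index) for a control + rhythmic trial
#' series, summarises them per (frequency, pulse level), and reports the
#' absolute between-frequency difference of every metric at each pulse
#' level — the quantity whose shrinkage with pulse repetitions indicates
#' adaptive convergence.
#'
#' @inheritParams run_connectivity_series
#' @return A `rhythmic_report`: list with `trials` (per-trial metric
#'   tibble), `summary` (per-condition means), `gaps` (per pulse level and
#'   metric, `|40 Hz - 7.8 Hz|`), `config`.
#' @export
run_rhythmic_series <- function(trials, config = analysis_config(),
                                out_dir = NULL, dir = ".") {
  recs <- resolve_trials(trials, dir)
  rows <- map(unname(recs), function(rec) {
    sm <- synchrony_matrix(rec, config$bin_width_s, config$min_rate_hz)
    graph <- functional_edges(sm, config$edge_threshold)
    si <- short_interval_metrics(rec, config$short_window_s,
                                 config$short_mode)
    tibble(
      trial_id = rec$trial_id,
      paradigm = rec$condition$paradigm,
      frequency_hz = rec$condition$frequency_hz,
      n_pulses = rec$condition$n_pulses,
      mfr_hz = mean_firing_rate(rec),
      short_interval_count = si$count,
      short_interval_proportion = si$proportion,
      burst_spike_rate = burst_spike_rate(rec, config$burst_max_isi_s,
                                          config$burst_min_spikes),
      mean_synchrony = mean_synchrony(sm),
      n_edges = nrow(graph),
      activity_index = sync_activity_index(graph))
  }) %>% list_rbind()
  metrics <- c("mfr_hz", "short_interval_proportion", "burst_spike_rate",
               "mean_synchrony", "activity_index")
  summary <- rows %>%
    group_by(.data$paradigm, .data$frequency_hz, .data$n_pulses) %>%
    summarise(across(all_of(metrics), mean), n_trials = n(),
              .groups = "drop")
  rhythmic <- filter(rows, .data$paradigm == "rhythmic")
  gaps <- if (nrow(rhythmic) > 0 &&
              length(unique(rhythmic$frequency_hz)) == 2) {
    rhythmic %>%
      tidyr::pivot_longer(all_of(metrics), names_to = "metric",
                          values_to = "value") %>%
      group_by(.data$n_pulses, .data$metric, .data$frequency_hz) %>%
      summarise(value = mean(.data$value), .groups = "drop") %>%
      group_by(.data$n_pulses, .data$metric) %>%
      summarise(abs_gap = abs(diff(.data$value)), .groups = "drop")
  } else {
    tibble(n_pulses = double(), metric = character(), abs_gap = double())
  }
  report <- structure(
    list(trials = rows, summary = summary, gaps = gaps, config = config),
    class = "rhythmic_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- config$hash
    readr::write_csv(mutate(rows, config_hash = h),
                     file.path(out_dir, "rhythmic_trials.csv"))
    readr::write_csv(mutate(summary, config_hash = h),
                     file.path(out_dir, "rhythmic_summary.csv"))
    readr::write_csv(mutate(gaps, config_hash = h),
                     file.path(out_dir, "rhythmic_gaps.csv"))
  }
  report
}

#' @export
print.rhythmic_report <- function(x, ...) {
  cat(sprintf("<rhythmic_report> %d trials [config %s]\n",
              nrow(x$trials), substr(x$config$hash, 1, 8)))
  print(x$summary)
  invisible(x)
}

#' @export
#' @method tidy rhythmic_report
tidy.rhythmic_report <- function(x, ...) x$trials

#' @export
#' @method glance rhythmic_report
glance.rhythmic_report <- function(x, ...) x$summary
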