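#' Read a delimited spike table
#'
#' Spike tables are comma-separated text with two columns, `channel` and
#' `time_s` (header optional), one row per spike. Times are seconds from
#' trial start with a decimal point (no locale handling).
#'
#' @param path Path to the CSV file.
#' @param duration Trial duration in seconds; all times must satisfy
#'   `0 <= t < duration`.
#' @param channels Optional declared channel list; declared channels with no
#'   spikes become zero-spike trains.
#' @param trial_id,condition Passed through to [trial_recording()].
#' @return A [trial_recording()].
#' @details Rows need not be sorted; output trains are always sorted by
#'   channel then time. Exact duplicate rows are dropped with a warning.
#'   A non-numeric time raises a format error naming the offending line.
#' @export
read_spike_table <- function(path, duration, channels = NULL,
                             trial_id = NA_character_,
                             condition = stim_condition()) {
  if (!file.exists(path)) {
    abort(sprintf("spike table not found: %s", path),
          class = "spikesync_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(trial_recording(tibble(channel = character(), time_s = double()),
                           duration, trial_id = trial_id,
                           condition = condition, channels = channels))
  }
  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  has_header <- length(first) >= 2 &&
    is.na(suppressWarnings(as.numeric(trimws(first[[2]]))))
  body_idx <- if (has_header) seq_along(lines)[-1] else seq_along(lines)
  if (length(body_idx) == 0) {
    return(trial_recording(tibble(channel = character(), time_s = double()),
                           duration, trial_id = trial_id,
                           condition = condition, channels = channels))
  }
  parts <- strsplit(lines[body_idx], ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2)) {
    bad <- body_idx[which(nfield < 2)[1]]
    abort(sprintf("line %d of %s has fewer than 2 fields.", bad, path),
          class = "spikesync_format_error")
  }
  ch <- trimws(vapply(parts, `[[`, character(1), 1))
  tm_raw <- trimws(vapply(parts, `[[`, character(1), 2))
  tm <- suppressWarnings(as.numeric(tm_raw))
  if (anyNA(tm)) {
    bad <- which(is.na(tm))[1]
    abort(sprintf("non-numeric spike time %s on line %d of %s.",
                  deparse(tm_raw[bad]), body_idx[bad], path),
          class = "spikesync_format_error")
  }
  trial_recording(tibble(channel = ch, time_s = tm), duration,
                  trial_id = trial_id, condition = condition,
                  channels = channels)
}

#' Write a spike table
#'
#' Writes the canonical comma-separated form (`channel,time_s` header, rows
#' sorted by channel id then time) so that write-then-read is the identity
#' up to floating-point round-trip (times are written with 17 significant
#' digits, which round-trips doubles exactly).
#'
#' @param recording A [trial_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(recording, path) {
  stopifnot(inherits(recording, "trial_recording"))
  tryCatch(
    readr::write_csv(recording$spikes, path),  # shortest round-trip doubles
    error = function(e) {
      abort(sprintf("cannot write spike table to %s: %s", path,
                    conditionMessage(e)),
            class = "spikesync_io_error")
    })
  invisible(path)
}

#' Read a trial manifest
#'
#' A manifest is a YAML file with a top-level `trials:` list; each entry
#' carries `id`, `path`, `paradigm`, `frequency_hz`, `n_pulses` and
#' optionally `duration_s` and `group_label`. Trial order in the file is
#' preserved (downstream similarity compares each trial to its predecessor).
#'
#' @param path Manifest file path.
#' @param allowed_freqs Declared rhythmic stimulation frequencies.
#' @return A tibble with one row per trial, in file order, columns
#'   `trial_id`, `path`, `paradigm`, `frequency_hz`, `n_pulses`,
#'   `duration_s`, `group_label`.
#' @export
read_manifest <- function(path, allowed_freqs = c(7.8, 40)) {
  if (!file.exists(path)) {
    abort(sprintf("manifest not found: %s", path),
          class = "spikesync_io_error")
  }
  doc <- yaml::read_yaml(path)
  trials <- doc$trials %||% abort("manifest has no `trials:` list.",
                                  class = "spikesync_format_error")
  rows <- imap(trials, function(tr, i) {
    cond <- stim_condition(
      paradigm = tr$paradigm %||% abort(
        sprintf("manifest trial %d lacks a paradigm.", i),
        class = "spikesync_validation_error"),
      frequency_hz = tr$frequency_hz %||% 0,
      n_pulses = tr$n_pulses %||% 0,
      group_label = tr$group_label %||% NA_character_,
      allowed_freqs = allowed_freqs)
    tibble(trial_id = as.character(tr$id %||% sprintf("trial%02d", i)),
           path = as.character(tr$path %||% NA_character_),
           paradigm = cond$paradigm,
           frequency_hz = cond$frequency_hz,
           n_pulses = cond$n_pulses,
           duration_s = as.double(tr$duration_s %||% 180),
           group_label = cond$group_label)
  })
  list_rbind(rows)
}

#' Write a trial manifest
#'
#' @param manifest Tibble as returned by [read_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  trials <- purrr::pmap(manifest, function(trial_id, path, paradigm,
                                           frequency_hz, n_pulses,
                                           duration_s = 180,
                                           group_label = NA, ...) {
    tr <- list(id = trial_id, path = path, paradigm = paradigm,
               frequency_hz = frequency_hz, n_pulses = n_pulses,
               duration_s = duration_s)
    if (!is.na(group_label)) tr$group_label <- group_label
    tr
  })
  yaml::write_yaml(list(trials = trials), path)
  invisible(path)
}

#' Load all trials referenced by a manifest
#'
#' @param manifest Manifest tibble ([read_manifest()]).
#' @param dir Directory against which relative spike-table paths resolve.
#' @return Named list of [trial_recording()] objects, in manifest order.
#' @export
load_manifest_trials <- function(manifest, dir = ".") {
  recs <- purrr::pmap(manifest, function(trial_id, path, paradigm,
                                         frequency_hz, n_pulses,
                                         duration_s = 180,
                                         group_label = NA, ...) {
    fp <- if (file.exists(path)) path else file.path(dir, path)
    read_spike_table(
      fp, duration = duration_s, trial_id = trial_id,
      condition = stim_condition(paradigm, frequency_hz, n_pulses,
                                 group_label))
  })
  setNames(recs, manifest$trial_id)
}
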