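#' Stimulation condition metadata
#'
#' Describes the stimulation applied before a recording trial. `"control"`
#' trials carry no stimulation (`frequency_hz = 0`, `n_pulses = 0`);
#' `"rhythmic"` trials must use one of the declared stimulation frequencies
#' (theta-band 7.8 Hz or gamma-band 40 Hz by default); `"disrupt"` and
#' `"stabilize"` label the two plasticity-probing pulse paradigms.
#'
#' @param paradigm One of `"control"`, `"disrupt"`, `"stabilize"`,
#'   `"rhythmic"`.
#' @param frequency_hz Stimulation frequency in Hz (0 for control).
#' @param n_pulses Number of pulse repetitions delivered before the trial.
#' @param group_label Optional free-text group tag.
#' @param allowed_freqs Declared rhythmic stimulation frequencies.
#' @return A list of class `stim_condition`.
#' @export
#' @examples
#' stim_condition("rhythmic", frequency_hz = 40, n_pulses = 100)
stim_condition <- function(paradigm = "control", frequency_hz = 0,
                           n_pulses = 0, group_label = NA_character_,
                           allowed_freqs = c(7.8, 40)) {
  paradigms <- c("control", "disrupt", "stabilize", "rhythmic")
  if (!is.character(paradigm) || length(paradigm) != 1 ||
      !paradigm %in% paradigms) {
    abort(paste0("`paradigm` must be one of ",
                 paste(paradigms, collapse = ", "),
                 "; got ", deparse(paradigm), "."),
          class = "spikesync_validation_error")
  }
  frequency_hz <- as.double(frequency_hz)
  n_pulses <- as.double(n_pulses)
  if (!is.finite(frequency_hz) || frequency_hz < 0) {
    abort("`frequency_hz` must be a nonnegative number.",
          class = "spikesync_validation_error")
  }
  if (!is.finite(n_pulses) || n_pulses < 0 || n_pulses != floor(n_pulses)) {
    abort("`n_pulses` must be a nonnegative integer.",
          class = "spikesync_validation_error")
  }
  if (paradigm == "control" && (frequency_hz != 0 || n_pulses != 0)) {
    abort("control trials must have frequency_hz = 0 and n_pulses = 0.",
          class = "spikesync_validation_error")
  }
  if (paradigm == "rhythmic" &&
      !any(abs(frequency_hz - allowed_freqs) < 1e-9)) {
    abort(paste0("rhythmic trials must use a declared frequency (",
                 paste(allowed_freqs, collapse = ", "), " Hz)."),
          class = "spikesync_validation_error")
  }
  structure(
    list(paradigm = paradigm, frequency_hz = frequency_hz,
         n_pulses = n_pulses, group_label = group_label),
    class = "stim_condition"
  )
}

#' @export
print.stim_condition <- function(x, ...) {
  cat(sprintf("<stim_condition> %s (%g Hz, %g pulses)\n",
              x$paradigm, x$frequency_hz, x$n_pulses))
  invisible(x)
}

#' A single multichannel recording trial
#'
#' Bundles all channels' spike timestamps for one trial with its duration,
#' declared channel set and stimulation condition. Spike times are seconds
#' from trial start, stored at double precision (acquisition-clock
#' quantisation is treated as metadata, never applied). Channels declared in
#' `channels` but absent from `spikes` become zero-spike trains, so that
#' active-channel filtering downstream is meaningful.
#'
#' @param spikes Data frame with columns `channel` (character) and `time_s`
#'   (numeric, `0 <= t < duration`).
#' @param duration Trial duration in seconds (> 0).
#' @param trial_id Optional trial identifier.
#' @param condition A [stim_condition()].
#' @param channels Declared channel ids; defaults to the channels present
#'   in `spikes`.
#' @return An object of class `trial_recording` with elements `spikes`
#'   (canonically ordered tibble), `duration`, `channels`, `trial_id`,
#'   `condition`.
#' @export
#' @examples
#' trial_recording(
#'   data.frame(channel = c("ch1", "ch1", "ch2"),
#'              time_s = c(0.10, 0.25, 1.00)),
#'   duration = 3
#' )
trial_recording <- function(spikes, duration, trial_id = NA_character_,
                            condition = stim_condition(), channels = NULL) {
  if (!is.data.frame(spikes)) {
    abort("`spikes` must be a data frame with columns channel, time_s.",
          class = "spikesync_validation_error")
  }
  if (nrow(spikes) == 0 && !all(c("channel", "time_s") %in% names(spikes))) {
    spikes <- tibble(channel = character(), time_s = double())
  }
  if (!all(c("channel", "time_s") %in% names(spikes))) {
    abort("`spikes` must have columns `channel` and `time_s`.",
          class = "spikesync_validation_error")
  }
  duration <- as.double(duration)
  if (!is.finite(duration) || duration <= 0) {
    abort("`duration` must be finite and positive.",
          class = "spikesync_validation_error")
  }
  spikes <- tibble(channel = as.character(spikes$channel),
                   time_s = as.double(spikes$time_s))
  if (anyNA(spikes$time_s) || anyNA(spikes$channel)) {
    abort("`spikes` contains missing channel ids or times.",
          class = "spikesync_validation_error")
  }
  bad <- spikes$time_s < 0 | spikes$time_s >= duration
  if (any(bad)) {
    abort(sprintf(
      "%d spike time(s) outside [0, duration): first offending time %g s.",
      sum(bad), spikes$time_s[which(bad)[1]]),
      class = "spikesync_range_error")
  }
  ndup <- nrow(spikes) - nrow(distinct(spikes))
  if (ndup > 0) {
    warn(sprintf("dropped %d duplicate (channel, time) spike row(s).", ndup),
         class = "spikesync_dedup_warning")
    spikes <- distinct(spikes)
  }
  spikes <- arrange(spikes, .data$channel, .data$time_s)
  channels <- sort(unique(c(as.character(channels %||% character()),
                            spikes$channel)))
  if (inherits(condition, "stim_condition") == FALSE) {
    abort("`condition` must be a stim_condition object.",
          class = "spikesync_validation_error")
  }
  structure(
    list(trial_id = trial_id, condition = condition, spikes = spikes,
         channels = channels, duration = duration),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %s: %d spikes on %d/%d channels over %g s [%s]\n",
    x$trial_id %||% "?", nrow(x$spikes),
    length(unique(x$spikes$channel)), length(x$channels), x$duration,
    x$condition$paradigm))
  invisible(x)
}

#' @export
#' @method tidy trial_recording
tidy.trial_recording <- function(x, ...) {
  mutate(x$spikes, trial_id = x$trial_id, .before = 1)
}

#' Spike times of one channel
#'
#' @param recording A [trial_recording()].
#' @param channel Channel id.
#' @return Numeric vector of spike times (possibly empty), sorted ascending.
#' @export
spike_times <- function(recording, channel) {
  stopifnot(inherits(recording, "trial_recording"))
  recording$spikes$time_s[recording$spikes$channel == channel]
}

# Accepts a trial_recording or a bare spikes data frame (+ duration) and
# normalizes to a trial_recording. Internal plumbing for df-first interfaces.
as_trial_recording <- function(x, duration = NULL, channels = NULL) {
  if (inherits(x, "trial_recording")) return(x)
  if (is.data.frame(x)) {
    if (is.null(duration)) {
      abort("`duration` is required when passing a bare spike data frame.",
            class = "spikesync_validation_error")
    }
    return(trial_recording(x, duration, channels = channels))
  }
  abort("expected a trial_recording or a spike data frame.",
        class = "spikesync_validation_error")
}
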