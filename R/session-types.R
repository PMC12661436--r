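#' Construct a continuous signal (LFP channel)
#'
#' A uniformly sampled continuous recording, typically a local field
#' potential. All session times are in seconds on a single session clock
#' whose origin is `t0`.
#'
#' @param samples Numeric vector of samples (arbitrary units, e.g. uV).
#' @param rate Sampling rate in Hz; must be positive.
#' @param t0 Time of the first sample in seconds (session clock).
#' @param region Region label, e.g. "VP", "LHb", "MD", "mPFC", "ACC",
#'   "PrL", "AC".
#' @param channel_id Optional channel identifier.
#' @return An object of class `continuous_signal`.
#' @export
continuous_signal <- function(samples, rate, t0 = 0, region = "other",
                              channel_id = "ch1") {
  samples <- as.double(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop_validation("rate", "sampling rate must be a single positive number")
  if (any(!is.finite(samples)))
    stop_validation("samples", "samples must be finite")
  structure(
    list(samples = samples, rate = as.double(rate), t0 = as.double(t0),
         region = as.character(region), channel_id = as.character(channel_id)),
    class = "continuous_signal")
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("<continuous_signal> %s [%s]: %d samples @ %g Hz (%.3f s)\n",
              x$channel_id, x$region, length(x$samples), x$rate,
              signal_duration(x)))
  invisible(x)
}

#' Duration of a continuous signal in seconds
#' @param x A `continuous_signal`.
#' @return Duration `n_samples / rate` in seconds.
#' @export
signal_duration <- function(x) length(x$samples) / x$rate

#' Sample times of a continuous signal
#' @param x A `continuous_signal`.
#' @return Numeric vector of sample times (s), session clock.
#' @export
signal_times <- function(x) x$t0 + seq_along(x$samples - 1L) / x$rate - 1 / x$rate

#' Construct a spike train
#'
#' Sorted spike times for one unit. Times must be non-negative and strictly
#' increasing; duplicates closer than `dedup_tol` (spike-sorter artifacts)
#' are collapsed to one event with a warning.
#'
#' @param times Numeric vector of spike times in seconds.
#' @param unit_id Unit identifier.
#' @param region Region label.
#' @param dedup_tol Duplicate-collapse tolerance in seconds (default 1e-6).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, unit_id = "u1", region = "other",
                        dedup_tol = 1e-6) {
  times <- as.double(times)
  if (any(!is.finite(times))) stop_validation("times", "spike times must be finite")
  if (any(times < 0)) stop_validation("times", "spike times must be non-negative")
  if (is.unsorted(times)) stop_validation("times", "spike times must be sorted")
  if (length(times) > 1L) {
    dup <- c(FALSE, diff(times) < dedup_tol)
    if (any(dup)) {
      warning(sprintf("collapsed %d duplicate spike time(s) within %g s for unit %s",
                      sum(dup), dedup_tol, unit_id))
      times <- times[!dup]
    }
  }
  structure(list(times = times, unit_id = as.character(unit_id),
                 region = as.character(region)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s [%s]: %d spikes\n", x$unit_id, x$region,
              length(x$times)))
  invisible(x)
}

#' Construct a pulse train (stimulation clock)
#'
#' Laser on/off intervals plus the nominal frequency and duty cycle. Pulse
#' onsets define phase zero for all phase-locking analyses.
#'
#' @param onsets,offsets Pulse on/off times in seconds; equal length,
#'   `offsets[i] > onsets[i]`, onsets increasing.
#' @param freq Nominal stimulation frequency in Hz.
#' @param duty Duty cycle, a fraction in (0, 1].
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(onsets, offsets, freq, duty = 0.5) {
  onsets <- as.double(onsets); offsets <- as.double(offsets)
  if (length(onsets) != length(offsets))
    stop_validation("offsets", "onsets and offsets must have equal length")
  if (!is.numeric(freq) || freq <= 0) stop_validation("freq", "must be > 0")
  if (!is.numeric(duty) || duty <= 0 || duty > 1)
    stop_validation("duty", "must be in (0, 1]")
  if (length(onsets)) {
    if (is.unsorted(onsets, strictly = TRUE))
      stop_validation("onsets", "must be strictly increasing")
    if (any(offsets <= onsets))
      stop_validation("offsets", "each offset must exceed its onset")
  }
  structure(list(onsets = onsets, offsets = offsets, freq = as.double(freq),
                 duty = as.double(duty)),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses @ %g Hz, duty %.2f\n",
              length(x$onsets), x$freq, x$duty))
  invisible(x)
}

#' Construct a table of behavioral trial blocks
#'
#' @param type Character vector of trial types among
#'   `"S+A", "S-A", "S+B", "S-B", "plain"`.
#' @param start,end Block start/end times in seconds; `end > start` and
#'   blocks must not overlap.
#' @param opto Logical vector: was optogenetic light delivered in the block.
#' @return A `data.frame` with class `trial_blocks`.
#' @export
trial_blocks <- function(type, start, end, opto = FALSE) {
  valid <- c("S+A", "S-A", "S+B", "S-B", "plain")
  type <- as.character(type)
  if (!all(type %in% valid))
    stop_validation("type", "types must be among ", paste(valid, collapse = ", "))
  start <- as.double(start); end <- as.double(end)
  if (any(end <= start)) stop_validation("end", "block end must exceed start")
  if (length(start) > 1L) {
    o <- order(start)
    if (any(start[o][-1L] < end[o][-length(end)]))
      stop_validation("start", "blocks must not overlap")
  }
  df <- data.frame(type = type, start = start, end = end,
                   opto = rep_len(as.logical(opto), length(type)),
                   stringsAsFactors = FALSE)
  class(df) <- c("trial_blocks", "data.frame")
  df
}

#' Construct a behavioral event series (presses and rewards)
#'
#' @param presses Sorted lever-press times (s).
#' @param rewards Sorted reward times (s).
#' @return An object of class `event_series`.
#' @export
event_series <- function(presses = numeric(), rewards = numeric()) {
  presses <- as.double(presses); rewards <- as.double(rewards)
  if (is.unsorted(presses)) stop_validation("presses", "must be sorted")
  if (is.unsorted(rewards)) stop_validation("rewards", "must be sorted")
  structure(list(presses = presses, rewards = rewards),
            class = "event_series")
}

#' Assemble a recording session
#'
#' The session is the unit of analysis: continuous signals, sorted units,
#' stimulation pulse trains, behavioral trial blocks, and press/reward
#' events, all on one clock (seconds, origin at t0 = 0).
#'
#' @param signals List of [continuous_signal()] objects.
#' @param spikes List of [spike_train()] objects.
#' @param stim List of [pulse_train()] objects.
#' @param blocks A [trial_blocks()] data frame (or NULL).
#' @param events An [event_series()] (or NULL).
#' @param metadata Named list (subject, day, schedule, ...).
#' @return An object of class `session`.
#' @export
session <- function(signals = list(), spikes = list(), stim = list(),
                    blocks = NULL, events = NULL, metadata = list()) {
  s <- structure(list(signals = signals, spikes = spikes, stim = stim,
                      blocks = blocks, events = events %||% event_series(),
                      metadata = metadata),
                 class = "session")
  validate_session(s)
  s
}

#' Validate a session's invariants
#'
#' Checks every child object's invariants (types, sorted times, positive
#' rates, non-overlapping blocks) and errors naming the offending field.
#'
#' @param s A `session`.
#' @return The session, invisibly, if valid.
#' @export
validate_session <- function(s) {
  if (!inherits(s, "session")) stop_validation("session", "not a session object")
  for (x in s$signals)
    if (!inherits(x, "continuous_signal"))
      stop_validation("signals", "all entries must be continuous_signal")
  for (x in s$spikes) {
    if (!inherits(x, "spike_train"))
      stop_validation("spikes", "all entries must be spike_train")
    if (is.unsorted(x$times)) stop_validation("spikes.times", "unsorted")
  }
  for (x in s$stim)
    if (!inherits(x, "pulse_train"))
      stop_validation("stim", "all entries must be pulse_train")
  if (!is.null(s$blocks) && !inherits(s$blocks, "trial_blocks"))
    stop_validation("blocks", "must be a trial_blocks table")
  if (!inherits(s$events, "event_series"))
    stop_validation("events", "must be an event_series")
  invisible(s)
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %d signal(s), %d unit(s), %d pulse train(s), %d block(s), %d press(es)\n",
              length(x$signals), length(x$spikes), length(x$stim),
              if (is.null(x$blocks)) 0L else nrow(x$blocks),
              length(x$events$presses)))
  invisible(x)
}
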