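#' Spike phases relative to pulsatile stimulation
#'
#' The phase of each spike is `2*pi*f*(spt - t0) mod 2*pi`, where `f` is
#' the stimulation frequency and `spt` the spike time in seconds; phase 0
#' coincides with a pulse onset (t0 is the first pulse onset of the
#' analyzed train). With a 50% duty cycle, light-on maps to `[0, pi)`.
#' Spikes outside the stimulation epochs are excluded and counted.
#'
#' @param spikes A [spike_train()] or numeric spike times (s).
#' @param f Stimulation frequency in Hz.
#' @param t0 Phase origin: the first pulse onset (s).
#' @param epochs Optional data frame with `onset`, `offset` columns
#'   restricting spikes to stimulation-on epochs (e.g. from
#'   [group_pulse_trains()]). NULL keeps all spikes.
#' @return Numeric phases in `[0, 2*pi)`; attribute `"n_excluded"` counts
#'   spikes dropped for lying outside the epochs.
#' @export
spike_phases <- function(spikes, f, t0 = 0, epochs = NULL) {
  if (f <= 0) stop_domain("f must be > 0")
  spt <- if (inherits(spikes, "spike_train")) spikes$times else as.double(spikes)
  n0 <- length(spt)
  if (!is.null(epochs) && nrow(epochs)) {
    keep <- rep(FALSE, length(spt))
    for (i in seq_len(nrow(epochs)))
      keep <- keep | (spt >= epochs$onset[i] & spt < epochs$offset[i])
    spt <- spt[keep]
  }
  ph <- (2 * pi * f * (spt - t0)) %% (2 * pi)
  attr(ph, "n_excluded") <- n0 - length(spt)
  ph
}

#' Rayleigh test for circular uniformity
#'
#' Resultant length `R = |sum(exp(i*phi))| / n`, statistic `Z = n R^2`,
#' and the standard small-sample-corrected approximation to the p-value
#' (as in the circular-statistics toolbox's `circ_rtest`):
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` with `Rn = n R`.
#'
#' @param phases Phases in radians (n >= 2).
#' @return List: `R`, `Z`, `p`, `n`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 2) stop_domain("need at least 2 phases")
  C <- sum(cos(phases)); S <- sum(sin(phases))
  Rn <- sqrt(C^2 + S^2)
  R <- Rn / n
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(R = R, Z = Z, p = min(p, 1), n = n)
}

#' Circular mean, histogram mode, and phase histogram
#'
#' @param phases Phases in radians (n >= 1).
#' @param n_bins Number of histogram bins over `[0, 2*pi)` (default 18,
#'   i.e. 20-degree bins; ties in the mode resolve to the lowest bin).
#' @return List: `mean_phase` (circular mean in `[0, 2*pi)`, `NA` and
#'   flagged undefined when the resultant length is 0), `mode_phase`
#'   (center of the peak bin), `histogram` (data frame `bin_center`,
#'   `count`), `R`.
#' @export
preferred_phase <- function(phases, n_bins = 18) {
  if (length(phases) < 1) stop_domain("need at least 1 phase")
  if (n_bins < 4) stop_domain("need at least 4 bins")
  C <- mean(cos(phases)); S <- mean(sin(phases))
  R <- sqrt(C^2 + S^2)
  mean_phase <- if (R < 1e-12) NA_real_ else atan2(S, C) %% (2 * pi)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1L)
  idx <- findInterval(phases %% (2 * pi), edges, rightmost.closed = TRUE)
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  centers <- edges[-(n_bins + 1L)] + pi / n_bins
  out <- list(mean_phase = mean_phase,
              mode_phase = centers[which.max(counts)],
              histogram = data.frame(bin_center = centers, count = counts),
              R = R)
  if (is.na(mean_phase)) attr(out, "undefined_mean") <- TRUE
  out
}

#' Classify the preferred phase as light-on or light-off
#'
#' With phase 0 at pulse onset and duty cycle `duty`, the light-on
#' interval maps to `[0, 2*pi*duty)`; a unit whose circular mean falls
#' there fires preferentially while the laser is on (angles below 180
#' degrees at 50% duty), otherwise at light-off (the rebound side). The
#' boundary is excluded from light-on (half-open convention).
#'
#' @param mean_phase Circular mean phase in radians (NA -> unclassified).
#' @param duty Duty cycle (default 0.5).
#' @return `"light_on"`, `"light_off"`, or `NA` for an undefined mean.
#' @export
classify_side <- function(mean_phase, duty = 0.5) {
  if (is.na(mean_phase)) return(NA_character_)
  if (mean_phase %% (2 * pi) < 2 * pi * duty) "light_on" else "light_off"
}

#' Full phase-locking analysis of one unit at one frequency
#'
#' Computes spike phases on the stimulus clock, the Rayleigh test, the
#' preferred phase (circular mean and histogram mode), and the
#' light-on/light-off side. Locking is assessed per frequency condition
#' (no pooling across frequencies).
#'
#' @param spikes A [spike_train()].
#' @param stim A [pulse_train()]; phases use `stim$freq` and originate at
#'   the first pulse onset, restricted to the stimulation trains.
#' @param alpha Significance level for the Rayleigh test.
#' @param n_bins Histogram bins (default 18).
#' @return A `phase_locking_result` list: `unit_id`, `f`, `phases`, `R`,
#'   `rayleigh_p`, `mean_phase`, `mode_phase`, `n_spikes`, `locked`,
#'   `side`.
#' @export
phase_locking <- function(spikes, stim, alpha = 0.05, n_bins = 18) {
  stopifnot(inherits(spikes, "spike_train"), inherits(stim, "pulse_train"))
  trains <- group_pulse_trains(stim)
  ph <- spike_phases(spikes, f = stim$freq, t0 = stim$onsets[1L],
                     epochs = trains)
  if (length(ph) < 2) {
    return(structure(list(unit_id = spikes$unit_id, f = stim$freq,
                          phases = ph, R = NA_real_, rayleigh_p = NA_real_,
                          mean_phase = NA_real_, mode_phase = NA_real_,
                          n_spikes = length(ph), locked = FALSE,
                          side = NA_character_),
                     class = "phase_locking_result"))
  }
  rt <- rayleigh_test(ph)
  pp <- preferred_phase(ph, n_bins = n_bins)
  structure(list(unit_id = spikes$unit_id, f = stim$freq, phases = ph,
                 R = rt$R, rayleigh_p = rt$p, mean_phase = pp$mean_phase,
                 mode_phase = pp$mode_phase, n_spikes = length(ph),
                 locked = rt$p < alpha,
                 side = classify_side(pp$mean_phase, stim$duty)),
            class = "phase_locking_result")
}

#' @export
print.phase_locking_result <- function(x, ...) {
  cat(sprintf("<phase_locking_result> %s @ %g Hz: R = %.3f, p = %.3g, mean = %.1f deg, %s%s\n",
              x$unit_id, x$f, x$R, x$rayleigh_p,
              if (is.na(x$mean_phase)) NA else x$mean_phase * 180 / pi,
              if (isTRUE(x$locked)) "locked" else "not locked",
              if (is.na(x$side)) "" else paste0(" (", x$side, ")")))
  invisible(x)
}
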