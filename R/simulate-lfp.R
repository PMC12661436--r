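#' Define an LFP synthesis recipe
#'
#' The synthetic LFP is a sum of 1/f ("pink") background noise, a
#' stimulation-locked oscillation at the pulse-train frequency (with
#' optional odd harmonics approximating the square 50%-duty drive), gamma
#' bursts whose amplitude is gated by the behavioral state, and sparse
#' high-amplitude artifacts.
#'
#' @param pink_noise_sd SD of the 1/f background (a.u.).
#' @param entrain_amp Amplitude of the stimulation-locked component (a.u.).
#' @param entrain_phase_lag Phase lag of that component (rad).
#' @param harmonics Include harmonics (2f, 3f) at 1/k amplitude? The
#'   pulse-locked LFP deflection evoked by a square light pulse is not
#'   sinusoidal (distinct onset and offset transients), so its Fourier
#'   series carries energy at every multiple of the stimulation
#'   frequency, the first harmonic (2f, e.g. 80 Hz under 40 Hz
#'   stimulation) being the strongest. Default TRUE.
#' @param gamma_burst_amp Base gamma amplitude (a.u.).
#' @param gamma_freq Gamma frequency in Hz (default 50, within 40-60).
#' @param behavior_gate Named numeric vector mapping behavioral-state
#'   labels to gamma amplitude multipliers (e.g.
#'   `c(high = 2, low = 1)`). States not listed get multiplier 0.
#' @param artifact_rate Artifact events per second.
#' @param artifact_amp Artifact amplitude (a.u.).
#' @return An object of class `lfp_recipe`.
#' @export
lfp_recipe <- function(pink_noise_sd = 1, entrain_amp = 0,
                       entrain_phase_lag = 0, harmonics = TRUE,
                       gamma_burst_amp = 0, gamma_freq = 50,
                       behavior_gate = c(high = 1, low = 1),
                       artifact_rate = 0, artifact_amp = 0) {
  if (pink_noise_sd < 0 || entrain_amp < 0 || gamma_burst_amp < 0 ||
      artifact_amp < 0 || artifact_rate < 0)
    stop_domain("amplitudes and rates must be >= 0")
  if (gamma_freq <= 0) stop_domain("gamma_freq must be > 0")
  structure(list(pink_noise_sd = pink_noise_sd, entrain_amp = entrain_amp,
                 entrain_phase_lag = entrain_phase_lag, harmonics = harmonics,
                 gamma_burst_amp = gamma_burst_amp, gamma_freq = gamma_freq,
                 behavior_gate = behavior_gate, artifact_rate = artifact_rate,
                 artifact_amp = artifact_amp),
            class = "lfp_recipe")
}

# 1/f-amplitude noise via spectral shaping of white Gaussian noise,
# rescaled to the requested SD.
pink_noise <- function(n, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  k <- seq_len(n) - 1L
  fidx <- pmin(k, n - k)           # symmetric frequency index
  scale <- c(0, 1 / sqrt(fidx[-1L]))
  x <- Re(fft(W * scale, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

#' Simulate a local field potential
#'
#' @param recipe An [lfp_recipe()].
#' @param stim A [pulse_train()] driving the entrained component, or NULL.
#' @param states Data frame of labeled behavioral intervals with columns
#'   `state`, `start`, `end` (s), or NULL. Gamma amplitude at time t is
#'   `gamma_burst_amp * behavior_gate[state(t)]`; outside any interval the
#'   multiplier is the mean of the gate (ungated background), or 1 if the
#'   gate is empty.
#' @param rate Sampling rate in Hz; must be at least 4x the larger of the
#'   gamma and stimulation frequencies.
#' @param duration Duration in seconds.
#' @param seed Integer seed.
#' @param region,channel_id Labels for the returned signal.
#' @return A [continuous_signal()]; the ground-truth components
#'   (`pink`, `entrain`, `gamma`, `artifact`) are attached as attribute
#'   `"components"` so recovery tests never re-derive truth from the
#'   mixture.
#' @export
simulate_lfp <- function(recipe, stim = NULL, states = NULL, rate, duration,
                         seed, region = "VP", channel_id = "lfp1") {
  stopifnot(inherits(recipe, "lfp_recipe"))
  fmax <- max(recipe$gamma_freq,
              if (!is.null(stim)) stim$freq * (if (recipe$harmonics) 3 else 1) else 0)
  if (rate < 4 * max(recipe$gamma_freq, if (!is.null(stim)) stim$freq else 0))
    stop_domain("sampling rate must be >= 4x the highest component frequency")
  if (fmax >= rate / 2)
    stop_domain("component frequency exceeds Nyquist")
  n <- round(rate * duration)
  t <- (seq_len(n) - 1L) / rate

  comps <- with_seed(seed, {
    pink <- pink_noise(n, recipe$pink_noise_sd)

    entrain <- numeric(n)
    if (!is.null(stim) && recipe$entrain_amp > 0 && length(stim$onsets)) {
      on_mask <- rep(FALSE, n)
      for (i in seq_along(stim$onsets)) {
        lo <- stim$onsets[i]
        hi <- min(stim$offsets[i] + (1 - stim$duty) / stim$freq, duration)
        on_mask[t >= lo & t < hi] <- TRUE
      }
      ph <- 2 * pi * stim$freq * (t - stim$onsets[1L]) - recipe$entrain_phase_lag
      wave <- sin(ph)
      if (recipe$harmonics) wave <- wave + sin(2 * ph) / 2 + sin(3 * ph) / 3
      entrain <- recipe$entrain_amp * wave * on_mask
    }

    gamma <- numeric(n)
    if (recipe$gamma_burst_amp > 0) {
      mult <- rep(if (length(recipe$behavior_gate))
        mean(recipe$behavior_gate) else 1, n)
      if (!is.null(states) && nrow(states)) {
        for (i in seq_len(nrow(states))) {
          g <- recipe$behavior_gate[as.character(states$state[i])]
          if (is.na(g)) g <- 0
          mult[t >= states$start[i] & t < states$end[i]] <- g
        }
      }
      gamma <- recipe$gamma_burst_amp * mult *
        sin(2 * pi * recipe$gamma_freq * t + runif(1, 0, 2 * pi))
    }

    artifact <- numeric(n)
    if (recipe$artifact_rate > 0 && recipe$artifact_amp > 0) {
      n_art <- rpois(1L, recipe$artifact_rate * duration)
      if (n_art > 0) {
        at <- round(runif(n_art, 1, n))
        artifact[at] <- recipe$artifact_amp * sample(c(-1, 1), n_art, TRUE)
      }
    }
    list(pink = pink, entrain = entrain, gamma = gamma, artifact = artifact)
  })

  sig <- continuous_signal(comps$pink + comps$entrain + comps$gamma +
                             comps$artifact,
                           rate = rate, t0 = 0, region = region,
                           channel_id = channel_id)
  attr(sig, "components") <- comps
  sig
}
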