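#' Extract spike-centered LFP epochs
#'
#' One epoch of `2*round(half_window*rate) + 1` samples per spike,
#' centered on the LFP sample nearest the spike (200 ms epochs at the
#' default 100 ms half-window). Spikes too close to the signal edges for
#' full coverage are dropped and counted.
#'
#' @param lfp A [continuous_signal()].
#' @param spikes A [spike_train()] or numeric spike times (s).
#' @param half_window Half-window in seconds (default 0.1).
#' @return Matrix (epochs x samples) with attributes `rate`,
#'   `half_window`, `n_dropped`.
#' @export
spike_centered_epochs <- function(lfp, spikes, half_window = 0.1) {
  stopifnot(inherits(lfp, "continuous_signal"))
  spt <- if (inherits(spikes, "spike_train")) spikes$times else as.double(spikes)
  m <- round(half_window * lfp$rate)
  centers <- round((spt - lfp$t0) * lfp$rate) + 1L
  ok <- centers - m >= 1L & centers + m <= length(lfp$samples)
  n_dropped <- sum(!ok)
  centers <- centers[ok]
  if (!length(centers)) stop_domain("no spikes with full epoch coverage")
  ep <- vapply(centers,
               function(ci) lfp$samples[(ci - m):(ci + m)],
               numeric(2L * m + 1L))
  out <- t(ep)
  attr(out, "rate") <- lfp$rate
  attr(out, "half_window") <- half_window
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Spike-triggered average
#'
#' Pointwise mean of the spike-centered epochs.
#'
#' @param epochs Epoch matrix from [spike_centered_epochs()].
#' @return Numeric STA vector with attribute `lag_s` (lags in seconds,
#'   0 at the spike).
#' @export
spike_triggered_average <- function(epochs) {
  if (!is.matrix(epochs) || nrow(epochs) < 1) stop_domain("need >= 1 epoch")
  sta <- colMeans(epochs)
  rate <- attr(epochs, "rate")
  if (!is.null(rate)) {
    m <- (length(sta) - 1L) / 2
    attr(sta, "lag_s") <- (seq_along(sta) - 1L - m) / rate
  }
  sta
}

# One-sided power spectrum on the first 2m samples of each row (even
# length), so the frequency grid is exactly k / (2 * half_window) Hz.
epoch_power <- function(x, nfft) {
  X <- if (is.matrix(x)) mvfft(t(x[, seq_len(nfft), drop = FALSE])) else
    as.matrix(fft(x[seq_len(nfft)]))
  P <- Mod(X[seq_len(nfft / 2 + 1L), , drop = FALSE])^2
  P
}

#' Spike-field coherence
#'
#' The power spectrum of the spike-triggered average divided by the mean
#' of the individual epochs' power spectra on the same grid:
#' `SFC(f) = P_STA(f) / P_bar(f)`. The normalization by existing LFP
#' power makes the measure dimensionless and bounded in `[0, 1]`, with 1
#' meaning perfect locking. The frequency resolution is
#' `1 / (2 * half_window)` (5 Hz for 200 ms epochs).
#'
#' @param epochs Epoch matrix from [spike_centered_epochs()] (>= 2 rows).
#' @return A `spike_field_result` list: `freqs` (Hz), `sfc` (in `[0, 1]`;
#'   `NA` where the mean power is 0), `sta`, `p_bar`, `n_epochs`.
#' @export
spike_field_coherence <- function(epochs) {
  if (!is.matrix(epochs) || nrow(epochs) < 2) stop_domain("need >= 2 epochs")
  rate <- attr(epochs, "rate")
  if (is.null(rate)) stop_domain("epoch matrix lacks a sampling rate")
  n <- ncol(epochs)
  nfft <- if (n %% 2L == 1L) n - 1L else n
  sta <- spike_triggered_average(epochs)
  p_sta <- epoch_power(matrix(sta, nrow = 1), nfft)[, 1L]
  p_bar <- rowMeans(epoch_power(epochs, nfft))
  sfc <- ifelse(p_bar > 0, p_sta / p_bar, NA_real_)
  freqs <- (seq_len(nfft / 2 + 1L) - 1L) * rate / nfft
  structure(list(freqs = freqs, sfc = sfc, sta = sta, p_bar = p_bar,
                 n_epochs = nrow(epochs)),
            class = "spike_field_result")
}

#' @export
print.spike_field_result <- function(x, ...) {
  i <- which.max(x$sfc)
  cat(sprintf("<spike_field_result> %d epochs; SFC peak %.3f at %g Hz\n",
              x$n_epochs, x$sfc[i], x$freqs[i]))
  invisible(x)
}

#' Peak frequency of a spike-field coherence spectrum
#'
#' @param sf A `spike_field_result`.
#' @param fmin,fmax Frequency range searched (Hz).
#' @return Frequency (Hz) of the global SFC maximum in the range.
#' @export
sfc_argmax <- function(sf, fmin = 5, fmax = 100) {
  keep <- which(sf$freqs >= fmin & sf$freqs <= fmax & !is.na(sf$sfc))
  if (!length(keep)) stop_domain("no SFC bins in range")
  sf$freqs[keep[which.max(sf$sfc[keep])]]
}

#' Harmonic (second-largest local-maximum) frequency of an SFC spectrum
#'
#' Excludes the global maximum bin and its immediate neighbors, then
#' returns the frequency of the largest remaining local maximum — for a
#' square-pulse-entrained session, the first harmonic of the stimulation
#' frequency.
#'
#' @param sf A `spike_field_result`.
#' @param fmin,fmax Frequency range searched (Hz).
#' @param exclude_bins Bins on each side of the global maximum to exclude.
#' @return Frequency (Hz) of the secondary peak (NA when none exists).
#' @export
sfc_harmonic_peak <- function(sf, fmin = 5, fmax = 100, exclude_bins = 1) {
  keep <- which(sf$freqs >= fmin & sf$freqs <= fmax & !is.na(sf$sfc))
  if (length(keep) < 3) return(NA_real_)
  v <- sf$sfc[keep]; f <- sf$freqs[keep]
  gmax <- which.max(v)
  excluded <- abs(seq_along(v) - gmax) <= exclude_bins
  vpad <- c(-Inf, v, -Inf)
  is_locmax <- v >= vpad[seq_along(v)] & v >= vpad[seq_along(v) + 2L]
  cand <- which(is_locmax & !excluded)
  if (!length(cand)) return(NA_real_)
  f[cand[which.max(v[cand])]]
}

#' Compare spike-field coherence at a target vs a control frequency
#'
#' Splits the unit's spikes into contiguous, non-overlapping,
#' equal-spike-count segments, computes the SFC per segment, and applies
#' the normality-gated paired test to SFC(target) - SFC(control) across
#' segments (e.g. the stimulation frequency 40 Hz against the adjacent
#' 35 Hz control, both on the 5 Hz grid).
#'
#' @param lfp A [continuous_signal()].
#' @param spikes A [spike_train()].
#' @param f_target,f_control Target and control frequencies (Hz); must
#'   fall on the epoch frequency grid.
#' @param n_segments Number of segments (>= 5; default 10).
#' @param half_window Epoch half-window (s, default 0.1).
#' @param alpha Significance level.
#' @return List: `per_segment` (data frame `segment`, `sfc_target`,
#'   `sfc_control`), `delta` (mean difference), `test_used`, `statistic`,
#'   `p`, `significant`.
#' @export
compare_sfc <- function(lfp, spikes, f_target = 40, f_control = 35,
                        n_segments = 10, half_window = 0.1, alpha = 0.05) {
  if (n_segments < 5) stop_domain("need at least 5 segments")
  spt <- if (inherits(spikes, "spike_train")) spikes$times else as.double(spikes)
  if (length(spt) < 2 * n_segments)
    stop_domain("too few spikes for the requested segments")
  grp <- ceiling(seq_along(spt) / (length(spt) / n_segments))
  grp[grp > n_segments] <- n_segments
  at_bin <- function(sf, f0) {
    i <- which(abs(sf$freqs - f0) < 1e-9)
    if (!length(i)) stop_domain("frequency ", f0, " Hz is not on the SFC grid")
    sf$sfc[i]
  }
  vals <- lapply(seq_len(n_segments), function(g) {
    ep <- spike_centered_epochs(lfp, spt[grp == g], half_window = half_window)
    sf <- spike_field_coherence(ep)
    c(target = at_bin(sf, f_target), control = at_bin(sf, f_control))
  })
  tar <- vapply(vals, `[[`, numeric(1), "target")
  ctl <- vapply(vals, `[[`, numeric(1), "control")
  gt <- normality_gated_paired_test(tar, ctl, alpha = alpha)
  list(per_segment = data.frame(segment = seq_len(n_segments),
                                sfc_target = tar, sfc_control = ctl),
       delta = mean(tar - ctl), test_used = gt$test_used,
       statistic = gt$statistic, p = gt$p, significant = gt$significant)
}

#' Population test of target-vs-control SFC across sites
#'
#' Wilcoxon signed-rank test on the per-site mean SFC differences
#' (target minus control) across >= 5 recording sites.
#'
#' @param deltas Per-site mean differences (numeric, length >= 5).
#' @param alpha Significance level.
#' @return List: `statistic`, `p`, `significant`, `n_sites`.
#' @export
compare_sfc_population <- function(deltas, alpha = 0.05) {
  if (length(deltas) < 5) stop_domain("need at least 5 sites")
  ht <- suppressWarnings(wilcox.test(deltas, exact = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha, n_sites = length(deltas))
}
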