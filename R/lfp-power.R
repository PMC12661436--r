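#' Down-sample a continuous signal with anti-alias filtering
#'
#' Multistage decimation: the overall factor is split into stages of at
#' most 10, each stage applying a zero-phase (forward-backward)
#' Butterworth low-pass at 0.8x the stage's output Nyquist before taking
#' every q-th sample. At the default target of 200 Hz the final passband
#' edge is 80 Hz, well below the 100 Hz Nyquist. Only integer overall
#' factors are supported (the 25 kHz -> 200 Hz case is a factor of 125).
#'
#' @param x A [continuous_signal()].
#' @param target_rate Target rate in Hz (default 200); must divide the
#'   source rate.
#' @param order Butterworth order per stage (default 6; applied twice by
#'   filtfilt).
#' @return A [continuous_signal()] at `target_rate`.
#' @export
downsample <- function(x, target_rate = 200, order = 6) {
  stopifnot(inherits(x, "continuous_signal"))
  if (target_rate >= x$rate) stop_domain("target rate must be below source rate")
  q_total <- x$rate / target_rate
  if (abs(q_total - round(q_total)) > 1e-9)
    stop_domain("source rate must be an integer multiple of target rate")
  q_total <- round(q_total)
  samples <- x$samples
  remaining <- q_total
  while (remaining > 1) {
    q <- if (remaining <= 10) remaining else {
      divs <- which(remaining %% seq_len(10) == 0)
      divs <- divs[divs > 1]
      if (length(divs)) max(divs) else remaining   # prime factor: one stage
    }
    bf <- signal::butter(order, 0.8 / q, type = "low")
    # reflect-pad before zero-phase filtering to suppress edge transients
    np <- min(length(samples) - 1L, 500L)
    padded <- c(rev(samples[2:(np + 1L)]), samples,
                rev(samples[(length(samples) - np):(length(samples) - 1L)]))
    filtered <- signal::filtfilt(bf, padded)
    samples <- filtered[(np + 1L):(np + length(samples))]
    samples <- samples[seq(1L, length(samples), by = q)]
    remaining <- remaining / q
  }
  continuous_signal(samples, rate = target_rate, t0 = x$t0,
                    region = x$region, channel_id = x$channel_id)
}

#' Segment a signal into fixed epochs and reject artifact epochs
#'
#' Non-overlapping `epoch_len`-s epochs (a trailing remainder is
#' dropped). An epoch is excluded when any sample deviates from the
#' signal median by more than `k_sd` robust SDs (1.4826 x MAD), or when
#' it contains >= 3 consecutive identical extreme values (saturation).
#' Robust statistics keep the artifacts themselves from masking the
#' threshold.
#'
#' @param x A [continuous_signal()].
#' @param epoch_len Epoch length in seconds (default 1).
#' @param k_sd Rejection threshold in robust SDs (default 6).
#' @return List: `epochs` (matrix, epochs x samples), `kept` (logical
#'   mask), `epoch_times` (epoch center times, s), `rate`.
#' @export
epoch_and_reject <- function(x, epoch_len = 1, k_sd = 6) {
  stopifnot(inherits(x, "continuous_signal"))
  spe <- round(epoch_len * x$rate)
  n_ep <- floor(length(x$samples) / spe)
  if (n_ep < 1) stop_domain("signal shorter than one epoch")
  ep <- matrix(x$samples[seq_len(n_ep * spe)], nrow = n_ep, ncol = spe,
               byrow = TRUE)
  med <- median(x$samples)
  rsd <- stats::mad(x$samples)
  dev <- abs(ep - med)
  amp_bad <- if (rsd > 0) apply(dev, 1L, max) > k_sd * rsd else rep(FALSE, n_ep)
  extreme <- range(x$samples)
  sat_bad <- apply(ep, 1L, function(v) {
    r <- rle(v)
    any(r$lengths >= 3 & r$values %in% extreme & r$values != med)
  })
  kept <- !(amp_bad | sat_bad)
  list(epochs = ep, kept = kept,
       epoch_times = x$t0 + (seq_len(n_ep) - 0.5) * epoch_len,
       rate = x$rate)
}

#' Mean power spectral density of artifact-free epochs
#'
#' Per-epoch periodograms (rectangular window, epochs demeaned), averaged
#' over kept epochs. The normalization satisfies Parseval's relation: the
#' sum of the spectrum over the frequency grid equals the mean epoch
#' variance. At 1-s epochs and 200 Hz the grid is 0..100 Hz in 1 Hz
#' steps.
#'
#' @param epochs Epoch matrix (epochs x samples).
#' @param rate Sampling rate in Hz.
#' @param kept Optional logical mask of epochs to use (default all).
#' @return List: `freqs` (Hz), `spectrum` (a.u.^2 per bin, averaged),
#'   `per_epoch` (matrix, kept epochs x bins), `n_epochs`.
#' @export
psd <- function(epochs, rate, kept = NULL) {
  if (!is.matrix(epochs)) epochs <- matrix(epochs, nrow = 1)
  if (!is.null(kept)) epochs <- epochs[kept, , drop = FALSE]
  if (nrow(epochs) < 1) stop_domain("zero kept epochs")
  n <- ncol(epochs)
  x <- epochs - rowMeans(epochs)
  X <- mvfft(t(x))
  nh <- floor(n / 2)
  P <- Mod(X[seq_len(nh + 1L), , drop = FALSE])^2 / n^2
  # fold negative frequencies into the one-sided spectrum
  if (n %% 2L == 0L) {
    P[2:nh, ] <- 2 * P[2:nh, , drop = FALSE]
  } else {
    P[2:(nh + 1L), ] <- 2 * P[2:(nh + 1L), , drop = FALSE]
  }
  freqs <- (seq_len(nh + 1L) - 1L) * rate / n
  list(freqs = freqs, spectrum = rowMeans(P), per_epoch = t(P),
       n_epochs = nrow(epochs))
}

#' Mean band power of a spectrum
#'
#' Mean spectral value over the bins inside the (inclusive) band — the
#' gamma readout uses 40-60 Hz.
#'
#' @param freqs Frequency grid (Hz).
#' @param spectrum Spectral values on the grid (one PSD, or a matrix with
#'   epochs in rows for per-epoch band power).
#' @param band Two-element band `c(lo, hi)` in Hz (default `c(40, 60)`).
#' @return Scalar band power, or a vector per row of `spectrum`.
#' @export
band_power <- function(freqs, spectrum, band = c(40, 60)) {
  if (band[1] > band[2]) stop_domain("band must be increasing")
  idx <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(idx) || band[1] < min(freqs) || band[2] > max(freqs))
    stop_domain("band outside the frequency grid")
  if (is.matrix(spectrum)) rowMeans(spectrum[, idx, drop = FALSE])
  else mean(spectrum[idx])
}

#' Label epochs by lever-pressing intensity
#'
#' Counts presses inside a centered window around each epoch: `high` when
#' at least `high_min` presses fall in the window, `low` when at most
#' `low_max`, otherwise `excluded` (a conservative buffer between the two
#' states).
#'
#' @param press_times Sorted press times (s).
#' @param epoch_times Epoch center times (s).
#' @param window Window length in seconds, centered on the epoch
#'   (default 10).
#' @param high_min Minimum presses for `high` (default 2).
#' @param low_max Maximum presses for `low` (default 0).
#' @return Character vector of labels (`"high"`, `"low"`, `"excluded"`).
#' @export
label_press_epochs <- function(press_times, epoch_times, window = 10,
                               high_min = 2, low_max = 0) {
  if (window <= 0) stop_domain("window must be > 0")
  counts <- vapply(epoch_times, function(tc)
    sum(press_times >= tc - window / 2 & press_times <= tc + window / 2),
    numeric(1))
  ifelse(counts >= high_min, "high",
         ifelse(counts <= low_max, "low", "excluded"))
}

#' Compare band power between behavioral conditions
#'
#' Three designs, matching how such comparisons are layered: epoch-level
#' high-vs-low within a session (`"unpaired"`, Wilcoxon rank-sum);
#' session-level paired comparisons per region/schedule
#' (`"paired_sessions"`, Wilcoxon signed-rank); and a region-x-schedule
#' family of paired comparisons (`"sign_family"`, sign tests with
#' Bonferroni correction across the family).
#'
#' @param x,y Band-power observations: the two groups (`unpaired`) or the
#'   paired vectors (`paired_sessions`, `sign_family`).
#' @param design `"unpaired"`, `"paired_sessions"`, or `"sign_family"`.
#' @param family_size Number of comparisons in the Bonferroni family
#'   (used for `sign_family`; default 1).
#' @param alpha Nominal level (default 0.05).
#' @return List: `test`, `statistic`, `p`, `alpha_adjusted`,
#'   `significant`.
#' @export
compare_band_power <- function(x, y,
                               design = c("unpaired", "paired_sessions",
                                          "sign_family"),
                               family_size = 1, alpha = 0.05) {
  design <- match.arg(design)
  if (length(x) < 5 || length(y) < 5)
    stop_domain("need at least 5 observations per group")
  alpha_adj <- alpha / family_size
  if (design == "unpaired") {
    if (stats::sd(c(x, y)) == 0)
      return(list(test = "wilcoxon_rank_sum", statistic = NA_real_, p = 1,
                  alpha_adjusted = alpha_adj, significant = FALSE))
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    test <- "wilcoxon_rank_sum"
  } else if (design == "paired_sessions") {
    if (all(x == y))
      return(list(test = "wilcoxon_signed_rank", statistic = NA_real_, p = 1,
                  alpha_adjusted = alpha_adj, significant = FALSE))
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
    test <- "wilcoxon_signed_rank"
  } else {
    d <- x - y
    d <- d[d != 0]
    if (!length(d))
      return(list(test = "sign_test", statistic = NA_real_, p = 1,
                  alpha_adjusted = alpha_adj, significant = FALSE))
    ht <- binom.test(sum(d > 0), length(d), p = 0.5)
    test <- "sign_test"
  }
  p <- ht$p.value
  list(test = test, statistic = unname(ht$statistic), p = p,
       alpha_adjusted = alpha_adj, significant = p < alpha_adj)
}

#' Gamma band power by trial-block condition (S+ vs S-)
#'
#' Runs the full epoch pipeline on the signal, assigns each kept epoch to
#' the trial block containing its center (epochs outside every block are
#' dropped), and aggregates per-epoch band power by rewarded (S+) vs
#' unrewarded (S-) condition.
#'
#' @param x A [continuous_signal()] (already down-sampled).
#' @param blocks A [trial_blocks()] table; types starting "S+" are
#'   rewarded, "S-" unrewarded. Every block must contain at least one
#'   kept epoch.
#' @param band Band in Hz (default `c(40, 60)`).
#' @param epoch_len,k_sd Epoching parameters (see [epoch_and_reject()]).
#' @return List: `per_epoch` (data frame `time`, `condition`, `power`),
#'   `condition_means` (named vector, S+ and S-).
#' @export
block_band_power <- function(x, blocks, band = c(40, 60), epoch_len = 1,
                             k_sd = 6) {
  stopifnot(inherits(blocks, "trial_blocks"))
  er <- epoch_and_reject(x, epoch_len = epoch_len, k_sd = k_sd)
  sp <- psd(er$epochs, er$rate, kept = er$kept)
  pw <- band_power(sp$freqs, sp$per_epoch, band = band)
  tt <- er$epoch_times[er$kept]
  block_of <- vapply(tt, function(tc) {
    i <- which(blocks$start <= tc & tc < blocks$end)
    if (length(i)) i[1L] else NA_integer_
  }, integer(1))
  keep <- !is.na(block_of)
  cond <- ifelse(startsWith(blocks$type[block_of[keep]], "S+"), "S+", "S-")
  per_epoch <- data.frame(time = tt[keep], condition = cond,
                          power = pw[keep])
  n_per_block <- tabulate(block_of[keep], nbins = nrow(blocks))
  if (any(n_per_block == 0))
    stop_domain("block(s) with zero contained epochs: ",
                paste(which(n_per_block == 0), collapse = ", "))
  means <- tapply(per_epoch$power, per_epoch$condition, mean)
  list(per_epoch = per_epoch, condition_means = means)
}
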