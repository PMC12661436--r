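#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate aligned to event onsets, with half-open
#' `[left, right)` bins (a spike on a bin edge counts in the right-hand
#' bin).
#'
#' @param spikes A [spike_train()] or numeric spike times (s).
#' @param onsets Event onset times (s); at least one.
#' @param window Two-element window `c(pre, post)` in seconds relative to
#'   onset, e.g. `c(-0.5, 1)`.
#' @param binwidth Bin width in seconds.
#' @return Data frame with `bin_left`, `bin_center`, `rate` (Hz);
#'   attribute `"n_trials"`.
#' @export
psth <- function(spikes, onsets, window = c(-0.5, 1), binwidth = 0.01) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else as.double(spikes)
  if (!length(onsets)) stop_domain("no onsets")
  if (binwidth <= 0) stop_domain("binwidth must be > 0")
  if (diff(window) < binwidth) stop_domain("window must span at least one bin")
  edges <- seq(window[1], window[2], by = binwidth)
  if (abs(edges[length(edges)] - window[2]) > 1e-12)
    edges <- c(edges, edges[length(edges)] + binwidth)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (on in onsets) {
    rel <- times - on
    rel <- rel[rel >= edges[1L] & rel < edges[nb + 1L]]
    idx <- findInterval(rel, edges)      # half-open [left, right)
    counts <- counts + tabulate(idx, nbins = nb)
  }
  out <- data.frame(bin_left = edges[-(nb + 1L)],
                    bin_center = edges[-(nb + 1L)] + binwidth / 2,
                    rate = counts / (binwidth * length(onsets)))
  attr(out, "n_trials") <- length(onsets)
  out
}

# TRUE when neither normality test rejects at `alpha`.
# Anderson-Darling requires n >= 8; below that the gate is Lilliefors alone.
normality_ok <- function(d, alpha = 0.05) {
  if (stats::sd(d) == 0) return(FALSE)
  lp <- nortest::lillie.test(d)$p.value
  ap <- if (length(d) >= 8) nortest::ad.test(d)$p.value else 1
  lp >= alpha && ap >= alpha
}

#' Normality-gated paired comparison
#'
#' Applies both the Lilliefors and Anderson-Darling tests to the paired
#' differences; if both fail to reject normality (at level `gate_alpha`)
#' a paired t-test is used, otherwise the Wilcoxon signed-rank test.
#'
#' @param x,y Equal-length per-trial measurements (e.g. rates in Hz).
#' @param alpha Significance level for the final test (default 0.05).
#' @param gate_alpha Level of the normality gate (default 0.05).
#' @return List: `test_used` ("paired_t" or "wilcoxon_signed_rank"),
#'   `statistic`, `p`, `significant`.
#' @export
normality_gated_paired_test <- function(x, y, alpha = 0.05,
                                        gate_alpha = 0.05) {
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  if (length(x) < 5) stop_domain("need at least 5 pairs")
  d <- x - y
  if (all(d == 0))
    return(list(test_used = "degenerate", statistic = NA_real_, p = 1,
                significant = FALSE))
  if (normality_ok(d, gate_alpha)) {
    ht <- t.test(x, y, paired = TRUE)
    test_used <- "paired_t"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
    test_used <- "wilcoxon_signed_rank"
  }
  p <- ht$p.value
  if (is.nan(p)) p <- 1
  list(test_used = test_used, statistic = unname(ht$statistic), p = p,
       significant = p < alpha)
}

#' Classify a unit's firing-rate modulation by stimulation
#'
#' Pulses are grouped into stimulation trains ([group_pulse_trains()]);
#' per-train rates during stimulation are compared against rates in an
#' equal-duration window immediately preceding each train, with the
#' normality-gated paired test. A unit is `excited` when significant with
#' stimulation rate above baseline, `inhibited` when below, else `ns`.
#'
#' @param spikes A [spike_train()].
#' @param stim A [pulse_train()] whose pulses form >= 5 trains.
#' @param alpha Significance level (default 0.05).
#' @param rate_window Optional window length (s) within each train over
#'   which the stimulation rate is computed, measured from train onset;
#'   default NULL uses the whole train (used by
#'   [transient_window_classify()]).
#' @return A `modulation_result` list: `unit_id`, `baseline_rate`,
#'   `stim_rate` (Hz, means over trains), `test_used`, `statistic`, `p`,
#'   `class`.
#' @export
classify_modulation <- function(spikes, stim, alpha = 0.05,
                                rate_window = NULL) {
  stopifnot(inherits(spikes, "spike_train"), inherits(stim, "pulse_train"))
  trains <- group_pulse_trains(stim)
  if (nrow(trains) < 5) stop_domain("need at least 5 stimulation trains")
  if (!length(spikes$times)) {
    message("empty spike train ", spikes$unit_id, "; classified ns")
    return(structure(list(unit_id = spikes$unit_id, baseline_rate = 0,
                          stim_rate = 0, test_used = "degenerate",
                          statistic = NA_real_, p = 1, class = "ns"),
                     class = "modulation_result"))
  }
  dur <- trains$offset - trains$onset
  win <- if (is.null(rate_window)) dur else pmin(rate_window, dur)
  n_in <- function(lo, hi) vapply(seq_along(lo), function(i)
    sum(spikes$times >= lo[i] & spikes$times < hi[i]), numeric(1))
  stim_rate <- n_in(trains$onset, trains$onset + win) / win
  base_rate <- n_in(trains$onset - win, trains$onset) / win
  gt <- normality_gated_paired_test(stim_rate, base_rate, alpha = alpha)
  cls <- if (!gt$significant) "ns"
         else if (mean(stim_rate) > mean(base_rate)) "excited" else "inhibited"
  structure(list(unit_id = spikes$unit_id,
                 baseline_rate = mean(base_rate), stim_rate = mean(stim_rate),
                 test_used = gt$test_used, statistic = gt$statistic,
                 p = gt$p, class = cls),
            class = "modulation_result")
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("<modulation_result> %s: %s (baseline %.2f Hz, stim %.2f Hz, %s p = %.3g)\n",
              x$unit_id, x$class, x$baseline_rate, x$stim_rate,
              x$test_used, x$p))
  invisible(x)
}

#' Classify the transient response at train onset
#'
#' Same contract as [classify_modulation()] but the stimulation-window
#' rate is computed over only the first `transient` seconds of each train
#' (default 100 ms), capturing transient inhibition that precedes overall
#' excitation.
#'
#' @inheritParams classify_modulation
#' @param transient Transient window length in seconds (default 0.1).
#' @return A `modulation_result` for the transient window.
#' @export
transient_window_classify <- function(spikes, stim, transient = 0.1,
                                      alpha = 0.05) {
  classify_modulation(spikes, stim, alpha = alpha, rate_window = transient)
}

#' Pearson chi-square goodness-of-fit on counts
#'
#' Plain Pearson statistic without continuity correction, e.g. for
#' comparing counts of transiently inhibited vs excited units against an
#' equal-proportion null.
#'
#' @param observed Non-negative counts with positive sum.
#' @param expected_proportions Null proportions (same length), summing
#'   to 1.
#' @return List: `chisq`, `df`, `p`.
#' @export
chi_square_counts <- function(observed,
                              expected_proportions = rep(1 / length(observed),
                                                         length(observed))) {
  if (any(observed < 0) || sum(observed) <= 0)
    stop_domain("counts must be >= 0 with positive sum")
  if (any(expected_proportions <= 0 & observed > 0))
    stop_domain("zero expected proportion with nonzero observed count")
  ht <- suppressWarnings(chisq.test(observed, p = expected_proportions,
                                    correct = FALSE))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Depth-binned activation profile with one-way ANOVA
#'
#' Bins stimulation sites into `bin_width`-mm depth bins (half-open
#' `[lo, hi)` anchored at the shallowest depth rounded down to a bin
#' multiple), averages the evoked firing-rate increase per bin, and runs a
#' one-way ANOVA of response on depth bin.
#'
#' @param depth Stimulation depths in mm.
#' @param response Firing-rate increase over baseline (Hz), same length.
#' @param bin_width Bin width in mm (default 0.5, i.e. 500 um).
#' @return A `depth_profile` list: `bins` (data frame `bin_center`,
#'   `n`, `mean_response`), `anova_F`, `anova_df`, `anova_p` (NA when
#'   fewer than 2 non-empty bins).
#' @export
depth_profile <- function(depth, response, bin_width = 0.5) {
  stopifnot(length(depth) == length(response), length(depth) > 0)
  anchor <- floor(min(depth) / bin_width) * bin_width
  idx <- floor((depth - anchor) / bin_width)
  centers <- anchor + (idx + 0.5) * bin_width
  agg <- stats::aggregate(response, list(bin_center = centers),
                          function(v) c(n = length(v), m = mean(v)))
  bins <- data.frame(bin_center = agg$bin_center,
                     n = agg$x[, "n"], mean_response = agg$x[, "m"])
  bins <- bins[order(bins$bin_center), , drop = FALSE]
  rownames(bins) <- NULL
  if (nrow(bins) >= 2 && length(response) > nrow(bins)) {
    an <- anova(lm(response ~ factor(centers)))
    out <- list(bins = bins, anova_F = an[1, "F value"],
                anova_df = c(an[1, "Df"], an[2, "Df"]),
                anova_p = an[1, "Pr(>F)"])
  } else {
    out <- list(bins = bins, anova_F = NA_real_, anova_df = c(NA, NA),
                anova_p = NA_real_)
  }
  structure(out, class = "depth_profile")
}
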