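test_that("decimation preserves the passband and rejects above-Nyquist tones", {
  n <- 25000 * 2
  t25 <- (0:(n - 1)) / 25000
  x50 <- continuous_signal(sin(2 * pi * 50 * t25), 25000)
  d <- downsample(x50, 200)
  expect_equal(d$rate, 200)
  expect_equal(length(d$samples), 400)        # duration preserved
  expect_lt(abs(max(abs(d$samples[150:250])) - 1), 0.01)
  x120 <- continuous_signal(sin(2 * pi * 120 * t25), 25000)
  expect_lt(max(abs(downsample(x120, 200)$samples[100:300])), 0.1)
  dc <- continuous_signal(rep(2.5, 2000), 1000)
  expect_equal(downsample(dc, 200)$samples, rep(2.5, 400), tolerance = 1e-6)
  expect_error(downsample(dc, 1000), "below source")
  expect_error(downsample(dc, 300), "integer multiple")
})

test_that("epoching truncates remainders and rejects artifact epochs", {
  x <- withr::with_seed(4, continuous_signal(rnorm(2100), rate = 200))
  er <- epoch_and_reject(x)                    # 10.5 s -> 10 epochs
  expect_equal(nrow(er$epochs), 10L)
  expect_gte(mean(er$kept), 0.9)
  # clean stationary noise keeps nearly everything at k_sd = 6
  xl <- withr::with_seed(5, continuous_signal(rnorm(200 * 300), rate = 200))
  expect_gte(mean(epoch_and_reject(xl)$kept), 0.99)
  # an injected 10 SD transient knocks out exactly its epoch
  v <- xl$samples
  v[200 * 3 + 100] <- 10
  er2 <- epoch_and_reject(continuous_signal(v, 200))
  expect_false(er2$kept[4])
  expect_error(epoch_and_reject(continuous_signal(rnorm(50), 200)), "epoch")
})

test_that("the periodogram satisfies Parseval and localizes sinusoids", {
  t <- (0:1999) / 200
  x <- continuous_signal(sin(2 * pi * 50 * t), 200)
  er <- epoch_and_reject(x)
  sp <- psd(er$epochs, 200, er$kept)
  expect_equal(sum(sp$spectrum), 0.5, tolerance = 1e-9)
  expect_equal(sp$spectrum[sp$freqs == 50], 0.5, tolerance = 1e-9)
  expect_lt(max(sp$spectrum[sp$freqs != 50]), 1e-12)
  # Parseval on arbitrary epochs: sum of PSD = mean epoch variance
  ep <- withr::with_seed(6, matrix(rnorm(40 * 200), nrow = 40))
  sp2 <- psd(ep, 200)
  v <- mean(apply(ep, 1, function(r) mean((r - mean(r))^2)))
  expect_equal(sum(sp2$spectrum), v, tolerance = 1e-6)
  # white noise: flat-ish spectrum integrating to sigma^2
  epw <- withr::with_seed(7, matrix(rnorm(500 * 200, sd = 2), nrow = 500))
  spw <- psd(epw, 200)
  expect_equal(sum(spw$spectrum), 4, tolerance = 0.05 * 4)
  # identical epochs average to either one
  two <- rbind(ep[1, ], ep[1, ])
  expect_equal(psd(two, 200)$spectrum, psd(ep[1, , drop = FALSE], 200)$spectrum)
  expect_error(psd(ep, 200, kept = rep(FALSE, 40)), "zero kept")
})

test_that("band power integrates the right bins and scales quadratically", {
  t <- (0:999) / 200
  er <- epoch_and_reject(continuous_signal(sin(2 * pi * 50 * t), 200))
  sp <- psd(er$epochs, 200, er$kept)
  expect_gt(band_power(sp$freqs, sp$spectrum, c(40, 60)), 0)
  expect_lt(band_power(sp$freqs, sp$spectrum, c(10, 30)), 1e-12)
  er20 <- epoch_and_reject(continuous_signal(sin(2 * pi * 20 * t), 200))
  sp20 <- psd(er20$epochs, 200, er20$kept)
  expect_lt(band_power(sp20$freqs, sp20$spectrum, c(40, 60)), 1e-12)
  er2 <- epoch_and_reject(continuous_signal(2 * sin(2 * pi * 50 * t), 200))
  sp2 <- psd(er2$epochs, 200, er2$kept)
  expect_equal(band_power(sp2$freqs, sp2$spectrum) /
                 band_power(sp$freqs, sp$spectrum), 4, tolerance = 1e-9)
  expect_error(band_power(sp$freqs, sp$spectrum, c(60, 40)), "increasing")
  expect_error(band_power(sp$freqs, sp$spectrum, c(90, 120)), "grid")
})

test_that("press-epoch labels follow the centered-window counting rule", {
  centers <- seq(0.5, 239.5, by = 1)
  steady <- seq(0, 240, by = 2)
  expect_true(all(label_press_epochs(steady, centers) == "high"))
  expect_true(all(label_press_epochs(numeric(), centers) == "low"))
  # a 60 s pause in steady pressing: interior pause epochs low,
  # boundary epochs excluded where exactly one press enters the window
  paused <- c(seq(0, 100, by = 2), seq(160, 240, by = 2))
  lab <- label_press_epochs(paused, centers)
  expect_true(all(lab[centers > 106 & centers < 154] == "low"))
  expect_true(all(lab[centers < 95 | centers > 165] == "high"))
  expect_true("excluded" %in% lab)
})

test_that("band-power comparisons use the design-matched test and correction", {
  withr::with_seed(12, {
    hi <- rexp(300, 1 / 4); lo <- rexp(300, 1)
  })
  res <- compare_band_power(hi, lo, design = "unpaired")
  expect_identical(res$test, "wilcoxon_rank_sum")
  expect_lt(res$p, 0.01)
  paired <- compare_band_power(hi[1:20], hi[1:20] * 0.5,
                               design = "paired_sessions")
  expect_identical(paired$test, "wilcoxon_signed_rank")
  expect_lt(paired$p, 0.01)
  fam <- compare_band_power(hi[1:10], hi[1:10] * 0.5, design = "sign_family",
                            family_size = 8)
  expect_identical(fam$test, "sign_test")
  expect_equal(fam$alpha_adjusted, 0.05 / 8)
  ties <- compare_band_power(rep(1, 10), rep(1, 10), design = "paired_sessions")
  expect_equal(ties$p, 1)
  expect_error(compare_band_power(1:3, 1:3), "at least 5")
})

test_that("S+ blocks with doubled gamma show elevated band power", {
  blocks <- trial_blocks(rep(c("S+A", "S-A"), 5),
                         start = seq(0, 180, by = 20),
                         end = seq(0, 180, by = 20) + 18)
  states <- data.frame(state = ifelse(startsWith(blocks$type, "S+"),
                                      "plus", "minus"),
                       start = blocks$start, end = blocks$end)
  x <- simulate_lfp(lfp_recipe(pink_noise_sd = 0.3, gamma_burst_amp = 0.5,
                               behavior_gate = c(plus = 2, minus = 1)),
                    states = states, rate = 200, duration = 200, seed = 13)
  res <- block_band_power(x, blocks)
  expect_gt(res$condition_means[["S+"]], res$condition_means[["S-"]])
  expect_gt(res$condition_means[["S+"]] / res$condition_means[["S-"]], 1.5)
  # a block too short to contain a full epoch errors
  tiny <- trial_blocks(c("S+A", "S-A"), c(0, 0.6), c(0.5, 200))
  expect_error(block_band_power(x, tiny), "zero contained")
})
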