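test_that("excited units hit the expected on/off rates (Poisson expectation)", {
  dur <- 100
  stim <- make_pulse_train(40, 0.5, dur)
  st <- simulate_unit(unit_archetype("excited_on", baseline_rate = 5, gain = 20),
                      stim, dur, seed = 42)
  ph <- spike_phases(st, 40, 0)
  on <- ph < pi
  t_on <- dur / 2
  on_rate <- sum(on) / t_on
  off_rate <- sum(!on) / t_on
  expect_lt(abs(on_rate - 25), 3 * sqrt(25 / t_on))
  expect_lt(abs(off_rate - 5), 3 * sqrt(5 / t_on))
})

test_that("fully suppressed units are silent during light-on", {
  stim <- make_pulse_train(20, 0.5, 50)
  st <- simulate_unit(unit_archetype("inhibited", baseline_rate = 10,
                                     suppression = 1),
                      stim, 50, seed = 1)
  ph <- spike_phases(st, 20, 0)
  expect_true(all(ph >= pi))
  expect_gt(length(st$times), 0)
})

test_that("unmodulated units produce uniform Rayleigh p-values (null oracle)", {
  stim <- make_pulse_train(40, 0.5, 20)
  ps <- vapply(1:500, function(sd) {
    st <- simulate_unit(unit_archetype("unmodulated", baseline_rate = 10),
                        stim, 20, seed = sd)
    rayleigh_test(spike_phases(st, 40, 0))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("generators are bit-identical under a repeated seed", {
  stim <- make_pulse_train(40, 0.5, 10)
  a <- simulate_unit(unit_archetype("excited_on", gain = 10), stim, 10, seed = 9)
  b <- simulate_unit(unit_archetype("excited_on", gain = 10), stim, 10, seed = 9)
  expect_identical(a$times, b$times)
  r <- lfp_recipe(entrain_amp = 1, gamma_burst_amp = 0.5)
  x <- simulate_lfp(r, stim = stim, rate = 1000, duration = 10, seed = 4)
  y <- simulate_lfp(r, stim = stim, rate = 1000, duration = 10, seed = 4)
  expect_identical(x$samples, y$samples)
  s1 <- make_trial_sequence(20, seed = 5)
  s2 <- make_trial_sequence(20, seed = 5)
  expect_identical(s1$type, s2$type)
  expect_identical(s1$start, s2$start)
})

test_that("entrained synthetic LFP shows a PSD peak at the drive frequency", {
  stim <- make_pulse_train(40, 0.5, 30)
  x <- simulate_lfp(lfp_recipe(pink_noise_sd = 0.5, entrain_amp = 1),
                    stim = stim, rate = 500, duration = 30, seed = 2)
  er <- epoch_and_reject(x)
  sp <- psd(er$epochs, er$rate, er$kept)
  pk <- sp$freqs[sp$freqs >= 5][which.max(sp$spectrum[sp$freqs >= 5])]
  expect_equal(pk, 40)
})

test_that("a 2:1 gamma amplitude gate yields a ~4:1 band-power ratio", {
  states <- data.frame(state = c("high", "low"),
                       start = c(0, 30), end = c(30, 60))
  x <- simulate_lfp(lfp_recipe(pink_noise_sd = 0, gamma_burst_amp = 1,
                               behavior_gate = c(high = 2, low = 1)),
                    states = states, rate = 200, duration = 60, seed = 3)
  er <- epoch_and_reject(x)
  sp <- psd(er$epochs, er$rate)
  pw <- band_power(sp$freqs, sp$per_epoch)
  hi <- mean(pw[er$epoch_times < 30])
  lo <- mean(pw[er$epoch_times > 30])
  expect_equal(hi / lo, 4, tolerance = 0.05)
})

test_that("zero-amplitude recipes yield a zero signal and components", {
  x <- simulate_lfp(lfp_recipe(pink_noise_sd = 0), rate = 200, duration = 2,
                    seed = 1)
  expect_true(all(x$samples == 0))
  comps <- attr(x, "components")
  expect_named(comps, c("pink", "entrain", "gamma", "artifact"))
  expect_true(all(vapply(comps, function(v) all(v == 0), logical(1))))
})

test_that("ground-truth components sum to the composite signal", {
  stim <- make_pulse_train(40, 0.5, 5)
  x <- simulate_lfp(lfp_recipe(pink_noise_sd = 1, entrain_amp = 1,
                               gamma_burst_amp = 0.5, artifact_rate = 1,
                               artifact_amp = 10),
                    stim = stim, rate = 500, duration = 5, seed = 8)
  comps <- attr(x, "components")
  expect_equal(x$samples, comps$pink + comps$entrain + comps$gamma +
                 comps$artifact)
})

test_that("operant schedules pay per their contracts", {
  ev <- simulate_operant_session(schedule_crf(), press_rate = 0.5,
                                 duration = 100, seed = 1)
  expect_identical(ev$rewards, ev$presses)
  expect_length(run_schedule(schedule_fr(10), seq_len(35)), 3)
  r <- run_schedule(schedule_vi(30, 0), seq_len(300), seed = 1)
  expect_length(r, 10)
  expect_true(all(abs(diff(r) - 30) <= 1))
  expect_error(simulate_operant_session(list(kind = "bogus"), 1, 10, 1),
               "schedule")
})

test_that("trial sequences respect counts, run length, and time equalization", {
  for (sd in 1:300) {
    tb <- make_trial_sequence(20, seed = sd)
    expect_equal(as.integer(table(tb$type)), rep(5L, 4))
    expect_lte(max(rle(tb$type)$lengths), 3)
  }
  tb <- make_trial_sequence(60, seed = 1)
  tot <- tapply(tb$end - tb$start, tb$type, sum)
  expect_lt(diff(range(tot)) / mean(tot), 0.05)
  expect_true(all(tb$end - tb$start >= 57 & tb$end - tb$start <= 63))
  gaps <- tb$start[-1] - tb$end[-nrow(tb)]
  expect_true(all(gaps >= 1 & gaps <= 4))
  expect_error(make_trial_sequence(10, seed = 1), "divisible")
  expect_error(make_trial_sequence(20, max_run = 0, seed = 1), "max_run")
})

test_that("learning curves sit at chance when flat and respond to opto effects", {
  flat <- learning_recipe(n_subjects = 4, n_days = 21, asymptote = 50,
                          slope = 0, session_noise_sd = 0)
  tab <- simulate_discrimination_course(flat, seed = 1)
  expect_true(all(abs(tab$percent_correct - 50) < 1e-9))
  # null opto effect: conditions indistinguishable at n = 20 subjects
  null <- learning_recipe(n_subjects = 20, n_days = 21, session_noise_sd = 3)
  tab <- simulate_discrimination_course(null, seed = 7)
  agg <- stats::aggregate(percent_correct ~ subject + condition, tab, mean)
  p <- stats::t.test(percent_correct ~ condition, agg, paired = TRUE)$p.value
  expect_gt(p, 0.05)
  # a first-stage effect shifts only the first stage
  eff <- learning_recipe(n_subjects = 7, n_days = 21, session_noise_sd = 0,
                         opto_effect = c(first = 15, middle = 0, last = 0))
  tab <- simulate_discrimination_course(eff, seed = 2)
  stg <- stage_split(1:21)
  d_first <- with(tab[tab$day %in% stg$first, ],
                  mean(percent_correct[condition == "opto"]) -
                    mean(percent_correct[condition == "control"]))
  d_last <- with(tab[tab$day %in% stg$last, ],
                 mean(percent_correct[condition == "opto"]) -
                   mean(percent_correct[condition == "control"]))
  expect_equal(d_first, 15, tolerance = 1e-6)
  expect_equal(d_last, 0, tolerance = 1e-6)
})

test_that("generated sessions pass core-model validation", {
  for (preset in c("entrain40", "vi30", "discrimination")) {
    s <- simulate_preset(preset, seed = 1,
                         duration = if (preset == "entrain40") 10 else 120)
    expect_silent(validate_session(s))
  }
})
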