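test_that("schedule engines pay exactly per contract and conserve rewards", {
  presses <- seq(0.5, 300, by = 0.5)
  expect_identical(run_schedule(schedule_crf(), presses), presses)
  expect_length(run_schedule(schedule_fr(10), seq_len(35)), 3)
  vi <- run_schedule(schedule_vi(30, 0), seq_len(300) + 0, seed = 2)
  expect_length(vi, 10)
  expect_true(all(diff(vi) == 30))
  # conservation properties over random press trains
  for (sd in 1:20) {
    p <- withr::with_seed(sd, sort(runif(rpois(1, 80), 0, 400)))
    for (sch in list(schedule_crf(), schedule_fr(7), schedule_vi(30, 5))) {
      r <- run_schedule(sch, p, seed = sd)
      expect_lte(length(r), length(p))
      expect_true(all(r %in% p))
      if (sch$kind == "VI")
        expect_lte(length(r), 400 / (30 - 5) + 1)
    }
  }
  expect_error(run_schedule(structure(list(kind = "XX"),
                                      class = "schedule_spec"), 1:5),
               "unknown schedule kind")
})

test_that("cumulative records reset every 50 presses and track rate", {
  presses <- seq(1, 120, by = 1)
  cr <- cumulative_record(presses, rewards = c(10.5, 60.5))
  expect_length(cr$resets, 2)                     # floor(120/50)
  expect_equal(max(cr$record$count), 49)
  expect_equal(cr$record$count[50], 0)            # reset lands at zero
  expect_equal(nrow(cumulative_record(numeric())$record), 0)
  # slope over a window equals the press rate in that window
  win <- cr$record$time >= 20 & cr$record$time <= 40
  slope <- (max(cr$record$count[win]) - min(cr$record$count[win])) /
    (40 - 20)
  expect_equal(slope, 1, tolerance = 0.05)
})

test_that("press rates are compared pairwise across opto and control trials", {
  blocks <- make_trial_sequence(20, types = c("S+A", "S+B"), seed = 3,
                                opto_types = "S+A")
  dur <- max(blocks$end)
  # identical policy in both conditions: null comparison
  ev <- simulate_operant_session(schedule_vi(30, 5), press_rate = 0.4,
                                 duration = dur, seed = 4)
  res <- press_rate_by_condition(blocks, ev$presses)
  expect_true(res$paired)
  expect_gt(res$p, 0.001)
  # halved rate on opto trials is detected
  halves <- withr::with_seed(6, {
    unlist(lapply(seq_len(nrow(blocks)), function(i) {
      r <- if (blocks$opto[i]) 0.2 else 0.6
      n <- rpois(1, r * (blocks$end[i] - blocks$start[i]))
      sort(runif(n, blocks$start[i], blocks$end[i]))
    }))
  })
  res2 <- press_rate_by_condition(blocks, sort(halves))
  expect_lt(res2$p, 0.05)
  # calibration: the null comparison rejects at about the nominal rate
  rej <- vapply(1:200, function(sd) {
    ev <- simulate_operant_session(schedule_vi(30, 5), press_rate = 0.4,
                                   duration = dur, seed = 1000 + sd)
    press_rate_by_condition(blocks, ev$presses)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)
  expect_error(press_rate_by_condition(blocks[1:4, ], ev$presses),
               "5 trials")
})

test_that("percent correct implements S+/(S+ + S-) per condition set", {
  blocks <- trial_blocks(c("S+A", "S-A", "S+B", "S-B"),
                         start = c(0, 10, 20, 30), end = c(9, 19, 29, 39))
  presses <- c(seq(0.1, 8.9, length.out = 120),   # 120 in S+A
               seq(10.1, 18.9, length.out = 40),  #  40 in S-A
               seq(20.1, 28.9, length.out = 10))  #  10 in S+B, 0 in S-B
  expect_equal(percent_correct(blocks, presses, "A"), 75)
  expect_equal(percent_correct(blocks, presses, "B"), 100)
  # invariance to uniform scaling of press counts
  dense <- c(seq(0.1, 8.9, length.out = 360), seq(10.1, 18.9, length.out = 120))
  expect_equal(percent_correct(blocks, dense, "A"), 75)
  none <- percent_correct(blocks, numeric(), "A")
  expect_true(is.na(none))
  expect_true(isTRUE(attr(none, "undefined")))
})

test_that("stage splitting takes the first, centered-middle, and last 7 days", {
  s21 <- stage_split(1:21)
  expect_equal(s21$first, 1:7)
  expect_equal(s21$middle, 8:14)
  expect_equal(s21$last, 15:21)
  s25 <- stage_split(1:25)
  expect_equal(s25$middle, 10:16)
  expect_error(stage_split(1:20), "21")
})

test_that("the rm-ANOVA matches brute-force sums-of-squares oracles", {
  # day-replication branch: 2 x 7 subject-averaged table
  withr::with_seed(14, {
    y <- matrix(rnorm(14, mean = 70, sd = 5), nrow = 2)
    y[1, ] <- y[1, ] + 6
  })
  tab <- data.frame(subject = 1L,
                    day = rep(1:7, each = 2),
                    condition = rep(c("opto", "control"), 7),
                    percent_correct = as.vector(y))
  res <- rm_anova_2way(tab, unit = "day")
  oracle <- ss_anova_norep(y)
  expect_equal(res$F[res$effect == "condition"], oracle$F_cond,
               tolerance = 1e-9)
  expect_equal(res$F[res$effect == "day"], oracle$F_day, tolerance = 1e-9)
  expect_equal(res$df1[res$effect == "condition"], 1)
  expect_equal(res$df2[res$effect == "condition"], 6)
  expect_true(is.na(res$F[res$effect == "interaction"]))
  # subject-replication branch: 2 cond x 3 day x 4 subjects
  arr <- withr::with_seed(15, array(rnorm(24, 70, 4), dim = c(2, 3, 4)))
  arr[2, , ] <- arr[2, , ] + 5
  long <- expand.grid(condition = c("control", "opto"), day = 1:3,
                      subject = 1:4)
  long$percent_correct <- as.vector(arr)
  res2 <- rm_anova_2way(long, unit = "subject")
  oracle2 <- ss_anova_rm(arr)
  expect_equal(res2$F[res2$effect == "condition"], oracle2$F_cond,
               tolerance = 1e-9)
  expect_equal(res2$F[res2$effect == "day"], oracle2$F_day, tolerance = 1e-9)
  expect_equal(res2$F[res2$effect == "interaction"], oracle2$F_int,
               tolerance = 1e-9)
  expect_false(is.na(attr(res2, "lilliefors_p")))
  # missing cells abort rather than impute
  expect_error(rm_anova_2way(tab[-1, ], unit = "day"), "balanced")
})

test_that("condition F grows with the opto effect size (power monotonicity)", {
  mean_F <- vapply(c(0, 5, 10, 15), function(eff) {
    fs <- vapply(1:30, function(sd) {
      rec <- learning_recipe(n_subjects = 7, n_days = 21, session_noise_sd = 3,
                             opto_effect = c(first = eff, middle = 0, last = 0))
      tab <- simulate_discrimination_course(rec, seed = sd)
      sub <- tab[tab$day %in% stage_split(1:21)$first, ]
      res <- rm_anova_2way(sub, unit = "day")
      res$F[res$effect == "condition"]
    }, numeric(1))
    mean(fs)
  }, numeric(1))
  expect_true(all(diff(mean_F) > 0))
})
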