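#' Reinforcement-schedule specifications
#'
#' `schedule_crf()` rewards every press; `schedule_fr(k)` rewards every
#' k-th press; `schedule_vi(mean, jitter)` arms after a
#' Uniform(mean - jitter, mean + jitter) interval and rewards the first
#' subsequent press (the training protocol's VI30 uses mean 30 s,
#' jitter 5 s).
#'
#' @param k Fixed ratio (presses per reward).
#' @param mean,jitter VI interval mean and half-range in seconds.
#' @return A `schedule_spec` object.
#' @export
schedule_crf <- function() {
  structure(list(kind = "CRF"), class = "schedule_spec")
}

#' @rdname schedule_crf
#' @export
schedule_fr <- function(k) {
  if (k < 1) stop_domain("FR ratio must be >= 1")
  structure(list(kind = "FR", k = as.integer(k)), class = "schedule_spec")
}

#' @rdname schedule_crf
#' @export
schedule_vi <- function(mean = 30, jitter = 5) {
  if (mean <= 0 || jitter < 0 || jitter > mean)
    stop_domain("need mean > 0 and 0 <= jitter <= mean")
  structure(list(kind = "VI", mean = mean, jitter = jitter),
            class = "schedule_spec")
}

#' Run a reinforcement schedule over a press train
#'
#' For VI, the first interval is drawn at t = 0 and each reward draws the
#' next interval (measured from the reward time). Rewards coincide with
#' rewarded presses.
#'
#' @param schedule A `schedule_spec`.
#' @param press_times Sorted press times (s).
#' @param seed Integer seed (used by the VI interval draws only).
#' @return Numeric vector of reward times, a subset of `press_times`.
#' @export
run_schedule <- function(schedule, press_times, seed = 1) {
  if (!inherits(schedule, "schedule_spec")) stop_domain("unknown schedule")
  if (is.unsorted(press_times)) stop_domain("press times must be sorted")
  switch(schedule$kind,
    CRF = press_times,
    FR = press_times[seq_along(press_times) %% schedule$k == 0],
    VI = with_seed(seed, {
      draw <- function() runif(1, schedule$mean - schedule$jitter,
                               schedule$mean + schedule$jitter)
      arm <- draw()
      rewards <- numeric()
      for (p in press_times) {
        if (p >= arm) {
          rewards <- c(rewards, p)
          arm <- p + draw()
        }
      }
      rewards
    }),
    stop_domain("unknown schedule kind '", schedule$kind, "'"))
}

#' Cumulative lever-press record
#'
#' The classic cumulative record: the count steps up at each press and
#' resets to zero after every `reset` presses; the slope of the record over
#' any window equals the press rate in that window.
#'
#' @param presses Sorted press times (s).
#' @param rewards Reward times (marked on the record).
#' @param reset Reset the record to zero after this many presses.
#' @return List with `record` (data frame `time`, `count`), `resets`
#'   (times of resets) and `reward_marks` (data frame `time`, `count`).
#' @export
cumulative_record <- function(presses, rewards = numeric(), reset = 50) {
  if (is.unsorted(presses)) stop_domain("press times must be sorted")
  n <- length(presses)
  counts <- if (n) seq_len(n) %% reset else integer()
  rec <- data.frame(time = presses, count = counts)
  reset_times <- presses[seq_len(n) %% reset == 0]
  rmarks <- if (length(rewards)) {
    idx <- findInterval(rewards, presses)
    data.frame(time = rewards, count = ifelse(idx > 0, counts[pmax(idx, 1L)], 0))
  } else data.frame(time = numeric(), count = numeric())
  list(record = rec, resets = reset_times, reward_marks = rmarks)
}

#' Per-trial press rates and the opto-vs-control comparison
#'
#' Computes presses / trial duration per block and compares optogenetic
#' and control trials with the normality-gated paired test (opto and
#' control trials paired in time order). Unbalanced designs fall back to
#' an unpaired comparison with a warning.
#'
#' @param blocks A [trial_blocks()] table with the `opto` flag set.
#' @param presses Sorted press times (s).
#' @param alpha Significance level (default 0.05).
#' @return List with `rates` (per-trial data frame), `test_used`,
#'   `statistic`, `p`, and `paired`.
#' @export
press_rate_by_condition <- function(blocks, presses, alpha = 0.05) {
  stopifnot(inherits(blocks, "trial_blocks"))
  dur <- blocks$end - blocks$start
  if (any(dur <= 0)) stop_domain("zero-duration trial")
  cnt <- vapply(seq_len(nrow(blocks)), function(i)
    sum(presses >= blocks$start[i] & presses < blocks$end[i]), numeric(1))
  rates <- data.frame(trial = seq_len(nrow(blocks)), opto = blocks$opto,
                      rate = cnt / dur)
  x <- rates$rate[rates$opto]
  y <- rates$rate[!rates$opto]
  if (length(x) < 5 || length(y) < 5)
    stop_domain("need at least 5 trials per condition")
  if (length(x) == length(y)) {
    gt <- normality_gated_paired_test(x, y, alpha = alpha)
    list(rates = rates, test_used = gt$test_used, statistic = gt$statistic,
         p = gt$p, paired = TRUE)
  } else {
    warning("unbalanced opto/control trials; analyzed unpaired")
    ok <- tryCatch(normality_ok(x) && normality_ok(y), error = function(e) FALSE)
    ht <- if (ok) t.test(x, y) else wilcox.test(x, y, exact = FALSE)
    list(rates = rates,
         test_used = if (ok) "welch_t" else "wilcoxon_rank_sum",
         statistic = unname(ht$statistic), p = ht$p.value, paired = FALSE)
  }
}

#' Discrimination percent correct
#'
#' Percent correct for one condition set: 100 * S+ presses /
#' (S+ presses + S- presses), computed over the blocks of that set only
#' (set A carries the optogenetic light; set B is the control, or as
#' configured in the trial table). Block durations are equalized by
#' design, so raw counts are used; `rate_based = TRUE` divides each
#' count by the summed block duration first.
#'
#' @param blocks A [trial_blocks()] table.
#' @param presses Sorted press times (s).
#' @param condition_set `"A"` or `"B"`.
#' @param rate_based Use press rates instead of raw counts.
#' @return Percent correct in `[0, 100]`; `NA` (flagged via attribute
#'   `"undefined"`) when the set contains no presses.
#' @export
percent_correct <- function(blocks, presses, condition_set = c("A", "B"),
                            rate_based = FALSE) {
  condition_set <- match.arg(condition_set)
  plus_type <- paste0("S+", condition_set)
  minus_type <- paste0("S-", condition_set)
  count_in <- function(type) {
    b <- blocks[blocks$type == type, , drop = FALSE]
    n <- sum(vapply(seq_len(nrow(b)), function(i)
      sum(presses >= b$start[i] & presses < b$end[i]), numeric(1)))
    if (rate_based) {
      tot <- sum(b$end - b$start)
      if (tot > 0) n / tot else 0
    } else n
  }
  np <- count_in(plus_type); nm <- count_in(minus_type)
  if (np + nm == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * np / (np + nm)
}

#' Split training days into first, middle, and last stages
#'
#' Learning stages are the first, middle and last `stage_len` days of
#' training; the middle stage is centered on the median training day.
#'
#' @param days Sorted vector of training days.
#' @param stage_len Days per stage (default 7).
#' @return Named list of day vectors: `first`, `middle`, `last`.
#' @export
stage_split <- function(days, stage_len = 7) {
  days <- sort(days)
  n <- length(days)
  if (n < 3 * stage_len)
    stop_domain("need at least ", 3 * stage_len, " days for non-overlapping stages")
  center <- floor((n + 1) / 2)
  half <- floor(stage_len / 2)
  mid_idx <- (center - half):(center - half + stage_len - 1)
  list(first = days[seq_len(stage_len)],
       middle = days[mid_idx],
       last = days[(n - stage_len + 1):n])
}

#' Two-way repeated-measures ANOVA on discrimination performance
#'
#' Tests the main effects of optogenetic condition and training day on
#' percent correct within one learning stage. With `unit = "day"`
#' (default, matching the degrees of freedom F(1, stage_len - 1) such
#' designs report), percent correct is first averaged over subjects and a
#' two-way ANOVA without replication is fitted on the condition x day
#' table; the interaction is then not estimable and reported `NA`. With
#' `unit = "subject"`, a full within-subject repeated-measures ANOVA is
#' fitted (`aov` with an `Error(subject/(condition*day))` stratum
#' structure), giving condition, day and interaction effects. A Lilliefors
#' test on the conditional residuals accompanies the result, mirroring the
#' residual-normality check this analysis assumes. No sphericity
#' correction is applied.
#'
#' @param table A `performance_table` data frame (columns `subject`,
#'   `day`, `condition`, `percent_correct`) restricted to one stage.
#' @param unit Replication unit, `"day"` or `"subject"`.
#' @return An `anova_result`: data frame of effects (`effect`, `df1`,
#'   `df2`, `F`, `p`) with attribute `lilliefors_p`.
#' @export
rm_anova_2way <- function(table, unit = c("day", "subject")) {
  unit <- match.arg(unit)
  need <- c("subject", "day", "condition", "percent_correct")
  if (!all(need %in% names(table))) stop_domain("missing performance-table columns")
  tab <- as.data.frame(table)[, need]
  if (any(!complete.cases(tab))) stop_domain("missing cells; no imputation")
  cells <- with(tab, table(condition, day))
  if (any(cells == 0) || length(unique(as.vector(cells))) != 1)
    stop_domain("design must be complete and balanced over condition x day")

  if (unit == "day") {
    agg <- stats::aggregate(percent_correct ~ condition + day, tab, mean)
    agg$condition <- factor(agg$condition)
    agg$day <- factor(agg$day)
    fit <- lm(percent_correct ~ condition + day, data = agg)
    an <- anova(fit)
    dfe <- an["Residuals", "Df"]
    res <- data.frame(
      effect = c("condition", "day", "interaction"),
      df1 = c(an["condition", "Df"], an["day", "Df"], NA),
      df2 = c(dfe, dfe, NA),
      F = c(an["condition", "F value"], an["day", "F value"], NA),
      p = c(an["condition", "Pr(>F)"], an["day", "Pr(>F)"], NA))
    resid_vec <- stats::residuals(fit)
  } else {
    tab$subject <- factor(tab$subject)
    tab$day <- factor(tab$day)
    tab$condition <- factor(tab$condition)
    fit <- aov(percent_correct ~ condition * day +
                 Error(subject / (condition * day)), data = tab)
    sm <- summary(fit)
    pick <- function(stratum, term) {
      tab2 <- sm[[stratum]][[1L]]
      i <- grep(term, trimws(rownames(tab2)), fixed = TRUE)[1L]
      j <- grep("Residuals", trimws(rownames(tab2)), fixed = TRUE)[1L]
      c(df1 = tab2[i, "Df"], df2 = tab2[j, "Df"],
        F = tab2[i, "F value"], p = tab2[i, "Pr(>F)"])
    }
    ce <- pick("Error: subject:condition", "condition")
    de <- pick("Error: subject:day", "day")
    ie <- pick("Error: subject:condition:day", "condition:day")
    res <- data.frame(effect = c("condition", "day", "interaction"),
                      df1 = c(ce[1], de[1], ie[1]),
                      df2 = c(ce[2], de[2], ie[2]),
                      F = c(ce[3], de[3], ie[3]),
                      p = c(ce[4], de[4], ie[4]))
    resid_vec <- stats::residuals(lm(percent_correct ~ subject + condition * day,
                                     data = tab))
  }
  lp <- tryCatch(nortest::lillie.test(resid_vec)$p.value,
                 error = function(e) NA_real_)
  structure(res, class = c("anova_result", "data.frame"), lilliefors_p = lp,
            unit = unit)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (unit: %s)\n", attr(x, "unit")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("Lilliefors p on conditional residuals: %.4g\n",
              attr(x, "lilliefors_p")))
  invisible(x)
}
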