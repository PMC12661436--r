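#' Simulate an operant lever-pressing session
#'
#' Presses are drawn from a homogeneous Poisson policy (the press-rate
#' magnitudes on interval schedules are free parameters of the simulation);
#' rewards are assigned by the reinforcement-schedule engine
#' ([run_schedule()]): CRF pays every press, FR(k) every k-th press, and a
#' variable-interval schedule arms after Uniform(mean - jitter,
#' mean + jitter) seconds and pays the first subsequent press (the VI30
#' protocol uses mean 30 s, jitter 5 s).
#'
#' @param schedule A schedule spec from [schedule_crf()], [schedule_fr()] or
#'   [schedule_vi()].
#' @param press_rate Poisson press rate in presses/s, or a function
#'   `f(t)` giving the instantaneous rate (state-dependent policies).
#' @param duration Session length in seconds.
#' @param seed Integer seed.
#' @return An [event_series()] with presses and rewards.
#' @export
simulate_operant_session <- function(schedule, press_rate, duration, seed) {
  if (!inherits(schedule, "schedule_spec")) stop_domain("unknown schedule")
  if (duration <= 0) stop_domain("duration must be > 0")
  with_seed(seed, {
    presses <- if (is.function(press_rate)) {
      rmax <- max(vapply(seq(0, duration, length.out = 1001), press_rate,
                         numeric(1)))
      if (rmax <= 0) stop_domain("press rate must be > 0")
      cand <- sort(runif(rpois(1L, rmax * duration), 0, duration))
      cand[runif(length(cand)) < vapply(cand, press_rate, numeric(1)) / rmax]
    } else {
      if (press_rate <= 0) stop_domain("press rate must be > 0")
      sort(runif(rpois(1L, press_rate * duration), 0, duration))
    }
    rewards <- run_schedule(schedule, presses, seed = derive_seed(seed, 1L))
    event_series(presses, rewards)
  })
}

#' Build a randomized trial-block sequence
#'
#' Equal counts per type, no type repeating more than `max_run` times in a
#' row, block durations Uniform(60 - 3, 60 + 3) s, and inter-trial
#' intervals Uniform(1, 4) s. The same set of durations is assigned to
#' every type (shuffled within type), so total time per type is equalized
#' exactly.
#'
#' @param n_trials Number of trials; must be divisible by the number of
#'   types.
#' @param types Character vector of trial types.
#' @param max_run Maximum run length of a single type (default 3).
#' @param seed Integer seed.
#' @param duration_mean,duration_jitter Block duration parameters (s);
#'   defaults 60 and 3.
#' @param iti_range Inter-trial-interval range (s), default `c(1, 4)`.
#' @param opto_types Types flagged as receiving optogenetic light.
#' @return A [trial_blocks()] table.
#' @export
make_trial_sequence <- function(n_trials, types = c("S+A", "S-A", "S+B", "S-B"),
                                max_run = 3, seed = 1,
                                duration_mean = 60, duration_jitter = 3,
                                iti_range = c(1, 4),
                                opto_types = c("S+A", "S-A")) {
  k <- length(types)
  if (k < 1 || n_trials %% k != 0)
    stop_domain("n_trials must be divisible by the number of types")
  if (max_run < 1) stop_domain("max_run must be >= 1")
  per <- n_trials / k
  if (k == 1 && per > max_run) stop_domain("constraint infeasible with one type")
  with_seed(seed, {
    seq_types <- NULL
    for (attempt in seq_len(10000L)) {
      cand <- sample(rep(types, per))
      r <- rle(cand)
      if (max(r$lengths) <= max_run) { seq_types <- cand; break }
    }
    if (is.null(seq_types)) stop_domain("could not satisfy run-length constraint")
    durs_one <- runif(per, duration_mean - duration_jitter,
                      duration_mean + duration_jitter)
    durations <- numeric(n_trials)
    for (ty in types)            # same duration multiset per type
      durations[seq_types == ty] <- sample(durs_one)
    itis <- pmax(runif(n_trials, iti_range[1], iti_range[2]), 0)
    start <- cumsum(c(0, durations[-n_trials] + itis[-n_trials]))
    trial_blocks(seq_types, start, start + durations,
                 opto = seq_types %in% opto_types)
  })
}

#' Define a discrimination-learning recipe
#'
#' Control performance follows a logistic learning curve from chance to
#' asymptote; the opto condition adds a stage-specific additive effect
#' (in percentage points). Stages are the first, middle and last
#' `stage_len` days of training.
#'
#' @param n_subjects,n_days Design size.
#' @param asymptote Asymptotic percent correct.
#' @param slope Logistic slope per day.
#' @param chance Chance level (default 50).
#' @param opto_effect Named numeric vector of additive effects (percentage
#'   points) by stage, e.g. `c(first = 15, middle = 0, last = 0)`.
#' @param session_noise_sd SD of the per-session noise in percentage points.
#' @param stage_len Days per stage (default 7).
#' @return An object of class `learning_recipe`.
#' @export
learning_recipe <- function(n_subjects = 7, n_days = 21, asymptote = 85,
                            slope = 0.4, chance = 50,
                            opto_effect = c(first = 0, middle = 0, last = 0),
                            session_noise_sd = 3, stage_len = 7) {
  if (!(chance >= 0 && chance <= asymptote && asymptote <= 100))
    stop_domain("need 0 <= chance <= asymptote <= 100")
  if (session_noise_sd < 0) stop_domain("session_noise_sd must be >= 0")
  structure(list(n_subjects = n_subjects, n_days = n_days,
                 asymptote = asymptote, slope = slope, chance = chance,
                 opto_effect = opto_effect,
                 session_noise_sd = session_noise_sd, stage_len = stage_len),
            class = "learning_recipe")
}

#' Simulate a multi-day discrimination-learning course
#'
#' @param recipe A [learning_recipe()].
#' @param seed Integer seed.
#' @return A `performance_table` data frame with columns `subject`, `day`,
#'   `condition` ("opto"/"control") and `percent_correct` (clipped to
#'   `[0, 100]`).
#' @export
simulate_discrimination_course <- function(recipe, seed) {
  stopifnot(inherits(recipe, "learning_recipe"))
  with_seed(seed, {
    days <- seq_len(recipe$n_days)
    mid <- (1 + recipe$n_days) / 2
    base <- recipe$chance +
      (recipe$asymptote - recipe$chance) * plogis(recipe$slope * (days - mid))
    stages <- stage_split(days, stage_len = recipe$stage_len)
    stage_of <- rep(NA_character_, recipe$n_days)
    for (snm in names(stages)) stage_of[match(stages[[snm]], days)] <- snm
    grid <- expand.grid(subject = seq_len(recipe$n_subjects), day = days,
                        condition = c("control", "opto"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    eff <- ifelse(grid$condition == "opto" & !is.na(stage_of[grid$day]),
                  unname(recipe$opto_effect[stage_of[grid$day]]), 0)
    eff[is.na(eff)] <- 0
    pc <- base[grid$day] + eff + rnorm(nrow(grid), 0, recipe$session_noise_sd)
    grid$percent_correct <- pmin(pmax(pc, 0), 100)
    class(grid) <- c("performance_table", "data.frame")
    grid
  })
}
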