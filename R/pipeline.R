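#' Pipeline run configuration
#'
#' Aggregates the protocol constants every stage consumes: the
#' stimulation frequency set (5, 10, 20, 30, 40 Hz at 50% duty), the
#' gamma band (40-60 Hz), epoch and STA windows, the 40/35 Hz SFC
#' target/control pair, and the 7-day learning-stage length. Values are
#' validated against the preconditions of the operations they feed.
#'
#' @param seed Master seed; stages derive sub-seeds via [derive_seed()].
#' @param alpha Significance level.
#' @param stim_freqs Stimulation frequencies (Hz).
#' @param duty Duty cycle.
#' @param band Gamma band (Hz).
#' @param epoch_len LFP epoch length (s).
#' @param sta_window STA window length (s); the half-window is half this.
#' @param f_target,f_control SFC target/control frequencies (Hz).
#' @param stage_len Learning-stage length in days.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, alpha = 0.05,
                       stim_freqs = c(5, 10, 20, 30, 40), duty = 0.5,
                       band = c(40, 60), epoch_len = 1, sta_window = 0.2,
                       f_target = 40, f_control = 35, stage_len = 7,
                       out_dir = tempfile("optoentrain_run_")) {
  if (any(stim_freqs <= 0)) stop_domain("stimulation frequencies must be > 0")
  if (duty <= 0 || duty > 1) stop_domain("duty must be in (0, 1]")
  if (length(band) != 2 || band[1] >= band[2])
    stop_domain("band must be an increasing pair")
  if (alpha <= 0 || alpha >= 1) stop_domain("alpha must be in (0, 1)")
  if (epoch_len <= 0 || sta_window <= 0) stop_domain("windows must be > 0")
  if (stage_len < 1) stop_domain("stage_len must be >= 1")
  structure(list(seed = seed, alpha = alpha, stim_freqs = stim_freqs,
                 duty = duty, band = band, epoch_len = epoch_len,
                 sta_window = sta_window, f_target = f_target,
                 f_control = f_control, stage_len = stage_len,
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Generate a preset synthetic session bundle
#'
#' Presets: `"entrain40"` — 40 Hz square-pulse-entrained LFP plus an
#' excited-on unit (the spike-field fixture); `"vi30"` — a VI30 +/- 5 s
#' operant session with behavior-gated gamma; `"discrimination"` — an
#' auditory-discrimination session with a randomized trial-block
#' sequence.
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @param duration Session duration (s); defaults per preset.
#' @return A [session()].
#' @export
simulate_preset <- function(preset = c("entrain40", "vi30", "discrimination"),
                            seed = 1, duration = NULL) {
  preset <- match.arg(preset)
  if (preset == "entrain40") {
    duration <- duration %||% 120
    stim <- make_pulse_train(40, 0.5, duration)
    lfp <- simulate_lfp(lfp_recipe(pink_noise_sd = 1, entrain_amp = 1.5,
                                   harmonics = TRUE),
                        stim = stim, rate = 1000, duration = duration,
                        seed = derive_seed(seed, 1L), region = "LHb")
    unit <- simulate_unit(unit_archetype("excited_on", baseline_rate = 5,
                                         gain = 20),
                          stim, duration, seed = derive_seed(seed, 2L),
                          unit_id = "vp1", region = "VP")
    session(signals = list(lfp), spikes = list(unit), stim = list(stim),
            metadata = list(preset = preset, seed = seed))
  } else if (preset == "vi30") {
    duration <- duration %||% 600
    ev <- simulate_operant_session(schedule_vi(30, 5), press_rate = 0.3,
                                   duration = duration,
                                   seed = derive_seed(seed, 1L))
    states <- press_state_intervals(ev$presses, duration)
    lfp <- simulate_lfp(lfp_recipe(pink_noise_sd = 1, gamma_burst_amp = 0.5,
                                   behavior_gate = c(high = 2, low = 1)),
                        states = states, rate = 200, duration = duration,
                        seed = derive_seed(seed, 2L), region = "VP")
    session(signals = list(lfp), events = ev,
            metadata = list(preset = preset, seed = seed, schedule = "VI30"))
  } else {
    duration <- duration %||% NULL
    blocks <- make_trial_sequence(12, seed = derive_seed(seed, 1L))
    total <- max(blocks$end)
    ev <- simulate_operant_session(schedule_vi(30, 5), press_rate = 0.3,
                                   duration = total,
                                   seed = derive_seed(seed, 2L))
    session(blocks = blocks, events = ev,
            metadata = list(preset = preset, seed = seed, schedule = "AD"))
  }
}

# High/low pressing intervals from the press train itself (10 s grid),
# used to gate synthetic gamma by behavioral state.
press_state_intervals <- function(presses, duration, window = 10) {
  edges <- seq(0, duration, by = window)
  if (length(edges) < 2) return(data.frame(state = character(),
                                           start = numeric(), end = numeric()))
  n <- length(edges) - 1L
  counts <- vapply(seq_len(n), function(i)
    sum(presses >= edges[i] & presses < edges[i + 1L]), numeric(1))
  data.frame(state = ifelse(counts >= 2, "high",
                            ifelse(counts == 0, "low", "mid")),
             start = edges[-length(edges)], end = edges[-1L])
}

#' Run the analysis pipeline on a session
#'
#' Executes the stages applicable to the session's contents in dependency
#' order — stimulation-response classification and phase locking when
#' spikes and pulse trains are present, spike-field coherence when an LFP
#' accompanies them, band-power analysis when an LFP and press events are
#' present — and writes machine-readable TSV/JSON results plus per-stage
#' provenance (config, derived sub-seed) to `config$out_dir`. Reruns with
#' the same config and seed produce byte-identical results.
#'
#' @param config A [run_config()].
#' @param bundle A [session()] or a bundle directory path.
#' @return Named list of stage results, invisibly; written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, bundle) {
  stopifnot(inherits(config, "run_config"))
  s <- if (inherits(bundle, "session")) bundle else read_session(bundle)
  validate_session(s)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  # a session that does not meet a stage's preconditions (e.g. too few
  # stimulation trains) skips that stage; any other failure aborts naming it
  stage <- function(name, expr) {
    tryCatch(expr,
             optoentrain_domain_error = function(e) {
               message("stage '", name, "' skipped: ", conditionMessage(e))
               NULL
             },
             error = function(e)
               stop_io("stage '", name, "' failed: ", conditionMessage(e)))
  }

  if (length(s$spikes) && length(s$stim)) {
    results$modulation <- stage("analyze-stim", {
      rows <- do.call(rbind, lapply(s$spikes, function(u) {
        do.call(rbind, lapply(s$stim, function(pt) {
          m <- classify_modulation(u, pt, alpha = config$alpha)
          data.frame(unit_id = m$unit_id, f = pt$freq,
                     baseline_rate = m$baseline_rate, stim_rate = m$stim_rate,
                     test_used = m$test_used, p = m$p, class = m$class)
        }))
      }))
      utils::write.table(rows, file.path(config$out_dir, "modulation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rows
    })
    results$phase <- stage("analyze-phase", {
      rows <- do.call(rbind, lapply(s$spikes, function(u) {
        do.call(rbind, lapply(s$stim, function(pt) {
          r <- phase_locking(u, pt, alpha = config$alpha)
          data.frame(unit_id = r$unit_id, f = r$f, R = r$R,
                     rayleigh_p = r$rayleigh_p,
                     mean_phase_deg = r$mean_phase * 180 / pi,
                     mode_phase_deg = r$mode_phase * 180 / pi,
                     n_spikes = r$n_spikes, locked = r$locked,
                     side = r$side %||% NA_character_)
        }))
      }))
      utils::write.table(rows, file.path(config$out_dir, "phase_locking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rows
    })
  }

  if (length(s$signals) && length(s$spikes)) {
    results$sfc <- stage("analyze-sfc", {
      lfp <- s$signals[[1L]]
      ep <- spike_centered_epochs(lfp, s$spikes[[1L]],
                                  half_window = config$sta_window / 2)
      sf <- spike_field_coherence(ep)
      tab <- data.frame(freq = sf$freqs, sfc = sf$sfc)
      attr(tab, "argmax") <- sfc_argmax(sf)
      utils::write.table(tab, file.path(config$out_dir, "sfc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
  }

  if (length(s$signals) && length(s$events$presses)) {
    results$band_power <- stage("analyze-lfp", {
      x <- s$signals[[1L]]
      if (x$rate > 200) x <- downsample(x, 200)
      er <- epoch_and_reject(x, epoch_len = config$epoch_len)
      sp <- psd(er$epochs, er$rate, kept = er$kept)
      pw <- band_power(sp$freqs, sp$per_epoch, band = config$band)
      lab <- label_press_epochs(s$events$presses, er$epoch_times[er$kept])
      cmp <- if (sum(lab == "high") >= 5 && sum(lab == "low") >= 5)
        compare_band_power(pw[lab == "high"], pw[lab == "low"],
                           design = "unpaired", alpha = config$alpha)
      else list(test = NA, statistic = NA, p = NA, significant = NA)
      tab <- data.frame(time = er$epoch_times[er$kept], power = pw,
                        label = lab)
      utils::write.table(tab, file.path(config$out_dir, "band_power.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(per_epoch = tab, comparison = cmp)
    })
  }

  provenance <- list(config = unclass(config),
                     seed = config$seed,
                     stages = names(results),
                     package_version = as.character(utils::packageVersion("optoentrain")))
  jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
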