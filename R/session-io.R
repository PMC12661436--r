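#' Write a session bundle to disk
#'
#' The on-disk bundle is language-neutral and bit-exact: a JSON manifest,
#' event tables as tab-delimited text, and signals as raw binary with
#' declared dtype and endianness.
#'
#' @param s A valid [session()].
#' @param path Directory to create.
#' @param force Overwrite an existing bundle? Default FALSE (error).
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path, force = FALSE) {
  validate_session(s)
  if (file.exists(file.path(path, "manifest.json")) && !force)
    stop_io("bundle already exists at '", path, "'; use force = TRUE to overwrite")
  ok <- dir.create(file.path(path, "events"), recursive = TRUE,
                   showWarnings = FALSE)
  dir.create(file.path(path, "signals"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(file.path(path, "events")))
    stop_io("cannot create bundle directory '", path, "'")

  write_tsv <- function(df, file) {
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       file, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  sig_entries <- lapply(seq_along(s$signals), function(i) {
    x <- s$signals[[i]]
    f <- sprintf("signals/%03d_%s.bin", i, x$channel_id)
    con <- file(file.path(path, f), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(x$samples, con, size = 8, endian = "little")
    list(file = f, channel_id = x$channel_id, region = x$region,
         rate = x$rate, t0 = x$t0, n = length(x$samples),
         dtype = "float64", endian = "little")
  })

  spk_entries <- lapply(seq_along(s$spikes), function(i) {
    x <- s$spikes[[i]]
    f <- sprintf("events/spikes_%03d.tsv", i)
    write_tsv(data.frame(time_s = x$times, label = x$unit_id), file.path(path, f))
    list(file = f, unit_id = x$unit_id, region = x$region)
  })

  stim_entries <- lapply(seq_along(s$stim), function(i) {
    x <- s$stim[[i]]
    f <- sprintf("events/stim_%03d.tsv", i)
    write_tsv(data.frame(onset_s = x$onsets, offset_s = x$offsets),
              file.path(path, f))
    list(file = f, freq = x$freq, duty = x$duty)
  })

  blocks_file <- NULL
  if (!is.null(s$blocks) && nrow(s$blocks)) {
    blocks_file <- "events/blocks.tsv"
    write_tsv(as.data.frame(s$blocks), file.path(path, blocks_file))
  }
  write_tsv(data.frame(time_s = s$events$presses,
                       label = rep("press", length(s$events$presses))),
            file.path(path, "events/presses.tsv"))
  write_tsv(data.frame(time_s = s$events$rewards,
                       label = rep("reward", length(s$events$rewards))),
            file.path(path, "events/rewards.tsv"))

  manifest <- list(format = "optoentrain-bundle", version = 1L,
                   metadata = s$metadata,
                   signals = sig_entries, spikes = spk_entries,
                   stim = stim_entries, blocks = blocks_file,
                   events = list(presses = "events/presses.tsv",
                                 rewards = "events/rewards.tsv"))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Reads a bundle written by [write_session()] and revalidates every
#' invariant; corrupt fields raise a validation error naming the field.
#'
#' @param path Bundle directory containing `manifest.json`.
#' @return A validated [session()].
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_io("no manifest.json under '", path, "'")
  manifest <- jsonlite::read_json(mf)

  read_tsv <- function(rel) {
    f <- file.path(path, rel)
    if (!file.exists(f)) stop_io("missing bundle file '", rel, "'")
    utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }

  signals <- lapply(manifest$signals, function(e) {
    f <- file.path(path, e$file)
    if (!file.exists(f)) stop_io("missing signal file '", e$file, "'")
    if (!identical(e$dtype, "float64"))
      stop_validation("dtype", "unsupported dtype '", e$dtype, "'")
    con <- file(f, "rb")
    on.exit(close(con), add = TRUE)
    samples <- readBin(con, "double", n = e$n, size = 8, endian = e$endian)
    if (length(samples) != e$n)
      stop_validation("n", "signal '", e$file, "' shorter than declared")
    continuous_signal(samples, rate = e$rate, t0 = e$t0, region = e$region,
                      channel_id = e$channel_id)
  })
  spikes <- lapply(manifest$spikes, function(e) {
    tab <- read_tsv(e$file)
    spike_train(tab$time_s, unit_id = e$unit_id, region = e$region)
  })
  stim <- lapply(manifest$stim, function(e) {
    tab <- read_tsv(e$file)
    pulse_train(tab$onset_s, tab$offset_s, freq = e$freq, duty = e$duty)
  })
  blocks <- NULL
  if (!is.null(manifest$blocks)) {
    tab <- read_tsv(manifest$blocks)
    blocks <- trial_blocks(tab$type, tab$start, tab$end, tab$opto)
  }
  presses <- read_tsv(manifest$events$presses)$time_s %||% numeric()
  rewards <- read_tsv(manifest$events$rewards)$time_s %||% numeric()
  session(signals = signals, spikes = spikes, stim = stim, blocks = blocks,
          events = event_series(as.double(presses), as.double(rewards)),
          metadata = manifest$metadata)
}
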