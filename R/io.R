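#' Write and read EEG recordings
#'
#' Two on-disk dialects are supported. CSV: a header row of `time` plus the
#' montage channel labels, one sample per row, values in uV; lossless.
#' EDF (European Data Format): standard 16-bit EDF with one data record per
#' second, physical dimension uV and channel labels equal to the montage
#' names; values round-trip to within the 16-bit quantization step.
#' `read_eeg()` dispatches on the file extension, reorders channels to the
#' device profile, and checks labels and sampling rate against it.
#'
#' @param rec An [eeg_recording()].
#' @param path Output/input file path (`.csv` or `.edf`).
#' @param device Expected [device_profile()] on read.
#' @return `read_eeg()` returns an [eeg_recording()]; the writers return
#'   `path` invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(rec)[, c("time", eeg_channels(rec))]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg <- function(path, device = device_profile()) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    read_eeg_csv(path, device)
  } else if (ext == "edf") {
    read_edf(path, device)
  } else {
    abort(sprintf("unsupported EEG file extension '.%s' (use .csv or .edf).", ext))
  }
}

read_eeg_csv <- function(path, device = device_profile()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) {
    abort("CSV must have a `time` first column.")
  }
  missing <- setdiff(device$channel_names, names(df))
  if (length(missing)) {
    abort(paste0(
      "CSV lacks channel column(s): ", paste(missing, collapse = ", ")
    ))
  }
  dt <- diff(df$time)
  if (any(dt <= 0)) {
    abort("`time` column must be strictly increasing.")
  }
  fs <- 1 / stats::median(dt)
  if (abs(fs - device$sampling_rate_hz) / device$sampling_rate_hz > 0.001) {
    abort(sprintf(
      "sampling rate in file (%.3f Hz) does not match the device profile (%g Hz).",
      fs, device$sampling_rate_hz
    ))
  }
  eeg_recording(
    as.matrix(df[, device$channel_names, drop = FALSE]),
    device = device,
    start_time_s = df$time[1]
  )
}

# ---- EDF (16-bit European Data Format) -----------------------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' @rdname write_eeg_csv
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- eeg_srate(rec)
  if (abs(fs - round(fs)) > 1e-9) {
    abort("EDF export needs an integer sampling rate.")
  }
  fs <- as.integer(round(fs))
  data <- eeg_matrix(rec)
  ns <- ncol(data)
  # whole data records of 1 s; pad the tail with zeros
  n_rec <- ceiling(nrow(data) / fs)
  pad <- n_rec * fs - nrow(data)
  if (pad > 0) {
    data <- rbind(data, matrix(0, pad, ns))
  }
  phys_max <- pmax(apply(abs(data), 2, max), 1)
  phys_max <- ceiling(phys_max)
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste0("X X X ", attr(rec, "participant_id") %||% "X"), 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    paste0(vapply(eeg_channels(rec), edf_pad, character(1), width = 16), collapse = ""),
    paste0(rep(edf_pad("synthetic EEG", 80), ns), collapse = ""),
    paste0(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste0(vapply(-phys_max, edf_pad, character(1), width = 8), collapse = ""),
    paste0(vapply(phys_max, edf_pad, character(1), width = 8), collapse = ""),
    paste0(rep(edf_pad(-dig_max, 8), ns), collapse = ""),
    paste0(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste0(rep(edf_pad("", 80), ns), collapse = ""),
    paste0(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste0(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(fields, collapse = ""), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- vapply(seq_len(ns), function(ch) {
      as.integer(round(data[idx, ch] / phys_max[ch] * dig_max))
    }, integer(fs))
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_edf <- function(path, device = device_profile()) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8 + 80 + 80 + 8 + 8, useBytes = TRUE)
  readChar(con, 8, useBytes = TRUE) # header bytes
  readChar(con, 44, useBytes = TRUE)
  n_rec <- as.integer(readChar(con, 8, useBytes = TRUE))
  rec_dur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))
  labels <- trimws(vapply(seq_len(ns), function(i) {
    readChar(con, 16, useBytes = TRUE)
  }, character(1)))
  readChar(con, 80 * ns, useBytes = TRUE)
  units <- trimws(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), character(1)))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), character(1)))
  readChar(con, 80 * ns, useBytes = TRUE)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), character(1)))
  readChar(con, 32 * ns, useBytes = TRUE)

  missing <- setdiff(device$channel_names, labels)
  if (length(missing)) {
    abort(paste0(
      "EDF lacks channel(s): ", paste(missing, collapse = ", ")
    ))
  }
  fs <- nsamp[1] / rec_dur
  if (abs(fs - device$sampling_rate_hz) / device$sampling_rate_hz > 0.001) {
    abort(sprintf(
      "sampling rate in file (%.3f Hz) does not match the device profile (%g Hz).",
      fs, device$sampling_rate_hz
    ))
  }
  data <- matrix(0, n_rec * nsamp[1], ns)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, integer(), n = nsamp[ch], size = 2, endian = "little")
      scaled <- phys_min[ch] +
        (raw - dig_min[ch]) / (dig_max[ch] - dig_min[ch]) *
          (phys_max[ch] - phys_min[ch])
      data[((r - 1) * nsamp[ch] + 1):(r * nsamp[ch]), ch] <- scaled
    }
  }
  colnames(data) <- labels
  eeg_recording(
    data[, device$channel_names, drop = FALSE],
    device = device
  )
}

# ---- TSV interchange ------------------------------------------------------

#' Events, responses, features, centroids and ground-truth TSV files
#'
#' Tab-separated interchange formats. Events files follow a BIDS-events-like
#' dialect: `onset` and `duration` in seconds, `trial_type` holding the
#' emotion label, plus `condition`, `stimulus_id`, `with_music`, `face_sex`
#' and the participant metadata columns. Feature files hold one row per
#' retained analysis window and round-trip [epoch_affect()] output exactly.
#'
#' @param schedule,responses,features,centroids,truth The object to write.
#' @param path File path.
#' @param transition_s Transition length restored on read (default 5 s).
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  df <- as_tibble(schedule) %>%
    mutate(onset = .data$onset_s, duration = .data$duration_s,
           trial_type = .data$emotion) %>%
    select("onset", "duration", "trial_type", "condition", "stimulus_id",
           "with_music", "face_sex", "participant_id", "group",
           "session_index")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path, transition_s = 5) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  events <- tibble(
    participant_id = as.character(df$participant_id),
    group = as.character(df$group),
    session_index = as.integer(df$session_index),
    condition = as.character(df$condition),
    onset_s = df$onset,
    duration_s = df$duration,
    emotion = as.character(df$trial_type),
    face_sex = as.character(df$face_sex),
    stimulus_id = as.character(df$stimulus_id),
    with_music = as.logical(df$with_music)
  )
  new_stimulus_schedule(events, transition_s = transition_s)
}

#' @rdname write_events_tsv
#' @export
write_responses_tsv <- function(responses, path) {
  write.table(responses, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_responses_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  as_tibble(df) %>%
    mutate(
      session_index = as.integer(.data$session_index),
      correct = as.logical(.data$correct)
    )
}

#' @rdname write_events_tsv
#' @export
write_features_tsv <- function(features, path) {
  stopifnot(inherits(features, "epoch_feature_set"))
  df <- as_tibble(features) %>%
    mutate(normalization = attr(features, "normalization") %||% "raw")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_features_tsv <- function(path) {
  df <- as_tibble(read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE))
  norm <- if ("normalization" %in% names(df)) df$normalization[1] else "raw"
  df$normalization <- NULL
  df$session_index <- as.integer(df$session_index)
  new_epoch_feature_set(df, normalization = norm)
}

#' @rdname write_events_tsv
#' @export
write_centroids_tsv <- function(centroids, path) {
  stopifnot(inherits(centroids, "centroid_set"))
  write.table(as_tibble(centroids), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
write_ground_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "affect_ground_truth"))
  write.table(as_tibble(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
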