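#' Epoched EEG container
#'
#' A minimal trials x channels x samples container for epoched EEG, with
#' sampling rate, channel labels, the time of the first sample relative
#' to stimulus onset, and an aligned per-trial event table.
#'
#' @param data numeric array `[trials, channels, samples]`, in microvolts.
#' @param srate sampling rate in Hz.
#' @param channels character vector of unique channel labels.
#' @param tmin_ms time of the first sample relative to stimulus onset (ms).
#' @param events data.frame with one row per trial (roles, items,
#'   correctness, RT, ...); may be `NULL`.
#' @return object of class `epochset`.
#' @export
epochset <- function(data, srate, channels, tmin_ms, events = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, srate > 0)
  if (dim(data)[2] != length(channels)) {
    stopf("data has %d channels but %d labels given", dim(data)[2],
          length(channels))
  }
  if (anyDuplicated(channels)) stopf("channel labels must be unique")
  if (!is.null(events) && nrow(events) != dim(data)[1]) {
    stopf("event table has %d rows but data has %d trials", nrow(events),
          dim(data)[1])
  }
  structure(list(data = data, srate = srate, channels = channels,
                 tmin_ms = tmin_ms, events = events),
            class = "epochset")
}

#' @export
print.epochset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epochset: %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g) ms\n",
              d[1], d[2], d[3], x$srate, x$tmin_ms,
              x$tmin_ms + d[3] / x$srate * 1000))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Sample times of an epochset (ms relative to stimulus onset)
#' @param x an `epochset`.
#' @return numeric vector, one time per sample.
#' @export
epoch_times <- function(x) {
  x$tmin_ms + (seq_len(dim(x$data)[3]) - 1L) / x$srate * 1000
}

#' Number of epochs
#' @param x an `epochset`.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' Subset epochs (and the aligned event table)
#' @param x an `epochset`.
#' @param idx trial indices or logical mask.
#' @export
subset_epochs <- function(x, idx) {
  x$data <- x$data[idx, , , drop = FALSE]
  if (!is.null(x$events)) x$events <- x$events[idx, , drop = FALSE]
  x
}

#' Extract one channel as a trials x samples matrix
#' @param x an `epochset`.
#' @param channel channel label.
#' @export
channel_matrix <- function(x, channel) {
  i <- match(channel, x$channels)
  if (is.na(i)) stopf("channel '%s' not present", channel)
  m <- x$data[, i, , drop = FALSE]
  dim(m) <- dim(x$data)[c(1, 3)]
  m
}

#' Write an epochset to a directory (plain-text container)
#'
#' Writes `meta.json` (srate, channels, window), `events.csv`, and one
#' `data_<channel>.csv` matrix (trials x samples) per channel.
#'
#' @param x an `epochset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epochset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(srate = x$srate, channels = x$channels, tmin_ms = x$tmin_ms,
               n_trials = dim(x$data)[1], n_samples = dim(x$data)[3])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(x$events)) {
    utils::write.csv(x$events, file.path(dir, "events.csv"),
                     row.names = FALSE)
  }
  for (ch in x$channels) {
    utils::write.table(channel_matrix(x, ch),
                       file.path(dir, paste0("data_", ch, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read an epochset written by [write_epochset()]
#' @param dir directory containing the container files.
#' @return an `epochset`.
#' @export
read_epochset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  events_path <- file.path(dir, "events.csv")
  events <- if (file.exists(events_path)) {
    utils::read.csv(events_path, stringsAsFactors = FALSE)
  } else NULL
  data <- array(NA_real_, c(meta$n_trials, length(meta$channels),
                            meta$n_samples))
  for (i in seq_along(meta$channels)) {
    m <- as.matrix(utils::read.csv(
      file.path(dir, paste0("data_", meta$channels[i], ".csv")),
      header = FALSE))
    data[, i, ] <- m
  }
  epochset(data, meta$srate, meta$channels, meta$tmin_ms, events)
}
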