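#' @title EEG preprocessing chain
#'
#' @description
#' Reproduces the processing chain from (continuous or epoched)
#' recordings to clean, baseline-corrected, linked-mastoid-referenced Pz
#' epochs, in this fixed order: resample to 250 Hz, Hamming-windowed sinc
#' FIR bandpass (0.3-30 Hz, cutoffs at -6 dB), epoch extraction
#' (-100 to 1400 ms), baseline correction (-100 to 0 ms), ocular-artifact
#' removal by least-squares EOG regression, rejection of epochs exceeding
#' +/- 75 uV on Pz or either mastoid, and re-referencing of Pz to linked
#' mastoids.
#' @name preprocess
NULL

#' Continuous multichannel recording container
#'
#' @param data numeric matrix, channels x samples (uV).
#' @param srate sampling rate (Hz).
#' @param channels channel labels (one per row).
#' @return object of class `recording`.
#' @export
recording <- function(data, srate, channels) {
  stopifnot(is.matrix(data), nrow(data) == length(channels), srate > 0)
  structure(list(data = data, srate = srate, channels = channels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  invisible(x)
}

#' Bandpass FIR filter specification
#'
#' Windowed-sinc FIR design with a Hamming window; the cutoff frequencies
#' sit at the -6 dB points of the transition bands. Transition bandwidths
#' default to the common heuristic `min(max(0.25 * low, 2), low)` Hz at
#' the low edge (a transition wider than the cutoff itself would misplace
#' the -6 dB point) and 7.5 Hz at the high edge; the kernel length is set
#' by the narrower band.
#'
#' @param low,high cutoff frequencies in Hz.
#' @param trans_low,trans_high transition bandwidths in Hz.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.3, high = 30,
                        trans_low = min(max(0.25 * low, 2), low),
                        trans_high = 7.5) {
  stopifnot(low > 0, high > low)
  structure(list(low = low, high = high, trans_low = trans_low,
                 trans_high = trans_high), class = "filter_spec")
}

# Hamming-windowed sinc lowpass kernel with unit DC gain and -6 dB at fc.
sinc_lowpass <- function(fc, srate, n_taps) {
  stopifnot(n_taps %% 2 == 1)
  m <- (n_taps - 1) / 2
  t <- (-m):m
  x <- 2 * fc / srate * t
  h <- 2 * fc / srate * ifelse(t == 0, 1, sin(pi * x) / (pi * x))
  w <- 0.54 + 0.46 * cos(pi * t / m)
  h <- h * w
  h / sum(h)
}

#' Design the Hamming-windowed sinc FIR bandpass kernel
#'
#' @param spec a [filter_spec()].
#' @param srate sampling rate (Hz).
#' @return numeric vector of filter taps (odd length, linear phase).
#' @export
fir_bandpass_kernel <- function(spec, srate) {
  if (spec$high >= srate / 2) {
    stopf("high cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          spec$high, srate / 2)
  }
  # Hamming transition width ~= 3.3 / (N * dt); narrower band sets N
  tb <- min(spec$trans_low, spec$trans_high)
  n_taps <- ceiling(3.3 * srate / tb)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  sinc_lowpass(spec$high, srate, n_taps) - sinc_lowpass(spec$low, srate, n_taps)
}

# Zero-phase FIR application: symmetric (linear-phase) kernel applied by
# convolution with edge padding and group-delay compensation.
fir_apply <- function(x, h) {
  m <- (length(h) - 1) / 2
  padded <- c(rep(x[1], m), x, rep(x[length(x)], m))
  y <- stats::filter(padded, h, method = "convolution", sides = 2)
  as.numeric(y[(m + 1):(m + length(x))])
}

#' Apply the bandpass filter
#'
#' Zero-phase application (symmetric FIR, group delay compensated) to a
#' numeric vector, a `recording` (per channel) or an `epochset` (per
#' trial and channel; intended for simulation checks — recorded data
#' should be filtered continuously, before epoching).
#'
#' @param x numeric vector, `recording` or `epochset`.
#' @param spec a [filter_spec()].
#' @param srate sampling rate, required for plain vectors.
#' @return filtered object of the same type.
#' @export
bandpass_fir <- function(x, spec = filter_spec(), srate = NULL) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (is.null(srate)) stopf("srate required for plain vectors")
    return(fir_apply(x, fir_bandpass_kernel(spec, srate)))
  }
  if (inherits(x, "recording")) {
    h <- fir_bandpass_kernel(spec, x$srate)
    x$data <- t(apply(x$data, 1, fir_apply, h = h))
    return(x)
  }
  if (inherits(x, "epochset")) {
    h <- fir_bandpass_kernel(spec, x$srate)
    d <- dim(x$data)
    for (c_i in seq_len(d[2])) {
      x$data[, c_i, ] <- t(apply(x$data[, c_i, , drop = TRUE], 1,
                                 fir_apply, h = h))
    }
    return(x)
  }
  stopf("unsupported input of class %s", paste(class(x), collapse = "/"))
}

#' Resample a recording (anti-aliased downsampling)
#'
#' Integer-factor decimation: a Hamming-windowed sinc anti-alias lowpass
#' (cutoff at 0.45 times the target rate) applied zero-phase, then every
#' q-th sample kept.
#'
#' @param x a `recording`.
#' @param target_srate target rate in Hz; must not exceed the original
#'   and must divide it.
#' @param events optional data.frame with an `onset_sample` column;
#'   indices are remapped to the new rate and returned as the
#'   `"events"` attribute.
#' @return the resampled `recording`.
#' @export
resample_recording <- function(x, target_srate, events = NULL) {
  stopifnot(inherits(x, "recording"))
  if (target_srate > x$srate) {
    stopf("upsampling (%g -> %g Hz) is not supported", x$srate, target_srate)
  }
  if (target_srate == x$srate) {
    if (!is.null(events)) attr(x, "events") <- events
    return(x)
  }
  q <- x$srate / target_srate
  if (abs(q - round(q)) > 1e-9) {
    stopf("target rate must divide the original rate (%g / %g)",
          x$srate, target_srate)
  }
  q <- round(q)
  fc <- 0.45 * target_srate
  tb <- 0.1 * target_srate
  n_taps <- ceiling(3.3 * x$srate / tb)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  h <- sinc_lowpass(fc, x$srate, n_taps)
  keep <- seq(1, ncol(x$data), by = q)
  x$data <- t(apply(x$data, 1, function(ch) fir_apply(ch, h)[keep]))
  x$srate <- target_srate
  if (!is.null(events)) {
    events$onset_sample <- floor((events$onset_sample - 1) / q) + 1L
    attr(x, "events") <- events
  }
  x
}

#' Extract fixed-window epochs around stimulus onsets
#'
#' Uses the half-open `[t0, t1)` sample convention: an epoch spans
#' `round((t1 - t0)/1000 * srate)` samples and the sample at time zero is
#' the stimulus-onset sample. Onsets without room for the full window are
#' skipped and reported in the `"skipped"` attribute.
#'
#' @param x a `recording`.
#' @param events data.frame with an `onset_sample` column (1-based sample
#'   index of stimulus onset); remaining columns become the epoch event
#'   table.
#' @param window epoch window in ms, default `c(-100, 1400)`.
#' @return an `epochset`.
#' @export
extract_epochs <- function(x, events, window = c(-100, 1400)) {
  stopifnot(inherits(x, "recording"), "onset_sample" %in% names(events))
  n_samp <- round(diff(window) / 1000 * x$srate)
  pre <- round(-window[1] / 1000 * x$srate)
  starts <- events$onset_sample - pre
  ok <- starts >= 1 & (starts + n_samp - 1) <= ncol(x$data)
  skipped <- which(!ok)
  if (length(skipped)) {
    message(sprintf("extract_epochs: skipped %d truncated epoch(s): %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  starts <- starts[ok]
  data <- array(0, c(length(starts), nrow(x$data), n_samp))
  for (e in seq_along(starts)) {
    data[e, , ] <- x$data[, starts[e]:(starts[e] + n_samp - 1)]
  }
  out <- epochset(data, x$srate, x$channels, window[1],
                  events[ok, setdiff(names(events), "onset_sample"),
                         drop = FALSE])
  attr(out, "skipped") <- skipped
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (half-open `[t0, t1)`; default the 100 ms before stimulus onset).
#'
#' @param x an `epochset`.
#' @param baseline two-element window in ms.
#' @return the corrected `epochset`.
#' @export
baseline_correct <- function(x, baseline = c(-100, 0)) {
  t <- epoch_times(x)
  sel <- t >= baseline[1] - 1e-9 & t < baseline[2] - 1e-9
  if (!any(sel)) stopf("baseline window [%g, %g) contains no samples",
                       baseline[1], baseline[2])
  for (c_i in seq_along(x$channels)) {
    m <- x$data[, c_i, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(x$data)[1])
    x$data[, c_i, ] <- m - rowMeans(m[, sel, drop = FALSE])
  }
  x
}

#' Remove ocular artifacts by least-squares EOG regression
#'
#' Fits, per scalp channel, an ordinary least-squares regression of the
#' channel on the EOG channels over all epochs jointly and subtracts the
#' fitted EOG projection, leaving residuals orthogonal to the regressors.
#' A stationary (whole-recording) fit rather than an adaptive one: the
#' leakage topography is treated as fixed over the session. Zero-variance
#' EOG channels are dropped; if none remain the data pass unchanged.
#'
#' @param x an `epochset`.
#' @param eog_channels labels of the EOG regressor channels.
#' @return the corrected `epochset`; estimated leakage coefficients are in
#'   the `"eog_betas"` attribute (scalp channel x regressor).
#' @export
regress_eog <- function(x, eog_channels = c("HEOGL", "HEOGR", "VEOGU",
                                            "VEOGL")) {
  eog_channels <- intersect(eog_channels, x$channels)
  if (length(eog_channels) == 0L) stopf("no EOG channels present")
  d <- dim(x$data)
  flat <- function(ch) as.numeric(t(channel_matrix(x, ch)))
  E <- vapply(eog_channels, flat, numeric(d[1] * d[3]))
  keep <- apply(E, 2, stats::sd) > 0
  if (!any(keep)) return(x)  # all-zero regressors: nothing to remove
  E <- E[, keep, drop = FALSE]
  if (qr(E)$rank < ncol(E)) stopf("singular EOG regressor matrix")
  X <- cbind(1, E)
  XtXinv <- solve(crossprod(X))
  scalp <- setdiff(x$channels, eog_channels)
  betas <- matrix(0, length(scalp), ncol(E),
                  dimnames = list(scalp, colnames(E)))
  for (ch in scalp) {
    y <- flat(ch)
    b <- XtXinv %*% crossprod(X, y)
    proj <- E %*% b[-1, , drop = FALSE]
    betas[ch, ] <- b[-1]
    x$data[, match(ch, x$channels), ] <-
      matrix(y - proj, d[1], d[3], byrow = TRUE)
  }
  attr(x, "eog_betas") <- betas
  x
}

#' Reject epochs by peak absolute amplitude
#'
#' An epoch is dropped iff its absolute amplitude exceeds the threshold
#' on any monitored channel (the analysis channel and both mastoids by
#' default).
#'
#' @param x an `epochset`.
#' @param threshold_uv rejection threshold (uV), default 75.
#' @param channels monitored channels.
#' @return list with `epochs` (retained trials) and `log` (data.frame:
#'   `epoch`, `keep`, `channel`, `peak_uv`).
#' @export
reject_amplitude <- function(x, threshold_uv = 75,
                             channels = c("Pz", "TP9", "TP10")) {
  miss <- setdiff(channels, x$channels)
  if (length(miss)) stopf("monitored channel(s) missing: %s",
                          paste(miss, collapse = ", "))
  idx <- match(channels, x$channels)
  peaks <- vapply(idx, function(c_i) {
    m <- abs(x$data[, c_i, , drop = TRUE])
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(x$data)[1])
    do.call(pmax, as.data.frame(m))
  }, numeric(dim(x$data)[1]))
  peaks <- matrix(peaks, ncol = length(idx))
  worst <- max.col(peaks, ties.method = "first")
  peak_uv <- peaks[cbind(seq_len(nrow(peaks)), worst)]
  keep <- peak_uv <= threshold_uv
  log <- data.frame(epoch = seq_len(n_epochs(x)), keep = keep,
                    channel = channels[worst], peak_uv = peak_uv,
                    stringsAsFactors = FALSE)
  list(epochs = subset_epochs(x, keep), log = log)
}

#' Re-reference a channel to linked mastoids
#'
#' Replaces the target channel with `target - (m1 + m2)/2`, samplewise.
#'
#' @param x an `epochset`.
#' @param target channel to re-reference (default `"Pz"`).
#' @param mastoids the two mastoid channels.
#' @return the `epochset` with the re-referenced target channel.
#' @export
rereference_linked_mastoids <- function(x, target = "Pz",
                                        mastoids = c("TP9", "TP10")) {
  miss <- setdiff(c(target, mastoids), x$channels)
  if (length(miss)) stopf("channel(s) missing: %s",
                          paste(miss, collapse = ", "))
  ti <- match(target, x$channels)
  mi <- match(mastoids, x$channels)
  x$data[, ti, ] <- x$data[, ti, ] -
    (x$data[, mi[1], ] + x$data[, mi[2], ]) / 2
  x
}

#' Preprocess already-epoched data
#'
#' Applies the epoch-domain part of the chain in its fixed order:
#' baseline correction, EOG regression, amplitude rejection,
#' linked-mastoid re-referencing. (Resampling and filtering apply to
#' continuous recordings; simulated data are generated as epochs at the
#' target rate with band-limited components.)
#'
#' @param x an `epochset`.
#' @param baseline baseline window (ms).
#' @param eog_channels EOG regressor channels.
#' @param threshold_uv rejection threshold (uV).
#' @param reject_channels monitored channels for rejection.
#' @param target,mastoids re-referencing channels.
#' @return list of class `cit_clean`: `epochs`, `rejection_log`,
#'   `provenance` (ordered step list with every parameter used).
#' @export
preprocess_epochs <- function(x, baseline = c(-100, 0),
                              eog_channels = c("HEOGL", "HEOGR", "VEOGU",
                                               "VEOGL"),
                              threshold_uv = 75,
                              reject_channels = c("Pz", "TP9", "TP10"),
                              target = "Pz", mastoids = c("TP9", "TP10")) {
  prov <- list()
  step <- function(name, ...) {
    prov[[length(prov) + 1L]] <<- c(list(step = name), list(...))
  }
  x <- baseline_correct(x, baseline)
  step("baseline_correct", window_ms = baseline)
  x <- regress_eog(x, eog_channels)
  step("regress_eog", channels = eog_channels,
       method = "stationary ordinary least squares (not adaptive RLS)")
  rej <- reject_amplitude(x, threshold_uv, reject_channels)
  x <- rej$epochs
  step("reject_amplitude", threshold_uv = threshold_uv,
       channels = reject_channels, dropped = sum(!rej$log$keep))
  x <- rereference_linked_mastoids(x, target, mastoids)
  step("rereference_linked_mastoids", target = target, mastoids = mastoids)
  structure(list(epochs = x, rejection_log = rej$log, provenance = prov),
            class = "cit_clean")
}

#' Preprocess a continuous recording end to end
#'
#' Full chain: resample, bandpass filter, epoch, then
#' [preprocess_epochs()]. The provenance records every step in order.
#'
#' @param x a `recording`.
#' @param events data.frame with `onset_sample` (at the original rate)
#'   plus event columns.
#' @param target_srate resampling target (Hz), default 250.
#' @param spec a [filter_spec()].
#' @param window epoch window (ms).
#' @param ... passed to [preprocess_epochs()].
#' @return a `cit_clean` (see [preprocess_epochs()]).
#' @export
preprocess_recording <- function(x, events, target_srate = 250,
                                 spec = filter_spec(),
                                 window = c(-100, 1400), ...) {
  x <- resample_recording(x, target_srate, events)
  events <- attr(x, "events") %||% events
  x <- bandpass_fir(x, spec)
  ep <- extract_epochs(x, events, window)
  out <- preprocess_epochs(ep, ...)
  out$provenance <- c(
    list(list(step = "resample", target_srate = target_srate),
         list(step = "bandpass_fir", low = spec$low, high = spec$high,
              trans_low = spec$trans_low, trans_high = spec$trans_high,
              design = "Hamming-windowed sinc FIR, -6 dB at cutoffs"),
         list(step = "extract_epochs", window_ms = window,
              skipped = length(attr(ep, "skipped")))),
    out$provenance)
  out
}
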