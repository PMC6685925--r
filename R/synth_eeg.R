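#' @title Synthetic epoched EEG and behavior for the CTP CIT
#'
#' @description
#' Generates epoched multi-channel EEG with the statistical structure the
#' downstream analysis assumes: a parietal P300-like component whose
#' peak-to-peak amplitude is larger for probes than irrelevants in guilty
#' subjects (category-graded: forename > date > animal), larger for rare
#' targets than nontargets, realistic single-trial noise (white, alpha,
#' drift), stereotyped blinks on the EOG channels that leak into scalp
#' channels, occasional large artifacts, and behavioral responses (RTs
#' from a shifted lognormal with probe slowing, role-specific error
#' rates).
#'
#' All component amplitudes are specified on the peak-to-peak P300 scale
#' at the analysis channel (Pz re-referenced to linked mastoids), so a
#' noiseless simulated subject scores exactly the specified values.
#' @name synth_eeg
NULL

#' P300-like component waveform
#'
#' A raised-cosine (half-sine squared) bump centered at `peak_ms`, zero
#' outside `peak_ms +/- width_ms/2`, with maximum `amplitude_uv`. The
#' shape is a modeling choice; only the peak location (inside the
#' scoring window) is constrained by the analysis.
#'
#' @param peak_ms peak latency (ms post-stimulus), default 550.
#' @param width_ms full width of the bump (ms), default 400.
#' @param amplitude_uv peak amplitude (uV).
#' @param srate sampling rate (Hz).
#' @param window epoch window `c(t0, t1)` in ms (half-open `[t0, t1)`).
#' @return numeric waveform (one value per sample) with a `times`
#'   attribute in ms.
#' @export
p300_kernel <- function(peak_ms = 550, width_ms = 400, amplitude_uv = 1,
                        srate = 250, window = c(-100, 1400)) {
  stopifnot(width_ms > 0)
  if (peak_ms < window[1] || peak_ms >= window[2]) {
    stopf("kernel peak (%g ms) outside the epoch window [%g, %g)",
          peak_ms, window[1], window[2])
  }
  n <- round(diff(window) / 1000 * srate)
  times <- window[1] + (seq_len(n) - 1L) / srate * 1000
  u <- (times - peak_ms) / width_ms
  w <- ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
  structure(amplitude_uv * w, times = times)
}

#' Peak-to-peak P300 of the unit-amplitude kernel
#'
#' The scored P300pp of a unit kernel is slightly below 1 (the maximum
#' 100 ms segment averages over the peak). The simulator divides target
#' amplitudes by this factor so injected values are recovered exactly on
#' the P300pp scale.
#'
#' @inheritParams p300_kernel
#' @param cfg a [segment_search_config()].
#' @return scalar, the P300pp of the unit kernel.
#' @export
kernel_p300pp <- function(peak_ms = 550, width_ms = 400, srate = 250,
                          window = c(-100, 1400),
                          cfg = segment_search_config()) {
  k <- p300_kernel(peak_ms, width_ms, 1, srate, window)
  p300_pp(as.numeric(k), attr(k, "times"), cfg)$p300pp_uv
}

#' Single-trial noise model
#'
#' @param white_sd white-noise SD per scalp channel (uV), default 10.
#' @param alpha_amp amplitude of the alpha-band oscillation (uV).
#' @param alpha_freq alpha frequency (Hz).
#' @param drift_amp SD of the linear low-frequency drift across the
#'   epoch (uV at the epoch edges).
#' @param blink_rate_per_min blink rate (events/min).
#' @param blink_amp blink amplitude at the upper vertical EOG (uV).
#' @param blink_width_ms blink duration (ms).
#' @param eog_white_sd white-noise SD on EOG channels (uV).
#' @param artifact_amp range of non-ocular artifact amplitudes (uV) used
#'   with the subject's artifact rate.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(white_sd = 10, alpha_amp = 2, alpha_freq = 10,
                        drift_amp = 2, blink_rate_per_min = 3,
                        blink_amp = 100, blink_width_ms = 300,
                        eog_white_sd = 5, artifact_amp = c(80, 150)) {
  vals <- c(white_sd, alpha_amp, alpha_freq, drift_amp, blink_rate_per_min,
            blink_amp, blink_width_ms, eog_white_sd, artifact_amp)
  stopifnot(all(vals >= 0))
  structure(list(white_sd = white_sd, alpha_amp = alpha_amp,
                 alpha_freq = alpha_freq, drift_amp = drift_amp,
                 blink_rate_per_min = blink_rate_per_min,
                 blink_amp = blink_amp, blink_width_ms = blink_width_ms,
                 eog_white_sd = eog_white_sd, artifact_amp = artifact_amp),
            class = "noise_model")
}

# Channel montage: signal scale of the P300 component and blink leakage
# per channel. Mastoids carry a small attenuated copy of the component;
# amplitudes are calibrated at Pz minus the linked-mastoid average.
channel_montage <- function() {
  data.frame(
    channel = c("Pz", "Cz", "Fz", "TP9", "TP10",
                "HEOGL", "HEOGR", "VEOGU", "VEOGL"),
    signal = c(1.0, 0.8, 0.5, 0.10, 0.10, 0, 0, 0, 0),
    blink = c(0.07, 0.18, 0.35, 0.03, 0.03, 0.15, 0.15, 1.0, -0.6),
    eog = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Subject profile for the simulator
#'
#' Component amplitudes are peak-to-peak P300 values (uV) at the
#' re-referenced Pz; defaults follow the calibration of a typical guilty
#' participant (probe minus irrelevant differences graded
#' forename > date > animal; targets larger than nontargets). Innocent
#' subjects have all probe increments equal to zero, so their probes are
#' statistically indistinguishable from irrelevants.
#'
#' @param guilty logical.
#' @param probe_pp_uv named vector of per-category probe increments (uV,
#'   added to the irrelevant base); forced to zero when `guilty = FALSE`.
#' @param irrelevant_pp_uv irrelevant-base P300pp (uV).
#' @param target_pp_uv,nontarget_pp_uv secondary-task P300pp values (uV).
#' @param rt_shift_ms,rt_meanlog,rt_sdlog shifted-lognormal primary-task
#'   RT parameters (ms; RT = shift + lognormal).
#' @param probe_rt_slowing_ms named vector, per-category probe RT slowing
#'   (ms).
#' @param sec_rt_meanlog,sec_rt_sdlog,target_rt_slowing_ms secondary-task
#'   RT parameters.
#' @param error_rates named vector of response error probabilities for
#'   roles probe, irrelevant, target, nontarget.
#' @param artifact_rate probability that an epoch carries a large
#'   non-ocular artifact (rejected downstream).
#' @param anticipation_rate probability of an anticipatory (< 150 ms)
#'   response.
#' @return list of class `subject_profile`.
#' @export
subject_profile <- function(guilty = TRUE,
                            probe_pp_uv = c(forename = 9.16, date = 5.66,
                                            animal = 3.57),
                            irrelevant_pp_uv = 4.84,
                            target_pp_uv = 13.10, nontarget_pp_uv = 6.44,
                            rt_shift_ms = 150, rt_meanlog = log(270),
                            rt_sdlog = 0.30,
                            probe_rt_slowing_ms = c(forename = 14, date = 8,
                                                    animal = 0),
                            sec_rt_meanlog = log(320), sec_rt_sdlog = 0.25,
                            target_rt_slowing_ms = 45,
                            error_rates = c(probe = 0.027, irrelevant = 0.023,
                                            target = 0.185,
                                            nontarget = 0.025),
                            artifact_rate = 0.06, anticipation_rate = 0.01) {
  if (!guilty) probe_pp_uv[] <- 0
  if (any(probe_pp_uv < 0)) stopf("probe increments must be nonnegative")
  structure(list(guilty = guilty, probe_pp_uv = probe_pp_uv,
                 irrelevant_pp_uv = irrelevant_pp_uv,
                 target_pp_uv = target_pp_uv,
                 nontarget_pp_uv = nontarget_pp_uv,
                 rt_shift_ms = rt_shift_ms, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog,
                 probe_rt_slowing_ms = probe_rt_slowing_ms,
                 sec_rt_meanlog = sec_rt_meanlog, sec_rt_sdlog = sec_rt_sdlog,
                 target_rt_slowing_ms = target_rt_slowing_ms,
                 error_rates = error_rates, artifact_rate = artifact_rate,
                 anticipation_rate = anticipation_rate),
            class = "subject_profile")
}

# Raised-cosine bump on an arbitrary time grid (blinks, artifacts).
bump_on <- function(times, center, width) {
  u <- (times - center) / width
  ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

# Simulate one set of epochs: per-trial component amplitude (kernel
# units) plus noise on every montage channel.
simulate_epochs <- function(amp, noise, srate, window, peak_ms, width_ms,
                            artifact_rate, artifact_amp) {
  mont <- channel_montage()
  n <- length(amp)
  kern <- p300_kernel(peak_ms, width_ms, 1, srate, window)
  times <- attr(kern, "times")
  S <- length(times)
  data <- array(0, c(n, nrow(mont), S))
  dur_min <- diff(window) / 1000 / 60
  p_blink <- min(1, noise$blink_rate_per_min * dur_min)
  has_blink <- stats::runif(n) < p_blink
  blink_center <- stats::runif(n, window[1], window[2])
  blink_amp <- noise$blink_amp * (0.7 + 0.6 * stats::runif(n))
  blink_shapes <- matrix(0, n, S)
  if (any(has_blink)) {
    idx <- which(has_blink)
    for (i in idx) {
      blink_shapes[i, ] <- blink_amp[i] *
        bump_on(times, blink_center[i], noise$blink_width_ms)
    }
  }
  has_art <- stats::runif(n) < artifact_rate
  scalp_mon <- match(c("Pz", "TP9", "TP10"), mont$channel)
  for (c_i in seq_len(nrow(mont))) {
    sig <- outer(amp * mont$signal[c_i], as.numeric(kern))
    sd_w <- if (mont$eog[c_i]) noise$eog_white_sd else noise$white_sd
    m <- sig + matrix(stats::rnorm(n * S, sd = sd_w), n, S)
    if (!mont$eog[c_i]) {
      if (noise$alpha_amp > 0) {
        phase <- stats::runif(n, 0, 2 * pi)
        m <- m + noise$alpha_amp *
          sin(outer(phase, rep(1, S)) +
                2 * pi * noise$alpha_freq / 1000 *
                outer(rep(1, n), times))
      }
      if (noise$drift_amp > 0) {
        ramp <- (times - mean(times)) / (diff(window) / 2)
        m <- m + outer(stats::rnorm(n, sd = noise$drift_amp), ramp)
      }
    }
    m <- m + mont$blink[c_i] * blink_shapes
    data[, c_i, ] <- m
  }
  if (any(has_art)) {
    for (i in which(has_art)) {
      ch <- sample(scalp_mon, 1)
      a <- stats::runif(1, artifact_amp[1], artifact_amp[2]) *
        sample(c(-1, 1), 1)
      data[i, ch, ] <- data[i, ch, ] +
        a * bump_on(times, stats::runif(1, window[1] + 100, window[2] - 100),
                    200)
    }
  }
  epochset(data, srate, mont$channel, window[1])
}

#' Simulate one full CTP session
#'
#' Walks the session schedule trial by trial and produces secondary- and
#' primary-stimulus epoch sets plus the behavioral response table. Every
#' trial's Pz carries the irrelevant-base component plus the role or
#' category increment; mastoids carry attenuated copies; EOG channels
#' carry blinks that leak (scaled) into the scalp channels.
#'
#' @param plan a `cit_plan` from [build_session_plan()].
#' @param profile a [subject_profile()].
#' @param noise a [noise_model()].
#' @param seed optional integer seed governing all draws.
#' @param srate sampling rate (Hz), default 250.
#' @param window epoch window in ms (half-open), default `c(-100, 1400)`.
#' @param peak_ms,width_ms P300 component shape.
#' @param tasks `"both"` (default) or `"primary"` (skip the secondary-task
#'   EEG; behavioral responses are still generated for both tasks).
#' @return list of class `cit_session`: `primary` and `secondary`
#'   epochsets (`secondary` is `NULL` when `tasks = "primary"`),
#'   `behavior` (both tasks' responses), `profile`.
#' @export
simulate_session <- function(plan, profile, noise = noise_model(),
                             seed = NULL, srate = 250,
                             window = c(-100, 1400), peak_ms = 550,
                             width_ms = 400, tasks = c("both", "primary")) {
  tasks <- match.arg(tasks)
  stopifnot(inherits(plan, "cit_plan"), inherits(profile, "subject_profile"))
  sched <- session_schedule(plan)
  n <- nrow(sched)
  # calibration: injected pp value -> kernel amplitude at re-referenced Pz
  mont <- channel_montage()
  eff <- mont$signal[mont$channel == "Pz"] -
    mean(mont$signal[mont$channel %in% c("TP9", "TP10")])
  scale <- kernel_p300pp(peak_ms, width_ms, srate, window) * eff
  with_seed(seed, {
    prim_pp <- profile$irrelevant_pp_uv +
      ifelse(sched$primary_role == "probe",
             profile$probe_pp_uv[sched$category], 0)
    sec_pp <- ifelse(sched$secondary_role == "target",
                     profile$target_pp_uv, profile$nontarget_pp_uv)
    primary <- simulate_epochs(prim_pp / scale, noise, srate, window,
                               peak_ms, width_ms, profile$artifact_rate,
                               noise$artifact_amp)
    secondary <- if (tasks == "both") {
      simulate_epochs(sec_pp / scale, noise, srate, window,
                      peak_ms, width_ms, profile$artifact_rate,
                      noise$artifact_amp)
    } else NULL
    # behavior: primary task
    rt_p <- profile$rt_shift_ms +
      stats::rlnorm(n, profile$rt_meanlog, profile$rt_sdlog) +
      ifelse(sched$primary_role == "probe",
             profile$probe_rt_slowing_ms[sched$category], 0)
    antic <- stats::runif(n) < profile$anticipation_rate
    rt_p[antic] <- stats::runif(sum(antic), 50, 145)
    ok_p <- stats::runif(n) >= profile$error_rates[sched$primary_role]
    rt_s <- profile$rt_shift_ms +
      stats::rlnorm(n, profile$sec_rt_meanlog, profile$sec_rt_sdlog) +
      ifelse(sched$secondary_role == "target",
             profile$target_rt_slowing_ms, 0)
    ok_s <- stats::runif(n) >= profile$error_rates[sched$secondary_role]
    primary$events <- data.frame(
      trial = sched$trial_index, block = sched$block,
      category = sched$category, role = sched$primary_role,
      item = sched$primary_text, rt_ms = rt_p, correct = ok_p,
      stringsAsFactors = FALSE
    )
    sec_events <- data.frame(
      trial = sched$trial_index, block = sched$block,
      category = sched$category, role = sched$secondary_role,
      item = sched$secondary_text, rt_ms = rt_s, correct = ok_s,
      stringsAsFactors = FALSE
    )
    if (!is.null(secondary)) secondary$events <- sec_events
    behavior <- rbind(
      cbind(task = "primary", primary$events),
      cbind(task = "secondary", sec_events)
    )
    structure(list(primary = primary, secondary = secondary,
                   behavior = behavior, profile = profile),
              class = "cit_session")
  })
}

rtruncnorm1 <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Population calibration for simulated cohorts
#'
#' Between-subject means and SDs of the component amplitudes (uV, on the
#' P300pp scale) with category-graded probe increments
#' (forename > date > animal) and targets larger than nontargets.
#'
#' @param probe_pp_mean,probe_pp_sd named per-category increment
#'   distributions (truncated normal at 0).
#' @param irrelevant_pp,target_pp,nontarget_pp `c(mean, sd)` pairs
#'   (truncated below at 0.5 uV).
#' @param rt_meanlog_sd between-subject SD of the lognormal RT location.
#' @return list of class `cohort_calibration`.
#' @export
cohort_calibration <- function(probe_pp_mean = c(forename = 9.16,
                                                 date = 5.66, animal = 3.57),
                               probe_pp_sd = c(forename = 4.43, date = 4.14,
                                               animal = 3.17),
                               irrelevant_pp = c(4.84, 3.12),
                               target_pp = c(13.10, 5.41),
                               nontarget_pp = c(6.44, 3.23),
                               rt_meanlog_sd = 0.10) {
  structure(list(probe_pp_mean = probe_pp_mean, probe_pp_sd = probe_pp_sd,
                 irrelevant_pp = irrelevant_pp, target_pp = target_pp,
                 nontarget_pp = nontarget_pp,
                 rt_meanlog_sd = rt_meanlog_sd),
            class = "cohort_calibration")
}

#' Generate a simulated cohort specification
#'
#' Draws independent per-subject profiles (between-subject variability on
#' amplitudes and RT parameters) and per-subject seeds; sessions are
#' materialized lazily with [simulate_subject()], so large cohorts never
#' hold all EEG in memory at once.
#'
#' @param n_guilty,n_innocent subject counts.
#' @param group `"standard"` or `"induced"` (secondary-task item type).
#' @param seed integer seed.
#' @param calibration a [cohort_calibration()].
#' @return object of class `cit_cohort`: list with `subjects` (per-subject
#'   list of id, guilty flag, profile, seeds), `labels` (logical, `TRUE` =
#'   guilty), `group`.
#' @export
generate_cohort <- function(n_guilty, n_innocent,
                            group = c("standard", "induced"), seed = NULL,
                            calibration = cohort_calibration()) {
  group <- match.arg(group)
  stopifnot(n_guilty >= 0, n_innocent >= 0)
  n <- n_guilty + n_innocent
  labels <- rep(c(TRUE, FALSE), c(n_guilty, n_innocent))
  subjects <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      guilty <- labels[i]
      inc <- if (guilty) {
        v <- mapply(function(m, s) rtruncnorm1(1, m, s, 0),
                    calibration$probe_pp_mean, calibration$probe_pp_sd)
        stats::setNames(v, names(calibration$probe_pp_mean))
      } else {
        stats::setNames(rep(0, length(calibration$probe_pp_mean)),
                        names(calibration$probe_pp_mean))
      }
      prof <- subject_profile(
        guilty = guilty,
        probe_pp_uv = inc,
        irrelevant_pp_uv = rtruncnorm1(1, calibration$irrelevant_pp[1],
                                       calibration$irrelevant_pp[2], 0.5),
        target_pp_uv = rtruncnorm1(1, calibration$target_pp[1],
                                   calibration$target_pp[2], 0.5),
        nontarget_pp_uv = rtruncnorm1(1, calibration$nontarget_pp[1],
                                      calibration$nontarget_pp[2], 0.5),
        rt_meanlog = stats::rnorm(1, log(270), calibration$rt_meanlog_sd)
      )
      list(id = sprintf("S%03d", i), guilty = guilty, profile = prof,
           seeds = sample.int(.Machine$integer.max - 1L, 3L))
    })
  })
  structure(list(subjects = subjects, labels = labels, group = group),
            class = "cit_cohort")
}

#' @export
print.cit_cohort <- function(x, ...) {
  cat(sprintf("simulated cohort (%s group): %d guilty, %d innocent\n",
              x$group, sum(x$labels), sum(!x$labels)))
  invisible(x)
}

#' Materialize one simulated subject
#'
#' Builds the subject's item set (random probes from the bundled pools),
#' the constrained session plan with recall checks, and the simulated
#' session, all deterministically from the cohort's stored seeds.
#'
#' @param cohort a `cit_cohort`.
#' @param i subject index.
#' @param reps repetitions per primary item per block (default 30).
#' @param noise a [noise_model()].
#' @param categories optional subset of categories to simulate (fewer
#'   blocks; default all three).
#' @param ... passed to [simulate_session()].
#' @return a `cit_session` (see [simulate_session()]), with the subject
#'   id attached to the behavior and event tables.
#' @export
simulate_subject <- function(cohort, i, reps = 30, noise = noise_model(),
                             categories = NULL, ...) {
  sub <- cohort$subjects[[i]]
  items <- with_seed(sub$seeds[1], {
    pools <- list(forename = word_pool("forename"), date = date_pool(),
                  animal = word_pool("animal"))
    probes <- list(forename = sample(pools$forename, 1),
                   date = sample(date_pool(), 1),
                   animal = sample(pools$animal, 1))
    build_item_set(probes, group = cohort$group, pools = pools,
                   seed = sub$seeds[1])
  })
  if (!is.null(categories)) {
    items$primary <- items$primary[items$primary$category %in% categories, ]
  }
  plan <- build_session_plan(items, reps = reps, seed = sub$seeds[2])
  plan <- schedule_recall_checks(plan, per_category = 3, seed = sub$seeds[2])
  ses <- simulate_session(plan, sub$profile, noise = noise,
                          seed = sub$seeds[3], ...)
  ses$primary$events$subject <- sub$id
  if (!is.null(ses$secondary)) ses$secondary$events$subject <- sub$id
  ses$behavior$subject <- sub$id
  ses$id <- sub$id
  ses
}
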