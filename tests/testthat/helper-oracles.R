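# Independent brute-force oracles and small fixtures, built in code.

# Exhaustive segment-search oracle for the peak-to-peak P300: scans every
# admissible (max, min) segment pair with plain arithmetic, independent of
# the package's cumulative-sum implementation.
bf_p300pp <- function(w, times, max_window = c(400, 800), segment_ms = 100,
                      min_end = 1400) {
  srate <- 1000 / (times[2] - times[1])
  L <- round(segment_ms / 1000 * srate)
  starts <- seq_len(length(w) - L + 1)
  seg_mean <- vapply(starts, function(s) mean(w[s:(s + L - 1)]), numeric(1))
  ok_max <- times[starts] >= max_window[1] - 1e-9 &
    times[starts + L - 1] <= max_window[2] + 1e-9
  i_max <- which(ok_max)[which.max(seg_mean[ok_max])]
  mid <- (times[i_max] + times[i_max + L - 1]) / 2
  mid_grid <- max(times[times <= mid + 1e-9])
  ok_min <- times[starts] >= mid_grid - 1e-9 &
    times[starts + L - 1] <= min_end + 1e-9
  i_min <- which(ok_min)[which.min(seg_mean[ok_min])]
  list(max_mean = seg_mean[i_max], min_mean = seg_mean[i_min],
       p300pp = seg_mean[i_max] - seg_mean[i_min])
}

# Standard epoch time grid used across tests: [-100, 1400) ms at 250 Hz.
test_times <- function(srate = 250, window = c(-100, 1400)) {
  n <- round(diff(window) / 1000 * srate)
  window[1] + (seq_len(n) - 1) / srate * 1000
}

# A fixed small item set with inline pools (no file access, fully seeded).
make_test_itemset <- function(group = "standard", seed = 42) {
  pools <- list(
    forename = c("MICHAEL", "SARAH", "DAVID", "LAURA", "THOMAS", "ANNA",
                 "PETER", "JULIA", "MARTIN", "LENA", "STEFAN", "MARIE",
                 "OLIVER", "NINA", "JONAS", "EMMA", "FELIX", "CLARA",
                 "SIMON", "PAULA"),
    date = date_pool(),
    animal = c("DOLPHIN", "TIGER", "ELEPHANT", "GIRAFFE", "PENGUIN",
               "KANGAROO", "RABBIT", "HORSE", "EAGLE", "WOLF", "BEAR",
               "FOX", "OTTER", "SEAL", "WHALE", "SHARK", "TURTLE",
               "SNAKE", "FROG", "OWL")
  )
  build_item_set(list(forename = "MICHAEL", date = format_date_item(6, 19),
                      animal = "DOLPHIN"),
                 group = group, pools = pools, seed = seed)
}

# A one-category session plan for quick simulations.
make_block_plan <- function(category = "forename", reps = 30, seed = 1,
                            group = "standard") {
  items <- make_test_itemset(group = group, seed = seed)
  items$primary <- items$primary[items$primary$category == category, ]
  build_session_plan(items, reps = reps, seed = seed)
}

# Zero-noise model for exact-recovery checks.
silent_noise <- function() {
  noise_model(white_sd = 0, alpha_amp = 0, drift_amp = 0,
              blink_rate_per_min = 0, eog_white_sd = 0)
}

# A deterministic profile without behavioral noise sources.
clean_profile <- function(...) {
  p <- subject_profile(...)
  p$artifact_rate <- 0
  p$anticipation_rate <- 0
  p$error_rates[] <- 0
  p
}

# Minimal epochset with the standard montage built from a Pz trials x
# samples matrix (other channels zero unless supplied).
epochs_from_pz <- function(pz, srate = 250, tmin = -100, events = NULL,
                           extra = list()) {
  channels <- c("Pz", "Cz", "Fz", "TP9", "TP10",
                "HEOGL", "HEOGR", "VEOGU", "VEOGL")
  data <- array(0, c(nrow(pz), length(channels), ncol(pz)))
  data[, 1, ] <- pz
  for (ch in names(extra)) data[, match(ch, channels), ] <- extra[[ch]]
  epochset(data, srate, channels, tmin, events)
}
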