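test_that("resampling preserves sinusoids and remaps event indices", {
  srate <- 1000
  t <- (0:(4 * srate - 1)) / srate
  sine <- sin(2 * pi * 10 * t)
  rec <- recording(rbind(Pz = sine, TP9 = sine), srate, c("Pz", "TP9"))
  ev <- data.frame(onset_sample = c(1000, 2000), role = c("a", "b"))
  out <- resample_recording(rec, 250, ev)
  expect_equal(ncol(out$data), length(sine) / 4)
  expect_equal(out$srate, 250)
  # amplitude of the 10 Hz sine preserved within 1% (interior samples)
  mid <- out$data[1, 100:900]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01)
  ev2 <- attr(out, "events")
  expect_equal(ev2$onset_sample, c(250, 500), tolerance = 1)
  # identity and upsampling guard
  expect_identical(resample_recording(rec, 1000)$data, rec$data)
  expect_error(resample_recording(rec, 2000), "upsampling")
})

test_that("the FIR bandpass removes DC, passes 10 Hz and attenuates 50 Hz", {
  srate <- 250
  spec <- filter_spec()
  n <- 10 * srate
  t <- (0:(n - 1)) / srate
  dc <- bandpass_fir(rep(5, n), spec, srate = srate)
  expect_lt(max(abs(dc[(srate):(n - srate)])), 0.05)
  gain <- function(f) {
    y <- bandpass_fir(sin(2 * pi * f * t), spec, srate = srate)
    core <- (2 * srate):(n - 2 * srate)
    sqrt(mean(y[core]^2)) / sqrt(0.5)
  }
  expect_equal(gain(10), 1, tolerance = 0.02)
  expect_lt(gain(50), 10^(-20 / 20))          # >= 20 dB down in the stopband
  expect_equal(gain(0.3), 0.5, tolerance = 0.1)  # -6 dB at the low cutoff
  expect_equal(gain(30), 0.5, tolerance = 0.05)  # -6 dB at the high cutoff
  expect_error(bandpass_fir(rep(0, n), filter_spec(high = 130),
                            srate = srate), "Nyquist")
})

test_that("filtering a noiseless component changes its P300pp by < 5%", {
  srate <- 250
  kern <- p300_kernel(550, 400, 10, srate, c(-100, 1400))
  pad <- rep(0, 2 * srate)
  cont <- c(pad, as.numeric(kern), pad)
  filt <- bandpass_fir(cont, filter_spec(), srate = srate)
  w <- filt[(length(pad) + 1):(length(pad) + length(kern))]
  t <- attr(kern, "times")
  expect_equal(p300_pp(w, t)$p300pp_uv, p300_pp(as.numeric(kern), t)$p300pp_uv,
               tolerance = 0.05)
})

test_that("epoch extraction follows the half-open window convention", {
  srate <- 250
  n <- 5 * srate
  sig <- rep(0, n)
  sig[600] <- 42  # spike at the onset of the second event
  rec <- recording(rbind(Pz = sig), srate, "Pz")
  ev <- data.frame(onset_sample = c(10, 600, 700), role = "x")
  expect_message(ep <- extract_epochs(rec, ev, c(-100, 1400)), "skipped 1")
  expect_equal(dim(ep$data), c(2, 1, 375))          # 1.5 s x 250 Hz
  expect_equal(attr(ep, "skipped"), 1L)             # no 100 ms margin
  # stimulus onset lands at the sample where t = 0 (26th, zero-based 25)
  expect_equal(which(epoch_times(ep) == 0), 26)
  expect_equal(ep$data[1, 1, 26], 42)
  expect_equal(sum(ep$data[2, 1, ] != 0), 0)
})

test_that("baseline correction zeroes the prestimulus mean, elementwise", {
  set.seed(31)
  pz <- matrix(stats::rnorm(8 * 375, mean = 3), 8)
  x <- epochs_from_pz(pz)
  bc <- baseline_correct(x)
  t <- epoch_times(bc)
  sel <- t >= -100 & t < 0
  expect_equal(max(abs(rowMeans(channel_matrix(bc, "Pz")[, sel]))), 0,
               tolerance = 1e-12)
  # equals direct arithmetic
  expect_equal(channel_matrix(bc, "Pz"),
               pz - rowMeans(pz[, sel, drop = FALSE]), tolerance = 1e-12)
  # constant epoch becomes exactly zero
  const <- baseline_correct(epochs_from_pz(matrix(7, 2, 375)))
  expect_equal(max(abs(const$data[, 1, ])), 0)
  expect_error(baseline_correct(x, baseline = c(-300, -200)), "baseline")
})

test_that("EOG regression removes known leakage and recovers coefficients", {
  set.seed(32)
  n <- 40
  S <- 375
  eog1 <- matrix(stats::rnorm(n * S, sd = 30), n)
  eog2 <- matrix(stats::rnorm(n * S, sd = 20), n)
  pz <- 0.4 * eog1 + 0.1 * eog2 + matrix(stats::rnorm(n * S), n)
  x <- epochs_from_pz(pz, extra = list(VEOGU = eog1, HEOGL = eog2))
  out <- regress_eog(x)
  betas <- attr(out, "eog_betas")
  expect_equal(unname(betas["Pz", "VEOGU"]), 0.4, tolerance = 0.01)
  expect_equal(unname(betas["Pz", "HEOGL"]), 0.1, tolerance = 0.01)
  # residuals orthogonal to the regressors
  r <- as.numeric(t(channel_matrix(out, "Pz")))
  e <- as.numeric(t(eog1))
  expect_equal(abs(cor(r, e)), 0, tolerance = 1e-6)

  # exact leakage with no noise is fully removed
  y <- epochs_from_pz(0.4 * eog1, extra = list(VEOGU = eog1))
  clean <- regress_eog(y)
  expect_equal(max(abs(channel_matrix(clean, "Pz"))), 0, tolerance = 1e-9)

  # all-zero EOG: a no-op, not an error
  z <- epochs_from_pz(pz)
  expect_identical(regress_eog(z)$data, z$data)

  # duplicated regressors are singular
  dup <- epochs_from_pz(pz, extra = list(VEOGU = eog1, VEOGL = eog1))
  expect_error(regress_eog(dup), "singular")
})

test_that("amplitude rejection drops exactly the planted exceedances", {
  set.seed(33)
  pz <- matrix(stats::rnorm(20 * 375, sd = 5), 20)
  bad <- c(3, 11, 17)
  pz[bad, 100] <- c(80, -90, 120)
  x <- epochs_from_pz(pz)
  out <- reject_amplitude(x)
  expect_equal(which(!out$log$keep), bad)
  expect_equal(n_epochs(out$epochs), 17)
  expect_equal(out$log$channel[bad], rep("Pz", 3))
  expect_equal(out$log$peak_uv[3], 80)
  # all-zero data: nothing dropped; mastoids are monitored too
  z <- epochs_from_pz(matrix(0, 4, 375))
  expect_true(all(reject_amplitude(z)$log$keep))
  z$data[2, match("TP10", z$channels), 50] <- -100
  expect_equal(which(!reject_amplitude(z)$log$keep), 2L)
  expect_error(reject_amplitude(x, channels = "Oz"), "missing")
})

test_that("linked-mastoid re-referencing is exact samplewise arithmetic", {
  pz <- matrix(5, 2, 375)
  x <- epochs_from_pz(pz, extra = list(TP9 = matrix(2, 2, 375),
                                       TP10 = matrix(4, 2, 375)))
  out <- rereference_linked_mastoids(x)
  expect_equal(unique(as.numeric(channel_matrix(out, "Pz"))), 2)  # 5 - 3
  # zero mastoids leave the channel unchanged; equal mastoid mean cancels
  y <- epochs_from_pz(pz)
  expect_equal(channel_matrix(rereference_linked_mastoids(y), "Pz"), pz)
  z <- epochs_from_pz(pz, extra = list(TP9 = pz, TP10 = pz))
  expect_equal(max(abs(channel_matrix(rereference_linked_mastoids(z), "Pz"))),
               0)
  expect_error(rereference_linked_mastoids(epochset(
    array(0, c(1, 1, 10)), 250, "Pz", -100)), "missing")
})

test_that("the pipeline runs its steps in the prescribed order", {
  set.seed(34)
  plan <- make_block_plan("animal", reps = 10, seed = 6)
  ses <- simulate_session(plan, subject_profile(), seed = 7,
                          tasks = "primary")
  out <- preprocess_epochs(ses$primary)
  expect_equal(vapply(out$provenance, `[[`, character(1), "step"),
               c("baseline_correct", "regress_eog", "reject_amplitude",
                 "rereference_linked_mastoids"))
  expect_equal(n_epochs(out$epochs), sum(out$rejection_log$keep))
  expect_lte(n_epochs(out$epochs), n_epochs(ses$primary))
  # full chain from a continuous recording
  srate <- 1000
  sig <- matrix(stats::rnorm(9 * 8 * srate, sd = 3), nrow = 9)
  rec <- recording(sig, srate, c("Pz", "Cz", "Fz", "TP9", "TP10",
                                 "HEOGL", "HEOGR", "VEOGU", "VEOGL"))
  ev <- data.frame(onset_sample = c(2000, 4000, 6000), role = "irrelevant")
  res <- preprocess_recording(rec, ev)
  expect_equal(vapply(res$provenance, `[[`, character(1), "step"),
               c("resample", "bandpass_fir", "extract_epochs",
                 "baseline_correct", "regress_eog", "reject_amplitude",
                 "rereference_linked_mastoids"))
  expect_equal(res$epochs$srate, 250)
  expect_equal(dim(res$epochs$data)[3], 375)
})
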