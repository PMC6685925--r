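test_that("the P300 kernel has the promised shape and support", {
  k <- p300_kernel(550, 400, 10, 250, c(-100, 1400))
  t <- attr(k, "times")
  expect_length(k, 375)
  expect_equal(max(k), 10, tolerance = 1e-3)  # peak may fall between samples
  expect_equal(t[which.max(k)], 550, tolerance = 2)
  expect_true(all(k[t < 350 | t > 750] == 0))
  expect_equal(as.numeric(p300_kernel(550, 400, 0, 250)), rep(0, 375))
  expect_error(p300_kernel(peak_ms = 1500), "outside")
  # scored peak-to-peak of the kernel matches the brute-force oracle
  expect_equal(p300_pp(as.numeric(k), t)$p300pp_uv,
               bf_p300pp(as.numeric(k), t)$p300pp, tolerance = 1e-10)
  expect_equal(kernel_p300pp(), bf_p300pp(as.numeric(p300_kernel()),
                                          t)$p300pp, tolerance = 1e-10)
})

test_that("simulated sessions are reproducible and aligned with their events", {
  plan <- make_block_plan("date", reps = 10, seed = 14)
  prof <- subject_profile()
  a <- simulate_session(plan, prof, seed = 99)
  b <- simulate_session(plan, prof, seed = 99)
  expect_identical(a$primary$data, b$primary$data)
  expect_identical(a$behavior, b$behavior)
  expect_false(identical(
    a$primary$data, simulate_session(plan, prof, seed = 100)$primary$data))
  # event alignment: one event row per epoch, both tasks
  expect_equal(nrow(a$primary$events), n_epochs(a$primary))
  expect_equal(nrow(a$secondary$events), n_epochs(a$secondary))
  expect_equal(nrow(a$behavior), 2 * n_epochs(a$primary))
  expect_true(all(c("Pz", "TP9", "TP10", "VEOGU") %in% a$primary$channels))
})

test_that("behavioral draws converge to the profile parameters", {
  plan <- make_block_plan("forename", reps = 30, seed = 15)
  prof <- subject_profile()
  prof$anticipation_rate <- 0
  ses <- simulate_session(plan, prof, seed = 41, tasks = "primary")
  beh <- ses$behavior
  # secondary-task error rate: targets ~ 18.5% across 36 targets x many
  sec <- beh[beh$task == "secondary", ]
  tgt_err <- 1 - mean(sec$correct[sec$role == "target"])
  p <- prof$error_rates["target"]
  expect_lt(abs(tgt_err - p), 3 * sqrt(p * (1 - p) / 36) + 1e-9)
  # primary RTs: probes slower than irrelevants by about the planted amount
  pri <- beh[beh$task == "primary", ]
  slow <- mean(pri$rt_ms[pri$role == "probe"]) -
    mean(pri$rt_ms[pri$role == "irrelevant"])
  expect_equal(slow, unname(prof$probe_rt_slowing_ms["forename"]),
               tolerance = 30)
  expect_true(all(pri$rt_ms > prof$rt_shift_ms))
})

test_that("innocent profiles force zero increments and cohorts are labeled", {
  p <- subject_profile(guilty = FALSE,
                       probe_pp_uv = c(forename = 9, date = 5, animal = 3))
  expect_equal(unname(p$probe_pp_uv), c(0, 0, 0))
  expect_error(subject_profile(probe_pp_uv = c(forename = -1, date = 0,
                                               animal = 0)), "nonnegative")
  coh <- generate_cohort(19, 16, group = "standard", seed = 8)
  expect_equal(sum(coh$labels), 19)
  expect_equal(sum(!coh$labels), 16)
  expect_true(all(vapply(coh$subjects[20:35], function(s)
    all(s$profile$probe_pp_uv == 0), logical(1))))
  expect_true(all(vapply(coh$subjects[1:19], function(s)
    all(s$profile$probe_pp_uv >= 0), logical(1))))
  coh2 <- generate_cohort(19, 16, group = "standard", seed = 8)
  expect_identical(coh, coh2)
  empty <- generate_cohort(0, 0, seed = 1)
  expect_length(empty$subjects, 0)
})

test_that("a materialized subject is deterministic and category-restricted", {
  coh <- generate_cohort(1, 0, seed = 77)
  s1 <- simulate_subject(coh, 1, reps = 10, categories = "animal",
                         tasks = "primary")
  s2 <- simulate_subject(coh, 1, reps = 10, categories = "animal",
                         tasks = "primary")
  expect_identical(s1$primary$data, s2$primary$data)
  expect_equal(unique(s1$primary$events$category), "animal")
  expect_equal(n_epochs(s1$primary), 60)
  expect_null(s1$secondary)
})

test_that("the epochset container round-trips through its text format", {
  plan <- make_block_plan("date", reps = 10, seed = 3)
  ses <- simulate_session(plan, subject_profile(), seed = 5,
                          tasks = "primary")
  x <- subset_epochs(ses$primary, 1:4)
  dir <- file.path(tempdir(), "epochs-roundtrip")
  write_epochset(x, dir)
  y <- read_epochset(dir)
  expect_equal(y$srate, x$srate)
  expect_equal(y$channels, x$channels)
  expect_equal(y$data, x$data, tolerance = 1e-9)
  expect_equal(y$events$item, x$events$item)
  unlink(dir, recursive = TRUE)
})
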