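test_that("behavioral summaries apply the validity and correctness rules", {
  beh <- data.frame(
    subject = "S1", category = "forename", role = "probe",
    rt_ms = c(100, 300, 400, 500, 600),
    correct = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  s <- behavioral_summary(beh)
  expect_equal(s$n_valid, 4)          # the 100 ms response is invalid
  expect_equal(s$accuracy, 0.5)
  expect_equal(s$rt_mean_ms, 350)     # mean over correct valid trials
  expect_false(s$empty_cell)
  # boundary: exactly 150 ms is still invalid, 151 ms is valid
  b2 <- data.frame(subject = "S1", category = "a", role = "probe",
                   rt_ms = c(149, 150, 151), correct = TRUE)
  expect_equal(behavioral_summary(b2)$n_valid, 1)
  # empty cells are flagged, not dropped
  b3 <- data.frame(subject = "S1", category = "a", role = "probe",
                   rt_ms = 100, correct = TRUE)
  expect_true(behavioral_summary(b3)$empty_cell)
  expect_error(behavioral_summary(data.frame(rt_ms = 1)), "lacks column")
})

test_that("difference scores subtract irrelevant from probe per cell", {
  d <- data.frame(subject = rep(c("S1", "S2"), each = 2),
                  category = "forename",
                  role = rep(c("probe", "irrelevant"), 2),
                  rt_mean_ms = c(450, 430, 410, 420))
  out <- diff_scores(d, "rt_mean_ms")
  expect_equal(out$diff[out$subject == "S1"], 20)
  expect_equal(out$diff[out$subject == "S2"], -10)
})

test_that("within-subject Cohen's d follows its two definitions", {
  expect_equal(cohen_d_within(c(1, 2, 3)), 2)        # mean 2, SD 1
  expect_equal(cohen_d_within(c(-2, -1, 0, 1, 2)), 0)
  expect_error(cohen_d_within(c(1, 1, 1)), "zero SD")
  expect_error(cohen_d_within(1), "at least 2")
  x <- c(5, 7, 9)
  y <- c(4, 5, 6)
  expect_equal(cohen_d_within(x, y), mean(x - y) / sd(x - y))
  expect_equal(cohen_d_within(x, y, method = "dav"),
               mean(x - y) / ((sd(x) + sd(y)) / 2))
  # recovers a planted effect/SD ratio over many subjects
  set.seed(71)
  diffs <- stats::rnorm(200, mean = 1.5, sd = 1)
  expect_equal(cohen_d_within(diffs), 1.5, tolerance = 0.2)
})

test_that("t tests reproduce hand-computed values and degenerate cases", {
  # paired toy data {(1,0), (2,1), (3,1)}: diffs {1, 1, 2}
  r <- cit_ttest(c(1, 2, 3), c(0, 1, 1), paired = TRUE)
  expect_equal(r$t, 4, tolerance = 1e-9)
  expect_equal(r$df, 2)
  # identical paired samples: no variance, no effect -> t = 0
  r0 <- cit_ttest(c(2, 2, 2), c(2, 2, 2), paired = TRUE)
  expect_equal(r0$t, 0)
  expect_error(cit_ttest(c(3, 3, 3), c(1, 1, 1), paired = TRUE),
               "zero variance")
  # pooled two-sample df = n1 + n2 - 2
  ind <- cit_ttest(stats::rnorm(19), stats::rnorm(16) + 1)
  expect_equal(ind$df, 33)
})

test_that("planted saliency ratings recover their ordering at n = 35", {
  set.seed(72)
  n <- 35
  fore <- pmin(6, pmax(1, stats::rnorm(n, 5.57, 1.00)))
  bday <- pmin(6, pmax(1, stats::rnorm(n, 4.34, 1.00)))
  anim <- pmin(6, pmax(1, stats::rnorm(n, 3.34, 1.21)))
  expect_lt(cit_ttest(fore, bday, paired = TRUE)$p, 0.05)
  expect_lt(cit_ttest(bday, anim, paired = TRUE)$p, 0.05)
  expect_gt(cit_ttest(fore, bday, paired = TRUE)$t, 0)
})

test_that("the mixed ANOVA agrees with aov on balanced and unbalanced designs", {
  set.seed(73)
  for (sizes in list(c(4, 4), c(5, 4))) {
    N <- sum(sizes)
    d <- expand.grid(subject = paste0("s", 1:N),
                     item_type = c("probe", "irrelevant", "target"))
    d$group <- rep(rep(c("std", "ind"), sizes), 3)
    d$value <- stats::rnorm(nrow(d), sd = 2) +
      ifelse(d$item_type == "probe", 3, 0)
    got <- mixed_anova(d, "value", "item_type", "group", "subject")
    ref <- summary(stats::aov(value ~ group * item_type +
                                Error(subject / item_type), data = d))
    btw <- ref[["Error: subject"]][[1]]
    wth <- ref[["Error: subject:item_type"]][[1]]
    expect_equal(got$F[got$effect == "between"], btw["group", "F value"],
                 tolerance = 1e-8)
    expect_equal(got$F[got$effect == "within"], wth["item_type", "F value"],
                 tolerance = 1e-8)
    expect_equal(got$F[got$effect == "within:between"],
                 wth["group:item_type", "F value"], tolerance = 1e-8)
    expect_equal(got$df1, c(1, 2, 2))
    expect_equal(got$df2[1], N - 2)
    expect_equal(got$df2[2], (N - 2) * 2)
    # partial eta^2 from the same sums of squares
    expect_equal(got$pes[got$effect == "within"],
                 wth["item_type", "Sum Sq"] /
                   (wth["item_type", "Sum Sq"] + wth["Residuals", "Sum Sq"]),
                 tolerance = 1e-8)
  }
})

test_that("two-level within factors have epsilon exactly 1; identical groups give F near 0", {
  set.seed(74)
  d <- expand.grid(subject = paste0("s", 1:10),
                   item_type = c("probe", "irrelevant"))
  d$group <- rep(c("a", "b"), 5)
  d$value <- stats::rnorm(20)
  got <- mixed_anova(d, "value", "item_type", "group", "subject")
  expect_equal(got$gg_epsilon[got$effect == "within"], 1)
  expect_equal(got$p_gg[got$effect == "within"], got$p[got$effect == "within"])
  # identical data in both groups: between F exactly 0
  base <- stats::rnorm(5)
  d2 <- data.frame(
    subject = rep(paste0("s", 1:10), 2),
    item_type = rep(c("p", "i"), each = 10),
    group = rep(rep(c("a", "b"), each = 5), 2),
    value = rep(c(base, base), 2) + rep(c(0, 1), each = 10)
  )
  got2 <- mixed_anova(d2, "value", "item_type", "group", "subject")
  expect_equal(got2$F[got2$effect == "between"], 0, tolerance = 1e-12)
  expect_error(mixed_anova(d[-1, ], "value", "item_type", "group", "subject"),
               "missing cells")
})

test_that("collapsing the within factor reduces the mixed ANOVA to a one-way ANOVA", {
  set.seed(75)
  N <- 12
  d <- expand.grid(subject = paste0("s", 1:N), item_type = c("p", "i"))
  d$group <- rep(rep(c("a", "b"), c(7, 5)), 2)
  d$value <- stats::rnorm(nrow(d)) + ifelse(d$group == "a", 0.8, 0)
  got <- mixed_anova(d, "value", "item_type", "group", "subject")
  subj_means <- tapply(d$value, d$subject, mean)
  grp <- tapply(as.character(d$group), d$subject, `[`, 1)
  oneway <- stats::anova(stats::lm(subj_means ~ grp))
  expect_equal(got$F[got$effect == "between"], oneway$`F value`[1],
               tolerance = 1e-8)
})

test_that("analytic interaction power behaves like a power function", {
  expect_equal(power_mixed_interaction(0, N = 35), 0.05, tolerance = 1e-9)
  p1 <- power_mixed_interaction(0.15, N = 35)
  p2 <- power_mixed_interaction(0.25, N = 35)
  p3 <- power_mixed_interaction(0.25, N = 70)
  p4 <- power_mixed_interaction(0.25, N = 35, rho = 0.7)
  expect_true(p1 < p2 && p2 < p3)
  expect_gt(p4, p2)
  expect_error(power_mixed_interaction(0.25, N = 1))
})

test_that("exclusion rules drop the documented failure modes", {
  qc <- data.frame(
    subject = c("ok", "lowprobe", "lowtarget", "recall"),
    probe_accuracy = c(0.97, 0.49, 0.95, 0.96),
    target_accuracy = c(0.85, 0.80, 0.56, 0.82),
    recall_failures = c(0, 1, 0, 7)
  )
  out <- apply_exclusions(qc)
  expect_equal(out$kept, "ok")
  expect_equal(sort(out$excluded$subject), c("lowprobe", "lowtarget",
                                             "recall"))
  expect_match(out$excluded$reason[out$excluded$subject == "lowprobe"],
               "probe accuracy 49%")
  expect_match(out$excluded$reason[out$excluded$subject == "recall"],
               "7 recall failures")
})
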