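#!/usr/bin/env Rscript

# Step 4: group statistics. From the per-subject score and behavior tables:
# a Table-1-style summary (RT means, accuracies, P300pp amplitudes, within-
# subject Cohen's d per group), the mixed ANOVAs (item type x group on
# amplitudes and RTs; item category x group on difference scores, with
# Greenhouse-Geisser correction and partial eta squared), bootstrap
# classification rates, exclusion screening, and the design power check.

suppressPackageStartupMessages(library(ctpcit))

scores <- read.csv("results/scores.csv")
diffs <- read.csv("results/diff_scores.csv")
behav <- read.csv("results/behavior_summary.csv")
verdicts <- read.csv("results/verdicts.csv")

## ---- Table-1-style summary -------------------------------------------------
pri_beh <- behav[behav$role %in% c("probe", "irrelevant"), ]
sec_beh <- behav[behav$role %in% c("target", "nontarget"), ]
# per subject x role means (categories merged), then group means
cell <- function(df, value) {
  agg <- aggregate(df[[value]],
                   by = list(subject = df$subject, group = df$group,
                             role = df$role),
                   FUN = mean, na.rm = TRUE)
  names(agg)[4] <- value
  agg
}
rt <- cell(rbind(pri_beh, sec_beh), "rt_mean_ms")
acc <- cell(rbind(pri_beh, sec_beh), "accuracy")
pp_cond <- aggregate(p300pp_uv ~ subject + group + condition, scores, mean)

fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), sd(x))
table1 <- do.call(rbind, lapply(c("probe", "irrelevant", "target",
                                  "nontarget"), function(role) {
  do.call(rbind, lapply(c("standard", "induced"), function(g) {
    data.frame(
      condition = role, group = g,
      rt_ms = fmt(rt$rt_mean_ms[rt$role == role & rt$group == g]),
      accuracy_pct = fmt(100 * acc$accuracy[acc$role == role &
                                              acc$group == g]),
      p300pp_uv = fmt(pp_cond$p300pp_uv[pp_cond$condition == role &
                                          pp_cond$group == g])
    )
  }))
}))
write.csv(table1, "results/table1.csv", row.names = FALSE)
cat("Condition summaries (mean ± SD across subjects):\n")
print(table1, row.names = FALSE)

## ---- within-subject effect sizes -------------------------------------------
cat("\nWithin-subject Cohen's d (probe - irrelevant P300pp, per group):\n")
for (g in c("standard", "induced")) {
  pp <- pp_cond[pp_cond$group == g, ]
  wide <- merge(pp[pp$condition == "probe", c("subject", "p300pp_uv")],
                pp[pp$condition == "irrelevant", c("subject", "p300pp_uv")],
                by = "subject", suffixes = c("_p", "_i"))
  cat(sprintf("  %-9s d_z = %.2f\n", g,
              cohen_d_within(wide$p300pp_uv_p, wide$p300pp_uv_i)))
}

## ---- mixed ANOVAs -----------------------------------------------------------
long_pp <- pp_cond[pp_cond$condition %in% c("probe", "irrelevant"), ]
a1 <- mixed_anova(long_pp, "p300pp_uv", "condition", "group", "subject")
a1$analysis <- "P300pp: item type x group"

rt_pi <- rt[rt$role %in% c("probe", "irrelevant"), ]
a2 <- mixed_anova(rt_pi, "rt_mean_ms", "role", "group", "subject")
a2$analysis <- "RT: item type x group"

a3 <- mixed_anova(diffs, "p300pp_diff_uv", "category", "group", "subject")
a3$analysis <- "P300pp diff: item category x group"

anovas <- rbind(a1, a2, a3)
write.csv(anovas, "results/anova.csv", row.names = FALSE)
cat("\nMixed ANOVAs (GG-corrected p, partial eta squared):\n")
print(anovas[, c("analysis", "effect", "F", "df1", "df2", "gg_epsilon",
                 "p_gg", "pes")], row.names = FALSE, digits = 3)

cat("\nMean probe-irrelevant P300pp difference by category (uV):\n")
print(round(tapply(diffs$p300pp_diff_uv, diffs$category, mean), 2))

## ---- classification rates ---------------------------------------------------
rates <- cohort_rates(verdicts$p_hat, rep(TRUE, nrow(verdicts)), theta = 0.9)
cat(sprintf("\nBootstrap hit rate at theta = 0.9 (all subjects guilty): %.2f (%d tests)\n",
            rates$hit_rate, nrow(verdicts)))

## ---- exclusion screening ----------------------------------------------------
qc <- do.call(rbind, lapply(split(behav, behav$subject), function(d) {
  data.frame(subject = d$subject[1],
             probe_accuracy = mean(d$accuracy[d$role == "probe"]),
             target_accuracy = mean(d$accuracy[d$role == "target"]),
             recall_failures = 0)  # recall responses are not simulated
}))
excl <- apply_exclusions(qc)
cat(sprintf("\nExclusion screening: %d kept, %d excluded\n",
            length(excl$kept), nrow(excl$excluded)))
if (nrow(excl$excluded)) print(excl$excluded, row.names = FALSE)

## ---- design power ------------------------------------------------------------
pw <- power_mixed_interaction(f = 0.25, alpha = 0.05, N = 35, g = 2, m = 2,
                              rho = 0.5, epsilon = 1)
cat(sprintf("\nDesign power (interaction, f = .25, alpha = .05, N = 35): %.3f\n",
            pw))
cat("wrote results/table1.csv, results/anova.csv\n")
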