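#' @title Behavioral summaries, effect sizes, mixed ANOVA and power
#'
#' @description
#' Group-level statistics for the CTP CIT: per-subject behavioral
#' summaries under the validity rule (responses faster than 150 ms are
#' excluded; accuracy = correct / valid; RT means over correct valid
#' trials), probe minus irrelevant difference scores, within-subject
#' Cohen's d, mixed (split-plot) ANOVA with Greenhouse-Geisser
#' correction and partial eta squared, t tests, subject exclusion rules,
#' and noncentral-F power for the within-between interaction.
#' @name cit_stats
NULL

#' Per-subject behavioral summary
#'
#' Filters to valid trials (RT above `min_rt_ms`), then aggregates per
#' subject x category x role: `n_valid`, `n_correct`, `accuracy`
#' (= correct / valid) and `rt_mean_ms` over correct valid trials. Cells
#' with no valid trials are kept and flagged rather than dropped.
#'
#' @param behavior data.frame with columns `subject`, `category`, `role`,
#'   `rt_ms`, `correct` (e.g. the `behavior` table of a simulated
#'   session).
#' @param min_rt_ms validity cutoff in ms (default 150; a 149 ms response
#'   is invalid).
#' @return data.frame, one row per subject x category x role, with a
#'   logical `empty_cell` flag.
#' @export
behavioral_summary <- function(behavior, min_rt_ms = 150) {
  need <- c("subject", "category", "role", "rt_ms", "correct")
  miss <- setdiff(need, names(behavior))
  if (length(miss)) stopf("behavior table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  cells <- unique(behavior[, c("subject", "category", "role")])
  cells <- cells[order(cells$subject, cells$category, cells$role), ]
  res <- lapply(seq_len(nrow(cells)), function(r) {
    sel <- behavior$subject == cells$subject[r] &
      behavior$category == cells$category[r] &
      behavior$role == cells$role[r]
    valid <- sel & behavior$rt_ms > min_rt_ms
    n_valid <- sum(valid)
    n_correct <- sum(valid & behavior$correct)
    data.frame(
      cells[r, ], n_valid = n_valid, n_correct = n_correct,
      accuracy = if (n_valid > 0) n_correct / n_valid else NA_real_,
      rt_mean_ms = if (n_correct > 0) {
        mean(behavior$rt_ms[valid & behavior$correct])
      } else NA_real_,
      empty_cell = n_valid == 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Probe minus irrelevant difference scores
#'
#' @param summary_or_scores data.frame with `subject`, `category` and a
#'   value per condition: either a behavioral summary (uses
#'   `rt_mean_ms`) or a long score table with `condition` and a value
#'   column.
#' @param value name of the value column.
#' @param condition name of the column holding `"probe"`/`"irrelevant"`
#'   (default `"role"`).
#' @return data.frame: `subject`, `category`, `diff` (probe minus
#'   irrelevant).
#' @export
diff_scores <- function(summary_or_scores, value, condition = "role") {
  d <- summary_or_scores
  p <- d[d[[condition]] == "probe", c("subject", "category", value)]
  i <- d[d[[condition]] == "irrelevant", c("subject", "category", value)]
  m <- merge(p, i, by = c("subject", "category"),
             suffixes = c("_probe", "_irrelevant"))
  m$diff <- m[[paste0(value, "_probe")]] - m[[paste0(value, "_irrelevant")]]
  m[, c("subject", "category", "diff")]
}

#' Within-subject Cohen's d for probe-irrelevant differences
#'
#' Default `"dz"`: mean of the per-subject differences divided by their
#' sample SD (n - 1). The `"dav"` variant divides by the average of the
#' two condition SDs instead and requires the paired condition values.
#'
#' @param x per-subject differences (for `"dz"`), or the probe values
#'   (for `"dav"`).
#' @param y irrelevant values, required for `"dav"`.
#' @param method `"dz"` or `"dav"`.
#' @return scalar d.
#' @export
cohen_d_within <- function(x, y = NULL, method = c("dz", "dav")) {
  method <- match.arg(method)
  if (method == "dav") {
    stopifnot(!is.null(y), length(x) == length(y))
    diffs <- x - y
    denom <- (stats::sd(x) + stats::sd(y)) / 2
  } else {
    diffs <- if (is.null(y)) x else x - y
    denom <- stats::sd(diffs)
  }
  if (length(diffs) < 2) stopf("need at least 2 subjects")
  if (!is.finite(denom) || denom == 0) stopf("zero SD: d undefined")
  mean(diffs) / denom
}

#' t tests as tidy rows
#'
#' @param x,y numeric samples (`y` optional for one-sample tests).
#' @param paired paired test (df = n - 1).
#' @param var_equal pooled-variance independent test (default `TRUE`,
#'   matching classical two-group dfs); `FALSE` gives Welch.
#' @param mu null value.
#' @return one-row data.frame: `t`, `df`, `p`, `mean_diff`.
#' @export
cit_ttest <- function(x, y = NULL, paired = FALSE, var_equal = TRUE,
                      mu = 0) {
  if (paired) {
    stopifnot(!is.null(y))
    x <- x - y
    y <- NULL
  }
  if (stats::sd(c(x, y)) == 0) {
    # degenerate but well-defined case: no variability and no effect
    if (is.null(y) && isTRUE(all.equal(mean(x), mu))) {
      return(data.frame(t = 0, df = length(x) - 1, p = 1, mean_diff = 0))
    }
    stopf("zero variance: t undefined")
  }
  tt <- if (is.null(y)) {
    stats::t.test(x, mu = mu)
  } else {
    stats::t.test(x, y, var.equal = var_equal, mu = mu)
  }
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value,
             mean_diff = if (is.null(y)) mean(x) else mean(x) - mean(y))
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the k repeated measurements. Equals 1 exactly for k = 2.
gg_epsilon <- function(Y, group) {
  k <- ncol(Y)
  if (k == 2) return(1)
  groups <- split(seq_len(nrow(Y)), group)
  S <- Reduce(`+`, lapply(groups, function(idx) {
    if (length(idx) < 2) return(matrix(0, k, k))
    (length(idx) - 1) * stats::cov(Y[idx, , drop = FALSE])
  })) / (nrow(Y) - length(groups))
  M <- diag(k) - matrix(1 / k, k, k)
  Sc <- M %*% S %*% M
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc * Sc)
  max(1 / (k - 1), min(1, num / den))
}

#' Mixed (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' One within-subject factor crossed with one between-subjects factor;
#' every subject must provide every within level (balanced within,
#' possibly unequal group sizes). Sequential sums of squares per stratum:
#' the between effect is tested against subjects-within-groups, the
#' within main effect and the interaction against the within-subject
#' residual. Greenhouse-Geisser epsilon is estimated from the pooled
#' within-group covariance of the repeated measurements and applied to
#' both degrees of freedom of each within-stratum test; partial eta
#' squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data long data.frame.
#' @param dv,within,between,subject column names.
#' @return data.frame with one row per effect (`between`, `within`,
#'   `within:between`): `F`, `df1`, `df2`, `gg_epsilon`, `p`
#'   (uncorrected), `p_gg`, `pes`.
#' @export
mixed_anova <- function(data, dv, within, between, subject) {
  f <- data[[within]]
  g <- data[[between]]
  s <- data[[subject]]
  lv <- sort(unique(as.character(f)))
  k <- length(lv)
  subj <- unique(as.character(s))
  N <- length(subj)
  Y <- matrix(NA_real_, N, k, dimnames = list(subj, lv))
  for (r in seq_len(nrow(data))) {
    Y[as.character(s[r]), as.character(f[r])] <- data[[dv]][r]
  }
  if (anyNA(Y)) stopf("missing cells: every subject needs every within level")
  grp <- vapply(subj, function(si) as.character(g[match(si, as.character(s))]),
                character(1))
  glv <- sort(unique(grp))
  ng <- length(glv)
  if (any(table(grp) < 2)) stopf("need at least 2 subjects per group")
  GM <- mean(Y)
  subj_means <- rowMeans(Y)
  grp_means <- tapply(subj_means, grp, mean)
  n_j <- table(grp)[glv]
  # between stratum
  ss_g <- k * sum(n_j * (grp_means[glv] - GM)^2)
  ss_sg <- k * sum((subj_means - grp_means[grp])^2)
  df_g <- ng - 1
  df_sg <- N - ng
  # within stratum (sequential: within main, then interaction)
  lvl_means <- colMeans(Y)
  ss_w <- N * sum((lvl_means - GM)^2)
  cell_means <- apply(Y, 2, function(col) tapply(col, grp, mean))  # g x k
  inter_dev <- sweep(sweep(cell_means, 1, grp_means[glv]), 2,
                     lvl_means - GM)
  ss_wg <- sum(as.numeric(n_j) * inter_dev^2)
  sst_w <- sum((Y - subj_means)^2)
  ss_err_w <- sst_w - ss_w - ss_wg
  df_w <- k - 1
  df_wg <- (ng - 1) * (k - 1)
  df_err_w <- (N - ng) * (k - 1)
  eps <- gg_epsilon(Y, grp)
  row <- function(effect, ss, df1, ss_err, df2, use_eps) {
    Fv <- (ss / df1) / (ss_err / df2)
    e <- if (use_eps) eps else NA_real_
    data.frame(effect = effect, F = Fv, df1 = df1, df2 = df2,
               gg_epsilon = e,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               p_gg = if (use_eps) {
                 stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
               } else {
                 stats::pf(Fv, df1, df2, lower.tail = FALSE)
               },
               pes = ss / (ss + ss_err), stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("between", ss_g, df_g, ss_sg, df_sg, FALSE),
    row("within", ss_w, df_w, ss_err_w, df_err_w, TRUE),
    row("within:between", ss_wg, df_wg, ss_err_w, df_err_w, TRUE)
  )
  rownames(out) <- NULL
  out
}

#' Analytic power of the within-between interaction F test
#'
#' Noncentral-F power for the interaction in a mixed design with `g`
#' groups and `m` repeated measurements, following the repeated-measures
#' convention of common power software: noncentrality
#' `lambda = f^2 * N * m / (1 - rho) * epsilon`, numerator df
#' `(g - 1)(m - 1) epsilon`, denominator df `(N - g)(m - 1) epsilon`.
#'
#' @param f Cohen's f effect size.
#' @param alpha significance level.
#' @param N total sample size.
#' @param g number of groups.
#' @param m number of repeated measurements.
#' @param rho correlation among repeated measurements (default 0.5).
#' @param epsilon nonsphericity correction (default 1).
#' @return power (scalar in `[alpha, 1]` for `f >= 0`).
#' @export
power_mixed_interaction <- function(f, alpha = 0.05, N, g = 2, m = 2,
                                    rho = 0.5, epsilon = 1) {
  stopifnot(f >= 0, alpha > 0, alpha < 1, N > g, g >= 2, m >= 2,
            rho > -1, rho < 1, epsilon > 0)
  lambda <- f^2 * N * m / (1 - rho) * epsilon
  df1 <- (g - 1) * (m - 1) * epsilon
  df2 <- (N - g) * (m - 1) * epsilon
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Monte-Carlo power of the 2 x 2 mixed-design interaction
#'
#' Simulates equicorrelated repeated measurements (variance 1,
#' correlation `rho`) with a group x measurement interaction planted at
#' Cohen's f, runs [mixed_anova()] on every replicate and counts
#' rejections. Serves as a simulation cross-check of
#' [power_mixed_interaction()].
#'
#' @inheritParams power_mixed_interaction
#' @param reps number of simulated experiments.
#' @param seed integer seed.
#' @return empirical power.
#' @export
power_mc_interaction <- function(f, alpha = 0.05, N, rho = 0.5,
                                 reps = 5000, seed = NULL) {
  n1 <- floor(N / 2)
  n2 <- N - n1
  # plant the interaction so the exact noncentrality matches the
  # analytic convention: lambda = f^2 * N * m / (1 - rho), m = 2
  lambda <- f^2 * N * 2 / (1 - rho)
  var_d <- 2 * (1 - rho)
  delta <- sqrt(lambda * var_d * (1 / n1 + 1 / n2))  # group diff of diffs
  h <- delta / 4
  grp <- rep(c(1, 2), c(n1, n2))
  sign_g <- ifelse(grp == 1, 1, -1)
  with_seed(seed, {
    hits <- 0L
    for (r in seq_len(reps)) {
      u <- stats::rnorm(N, sd = sqrt(rho))
      e1 <- stats::rnorm(N, sd = sqrt(1 - rho))
      e2 <- stats::rnorm(N, sd = sqrt(1 - rho))
      y1 <- u + e1 + sign_g * h
      y2 <- u + e2 - sign_g * h
      d <- y1 - y2
      # interaction F in the 2x2 mixed design = squared two-sample t on
      # the within-subject differences
      tt <- stats::t.test(d[grp == 1], d[grp == 2], var.equal = TRUE)
      if (tt$p.value < alpha) hits <- hits + 1L
    }
    hits / reps
  })
}

#' Apply subject exclusion rules
#'
#' Excludes subjects failing any configured quality threshold: low
#' primary-task probe accuracy, low secondary-task target accuracy, or
#' too many failed item-recall checks (default: more than 4 incorrect of
#' 9).
#'
#' @param qc data.frame with columns `subject`, `probe_accuracy`,
#'   `target_accuracy`, `recall_failures`.
#' @param probe_acc_min,target_acc_min,max_recall_failures thresholds.
#' @return list with `kept` (subject ids) and `excluded` (data.frame:
#'   `subject`, `reason`).
#' @export
apply_exclusions <- function(qc, probe_acc_min = 0.75,
                             target_acc_min = 0.60,
                             max_recall_failures = 4) {
  reasons <- lapply(seq_len(nrow(qc)), function(r) {
    why <- character(0)
    if (qc$probe_accuracy[r] < probe_acc_min) {
      why <- c(why, sprintf("probe accuracy %.0f%% < %.0f%%",
                            100 * qc$probe_accuracy[r], 100 * probe_acc_min))
    }
    if (qc$target_accuracy[r] < target_acc_min) {
      why <- c(why, sprintf("target accuracy %.0f%% < %.0f%%",
                            100 * qc$target_accuracy[r], 100 * target_acc_min))
    }
    if (qc$recall_failures[r] > max_recall_failures) {
      why <- c(why, sprintf("%d recall failures > %d",
                            qc$recall_failures[r], max_recall_failures))
    }
    why
  })
  excluded_idx <- which(lengths(reasons) > 0)
  list(
    kept = qc$subject[setdiff(seq_len(nrow(qc)), excluded_idx)],
    excluded = data.frame(
      subject = qc$subject[excluded_idx],
      reason = vapply(reasons[excluded_idx], paste, character(1),
                      collapse = "; "),
      stringsAsFactors = FALSE
    )
  )
}
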