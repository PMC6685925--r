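#' @title Bootstrapped amplitude-difference (BAD) diagnostic
#'
#' @description
#' Per-subject classification by epoch resampling: on each bootstrap
#' iteration, probe epochs and irrelevant epochs are redrawn with
#' replacement at their original counts, averaged, and scored with the
#' peak-to-peak P300 measure; the proportion of iterations in which the
#' probe P300pp exceeds the irrelevant P300pp estimates the probability
#' that the subject's probe response is genuinely larger. A subject is
#' called knowledgeable when that proportion reaches the verdict
#' threshold (0.9 by default, following the convention of the P300 CIT
#' literature).
#' @name classify
NULL

#' Bootstrap classifier configuration
#'
#' @param B bootstrap iterations (default 1000).
#' @param mode `"probe_vs_all_irrelevants"` compares the probe average
#'   with the average of all irrelevant epochs;
#'   `"probe_vs_max_irrelevant"` with the largest per-item irrelevant
#'   P300pp (more conservative).
#' @param draws how many epochs to draw per condition. The peak-to-peak
#'   measure of a noisier average is systematically larger, so unequal
#'   noise between the two bootstrap averages biases the comparison
#'   toward "probe larger". `"variance_matched"` (default) chooses draw
#'   counts so both bootstrap averages have the same total variance
#'   around their true means (`1/m + 1/n` equated across conditions,
#'   where `n` is the pool size and `m` the draw count), which keeps the
#'   proportion centered at 0.5 under the null even when the probe pool
#'   is much smaller than the irrelevant pool. `"match_probe"` draws the
#'   probe count from both pools; `"original_counts"` draws each pool at
#'   its own size (the historical convention; anticonservative with
#'   peak-to-peak scoring).
#' @param theta verdict threshold on the bootstrap proportion.
#' @param seed optional integer seed.
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 1000,
                             mode = c("probe_vs_all_irrelevants",
                                      "probe_vs_max_irrelevant"),
                             draws = c("variance_matched", "match_probe",
                                       "original_counts"),
                             theta = 0.9, seed = NULL) {
  mode <- match.arg(mode)
  draws <- match.arg(draws)
  stopifnot(B >= 1, theta > 0, theta < 1)
  structure(list(B = B, mode = mode, draws = draws, theta = theta,
                 seed = seed),
            class = "bootstrap_config")
}

# Draw counts (m_p, m_i) for pools of size (n_p, n_i). Variance matching
# equates 1/m + 1/n across conditions: the smaller pool is drawn at its
# own size and the larger pool's draw count is reduced accordingly.
draw_counts <- function(n_p, n_i, draws) {
  if (draws == "original_counts") return(c(n_p, n_i))
  if (draws == "match_probe") return(c(n_p, n_p))
  if (n_p <= n_i) {
    m_i <- 1 / (2 / n_p - 1 / n_i)
    c(n_p, max(2L, as.integer(round(m_i))))
  } else {
    m_p <- 1 / (2 / n_i - 1 / n_p)
    c(max(2L, as.integer(round(m_p))), n_i)
  }
}

#' Bootstrapped amplitude-difference test for one subject
#'
#' Iteration `b` draws, in this order, probe epochs then irrelevant
#' epochs with replacement (per irrelevant item in the max-irrelevant
#' mode), averages each draw, scores both averages with the P300pp
#' segment search, and records whether the probe value is larger. The
#' number drawn per condition follows `cfg$draws` (see
#' [bootstrap_config()]). Deterministic under `cfg$seed`.
#'
#' @param probe numeric matrix of probe epochs (trials x samples) at the
#'   analysis channel.
#' @param irrelevant numeric matrix of irrelevant epochs.
#' @param times sample times in ms (shared by both matrices).
#' @param cfg a [bootstrap_config()].
#' @param scorer_cfg a [segment_search_config()].
#' @param irr_items item label per irrelevant epoch, required for the
#'   max-irrelevant mode.
#' @return list of class `bootstrap_result`: `p_hat`, `ci` (95 percent
#'   Clopper-Pearson), `verdict` (`"knowledgeable"` or
#'   `"not knowledgeable"`), `B`, `theta`, `mode`, `n_probe`, `n_irrelevant`.
#' @export
bootstrap_bad <- function(probe, irrelevant, times,
                          cfg = bootstrap_config(),
                          scorer_cfg = segment_search_config(),
                          irr_items = NULL) {
  stopifnot(is.matrix(probe), is.matrix(irrelevant),
            ncol(probe) == length(times), ncol(irrelevant) == length(times))
  n_p <- nrow(probe)
  n_i <- nrow(irrelevant)
  if (n_p < 2 || n_i < 2) stopf("need at least 2 epochs per condition")
  if (cfg$mode == "probe_vs_max_irrelevant") {
    if (is.null(irr_items) || length(irr_items) != n_i) {
      stopf("irr_items (one label per irrelevant epoch) required for %s",
            cfg$mode)
    }
    item_rows <- split(seq_len(n_i), irr_items)
  }
  avg_p <- matrix(0, cfg$B, ncol(probe))
  kd <- draw_counts(n_p, n_i, cfg$draws)
  k_p <- kd[1]
  k_i <- kd[2]
  with_seed(cfg$seed, {
    if (cfg$mode == "probe_vs_all_irrelevants") {
      avg_i <- matrix(0, cfg$B, ncol(irrelevant))
      for (b in seq_len(cfg$B)) {
        avg_p[b, ] <- colMeans(probe[sample.int(n_p, k_p, replace = TRUE), ,
                                     drop = FALSE])
        avg_i[b, ] <- colMeans(irrelevant[sample.int(n_i, k_i,
                                                     replace = TRUE), ,
                                          drop = FALSE])
      }
      pp_p <- p300_pp_matrix(avg_p, times, scorer_cfg)$p300pp_uv
      pp_i <- p300_pp_matrix(avg_i, times, scorer_cfg)$p300pp_uv
    } else {
      pp_items <- matrix(0, cfg$B, length(item_rows))
      avg_items <- array(0, c(cfg$B, length(item_rows), ncol(irrelevant)))
      kd_item <- lapply(item_rows, function(rows)
        draw_counts(n_p, length(rows), cfg$draws))
      for (b in seq_len(cfg$B)) {
        avg_p[b, ] <- colMeans(probe[sample.int(n_p, k_p, replace = TRUE), ,
                                     drop = FALSE])
        for (j in seq_along(item_rows)) {
          rows <- item_rows[[j]]
          pick <- rows[sample.int(length(rows), kd_item[[j]][2],
                                  replace = TRUE)]
          avg_items[b, j, ] <- colMeans(irrelevant[pick, , drop = FALSE])
        }
      }
      pp_p <- p300_pp_matrix(avg_p, times, scorer_cfg)$p300pp_uv
      for (j in seq_along(item_rows)) {
        pp_items[, j] <- p300_pp_matrix(avg_items[, j, ], times,
                                        scorer_cfg)$p300pp_uv
      }
      pp_i <- apply(pp_items, 1, max)
    }
    wins <- sum(pp_p > pp_i)
    p_hat <- wins / cfg$B
    ci <- as.numeric(stats::binom.test(wins, cfg$B)$conf.int)
    structure(list(p_hat = p_hat, ci = ci,
                   verdict = if (p_hat >= cfg$theta) "knowledgeable"
                             else "not knowledgeable",
                   B = cfg$B, theta = cfg$theta, mode = cfg$mode,
                   n_probe = n_p, n_irrelevant = n_i),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("BAD bootstrap (%s, B = %d): p_hat = %.3f [%.3f, %.3f] -> %s (theta = %g)\n",
              x$mode, x$B, x$p_hat, x$ci[1], x$ci[2], x$verdict, x$theta))
  invisible(x)
}

#' Bootstrap verdicts per category for one cleaned subject
#'
#' @param epochs cleaned primary-task `epochset` (events: `role`,
#'   `category`, `correct`, `item`).
#' @param cfg a [bootstrap_config()].
#' @param scorer_cfg a [segment_search_config()].
#' @param channel analysis channel.
#' @return data.frame: one row per category with `B`, `p_hat`, `ci_low`,
#'   `ci_high`, `verdict`.
#' @export
bad_by_category <- function(epochs, cfg = bootstrap_config(),
                            scorer_cfg = segment_search_config(),
                            channel = "Pz") {
  ev <- epochs$events
  times <- epoch_times(epochs)
  m <- channel_matrix(epochs, channel)
  cats <- unique(ev$category)
  seeds <- derive_seeds(cfg$seed %||% 0L, length(cats))
  out <- lapply(seq_along(cats), function(ci) {
    cat_ <- cats[ci]
    keep <- ev$correct & ev$category == cat_
    p_rows <- which(keep & ev$role == "probe")
    i_rows <- which(keep & ev$role == "irrelevant")
    cfg_i <- cfg
    if (!is.null(cfg$seed)) cfg_i$seed <- seeds[ci]
    r <- bootstrap_bad(m[p_rows, , drop = FALSE], m[i_rows, , drop = FALSE],
                       times, cfg_i, scorer_cfg,
                       irr_items = ev$item[i_rows])
    data.frame(category = cat_, B = r$B, p_hat = r$p_hat,
               ci_low = r$ci[1], ci_high = r$ci[2], verdict = r$verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cohort classification rates
#'
#' @param p_hat per-subject bootstrap proportions.
#' @param truth logical ground truth (`TRUE` = knowledgeable/guilty).
#' @param theta verdict threshold.
#' @param theta_grid thresholds for the ROC sweep.
#' @return list with `hit_rate`, `false_positive_rate`, `n_guilty`,
#'   `n_innocent`, and `roc` (data.frame over `theta_grid`).
#' @export
cohort_rates <- function(p_hat, truth, theta = 0.9,
                         theta_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(p_hat) == length(truth))
  if (length(p_hat) == 0) stopf("empty cohort")
  rate <- function(th) {
    c(hit = if (any(truth)) mean(p_hat[truth] >= th) else NA_real_,
      fpr = if (any(!truth)) mean(p_hat[!truth] >= th) else NA_real_)
  }
  at <- rate(theta)
  roc <- t(vapply(theta_grid, rate, numeric(2)))
  list(hit_rate = unname(at["hit"]), false_positive_rate = unname(at["fpr"]),
       n_guilty = sum(truth), n_innocent = sum(!truth),
       roc = data.frame(theta = theta_grid, hit_rate = roc[, "hit"],
                        false_positive_rate = roc[, "fpr"]))
}
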