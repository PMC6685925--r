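#' @title Condition averaging and the peak-to-peak P300 measure
#'
#' @description
#' The peak-to-peak P300 (P300pp) is scored on a condition-averaged
#' waveform by segment search: find the 100 ms segment with the maximum
#' mean lying entirely within 400-800 ms post-stimulus, then, between the
#' midpoint of that segment and 1400 ms, the 100 ms segment with the
#' minimum mean. P300pp is the difference of the two segment means. This
#' measure is offset-invariant and captures the full positive-negative
#' excursion of the late ERP complex.
#' @name erp_score
NULL

#' Segment-search configuration for the P300pp measure
#'
#' @param max_window two-element vector, window (ms) that must contain
#'   the maximum segment (default `c(400, 800)`).
#' @param segment_ms segment length in ms (default 100).
#' @param min_search_end_ms end of the minimum-search window (default 1400).
#' @param bound `"segment"` (default) requires whole segments inside the
#'   windows; `"start"` only bounds segment start times.
#' @return list of class `segment_search_config`.
#' @export
segment_search_config <- function(max_window = c(400, 800), segment_ms = 100,
                                  min_search_end_ms = 1400,
                                  bound = c("segment", "start")) {
  bound <- match.arg(bound)
  stopifnot(length(max_window) == 2L, max_window[1] < max_window[2],
            segment_ms > 0)
  structure(list(max_window = max_window, segment_ms = segment_ms,
                 min_search_end_ms = min_search_end_ms, bound = bound),
            class = "segment_search_config")
}

# All candidate 100 ms segment means for a set of waveforms.
# mat: n_waveforms x n_samples. Returns list(means = n x n_starts matrix,
# starts, ends, L) where starts/ends are sample indices.
segment_means <- function(mat, times, cfg) {
  srate <- 1000 / (times[2] - times[1])
  L <- round(cfg$segment_ms / 1000 * srate)
  if (L < 1L) stopf("segment shorter than one sample")
  S <- ncol(mat)
  if (L > S) stopf("segment longer than the epoch")
  starts <- seq_len(S - L + 1L)
  # averaging by cumulative sums along each row
  cs <- cbind(0, t(apply(mat, 1L, cumsum)))
  means <- (cs[, starts + L, drop = FALSE] - cs[, starts, drop = FALSE]) / L
  list(means = means, starts = starts, ends = starts + L - 1L, L = L)
}

# Scan step is one sample: the finest deterministic grid. Ties broken by
# the earliest segment start so results are order-independent.
p300_pp_core <- function(mat, times, cfg) {
  eps <- 1e-9
  srate <- 1000 / (times[2] - times[1])
  if (times[length(times)] < cfg$min_search_end_ms - 1000 / srate - eps) {
    stopf("epoch ends at %g ms but the minimum-search window extends to %g ms",
          times[length(times)], cfg$min_search_end_ms)
  }
  seg <- segment_means(mat, times, cfg)
  t_start <- times[seg$starts]
  t_end <- times[seg$ends]
  in_max <- if (cfg$bound == "segment") {
    t_start >= cfg$max_window[1] - eps & t_end <= cfg$max_window[2] + eps
  } else {
    t_start >= cfg$max_window[1] - eps & t_start <= cfg$max_window[2] + eps
  }
  if (!any(in_max)) stopf("no %g ms segment fits inside the maximum-search window",
                          cfg$segment_ms)
  max_cols <- which(in_max)
  mm <- seg$means[, max_cols, drop = FALSE]
  max_pos <- max.col(mm, ties.method = "first")
  max_mean <- mm[cbind(seq_len(nrow(mm)), max_pos)]
  max_start_idx <- seg$starts[max_cols[max_pos]]
  mid_ms <- (times[max_start_idx] + times[max_start_idx + seg$L - 1L]) / 2
  # midpoint floored to the sample grid
  mid_idx <- findInterval(mid_ms + eps, times)
  mid_grid_ms <- times[mid_idx]
  end_ok <- t_end <= cfg$min_search_end_ms + eps
  n <- nrow(mat)
  min_mean <- numeric(n)
  min_mid <- numeric(n)
  at_edge <- logical(n)
  for (r in seq_len(n)) {
    in_min <- end_ok & t_start >= mid_grid_ms[r] - eps
    if (!any(in_min)) {
      stopf("minimum-search window [%g, %g] ms too short for a %g ms segment",
            mid_grid_ms[r], cfg$min_search_end_ms, cfg$segment_ms)
    }
    cols <- which(in_min)
    v <- seg$means[r, cols]
    j <- which.min(v)
    min_mean[r] <- v[j]
    s <- seg$starts[cols[j]]
    min_mid[r] <- (times[s] + times[s + seg$L - 1L]) / 2
    at_edge[r] <- max_pos[r] == 1L || max_pos[r] == length(max_cols)
  }
  data.frame(max_mean_uv = max_mean, max_mid_ms = mid_ms,
             min_mean_uv = min_mean, min_mid_ms = min_mid,
             p300pp_uv = max_mean - min_mean, max_at_edge = at_edge)
}

#' Peak-to-peak P300 of one averaged waveform
#'
#' @param waveform numeric vector, the condition-averaged voltage (uV).
#' @param times sample times in ms relative to stimulus onset (uniform
#'   grid), e.g. [epoch_times()].
#' @param cfg a [segment_search_config()].
#' @param warn_edge if `TRUE`, warn when the maximum segment abuts a
#'   search-window edge (the automated analogue of visually verifying
#'   that the P300 peak falls inside the window).
#' @return one-row data.frame: `max_mean_uv`, `max_mid_ms`, `min_mean_uv`,
#'   `min_mid_ms`, `p300pp_uv`, `max_at_edge`.
#' @export
p300_pp <- function(waveform, times, cfg = segment_search_config(),
                    warn_edge = FALSE) {
  stopifnot(length(waveform) == length(times))
  res <- p300_pp_core(matrix(waveform, nrow = 1L), times, cfg)
  if (warn_edge && res$max_at_edge) {
    warning("maximum segment abuts a search-window edge; ",
            "the P300 peak may lie outside the window", call. = FALSE)
  }
  res
}

#' Peak-to-peak P300 of many waveforms at once
#'
#' Vectorized form of [p300_pp()] used by the bootstrap classifier; row
#' `i` of the result equals `p300_pp(mat[i, ], times, cfg)`.
#'
#' @param mat numeric matrix, one waveform per row.
#' @inheritParams p300_pp
#' @return data.frame with one row per waveform.
#' @export
p300_pp_matrix <- function(mat, times, cfg = segment_search_config()) {
  p300_pp_core(mat, times, cfg)
}

#' Average epochs into a condition ERP
#'
#' @param x an `epochset`.
#' @param select logical/integer trial selector, or a function of the
#'   event table returning one; `NULL` selects all trials.
#' @param correct_only drop trials whose `correct` event flag is `FALSE`
#'   (default `TRUE`; P300 analyses use correct-response trials only).
#' @param channel channel to average (default `"Pz"`).
#' @param condition optional condition label stored in the result.
#' @return object of class `average_erp`: list with `waveform`, `times`,
#'   `srate`, `n_epochs`, `condition`.
#' @export
average_epochs <- function(x, select = NULL, correct_only = TRUE,
                           channel = "Pz", condition = NA_character_) {
  keep <- rep(TRUE, n_epochs(x))
  if (is.function(select)) select <- select(x$events)
  if (!is.null(select)) {
    keep <- if (is.logical(select)) select else seq_len(n_epochs(x)) %in% select
  }
  if (correct_only) {
    if (is.null(x$events$correct)) stopf("no 'correct' column in the event table")
    keep <- keep & x$events$correct
  }
  if (!any(keep)) stopf("no epochs match condition '%s'", condition)
  m <- channel_matrix(x, channel)[keep, , drop = FALSE]
  structure(list(waveform = colMeans(m), times = epoch_times(x),
                 srate = x$srate, n_epochs = sum(keep),
                 condition = condition),
            class = "average_erp")
}

#' @export
print.average_erp <- function(x, ...) {
  cat(sprintf("average ERP '%s': %d epochs, %d samples @ %g Hz\n",
              x$condition, x$n_epochs, length(x$waveform), x$srate))
  invisible(x)
}

#' Score all conditions of one subject
#'
#' Produces the per-condition P300pp table: probe and pooled-irrelevant
#' rows per item category from the primary-task epochs, and overall
#' target and nontarget rows from the secondary-task epochs, plus the
#' per-category probe minus irrelevant difference scores.
#'
#' The difference score compares averages built from very different trial
#' counts (one probe item vs five irrelevant items), and the peak-to-peak
#' measure of a noisier average is systematically larger. The default
#' `diff_irrelevant = "per_item"` therefore subtracts the mean of the
#' per-item irrelevant P300pp values — each item average carries the same
#' number of trials as the probe average, so the noise contribution
#' cancels in expectation. `"pooled"` subtracts the all-irrelevant
#' average's P300pp instead (the classical convention; anticonservative
#' under noise). Both variants coincide on noiseless data.
#'
#' @param primary `epochset` of primary-task epochs; events need `role`
#'   (probe/irrelevant), `category`, `correct`, `item`.
#' @param secondary optional `epochset` of secondary-task epochs; events
#'   need `role` (target/nontarget) and `correct`.
#' @param cfg a [segment_search_config()].
#' @param channel scored channel (default `"Pz"`).
#' @param diff_irrelevant `"per_item"` (default) or `"pooled"`; see
#'   Details.
#' @return list of class `cit_scores`: `scores` (one row per condition,
#'   including the pooled irrelevant rows) and `diffs` (category,
#'   `p300pp_diff_uv` per the chosen variant, plus
#'   `p300pp_diff_pooled_uv`).
#' @export
score_subject <- function(primary, secondary = NULL,
                          cfg = segment_search_config(), channel = "Pz",
                          diff_irrelevant = c("per_item", "pooled")) {
  diff_irrelevant <- match.arg(diff_irrelevant)
  ev <- primary$events
  stopifnot(all(c("role", "category", "correct") %in% names(ev)))
  rows <- list()
  score_one <- function(x, sel, condition, category) {
    avg <- average_epochs(x, sel, correct_only = TRUE, channel = channel,
                          condition = condition)
    pp <- p300_pp(avg$waveform, avg$times, cfg)
    cbind(data.frame(category = category, condition = condition,
                     n_epochs = avg$n_epochs, stringsAsFactors = FALSE), pp)
  }
  for (cat_ in unique(ev$category)) {
    rows[[length(rows) + 1L]] <-
      score_one(primary, ev$role == "probe" & ev$category == cat_,
                "probe", cat_)
    rows[[length(rows) + 1L]] <-
      score_one(primary, ev$role == "irrelevant" & ev$category == cat_,
                "irrelevant", cat_)
  }
  if (!is.null(secondary)) {
    sev <- secondary$events
    for (role in c("target", "nontarget")) {
      rows[[length(rows) + 1L]] <-
        score_one(secondary, sev$role == role, role, "all")
    }
  }
  scores <- do.call(rbind, rows)
  cats <- unique(ev$category)
  pooled_diff <- vapply(cats, function(cat_) {
    scores$p300pp_uv[scores$category == cat_ & scores$condition == "probe"] -
      scores$p300pp_uv[scores$category == cat_ &
                         scores$condition == "irrelevant"]
  }, numeric(1))
  diff_uv <- if (diff_irrelevant == "pooled") pooled_diff else {
    vapply(cats, function(cat_) {
      probe_pp <- scores$p300pp_uv[scores$category == cat_ &
                                     scores$condition == "probe"]
      irr <- ev$role == "irrelevant" & ev$category == cat_
      item_pp <- vapply(unique(ev$item[irr]), function(it) {
        avg <- average_epochs(primary, irr & ev$item == it,
                              correct_only = TRUE, channel = channel,
                              condition = paste0("irrelevant:", it))
        p300_pp(avg$waveform, avg$times, cfg)$p300pp_uv
      }, numeric(1))
      probe_pp - mean(item_pp)
    }, numeric(1))
  }
  diffs <- data.frame(category = cats, p300pp_diff_uv = diff_uv,
                      p300pp_diff_pooled_uv = pooled_diff,
                      stringsAsFactors = FALSE)
  structure(list(scores = scores, diffs = diffs), class = "cit_scores")
}

#' @export
print.cit_scores <- function(x, ...) {
  cat("P300pp scores:\n")
  print(x$scores, row.names = FALSE)
  cat("probe - irrelevant differences:\n")
  print(x$diffs, row.names = FALSE)
  invisible(x)
}
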