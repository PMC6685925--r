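#' @title Stimulus-set construction for the CTP concealed information test
#'
#' @description
#' A Complex Trial Protocol (CTP) session presents, in every trial, one
#' secondary-task item (target or nontarget) followed by one primary-task
#' item (the examinee's own detail, the *probe*, or one of five matched
#' foils, the *irrelevants*). The functions here build the per-category
#' item sets and the constrained trial schedule:
#' candidate foils are matched to the probe on character length and must
#' not share its initial letter (month names exempt), participant-flagged
#' candidates are excluded, and the trial order is randomized under exact
#' balance constraints (every primary item preceded equally often by every
#' secondary item, targets half as often as nontargets; no immediate item
#' repeats in either task slot).
#' @name stimgen
NULL

#' Build a candidate pool of irrelevant items for one probe
#'
#' Draws `n_candidates` items from `pool`, excluding the probe itself and
#' (unless `exempt_initial`) any word sharing the probe's initial letter,
#' preferring candidates whose character length is closest to the probe's.
#' Ties at the deciding length distance are broken by seeded random choice.
#'
#' @param probe probe text (single string).
#' @param pool character vector of available items for the category.
#' @param n_candidates number of candidates to return (default 8).
#' @param exempt_initial if `TRUE`, the initial-letter filter is disabled
#'   (used for date items, whose month names cannot be avoided).
#' @param seed optional integer seed for the tie-break draw.
#' @return character vector of `n_candidates` candidate texts.
#' @export
build_candidate_pool <- function(probe, pool, n_candidates = 8,
                                 exempt_initial = FALSE, seed = NULL) {
  stopifnot(is.character(probe), length(probe) == 1L, nzchar(probe))
  pool <- unique(pool)
  pool <- pool[pool != probe]
  if (!exempt_initial) {
    first <- toupper(substr(pool, 1, 1))
    pool <- pool[first != toupper(substr(probe, 1, 1))]
  }
  if (length(pool) < n_candidates) {
    stopf("insufficient candidates: %d eligible items in pool, %d required",
          length(pool), n_candidates)
  }
  dist <- abs(nchar(pool) - nchar(probe))
  with_seed(seed, {
    picked <- character(0)
    for (d in sort(unique(dist))) {
      tier <- pool[dist == d]
      need <- n_candidates - length(picked)
      if (need <= 0) break
      if (length(tier) <= need) {
        picked <- c(picked, tier)
      } else {
        picked <- c(picked, sample(tier, need))
      }
    }
    picked
  })
}

#' Select task irrelevants from an unflagged candidate pool
#'
#' Participants mark candidates that are personally meaningful to them
#' (at most two per category); the task irrelevants are then drawn at
#' random from the remaining, genuinely irrelevant candidates.
#'
#' @param candidates character vector of candidate texts.
#' @param flagged character vector of candidate texts flagged by the
#'   participant (maximum two).
#' @param n_select number of irrelevants to select (default 5).
#' @param seed optional integer seed.
#' @return character vector of `n_select` selected texts.
#' @export
select_irrelevants <- function(candidates, flagged = character(0),
                               n_select = 5, seed = NULL) {
  if (length(flagged) > 2) {
    stopf("at most two candidates may be flagged per category (got %d)",
          length(flagged))
  }
  if (!all(flagged %in% candidates)) {
    stopf("flagged items must be among the candidates")
  }
  keep <- setdiff(candidates, flagged)
  if (length(keep) < n_select) {
    stopf("too few unflagged candidates: %d left, %d required",
          length(keep), n_select)
  }
  with_seed(seed, sample(keep, n_select))
}

#' Secondary-task items for a group
#'
#' The Standard group discriminates number strings (two rare targets,
#' four nontargets, 1:4 target:nontarget ratio); the Induced group uses
#' familiarity inducer words instead (self-referring targets,
#' other-referring nontargets).
#'
#' @param group `"standard"` or `"induced"`.
#' @return data.frame with columns `text` and `role`.
#' @export
secondary_items <- function(group = c("standard", "induced")) {
  group <- match.arg(group)
  if (group == "standard") {
    data.frame(
      text = c("88888", "99999", "11111", "22222", "33333", "44444"),
      role = c("target", "target", rep("nontarget", 4)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      text = c("MINE", "FAMILIAR", "OTHER", "MISC", "FOREIGN", "UNRELATED"),
      role = c("target", "target", rep("nontarget", 4)),
      stringsAsFactors = FALSE
    )
  }
}

#' Format a date item
#'
#' @param month month index 1-12.
#' @param day day of month.
#' @return string such as `"JUN 19"`.
#' @export
format_date_item <- function(month, day) {
  months <- c("JAN", "FEB", "MAR", "APR", "MAY", "JUN",
              "JUL", "AUG", "SEP", "OCT", "NOV", "DEC")
  stopifnot(month %in% 1:12, day %in% 1:31)
  paste(months[month], day)
}

#' All date items usable as probes or foils
#'
#' @return character vector of `"MON d"` strings (days 1-28 so every
#'   month contributes equally).
#' @export
date_pool <- function() {
  grid <- expand.grid(month = 1:12, day = 1:28)
  mapply(format_date_item, grid$month, grid$day)
}

#' Bundled word pools
#'
#' Generic forename and animal-name pools shipped with the package
#' (plain-text, one item per line, uppercase).
#'
#' @param which `"forename"` or `"animal"`.
#' @return character vector.
#' @export
word_pool <- function(which = c("forename", "animal")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "s.txt"), package = "ctpcit")
  toupper(readLines(path))
}

#' Build the full three-category item set for one participant
#'
#' For each category (forename, date, animal) the probe is paired with
#' `n_candidates` length-matched candidates from which `n_irrelevants`
#' unflagged foils are drawn, yielding 3 x (1 probe + 5 irrelevants) = 18
#' unique primary items, plus the group's 2 targets and 4 nontargets.
#'
#' @param probes named list with elements `forename`, `date`, `animal`
#'   (probe texts; build dates with [format_date_item()]).
#' @param group `"standard"` or `"induced"`.
#' @param flagged named list of per-category flagged candidate texts.
#' @param pools named list of per-category candidate pools; defaults to
#'   the bundled pools and [date_pool()].
#' @param n_candidates candidates drawn per category (default 8).
#' @param n_irrelevants foils selected per category (default 5).
#' @param seed optional integer seed.
#' @return an object of class `cit_itemset`: list with `primary`
#'   (data.frame: text, category, role, visual_type), `secondary`
#'   (data.frame: text, role), and `group`.
#' @export
build_item_set <- function(probes, group = c("standard", "induced"),
                           flagged = list(), pools = NULL,
                           n_candidates = 8, n_irrelevants = 5,
                           seed = NULL) {
  group <- match.arg(group)
  categories <- c("forename", "date", "animal")
  stopifnot(all(categories %in% names(probes)))
  if (is.null(pools)) {
    pools <- list(forename = word_pool("forename"),
                  date = date_pool(),
                  animal = word_pool("animal"))
  }
  seeds <- derive_seeds(seed %||% 0L, 2L * length(categories))
  primary <- do.call(rbind, lapply(seq_along(categories), function(i) {
    cat <- categories[i]
    probe <- toupper(probes[[cat]])
    cand <- build_candidate_pool(probe, toupper(pools[[cat]]),
                                 n_candidates = n_candidates,
                                 exempt_initial = identical(cat, "date"),
                                 seed = if (is.null(seed)) NULL else seeds[2 * i - 1])
    # flags apply to displayed candidates only; marks on other items are moot
    flags <- intersect(toupper(flagged[[cat]] %||% character(0)), cand)
    irr <- select_irrelevants(cand, flags, n_select = n_irrelevants,
                              seed = if (is.null(seed)) NULL else seeds[2 * i])
    data.frame(
      text = c(probe, irr),
      category = cat,
      role = c("probe", rep("irrelevant", n_irrelevants)),
      visual_type = if (cat == "date") "mixed_character" else "letters_only",
      stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(primary$text)) {
    stopf("primary items are not unique across categories: %s",
          paste(primary$text[duplicated(primary$text)], collapse = ", "))
  }
  out <- list(primary = primary, secondary = secondary_items(group),
              group = group)
  class(out) <- "cit_itemset"
  out
}

#' @export
print.cit_itemset <- function(x, ...) {
  cat(sprintf("CTP CIT item set (%s group): %d primary items, %d secondary\n",
              x$group, nrow(x$primary), nrow(x$secondary)))
  for (cat_ in unique(x$primary$category)) {
    sub <- x$primary[x$primary$category == cat_, ]
    cat(sprintf("  %-9s probe %-12s irrelevants: %s\n", cat_,
                sub$text[sub$role == "probe"],
                paste(sub$text[sub$role == "irrelevant"], collapse = ", ")))
  }
  invisible(x)
}

# Assign a secondary item to every trial under the exact precedence quota
# (each nontarget precedes each primary item reps/5 times, each target
# reps/10 times) and the no-immediate-repeat constraint. Randomized greedy
# with bounded restarts, then a depth-first backtracking pass.
assign_secondaries <- function(primary_idx, n_secondary, quota,
                               max_restarts = 200L) {
  n <- length(primary_idx)
  greedy_once <- function() {
    q <- quota
    out <- integer(n)
    for (t in seq_len(n)) {
      p <- primary_idx[t]
      allowed <- which(q[p, ] > 0L)
      if (t > 1L) allowed <- setdiff(allowed, out[t - 1L])
      if (length(allowed) == 0L) return(NULL)
      # weight by remaining quota to steer away from dead ends
      s <- if (length(allowed) == 1L) allowed else
        sample(allowed, 1L, prob = q[p, allowed])
      out[t] <- s
      q[p, s] <- q[p, s] - 1L
    }
    out
  }
  for (r in seq_len(max_restarts)) {
    out <- greedy_once()
    if (!is.null(out)) return(out)
  }
  # backtracking fallback with a node budget
  q <- quota
  out <- integer(n)
  choices <- vector("list", n)
  t <- 1L
  budget <- 500000L
  while (t >= 1L && t <= n) {
    if (is.null(choices[[t]])) {
      p <- primary_idx[t]
      allowed <- which(q[p, ] > 0L)
      if (t > 1L) allowed <- setdiff(allowed, out[t - 1L])
      choices[[t]] <- if (length(allowed) > 1L) sample(allowed) else allowed
    }
    if (length(choices[[t]]) == 0L) {
      choices[[t]] <- NULL
      t <- t - 1L
      if (t >= 1L) q[primary_idx[t], out[t]] <- q[primary_idx[t], out[t]] + 1L
      next
    }
    s <- choices[[t]][1L]
    choices[[t]] <- choices[[t]][-1L]
    out[t] <- s
    q[primary_idx[t], s] <- q[primary_idx[t], s] - 1L
    t <- t + 1L
    budget <- budget - 1L
    if (budget <= 0L) {
      stopf("sequence generation failed: secondary precedence quota %s",
            "unsatisfiable within the search budget")
    }
  }
  if (t < 1L) {
    stopf("sequence generation failed: no secondary assignment satisfies %s",
          "the precedence quota with the no-repeat constraint")
  }
  out
}

#' Generate one constrained CTP block
#'
#' A block presents the six primary items of one category `reps` times
#' each, in successive groups of six containing every primary item once
#' (random order), with no primary or secondary item ever repeated on
#' consecutive trials. Every primary item is preceded by each nontarget
#' exactly `reps/5` times and by each target exactly `reps/10` times
#' (targets appear half as often as nontargets, keeping the 1:4
#' target:nontarget ratio). Inter-stimulus intervals are drawn uniformly
#' from `isi_range` at 1 ms resolution.
#'
#' @param item_set a `cit_itemset`.
#' @param category `"forename"`, `"date"` or `"animal"`.
#' @param reps repetitions per primary item; must be divisible by 10 so
#'   the precedence quotas are integral (default 30, i.e. 180 trials).
#' @param seed optional integer seed.
#' @param isi_range two-element vector of ISI bounds in ms.
#' @param max_restarts restarts allowed for the constrained shuffle.
#' @return data.frame (class `cit_block`) with one row per trial:
#'   `trial_index`, `category`, `secondary_text`, `secondary_role`,
#'   `primary_text`, `primary_role`, `isi1_ms`, `isi2_ms`, `recall_check`.
#' @export
generate_block <- function(item_set, category, reps = 30, seed = NULL,
                           isi_range = c(1500, 1700), max_restarts = 200L) {
  stopifnot(inherits(item_set, "cit_itemset"))
  prim <- item_set$primary[item_set$primary$category == category, ]
  sec <- item_set$secondary
  if (nrow(prim) == 0L) stopf("no primary items for category '%s'", category)
  n_prim <- nrow(prim)
  n_trials <- n_prim * reps
  single <- n_prim == 1L  # degenerate block: adjacency/quota constraints vacuous
  if (!single && reps %% 10 != 0) {
    stopf("reps must be divisible by 10 for integral precedence quotas (got %d)",
          reps)
  }
  with_seed(seed, {
    # primary order: successive permutations of all items, no repeat across
    # group boundaries
    primary_idx <- integer(n_trials)
    for (g in seq_len(reps)) {
      repeat {
        perm <- sample.int(n_prim)
        if (g == 1L || n_prim == 1L ||
            perm[1L] != primary_idx[(g - 1L) * n_prim]) break
      }
      primary_idx[((g - 1L) * n_prim + 1L):(g * n_prim)] <- perm
    }
    if (single) {
      sec_idx <- rep_len(sample.int(nrow(sec)), n_trials)
    } else {
      quota <- matrix(0L, n_prim, nrow(sec))
      quota[, sec$role == "nontarget"] <- as.integer(reps / 5)
      quota[, sec$role == "target"] <- as.integer(reps / 10)
      sec_idx <- assign_secondaries(primary_idx, nrow(sec), quota,
                                    max_restarts = max_restarts)
    }
    block <- data.frame(
      trial_index = seq_len(n_trials),
      category = category,
      secondary_text = sec$text[sec_idx],
      secondary_role = sec$role[sec_idx],
      primary_text = prim$text[primary_idx],
      primary_role = prim$role[primary_idx],
      isi1_ms = round(stats::runif(n_trials, isi_range[1], isi_range[2])),
      isi2_ms = round(stats::runif(n_trials, isi_range[1], isi_range[2])),
      recall_check = FALSE,
      stringsAsFactors = FALSE
    )
    class(block) <- c("cit_block", "data.frame")
    block
  })
}

#' Validate a generated block against the sequence contract
#'
#' Checks trial count, per-group completeness, adjacency (no consecutive
#' primary or secondary repeats), the exact precedence-count matrix, the
#' 1:4 target:nontarget ratio, and the ISI bounds. Returns a report, not
#' an exception, so planted violations can be inspected.
#'
#' @param block a block data.frame from [generate_block()].
#' @param isi_range ISI bounds used at generation.
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
validate_sequence <- function(block, isi_range = c(1500, 1700)) {
  items <- unique(block$primary_text)
  n_prim <- length(items)
  reps <- nrow(block) / n_prim
  res <- list()
  add <- function(check, pass, detail = "") {
    res[[length(res) + 1L]] <<- data.frame(check = check, pass = pass,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  add("trial_count", nrow(block) == n_prim * round(reps),
      sprintf("%d trials", nrow(block)))
  counts <- table(block$primary_text)
  add("primary_counts_equal", length(unique(as.integer(counts))) == 1L,
      paste(sprintf("%s=%d", names(counts), as.integer(counts)),
            collapse = " "))
  # groups of n_prim trials each contain every primary item once
  grp <- rep(seq_len(nrow(block) %/% n_prim), each = n_prim)[seq_len(nrow(block))]
  bad_groups <- which(vapply(split(block$primary_text, grp),
                             function(x) length(unique(x)) != n_prim,
                             logical(1)))
  add("groups_complete", length(bad_groups) == 0L,
      if (length(bad_groups)) paste("groups", paste(bad_groups, collapse = ","))
      else "")
  rep_p <- which(block$primary_text[-1] == block$primary_text[-nrow(block)]) + 1L
  add("no_consecutive_primary", length(rep_p) == 0L,
      if (length(rep_p)) paste("trials", paste(rep_p, collapse = ",")) else "")
  rep_s <- which(block$secondary_text[-1] == block$secondary_text[-nrow(block)]) + 1L
  add("no_consecutive_secondary", length(rep_s) == 0L,
      if (length(rep_s)) paste("trials", paste(rep_s, collapse = ",")) else "")
  if (n_prim > 1L) {
    prec <- table(block$primary_text, block$secondary_text)
    roles <- block$secondary_role[match(colnames(prec), block$secondary_text)]
    want <- ifelse(roles == "target", reps / 10, reps / 5)
    ok <- all(sweep(prec, 2, want, `==`))
    add("precedence_counts_exact", ok,
        sprintf("expected %s per column", paste(unique(want), collapse = "/")))
    n_t <- sum(block$secondary_role == "target")
    n_nt <- sum(block$secondary_role == "nontarget")
    add("target_nontarget_ratio_1_4", n_nt == 4L * n_t,
        sprintf("%d targets, %d nontargets", n_t, n_nt))
  }
  isi <- c(block$isi1_ms, block$isi2_ms)
  add("isi_in_range", all(isi >= isi_range[1] & isi <= isi_range[2]),
      sprintf("range %.0f-%.0f", min(isi), max(isi)))
  do.call(rbind, res)
}

#' Build a full session plan (three counterbalanced blocks)
#'
#' @param item_set a `cit_itemset`.
#' @param reps repetitions per primary item per block (default 30).
#' @param block_order permutation of the three categories; by default a
#'   seeded random permutation (counterbalanced across participants by
#'   the caller).
#' @param seed optional integer seed.
#' @return object of class `cit_plan`: list with `blocks` (named list of
#'   block data.frames in presentation order), `block_order`, `group`,
#'   `item_set`, `seed`.
#' @export
build_session_plan <- function(item_set, reps = 30, block_order = NULL,
                               seed = NULL) {
  categories <- unique(item_set$primary$category)
  seeds <- derive_seeds(seed %||% 0L, length(categories) + 1L)
  if (is.null(block_order)) {
    block_order <- with_seed(if (is.null(seed)) NULL else seeds[1],
                             sample(categories))
  }
  stopifnot(setequal(block_order, categories))
  blocks <- lapply(seq_along(block_order), function(i) {
    generate_block(item_set, block_order[i], reps = reps,
                   seed = if (is.null(seed)) NULL else seeds[i + 1L])
  })
  names(blocks) <- block_order
  structure(list(blocks = blocks, block_order = block_order,
                 group = item_set$group, item_set = item_set, seed = seed),
            class = "cit_plan")
}

#' Schedule item-recall attention checks
#'
#' The task pauses at seeded-random points (`per_category` times in each
#' block) and asks the participant to identify the last presented item;
#' positions are identical for any plan sharing the seed.
#'
#' @param plan a `cit_plan`.
#' @param per_category checks per block (default 3, i.e. 9 per session).
#' @param seed optional integer seed.
#' @return the plan with `recall_check` set on the chosen trials.
#' @export
schedule_recall_checks <- function(plan, per_category = 3, seed = NULL) {
  stopifnot(inherits(plan, "cit_plan"), per_category >= 0)
  seeds <- derive_seeds(seed %||% 0L, length(plan$blocks))
  plan$blocks <- lapply(seq_along(plan$blocks), function(i) {
    b <- plan$blocks[[i]]
    if (per_category > nrow(b)) {
      stopf("per_category (%d) exceeds block length (%d)", per_category,
            nrow(b))
    }
    b$recall_check <- FALSE
    if (per_category > 0) {
      pos <- with_seed(if (is.null(seed)) NULL else seeds[i],
                       sample.int(nrow(b), per_category))
      b$recall_check[pos] <- TRUE
    }
    b
  })
  names(plan$blocks) <- plan$block_order
  plan
}

#' Flatten a session plan to a single schedule table
#'
#' @param plan a `cit_plan`.
#' @return data.frame with a `block` column prepended to the per-block
#'   trial tables; `trial_index` runs over the whole session.
#' @export
session_schedule <- function(plan) {
  out <- do.call(rbind, lapply(seq_along(plan$blocks), function(i) {
    b <- plan$blocks[[i]]
    cbind(block = i, b)
  }))
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.cit_plan <- function(x, ...) {
  cat(sprintf("CTP CIT session plan (%s group): blocks %s, %d trials, %d recall checks\n",
              x$group, paste(x$block_order, collapse = " > "),
              sum(vapply(x$blocks, nrow, integer(1))),
              sum(vapply(x$blocks, function(b) sum(b$recall_check), numeric(1)))))
  invisible(x)
}
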