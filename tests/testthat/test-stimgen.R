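test_that("candidate pools honor the initial-letter and length-matching rules", {
  animals <- word_pool("animal")
  cand <- build_candidate_pool("DOLPHIN", animals, n_candidates = 8, seed = 1)
  expect_length(cand, 8)
  expect_false("DOLPHIN" %in% cand)
  expect_false(any(startsWith(cand, "D")))

  # month exemption: same-initial items allowed for dates
  dates <- date_pool()
  cand_d <- build_candidate_pool("JUN 19", dates, n_candidates = 8,
                                 exempt_initial = TRUE, seed = 1)
  expect_length(cand_d, 8)
  expect_false("JUN 19" %in% cand_d)

  # forced selection: exactly enough eligible items -> all returned
  pool <- c("AAA", "BBBB", "CCCCC", "DDD", "EEEE", "FFFFF", "GGG", "HHHH")
  for (s in 1:3) {
    expect_setequal(build_candidate_pool("ZZZZ", pool, 8, seed = s), pool)
  }

  expect_error(build_candidate_pool("ZZZZ", pool[1:5], 8),
               "insufficient candidates")
})

test_that("candidate selection matches the exhaustive length-distance oracle", {
  pool <- c("AB", "ABC", "ABCD", "ABCDE", "BCDEF", "CDEFGH", "DEFGHIJ",
            "EFG", "FGHI", "GHIJK", "HIJKLM", "IJKLMNO", "JK", "KLM",
            "LMNOP", "MNOPQR", "NOPQRST", "OP", "PQRS", "QRSTU")
  probe <- "QUENT"  # length 5
  for (s in 1:10) {
    got <- build_candidate_pool(probe, pool, 8, seed = s)
    # oracle: eligible items ranked by |len - 5|; the selection must
    # contain every item strictly closer than the cutoff tier and fill
    # the rest from the cutoff tier
    eligible <- setdiff(pool[!startsWith(pool, "Q")], probe)
    d <- abs(nchar(eligible) - nchar(probe))
    tiers <- sort(unique(d))
    taken <- 0
    for (tier in tiers) {
      members <- eligible[d == tier]
      need <- 8 - taken
      if (length(members) <= need) {
        expect_true(all(members %in% got),
                    label = sprintf("tier %d fully included (seed %d)", tier, s))
        taken <- taken + length(members)
      } else {
        expect_equal(sum(got %in% members), need)
        taken <- 8
      }
      if (taken == 8) break
    }
    expect_length(got, 8)
  }
})

test_that("irrelevant selection avoids flagged items and is seeded", {
  cand <- sprintf("ITEM%02d", 1:8)
  flagged <- cand[c(2, 5)]
  sel <- select_irrelevants(cand, flagged, n_select = 5, seed = 9)
  expect_length(sel, 5)
  expect_true(all(sel %in% setdiff(cand, flagged)))
  expect_identical(sel, select_irrelevants(cand, flagged, 5, seed = 9))
  expect_error(select_irrelevants(cand, cand[1:3], 5), "at most two")
  expect_error(select_irrelevants(cand[1:6], cand[1:2], 5), "too few")
})

test_that("item sets contain 18 unique primary items and the 2:4 secondary set", {
  items <- make_test_itemset(seed = 3)
  expect_equal(nrow(items$primary), 18)
  expect_equal(anyDuplicated(items$primary$text), 0)
  expect_equal(as.integer(table(items$primary$role)[c("probe", "irrelevant")]),
               c(3L, 15L))
  expect_equal(sum(items$secondary$role == "target"), 2)
  expect_equal(sum(items$secondary$role == "nontarget"), 4)
  # induced group swaps number strings for inducer words
  ind <- make_test_itemset(group = "induced", seed = 3)
  expect_false(any(grepl("^[0-9]+$", ind$secondary$text)))
  expect_true(all(grepl("^[0-9]+$", items$secondary$text)))
})

test_that("generated blocks satisfy every sequence constraint across seeds", {
  items <- make_test_itemset(seed = 5)
  for (s in c(1:40)) {
    b <- generate_block(items, "animal", reps = 30, seed = s)
    v <- validate_sequence(b)
    expect_true(all(v$pass),
                label = paste("seed", s, ":",
                              paste(v$check[!v$pass], collapse = ",")))
  }
  # smaller blocks too (reps = 10 -> quotas 2 and 1)
  for (s in 1:10) {
    v <- validate_sequence(generate_block(items, "date", reps = 10, seed = s))
    expect_true(all(v$pass))
  }
})

test_that("block generation is reproducible and rejects bad reps", {
  items <- make_test_itemset(seed = 5)
  b1 <- generate_block(items, "forename", reps = 30, seed = 77)
  b2 <- generate_block(items, "forename", reps = 30, seed = 77)
  expect_identical(b1, b2)
  expect_error(generate_block(items, "forename", reps = 7, seed = 1),
               "divisible")
  expect_error(generate_block(items, "vegetable", reps = 30), "no primary")
})

test_that("a degenerate single-item block is generated without constraints", {
  items <- make_test_itemset(seed = 5)
  items$primary <- items$primary[items$primary$role == "probe" &
                                   items$primary$category == "animal", ]
  b <- generate_block(items, "animal", reps = 1, seed = 1)
  expect_equal(nrow(b), 1)
  expect_equal(b$primary_role, "probe")
})

test_that("validate_sequence reports planted violations with trial indices", {
  items <- make_test_itemset(seed = 5)
  b <- generate_block(items, "forename", reps = 30, seed = 2)
  b$primary_text[10] <- b$primary_text[9]
  v <- validate_sequence(b)
  adj <- v[v$check == "no_consecutive_primary", ]
  expect_false(adj$pass)
  expect_match(adj$detail, "10")
  expect_false(v$pass[v$check == "groups_complete"])
})

test_that("recall checks are scheduled per block, deterministically", {
  items <- make_test_itemset(seed = 5)
  plan <- build_session_plan(items, reps = 10, seed = 4)
  p3 <- schedule_recall_checks(plan, per_category = 3, seed = 8)
  expect_equal(vapply(p3$blocks, function(b) sum(b$recall_check), numeric(1)),
               c(3, 3, 3), ignore_attr = TRUE)
  expect_equal(sum(session_schedule(p3)$recall_check), 9)
  p3b <- schedule_recall_checks(plan, per_category = 3, seed = 8)
  expect_identical(p3, p3b)
  p0 <- schedule_recall_checks(plan, per_category = 0, seed = 8)
  expect_equal(sum(session_schedule(p0)$recall_check), 0)
  expect_error(schedule_recall_checks(plan, per_category = 61, seed = 1),
               "exceeds")
})

test_that("session plans counterbalance block order under caller control", {
  items <- make_test_itemset(seed = 5)
  plan <- build_session_plan(items, reps = 10,
                             block_order = c("date", "animal", "forename"),
                             seed = 4)
  expect_equal(plan$block_order, c("date", "animal", "forename"))
  expect_equal(unique(session_schedule(plan)$category[1:60]), "date")
  expect_error(build_session_plan(items, block_order = c("date", "date",
                                                         "animal")))
})
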