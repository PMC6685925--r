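#!/usr/bin/env Rscript

# Step 1: stimulus design. Build one participant's item set (probe plus
# length-matched, initial-letter-filtered foils per category), generate the
# constrained three-block CTP trial schedule with recall checks, validate
# every sequence constraint, and write the schedule.

suppressPackageStartupMessages(library(ctpcit))
dir.create("results", showWarnings = FALSE)
set.seed(1)

items <- build_item_set(
  probes = list(forename = "MICHAEL", date = format_date_item(6, 19),
                animal = "DOLPHIN"),
  group = "standard",
  flagged = list(animal = "WHALE"),  # participant marked one foil as salient
  seed = 101
)
print(items)

plan <- build_session_plan(items, reps = 30, seed = 102)
plan <- schedule_recall_checks(plan, per_category = 3, seed = 103)
print(plan)

cat("\nPer-block validation:\n")
for (b in plan$block_order) {
  v <- validate_sequence(plan$blocks[[b]])
  cat(sprintf("  %-9s %s\n", b,
              if (all(v$pass)) "all constraints satisfied"
              else paste("FAILED:", paste(v$check[!v$pass], collapse = ", "))))
}

sched <- session_schedule(plan)
write.csv(sched, "results/schedule.csv", row.names = FALSE)
cat(sprintf("\nwrote results/schedule.csv (%d trials, %d recall checks)\n",
            nrow(sched), sum(sched$recall_check)))
prec <- table(sched$primary_text[sched$category == "forename"],
              sched$secondary_text[sched$category == "forename"])
cat("forename-block precedence counts (rows: primary, cols: secondary):\n")
print(prec)
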