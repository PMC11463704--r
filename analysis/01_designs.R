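#!/usr/bin/env Rscript
# Step 1 — the four study designs.
#
# Prints each built-in design and writes a one-row-per-level summary
# table. Confirms the per-participant trial budgets (360 / 240 / 600 /
# 300 trials), the 20%-catch rule for the Experiment 1 designs, and
# the condition grids (nine speeds 3.9–35 deg/s; six opacities
# 50–100%; three speeds 19.5/27.3/35 deg/s crossed with attention
# blocks).

library(splitprev)
library(dplyr)

dir.create("results", showWarnings = FALSE)

tab <- bind_rows(lapply(c("exp1a", "exp1b", "exp2a", "exp2b"), function(id) {
  d <- builtin_design(id)
  print(d)
  cat("\n")
  mutate(d$levels, design_id = id, n_participants = d$n_participants,
         factor = d$factor_name, baseline = d$baseline_kind,
         .before = 1)
}))
readr::write_csv(tab, "results/design_levels.csv")

cat("Totals per participant:\n")
print(tab |> group_by(design_id) |>
        summarise(trials = sum(n_experimental + n_catch),
                  catch = sum(n_catch),
                  catch_fraction = catch / trials))
cat("\nWrote results/design_levels.csv\n")
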