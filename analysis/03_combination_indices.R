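#!/usr/bin/env Rscript
# Combination-index analysis: per-experiment CI at every constant-ratio
# design level (each experiment judged against its own single-agent fits),
# aggregated to mean ± SD with verbal classification, and compared with the
# generating ground-truth CI*.

suppressPackageStartupMessages({
  library(combindex)
  library(dplyr)
})

wells <- read_wells("results/synthetic_study/wells.csv")
manifest <- readr::read_csv("results/synthetic_study/manifest.csv",
                            show_col_types = FALSE)

report <- run_study(wells, out_dir = "results/study_report")

truth <- manifest |>
  filter(!is.na(agent_b)) |>
  select(arm, ci_star)

ci_anchor <- report$ci_table |>
  filter(level == 4) |>    # the 1x IC50 anchor point of the 1/8..4 series
  left_join(truth, by = "arm") |>
  mutate(true_label = classify_ci(ci_star)) |>
  select(arm, ci_mean, ci_sd, n, classification, ci_star, true_label)

readr::write_csv(ci_anchor, "results/ci_anchor_table.csv")

cat("CI at the IC50-anchored design point (mean ± SD over experiments):\n")
print(as.data.frame(ci_anchor), digits = 3)
recovered <- with(ci_anchor, abs(ci_mean - ci_star) / ci_star)
cat(sprintf("\nRelative CI recovery error by arm: %s\n",
            paste(sprintf("%s %.1f%%", ci_anchor$arm, 100 * recovered),
                  collapse = ", ")))
cat(sprintf("Classifications matching ground truth: %d of %d\n",
            sum(ci_anchor$classification == ci_anchor$true_label),
            nrow(ci_anchor)))
cat("Full per-level tables under results/study_report/\n")
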