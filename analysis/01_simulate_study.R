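#!/usr/bin/env Rscript
# Generate the synthetic combination study analysed by the downstream
# scripts: four iron chelators with literature-scale potencies, four
# clinically used cytotoxic drugs, and four constant-ratio chelator-drug
# combinations whose ground-truth interactions span the verbal CI scale from
# strong synergism to antagonism. 4 independent experiments, 4 wells per
# dose, 8 control wells, 5% multiplicative plate-reader noise.

suppressPackageStartupMessages(library(combindex))

out_dir <- "results/synthetic_study"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

panel <- c(
  example_panel(),   # DFO-, SIH-, NHAPI-, Dp44mT-like chelators
  list(
    agent_spec("5FU", 47.912, 1.3),
    agent_spec("DOX", 0.163, 1.9),
    agent_spec("TMX", 10.773, 2.1),
    agent_spec("4HC", 11.726, 1.5)
  )
)

# ground-truth interactions chosen to span the verbal scale
pairs <- list(
  list(a = "Dp44mT", b = "5FU", interaction = interaction_spec(0.162)),
  list(a = "SIH", b = "TMX", interaction = interaction_spec(0.396)),
  list(a = "NHAPI", b = "4HC", interaction = interaction_spec(1.53)),
  list(a = "DFO", b = "DOX", interaction = interaction_spec(2.06))
)

plate <- plate_config(n_experiments = 4, replicates_per_dose = 4,
                      control_wells = 8, noise_sd = 0.05, seed = 20260101)

study <- generate_study(panel, pairs, plate)
write_wells(study$wells, file.path(out_dir, "wells.csv"))
readr::write_csv(study$manifest, file.path(out_dir, "manifest.csv"))

cat(sprintf("Simulated %d wells across %d arms and %d experiments.\n",
            nrow(study$wells), nrow(study$manifest), plate$n_experiments))
cat("Ground truth (manifest):\n")
print(as.data.frame(study$manifest[, c("arm", "true_dm_a", "true_m_a",
                                       "ci_star", "metal_ratio")]))
cat(sprintf("Wells written to %s\n", file.path(out_dir, "wells.csv")))
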