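# combindex

Quantitative analysis of two-drug combinations in proliferation assays by
the Chou–Talalay median-effect method: IC50/slope estimation, combination
index (CI) computation under constant-ratio designs, Fa–CI profile
simulation, and classification of interactions on the eleven-band verbal
scale from very strong synergism to very strong antagonism.

It is written for the workflow behind published chelator–chemotherapeutic
combination studies: 96-well viability data (e.g. neutral-red uptake read as
optical density), normalised to untreated controls, with each agent and each
fixed-ratio combination tested at fractions and multiples (1/8, 1/4, 1/2, 1,
2, 4) of its IC50 across n ≥ 4 independent experiments. Because such papers
report only summary tables (IC50 ± SD, CI ± SD), the package ships a
synthetic plate-data generator with known ground truth — per-agent (Dm, m),
a constant target CI interaction mechanism, multiplicative plate-reader
noise — so every stage of the analysis can be validated against truth.

## The model

Single-agent response follows the median-effect equation

    Fa / Fu = (D / Dm)^m ,      Fu = 1 − Fa,

log-linearised and fitted by OLS (slope m, Dm = 10^(−intercept/m), plot
correlation r as diagnostic). Interactions are measured against Loewe
additivity by the two-term combination index at observed effect level Fa:

    CI = Da/Dxa + Db/Dxb ,      Dx = Dm (Fa/Fu)^(1/m),

with CI = 1 additive, < 1 synergistic, > 1 antagonistic. Fa–CI profiles
treat the fixed-ratio mixture as a single agent over total dose and evaluate
CI(Fa) on a 0.01–0.99 grid.

## Worked example

```r
library(combindex)
panel <- list(agent_spec("A", 10, 2), agent_spec("B", 25, 2))
pairs <- list(list(a = "A", b = "B", interaction = interaction_spec(0.5)))
study <- generate_study(panel, pairs, plate_config(noise_sd = 0.05, seed = 7))
report <- run_study(study)
report$ci_table[, c("arm", "level", "ci_mean", "ci_sd", "n", "classification")]
```

The study generated here holds the true CI at 0.5 (synergism); the report
recovers it at every design level from the noisy wells:

    # A tibble: 6 × 6
      arm   level ci_mean  ci_sd     n classification
      <chr> <int>   <dbl>  <dbl> <int> <chr>
    1 A+B       1   0.548 0.0726     4 synergism
    2 A+B       2   0.504 0.0262     4 synergism
    3 A+B       3   0.494 0.0111     4 synergism
    4 A+B       4   0.485 0.0259     4 synergism
    5 A+B       5   0.487 0.0465     4 synergism
    6 A+B       6   0.487 0.0686     4 synergism

`ci_mean ± ci_sd` is the mean ± sample SD over the four experiments of the
CI computed from each experiment's own single-agent fits at that design
level (level 4 is the 1× IC50 anchor point); the label is the verbal band of
the mean.

The numbered scripts under `analysis/` run a full study end to end — 8
agents (four iron chelators with literature-scale IC50s of 16.902, 14.004,
19.137 and 0.004 µM, four cytotoxic drugs) and four combinations spanning
strong synergism (CI\* = 0.162) to antagonism (CI\* = 2.06):

```sh
Rscript analysis/01_simulate_study.R     # wells + ground-truth manifest
Rscript analysis/02_single_agent_potency.R
Rscript analysis/03_combination_indices.R
Rscript analysis/04_fa_ci_profiles.R
```

With the default seed the analysis recovers all eight IC50s with a mean
absolute error of 1.9%, all four CI values within 2–9%, and all four verbal
classifications correctly; tables and Fa–CI plots land under `results/`.

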