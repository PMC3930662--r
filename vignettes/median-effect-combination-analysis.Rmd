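---
title: "Median-effect dose-response analysis and combination-index synergy quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-effect dose-response analysis and combination-index synergy quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combindex)
```

## The model

combindex quantifies drug-combination effects in proliferation assays with
the Chou-Talalay median-effect method. A single agent's dose-response is
summarised by the median-effect equation

$$\frac{F_a}{F_u} = \left(\frac{D}{D_m}\right)^m,$$

where $F_a$ is the fraction of the maximal effect achieved at dose $D$
(here, fractional inhibition of proliferation relative to untreated
control), $F_u = 1 - F_a$, $D_m$ is the median-effect dose (the IC50) and
$m$ the slope. Taking log10 of both sides linearises the curve — the
median-effect plot — and the package fits it by unweighted ordinary least
squares: the slope is $m$, and $D_m = 10^{-b/m}$ from the intercept $b$. The
plot's linear correlation coefficient $r$ is carried as the fit diagnostic.

Two-drug interactions are judged against Loewe additivity through the
two-term combination index at an observed effect level $F_a$:

$$CI = \frac{D_a}{D_{xa}} + \frac{D_b}{D_{xb}},$$

where $(D_a, D_b)$ are the doses given together and $(D_{xa}, D_{xb})$ the
iso-effective single-agent doses producing the same $F_a$, obtained by
inverting each agent's fitted model ($D_x = D_m (F_a/F_u)^{1/m}$). $CI = 1$
is additivity (a drug is exactly additive with itself), $CI < 1$ synergism,
$CI > 1$ antagonism. The model assumes a monotone, saturating response with
a single phase; multi-phasic or non-monotone responses are out of scope.

Combinations follow the constant-ratio design: the two drugs are mixed at
the ratio of their IC50s and the mixture tested at fractions and multiples
(1/8, 1/4, 1/2, 1, 2, 4) of that anchor, so the dose split of the total is
fixed at $\rho_a = \mathrm{IC50}_a / (\mathrm{IC50}_a + \mathrm{IC50}_b)$.
For Fa-CI profiles the mixture is treated as a single agent over total dose,
fitted with the same model, and the CI evaluated on an $F_a$ grid:
$CI(F_a) = \rho_a D / D_{xa} + \rho_b D / D_{xb}$ with
$D = D_{x,\mathrm{mix}}(F_a)$.

## Parameters that matter

* `fa_window` (default 0.01, dimensionless): observations with
  $F_a \le 0.01$ or $\ge 0.99$ are excluded from the regression — the
  log-odds diverges at the boundaries and a single near-boundary point can
  dominate the unweighted fit. Excluded points are reported, never silently
  dropped. How boundary effects (complete kill at 4× IC50) should enter the
  fit is genuinely underdetermined; exclusion with logging is the least
  surprising choice.
* `min_points` (3): the minimum retained observations for a two-parameter
  line with one residual degree of freedom.
* `r_warn` (0.90): fits with $r$ below this are flagged with a warning but
  returned; there is no principled rejection threshold, and dropping
  experiments silently would bias the aggregate.
* `multipliers` (1/8 ... 4 × IC50): the dose series of both single-agent
  and combination arms.
* `fa_grid` (0.01 to 0.99, step 0.01): the profile grid; the extremes are
  extrapolations of both fits and should be read accordingly.
* `noise_sd` (0.05): multiplicative Gaussian SD on well signal in the
  generator, a typical plate-reader coefficient of variation.

All concentrations are in µM throughout.

## The synthetic study generator

No raw per-well data accompany the published potency and CI tables this
package's report format mirrors, so the generator stands in for them with
known truth. It emulates a 72-h proliferation assay read as optical density
on 96-well plates: per well, raw signal is
`baseline × Fu(dose) × (1 + e)` with `e ~ Normal(0, noise_sd)` truncated so
signal stays non-negative; untreated control wells sit at dose 0; viability
is normalised per experiment against the mean control signal, exactly as the
analysis side expects. Defaults follow the study conditions the report
tables assume: 4 independent experiments, 4 replicate wells per dose, 8
control wells, 5% multiplicative noise, the 1/8 ... 4 dose series. The
example panel carries literature-scale chelator potencies (IC50s 16.902,
14.004, 19.137 and 0.004 µM); slopes are unpublished quantities and the
defaults ($m \in [1, 3]$) are assumptions typical of such assays, not
literature values.

The interaction ground truth holds CI constant at a target `ci_star`: at
each design level the combination's $F_a$ is the unique root in (0, 1) of
$\rho_a D / D_{xa}(F_a) + \rho_b D / D_{xb}(F_a) = CI^*$ (the left side is
strictly decreasing, diverges as $F_a \to 0$ and vanishes as $F_a \to 1$),
found by bisection to $10^{-12}$. A constant CI makes the whole pipeline
exactly invertible — noise-free analysis must return `ci_star` to numerical
precision — and spans the full verbal scale. A dose-varying interaction can
be injected via `interaction_spec(ci_star_fn = ...)`. Optional log-normal
jitter on per-experiment Dm (`dm_jitter_sd`) emulates inter-experiment
biological spread; it is off by default because published between-experiment
SDs conflate biological and fit variance and no decomposition is attempted.

What the generator does not emulate: plate-position effects, edge
evaporation, correlated well noise, cytostatic-vs-cytotoxic distinctions,
or any pharmacokinetics. Passing tests therefore demonstrate correctness of
the computations under the stated statistical model, not robustness to every
artefact of real plates.

## Numerical choices

* Log base 10 throughout; Dm recovery is base-invariant but fixing the base
  makes intermediates reproducible.
* Unweighted OLS on the transformed plot: the classical median-effect
  workflow. Commercial implementations may weight or iterate; that detail is
  undocumented, and OLS is the transparent default.
* Exact-median-effect mixtures: when the two agents share a slope, the
  constant-CI mixture curve is itself median-effect
  ($D_{m,\mathrm{mix}} = CI^* / (\rho_a/D_{m,a} + \rho_b/D_{m,b})$, same
  $m$) and Fa-CI profiles recover `ci_star` to $10^{-6}$. With unequal
  slopes the true mixture curve is not median-effect; its OLS fit is an
  approximation and profiles bend at the grid extremes. CI values at
  measured design points are unaffected — they use observed $F_a$ directly.
* Per-experiment CI (the report-table quantity) uses each experiment's own
  single-agent fits and the replicate-averaged observed $F_a$ at the doses
  actually administered, then aggregates mean ± sample SD (n − 1) across
  experiments.
* Fa-CI profiles use pooled models — per-experiment fits averaged on the
  parameter scale (mean of $\log D_m$, mean of $m$) — because the
  study-level profile is one mean curve over experiments; averaging
  per-experiment curves pointwise is the plausible alternative and differs
  only at second order in the between-experiment spread.
* Classification boundaries: the classical printed bands overlap at 0.90
  and 1.45 and abut at 1.1/1.2. The adopted convention closes each interval
  on the side nearer 1 and opens it away from 1, giving an exact partition
  of $(0, \infty)$; e.g. CI = 0.90 is "nearly additive", 1.45 "moderate
  antagonism". This is a convention, not a claim about any other software's
  tie-breaking, and the scale table is replaceable via the `scale` argument.
* Replicates are averaged to one $F_a$ per dose per experiment before
  fitting (plate-reader workflow); fitting all wells is a trivial variant
  the data layout supports.

## Worked example

```{r example}
panel <- list(agent_spec("A", 10, 2), agent_spec("B", 25, 2))
pairs <- list(list(a = "A", b = "B", interaction = interaction_spec(0.5)))
study <- generate_study(panel, pairs,
                        plate_config(noise_sd = 0.05, seed = 7))
report <- run_study(study)
report$ic50_table
report$ci_table[, c("arm", "level", "ci_mean", "ci_sd", "n", "classification")]
```

```{r plot, fig.width = 5, fig.height = 4}
plot_fa_ci(report$fa_ci[["A+B"]], title = "A + B, constant CI* = 0.5")
```

## Problem sizes and limitations

The shipped analysis scripts and tests run studies of up to 12 arms × 4
experiments × 4 replicate wells (about 1,500 wells), which a laptop core
analyses in seconds; the same code scales linearly in wells. Known
limitations: the two-term (mutually exclusive) CI only — no third
interaction term, no Bliss/HSA/ZIP response-surface alternatives, no
dose-reduction index, no checkerboard (non-constant-ratio) designs, and no
three-drug combinations. CI estimates inherit the instability of the
median-effect fit near boundary effect levels; treat profile values outside
roughly $F_a \in [0.2, 0.8]$ as extrapolation.
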