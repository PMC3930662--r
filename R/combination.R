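#' Constant-ratio combination design
#'
#' In the constant-ratio design the two agents are mixed so that their dose
#' ratio equals the ratio of their single-agent IC50s, and the mixture is
#' tested at fractions and multiples of that anchor (default 1/8, 1/4, 1/2,
#' 1, 2 and 4). At every level the dose split of the total is therefore
#' `rho_a = ic50_a / (ic50_a + ic50_b)` for agent a and `rho_b = 1 - rho_a`
#' for agent b.
#'
#' @param agent_a,agent_b Labels.
#' @param ic50_a,ic50_b Anchoring IC50s (> 0, same units).
#' @param multipliers Ordered IC50 fractions/multiples tested.
#' @return An object of class `constant_ratio_design` with the anchor IC50s,
#'   multipliers, dose fractions `rho_a`/`rho_b` and a `levels` tibble
#'   (multiplier, dose_a, dose_b, total).
#' @examples
#' constant_ratio_design("A", "B", 10, 20)
#' @export
constant_ratio_design <- function(agent_a, agent_b, ic50_a, ic50_b,
                                  multipliers = c(1/8, 1/4, 1/2, 1, 2, 4)) {
  stopifnot(is.finite(ic50_a), is.finite(ic50_b), ic50_a > 0, ic50_b > 0,
            all(is.finite(multipliers)), all(multipliers > 0))
  rho_a <- ic50_a / (ic50_a + ic50_b)
  levels <- tibble::tibble(
    multiplier = sort(multipliers),
    dose_a = sort(multipliers) * ic50_a,
    dose_b = sort(multipliers) * ic50_b,
    total = sort(multipliers) * (ic50_a + ic50_b)
  )
  structure(
    list(agent_a = agent_a, agent_b = agent_b,
         ic50_a = ic50_a, ic50_b = ic50_b,
         rho_a = rho_a, rho_b = 1 - rho_a,
         multipliers = sort(multipliers), levels = levels),
    class = "constant_ratio_design"
  )
}

#' @export
print.constant_ratio_design <- function(x, ...) {
  cat(sprintf("Constant-ratio design %s + %s (ratio %.4g : %.4g, rho_a = %.4f)\n",
              x$agent_a, x$agent_b, x$ic50_a, x$ic50_b, x$rho_a))
  print(x$levels)
  invisible(x)
}

#' Combination index of one combination measurement
#'
#' The two-term combination index at observed effect level `fa` is
#' \deqn{CI = \frac{D_a}{D_{xa}} + \frac{D_b}{D_{xb}}}
#' where `(Da, Db)` are the doses given together and `(Dxa, Dxb)` the
#' iso-effective single-agent doses producing that same `fa`, obtained by
#' inverting each agent's median-effect model. `CI = 1` is Loewe additivity;
#' `CI < 1` synergism; `CI > 1` antagonism.
#'
#' @param dose_a,dose_b Doses administered together (> 0).
#' @param fa Observed fraction affected of the combination, strictly in
#'   (0, 1) — at 0 or 1 the iso-effective doses vanish/diverge and CI is
#'   undefined.
#' @param model_a,model_b Median-effect fits (or `list(dm=, m=)`) of the two
#'   single agents.
#' @return A one-row tibble: `ci`, `fa`, `dose_a`, `dose_b`, `dxa`, `dxb`.
#' @examples
#' combination_index(5, 10, 0.5, list(dm = 10, m = 1), list(dm = 20, m = 1))
#' @export
combination_index <- function(dose_a, dose_b, fa, model_a, model_b) {
  stopifnot(length(fa) == 1, length(dose_a) == 1, length(dose_b) == 1)
  if (!is.finite(dose_a) || !is.finite(dose_b) || dose_a <= 0 || dose_b <= 0) {
    stop("combination doses must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(fa) || fa <= 0 || fa >= 1) {
    stop("CI undefined: `fa` must be strictly inside (0, 1)", call. = FALSE)
  }
  dxa <- dose_for_fa(model_a, fa)
  dxb <- dose_for_fa(model_b, fa)
  tibble::tibble(
    ci = dose_a / dxa + dose_b / dxb,
    fa = fa, dose_a = dose_a, dose_b = dose_b, dxa = dxa, dxb = dxb
  )
}

#' Fit the median-effect model to a constant-ratio mixture
#'
#' A fixed-ratio mixture is treated as a single agent over its total dose
#' (`dose_a + dose_b`), giving a mixture `(Dm, m)` used to index Fa-CI
#' profiles by effect level.
#'
#' @param design A `constant_ratio_design` (carried on the result).
#' @param total_dose Total doses on the constant ratio.
#' @param fa Observed fractions affected of the mixture.
#' @inheritParams fit_median_effect
#' @return A `median_effect_fit` whose `agent_id` names the mixture.
#' @export
fit_mixture <- function(design, total_dose, fa, fa_window = 0.01,
                        min_points = 3, r_warn = 0.90,
                        experiment_id = NA_character_) {
  stopifnot(inherits(design, "constant_ratio_design"))
  fit <- fit_median_effect(
    total_dose, fa, fa_window = fa_window, min_points = min_points,
    r_warn = r_warn,
    agent_id = paste0(design$agent_a, "+", design$agent_b),
    experiment_id = experiment_id
  )
  fit$design <- design
  fit
}

#' Fa-CI profile of a constant-ratio combination
#'
#' For each effect level `fa` on the grid, the total mixture dose producing
#' that effect is read off the mixture fit, split into component doses by the
#' design's fixed fractions (`dose_a = rho_a * D`, `dose_b = rho_b * D`), and
#' the combination index evaluated against the single-agent models:
#' `ci(fa) = rho_a*D/Dxa(fa) + rho_b*D/Dxb(fa)`. The resulting Fa-CI curve
#' shows how the interaction changes with effect level (dose).
#'
#' @param model_a,model_b Single-agent median-effect fits.
#' @param mixture Median-effect fit of the mixture over total dose.
#' @param design The `constant_ratio_design`.
#' @param fa_grid Effect levels in (0, 1); default 0.01 to 0.99 step 0.01.
#' @return A tibble of class `fa_ci_profile`: `fa`, `ci`, `total_dose`,
#'   `dose_a`, `dose_b`.
#' @export
fa_ci_curve <- function(model_a, model_b, mixture, design,
                        fa_grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(inherits(design, "constant_ratio_design"))
  if (any(fa_grid <= 0) || any(fa_grid >= 1)) {
    stop("`fa_grid` must lie strictly inside (0, 1)", call. = FALSE)
  }
  check_model(model_a); check_model(model_b); check_model(mixture)
  total <- dose_for_fa(mixture, fa_grid)
  dose_a <- design$rho_a * total
  dose_b <- design$rho_b * total
  ci <- dose_a / dose_for_fa(model_a, fa_grid) +
    dose_b / dose_for_fa(model_b, fa_grid)
  out <- tibble::tibble(fa = fa_grid, ci = ci, total_dose = total,
                        dose_a = dose_a, dose_b = dose_b)
  class(out) <- c("fa_ci_profile", class(out))
  out
}

#' Per-experiment combination index at one design level
#'
#' Computes the combination index at one multiplier of the anchored IC50s,
#' separately for each experiment, using that experiment's own single-agent
#' fits and the combination's observed mean `fa` at that level. Experiments
#' whose single-agent fit failed (passed as `NULL`) or whose observed `fa`
#' lies on the boundary are excluded and reported in the `flag` column.
#'
#' @param design A `constant_ratio_design`.
#' @param multiplier The design level (e.g. 1 for the IC50-anchored point).
#' @param fits_a,fits_b Named lists of per-experiment `median_effect_fit`s
#'   (`NULL` for a failed fit); names are experiment ids.
#' @param fa_observed Named numeric vector: the combination's observed
#'   fraction affected at this level, one per experiment.
#' @return A tibble with one row per experiment: `experiment_id`, `ci` (`NA`
#'   if excluded), `fa`, `dose_a`, `dose_b`, `dxa`, `dxb`, `flag`.
#' @export
ci_at_design_point <- function(design, multiplier, fits_a, fits_b,
                               fa_observed) {
  stopifnot(inherits(design, "constant_ratio_design"), length(multiplier) == 1)
  exps <- names(fa_observed)
  if (is.null(exps)) stop("`fa_observed` must be named by experiment", call. = FALSE)
  dose_a <- multiplier * design$ic50_a
  dose_b <- multiplier * design$ic50_b
  rows <- lapply(exps, function(e) {
    fa <- unname(fa_observed[[e]])
    flag <- NA_character_
    if (is.null(fits_a[[e]]) || is.null(fits_b[[e]])) {
      flag <- "missing single-agent fit"
    } else if (!is.finite(fa) || fa <= 0 || fa >= 1) {
      flag <- "combination fa on boundary; CI undefined"
    }
    if (!is.na(flag)) {
      return(tibble::tibble(experiment_id = e, ci = NA_real_, fa = fa,
                            dose_a = dose_a, dose_b = dose_b,
                            dxa = NA_real_, dxb = NA_real_, flag = flag))
    }
    res <- combination_index(dose_a, dose_b, fa, fits_a[[e]], fits_b[[e]])
    tibble::tibble(experiment_id = e, ci = res$ci, fa = fa,
                   dose_a = dose_a, dose_b = dose_b,
                   dxa = res$dxa, dxb = res$dxb, flag = NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' Mean, sample SD and n across experiments
#'
#' The study-level summary used for the IC50 and CI report tables:
#' arithmetic mean, sample standard deviation (n - 1 denominator) and the
#' number of valid values. With a single value the SD is undefined and
#' returned as `NA` with a flag.
#'
#' @param x Numeric values, one per experiment; `NA`s are dropped (counted in
#'   `n_excluded`).
#' @return A one-row tibble: `mean`, `sd`, `n`, `n_excluded`, `flag`.
#' @examples
#' aggregate_experiments(c(2, 4, 4, 4, 5, 5, 7, 9))
#' @export
aggregate_experiments <- function(x) {
  ok <- x[is.finite(x)]
  if (length(ok) == 0) stop("no valid values to aggregate", call. = FALSE)
  tibble::tibble(
    mean = mean(ok),
    sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
    n = length(ok),
    n_excluded = length(x) - length(ok),
    flag = if (length(ok) == 1) "single value; SD undefined" else NA_character_
  )
}

#' Dose series at fractions and multiples of an IC50
#'
#' @param ic50 Anchor concentration (> 0).
#' @param multipliers Fractions/multiples (default 1/8, 1/4, 1/2, 1, 2, 4).
#' @return Ascending numeric vector `multipliers * ic50`.
#' @examples
#' design_dose_series(16)
#' @export
design_dose_series <- function(ic50, multipliers = c(1/8, 1/4, 1/2, 1, 2, 4)) {
  if (!is.numeric(ic50) || length(ic50) != 1 || !is.finite(ic50) || ic50 <= 0) {
    stop("`ic50` must be a single positive number", call. = FALSE)
  }
  stopifnot(all(is.finite(multipliers)), all(multipliers > 0))
  sort(multipliers) * ic50
}

#' Chelator-to-metal molar ratio for a metal-binding equivalent of 1
#'
#' One metal-binding equivalent means enough ligand to fully coordinate the
#' metal ion: one hexadentate ligand (DFO-like) or two tridentate ligands
#' (SIH-, NHAPI- or Dp44mT-like) per ion, i.e. molar ratios 1:1 and 2:1.
#'
#' @param denticity_class `"hexadentate"` or `"tridentate"`.
#' @return A list with `chelator` and `metal` integer parts and a `label`
#'   like `"2:1"`.
#' @export
metal_complex_ratio <- function(denticity_class) {
  switch(match.arg(denticity_class, c("hexadentate", "tridentate")),
    hexadentate = list(chelator = 1L, metal = 1L, label = "1:1"),
    tridentate = list(chelator = 2L, metal = 1L, label = "2:1")
  )
}
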