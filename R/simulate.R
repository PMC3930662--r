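#' Ground-truth agent specification
#'
#' @param agent_id Label.
#' @param true_dm True median-effect dose (µM, > 0).
#' @param true_m True median-effect slope (> 0).
#' @param denticity_class `"hexadentate"`, `"tridentate"` or `"none"`; used
#'   only to label chelator arms with their metal-complex ratio.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(agent_id, true_dm, true_m,
                       denticity_class = c("none", "hexadentate", "tridentate")) {
  stopifnot(is.character(agent_id), length(agent_id) == 1,
            is.finite(true_dm), true_dm > 0, is.finite(true_m), true_m > 0)
  structure(
    list(agent_id = agent_id, true_dm = true_dm, true_m = true_m,
         denticity_class = match.arg(denticity_class)),
    class = "agent_spec"
  )
}

#' Ground-truth interaction specification
#'
#' The generator's interaction mechanism holds the combination index constant
#' at `ci_star` across the whole dose range: at each design level the
#' combination's fraction affected is chosen so that the two-term CI against
#' the agents' true curves equals `ci_star` exactly. A constant ground truth
#' makes CI exactly recoverable and spans the full verbal scale; a
#' dose-varying interaction can be emulated by supplying `ci_star_fn`, a
#' function of `fa` returning the local target CI.
#'
#' @param ci_star Target constant combination index (> 0). 1 is Loewe
#'   additivity, < 1 synergism, > 1 antagonism.
#' @param ci_star_fn Optional function `fa -> ci`; overrides `ci_star` as a
#'   dose-varying target (evaluated pointwise inside the root solve).
#' @return An object of class `interaction_spec`.
#' @export
interaction_spec <- function(ci_star = 1, ci_star_fn = NULL) {
  stopifnot(is.finite(ci_star), ci_star > 0)
  if (!is.null(ci_star_fn)) stopifnot(is.function(ci_star_fn))
  structure(list(ci_star = ci_star, ci_star_fn = ci_star_fn),
            class = "interaction_spec")
}

#' Plate and replication configuration for the synthetic study
#'
#' Emulates a 72-h proliferation assay on 96-well plates read as optical
#' density: each well's raw signal is `baseline * fu(dose) * (1 + e)` with
#' `e ~ Normal(0, noise_sd)` (multiplicative plate-reader noise, truncated so
#' signal stays non-negative), untreated control wells at dose 0, and
#' `n_experiments` independent experiments.
#'
#' @param n_experiments Independent experiments (default 4).
#' @param replicates_per_dose Wells per dose per experiment (default 4).
#' @param control_wells Untreated wells per experiment (default 8).
#' @param noise_sd Multiplicative Gaussian SD on well signal (default 0.05;
#'   0 gives noise-free data).
#' @param baseline Mean raw control signal in arbitrary OD units (default 1).
#' @param multipliers IC50 fractions/multiples tested (default 1/8 ... 4).
#' @param dm_jitter_sd Optional log-normal SD of per-experiment jitter on
#'   each agent's true Dm (default 0 = off), emulating inter-experiment
#'   biological variability.
#' @param seed Integer seed fixing the whole generated stream.
#' @return An object of class `plate_config`.
#' @export
plate_config <- function(n_experiments = 4, replicates_per_dose = 4,
                         control_wells = 8, noise_sd = 0.05, baseline = 1,
                         multipliers = c(1/8, 1/4, 1/2, 1, 2, 4),
                         dm_jitter_sd = 0, seed = 1L) {
  stopifnot(n_experiments >= 1, replicates_per_dose >= 1, control_wells >= 1,
            noise_sd >= 0, baseline > 0, all(multipliers > 0), dm_jitter_sd >= 0)
  structure(
    list(n_experiments = as.integer(n_experiments),
         replicates_per_dose = as.integer(replicates_per_dose),
         control_wells = as.integer(control_wells),
         noise_sd = noise_sd, baseline = baseline,
         multipliers = sort(multipliers),
         dm_jitter_sd = dm_jitter_sd, seed = as.integer(seed)),
    class = "plate_config"
  )
}

#' Solve the combination's fraction affected for a target CI
#'
#' Inverts the CI equation as a generative mechanism: given a total dose `D`
#' split into `rho_a * D` and `rho_b * D`, finds the unique `fa` in (0, 1)
#' with
#' `rho_a*D / Dxa(fa) + rho_b*D / Dxb(fa) = ci_star`.
#' The left side is strictly decreasing in `fa` (iso-effective doses grow
#' with effect), diverging as `fa -> 0` and vanishing as `fa -> 1`, so a
#' unique root always exists; it is found by bisection ([stats::uniroot()])
#' on a bracket that is widened toward the boundaries if needed. Roots pushed
#' against the numerical boundary are clamped and flagged.
#'
#' @param total_dose Total dose of the mixture (> 0).
#' @param rho_a,rho_b Dose fractions (sum to 1).
#' @param model_a,model_b True single-agent models (`list(dm=, m=)`).
#' @param ci_star Target CI, or a function of `fa` for a dose-varying target.
#' @param tol Convergence tolerance on `fa` (default 1e-12).
#' @return A one-row tibble: `fa`, `clamped` (logical).
#' @export
solve_combination_fa <- function(total_dose, rho_a, rho_b, model_a, model_b,
                                 ci_star, tol = 1e-12) {
  stopifnot(total_dose > 0, abs(rho_a + rho_b - 1) < 1e-12,
            rho_a > 0, rho_b > 0)
  target <- if (is.function(ci_star)) ci_star else function(fa) ci_star
  f <- function(fa) {
    rho_a * total_dose / dose_for_fa(model_a, fa) +
      rho_b * total_dose / dose_for_fa(model_b, fa) - target(fa)
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo < 0 || fhi > 0) {
    # dose outside the achievable range at machine precision: clamp
    fa <- if (is.finite(flo) && flo < 0) lo else hi
    return(tibble::tibble(fa = fa, clamped = TRUE))
  }
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = tol)$root
  tibble::tibble(fa = root, clamped = FALSE)
}

new_well_records <- function(experiment_id, agent_a, dose_a, agent_b, dose_b,
                             replicate, signal, is_control) {
  tibble::tibble(
    experiment_id = experiment_id, agent_a = agent_a, dose_a = dose_a,
    agent_b = agent_b, dose_b = dose_b, replicate = as.integer(replicate),
    signal = signal, is_control = is_control
  )
}

# per-experiment Dm used when log-normal jitter is on
experiment_dm <- function(spec, plate) {
  if (plate$dm_jitter_sd == 0) return(rep(spec$true_dm, plate$n_experiments))
  spec$true_dm * exp(stats::rnorm(plate$n_experiments, 0, plate$dm_jitter_sd))
}

apply_noise <- function(expected, noise_sd) {
  if (noise_sd == 0) return(expected)
  pmax(expected * (1 + stats::rnorm(length(expected), 0, noise_sd)), 0)
}

#' Simulate one single-agent proliferation arm
#'
#' Generates long-format well records for one agent across all experiments:
#' a dose series at the configured IC50 fractions/multiples of the agent's
#' true Dm, `replicates_per_dose` wells per dose, plus untreated control
#' wells, with raw signal `baseline * fu(dose) * (1 + e)`. The output is
#' deterministic for a fixed `plate$seed`.
#'
#' @param spec An [agent_spec()].
#' @param plate A [plate_config()].
#' @param .seed_offset Internal offset so each arm of a study draws an
#'   independent, reproducible stream.
#' @return A tibble of well records (`experiment_id`, `agent_a`, `dose_a`,
#'   `agent_b`, `dose_b`, `replicate`, `signal`, `is_control`).
#' @export
simulate_single_agent <- function(spec, plate, .seed_offset = 0L) {
  stopifnot(inherits(spec, "agent_spec"), inherits(plate, "plate_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(plate$seed + .seed_offset)
  dms <- experiment_dm(spec, plate)
  rows <- lapply(seq_len(plate$n_experiments), function(i) {
    exp_id <- sprintf("exp%02d", i)
    doses <- design_dose_series(dms[i], plate$multipliers)
    treated <- new_well_records(
      experiment_id = exp_id,
      agent_a = spec$agent_id,
      dose_a = rep(doses, each = plate$replicates_per_dose),
      agent_b = NA_character_, dose_b = 0,
      replicate = rep(seq_len(plate$replicates_per_dose), times = length(doses)),
      signal = NA_real_, is_control = FALSE
    )
    treated$signal <- apply_noise(
      plate$baseline * (1 - predict_fa_true(treated$dose_a, dms[i], spec$true_m)),
      plate$noise_sd
    )
    controls <- new_well_records(
      experiment_id = exp_id, agent_a = spec$agent_id, dose_a = 0,
      agent_b = NA_character_, dose_b = 0,
      replicate = seq_len(plate$control_wells),
      signal = apply_noise(rep(plate$baseline, plate$control_wells),
                           plate$noise_sd),
      is_control = TRUE
    )
    dplyr::bind_rows(controls, treated)
  })
  dplyr::bind_rows(rows)
}

#' Simulate one constant-ratio combination arm
#'
#' Builds the constant-ratio design from the agents' true Dm values, and at
#' each design level solves the CI equation for the fraction affected that
#' makes the combination index exactly `ci_star` against the true
#' single-agent curves ([solve_combination_fa()]); multiplicative well noise
#' is then applied as in [simulate_single_agent()]. Levels whose root is
#' pushed to the numerical boundary are emitted clamped and flagged in the
#' `clamped` column.
#'
#' @param spec_a,spec_b [agent_spec()]s of the two agents.
#' @param interaction An [interaction_spec()].
#' @param plate A [plate_config()].
#' @param .seed_offset Internal stream offset (see [simulate_single_agent()]).
#' @return A tibble of well records with an extra `clamped` column.
#' @export
simulate_combination <- function(spec_a, spec_b, interaction, plate,
                                 .seed_offset = 0L) {
  stopifnot(inherits(spec_a, "agent_spec"), inherits(spec_b, "agent_spec"),
            inherits(interaction, "interaction_spec"),
            inherits(plate, "plate_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(plate$seed + .seed_offset)
  target <- if (!is.null(interaction$ci_star_fn)) interaction$ci_star_fn
            else interaction$ci_star
  dms_a <- experiment_dm(spec_a, plate)
  dms_b <- experiment_dm(spec_b, plate)
  rows <- lapply(seq_len(plate$n_experiments), function(i) {
    exp_id <- sprintf("exp%02d", i)
    design <- constant_ratio_design(spec_a$agent_id, spec_b$agent_id,
                                    dms_a[i], dms_b[i], plate$multipliers)
    model_a <- list(dm = dms_a[i], m = spec_a$true_m)
    model_b <- list(dm = dms_b[i], m = spec_b$true_m)
    lv <- design$levels
    sol <- dplyr::bind_rows(lapply(lv$total, function(D) {
      solve_combination_fa(D, design$rho_a, design$rho_b,
                           model_a, model_b, target)
    }))
    nrep <- plate$replicates_per_dose
    treated <- new_well_records(
      experiment_id = exp_id,
      agent_a = spec_a$agent_id,
      dose_a = rep(lv$dose_a, each = nrep),
      agent_b = spec_b$agent_id,
      dose_b = rep(lv$dose_b, each = nrep),
      replicate = rep(seq_len(nrep), times = nrow(lv)),
      signal = NA_real_, is_control = FALSE
    )
    treated$signal <- apply_noise(
      plate$baseline * rep(1 - sol$fa, each = nrep), plate$noise_sd
    )
    treated$clamped <- rep(sol$clamped, each = nrep)
    controls <- new_well_records(
      experiment_id = exp_id, agent_a = spec_a$agent_id, dose_a = 0,
      agent_b = spec_b$agent_id, dose_b = 0,
      replicate = seq_len(plate$control_wells),
      signal = apply_noise(rep(plate$baseline, plate$control_wells),
                           plate$noise_sd),
      is_control = TRUE
    )
    controls$clamped <- FALSE
    dplyr::bind_rows(controls, treated)
  })
  dplyr::bind_rows(rows)
}

#' Generate a complete synthetic combination study
#'
#' One single-agent arm per panel member plus one constant-ratio combination
#' arm per requested pair, across all experiments, together with a manifest
#' of the generating ground truth for parameter-recovery checks. Each arm
#' draws from its own reproducible sub-stream of `plate$seed`, so the whole
#' study is deterministic for a fixed config.
#'
#' @param panel List of [agent_spec()]s (unique ids).
#' @param pairs List of `list(a = <id>, b = <id>, interaction =
#'   interaction_spec(...))` entries.
#' @param plate A [plate_config()].
#' @return A list of class `synthetic_study`: `wells` (one long tibble, all
#'   arms), `manifest` (tibble of ground-truth parameters per arm), `panel`,
#'   `pairs`, `plate`.
#' @export
generate_study <- function(panel, pairs = list(), plate = plate_config()) {
  ids <- vapply(panel, function(s) s$agent_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate agent ids in panel", call. = FALSE)
  for (p in pairs) {
    if (!all(c(p$a, p$b) %in% ids)) {
      stop(sprintf("pair %s+%s references agents missing from the panel",
                   p$a, p$b), call. = FALSE)
    }
  }
  single <- lapply(seq_along(panel), function(k) {
    simulate_single_agent(panel[[k]], plate, .seed_offset = 1000L * k)
  })
  combos <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    sa <- panel[[match(p$a, ids)]]
    sb <- panel[[match(p$b, ids)]]
    simulate_combination(sa, sb, p$interaction, plate,
                         .seed_offset = 100000L + 1000L * k)
  })
  wells <- dplyr::bind_rows(c(single, combos))
  manifest <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(panel, function(s) tibble::tibble(
      arm = s$agent_id, agent_a = s$agent_id, agent_b = NA_character_,
      true_dm_a = s$true_dm, true_m_a = s$true_m,
      true_dm_b = NA_real_, true_m_b = NA_real_, ci_star = NA_real_,
      denticity_class = s$denticity_class,
      metal_ratio = if (s$denticity_class == "none") NA_character_
                    else metal_complex_ratio(s$denticity_class)$label
    ))),
    dplyr::bind_rows(lapply(pairs, function(p) {
      sa <- panel[[match(p$a, ids)]]; sb <- panel[[match(p$b, ids)]]
      tibble::tibble(
        arm = paste0(p$a, "+", p$b), agent_a = p$a, agent_b = p$b,
        true_dm_a = sa$true_dm, true_m_a = sa$true_m,
        true_dm_b = sb$true_dm, true_m_b = sb$true_m,
        ci_star = p$interaction$ci_star,
        denticity_class = NA_character_, metal_ratio = NA_character_
      )
    }))
  )
  manifest$seed <- plate$seed
  structure(list(wells = wells, manifest = manifest, panel = panel,
                 pairs = pairs, plate = plate),
            class = "synthetic_study")
}

#' Example chelator panel with literature-scale potencies
#'
#' Four iron chelators spanning the potency range seen in 72-h MCF-7
#' proliferation assays: DFO-like (IC50 ~ 16.9 µM, hexadentate), SIH-like
#' (~ 14.0 µM, tridentate), NHAPI-like (~ 19.1 µM, tridentate) and a
#' Dp44mT-like thiosemicarbazone (~ 0.004 µM, tridentate). Slopes are
#' plausible assay values, not literature constants.
#'
#' @return A list of [agent_spec()]s.
#' @export
example_panel <- function() {
  list(
    agent_spec("DFO", 16.902, 1.6, "hexadentate"),
    agent_spec("SIH", 14.004, 1.8, "tridentate"),
    agent_spec("NHAPI", 19.137, 1.4, "tridentate"),
    agent_spec("Dp44mT", 0.004, 2.2, "tridentate")
  )
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
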