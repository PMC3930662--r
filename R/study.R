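#' Run the full combination-study analysis
#'
#' End-to-end pipeline over long-format well data (measured or synthetic):
#' control normalisation, replicate averaging, per-experiment median-effect
#' fits of every single-agent arm, per-experiment combination indices at
#' every constant-ratio design level, cross-experiment aggregation (mean ±
#' sample SD, n), verbal classification of each aggregated CI, and pooled
#' Fa-CI profiles per combination arm. Nothing is dropped silently: failed
#' fits, excluded observations, clamped fractions and low-correlation fits
#' are all recorded in the `flags` table.
#'
#' Per-experiment CI values at a design level use that experiment's own
#' single-agent fits and the combination's replicate-averaged observed `fa`
#' at the doses actually administered. Fa-CI profiles are computed from
#' pooled models — per-experiment fits averaged on the parameter scale
#' (mean of `log(dm)`, mean of `m`) — since the study-level profile is the
#' mean curve over experiments; the design's dose split is anchored on the
#' pooled estimated IC50s.
#'
#' @param wells A well-record tibble ([read_wells()], [simulate_single_agent()]
#'   etc.) or a `synthetic_study` from [generate_study()].
#' @param fa_window Median-effect fit window (see [median_effect_transform()]).
#' @param fa_grid Effect grid for Fa-CI profiles.
#' @param r_warn Correlation threshold for flagging weak fits.
#' @param out_dir Optional directory; when given, report tables, Fa-CI CSVs,
#'   plots and the flag log are written there.
#' @return An object of class `study_report`: tibbles `ic50_table`,
#'   `ci_table`, `ci_by_experiment`, `flags`; lists `single_fits` (per agent,
#'   per experiment), `mixture_fits`, `pooled_models`, `fa_ci` (one
#'   `fa_ci_profile` per combination arm) and `designs`.
#' @export
run_study <- function(wells, fa_window = 0.01,
                      fa_grid = seq(0.01, 0.99, by = 0.01),
                      r_warn = 0.90, out_dir = NULL) {
  if (inherits(wells, "synthetic_study")) wells <- wells$wells
  flags <- new_flag_log()
  normalized <- normalize_wells(wells)
  n_clamped <- sum(normalized$fa_clamped)
  if (n_clamped > 0) {
    flags$add("normalize", NA, NA,
              sprintf("%d well(s) clamped to [0,1] after normalisation",
                      n_clamped))
  }
  per_dose <- collapse_replicates(normalized)
  single <- dplyr::filter(per_dose, is.na(.data$agent_b))
  combos <- dplyr::filter(per_dose, !is.na(.data$agent_b))

  single_fits <- fit_single_arms(single, fa_window, r_warn, flags)
  ic50_table <- summarise_ic50(single_fits)

  combo_arms <- unique(combos$arm)
  ci_by_experiment <- list(); ci_table <- list()
  fa_ci <- list(); mixture_fits <- list(); pooled_models <- list()
  designs <- list()
  for (a in combo_arms) {
    arm_data <- dplyr::filter(combos, .data$arm == a)
    res <- analyse_combination_arm(arm_data, single_fits, fa_window, r_warn,
                                   fa_grid, flags)
    ci_by_experiment[[a]] <- res$ci_by_experiment
    ci_table[[a]] <- res$ci_table
    fa_ci[[a]] <- res$fa_ci
    mixture_fits[[a]] <- res$mixture_fits
    pooled_models[[a]] <- res$pooled
    designs[[a]] <- res$design
  }
  report <- structure(
    list(
      ic50_table = ic50_table,
      ci_table = dplyr::bind_rows(ci_table),
      ci_by_experiment = dplyr::bind_rows(ci_by_experiment),
      fa_ci = fa_ci,
      single_fits = single_fits,
      mixture_fits = mixture_fits,
      pooled_models = pooled_models,
      designs = designs,
      flags = flags$table()
    ),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

new_flag_log <- function() {
  rows <- list()
  list(
    add = function(stage, arm, experiment_id, message) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        stage = stage, arm = as.character(arm),
        experiment_id = as.character(experiment_id), message = message
      )
    },
    table = function() {
      if (length(rows) == 0) {
        tibble::tibble(stage = character(), arm = character(),
                       experiment_id = character(), message = character())
      } else dplyr::bind_rows(rows)
    }
  )
}

# fit every (agent, experiment) single-agent dataset, logging failures and
# low-r warnings instead of aborting the study
fit_single_arms <- function(single, fa_window, r_warn, flags) {
  fits <- list()
  for (ag in unique(single$agent_a)) {
    fits[[ag]] <- list()
    ag_data <- dplyr::filter(single, .data$agent_a == ag)
    for (e in unique(ag_data$experiment_id)) {
      d <- dplyr::filter(ag_data, .data$experiment_id == e)
      fit <- withCallingHandlers(
        tryCatch(
          fit_median_effect(d$dose_a, d$fa, fa_window = fa_window,
                            r_warn = r_warn, agent_id = ag, experiment_id = e),
          error = function(err) {
            flags$add("fit_single", ag, e, conditionMessage(err))
            NULL
          }
        ),
        warning = function(w) {
          flags$add("fit_single", ag, e, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      if (!is.null(fit) && any(!fit$data$retained)) {
        excl <- fit$data[!fit$data$retained, ]
        flags$add("fit_single", ag, e,
                  sprintf("%d point(s) excluded: %s", nrow(excl),
                          paste(sprintf("dose=%g (%s)", excl$dose,
                                        excl$reason), collapse = "; ")))
      }
      # keep failed fits as explicit NULL entries (plain [[<- drops them)
      fits[[ag]][e] <- list(fit)
    }
  }
  fits
}

summarise_ic50 <- function(single_fits) {
  dplyr::bind_rows(lapply(names(single_fits), function(ag) {
    vals <- vapply(single_fits[[ag]],
                   function(f) if (is.null(f)) NA_real_ else f$dm, numeric(1))
    ms <- vapply(single_fits[[ag]],
                 function(f) if (is.null(f)) NA_real_ else f$m, numeric(1))
    agg <- aggregate_experiments(vals)
    tibble::tibble(
      agent = ag, ic50_mean = agg$mean, ic50_sd = agg$sd, n = agg$n,
      n_failed = agg$n_excluded, m_mean = mean(ms, na.rm = TRUE),
      flag = agg$flag
    )
  }))
}

pool_models <- function(fits) {
  ok <- Filter(Negate(is.null), fits)
  if (length(ok) == 0) return(NULL)
  list(dm = exp(mean(log(vapply(ok, `[[`, numeric(1), "dm")))),
       m = mean(vapply(ok, `[[`, numeric(1), "m")))
}

analyse_combination_arm <- function(arm_data, single_fits, fa_window, r_warn,
                                    fa_grid, flags) {
  a <- arm_data$agent_a[1]; b <- arm_data$agent_b[1]
  arm <- arm_data$arm[1]
  fits_a <- single_fits[[a]] %||% list()
  fits_b <- single_fits[[b]] %||% list()
  arm_data <- dplyr::group_by(arm_data, .data$experiment_id) |>
    dplyr::mutate(level = dplyr::dense_rank(.data$total_dose)) |>
    dplyr::ungroup()

  # per-experiment CI at every administered design level
  ci_rows <- list()
  for (i in seq_len(nrow(arm_data))) {
    row <- arm_data[i, ]
    e <- row$experiment_id
    fa <- row$fa
    flag <- NA_character_
    ci <- dxa <- dxb <- NA_real_
    if (is.null(fits_a[[e]]) || is.null(fits_b[[e]])) {
      flag <- "missing single-agent fit"
    } else if (fa <= 0 || fa >= 1) {
      flag <- "combination fa on boundary; CI undefined"
    } else {
      res <- combination_index(row$dose_a, row$dose_b, fa,
                               fits_a[[e]], fits_b[[e]])
      ci <- res$ci; dxa <- res$dxa; dxb <- res$dxb
    }
    if (!is.na(flag)) flags$add("ci", arm, e, flag)
    ci_rows[[i]] <- tibble::tibble(
      arm = arm, agent_a = a, agent_b = b, experiment_id = e,
      level = row$level, dose_a = row$dose_a, dose_b = row$dose_b,
      total_dose = row$total_dose, fa = fa, ci = ci, dxa = dxa, dxb = dxb,
      flag = flag
    )
  }
  ci_by_experiment <- dplyr::bind_rows(ci_rows)

  ci_table <- dplyr::group_by(ci_by_experiment, .data$level) |>
    dplyr::summarise(
      dose_a = mean(.data$dose_a), dose_b = mean(.data$dose_b),
      ci_mean = mean(.data$ci[is.finite(.data$ci)]),
      ci_sd = if (sum(is.finite(.data$ci)) > 1)
        stats::sd(.data$ci[is.finite(.data$ci)]) else NA_real_,
      n = sum(is.finite(.data$ci)),
      fa_mean = mean(.data$fa),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      arm = arm, agent_a = a, agent_b = b,
      classification = ifelse(
        is.finite(.data$ci_mean), classify_ci_safe(.data$ci_mean),
        NA_character_
      )
    ) |>
    dplyr::relocate("arm", "agent_a", "agent_b")

  # mixture fits over total dose, per experiment, then pooled
  mixture_fits <- list()
  pooled_design <- NULL
  pooled_a <- pool_models(fits_a)
  pooled_b <- pool_models(fits_b)
  if (!is.null(pooled_a) && !is.null(pooled_b)) {
    pooled_design <- constant_ratio_design(a, b, pooled_a$dm, pooled_b$dm)
  }
  for (e in unique(arm_data$experiment_id)) {
    d <- dplyr::filter(arm_data, .data$experiment_id == e)
    if (is.null(pooled_design)) { mixture_fits[[e]] <- NULL; next }
    mixture_fits[[e]] <- withCallingHandlers(
      tryCatch(
        fit_mixture(pooled_design, d$total_dose, d$fa, fa_window = fa_window,
                    r_warn = r_warn, experiment_id = e),
        error = function(err) {
          flags$add("fit_mixture", arm, e, conditionMessage(err))
          NULL
        }
      ),
      warning = function(w) {
        flags$add("fit_mixture", arm, e, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }
  pooled_mix <- pool_models(mixture_fits)
  fa_ci <- NULL
  if (!is.null(pooled_a) && !is.null(pooled_b) && !is.null(pooled_mix)) {
    fa_ci <- fa_ci_curve(pooled_a, pooled_b, pooled_mix, pooled_design,
                         fa_grid = fa_grid)
  } else {
    flags$add("fa_ci", arm, NA,
              "profile unavailable: insufficient valid fits")
  }
  list(ci_by_experiment = ci_by_experiment, ci_table = ci_table,
       fa_ci = fa_ci, mixture_fits = mixture_fits,
       pooled = list(a = pooled_a, b = pooled_b, mixture = pooled_mix),
       design = pooled_design)
}

classify_ci_safe <- function(ci) {
  vapply(ci, function(v) {
    if (!is.finite(v) || v <= 0) NA_character_ else classify_ci(v)
  }, character(1))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Combination study report\n")
  cat("\nSingle-agent potency (IC50, mean ± SD over experiments):\n")
  print(x$ic50_table)
  if (nrow(x$ci_table) > 0) {
    cat("\nCombination index by design level (mean ± SD over experiments):\n")
    print(x$ci_table)
  }
  if (nrow(x$flags) > 0) {
    cat(sprintf("\n%d flag(s) raised; see $flags\n", nrow(x$flags)))
  }
  invisible(x)
}

#' Write study report artifacts to a directory
#'
#' Emits `ic50_table.csv`, `ci_table.csv`, `ci_by_experiment.csv`,
#' `flags.csv`, one `fa_ci_<arm>.csv` and `fa_ci_<arm>.png` per combination
#' arm, and a human-readable `report.txt`. Table output is deterministic for
#' a fixed input.
#'
#' @param report A `study_report`.
#' @param out_dir Directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$ic50_table, file.path(out_dir, "ic50_table.csv"),
                   progress = FALSE)
  readr::write_csv(report$ci_table, file.path(out_dir, "ci_table.csv"),
                   progress = FALSE)
  readr::write_csv(report$ci_by_experiment,
                   file.path(out_dir, "ci_by_experiment.csv"),
                   progress = FALSE)
  readr::write_csv(report$flags, file.path(out_dir, "flags.csv"),
                   progress = FALSE)
  for (arm in names(report$fa_ci)) {
    prof <- report$fa_ci[[arm]]
    if (is.null(prof)) next
    safe <- gsub("[^A-Za-z0-9_+-]", "_", arm)
    readr::write_csv(prof[, c("fa", "ci")],
                     file.path(out_dir, paste0("fa_ci_", safe, ".csv")),
                     progress = FALSE)
    p <- plot_fa_ci(prof, title = arm)
    ggplot2::ggsave(file.path(out_dir, paste0("fa_ci_", safe, ".png")),
                    p, width = 5, height = 4, dpi = 150)
  }
  con <- file(file.path(out_dir, "report.txt"), open = "w")
  sink(con); on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  invisible(out_dir)
}

#' Plot an Fa-CI profile
#'
#' Combination index against fraction affected, with the Loewe additivity
#' line CI = 1 for reference; log scale on CI so synergism and antagonism
#' are symmetric about the line.
#'
#' @param profile An `fa_ci_profile` from [fa_ci_curve()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_fa_ci <- function(profile, title = NULL) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$fa, y = .data$ci)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Fraction affected (Fa)", y = "Combination index (CI)",
                  title = title) +
    ggplot2::theme_minimal()
}
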