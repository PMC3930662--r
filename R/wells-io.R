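well_columns <- c("experiment_id", "agent_a", "dose_a", "agent_b", "dose_b",
                  "replicate", "is_control")

#' Read long-format well records from CSV
#'
#' One row per well: `experiment_id`, `agent_a`, `dose_a` (µM), `agent_b`
#' (empty for single-agent arms), `dose_b`, `replicate`, `is_control`, and
#' exactly one of `signal` (raw plate-reader units) or `viability`
#' (control-normalised fraction), declared by which column the header
#' carries. Malformed rows (negative doses, non-zero doses on control wells,
#' missing signal) are collected into an error report with their line
#' numbers; any malformed row is a hard error naming the lines.
#'
#' @param path CSV file path (UTF-8, header required).
#' @return A tibble of validated well records with a `"value_kind"` attribute
#'   of `"signal"` or `"viability"`.
#' @export
read_wells <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  has_signal <- "signal" %in% names(raw)
  has_viab <- "viability" %in% names(raw)
  if (has_signal && has_viab) {
    stop("file declares both `signal` and `viability`; exactly one is allowed",
         call. = FALSE)
  }
  if (!has_signal && !has_viab) {
    stop("file must declare a `signal` or `viability` column", call. = FALSE)
  }
  value_col <- if (has_signal) "signal" else "viability"
  missing_cols <- setdiff(well_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw$agent_b <- as.character(raw$agent_b)
  raw$dose_b[is.na(raw$dose_b)] <- 0
  # line numbers in the file: +1 for the header
  line <- seq_len(nrow(raw)) + 1L
  problems <- character(0)
  bad <- function(which, msg) {
    if (any(which)) {
      problems <<- c(problems,
                     sprintf("line %d: %s", line[which], msg))
    }
  }
  bad(is.na(raw$dose_a) | raw$dose_a < 0, "negative or missing dose_a")
  bad(raw$dose_b < 0, "negative dose_b")
  bad(raw$is_control & (raw$dose_a != 0 | raw$dose_b != 0),
      "control well with non-zero dose")
  bad(!raw$is_control & raw$dose_a == 0 & raw$dose_b == 0,
      "treated well with all doses zero")
  bad(is.na(raw[[value_col]]) | raw[[value_col]] < 0,
      sprintf("negative or missing %s", value_col))
  if (length(problems) > 0) {
    stop("malformed well records:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  attr(out, "value_kind") <- value_col
  out
}

#' Write well records to CSV
#'
#' Inverse of [read_wells()]; [generate_study()] output round-trips through
#' `write_wells()`/[read_wells()] unchanged.
#'
#' @param wells Well-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path) {
  cols <- intersect(c(well_columns, "signal", "viability", "clamped"),
                    names(wells))
  readr::write_csv(wells[, cols], path, progress = FALSE)
  invisible(path)
}

#' Normalise well signal to fraction affected
#'
#' Viability of each well is its signal divided by the mean control-well
#' signal of the same experiment (the untreated control defines 100%
#' proliferation); the fraction affected is `fa = 1 - viability`, clamped to
#' `[0, 1]` with the number of clamped wells recorded. Files already
#' carrying a `viability` column skip the control normalisation.
#'
#' @param wells Well records from [read_wells()] or the simulator.
#' @param value_kind `"signal"` (normalise against controls) or
#'   `"viability"` (already normalised). Defaults to the tibble's
#'   `value_kind` attribute, else `"signal"`.
#' @return A tibble of treated wells with `viability`, `fa` and `fa_clamped`
#'   columns added, plus an `arm` label (`agent_a` or `"a+b"`).
#' @export
normalize_wells <- function(wells, value_kind = NULL) {
  value_kind <- value_kind %||% attr(wells, "value_kind") %||% "signal"
  value_kind <- match.arg(value_kind, c("signal", "viability"))
  if (value_kind == "signal") {
    ctl <- dplyr::filter(wells, .data$is_control)
    if (nrow(ctl) == 0) stop("no control wells present", call. = FALSE)
    ctl_means <- dplyr::summarise(
      dplyr::group_by(ctl, .data$experiment_id, .data$agent_a, .data$agent_b),
      control_mean = mean(.data$signal), .groups = "drop"
    )
    missing <- dplyr::anti_join(
      dplyr::distinct(wells, .data$experiment_id, .data$agent_a, .data$agent_b),
      ctl_means, by = c("experiment_id", "agent_a", "agent_b")
    )
    if (nrow(missing) > 0) {
      stop("experiment(s) without control wells: ",
           paste(unique(missing$experiment_id), collapse = ", "),
           call. = FALSE)
    }
    out <- dplyr::left_join(wells, ctl_means,
                            by = c("experiment_id", "agent_a", "agent_b"))
    out$viability <- out$signal / out$control_mean
  } else {
    out <- wells
  }
  out <- dplyr::filter(out, !.data$is_control)
  raw_fa <- 1 - out$viability
  out$fa <- pmin(pmax(raw_fa, 0), 1)
  out$fa_clamped <- raw_fa < 0 | raw_fa > 1
  out$arm <- ifelse(is.na(out$agent_b), out$agent_a,
                    paste0(out$agent_a, "+", out$agent_b))
  out
}

#' Average replicate wells to one fraction affected per dose
#'
#' Replicate wells of the same arm, experiment and dose are averaged to a
#' single `fa` before fitting, matching a plate-reader workflow; the well
#' count and any clamping are carried along.
#'
#' @param normalized Output of [normalize_wells()].
#' @return A tibble: `arm`, `agent_a`, `agent_b`, `experiment_id`, `dose_a`,
#'   `dose_b`, `total_dose`, `fa`, `n_wells`, `any_clamped`.
#' @export
collapse_replicates <- function(normalized) {
  dplyr::summarise(
    dplyr::group_by(normalized, .data$arm, .data$agent_a, .data$agent_b,
                    .data$experiment_id, .data$dose_a, .data$dose_b),
    fa = mean(.data$fa), n_wells = dplyr::n(),
    any_clamped = any(.data$fa_clamped), .groups = "drop"
  ) |>
    dplyr::mutate(total_dose = .data$dose_a + .data$dose_b) |>
    dplyr::arrange(.data$arm, .data$experiment_id, .data$total_dose)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
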