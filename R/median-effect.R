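#' Median-effect dose-response model
#'
#' The median-effect model relates the fraction of cells affected (inhibited)
#' `fa` to dose `D` through
#' \deqn{\frac{F_a}{F_u} = \left(\frac{D}{D_m}\right)^m}
#' where `Fu = 1 - Fa` is the unaffected fraction, `Dm` the median-effect dose
#' (operationally the IC50) and `m` the slope. Taking log10 of both sides
#' linearises the curve: `log10(fa/fu) = m*log10(D) - m*log10(Dm)`, the
#' median-effect plot. Fitting is ordinary least squares on that plot.
#'
#' @name median_effect
#' @keywords internal
NULL

#' Transform dose/fraction-affected observations to the median-effect plot
#'
#' Maps each observation `(dose, fa)` to `(x, y) = (log10 dose,
#' log10(fa/fu))`. Observations outside the fit window — `dose <= 0` or `fa`
#' outside `(fa_window, 1 - fa_window)` — are excluded from the returned
#' coordinates and reported in the `excluded` attribute/column rather than
#' silently dropped; the log-odds is numerically unstable near 0 and 1 and
#' undefined at them. `fa` values that fall outside `[0, 1]` (possible after
#' control normalisation of noisy signal) are clamped to `[0, 1]` first and
#' the clamping is flagged.
#'
#' @param dose Numeric vector of doses (concentration, e.g. µM).
#' @param fa Numeric vector of fractions affected, same length as `dose`.
#' @param fa_window Exclusion half-width `eps`: points with clamped
#'   `fa <= eps` or `fa >= 1 - eps` are not used. Default 0.01.
#' @return A tibble with one row per input observation: `dose`, `fa` (after
#'   clamping), `x`, `y` (`NA` for excluded rows), `retained` (logical),
#'   `clamped` (logical), `reason` (why a row was excluded, `NA` otherwise).
#' @examples
#' median_effect_transform(c(0.5, 1, 2), c(1/3, 0.5, 2/3))
#' @export
median_effect_transform <- function(dose, fa, fa_window = 0.01) {
  stopifnot(length(dose) == length(fa), is.numeric(dose), is.numeric(fa))
  if (!is.numeric(fa_window) || length(fa_window) != 1 ||
      fa_window <= 0 || fa_window >= 0.5) {
    stop("`fa_window` must be a single number in (0, 0.5)", call. = FALSE)
  }
  fa_clamped <- pmin(pmax(fa, 0), 1)
  clamped <- !is.na(fa) & (fa < 0 | fa > 1)

  reason <- rep(NA_character_, length(dose))
  reason[is.na(dose) | is.na(fa)] <- "missing dose or fa"
  bad_dose <- is.na(reason) & dose <= 0
  reason[bad_dose] <- "dose <= 0"
  low <- is.na(reason) & fa_clamped <= fa_window
  reason[low] <- sprintf("fa <= %g", fa_window)
  high <- is.na(reason) & fa_clamped >= 1 - fa_window
  reason[high] <- sprintf("fa >= %g", 1 - fa_window)

  retained <- is.na(reason)
  x <- ifelse(retained, log10(dose), NA_real_)
  y <- ifelse(retained, log10(fa_clamped / (1 - fa_clamped)), NA_real_)
  tibble::tibble(
    dose = dose, fa = fa_clamped, x = x, y = y,
    retained = retained, clamped = clamped, reason = reason
  )
}

#' Fit the median-effect model by log-linear regression
#'
#' Ordinary least squares through the median-effect plot of the retained
#' observations. The slope of the line is `m`; the intercept `b = -m log10 Dm`
#' gives `Dm = 10^(-b/m)`. The linear correlation coefficient `r` of the plot
#' is reported as the fit diagnostic; fits with `r < r_warn` are flagged with
#' a warning but returned.
#'
#' @inheritParams median_effect_transform
#' @param agent_id,experiment_id Optional labels carried on the fit.
#' @param min_points Minimum retained observations (default 3).
#' @param r_warn Correlation threshold below which a warning is raised
#'   (default 0.90). The fit is still returned.
#' @return An object of class `median_effect_fit`: a list with elements `dm`,
#'   `m`, `r`, `n_fit`, `intercept`, `agent_id`, `experiment_id`, and `data`
#'   (the transform table including exclusions).
#' @examples
#' d <- design_dose_series(1)
#' fit <- fit_median_effect(d, predict_fa_true(d, dm = 1, m = 2))
#' fit$dm
#' @export
fit_median_effect <- function(dose, fa, fa_window = 0.01, min_points = 3,
                              r_warn = 0.90, agent_id = NA_character_,
                              experiment_id = NA_character_) {
  tr <- median_effect_transform(dose, fa, fa_window = fa_window)
  keep <- tr[tr$retained, , drop = FALSE]
  if (nrow(keep) < min_points) {
    excl <- tr[!tr$retained, , drop = FALSE]
    stop(sprintf(
      "fit infeasible for %s/%s: %d observation(s) retained (need >= %d); excluded: %s",
      agent_id, experiment_id, nrow(keep), min_points,
      paste(sprintf("dose=%g (%s)", excl$dose, excl$reason), collapse = "; ")
    ), call. = FALSE)
  }
  if (length(unique(keep$x)) < 2) {
    stop("fit infeasible: all retained doses are equal (degenerate design)",
         call. = FALSE)
  }
  ls <- stats::lm(y ~ x, data = keep)
  m <- unname(stats::coef(ls)[["x"]])
  b <- unname(stats::coef(ls)[["(Intercept)"]])
  if (!is.finite(m) || m <= 0) {
    stop(sprintf(
      "model invalid for %s/%s: non-positive median-effect slope (m = %.4g); dose inversion undefined",
      agent_id, experiment_id, m
    ), call. = FALSE)
  }
  # r of a perfectly collinear plot is 1 up to rounding; guard zero variance in y
  r <- if (stats::sd(keep$y) == 0) 1 else stats::cor(keep$x, keep$y)
  fit <- structure(
    list(
      dm = 10^(-b / m), m = m, r = r, n_fit = nrow(keep), intercept = b,
      agent_id = agent_id, experiment_id = experiment_id, data = tr
    ),
    class = "median_effect_fit"
  )
  if (is.finite(r) && r < r_warn) {
    warning(sprintf("median-effect fit for %s/%s has r = %.3f < %.2f",
                    agent_id, experiment_id, r, r_warn), call. = FALSE)
  }
  fit
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("Median-effect fit",
      if (!is.na(x$agent_id)) paste0("[", x$agent_id, "]") else "", "\n")
  cat(sprintf("  Dm (IC50): %.6g    m: %.4g    r: %.4f    n: %d\n",
              x$dm, x$m, x$r, x$n_fit))
  n_excl <- sum(!x$data$retained)
  if (n_excl > 0) cat(sprintf("  %d observation(s) excluded from the fit\n", n_excl))
  invisible(x)
}

#' Predicted fraction affected at a dose
#'
#' Evaluates `fa = 1 / (1 + (dm/dose)^m)`, the rearranged median-effect
#' equation. Strictly increasing in dose for `m > 0`; `fa = 0.5` at
#' `dose = dm` by definition.
#'
#' @param model A `median_effect_fit`, or any list with numeric `dm` and `m`.
#' @param dose Numeric vector of doses, all `> 0`.
#' @return Fractions affected, strictly in (0, 1).
#' @export
predict_fa <- function(model, dose) {
  check_model(model)
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    stop("`dose` must be finite and > 0", call. = FALSE)
  }
  1 / (1 + (model$dm / dose)^model$m)
}

#' Iso-effective dose for a fraction affected
#'
#' Inverts the median-effect model: `D = dm * (fa/fu)^(1/m)`. This is the
#' single-agent dose producing effect level `fa`, the iso-effective dose used
#' in the combination-index denominator.
#'
#' @param model A `median_effect_fit`, or any list with numeric `dm` and `m`.
#' @param fa Numeric vector of effect levels, all strictly in (0, 1).
#' @return Doses, same units as `dm`.
#' @export
dose_for_fa <- function(model, fa) {
  check_model(model)
  if (any(!is.finite(fa)) || any(fa <= 0) || any(fa >= 1)) {
    stop("`fa` must be strictly inside (0, 1)", call. = FALSE)
  }
  model$dm * (fa / (1 - fa))^(1 / model$m)
}

#' Noise-free fraction affected from known parameters
#'
#' Convenience wrapper around the forward model for generating ground-truth
#' curves: `predict_fa_true(dose, dm, m)` equals
#' `predict_fa(list(dm = dm, m = m), dose)`.
#'
#' @param dose Doses (> 0).
#' @param dm,m True median-effect dose and slope.
#' @export
predict_fa_true <- function(dose, dm, m) {
  predict_fa(list(dm = dm, m = m), dose)
}

check_model <- function(model) {
  if (!is.list(model) || is.null(model$dm) || is.null(model$m)) {
    stop("`model` must be a median_effect_fit or a list with `dm` and `m`",
         call. = FALSE)
  }
  if (!is.finite(model$dm) || model$dm <= 0) {
    stop("model invalid: dm must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(model$m) || model$m <= 0) {
    stop("model invalid: slope m must be finite and > 0", call. = FALSE)
  }
  invisible(model)
}
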