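#' The eleven-band verbal combination-index scale
#'
#' Verbal description of drug interaction strength by CI value, from very
#' strong synergism (CI below 0.1) through a nearly additive effect (CI
#' around 1) to very strong antagonism (CI above 10). The printed bands of
#' the classical scale overlap at 0.90 and 1.45 and abut at 1.1/1.2; the
#' convention adopted here closes each interval on the side nearer 1 and
#' opens it away from 1, so the eleven intervals partition (0, Inf) exactly:
#'
#' * (0, 0.1) very strong synergism
#' * \[0.1, 0.3) strong synergism
#' * \[0.3, 0.7) synergism
#' * \[0.7, 0.85) moderate synergism
#' * \[0.85, 0.9) slight synergism
#' * \[0.9, 1.1\] nearly additive
#' * (1.1, 1.2\] slight antagonism
#' * (1.2, 1.45\] moderate antagonism
#' * (1.45, 3.3\] antagonism
#' * (3.3, 10\] strong antagonism
#' * (10, Inf) very strong antagonism
#'
#' @return A tibble with columns `label`, `lower`, `upper`,
#'   `lower_closed`, `upper_closed`, ordered from strongest synergism to
#'   strongest antagonism.
#' @examples
#' ci_classification_scale()
#' @export
ci_classification_scale <- function() {
  tibble::tibble(
    label = c(
      "very strong synergism", "strong synergism", "synergism",
      "moderate synergism", "slight synergism", "nearly additive",
      "slight antagonism", "moderate antagonism", "antagonism",
      "strong antagonism", "very strong antagonism"
    ),
    lower = c(0, 0.1, 0.3, 0.7, 0.85, 0.9, 1.1, 1.2, 1.45, 3.3, 10),
    upper = c(0.1, 0.3, 0.7, 0.85, 0.9, 1.1, 1.2, 1.45, 3.3, 10, Inf),
    lower_closed = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                     FALSE, FALSE, FALSE, FALSE, FALSE),
    upper_closed = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                     TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Classify a combination index on the verbal scale
#'
#' Maps each CI value to exactly one of the eleven verbal interaction labels
#' (see [ci_classification_scale()] for the band edges and the boundary
#' convention).
#'
#' @param ci Positive numeric vector of combination-index values.
#' @param scale A classification table as returned by
#'   [ci_classification_scale()]; supply a modified copy to change the
#'   boundary convention.
#' @return Character vector of labels, same length as `ci`.
#' @examples
#' classify_ci(c(0.162, 0.690, 1.0, 1.104))
#' @export
classify_ci <- function(ci, scale = ci_classification_scale()) {
  if (!is.numeric(ci) || any(!is.finite(ci)) || any(ci <= 0)) {
    stop("`ci` must be finite and > 0", call. = FALSE)
  }
  vapply(ci, function(v) {
    in_band <- ifelse(scale$lower_closed, v >= scale$lower, v > scale$lower) &
      ifelse(scale$upper_closed, v <= scale$upper, v < scale$upper)
    hit <- which(in_band)
    if (length(hit) != 1) {
      stop(sprintf("classification scale does not partition at ci = %g", v),
           call. = FALSE)
    }
    scale$label[hit]
  }, character(1))
}
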