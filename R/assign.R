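#' Assign the absolute configuration from the sign of a measured CID
#'
#' Compares the sign of a corrected measured circular intensity differential
#' against an ensemble of predictions and assigns the enantiomer label whose
#' predicted sign matches: a single-wavelength sign measurement suffices
#' because the predicted sign is robust against the choice of
#' electronic-structure method. `labels` maps the sign of the measured CID to
#' the enantiomer label (e.g. a positive measured delta means "(1S,5S)").
#'
#' `sign_agreement` is the fraction of ensemble members sharing the
#' ensemble's consensus sign — the cross-method robustness of the predicted
#' sign. It is 1 when every method agrees, and it is unchanged when the
#' measured value is negated (which swaps the assigned label), so a confident
#' assignment of one enantiomer implies an equally confident assignment of
#' the other from the mirrored measurement.
#'
#' A measurement within `k` standard errors of zero carries no sign
#' information and returns status `"indeterminate"` (not an error). The
#' assignment is `confident` only when every ensemble member agrees on the
#' sign and the measurement is at least `k` sigma from zero.
#'
#' @param delta Corrected measured CID (dimensionless scalar).
#' @param sigma Standard error of `delta` (> 0).
#' @param ensemble A `prediction_ensemble` (see [aggregate_predictions()]) or
#'   a `cid_prediction` tibble.
#' @param labels Named character vector with entries `positive` and
#'   `negative` giving the enantiomer label assigned to each measured sign.
#' @param k Significance threshold in units of `sigma` (default 3).
#' @return A one-row tibble: `status` ("assigned"/"indeterminate"),
#'   `assigned_label` (NA when indeterminate), `sign_agreement`, `confident`,
#'   `delta`, `sigma`, `k`.
#' @examples
#' preds <- dplyr::bind_rows(lapply(1:6, function(s)
#'   delta_scp90(make_tensor_set(seed = s, target_delta = (3.5 + s / 20) * 1e-4),
#'               method_label = paste0("dft-", s))))
#' assign_configuration(3.6e-4, 0.3e-4, aggregate_predictions(preds),
#'                      labels = c(positive = "(1S,5S)", negative = "(1R,5R)"))
#' @export
assign_configuration <- function(delta, sigma, ensemble,
                                 labels = c(positive = "(+)", negative = "(-)"),
                                 k = 3) {
  if (inherits(ensemble, "prediction_ensemble")) {
    members <- ensemble$predictions$delta
  } else if (is.data.frame(ensemble) && "delta" %in% names(ensemble)) {
    members <- ensemble$delta
  } else {
    abort("`ensemble` must be a `prediction_ensemble` or a prediction tibble.",
          class = "rayoa_invalid_prediction")
  }
  if (length(members) < 1) {
    abort("The prediction ensemble is empty.",
          class = "rayoa_invalid_prediction")
  }
  if (!all(c("positive", "negative") %in% names(labels))) {
    abort("`labels` must name both a `positive` and a `negative` enantiomer.",
          class = "rayoa_invalid_labels")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    abort("`sigma` must be a positive number.", class = "rayoa_invalid_measurement")
  }
  consensus <- sign(mean(sign(members)))
  if (consensus == 0) consensus <- sign(mean(members))
  agreement <- mean(sign(members) == consensus)

  indeterminate <- abs(delta) < k * sigma
  assigned <- if (indeterminate) NA_character_ else {
    unname(if (delta > 0) labels[["positive"]] else labels[["negative"]])
  }
  tibble::tibble(
    status = if (indeterminate) "indeterminate" else "assigned",
    assigned_label = assigned,
    sign_agreement = agreement,
    confident = !indeterminate && agreement == 1,
    delta = delta,
    sigma = sigma,
    k = k
  )
}
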