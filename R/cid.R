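#' Circular intensity differential for depolarized right-angle SCP scattering
#'
#' Evaluates the dimensionless RayOA observable measured in the scattered
#' circular polarization (SCP) strategy at right angles with the incident
#' beam linearly polarized in the scattering plane (equivalently, the
#' depolarized right-angle ICP geometry):
#' \deqn{\Delta = \frac{1}{c}\,\frac{24\,\beta(G')^2 - 8\,\beta(A)^2}{12\,\beta^2}}
#' with \eqn{c} the speed of light in atomic units and the invariants from
#' [compute_invariants()]. The minus sign before \eqn{8\beta(A)^2} is the
#' convention used throughout this package; some literature tabulations of
#' the depolarized CID differ in the sign attached to the quadrupole term,
#' which is absorbed here into the sign convention of the A tensor. Delta is
#' a normalized intensity difference, so \eqn{|\Delta| < 1}; an isotropic
#' scatterer (\eqn{\beta^2 = 0}) has no depolarized scattering and its CID is
#' undefined.
#'
#' @param inv A `rayoa_invariants` object (or a `rayoa_tensor_set`, which is
#'   reduced to its invariants first).
#' @param method_label Free-text label for the level of theory that produced
#'   the tensors; defaults to the label carried by `inv`.
#' @return A one-row tibble of class `cid_prediction` with columns `delta`,
#'   `wavelength_nm`, `geometry` (always `"SCP-90-depolarized"`) and
#'   `method_label`.
#' @examples
#' make_tensor_set(seed = 1, target_delta = 3.6e-4) |> delta_scp90()
#' @export
delta_scp90 <- function(inv, method_label = NULL) {
  if (is_tensor_set(inv)) inv <- compute_invariants(inv)
  if (!inherits(inv, "rayoa_invariants")) {
    abort("`inv` must be a `rayoa_invariants` or `rayoa_tensor_set`.",
          class = "rayoa_invalid_tensor")
  }
  if (!is.finite(inv$beta2) || inv$beta2 <= 0) {
    abort("beta^2 must be > 0: an isotropic scatterer has an undefined depolarized CID.",
          class = "rayoa_degenerate_molecule")
  }
  delta <- (24 * inv$betaG2 - 8 * inv$betaA2) /
    (12 * inv$beta2 * rayoa_constants$c_au)
  if (!is.finite(delta) || abs(delta) > 1) {
    abort("Computed CID is not a physical normalized intensity difference (|delta| >= 1).",
          class = "rayoa_unphysical_cid")
  }
  new_cid_prediction(
    delta = delta,
    wavelength_nm = inv$wavelength_nm,
    method_label = method_label %||% inv$label
  )
}

new_cid_prediction <- function(delta, wavelength_nm, method_label = "") {
  out <- tibble::tibble(
    delta = delta,
    wavelength_nm = wavelength_nm,
    geometry = "SCP-90-depolarized",
    method_label = as.character(method_label)
  )
  class(out) <- c("cid_prediction", class(out))
  out
}

#' Rescale a CID prediction to another wavelength
#'
#' Far off resonance the depolarized CID varies with wavelength as
#' \eqn{\Delta \propto 1/\lambda} to good approximation, so a prediction at
#' one wavelength carries over to another by
#' \eqn{\Delta_\mathrm{target} = \Delta_\mathrm{source}\,
#' \lambda_\mathrm{source}/\lambda_\mathrm{target}}. The law holds only far
#' from electronic resonance; a message cautions when extrapolating by more
#' than a factor of 2 in wavelength.
#'
#' @param p A `cid_prediction` tibble (one or more rows).
#' @param target_wavelength_nm Wavelength to rescale to (nm, > 0).
#' @return The rescaled `cid_prediction`, with `method_label` annotated.
#' @examples
#' p <- make_tensor_set(seed = 1, target_delta = 3.6e-4) |> delta_scp90()
#' rescale_wavelength(p, 1064)  # exactly half the 532 nm value
#' @export
rescale_wavelength <- function(p, target_wavelength_nm) {
  if (!inherits(p, "cid_prediction")) {
    abort("`p` must be a `cid_prediction`.", class = "rayoa_invalid_prediction")
  }
  if (!is.numeric(target_wavelength_nm) || length(target_wavelength_nm) != 1 ||
      !is.finite(target_wavelength_nm) || target_wavelength_nm <= 0) {
    abort("`target_wavelength_nm` must be a positive number.",
          class = "rayoa_invalid_wavelength")
  }
  ratio <- p$wavelength_nm / target_wavelength_nm
  if (any(ratio > 2 | ratio < 0.5)) {
    inform("Rescaling by more than a factor of 2 in wavelength: the 1/lambda law assumes far-off-resonance conditions.")
  }
  out <- p
  out$delta <- p$delta * ratio
  out$method_label <- ifelse(
    p$wavelength_nm == target_wavelength_nm, p$method_label,
    sprintf("%s (rescaled from %g nm)", p$method_label, p$wavelength_nm))
  out$wavelength_nm <- target_wavelength_nm
  out
}

#' Aggregate CID predictions from several levels of theory into an ensemble
#'
#' The sign of the depolarized CID is robust against the choice of
#' electronic-structure method, so predictions from several functionals are
#' summarized as an ensemble (min, max, mean) at a common wavelength and
#' geometry; the spread is the method-dependence of the magnitude.
#'
#' @param predictions A `cid_prediction` tibble (rows are methods), a plain
#'   data frame with the same columns, or a list of such to be row-bound.
#' @param tol Relative tolerance for the common-wavelength check.
#' @return An object of class `prediction_ensemble`: a list with
#'   `predictions` (the tibble) and `summary` (one-row tibble `n`,
#'   `delta_min`, `delta_max`, `delta_mean`, `wavelength_nm`, `geometry`).
#'   `tidy()` returns the member predictions, `glance()` the summary.
#' @examples
#' preds <- dplyr::bind_rows(lapply(1:4, function(s)
#'   delta_scp90(make_tensor_set(seed = s, target_delta = (3.5 + s / 10) * 1e-4),
#'               method_label = paste0("method-", s))))
#' aggregate_predictions(preds)
#' @export
aggregate_predictions <- function(predictions, tol = 1e-9) {
  if (is.list(predictions) && !is.data.frame(predictions)) {
    predictions <- dplyr::bind_rows(predictions)
  }
  needed <- c("delta", "wavelength_nm", "geometry", "method_label")
  if (!is.data.frame(predictions) || !all(needed %in% names(predictions)) ||
      nrow(predictions) < 1) {
    abort("`predictions` must hold at least one CID prediction row.",
          class = "rayoa_invalid_prediction")
  }
  wl <- predictions$wavelength_nm
  if (diff(range(wl)) > tol * max(abs(wl))) {
    abort("All ensemble members must share one wavelength.",
          class = "rayoa_mixed_ensemble")
  }
  if (length(unique(predictions$geometry)) != 1) {
    abort("All ensemble members must share one scattering geometry.",
          class = "rayoa_mixed_ensemble")
  }
  predictions <- tibble::as_tibble(predictions)
  summary <- dplyr::summarise(
    predictions,
    n = dplyr::n(),
    delta_min = min(.data$delta),
    delta_max = max(.data$delta),
    delta_mean = mean(.data$delta),
    wavelength_nm = .data$wavelength_nm[1],
    geometry = .data$geometry[1]
  )
  structure(list(predictions = predictions, summary = summary),
            class = "prediction_ensemble")
}

#' @export
print.prediction_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<prediction_ensemble> %d method(s) at %g nm (%s)\n",
              s$n, s$wavelength_nm, s$geometry))
  cat(sprintf("  delta: min %.4g, mean %.4g, max %.4g\n",
              s$delta_min, s$delta_mean, s$delta_max))
  invisible(x)
}

#' @rdname aggregate_predictions
#' @param x A `prediction_ensemble`.
#' @param ... Unused.
#' @export
tidy.prediction_ensemble <- function(x, ...) x$predictions

#' @rdname aggregate_predictions
#' @export
glance.prediction_ensemble <- function(x, ...) x$summary
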