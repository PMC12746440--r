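#' Instrument configuration for a photon-counting SCP measurement
#'
#' Describes one SCP RayOA acquisition: incident power, wavelength,
#' collection solid angle, total exposure, and the mean detected photon rate
#' summed over the two circular channels. The count rate is a direct input
#' rather than being derived from power and solid angle, because that
#' derivation needs a molecular scattering cross-section and detector
#' efficiency that are not part of this model; power and solid angle are
#' metadata describing the acquisition.
#'
#' @param power_mW Incident laser power (mW, > 0; default 30).
#' @param wavelength_nm Incident wavelength (nm, > 0; default 532).
#' @param solid_angle_sr Collection solid angle (sr, in (0, 4*pi]; default
#'   2e-5).
#' @param exposure_h Total exposure time (hours, > 0).
#' @param count_rate_per_s Mean detected photon rate summed over the right-
#'   and left-circular channels (counts/s, > 0).
#' @param seed Optional integer seed; when supplied, [simulate_scp()] is
#'   bit-for-bit reproducible.
#' @return A list of class `instrument_config`.
#' @examples
#' cfg <- instrument_config(exposure_h = 15, count_rate_per_s = 2e5, seed = 1)
#' @export
instrument_config <- function(power_mW = 30, wavelength_nm = 532,
                              solid_angle_sr = 2e-5, exposure_h,
                              count_rate_per_s, seed = NULL) {
  for (nm in c("power_mW", "wavelength_nm", "solid_angle_sr", "exposure_h",
               "count_rate_per_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a positive number.", nm),
            class = "rayoa_invalid_config")
    }
  }
  if (solid_angle_sr > 4 * pi) {
    abort("`solid_angle_sr` cannot exceed the full sphere (4*pi sr).",
          class = "rayoa_invalid_config")
  }
  structure(
    list(power_mW = power_mW, wavelength_nm = wavelength_nm,
         solid_angle_sr = solid_angle_sr, exposure_h = exposure_h,
         count_rate_per_s = count_rate_per_s,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "instrument_config"
  )
}

# Poisson draws that stay valid at the very large means photon counting
# reaches (rpois overflows integer storage above ~2^31): beyond 1e9 the
# Gaussian limit is used, where the skewness correction is below 3e-5.
rpois_large <- function(n, lambda) {
  out <- numeric(n)
  big <- lambda > 1e9
  if (any(!big)) out[!big] <- rpois(sum(!big), lambda[!big])
  if (any(big)) {
    out[big] <- round(rnorm(sum(big), mean = lambda[big],
                            sd = sqrt(lambda[big])))
  }
  pmax(out, 0)
}

#' Simulate a photon-counting SCP measurement
#'
#' Draws the total detected count from a Poisson law with mean
#' `count_rate_per_s * exposure_seconds`, splits it into circular channel
#' means \eqn{N (1 \pm \Delta)/2}, and draws the right- and left-circular
#' counts as independent Poisson variates on those means. The raw observable
#' is \eqn{\Delta_\mathrm{raw} = (n_R - n_L)/(n_R + n_L)} with shot-noise
#' standard error \eqn{\sigma_\Delta = 1/\sqrt{n_R + n_L}}; the precision is
#' therefore set entirely by the accumulated counts
#' (\eqn{10^{10}} counts for \eqn{\sigma_\Delta \sim 10^{-5}}).
#'
#' @param true_delta True circular intensity differential, `|true_delta| < 1`.
#' @param config An [instrument_config()]. When `config$seed` is set the
#'   simulation is reproducible; replicates within one call consume the
#'   seeded stream sequentially.
#' @param n_rep Number of independent replicate acquisitions (default 1).
#' @return A tibble of class `scp_measurement` with one row per replicate:
#'   `replicate`, `n_right`, `n_left`, `n_total`, `delta_raw`, `sigma_delta`.
#'   The configuration is attached as attribute `config`.
#' @examples
#' cfg <- instrument_config(exposure_h = 15, count_rate_per_s = 2e5, seed = 42)
#' simulate_scp(3.6e-4, cfg)
#' @export
simulate_scp <- function(true_delta, config, n_rep = 1) {
  if (!inherits(config, "instrument_config")) {
    abort("`config` must be an `instrument_config`.",
          class = "rayoa_invalid_config")
  }
  if (!is.numeric(true_delta) || length(true_delta) != 1 ||
      !is.finite(true_delta) || abs(true_delta) >= 1) {
    abort("`true_delta` must satisfy |true_delta| < 1.",
          class = "rayoa_invalid_config")
  }
  mean_total <- config$count_rate_per_s * config$exposure_h * 3600
  if (mean_total < 100) {
    warn("Expected total counts < 100: the delta estimator is unreliable at this exposure.")
  }
  draw <- function() {
    n_tot <- rpois_large(n_rep, rep(mean_total, n_rep))
    n_r <- rpois_large(n_rep, n_tot * (1 + true_delta) / 2)
    n_l <- rpois_large(n_rep, n_tot * (1 - true_delta) / 2)
    list(n_r = n_r, n_l = n_l)
  }
  counts <- if (is.null(config$seed)) draw() else {
    withr::with_seed(config$seed, draw())
  }
  n_sum <- counts$n_r + counts$n_l
  out <- tibble::tibble(
    replicate = seq_len(n_rep),
    n_right = counts$n_r,
    n_left = counts$n_l,
    n_total = n_sum,
    delta_raw = ifelse(n_sum > 0, (counts$n_r - counts$n_l) / n_sum, NA_real_),
    sigma_delta = ifelse(n_sum > 0, 1 / sqrt(n_sum), NA_real_)
  )
  attr(out, "config") <- config
  class(out) <- c("scp_measurement", class(out))
  out
}

#' Apply the SCP correction pipeline to a raw measurement
#'
#' Corrects a raw measured CID for the three instrumental and sample effects
#' of a real SCP acquisition, in order:
#' 1. *Enantiomer-independent offset*: if a paired measurement of the
#'    opposite enantiomer is supplied, the common offset
#'    \eqn{b = (\Delta_A + \Delta_B)/2} is removed and the antisymmetric part
#'    \eqn{(\Delta_A - \Delta_B)/2} is reported for the measurement at hand.
#' 2. *Enantiomeric excess*: the observed CID scales linearly with ee, so
#'    the offset-free value is divided by `enantiomeric_excess`.
#' 3. *Incident-beam optical rotation*: rotation of the incident linear
#'    polarization along the path through the optically active sample is
#'    modelled as a single multiplicative factor supplied by the caller
#'    (default 1, i.e. no correction).
#' Uncertainties propagate in quadrature through these linear steps.
#'
#' @param m An `scp_measurement` (from [simulate_scp()]) or a data frame
#'   with columns `delta_raw` and `sigma_delta`.
#' @param enantiomeric_excess Enantiomeric excess of the sample, in (0, 1].
#' @param rotation_correction_factor Multiplicative optical-rotation
#'   correction, >= 0 (default 1).
#' @param paired_measurement Optional measurement of the opposite enantiomer
#'   (same wavelength) used to remove the enantiomer-independent offset; must
#'   have the same number of rows as `m` or a single row.
#' @return A tibble with one row per row of `m`: `delta_raw`,
#'   `delta_corrected`, `sigma_corrected`, `offset` (NA when no pair was
#'   supplied), `enantiomeric_excess`, `rotation_correction_factor`.
#' @examples
#' cfg <- instrument_config(exposure_h = 15, count_rate_per_s = 2e5, seed = 1)
#' m <- simulate_scp(3.24e-4, cfg)
#' correct_measurement(m, enantiomeric_excess = 0.9)
#' @export
correct_measurement <- function(m, enantiomeric_excess = 1,
                                rotation_correction_factor = 1,
                                paired_measurement = NULL) {
  if (!is.data.frame(m) || !all(c("delta_raw", "sigma_delta") %in% names(m))) {
    abort("`m` must be a measurement with `delta_raw` and `sigma_delta`.",
          class = "rayoa_invalid_measurement")
  }
  ee <- enantiomeric_excess
  if (!is.numeric(ee) || length(ee) != 1 || !is.finite(ee) ||
      ee <= 0 || ee > 1) {
    abort("`enantiomeric_excess` must lie in (0, 1].",
          class = "rayoa_invalid_correction")
  }
  f <- rotation_correction_factor
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f) || f < 0) {
    abort("`rotation_correction_factor` must be >= 0.",
          class = "rayoa_invalid_correction")
  }
  delta <- m$delta_raw
  var_d <- m$sigma_delta^2
  offset <- rep(NA_real_, length(delta))
  if (!is.null(paired_measurement)) {
    p <- paired_measurement
    if (!is.data.frame(p) || !all(c("delta_raw", "sigma_delta") %in% names(p))) {
      abort("`paired_measurement` must be a measurement with `delta_raw` and `sigma_delta`.",
            class = "rayoa_invalid_measurement")
    }
    cfg_m <- attr(m, "config")
    cfg_p <- attr(p, "config")
    if (!is.null(cfg_m) && !is.null(cfg_p) &&
        cfg_m$wavelength_nm != cfg_p$wavelength_nm) {
      abort("Paired measurements must share one wavelength.",
            class = "rayoa_invalid_measurement")
    }
    if (!(nrow(p) == nrow(m) || nrow(p) == 1)) {
      abort("`paired_measurement` must have one row or as many rows as `m`.",
            class = "rayoa_invalid_measurement")
    }
    dp <- rep_len(p$delta_raw, length(delta))
    vp <- rep_len(p$sigma_delta^2, length(delta))
    offset <- (delta + dp) / 2
    delta <- (delta - dp) / 2
    var_d <- (var_d + vp) / 4
  }
  delta <- delta / ee * f
  sigma <- sqrt(var_d) / ee * f
  tibble::tibble(
    delta_raw = m$delta_raw,
    delta_corrected = delta,
    sigma_corrected = sigma,
    offset = offset,
    enantiomeric_excess = ee,
    rotation_correction_factor = f
  )
}

#' Exposure time needed to reach a target shot-noise precision
#'
#' Shot noise sets \eqn{\sigma_\Delta = 1/\sqrt{N}} for \eqn{N} accumulated
#' counts, so reaching a target precision needs
#' \eqn{N = 1/\sigma_\mathrm{target}^2} counts, i.e. an exposure of
#' \eqn{N / \mathrm{count\ rate}}. Exposure scales inversely with the count
#' rate, which is why higher powers or larger collection solid angles shorten
#' the acquisition proportionally.
#'
#' @param target_sigma Target standard error on the CID (> 0).
#' @param config An [instrument_config()] supplying the count rate.
#' @return Required exposure in hours.
#' @examples
#' cfg <- instrument_config(exposure_h = 1, count_rate_per_s = 2e5)
#' required_exposure(1e-5, cfg)
#' @export
required_exposure <- function(target_sigma, config) {
  if (!inherits(config, "instrument_config")) {
    abort("`config` must be an `instrument_config`.",
          class = "rayoa_invalid_config")
  }
  if (!is.numeric(target_sigma) || length(target_sigma) != 1 ||
      target_sigma <= 0) {
    abort("`target_sigma` must be > 0.", class = "rayoa_invalid_config")
  }
  n_required <- 1 / target_sigma^2
  n_required / config$count_rate_per_s / 3600
}
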