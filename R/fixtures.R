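#' Generate synthetic molecular property tensor sets
#'
#' Seeded generator of physically structured tensor sets so every part of
#' the pipeline can be exercised without a quantum-chemistry calculation.
#' Three families are available:
#' * `"chiral"`: a random symmetric positive-definite polarizability, a
#'   random G', and a random quadrupole tensor projected onto the
#'   symmetric-traceless subspace. G' and A are then rescaled by one common
#'   factor so the CID magnitude lands in the regime real monoterpenes
#'   occupy (1e-4 to 1e-3) — or exactly on `target_delta` when given
#'   (the CID is linear in a common scaling of G' and A at fixed alpha, so
#'   the calibration is exact).
#' * `"achiral-mirror"`: tensors constrained to commute with the reflection
#'   through the xy plane, which forces both pseudoscalar invariants — and
#'   hence the CID — to vanish identically.
#' * `"isotropic"`: alpha proportional to the identity with G' = A = 0; the
#'   depolarized CID is undefined for such a scatterer.
#'
#' The same seed always yields the bit-identical tensor set.
#'
#' @param seed Integer seed.
#' @param chirality One of `"chiral"`, `"achiral-mirror"`, `"isotropic"`.
#' @param target_delta Optional CID value the chiral fixture must produce
#'   exactly (|target_delta| < 1); an error for non-chiral families.
#' @param scale Overall tensor magnitude in atomic units (default 10,
#'   the order of a small organic molecule's polarizability anisotropy).
#' @param wavelength_nm Incident wavelength (default 532).
#' @return A `rayoa_tensor_set`.
#' @examples
#' t <- make_tensor_set(seed = 1, target_delta = 3.6e-4)
#' delta_scp90(t)
#' @export
make_tensor_set <- function(seed, chirality = c("chiral", "achiral-mirror",
                                                "isotropic"),
                            target_delta = NULL, scale = 10,
                            wavelength_nm = 532) {
  chirality <- match.arg(chirality)
  if (!is.null(target_delta)) {
    if (chirality != "chiral") {
      abort("`target_delta` can only be requested for a chiral fixture.",
            class = "rayoa_invalid_fixture")
    }
    if (!is.numeric(target_delta) || length(target_delta) != 1 ||
        abs(target_delta) >= 1) {
      abort("`target_delta` must satisfy |target_delta| < 1.",
            class = "rayoa_invalid_fixture")
    }
  }
  label <- sprintf("synthetic-%s-seed%d", chirality, as.integer(seed))

  withr::with_seed(as.integer(seed), {
    if (chirality == "isotropic") {
      return(tensor_set(diag(3) * scale, matrix(0, 3, 3), array(0, c(3, 3, 3)),
                        wavelength_nm, label = label))
    }
    if (chirality == "achiral-mirror") {
      # mirror sigma_z = diag(1, 1, -1): keep only components invariant
      # under the improper transform (polar alpha/A, axial G')
      al <- matrix(rnorm(9), 3); al <- (al + t(al)) / 2 * scale
      al[1, 3] <- al[3, 1] <- 0
      al[2, 3] <- al[3, 2] <- 0
      al <- al + diag(3) * 2 * scale   # keep it positive definite
      gp <- matrix(0, 3, 3)
      gp[1, 3] <- rnorm(1) * scale; gp[2, 3] <- rnorm(1) * scale
      gp[3, 1] <- rnorm(1) * scale; gp[3, 2] <- rnorm(1) * scale
      aq <- array(rnorm(27), c(3, 3, 3)) * scale
      s <- c(1, 1, -1)
      for (i in 1:3) for (j in 1:3) for (k in 1:3) {
        if (s[i] * s[j] * s[k] < 0) aq[i, j, k] <- 0
      }
      return(tensor_set(al, gp, project_aquad(aq), wavelength_nm,
                        label = label))
    }
    # chiral: random PD alpha, random G' and A, then one common rescaling
    # of the chirally sensitive tensors to set the CID magnitude
    m <- matrix(rnorm(9), 3)
    al <- crossprod(m) / 3 * scale + diag(3) * scale / 2
    gp <- matrix(rnorm(9), 3) * scale
    aq <- project_aquad(array(rnorm(27), c(3, 3, 3)) * scale)
    t0 <- tensor_set(al, gp, aq, wavelength_nm, label = label)
    delta0 <- (24 * beta_g2(t0) - 8 * beta_a2(t0)) /
      (12 * beta2(t0) * rayoa_constants$c_au)
    target <- if (is.null(target_delta)) {
      sign(delta0) * 10^runif(1, -4, -3)
    } else {
      target_delta
    }
    f <- target / delta0
    tensor_set(al, gp * f, aq * f, wavelength_nm, label = label)
  })
}

#' Generate an enantiomer pair of synthetic tensor sets
#'
#' The second member is the improper-transform (inversion) image of the
#' first, so the pair's CIDs are exact negatives and their beta^2 values are
#' identical — the tensor-level statement that enantiomers give equal
#' magnitudes and opposite signs.
#'
#' @inheritParams make_tensor_set
#' @return A list with elements `plus` and `minus`, two `rayoa_tensor_set`s
#'   related by the enantiomer map. `plus` carries the CID sign of
#'   `target_delta` (or the random draw).
#' @examples
#' pair <- make_enantiomer_pair(seed = 3, target_delta = 3.6e-4)
#' c(delta_scp90(pair$plus)$delta, delta_scp90(pair$minus)$delta)
#' @export
make_enantiomer_pair <- function(seed, target_delta = NULL, scale = 10,
                                 wavelength_nm = 532) {
  t1 <- make_tensor_set(seed, chirality = "chiral",
                        target_delta = target_delta, scale = scale,
                        wavelength_nm = wavelength_nm)
  t2 <- enantiomer(t1)
  t2$label <- paste0(t1$label, "-enantiomer")
  list(plus = t1, minus = t2)
}
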