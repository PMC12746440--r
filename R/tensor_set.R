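#' Molecular property tensor set
#'
#' Container for the three molecular property tensors that determine Rayleigh
#' optical activity far off resonance: the electric dipole-electric dipole
#' polarizability `alpha` (3x3, symmetric), the electric dipole-magnetic
#' dipole optical activity tensor `gprime` (G', 3x3), and the electric
#' dipole-electric quadrupole tensor `aquad` (A, 3x3x3, indexed
#' `A[i, j, k]` with `(j, k)` the quadrupole pair, symmetric and traceless in
#' those two indices). All values are in Hartree atomic units, as produced by
#' quantum-chemistry response calculations.
#'
#' Finite-precision electronic-structure output rarely satisfies the index
#' symmetries exactly, so the constructor always projects: `alpha` is
#' symmetrized, and `aquad` is symmetrized over its last two indices and has
#' its trace over them removed. When the relative magnitude of the projection
#' exceeds `sym_tol` a warning reports it; below the tolerance the projection
#' is silent.
#'
#' @param alpha 3x3 numeric matrix, polarizability (a.u.).
#' @param gprime 3x3 numeric matrix, G' tensor (a.u.).
#' @param aquad 3x3x3 numeric array, A tensor (a.u.).
#' @param wavelength_nm Incident wavelength in nanometres; the angular
#'   frequency `omega` (a.u.) is derived from it.
#' @param label Free-text provenance (e.g. "CAM-B3LYP/aug-cc-pVTZ").
#' @param sym_tol Relative Frobenius tolerance above which symmetry
#'   violations in the input are reported (default `1e-6`).
#' @return An object of class `rayoa_tensor_set`: a list with elements
#'   `alpha`, `gprime`, `aquad`, `omega`, `wavelength_nm`, `label`.
#' @examples
#' t <- make_tensor_set(seed = 1)
#' t
#' @seealso [compute_invariants()], [transform_tensors()], [make_tensor_set()]
#' @export
tensor_set <- function(alpha, gprime, aquad, wavelength_nm, label = "",
                       sym_tol = 1e-6) {
  alpha <- check_matrix3(alpha, "alpha")
  gprime <- check_matrix3(gprime, "gprime")
  if (!is.array(aquad) || !identical(dim(aquad), c(3L, 3L, 3L)) ||
      !is.numeric(aquad) || any(!is.finite(aquad))) {
    abort("`aquad` must be a finite numeric 3x3x3 array.",
          class = "rayoa_invalid_tensor")
  }

  # symmetrize alpha, report if the asymmetric part is large
  asym <- alpha - t(alpha)
  rel <- frob(asym) / max(frob(alpha), .Machine$double.eps)
  if (rel > sym_tol) {
    warn(sprintf(
      "alpha is asymmetric (relative Frobenius %.3g > sym_tol %.3g); symmetrized.",
      rel, sym_tol))
  }
  alpha <- (alpha + t(alpha)) / 2

  # project A onto the symmetric-traceless subspace of its quadrupole pair
  aq_proj <- project_aquad(aquad)
  rel_a <- frob(aquad - aq_proj) / max(frob(aquad), .Machine$double.eps)
  if (rel_a > sym_tol) {
    warn(sprintf(
      "aquad violates quadrupole-pair symmetry/tracelessness (relative Frobenius %.3g > sym_tol %.3g); projected.",
      rel_a, sym_tol))
  }

  structure(
    list(
      alpha = alpha,
      gprime = gprime,
      aquad = aq_proj,
      omega = wavelength_to_omega(wavelength_nm),
      wavelength_nm = wavelength_nm,
      label = as.character(label)
    ),
    class = "rayoa_tensor_set"
  )
}

check_matrix3 <- function(m, name) {
  m <- unclass(m)
  if (!is.matrix(m) || !identical(dim(m), c(3L, 3L)) || !is.numeric(m) ||
      any(!is.finite(m))) {
    abort(sprintf("`%s` must be a finite numeric 3x3 matrix.", name),
          class = "rayoa_invalid_tensor")
  }
  storage.mode(m) <- "double"
  m
}

frob <- function(x) sqrt(sum(x^2))

# symmetrize A over its last two indices and remove the trace over them
project_aquad <- function(a) {
  sym <- (a + aperm(a, c(1, 3, 2))) / 2
  tr <- sym[, 1, 1] + sym[, 2, 2] + sym[, 3, 3]
  for (j in 1:3) sym[, j, j] <- sym[, j, j] - tr / 3
  sym
}

#' @export
print.rayoa_tensor_set <- function(x, ...) {
  cat("<rayoa_tensor_set>\n")
  cat(sprintf("  wavelength: %g nm (omega = %.6g a.u.)\n",
              x$wavelength_nm, x$omega))
  if (nzchar(x$label)) cat(sprintf("  label: %s\n", x$label))
  cat(sprintf("  |alpha| = %.4g, |G'| = %.4g, |A| = %.4g (Frobenius, a.u.)\n",
              frob(x$alpha), frob(x$gprime), frob(x$aquad)))
  invisible(x)
}

is_tensor_set <- function(x) inherits(x, "rayoa_tensor_set")

stopifnot_tensor_set <- function(t) {
  if (!is_tensor_set(t)) {
    abort("Expected a `rayoa_tensor_set` (see `tensor_set()`).",
          class = "rayoa_invalid_tensor")
  }
  invisible(t)
}
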