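#' Rotational invariants of the property tensors
#'
#' The three anisotropy invariants that control depolarized right-angle
#' Rayleigh optical activity, in the normalization that makes the circular
#' intensity differential dimensionless with a single 1/c prefactor
#' (tensors in Hartree atomic units):
#' \deqn{\beta^2 = \tfrac{1}{2}\,(3\,\alpha_{ij}\alpha_{ij} - \alpha_{ii}\alpha_{jj})}
#' \deqn{\beta(G')^2 = \tfrac{1}{2}\,(3\,\alpha_{ij}G'_{ij} - \alpha_{ii}G'_{jj})}
#' \deqn{\beta(A)^2 = \tfrac{\omega}{2}\,\alpha_{ij}\,\epsilon_{ikl}\,A_{klj}}
#' (summation over repeated indices; \eqn{\epsilon} the rank-3 antisymmetric
#' symbol). The frequency factor \eqn{\omega} lives inside \eqn{\beta(A)^2}
#' so that it is directly commensurable with \eqn{\beta(G')^2}. All three are
#' invariant under proper rotations; \eqn{\beta(G')^2} and \eqn{\beta(A)^2}
#' are pseudoscalars that flip sign under improper transforms (and hence
#' vanish for achiral molecules), while \eqn{\beta^2 \ge 0} is parity even.
#'
#' @param t A `rayoa_tensor_set`.
#' @return `beta2()`, `beta_g2()`, `beta_a2()` return scalars (a.u.).
#'   `compute_invariants()` returns an object of class `rayoa_invariants`:
#'   a list with `beta2`, `betaG2`, `betaA2`, `alpha_iso` (mean
#'   polarizability, diagnostic), `omega`, `wavelength_nm`, `label`.
#' @examples
#' t <- make_tensor_set(seed = 1)
#' compute_invariants(t)
#' @seealso [delta_scp90()] for the circular intensity differential.
#' @name invariants
NULL

#' @rdname invariants
#' @export
beta2 <- function(t) {
  stopifnot_tensor_set(t)
  a <- t$alpha
  0.5 * (3 * sum(a * a) - sum(diag(a))^2)
}

#' @rdname invariants
#' @export
beta_g2 <- function(t) {
  stopifnot_tensor_set(t)
  0.5 * (3 * sum(t$alpha * t$gprime) -
           sum(diag(t$alpha)) * sum(diag(t$gprime)))
}

#' @rdname invariants
#' @export
beta_a2 <- function(t) {
  stopifnot_tensor_set(t)
  if (!is.finite(t$omega) || t$omega <= 0) {
    abort("`omega` must be positive to evaluate the quadrupole invariant.",
          class = "rayoa_invalid_frequency")
  }
  a <- t$alpha
  aq <- t$aquad
  # alpha_ij eps_ikl A_klj over the six nonzero entries of eps
  s <- 0
  perms <- list(c(1, 2, 3, 1), c(2, 3, 1, 1), c(3, 1, 2, 1),
                c(3, 2, 1, -1), c(1, 3, 2, -1), c(2, 1, 3, -1))
  for (p in perms) {
    i <- p[1]; k <- p[2]; l <- p[3]; sgn <- p[4]
    for (j in 1:3) s <- s + sgn * a[i, j] * aq[k, l, j]
  }
  (t$omega / 2) * s
}

#' @rdname invariants
#' @export
compute_invariants <- function(t) {
  stopifnot_tensor_set(t)
  structure(
    list(
      beta2 = beta2(t),
      betaG2 = beta_g2(t),
      betaA2 = beta_a2(t),
      alpha_iso = sum(diag(t$alpha)) / 3,
      omega = t$omega,
      wavelength_nm = t$wavelength_nm,
      label = t$label
    ),
    class = "rayoa_invariants"
  )
}

#' @export
print.rayoa_invariants <- function(x, ...) {
  cat("<rayoa_invariants> (Hartree atomic units)\n")
  cat(sprintf("  beta^2      = %.8g\n", x$beta2))
  cat(sprintf("  beta(G')^2  = %.8g\n", x$betaG2))
  cat(sprintf("  beta(A)^2   = %.8g\n", x$betaA2))
  cat(sprintf("  alpha_iso   = %.8g\n", x$alpha_iso))
  cat(sprintf("  at %g nm", x$wavelength_nm))
  if (nzchar(x$label)) cat(sprintf("  [%s]", x$label))
  cat("\n")
  invisible(x)
}

#' Tidy a set of rotational invariants into a one-row tibble
#'
#' @param x A `rayoa_invariants` object.
#' @param ... Unused.
#' @return A one-row tibble with columns `beta2`, `betaG2`, `betaA2`,
#'   `alpha_iso`, `omega`, `wavelength_nm`, `label`.
#' @export
tidy.rayoa_invariants <- function(x, ...) {
  tibble::tibble(
    beta2 = x$beta2, betaG2 = x$betaG2, betaA2 = x$betaA2,
    alpha_iso = x$alpha_iso, omega = x$omega,
    wavelength_nm = x$wavelength_nm, label = x$label
  )
}
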