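#' Spatial transformations of property tensors
#'
#' A `spatial_transform` is a real orthogonal 3x3 matrix, proper
#' (determinant +1, a rotation) or improper (determinant -1, a
#' rotation-reflection). Improper transforms realize the enantiomer map: a
#' chiral molecule's mirror image has property tensors obtained by an
#' improper transform, under which the chirally sensitive invariants and the
#' circular intensity differential flip sign while the ordinary anisotropy is
#' unchanged ("equal magnitudes but opposite signs for enantiomers").
#'
#' @param matrix 3x3 real orthogonal matrix.
#' @param tol Orthogonality tolerance (default `1e-12` on the Frobenius
#'   norm of `M M^T - I` and on `|det| - 1`).
#' @return An object of class `rayoa_transform` with elements `matrix` and
#'   `determinant` (+1 or -1 exactly).
#' @examples
#' g <- spatial_transform(diag(3))         # identity
#' inv <- spatial_transform(-diag(3))      # inversion: the enantiomer map
#' inv$determinant
#' @export
spatial_transform <- function(matrix, tol = 1e-12) {
  m <- check_matrix3(matrix, "matrix")
  if (frob(m %*% t(m) - diag(3)) > tol) {
    abort("Transform matrix is not orthogonal within tolerance.",
          class = "rayoa_invalid_transform")
  }
  d <- det(m)
  if (abs(abs(d) - 1) > tol) {
    abort("Transform determinant is not +/-1 within tolerance.",
          class = "rayoa_invalid_transform")
  }
  structure(list(matrix = m, determinant = if (d > 0) 1 else -1),
            class = "rayoa_transform")
}

#' Draw a uniformly random proper rotation
#'
#' QR-based Haar sampling on SO(3); used by the rotation-invariance property
#' checks. Consumes the current RNG stream.
#'
#' @return A `rayoa_transform` with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  spatial_transform(q)
}

#' Transform a tensor set by a rotation or improper rotation
#'
#' Applies the exact transformation laws of the three property tensors under
#' an orthogonal transformation `R`:
#' \deqn{\alpha'_{ij} = R_{ia} R_{jb} \alpha_{ab}}
#' \deqn{A'_{ijk} = R_{ia} R_{jb} R_{kc} A_{abc}}
#' \deqn{G''_{ij} = \det(R)\, R_{ia} R_{jb} G'_{ab}}
#' G' transforms as an axial (pseudo) rank-2 tensor, hence the
#' \eqn{\det(R)} factor; under the inversion \eqn{R = -I} this gives
#' \eqn{\alpha' = \alpha}, \eqn{G'' = -G'}, \eqn{A' = -A}, so the circular
#' intensity differential of the image (the enantiomer) is the exact
#' negative. The wavelength and frequency are unchanged.
#'
#' @param t A `rayoa_tensor_set`.
#' @param g A `rayoa_transform` (see [spatial_transform()]); passing a raw
#'   3x3 matrix validates it first.
#' @return The transformed `rayoa_tensor_set`.
#' @examples
#' t <- make_tensor_set(seed = 7)
#' t_img <- transform_tensors(t, spatial_transform(-diag(3)))
#' @export
transform_tensors <- function(t, g) {
  stopifnot_tensor_set(t)
  if (!inherits(g, "rayoa_transform")) g <- spatial_transform(g)
  r <- g$matrix
  out <- t
  out$alpha <- r %*% t$alpha %*% base::t(r)
  out$gprime <- g$determinant * (r %*% t$gprime %*% base::t(r))
  out$aquad <- rotate_rank3(t$aquad, r)
  out
}

# A'_{ijk} = R_{ia} R_{jb} R_{kc} A_{abc} via successive mode products
rotate_rank3 <- function(a, r) {
  out <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    s <- 0
    for (aa in 1:3) for (bb in 1:3) for (cc in 1:3) {
      s <- s + r[i, aa] * r[j, bb] * r[k, cc] * a[aa, bb, cc]
    }
    out[i, j, k] <- s
  }
  out
}

#' Enantiomer (mirror image) of a tensor set
#'
#' Convenience wrapper applying the inversion `-I` (an improper transform) to
#' the tensor set: alpha is unchanged, G' and A flip sign, and the predicted
#' circular intensity differential of the result is the exact negative.
#'
#' @param t A `rayoa_tensor_set`.
#' @return The enantiomer's `rayoa_tensor_set`.
#' @export
enantiomer <- function(t) {
  transform_tensors(t, spatial_transform(-diag(3)))
}

#' Refer the property tensors to a shifted origin
#'
#' The polarizability is origin independent, but G' and A are not: under a
#' shift of the multipole origin by `displacement` `d` (a.u.) they transform
#' by the standard translation rules of molecular light-scattering theory,
#' \deqn{G'_{ij} \to G'_{ij} - \tfrac{\omega}{2}\,\epsilon_{jkl}\, d_k\, \alpha_{il}}
#' \deqn{A_{ijk} \to A_{ijk} - \tfrac{3}{2} d_j \alpha_{ik}
#'       - \tfrac{3}{2} d_k \alpha_{ij} + \delta_{jk}\, d_l\, \alpha_{il}}
#' For a symmetric polarizability the origin-dependent parts cancel exactly
#' in the anisotropy invariants, so \eqn{\beta(G')^2} and \eqn{\beta(A)^2}
#' (and hence the circular intensity differential) are origin invariant; this
#' operation exists to exercise that cancellation. The cancellation requires
#' symmetric alpha, so an asymmetric alpha beyond `tol` is an error.
#'
#' @param t A `rayoa_tensor_set`.
#' @param displacement Numeric 3-vector, origin shift in bohr.
#' @param tol Relative Frobenius tolerance on the asymmetry of alpha
#'   (default `1e-10`; the constructor has already symmetrized, so this only
#'   triggers on tensor sets modified by hand).
#' @return The tensor set referred to the shifted origin.
#' @export
shift_origin <- function(t, displacement, tol = 1e-10) {
  stopifnot_tensor_set(t)
  d <- as.numeric(displacement)
  if (length(d) != 3 || any(!is.finite(d))) {
    abort("`displacement` must be a finite numeric 3-vector.",
          class = "rayoa_invalid_tensor")
  }
  asym <- frob(t$alpha - base::t(t$alpha)) /
    max(frob(t$alpha), .Machine$double.eps)
  if (asym > tol) {
    abort("`shift_origin()` requires a symmetric alpha: the invariant cancellation fails otherwise.",
          class = "rayoa_asymmetric_alpha")
  }
  al <- t$alpha
  gp <- t$gprime
  aq <- t$aquad
  eps <- levi_civita()
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (k in 1:3) for (l in 1:3) s <- s + eps[j, k, l] * d[k] * al[i, l]
    gp[i, j] <- gp[i, j] - (t$omega / 2) * s
  }
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    aq[i, j, k] <- aq[i, j, k] -
      1.5 * d[j] * al[i, k] - 1.5 * d[k] * al[i, j] +
      (if (j == k) sum(d * al[i, ]) else 0)
  }
  out <- t
  out$gprime <- gp
  out$aquad <- aq
  out
}

# rank-3 antisymmetric (Levi-Civita) symbol as a 3x3x3 array
levi_civita <- function() {
  e <- array(0, c(3, 3, 3))
  e[1, 2, 3] <- e[2, 3, 1] <- e[3, 1, 2] <- 1
  e[3, 2, 1] <- e[1, 3, 2] <- e[2, 1, 3] <- -1
  e
}
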