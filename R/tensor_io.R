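#' Read and write molecular tensor files
#'
#' Tensor sets are exchanged as a small JSON document with keys
#' `wavelength_nm`, `alpha` (9 numbers, row-major), `gprime` (9, row-major),
#' `aquad` (27, row-major over the indices i, j, k), `units` (must be
#' `"au"`), and `label`. Numbers are written at full IEEE double precision
#' (17 significant digits), so a write/read round trip reproduces the tensor
#' set bit for bit. This is the package's own interchange format for tensor
#' values exported from any quantum-chemistry program.
#'
#' Sign conventions for G' differ between electronic-structure codes, and a
#' globally wrong sign flips every predicted CID; `gprime_sign` (+1 default)
#' lets data from a code with the opposite convention be ingested without
#' editing the file.
#'
#' @param t A `rayoa_tensor_set`.
#' @param path File path.
#' @param gprime_sign +1 or -1, multiplied into G' on read.
#' @param sym_tol Symmetry-projection reporting tolerance passed to
#'   [tensor_set()].
#' @return `write_tensor_set()` returns `path` invisibly;
#'   `read_tensor_set()` returns a `rayoa_tensor_set`.
#' @examples
#' t <- make_tensor_set(seed = 1)
#' f <- tempfile(fileext = ".json")
#' write_tensor_set(t, f)
#' identical(read_tensor_set(f)$alpha, t$alpha)
#' @name tensor_io
NULL

#' @rdname tensor_io
#' @export
write_tensor_set <- function(t, path) {
  stopifnot_tensor_set(t)
  doc <- list(
    wavelength_nm = t$wavelength_nm,
    alpha = as.vector(base::t(t$alpha)),                 # row-major
    gprime = as.vector(base::t(t$gprime)),               # row-major
    aquad = as.vector(aperm(t$aquad, c(3, 2, 1))),       # row-major i,j,k
    units = "au",
    label = t$label
  )
  # I(17) forces 17 significant digits so doubles survive the round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname tensor_io
#' @export
read_tensor_set <- function(path, gprime_sign = 1, sym_tol = 1e-6) {
  if (!gprime_sign %in% c(1, -1)) {
    abort("`gprime_sign` must be +1 or -1.", class = "rayoa_invalid_tensor")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("wavelength_nm", "alpha", "gprime", "aquad", "units")
  missing <- setdiff(needed, names(doc))
  if (length(missing)) {
    abort(sprintf("Tensor file is missing key(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "rayoa_invalid_tensor_file")
  }
  if (!identical(doc$units, "au")) {
    abort("Tensor file `units` must be \"au\" (Hartree atomic units).",
          class = "rayoa_invalid_tensor_file")
  }
  if (length(doc$alpha) != 9 || length(doc$gprime) != 9 ||
      length(doc$aquad) != 27) {
    abort("Tensor file must hold 9 alpha, 9 gprime and 27 aquad values.",
          class = "rayoa_invalid_tensor_file")
  }
  alpha <- matrix(as.numeric(doc$alpha), 3, 3, byrow = TRUE)
  gprime <- gprime_sign * matrix(as.numeric(doc$gprime), 3, 3, byrow = TRUE)
  aquad <- aperm(array(as.numeric(doc$aquad), c(3, 3, 3)), c(3, 2, 1))
  tensor_set(alpha, gprime, aquad, wavelength_nm = as.numeric(doc$wavelength_nm),
             label = doc$label %||% "", sym_tol = sym_tol)
}
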