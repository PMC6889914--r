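#' Unit cell
#'
#' Construct a crystallographic unit cell.  Lengths are in Angstrom, angles
#' in degrees.  The cell volume and the standard orthogonalization matrix
#' (cell axis \eqn{a} along Cartesian x) are derived on construction.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with elements `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, `volume` (Angstrom^3), `orth` (3x3
#'   fractional-to-Cartesian matrix) and `frac` (its inverse).
#' @examples
#' cl <- unit_cell(42.80, 42.80, 253.78)
#' cl$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0))
    stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("degenerate cell: zero or imaginary volume")
  vol <- a * b * c * sqrt(disc)
  # standard PDB/CCP4 orthogonalization: a along x, b in the xy plane
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      vol / (a * b * sg)), nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 volume = vol, orth = orth, frac = solve(orth)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell %.3f %.3f %.3f  %.2f %.2f %.2f  V = %.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Fractional to Cartesian coordinates
#'
#' @param cell A [unit_cell()].
#' @param frac Fractional coordinates: a length-3 vector or an n x 3 matrix.
#' @return Cartesian coordinates in Angstrom, same shape as the input.
#' @export
orthogonalize <- function(cell, frac) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.null(dim(frac))) {
    stopifnot(length(frac) == 3)
    drop(cell$orth %*% frac)
  } else {
    t(cell$orth %*% t(frac))
  }
}

#' Cartesian to fractional coordinates
#'
#' Inverse of [orthogonalize()].
#'
#' @param cell A [unit_cell()].
#' @param xyz Cartesian coordinates in Angstrom: length-3 vector or n x 3 matrix.
#' @return Fractional coordinates, same shape as the input.
#' @export
fractionalize <- function(cell, xyz) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.null(dim(xyz))) {
    stopifnot(length(xyz) == 3)
    drop(cell$frac %*% xyz)
  } else {
    t(cell$frac %*% t(xyz))
  }
}

#' Resolution of reflections
#'
#' d-spacing for Miller indices under a given cell, from the reciprocal
#' metric tensor.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @return Numeric vector of d-spacings in Angstrom (`Inf` for (0,0,0)).
#' @export
d_spacing <- function(cell, hkl) {
  hkl <- rbind(hkl)
  gstar <- crossprod(cell$frac)          # reciprocal metric tensor
  q <- rowSums((hkl %*% gstar) * hkl)    # 1/d^2
  ifelse(q > 0, 1 / sqrt(q), Inf)
}
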