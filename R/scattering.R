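## Atomic scattering: Cromer-Mann f0, tabulated anomalous corrections f'/f''
## and absorption-edge energies for the elements present in the simulated
## crystals (C, N, O, S, Cl, Zn, I).  Tables ship as plain text under
## inst/extdata so they are auditable and replaceable.

.anomsite_cache <- new.env(parent = emptyenv())

#' keV. Angstrom conversion constant (hc)
#' @export
KEV_ANGSTROM <- 12.39842

.table_path <- function(name) {
  p <- system.file("extdata", name, package = "anomsite")
  if (!nzchar(p)) stop("bundled table ", name, " not found")
  p
}

.anom_table <- function() {
  if (is.null(.anomsite_cache$anom))
    .anomsite_cache$anom <- utils::read.delim(.table_path("anomalous.tsv"))
  .anomsite_cache$anom
}

.edge_table <- function() {
  if (is.null(.anomsite_cache$edges))
    .anomsite_cache$edges <- utils::read.delim(.table_path("edges.tsv"))
  .anomsite_cache$edges
}

.cm_table <- function() {
  if (is.null(.anomsite_cache$cm))
    .anomsite_cache$cm <- utils::read.delim(.table_path("cromer_mann.tsv"))
  .anomsite_cache$cm
}

#' Convert photon energy to wavelength
#'
#' \eqn{\lambda = 12.39842 / E} with E in keV and \eqn{\lambda} in Angstrom.
#'
#' @param energy_kev Photon energy in keV; must be positive.
#' @return Wavelength in Angstrom.
#' @examples
#' energy_to_wavelength(5.2)   # 2.3843
#' @export
energy_to_wavelength <- function(energy_kev) {
  if (any(energy_kev <= 0)) stop("energy must be positive")
  KEV_ANGSTROM / energy_kev
}

#' Convert wavelength to photon energy
#' @param lambda_ang Wavelength in Angstrom; must be positive.
#' @return Energy in keV.
#' @export
wavelength_to_energy <- function(lambda_ang) {
  if (any(lambda_ang <= 0)) stop("wavelength must be positive")
  KEV_ANGSTROM / lambda_ang
}

#' Absorption-edge energy
#'
#' @param element Chemical symbol.
#' @param edge Edge label: `"K"`, `"L_I"`, `"L_II"` or `"L_III"`.
#' @return Edge energy in keV.
#' @examples
#' edge_energy("I", "L_I")   # 5.188 keV
#' @export
edge_energy <- function(element, edge) {
  tb <- .edge_table()
  hit <- tb$element == element & tb$edge == edge
  if (!any(hit)) stop("no tabulated ", edge, " edge for element ", element)
  tb$energy_kev[hit][1]
}

.element_edges_in <- function(element, lo, hi) {
  tb <- .edge_table()
  e <- tb$energy_kev[tb$element == element]
  e[e > lo & e < hi]
}

#' Anomalous scattering coefficients f' and f''
#'
#' Interpolates the bundled per-element table, linearly in log(energy),
#' never across an absorption-edge discontinuity (the tables carry samples
#' a few eV on either side of each in-range edge).  Energies falling inside
#' the narrow edge gap require `side` to pick a branch.
#'
#' @param element Chemical symbol (one of C, N, O, S, Cl, Zn, I).
#' @param energy_kev Photon energy in keV, within the tabulated range.
#' @param side `"above"` or `"below"`, required only when `energy_kev` lies
#'   within the sampling gap that brackets an edge.
#' @return Named numeric vector `c(f_prime = , f_double_prime = )` in electrons.
#' @examples
#' anomalous_coefficients("I", 5.2)["f_double_prime"]   # 13.41 e-
#' @export
anomalous_coefficients <- function(element, energy_kev, side = NULL) {
  tb <- .anom_table()
  tb <- tb[tb$element == element, ]
  if (!nrow(tb)) stop("no anomalous table for element ", element)
  e <- tb$energy_kev
  if (energy_kev < min(e) || energy_kev > max(e))
    stop(sprintf("energy %.4f keV outside tabulated range [%.3f, %.3f] for %s",
                 energy_kev, min(e), max(e), element))
  i <- findInterval(energy_kev, e, rightmost.closed = TRUE)
  lo <- e[i]; hi <- e[min(i + 1, length(e))]
  edges_between <- .element_edges_in(element, lo - 1e-9, hi + 1e-9)
  if (length(edges_between) && lo != hi) {
    # inside the edge gap: caller must pick a branch
    if (is.null(side))
      stop(sprintf("%.4f keV is at the %s absorption edge; pass side = 'above' or 'below'",
                   energy_kev, element))
    i <- if (identical(side, "above")) i + 1 else i
    return(c(f_prime = tb$f_prime[i], f_double_prime = tb$f_double_prime[i]))
  }
  if (lo == hi) {
    w <- 0
  } else {
    w <- (log(energy_kev) - log(lo)) / (log(hi) - log(lo))
  }
  fp <- (1 - w) * tb$f_prime[i] + w * tb$f_prime[min(i + 1, nrow(tb))]
  fdp <- (1 - w) * tb$f_double_prime[i] + w * tb$f_double_prime[min(i + 1, nrow(tb))]
  c(f_prime = fp, f_double_prime = max(fdp, 0))
}

#' Absorption-edge contrast ratio
#'
#' Ratio of f'' just above to f'' just below an edge-bracketing energy pair:
#' the factor by which an element's anomalous signal is expected to drop
#' when data are collected below its edge.
#'
#' @param element Chemical symbol.
#' @param e_above,e_below Energies in keV (above-edge first).
#' @return Dimensionless ratio; `Inf` when f'' below is zero.
#' @examples
#' edge_contrast_ratio("I", 5.2, 4.5)   # ~3.9
#' @export
edge_contrast_ratio <- function(element, e_above, e_below) {
  fa <- anomalous_coefficients(element, e_above)[["f_double_prime"]]
  fb <- anomalous_coefficients(element, e_below)[["f_double_prime"]]
  if (fb == 0) return(Inf)
  fa / fb
}

#' Cromer-Mann form factor f0(s)
#'
#' Four-Gaussian-plus-constant parameterization of the elastic atomic
#' scattering factor, with \eqn{s = \sin\theta/\lambda} in 1/Angstrom.
#'
#' @param element Chemical symbol.
#' @param s Numeric vector of sin(theta)/lambda values (1/Angstrom).
#' @return f0 in electrons, same length as `s`.
#' @export
form_factor_f0 <- function(element, s) {
  cm <- .cm_table()
  row <- cm[cm$element == element, ]
  if (!nrow(row)) stop("no Cromer-Mann coefficients for element ", element)
  s2 <- s^2
  row$a1 * exp(-row$b1 * s2) + row$a2 * exp(-row$b2 * s2) +
    row$a3 * exp(-row$b3 * s2) + row$a4 * exp(-row$b4 * s2) + row$c
}

#' Elements with bundled scattering tables
#' @return Character vector of chemical symbols.
#' @export
bundled_elements <- function() sort(unique(.anom_table()$element))
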