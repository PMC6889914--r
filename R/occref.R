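## Multi-start occupancy/ADP estimation for a single anomalous site.
## Many random (occ, B) starting points are each refined for a fixed number
## of Gauss-Newton cycles against |F_obs| with all other sites held at
## their model values; the 2D histogram of the converged values is the
## readout, exposing the occupancy-B degeneracy that a single refinement
## would hide.

#' Multi-start occupancy/B refinement of one site
#'
#' For each start, occupancy and isotropic B of the named site are drawn
#' uniformly from `ranges` and refined by bounded Gauss-Newton
#' (occ in `[0, 1]`, B in `[1, 300]` Angstrom^2) on the weighted
#' least-squares amplitude target over both Friedel mates, for exactly
#' `n_cycles` cycles with no early stopping.  Converged values are binned
#' on a 50 x 50 (occ, B) histogram; the reported point estimate is the
#' maximal bin's centre (the mode), with the mean alongside.
#'
#' @param refl Observed [reflection_set()] (weights 1/sigma^2; unit weights
#'   when sigmas are zero).
#' @param model A [crystal_model()] supplying every other site's parameters
#'   and the target site's position.
#' @param site_label Label of the (probe) site to refine.
#' @param energy_kev Energy of the dataset, for the anomalous coefficients.
#' @param n_starts Number of random starts (protocol default 10000; a few
#'   hundred give the same histogram structure).
#' @param n_cycles Refinement cycles per start (default 50).
#' @param ranges Start ranges `c(occ_lo, occ_hi, b_lo, b_hi)`.
#' @param seed Seed for the start draw.
#' @param nbins Histogram bins per axis.
#' @param gn_damping Relative Levenberg damping added to the Gauss-Newton
#'   normal matrix (fraction of its trace).  The occupancy-B normal matrix
#'   is nearly singular along the occupancy/B trade-off; damping makes
#'   convergence slow along that valley, so after a fixed cycle count the
#'   converged starts trace out the degeneracy ridge instead of collapsing
#'   to a single point.
#' @return Object of class `occupancy_estimate`: `occ_mode`, `b_mode`,
#'   `occ_mean`, `b_mean`, `histogram` (nbins x nbins counts),
#'   `occ_breaks`, `b_breaks`, `converged` (per-start values), `ranges`,
#'   `n_starts`, `n_cycles`, `site_label`.
#' @export
multistart_refine <- function(refl, model, site_label, energy_kev,
                              n_starts = 10000, n_cycles = 50,
                              ranges = c(occ_lo = 0.01, occ_hi = 1.0,
                                         b_lo = 10, b_hi = 250),
                              seed = 1, nbins = 50, gn_damping = 1e-4) {
  idx <- match(site_label, model$sites$label)
  if (is.na(idx)) stop("no site labelled '", site_label, "' in the model")
  hkl <- refl$hkl
  s2 <- 1 / (4 * refl$d^2)

  rest <- .sf_kernel(model, hkl, energy_kev, anomalous = TRUE,
                     site_idx = setdiff(seq_len(nrow(model$sites)), idx))
  # per-reflection complex basis of the target site at occ = 1, B = 0
  site1 <- model$sites[idx, , drop = FALSE]
  basis_model <- model
  basis_model$sites <- transform(site1, occupancy = 1, b_iso = 0)
  g <- .sf_kernel(basis_model, hkl, energy_kev, anomalous = TRUE)

  fobs <- c(refl$f_plus, refl$f_minus)
  sig <- c(refl$sig_plus, refl$sig_minus)
  w <- if (all(sig == 0)) rep(1, length(fobs)) else 1 / pmax(sig, 1e-12)^2
  frest <- c(rest[, 1], rest[, 2])
  gsite <- c(g[, 1], g[, 2])
  s2d <- c(s2, s2)
  ok <- is.finite(fobs)
  conv <- local_seed(seed, {
    occ0 <- stats::runif(n_starts, ranges[["occ_lo"]], ranges[["occ_hi"]])
    b0 <- stats::runif(n_starts, ranges[["b_lo"]], ranges[["b_hi"]])
    cpp_multistart_gn(fobs[ok], w[ok], frest[ok], gsite[ok], s2d[ok],
                      occ0, b0, as.integer(n_cycles), 0, 1, 1, 300,
                      gn_damping)
  })
  good <- is.finite(conv[, 1]) & is.finite(conv[, 2])
  conv <- conv[good, , drop = FALSE]
  if (!nrow(conv)) stop("all refinement starts diverged; estimate invalid")
  occ_breaks <- seq(0, 1, length.out = nbins + 1)
  b_breaks <- seq(1, 300, length.out = nbins + 1)
  io <- pmin(pmax(findInterval(conv[, 1], occ_breaks, rightmost.closed = TRUE), 1), nbins)
  ib <- pmin(pmax(findInterval(conv[, 2], b_breaks, rightmost.closed = TRUE), 1), nbins)
  hist2 <- matrix(0L, nbins, nbins)
  for (k in seq_len(nrow(conv))) hist2[io[k], ib[k]] <- hist2[io[k], ib[k]] + 1L
  top <- arrayInd(which.max(hist2), dim(hist2))
  structure(list(
    site_label = site_label,
    occ_mode = mean(occ_breaks[top[1] + 0:1]),
    b_mode = mean(b_breaks[top[2] + 0:1]),
    occ_mean = mean(conv[, 1]), b_mean = mean(conv[, 2]),
    histogram = hist2, occ_breaks = occ_breaks, b_breaks = b_breaks,
    converged = conv, ranges = ranges,
    n_starts = n_starts, n_cycles = n_cycles,
    n_failed = sum(!good)), class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf("occupancy estimate for %s: mode (occ, B) = (%.3f, %.0f), mean = (%.3f, %.0f), %d starts\n",
              x$site_label, x$occ_mode, x$b_mode, x$occ_mean, x$b_mean,
              x$n_starts))
  invisible(x)
}

#' Export an occupancy histogram as text
#'
#' Dense count matrix as TSV plus a JSON metadata sidecar (ranges, modes,
#' start counts).
#'
#' @param est An [multistart_refine()] result.
#' @param path Output stem; writes `<path>.tsv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_occupancy_histogram <- function(est, path) {
  utils::write.table(est$histogram, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- est[c("site_label", "occ_mode", "b_mode", "occ_mean", "b_mean",
                "ranges", "n_starts", "n_cycles", "n_failed")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
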