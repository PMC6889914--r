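## Phased anomalous difference Fourier synthesis and sigma-normalized peak
## search.  Coefficients are dF(h) = |F+| - |F-| with phase phi(h) - 90
## degrees; the map is real by Hermitian completion and is normalized by
## the cell volume, so peak heights in sigma are the conventional readout.

#' Calculated model phases
#'
#' Phase (in degrees) of the non-anomalous calculated structure factor
#' \eqn{\sum occ \, f_0(s) e^{-B s^2} e^{2\pi i h (Rx+t)}} for every
#' reflection of `refl`; f' and f'' are omitted, standing in for refined
#' model phases.  An optional wrapped-Gaussian phase error emulates
#' imperfect starting phases.
#'
#' @param model A [crystal_model()] sharing the cell/symmetry of `refl`.
#' @param refl A [reflection_set()].
#' @param phase_error_deg Width (degrees) of wrapped Gaussian noise added to
#'   each phase; 0 gives deterministic phases.
#' @param seed Seed for the phase-error stream.
#' @return Numeric vector of phases in degrees, in (-180, 180].
#' @export
model_phases <- function(model, refl, phase_error_deg = 0, seed = 1) {
  if (any(refl$d < refl$d_min - 1e-6))
    stop("reflections extend beyond the set's resolution limit")
  fm <- .sf_kernel(model, refl$hkl, energy_kev = NA, anomalous = FALSE)
  ph <- Arg(fm[, 1]) * 180 / pi
  if (phase_error_deg > 0)
    ph <- local_seed(seed, {
      e <- (ph + stats::rnorm(length(ph), 0, phase_error_deg) + 180) %% 360 - 180
      e
    })
  ph
}

# next FFT-friendly size (factors 2,3,5,7 only)
.nice_grid <- function(n) {
  n <- as.integer(ceiling(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Phased anomalous difference Fourier map
#'
#' Fourier synthesis with coefficient amplitude dF(h) = |F+(h)| - |F-(h)|
#' and phase phi(h) - 90 degrees.  The unique reflections are expanded to
#' the full sphere with the set's symmetry operators, Hermitian mates are
#' filled so the map is real, and the grid is divided by the cell volume.
#' Reflections with a missing Friedel mate are skipped and counted.
#'
#' @param refl A [reflection_set()].
#' @param phases Phases in degrees for the rows of `refl` (from
#'   [model_phases()]).
#' @param grid_shape Integer length-3 grid dimensions; defaults to at least
#'   three samples per `d_min` along each cell edge, rounded up to
#'   FFT-friendly sizes.
#' @return Object of class `anomalous_map`: `grid` (3D real array), `cell`,
#'   `symops`, `rms`, `grid_shape`, `n_skipped`.
#' @export
anomalous_difference_map <- function(refl, phases, grid_shape = NULL) {
  stopifnot(inherits(refl, "reflection_set"),
            length(phases) == nrow(refl$hkl))
  cell <- refl$cell
  if (is.null(grid_shape)) {
    per <- c(cell$a, cell$b, cell$c) * 3 / refl$d_min
    grid_shape <- vapply(per, .nice_grid, 1L)
  }
  grid_shape <- as.integer(grid_shape)

  ok <- is.finite(refl$f_plus) & is.finite(refl$f_minus) & is.finite(phases)
  n_skipped <- sum(!ok)
  H <- refl$hkl[ok, , drop = FALSE]
  dF <- refl$f_plus[ok] - refl$f_minus[ok]
  phi <- (phases[ok] - 90) * pi / 180

  # expand to the full set: F(hR) = F(h) exp(-2 pi i h.t)
  He <- NULL; ce <- NULL
  for (op in refl$symops) {
    Hi <- H %*% op$rot
    ci <- dF * exp(1i * (phi - 2 * pi * drop(H %*% op$trans)))
    He <- rbind(He, Hi); ce <- c(ce, ci)
  }
  idx3 <- sweep(He, 2, grid_shape, "%%")                 # h mod N per axis
  lin <- (idx3[, 3] * grid_shape[2] + idx3[, 2]) * grid_shape[1] + idx3[, 1]
  keep <- !duplicated(lin)
  He <- He[keep, , drop = FALSE]; ce <- ce[keep]; lin <- lin[keep]

  C <- array(0i, grid_shape)
  C[lin + 1] <- ce
  # Hermitian mates: F(-h) = conj(F(h)); skip entries already present
  idx3m <- sweep(-He, 2, grid_shape, "%%")
  linm <- (idx3m[, 3] * grid_shape[2] + idx3m[, 2]) * grid_shape[1] + idx3m[, 1]
  fresh <- !(linm %in% lin) & !duplicated(linm)
  C[linm[fresh] + 1] <- Conj(ce[fresh])

  rho <- stats::fft(C) / cell$volume      # rho(x_j) = (1/V) sum c(h) e^{-2pi i h.j/N}
  im_resid <- max(abs(Im(rho)))
  grid <- Re(rho)
  rms <- stats::sd(as.numeric(grid)) * sqrt((length(grid) - 1) / length(grid))
  structure(list(grid = grid, cell = cell, symops = refl$symops,
                 rms = rms, grid_shape = grid_shape,
                 n_skipped = n_skipped, im_resid = im_resid,
                 n_coeff = length(ce)),
            class = "anomalous_map")
}

#' @export
print.anomalous_map <- function(x, ...) {
  cat(sprintf("anomalous map %d x %d x %d, rms %.4g, max %.1f sigma\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3], x$rms,
              max(x$grid) / x$rms))
  invisible(x)
}

#' Sigma-normalized peak search
#'
#' Finds all grid-local maxima (26-neighbourhood, periodic) at or above
#' `threshold_sigma` map-rms units, refines each by per-axis three-point
#' parabolic interpolation, merges peaks closer than `merge_tol` Angstrom
#' under symmetry (keeping the highest) and returns them sorted by height.
#'
#' @param map An [anomalous_difference_map()] result.
#' @param threshold_sigma Height cutoff in sigma (> 0); 4 is the
#'   conventional screening level.
#' @param merge_tol Symmetry-aware merge distance in Angstrom.
#' @return data.frame with columns `x, y, z` (fractional, in `[0,1)`) and
#'   `height_sigma`, sorted by decreasing height.  May have zero rows.
#' @export
find_peaks <- function(map, threshold_sigma = 4, merge_tol = 1.0) {
  stopifnot(threshold_sigma > 0)
  g <- map$grid; N <- map$grid_shape
  thr <- threshold_sigma * map$rms
  cand <- which(g >= thr)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      height_sigma = numeric(0))
  if (!length(cand)) return(empty)
  ijk <- arrayInd(cand, N) - 1L
  shifts <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  is_max <- rep(TRUE, length(cand))
  v0 <- g[cand]
  for (r in seq_len(nrow(shifts))) {
    nb <- sweep(ijk, 2, shifts[r, ], "+") %% matrix(N, length(cand), 3, byrow = TRUE)
    is_max <- is_max & v0 >= g[cbind(nb[, 1] + 1, nb[, 2] + 1, nb[, 3] + 1)]
  }
  if (!any(is_max)) return(empty)
  ijk <- ijk[is_max, , drop = FALSE]; v0 <- v0[is_max]

  # per-axis 3-point parabolic refinement of position and height
  frac <- matrix(0, nrow(ijk), 3); hts <- v0
  for (p in seq_len(nrow(ijk))) {
    pos <- ijk[p, ]; h <- v0[p]
    for (ax in 1:3) {
      lo <- pos; hi <- pos
      lo[ax] <- (pos[ax] - 1) %% N[ax]; hi[ax] <- (pos[ax] + 1) %% N[ax]
      ym <- g[matrix(lo + 1, 1)]; y0 <- v0[p]; yp <- g[matrix(hi + 1, 1)]
      den <- ym - 2 * y0 + yp
      del <- if (den < 0) 0.5 * (ym - yp) / den else 0
      del <- max(min(del, 0.5), -0.5)
      frac[p, ax] <- (pos[ax] + del) / N[ax]
      h <- max(h, y0 - 0.25 * (ym - yp) * del)
    }
    hts[p] <- h
  }
  ord <- order(-hts)
  frac <- frac[ord, , drop = FALSE] %% 1; hts <- hts[ord]
  keep <- rep(TRUE, length(hts))
  for (i in seq_along(hts)) {
    if (!keep[i]) next
    if (i < length(hts)) for (j in (i + 1):length(hts)) {
      if (keep[j] &&
          min_sym_distance(map$cell, map$symops, frac[i, ], frac[j, ]) < merge_tol)
        keep[j] <- FALSE
    }
  }
  data.frame(x = frac[keep, 1], y = frac[keep, 2], z = frac[keep, 3],
             height_sigma = hts[keep] / map$rms)
}

#' Write a peak list as tab-separated text
#' @param peaks data.frame from [find_peaks()].
#' @param path Output path.
#' @param dataset_ref Label recorded in the `dataset` column.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, dataset_ref = "") {
  df <- cbind(peaks, dataset = dataset_ref)
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- CCP4/MRC map I/O -------------------------------------------------------

#' Write an anomalous map in CCP4/MRC format
#'
#' Mode-2 (float32) map covering the full unit cell, fast axis x, origin at
#' (0,0,0), little-endian, with the standard 1024-byte header and "MAP "
#' stamp.
#'
#' @param map An [anomalous_difference_map()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccp4_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  N <- map$grid_shape; cl <- map$cell
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(N)                     # NC NR NS
  wi(2)                     # MODE float32
  wi(c(0, 0, 0))            # start
  wi(N)                     # intervals
  wf(c(cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma))
  wi(c(1, 2, 3))            # MAPC MAPR MAPS
  wf(c(min(map$grid), max(map$grid), mean(map$grid)))
  wi(1)                     # ISPG (operators travel with the data, not the file)
  wi(0)                     # NSYMBT
  wi(rep(0, 25))            # extra
  wi(c(0, 0, 0))            # origin (MRC words 50-52)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(map$rms)
  wi(0)                     # NLABL
  writeBin(raw(800), con)
  wf(as.numeric(map$grid))
  invisible(path)
}

#' Read a CCP4/MRC map written by [write_ccp4_map()]
#'
#' @param path Map path.
#' @param symops Operator list to attach (the format stores only a group
#'   number).
#' @return An `anomalous_map` object.
#' @export
read_ccp4_map <- function(path, symops = symops_p1()) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  N <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("map parse error: unsupported mode ", mode)
  ri(3); ncell <- ri(3)
  cp <- rf(6)
  axes <- ri(3)
  if (!all(axes == c(1, 2, 3))) stop("map parse error: unexpected axis order")
  rf(3); ri(1); nsym <- ri(1)
  seek(con, 1024 + nsym)
  grid <- array(rf(prod(N)), N)
  cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6])
  rms <- stats::sd(as.numeric(grid)) * sqrt((length(grid) - 1) / length(grid))
  structure(list(grid = grid, cell = cell, symops = symops, rms = rms,
                 grid_shape = N, n_skipped = NA, im_resid = NA,
                 n_coeff = NA),
            class = "anomalous_map")
}
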