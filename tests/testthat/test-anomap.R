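test_that("centrosymmetric models give centric phases", {
  cl <- unit_cell(15, 15, 15)
  x <- c(0.13, 0.27, 0.31)
  s <- atom_sites(c("C", "C"), c(x[1], -x[1]), c(x[2], -x[2]), c(x[3], -x[3]),
                  occupancy = 1, b_iso = 10)
  m <- crystal_model(cl, symops_p1(), s)
  rs <- structure_factors(m, 5.2, 3.0, anomalous = FALSE)
  ph <- model_phases(m, rs)
  wrapped <- pmin(abs(ph) %% 180, 180 - abs(ph) %% 180)
  expect_lt(max(wrapped), 1e-6)
})

test_that("phase error is an optional wrapped Gaussian", {
  m <- small_xtal(n_scaffold = 20)
  rs <- structure_factors(m, 5.2, 1.6)
  expect_identical(model_phases(m, rs), model_phases(m, rs))
  ph0 <- model_phases(m, rs)
  ph30 <- model_phases(m, rs, phase_error_deg = 30, seed = 2)
  shift <- (ph30 - ph0 + 180) %% 360 - 180
  # closed-form mean |N(0, 30 deg)| = 30 sqrt(2/pi) (wrapping negligible)
  expect_equal(mean(abs(shift)), 30 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("zero coefficients give a flat zero map", {
  m <- small_xtal(n_scaffold = 10)
  rs <- structure_factors(m, 5.2, 3.0, anomalous = FALSE)
  mp <- anomalous_difference_map(rs, model_phases(m, rs))
  expect_lt(max(abs(mp$grid)), 1e-9 * mean(rs$f_plus))
})

test_that("map synthesis is real, zero-mean and Parseval-consistent", {
  m <- small_xtal(n_scaffold = 25, with_s = TRUE)
  rs <- structure_factors(m, 5.2, 2.0)
  ph <- model_phases(m, rs)
  mp <- anomalous_difference_map(rs, ph)
  expect_lt(mp$im_resid, 1e-10 * mp$rms)
  expect_lt(abs(mean(mp$grid)), 1e-12 * mp$rms)
  # independent coefficient expansion for the Parseval sum
  dF <- rs$f_plus - rs$f_minus
  phi <- (ph - 90) * pi / 180
  He <- NULL; ce <- NULL
  for (op in m$symops) {
    He <- rbind(He, rs$hkl %*% op$rot)
    ce <- c(ce, dF * exp(1i * (phi - 2 * pi * drop(rs$hkl %*% op$trans))))
  }
  N <- mp$grid_shape
  lin <- ((He[, 3] %% N[3]) * N[2] + (He[, 2] %% N[2])) * N[1] + (He[, 1] %% N[1])
  keep <- !duplicated(lin); He <- He[keep, ]; ce <- ce[keep]; lin <- lin[keep]
  linm <- ((-He[, 3] %% N[3]) * N[2] + (-He[, 2] %% N[2])) * N[1] + (-He[, 1] %% N[1])
  fresh <- !(linm %in% lin) & !duplicated(linm)
  total <- sum(Mod(ce)^2) + sum(Mod(ce[fresh])^2)
  expect_equal(mean(mp$grid^2), total / m$cell$volume^2, tolerance = 1e-6)
})

test_that("the map peaks at the anomalous site and sigma heights are scale-free", {
  m <- small_xtal(n_scaffold = 25)
  rs <- structure_factors(m, 5.2, 2.0)
  ph <- model_phases(m, rs)
  mp <- anomalous_difference_map(rs, ph)
  pk <- find_peaks(mp, 4)
  true <- unlist(m$sites[nrow(m$sites), c("x", "y", "z")])
  expect_gt(nrow(pk), 0)
  expect_lt(min_sym_distance(m$cell, m$symops, unlist(pk[1, 1:3]), true),
            rs$d_min / 3)
  # symmetry copies deduplicated
  if (nrow(pk) > 1)
    for (i in 2:nrow(pk))
      expect_gt(min_sym_distance(m$cell, m$symops, unlist(pk[1, 1:3]),
                                 unlist(pk[i, 1:3])), 1.0)
  # doubling all amplitudes leaves sigma-normalized heights unchanged
  rs2 <- rs; rs2$f_plus <- 2 * rs$f_plus; rs2$f_minus <- 2 * rs$f_minus
  pk2 <- find_peaks(anomalous_difference_map(rs2, ph), 4)
  expect_equal(pk2$height_sigma, pk$height_sigma, tolerance = 1e-9)
  # raising the threshold never adds peaks
  expect_lte(nrow(find_peaks(mp, 6)), nrow(pk))
  expect_true(all(find_peaks(mp, 6)$height_sigma >= 6))
})

test_that("absolute peak height is linear in occ * f'' for a lone weak site", {
  m <- small_xtal(n_scaffold = 600, seed = 2)
  set.seed(2)   # wider scaffold spread keeps |F| large against the probe
  n <- nrow(m$sites)
  m$sites[seq_len(n - 1), c("x", "y", "z")] <-
    matrix(runif(3 * (n - 1), 0.05, 0.45), ncol = 3)
  pos <- unlist(m$sites[n, c("x", "y", "z")])
  m0 <- m; m0$sites$occupancy[n] <- 0
  r0 <- structure_factors(m0, 5.2, 2.5)
  ph0 <- model_phases(m0, r0)
  bg <- anomalous_difference_map(r0, ph0)
  val <- function(o) {
    m2 <- m; m2$sites$occupancy[n] <- o
    mp <- anomalous_difference_map(structure_factors(m2, 5.2, 2.5), ph0)
    idx <- round(pos * mp$grid_shape) + 1
    mp$grid[idx[1], idx[2], idx[3]] - bg$grid[idx[1], idx[2], idx[3]]
  }
  occ <- c(0.01, 0.02, 0.05, 0.1)
  r <- vapply(occ, val, 1) / occ
  expect_lt(max(abs(r / r[4] - 1)), 0.02)
})

test_that("missing Friedel mates are skipped and counted", {
  m <- small_xtal(n_scaffold = 10)
  rs <- structure_factors(m, 5.2, 3.0)
  rs$f_minus[1:5] <- NA
  mp <- anomalous_difference_map(rs, model_phases(m, rs))
  expect_equal(mp$n_skipped, 5)
})

test_that("CCP4 map round-trip preserves voxels to float precision", {
  m <- small_xtal(n_scaffold = 15)
  rs <- structure_factors(m, 5.2, 2.5)
  mp <- anomalous_difference_map(rs, model_phases(m, rs))
  path <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4_map(mp, path)
  mp2 <- read_ccp4_map(path, m$symops)
  expect_equal(mp2$grid_shape, mp$grid_shape)
  expect_equal(mp2$cell$a, mp$cell$a, tolerance = 1e-6)
  expect_lt(max(abs(mp2$grid - mp$grid)) / max(abs(mp$grid)), 1e-5)
})
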