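test_that("paper-like crystal presets carry the configured probes", {
  m <- build_paper_like_crystal("L19", n_scaffold = 60, seed = 7)
  probes <- m$sites[m$sites$role == "probe", ]
  expect_equal(nrow(probes), 4)
  expect_equal(sort(probes$occupancy), sort(c(0.31, 0.49, 0.27, 0.12)))
  expect_equal(sort(probes$b_iso), sort(c(87, 164, 106, 80)))

  k <- build_paper_like_crystal("K20", n_scaffold = 60, seed = 7)
  kp <- k$sites[k$sites$role == "probe", ]
  expect_equal(nrow(kp), 1)
  expect_equal(kp$occupancy, 0.33)
  expect_equal(kp$b_iso, 55)
  expect_gte(sum(k$sites$element == "Zn"), 2)
  expect_gte(sum(k$sites$element == "Cl"), 2)
  expect_gte(sum(k$sites$element == "S"), 1)

  # determinism and invalid-probe rejection
  expect_identical(build_paper_like_crystal("L18", n_scaffold = 40, seed = 3),
                   build_paper_like_crystal("L18", n_scaffold = 40, seed = 3))
  expect_error(build_paper_like_crystal(probes = data.frame(occupancy = 1.4,
                                                            b_iso = 50)),
               "occupancy")
})

test_that("a single carbon at the origin gives |F| = f0(s)", {
  cl <- unit_cell(10, 10, 10)
  s <- atom_sites("C", 0, 0, 0, occupancy = 1, b_iso = 0)
  m <- crystal_model(cl, symops_p1(), s)
  rs <- structure_factors(m, 5.2, 2.0, anomalous = FALSE)
  f0 <- form_factor_f0("C", 1 / (2 * rs$d))
  expect_equal(rs$f_plus, f0, tolerance = 1e-12)
  expect_equal(rs$f_minus, f0, tolerance = 1e-12)
})

test_that("structure factors match the direct-summation oracle", {
  set.seed(7)
  cl <- unit_cell(12, 14, 16, 85, 95, 100)
  n <- 10
  sites <- atom_sites(sample(c("C", "N", "O", "S"), n, TRUE),
                      runif(n), runif(n), runif(n),
                      occupancy = runif(n, 0.3, 1), b_iso = runif(n, 5, 60))
  m <- crystal_model(cl, symops_p1(), sites)
  rs <- structure_factors(m, 5.2, 2.5)
  br <- brute_structure_factors(m, rs$hkl, 5.2)
  expect_equal(rs$f_plus, br$f_plus, tolerance = 1e-8)
  expect_equal(rs$f_minus, br$f_minus, tolerance = 1e-8)
})

test_that("Friedel symmetry holds exactly without anomalous scattering", {
  m <- small_xtal(n_scaffold = 20, iodine_occ = 0.4)
  rs0 <- structure_factors(m, 5.2, 2.5, anomalous = FALSE)
  expect_equal(rs0$f_plus, rs0$f_minus, tolerance = 1e-9)
  rs1 <- structure_factors(m, 5.2, 2.5)
  expect_gt(max(abs(rs1$f_plus - rs1$f_minus)), 1e-3)
  # signed Friedel differences average out; rms grows with occ * f''
  df1 <- rs1$f_plus - rs1$f_minus
  expect_lt(abs(mean(df1)), stats::sd(df1) / 3)
  m2 <- m; m2$sites$occupancy[nrow(m2$sites)] <- 0.8
  rs2 <- structure_factors(m2, 5.2, 2.5)
  expect_gt(sqrt(mean((rs2$f_plus - rs2$f_minus)^2)), sqrt(mean(df1^2)))
})

test_that("noise model is reproducible and calibrated", {
  m <- small_xtal(n_scaffold = 15)
  rs <- structure_factors(m, 5.2, 2.5)
  # infinite target is the exact no-noise limit
  expect_equal(add_noise(rs, noise_spec(Inf, 1, 1))$f_plus, rs$f_plus)
  # determinism
  expect_identical(add_noise(rs, noise_spec(12, 0.9, 5)),
                   add_noise(rs, noise_spec(12, 0.9, 5)))
  expect_false(identical(add_noise(rs, noise_spec(12, 1, 5))$f_plus,
                         add_noise(rs, noise_spec(12, 1, 6))$f_plus))
  # completeness removes the right fraction
  rn <- add_noise(rs, noise_spec(12, 0.8, 5))
  expect_equal(nrow(rn$hkl), round(0.8 * nrow(rs$hkl)))
  # realized |dF|/sigma has the half-normal mean 0.798 (amplitudes >> sigma,
  # so zero-clipping is immaterial); closed form sqrt(2/pi)
  cl <- unit_cell(50, 50, 50)
  g <- as.matrix(expand.grid(h = 1:25, k = 1:25, l = 1:16))
  big <- reflection_set(g, rep(1000, 1e4), rep(1000, 1e4), 0, 0,
                        cl, symops_p1(), 1.2)
  bn <- add_noise(big, noise_spec(10, 1, 42))
  dev <- abs(c(bn$f_plus, bn$f_minus) - 1000) / bn$sig_plus[1]
  expect_equal(mean(dev), sqrt(2 / pi), tolerance = 0.05)
})

test_that("dose decay is exponential in dose with the stated half-dose", {
  m <- build_paper_like_crystal("L19", n_scaffold = 40, seed = 1)
  probe <- m$sites$role == "probe"
  expect_identical(apply_dose_decay(m, 0, 6), m)
  half <- apply_dose_decay(m, 6, 6)
  expect_equal(half$sites$occupancy[probe], m$sites$occupancy[probe] / 2)
  expect_equal(half$sites$occupancy[!probe], m$sites$occupancy[!probe])
  # semigroup: D1 then D2 equals D1 + D2
  two <- apply_dose_decay(apply_dose_decay(m, 1.7, 6), 4.3, 6)
  one <- apply_dose_decay(m, 6.0, 6)
  expect_equal(two$sites$occupancy, one$sites$occupancy, tolerance = 1e-12)
})

test_that("campaigns accumulate dose and derive independent noise streams", {
  m <- small_xtal(n_scaffold = 15)
  plan <- data.frame(energy = c(5.2, 4.5),
                     orientation = c("kappa=0", "kappa=0"),
                     crystal = "x1", dose_inc = c(1.35, 8.32))
  ds <- simulate_campaign(m, plan, noise_spec(Inf), d_half = 6, d_min = 2.5)
  expect_equal(ds[[2]]$dose_before, 1.35)
  expect_equal(ds[[2]]$dose_after, 9.67)
  # same settings, different orientations: identical truth, different noise
  plan2 <- data.frame(energy = 5.2, orientation = c("kappa=0", "kappa=-20"),
                      crystal = c("x1", "x2"), dose_inc = 0)
  quiet <- simulate_campaign(m, plan2, noise_spec(Inf), d_min = 2.5)
  expect_equal(quiet[[1]]$refl$f_plus, quiet[[2]]$refl$f_plus)
  noisy <- simulate_campaign(m, plan2, noise_spec(12, seed = 4), d_min = 2.5)
  expect_false(identical(noisy[[1]]$refl$f_plus, noisy[[2]]$refl$f_plus))
  # full campaign is a pure function of (model, plan, seed)
  again <- simulate_campaign(m, plan2, noise_spec(12, seed = 4), d_min = 2.5)
  expect_identical(lapply(noisy, `[[`, "refl"), lapply(again, `[[`, "refl"))
  expect_error(simulate_campaign(m, data.frame(energy = 5.2, orientation = "a",
                                               crystal = "x", dose_inc = -1),
                                 noise_spec(Inf)), "negative dose")
})
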