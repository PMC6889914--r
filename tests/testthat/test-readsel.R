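# a small P1 geometry keeps the distances easy to reason about
rs_cell <- unit_cell(20, 20, 20)
rs_ops <- symops_p1()

pool_from <- function(positions_by_member) {
  conformer_pool(lapply(seq_along(positions_by_member), function(i)
    list(id = sprintf("cf%03d", i),
         probe_positions = positions_by_member[[i]])),
    rs_cell, rs_ops)
}

test_that("ensemble scoring is a per-site nearest-probe distance", {
  sites <- observed_sites(c("res19", "res20"),
                          x = c(0.25, 0.60), y = c(0.25, 0.60),
                          z = c(0.25, 0.60), weight = c(8, 6))
  exact <- pool_from(list(
    list(res19 = c(0.25, 0.25, 0.25), res20 = c(0.60, 0.60, 0.60)),
    list(res19 = c(0.1, 0.1, 0.1), res20 = c(0.9, 0.9, 0.9))))
  sc <- score_ensemble(exact, "cf001", sites)
  expect_equal(sc$fit_error, 0)
  # a probe 1.3 A from the single site scores exactly that distance
  one <- pool_from(list(list(res19 = c(0.25 + 1.3 / 20, 0.25, 0.25))))
  s1 <- observed_sites("res19", 0.25, 0.25, 0.25, weight = 8)
  expect_equal(score_ensemble(one, "cf001", s1)$fit_error, 1.3, tolerance = 1e-9)
  # brute-force evaluation over all member x site pairs agrees
  set.seed(5)
  members <- lapply(1:4, function(i)
    list(res19 = runif(3), res20 = runif(3)))
  p <- pool_from(members)
  got <- score_ensemble(p, c("cf001", "cf002", "cf003", "cf004"), sites)
  brute <- vapply(seq_len(nrow(sites)), function(j) {
    min(vapply(members, function(mm)
      brute_min_sym_distance(rs_cell, rs_ops,
                             unlist(sites[j, c("x", "y", "z")]),
                             mm[[sites$label[j]]]), 1))
  }, numeric(1))
  expect_equal(unname(got$per_site_error), brute, tolerance = 1e-9)
  expect_equal(got$fit_error,
               sum(brute * sites$weight) / sum(sites$weight), tolerance = 1e-9)
})

test_that("sites with no matching probe are excluded and flagged", {
  p <- pool_from(list(list(res19 = c(0.2, 0.2, 0.2))))
  sites <- observed_sites(c("res19", "res21"), c(0.2, 0.5), c(0.2, 0.5),
                          c(0.2, 0.5))
  sc <- score_ensemble(p, "cf001", sites)
  expect_equal(sc$excluded, "res21")
  expect_true(is.na(sc$per_site_error[["res21"]]))
  expect_error(select_ensemble(p, sites, 1), "res21")
})

test_that("selection recovers a planted ensemble exactly", {
  set.seed(8)
  truth <- observed_sites(c("res18", "res19", "res20"),
                          runif(3), runif(3), runif(3), weight = c(26, 9, 32))
  decoys <- lapply(1:8, function(i)
    list(res18 = runif(3), res19 = runif(3), res20 = runif(3)))
  # two planted members jointly cover the three sites at distance 0
  planted <- list(
    list(res18 = c(truth$x[1], truth$y[1], truth$z[1]),
         res19 = c(truth$x[2], truth$y[2], truth$z[2]),
         res20 = c(0.9, 0.9, 0.9)),
    list(res18 = c(0.1, 0.9, 0.5),
         res19 = c(0.9, 0.1, 0.5),
         res20 = c(truth$x[3], truth$y[3], truth$z[3])))
  p <- pool_from(c(decoys, planted))
  ens <- select_ensemble(p, truth, 2, method = "exchange")
  expect_equal(ens$fit_error, 0, tolerance = 1e-9)
  expect_equal(ens$member_ids, c("cf009", "cf010"))
  # N = pool size scores the whole pool
  full <- select_ensemble(p, truth, 10, method = "greedy")
  expect_equal(full$fit_error, score_ensemble(p, paste0("cf", sprintf("%03d", 1:10)),
                                              truth)$fit_error)
})

test_that("exchange selection matches exhaustive enumeration on small pools", {
  for (seed in c(2, 13, 21)) {
    set.seed(seed)
    sites <- observed_sites(c("res18", "res19"), runif(2), runif(2), runif(2),
                            weight = c(10, 5))
    members <- lapply(1:10, function(i) list(res18 = runif(3), res19 = runif(3)))
    p <- pool_from(members)
    ids <- paste0("cf", sprintf("%03d", 1:10))
    for (N in 2:3) {
      ens <- select_ensemble(p, sites, N, method = "exchange")
      combos <- utils::combn(ids, N)
      best <- min(apply(combos, 2, function(s)
        score_ensemble(p, s, sites)$fit_error))
      expect_equal(ens$fit_error, best, tolerance = 1e-9)
      greedy <- select_ensemble(p, sites, N, method = "greedy")
      expect_lte(ens$fit_error, greedy$fit_error + 1e-12)
    }
  }
})

test_that("greedy fit error is monotone non-increasing in ensemble size", {
  set.seed(4)
  sites <- observed_sites(c("res18", "res19", "res20"),
                          runif(3), runif(3), runif(3))
  p <- pool_from(lapply(1:12, function(i)
    list(res18 = runif(3), res19 = runif(3), res20 = runif(3))))
  errs <- vapply(1:6, function(N)
    select_ensemble(p, sites, N, "greedy")$fit_error, 1)
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("back-prediction reflects the pool's correlation structure", {
  truthA <- c(0.30, 0.30, 0.30); truthB <- c(0.70, 0.70, 0.70)
  sites <- observed_sites(c("resA", "resB"),
                          c(truthA[1], truthB[1]), c(truthA[2], truthB[2]),
                          c(truthA[3], truthB[3]), weight = c(10, 10))
  # members covering A exactly also sit within 0.5 A of B
  near <- function(tr, d_ang) (tr * 20 + c(d_ang, 0, 0)) / 20
  covering <- lapply(1:3, function(i)
    list(resA = truthA, resB = near(truthB, 0.4)))
  decoys <- lapply(1:5, function(i) list(resA = runif(3), resB = runif(3)))
  p <- pool_from(c(covering, decoys))
  bp <- back_predict(p, sites, "resB", 1, method = "greedy")
  expect_lte(bp$deviation, 0.5)
  # held-out site coinciding with a selected probe predicts at zero error
  bp0 <- back_predict(pool_from(list(list(resA = truthA, resB = truthB))),
                      sites, "resB", 1)
  expect_equal(bp0$deviation, 0, tolerance = 1e-9)
  # an isolated site no selectable conformer approaches stays unpredicted
  iso <- pool_from(c(lapply(1:4, function(i)
    list(resA = truthA, resB = runif(3) * 0.2 + 0.01))))
  bpi <- back_predict(iso, sites, "resB", 1)
  expect_gt(bpi$deviation, 2)
  expect_error(back_predict(p, sites, "resC", 1), "not among")
})

test_that("synthetic pools are reproducible and PDB round-trips them", {
  sites <- observed_sites(c("res18", "res19"), c(0.2, 0.6), c(0.3, 0.7),
                          c(0.4, 0.8), weight = c(5, 5))
  p1 <- make_synthetic_pool(sites, rs_cell, rs_ops, n_pool = 6,
                            n_covering = 3, sd_ang = 0.3, seed = 2)
  p2 <- make_synthetic_pool(sites, rs_cell, rs_ops, n_pool = 6,
                            n_covering = 3, sd_ang = 0.3, seed = 2)
  expect_identical(p1$conformers, p2$conformers)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pool_pdb(p1, path)
  p3 <- read_pool_pdb(path)
  expect_length(p3$conformers, 6)
  for (i in 1:6)
    expect_equal(p3$conformers[[i]]$probe_positions$res18,
                 p1$conformers[[i]]$probe_positions$res18, tolerance = 1e-3)
})
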