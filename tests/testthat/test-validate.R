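# peak-list helpers for constructing validation scenarios directly
pk <- function(x, y, z, h) data.frame(x = x, y = y, z = z, height_sigma = h)

test_that("peaks a bond-length apart merge or split with the tolerance", {
  cell <- unit_cell(42.8, 42.8, 253.78)
  ops <- symops_p1()
  # two peaks 1.3 A apart along x
  p1 <- pk(0.10, 0.20, 0.05, 8)
  p2 <- pk(0.10 + 1.3 / 42.8, 0.20, 0.05, 6)
  cl15 <- match_peaks(list(a = p1, b = p2), tol = 1.5, cell, ops)
  expect_length(cl15, 1)
  expect_equal(nrow(cl15[[1]]), 2)
  cl10 <- match_peaks(list(a = p1, b = p2), tol = 1.0, cell, ops)
  expect_length(cl10, 2)
})

test_that("clustering matches brute-force single linkage", {
  cell <- unit_cell(20, 20, 30)
  ops <- symops_p4122()
  set.seed(11)
  for (rep in 1:3) {
    n <- sample(8:20, 1)
    pts <- data.frame(x = runif(n), y = runif(n), z = runif(n),
                      height_sigma = runif(n, 4, 20))
    lists <- split(pts, rep_len(c("d1", "d2", "d3"), n))
    tol <- runif(1, 2, 5)
    got <- match_peaks(lists, tol, cell, ops)
    pooled <- do.call(rbind, lapply(names(lists), function(nm)
      cbind(dataset = nm, lists[[nm]])))
    want <- brute_single_linkage(pooled[, c("x", "y", "z")], tol, cell, ops)
    # compare partitions via each point's cluster co-membership
    got_membership <- integer(nrow(pooled))
    for (k in seq_along(got)) {
      for (r in seq_len(nrow(got[[k]]))) {
        hit <- which(pooled$dataset == got[[k]]$dataset[r] &
                     abs(pooled$x - got[[k]]$x[r]) < 1e-12 &
                     abs(pooled$y - got[[k]]$y[r]) < 1e-12)
        got_membership[hit] <- k
      }
    }
    # clusters keep <= 1 peak per dataset, so compare only kept points
    kept <- got_membership > 0
    expect_equal(partition_key(got_membership[kept]),
                 partition_key(want[kept]))
  }
})

test_that("one peak per dataset survives in a cluster, highest first", {
  cell <- unit_cell(20, 20, 30)
  ops <- symops_p1()
  twice <- pk(c(0.5, 0.505), 0.5, 0.5, c(9, 5))   # same dataset, 0.1 A apart
  cl <- match_peaks(list(a = twice), tol = 1.5, cell, ops)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]), 1)
  expect_equal(cl[[1]]$height_sigma, 9)
  expect_equal(attr(cl[[1]], "conflicts"), 1)
})

test_that("edge-contrast classification follows the decision logic", {
  cell <- unit_cell(42.8, 42.8, 253.78)
  ops <- symops_p1()
  mk <- function(above, below) {
    lists <- list()
    for (i in seq_along(above))
      lists[[paste0("hi", i)]] <- if (above[i] > 0)
        pk(0.1, 0.2, 0.05, above[i]) else pk(numeric(0), numeric(0), numeric(0), numeric(0))
    for (i in seq_along(below))
      lists[[paste0("lo", i)]] <- if (below[i] > 0)
        pk(0.1, 0.2, 0.05, below[i]) else pk(numeric(0), numeric(0), numeric(0), numeric(0))
    classify_sites(match_peaks(lists, 1.5, cell, ops),
                   above_edge_refs = paste0("hi", seq_along(above)),
                   below_edge_refs = if (length(below)) paste0("lo", seq_along(below)) else character(),
                   cell = cell, symops = ops)
  }
  # strong, replicated above edge; absent below -> iodine
  expect_equal(mk(c(8.9, 7), 0)$classification, "iodine")
  # present both sides of the edge -> a Zn/Cl/S-type scatterer
  expect_equal(mk(c(5, 5), 5)$classification, "non_iodine_scatterer")
  # one very strong dataset, no replicate, no below-edge data -> unconfirmed
  one <- mk(26, numeric(0))
  expect_equal(one$classification, "unconfirmed")
  expect_match(one$reason, "edge-test unavailable")
  # strong iodine retains the edge-contrast residual below (~1/3.9), still iodine
  expect_equal(mk(c(32, 16), 7)$classification, "iodine")
  # a cluster with no above-edge member stays unconfirmed with a reason
  below_only <- mk(0, 5)
  expect_equal(below_only$classification, "unconfirmed")
  expect_match(below_only$reason, "no above-edge member")
  # and no above-edge dataset at all is a configuration error
  expect_error(classify_sites(list(), character(0), "lo1",
                              cell = cell, symops = ops), "above-edge")
})

test_that("classification is invariant to dataset order and amplitude scale", {
  cell <- unit_cell(20, 20, 30)
  ops <- symops_p4122()
  lists <- list(hi1 = pk(c(0.2, 0.6), c(0.3, 0.1), c(0.1, 0.4), c(9, 5)),
                hi2 = pk(0.201, 0.299, 0.101, 7.5),
                lo1 = pk(0.6, 0.1, 0.4, 5.5))
  run <- function(l) {
    s <- classify_sites(match_peaks(l, 1.5, cell, ops), c("hi1", "hi2"), "lo1",
                        cell = cell, symops = ops)
    s[order(s$x), "classification"]
  }
  expect_equal(run(lists), run(rev(lists)))
  # sigma heights are already scale-free, so classification sees no amplitude
  expect_equal(run(lists), c(run(lists)))
})

test_that("dose-decay ratios separate labile iodine from ordered sulfur", {
  # iodine drops to half over the campaign; the methionine reference barely moves
  iod <- dose_decay_check(c(32.5, 16.1), ref_heights = c(4.9, 4.2))
  expect_equal(iod$ratio, 16.1 / 32.5, tolerance = 1e-12)
  expect_true(iod$decayed)
  expect_equal(iod$flag, "decayed")
  expect_equal(iod$ref_ratio, 4.2 / 4.9, tolerance = 1e-12)
  ref <- dose_decay_check(c(4.9, 4.2))
  expect_false(ref$decayed)
  same <- dose_decay_check(c(7, 7))
  expect_equal(same$ratio, 1.0)
  expect_false(same$decayed)
  gone <- dose_decay_check(c(0, 5))
  expect_equal(gone$flag, "not_evaluable")
  expect_error(dose_decay_check(5), "two datasets")
})
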