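# Shared fixtures and independent oracles.  Oracles here deliberately use
# naive loops, separate from the package's vectorized/compiled paths.

# small tetragonal crystal: C scaffold + optional S + one iodine probe
small_xtal <- function(n_scaffold = 25, iodine_occ = 0.5, iodine_b = 40,
                       with_s = FALSE, seed = 2, cell = unit_cell(20, 20, 30)) {
  set.seed(seed)
  els <- c(rep("C", n_scaffold), if (with_s) "S", "I")
  n <- length(els)
  sites <- atom_sites(els,
                      c(runif(n - 1, 0.1, 0.4), 0.27),
                      c(runif(n - 1, 0.1, 0.4), 0.13),
                      c(runif(n - 1, 0.1, 0.4), 0.31),
                      occupancy = c(rep(1, n - 1), iodine_occ),
                      b_iso = c(rep(25, n - 1), iodine_b),
                      role = c(rep("scaffold", n - 1), "probe"))
  crystal_model(cell, symops_p4122(), sites, "P 41 2 2")
}

# direct-summation oracle: plain R loops over reflections, sites, symops
brute_structure_factors <- function(model, hkl, energy_kev) {
  n <- nrow(hkl)
  fp <- fm <- complex(n)
  for (i in seq_len(n)) {
    h <- hkl[i, ]
    s <- 1 / (2 * d_spacing(model$cell, h))
    for (j in seq_len(nrow(model$sites))) {
      st <- model$sites[j, ]
      an <- anomalous_coefficients(st$element, energy_kev)
      fel <- complex(real = form_factor_f0(st$element, s) + an[[1]],
                     imaginary = an[[2]])
      w <- st$occupancy * exp(-st$b_iso * s^2)
      for (op in model$symops) {
        x <- op$rot %*% c(st$x, st$y, st$z) + op$trans
        fp[i] <- fp[i] + w * fel * exp(2i * pi * sum(h * x))
        fm[i] <- fm[i] + w * fel * exp(2i * pi * sum(-h * x))
      }
    }
  }
  list(f_plus = Mod(fp), f_minus = Mod(fm))
}

# minimum-image oracle: explicit loops over ops and the 27 lattice shifts
brute_min_sym_distance <- function(cell, symops, p, q) {
  best <- Inf
  for (op in symops) {
    qi <- drop(op$rot %*% q + op$trans) %% 1
    for (u in -1:1) for (v in -1:1) for (w in -1:1) {
      d <- orthogonalize(cell, p - (qi + c(u, v, w)))
      best <- min(best, sqrt(sum(d^2)))
    }
  }
  best
}

# all-pairs single-linkage oracle: merge closest pair until above cutoff
brute_single_linkage <- function(pts, tol, cell, symops) {
  n <- nrow(pts)
  groups <- as.list(seq_len(n))
  dist_fun <- function(g1, g2) {
    min(vapply(g1, function(i) min(vapply(g2, function(j)
      brute_min_sym_distance(cell, symops, unlist(pts[i, 1:3]),
                             unlist(pts[j, 1:3])), 1)), numeric(1)))
  }
  repeat {
    if (length(groups) == 1) break
    best <- c(Inf, NA, NA)
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      d <- dist_fun(groups[[a]], groups[[b]])
      if (d < best[1]) best <- c(d, a, b)
    }
    if (best[1] >= tol) break
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  membership <- integer(n)
  for (k in seq_along(groups)) membership[groups[[k]]] <- k
  membership
}

# cluster memberships as canonical partition strings for comparison
partition_key <- function(membership) {
  paste(sort(vapply(split(seq_along(membership), membership),
                    function(ix) paste(ix, collapse = ","), "")),
        collapse = "|")
}
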