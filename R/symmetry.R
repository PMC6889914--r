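#' Symmetry operator
#'
#' A space-group operation acting on fractional coordinates as
#' \eqn{x' = R x + t}.  Translations are reduced modulo 1.
#'
#' @param rot 3x3 integer rotation matrix with determinant +1 or -1.
#' @param trans Length-3 translation vector (fractions of the cell edges).
#' @return Object of class `sym_op` with elements `rot` and `trans`.
#' @export
sym_op <- function(rot, trans = c(0, 0, 0)) {
  rot <- matrix(as.numeric(rot), 3, 3)
  if (abs(abs(det(rot)) - 1) > 1e-9)
    stop("rotation determinant must be +1 or -1")
  structure(list(rot = rot, trans = as.numeric(trans) %% 1), class = "sym_op")
}

#' Apply a symmetry operator to fractional coordinates
#'
#' @param op A [sym_op()].
#' @param frac Length-3 fractional vector or n x 3 matrix.
#' @param reduce Reduce the result into `[0, 1)` (default `TRUE`).
#' @return Transformed coordinates, same shape as input.
#' @export
apply_sym_op <- function(op, frac, reduce = TRUE) {
  out <- if (is.null(dim(frac))) drop(op$rot %*% frac + op$trans)
         else t(op$rot %*% t(frac) + op$trans)
  if (reduce) out %% 1 else out
}

#' Compose two symmetry operators
#'
#' Returns the operator equivalent to applying `op2` first and `op1` second.
#' @param op1,op2 [sym_op()] objects.
#' @return A [sym_op()].
#' @export
compose_sym_ops <- function(op1, op2) {
  sym_op(op1$rot %*% op2$rot, (op1$rot %*% op2$trans + op1$trans) %% 1)
}

#' Symmetry operators of space group P1
#' @return List with the identity operator.
#' @export
symops_p1 <- function() list(sym_op(diag(3)))

#' Symmetry operators of space group P4(1)22
#'
#' The eight proper rotations of tetragonal space group number 91, with the
#' 4(1) screw translations along c.
#'
#' @return List of eight [sym_op()] objects.
#' @export
symops_p4122 <- function() {
  m <- function(...) matrix(c(...), 3, 3, byrow = TRUE)
  list(
    sym_op(diag(3)),
    sym_op(m(0, -1, 0,  1,  0, 0,  0, 0,  1), c(0, 0, 1 / 4)),
    sym_op(m(-1, 0, 0,  0, -1, 0,  0, 0,  1), c(0, 0, 1 / 2)),
    sym_op(m(0,  1, 0, -1,  0, 0,  0, 0,  1), c(0, 0, 3 / 4)),
    sym_op(m(1,  0, 0,  0, -1, 0,  0, 0, -1), c(0, 0, 1 / 2)),
    sym_op(m(0, -1, 0, -1,  0, 0,  0, 0, -1), c(0, 0, 1 / 4)),
    sym_op(m(-1, 0, 0,  0,  1, 0,  0, 0, -1), c(0, 0, 0)),
    sym_op(m(0,  1, 0,  1,  0, 0,  0, 0, -1), c(0, 0, 3 / 4)))
}

#' Look up bundled symmetry operators by space-group symbol
#'
#' Only the two groups exercised by this package are bundled; arbitrary
#' operator lists can always be supplied directly where a `symops` argument
#' is accepted.
#'
#' @param symbol `"P1"` or `"P4122"` (also accepts `"P 41 2 2"`).
#' @return List of [sym_op()] objects.
#' @export
symops_for <- function(symbol) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", symbol))
  switch(key,
         P1 = symops_p1(),
         P41222 = ,  # "P 41 2 2" collapses to this key
         P4122 = symops_p4122(),
         stop("no bundled operators for space group '", symbol, "'"))
}

#' Verify group closure of an operator list
#'
#' Checks that the composition of any two operators (translations modulo 1)
#' is again in the list.
#'
#' @param symops List of [sym_op()] objects.
#' @return `TRUE` invisibly; errors if the set is not closed.
#' @export
check_group_closure <- function(symops) {
  key <- function(op) paste(c(round(op$rot), round(op$trans %% 1, 6)), collapse = ",")
  keys <- vapply(symops, key, "")
  for (i in seq_along(symops))
    for (j in seq_along(symops)) {
      k <- key(compose_sym_ops(symops[[i]], symops[[j]]))
      if (!k %in% keys) stop("operator set is not closed under composition")
    }
  invisible(TRUE)
}

#' Minimum symmetry-aware distance
#'
#' The minimum Cartesian distance between fractional point `p` and any
#' symmetry image of `q`, over all operators and lattice translations in
#' \{-1, 0, 1\}^3.  This is a pseudometric: it is zero for
#' symmetry-equivalent points.
#'
#' @param cell A [unit_cell()].
#' @param symops List of [sym_op()] objects.
#' @param p,q Fractional coordinates (length 3).
#' @return Distance in Angstrom.
#' @export
min_sym_distance <- function(cell, symops, p, q) {
  p <- as.numeric(p) %% 1
  q <- as.numeric(q) %% 1
  sh <- as.matrix(expand.grid(u = -1:1, v = -1:1, w = -1:1))
  best <- Inf
  for (op in symops) {
    qi <- apply_sym_op(op, q)          # image in [0,1)
    d <- sweep(sh, 2, p - qi, "+")     # p - qi - shift, all 27 shifts
    cart <- d %*% t(cell$orth)
    best <- min(best, min(rowSums(cart^2)))
  }
  sqrt(best)
}

#' Symmetry image of a point closest to a reference
#'
#' Returns the (unreduced) fractional coordinates of the symmetry/lattice
#' image of `q` that lies closest to `p`.  Used when averaging matched peak
#' positions recorded at different symmetry copies.
#'
#' @inheritParams min_sym_distance
#' @return Length-3 fractional vector (possibly outside `[0,1)`).
#' @export
closest_sym_image <- function(cell, symops, p, q) {
  p <- as.numeric(p); q <- as.numeric(q) %% 1
  sh <- as.matrix(expand.grid(u = -1:1, v = -1:1, w = -1:1))
  best <- Inf; best_img <- q
  for (op in symops) {
    qi <- apply_sym_op(op, q)
    cand <- sweep(sh, 2, qi, "+")
    d <- sweep(cand, 2, p, "-") %*% t(cell$orth)
    d2 <- rowSums(d^2)
    k <- which.min(d2)
    if (d2[k] < best) { best <- d2[k]; best_img <- cand[k, ] }
  }
  as.numeric(best_img)
}
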