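#' Friedel-paired reflection set
#'
#' Container for symmetry-unique structure-factor amplitudes with both
#' Friedel mates and their uncertainties, tied to a cell and operator list.
#'
#' @param hkl Integer n x 3 matrix of symmetry-unique Miller indices.
#' @param f_plus,f_minus Amplitudes |F(h)| and |F(-h)| (non-negative).
#' @param sig_plus,sig_minus Amplitude uncertainties (0 = noiseless).
#' @param cell A [unit_cell()].
#' @param symops List of [sym_op()]s the uniqueness is defined under.
#' @param d_min Resolution limit in Angstrom.
#' @return Object of class `reflection_set`; also carries per-reflection
#'   d-spacings in `$d`.
#' @export
reflection_set <- function(hkl, f_plus, f_minus, sig_plus = 0, sig_minus = 0,
                           cell, symops, d_min) {
  hkl <- rbind(hkl)
  storage.mode(hkl) <- "integer"
  dimnames(hkl) <- NULL
  n <- nrow(hkl)
  if (any(rowSums(abs(hkl)) == 0)) stop("(0,0,0) is not a reflection")
  f_plus <- as.numeric(f_plus); f_minus <- as.numeric(f_minus)
  if (any(f_plus < 0, na.rm = TRUE) || any(f_minus < 0, na.rm = TRUE))
    stop("amplitudes must be non-negative")
  d <- d_spacing(cell, hkl)
  if (any(d < d_min - 1e-6)) stop("reflection beyond stated d_min")
  structure(list(hkl = hkl, f_plus = f_plus,
                 sig_plus = rep_len(as.numeric(sig_plus), n),
                 f_minus = f_minus,
                 sig_minus = rep_len(as.numeric(sig_minus), n),
                 d = d, d_min = d_min, cell = cell, symops = symops),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection set: %d unique hkl to %.2f A, <F+> = %.3g\n",
              nrow(x$hkl), x$d_min, mean(x$f_plus, na.rm = TRUE)))
  invisible(x)
}

#' Symmetry-unique Miller indices to a resolution limit
#'
#' Enumerates all reflections with d >= d_min and reduces them to one
#' representative per orbit under the given proper rotations combined with
#' Friedel inversion (the Laue group).  The representative is the
#' lexicographically largest (h, k, l) in the orbit.
#'
#' @param cell A [unit_cell()].
#' @param symops List of [sym_op()]s.
#' @param d_min Resolution limit in Angstrom (> 0).
#' @return Integer matrix (n x 3) of unique indices.
#' @export
unique_reflections <- function(cell, symops, d_min) {
  stopifnot(d_min > 0)
  key <- paste(signif(unlist(cell[c("a", "b", "c", "alpha", "beta", "gamma")]), 8),
               collapse = ","); key <- paste(key, length(symops), d_min)
  hit <- .anomsite_cache$uhkl[[key]]
  if (!is.null(hit)) return(hit)
  rec <- sqrt(rowSums(cell$frac^2))       # |a*|, |b*|, |c*|
  hmax <- floor(1 / (d_min * rec))
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2], l = -hmax[3]:hmax[3])
  H <- as.matrix(g)
  d <- d_spacing(cell, H)
  H <- H[d >= d_min & rowSums(abs(H)) > 0, , drop = FALSE]
  M <- max(abs(H)) + 1L
  lex <- function(A) (A[, 1] * (2 * M) + A[, 2]) * (2 * M) + A[, 3]
  best <- rep(-Inf, nrow(H))
  for (op in symops) for (sgn in c(1, -1)) {
    img <- sgn * (H %*% op$rot)
    best <- pmax(best, lex(img))
  }
  out <- H[lex(H) == best, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  if (is.null(.anomsite_cache$uhkl)) .anomsite_cache$uhkl <- list()
  .anomsite_cache$uhkl[[key]] <- out
  out
}

#' Write a reflection set as tab-separated text
#'
#' Columns `h k l F_plus SIGF_plus F_minus SIGF_minus` at full precision,
#' plus a JSON sidecar (`<path>.json`) holding cell, d_min and any extra
#' metadata supplied.
#'
#' @param refl A [reflection_set()].
#' @param path Output TSV path.
#' @param meta Named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(refl, path, meta = list()) {
  df <- data.frame(h = refl$hkl[, 1], k = refl$hkl[, 2], l = refl$hkl[, 3],
                   F_plus = refl$f_plus, SIGF_plus = refl$sig_plus,
                   F_minus = refl$f_minus, SIGF_minus = refl$sig_minus)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(cell = unlist(refl$cell[c("a", "b", "c", "alpha", "beta", "gamma")]),
                 d_min = refl$d_min, n_symops = length(refl$symops)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reflection set written by [write_reflections()]
#'
#' @param path TSV path (the JSON sidecar `<path>.json` must exist).
#' @param symops Operator list (the sidecar stores only the count).
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path, symops = symops_p1()) {
  df <- utils::read.delim(path)
  need <- c("h", "k", "l", "F_plus", "SIGF_plus", "F_minus", "SIGF_minus")
  if (!all(need %in% names(df)))
    stop("reflection file ", path, " is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cl <- do.call(unit_cell, as.list(unname(side$cell)))
  reflection_set(as.matrix(df[, c("h", "k", "l")]), df$F_plus, df$F_minus,
                 df$SIGF_plus, df$SIGF_minus, cl, symops, side$d_min)
}
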