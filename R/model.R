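#' Atom site table
#'
#' Build/validate the site table of a crystal model.  Sites are stored as a
#' data.frame with one row per atom in the asymmetric unit.
#'
#' @param element Chemical symbols (e.g. `"C"`, `"Zn"`, `"I"`).
#' @param x,y,z Fractional coordinates; reduced into `[0, 1)`.
#' @param occupancy Occupancies in `[0, 1]`.
#' @param b_iso Isotropic B factors in Angstrom^2, non-negative.
#' @param role One of `"scaffold"`, `"marker"`, `"probe"` per site.
#' @param label Unique free-text site labels.
#' @return data.frame with columns `element, x, y, z, occupancy, b_iso,
#'   role, label`.
#' @export
atom_sites <- function(element, x, y, z, occupancy = 1, b_iso = 20,
                       role = "scaffold", label = NULL) {
  n <- length(element)
  if (is.null(label)) label <- paste0(element, "_", seq_len(n))
  df <- data.frame(element = as.character(element),
                   x = as.numeric(x) %% 1, y = as.numeric(y) %% 1,
                   z = as.numeric(z) %% 1,
                   occupancy = rep_len(as.numeric(occupancy), n),
                   b_iso = rep_len(as.numeric(b_iso), n),
                   role = rep_len(as.character(role), n),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  if (any(df$occupancy < 0 | df$occupancy > 1))
    stop("occupancy must lie in [0, 1]")
  if (any(df$b_iso < 0)) stop("b_iso must be non-negative")
  if (!all(df$role %in% c("scaffold", "marker", "probe")))
    stop("role must be scaffold, marker or probe")
  if (anyDuplicated(df$label)) stop("site labels must be unique")
  df
}

#' Crystal model
#'
#' Ground-truth description of a simulated crystal: unit cell, space-group
#' operators and the atom sites of the asymmetric unit.
#'
#' @param cell A [unit_cell()].
#' @param symops List of [sym_op()] objects.
#' @param sites Site table from [atom_sites()].
#' @param spacegroup Space-group symbol carried through to PDB output.
#' @return Object of class `crystal_model`.
#' @export
crystal_model <- function(cell, symops, sites, spacegroup = "P 1") {
  stopifnot(inherits(cell, "unit_cell"), is.list(symops), is.data.frame(sites))
  if (!any(sites$role == "scaffold"))
    stop("a crystal model needs at least one scaffold site")
  structure(list(cell = cell, symops = symops, sites = sites,
                 spacegroup = spacegroup),
            class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  cat(sprintf("crystal model: %d sites (%d scaffold, %d marker, %d probe), %d symops\n",
              nrow(x$sites), sum(x$sites$role == "scaffold"),
              sum(x$sites$role == "marker"), sum(x$sites$role == "probe"),
              length(x$symops)))
  print(x$cell)
  invisible(x)
}

# element -> a plausible PDB atom/residue naming for round-tripping roles
.role_resname <- c(scaffold = "SCF", marker = "MRK", probe = "PRB")

#' Write a crystal model as PDB
#'
#' Fixed-column PDB with a CRYST1 record carrying cell and space group.
#' Occupancy and B columns follow the standard 2-decimal convention; roles
#' are encoded in the residue name so that [read_pdb_model()] round-trips.
#'
#' @param model A [crystal_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cl <- model$cell
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                     cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
                     model$spacegroup), con)
  xyz <- orthogonalize(cl, as.matrix(model$sites[, c("x", "y", "z")]))
  for (i in seq_len(nrow(model$sites))) {
    s <- model$sites[i, ]
    el <- toupper(s$element)
    name <- sprintf("%-4s", substr(el, 1, 2))
    writeLines(sprintf(
      "HETATM%5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000, name, .role_resname[[s$role]], i %% 10000,
      xyz[i, 1], xyz[i, 2], xyz[i, 3], s$occupancy, s$b_iso, el), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a crystal model from PDB
#'
#' Parses CRYST1 plus ATOM/HETATM records written by [write_pdb_model()].
#' Space-group operators are restored from the CRYST1 symbol when it is one
#' of the bundled groups, else P1 with a warning.
#'
#' @param path PDB file path.
#' @return A [crystal_model()].
#' @export
read_pdb_model <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) stop("PDB parse error: no CRYST1 record in ", path)
  cell <- unit_cell(as.numeric(substr(cr, 7, 15)), as.numeric(substr(cr, 16, 24)),
                    as.numeric(substr(cr, 25, 33)), as.numeric(substr(cr, 34, 40)),
                    as.numeric(substr(cr, 41, 47)), as.numeric(substr(cr, 48, 54)))
  sg <- trimws(substr(cr, 56, 66))
  symops <- tryCatch(symops_for(sg), error = function(e) {
    warning("unknown space group '", sg, "', assuming P1"); symops_p1()
  })
  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (!length(at)) stop("PDB parse error: no atom records in ", path)
  num <- function(a, b) as.numeric(substr(at, a, b))
  xyz <- cbind(num(31, 38), num(39, 46), num(47, 54))
  resname <- trimws(substr(at, 18, 20))
  role <- names(.role_resname)[match(resname, .role_resname)]
  role[is.na(role)] <- "scaffold"
  frac <- fractionalize(cell, xyz)
  # PDB element columns are uppercase; normalize to symbol capitalization
  el <- trimws(substr(at, 77, 78))
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  sites <- atom_sites(element = el,
                      x = frac[, 1], y = frac[, 2], z = frac[, 3],
                      occupancy = num(55, 60), b_iso = num(61, 66),
                      role = role)
  crystal_model(cell, symops, sites, spacegroup = sg)
}
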