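#' Construct a small-molecule / receptor container
#'
#' A \code{molecule} is the shared currency of the package: an ordered atom
#' table plus a bond table.  Atoms carry Cartesian coordinates in Angstrom,
#' partial charges in elementary-charge units and (once assigned) a
#' Tripos-style atom type such as \code{"C.3"} or \code{"N.am"}.
#'
#' @param name identifier string.
#' @param atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{charge} and optionally \code{type_label}, \code{name}.
#' @param bonds data.frame with columns \code{a}, \code{b}, \code{order}
#'   (one of \code{"1"}, \code{"2"}, \code{"3"}, \code{"ar"}, \code{"am"})
#'   and optionally logical \code{in_ring}, \code{rotatable}.  May have zero
#'   rows.
#' @param meta named list of arbitrary metadata (e.g. the declared torsion
#'   count of a PDBQT file).
#' @return an object of class \code{molecule}.
#' @export
molecule <- function(name, atoms, bonds = NULL, meta = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$type_label)) atoms$type_label <- NA_character_
  if (is.null(atoms$name)) {
    atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
  }
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a = integer(), b = integer(), order = character(),
                        in_ring = logical(), rotatable = logical(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    stopifnot(all(c("a", "b") %in% names(bonds)))
    if (is.null(bonds$order)) bonds$order <- "1"
    bonds$order <- as.character(bonds$order)
    if (is.null(bonds$in_ring)) bonds$in_ring <- NA
    if (is.null(bonds$rotatable)) bonds$rotatable <- NA
  }
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  m <- structure(list(name = name, atoms = atoms, bonds = bonds, meta = meta),
                 class = "molecule")
  validate_molecule(m)
  m
}

#' Validate molecule invariants
#'
#' Checks atom-index references, uniqueness of unordered bond pairs, finite
#' coordinates and known element symbols.  Called by every constructor and
#' parser; exported so tests and user code can re-check after manual edits.
#'
#' @param m a \code{molecule}.
#' @return \code{m}, invisibly, or an error.
#' @export
validate_molecule <- function(m) {
  a <- m$atoms; b <- m$bonds
  if (nrow(a) == 0L) stop("molecule has no atoms", call. = FALSE)
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  bad <- setdiff(a$element, names(.covalent_radius))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(b)) {
    if (any(b$a == b$b)) stop("bond connecting an atom to itself", call. = FALSE)
    if (any(b$a < 1L | b$a > nrow(a) | b$b < 1L | b$b > nrow(a))) {
      stop("bond references a non-existent atom index", call. = FALSE)
    }
    key <- paste(pmin(b$a, b$b), pmax(b$a, b$b))
    if (anyDuplicated(key)) stop("duplicate bond (unordered pair)", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds\n",
              x$name, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms / heavy atoms
#' @param m a \code{molecule}.
#' @return integer count.
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' @rdname n_atoms
#' @export
n_heavy_atoms <- function(m) sum(m$atoms$element != "H")

#' Atom coordinates as an n x 3 matrix (Angstrom)
#' @param m a \code{molecule}.
#' @return numeric matrix with one row per atom.
#' @export
coords <- function(m) {
  as.matrix(m$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param m a \code{molecule}.
#' @param xyz n x 3 numeric matrix.
#' @return the updated \code{molecule}.
#' @export
set_coords <- function(m, xyz) {
  stopifnot(nrow(xyz) == n_atoms(m), ncol(xyz) == 3)
  m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
  m
}

# Covalent radii in Angstrom (Cordero et al. consensus values) for the
# elements the toolkit handles; used for geometric bond perception.
.covalent_radius <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
  Se = 1.20, Zn = 1.22, Fe = 1.32, Mg = 1.41, Mn = 1.39, Ca = 1.76,
  Na = 1.66, K = 2.03, Du = 0.00
)

#' Covalent radius lookup
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  r <- .covalent_radius[element]
  if (any(is.na(r))) {
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  unname(r)
}
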