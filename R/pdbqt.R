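# AutoDock atom types -> element.  Covers the standard AutoDock 4 / Vina
# ligand and receptor types; aromatic carbon "A" maps to element C and is
# remembered so the Tripos typer can emit C.ar.
.autodock_elements <- c(
  H = "H", HD = "H", HS = "H",
  C = "C", A = "C",
  N = "N", NA. = "N", NS = "N",
  O = "O", OA = "O", OS = "O",
  F = "F", Mg = "Mg", MG = "Mg", P = "P",
  S = "S", SA = "S", Cl = "Cl", CL = "Cl",
  Ca = "Ca", CA = "Ca", Mn = "Mn", MN = "Mn",
  Fe = "Fe", FE = "Fe", Zn = "Zn", ZN = "Zn",
  Br = "Br", BR = "Br", I = "I", Si = "Si", B = "B",
  NA_ = "N")

#' Map AutoDock atom types to element symbols
#'
#' @param type character vector of AutoDock type tokens (e.g. \code{"OA"},
#'   \code{"HD"}, \code{"A"}).
#' @return character vector of element symbols; unknown tokens raise an
#'   error naming them.
#' @export
autodock_element <- function(type) {
  key <- ifelse(type == "NA", "NA_", type)
  el <- .autodock_elements[key]
  if (any(is.na(el))) {
    stop("unrecognized AutoDock atom type(s): ",
         paste(unique(type[is.na(el)]), collapse = ", "), call. = FALSE)
  }
  unname(el)
}

#' Read a PDBQT ligand into a molecule
#'
#' Parses \code{ATOM}/\code{HETATM} records (coordinates, partial charge and
#' AutoDock atom type).  The torsion-tree records \code{ROOT}, \code{BRANCH}
#' and \code{TORSDOF} are tolerated and recorded in \code{meta} but the
#' docking torsion list is always recomputed from perceived connectivity, so
#' the file's own branch tree is never a second source of truth.  PDBQT
#' carries no bond table, so the returned molecule has zero bonds; follow
#' with \code{\link{perceive_bonds}}.
#'
#' @param text a single string or character vector of PDBQT lines.
#' @param path alternatively, a file path.
#' @return a \code{\link{molecule}} with empty bonds; \code{meta$torsdof}
#'   holds the declared torsion count (if any), \code{meta$autodock_type}
#'   the per-atom AutoDock types.
#' @export
read_pdbqt <- function(text = NULL, path = NULL) {
  if (is.null(text) == is.null(path)) {
    stop("supply exactly one of 'text' or 'path'", call. = FALSE)
  }
  lines <- if (!is.null(path)) readLines(path, warn = FALSE)
           else unlist(strsplit(text, "\n", fixed = TRUE))

  rec <- substr(lines, 1, 6)
  at <- lines[trimws(rec) %in% c("ATOM", "HETATM")]
  if (!length(at)) stop("no ATOM/HETATM records in PDBQT input", call. = FALSE)

  # PDBQT columns follow PDB: name 13-16, x 31-38, y 39-46, z 47-54,
  # partial charge 67-76 (fixed width not guaranteed by all writers), then
  # the AutoDock type as the final whitespace-separated token.
  toks <- strsplit(trimws(at), "\\s+")
  ad_type <- vapply(toks, function(t) t[[length(t)]], "")
  charge <- vapply(toks, function(t) suppressWarnings(as.numeric(t[[length(t) - 1L]])), 0)
  x <- suppressWarnings(as.numeric(substr(at, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(at, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(at, 47, 54)))
  if (any(is.na(c(x, y, z)))) {
    # fall back to token positions for free-format writers
    xyz <- t(vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t))
      v <- v[!is.na(v)]
      # tokens: serial ... x y z occ b charge ; coordinates are the first
      # run of three consecutive reals after the serial number
      utils::tail(utils::head(v, -2), 3)[1:3]
    }, numeric(3)))
    x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  }
  if (any(is.na(charge))) charge[is.na(charge)] <- 0

  nm <- trimws(substr(at, 13, 16))
  nm[!nzchar(nm)] <- paste0(autodock_element(ad_type), seq_along(at))[!nzchar(nm)]

  tors_line <- grep("^TORSDOF", lines, value = TRUE)
  torsdof <- if (length(tors_line)) {
    as.integer(strsplit(trimws(tors_line[1]), "\\s+")[[1]][2])
  } else NA_integer_

  mol_name <- {
    nml <- grep("^(REMARK\\s+Name\\s*=|COMPND)", lines, value = TRUE)
    if (length(nml)) trimws(sub("^.*(=|COMPND)", "", nml[1])) else "pdbqt_ligand"
  }

  molecule(
    name = mol_name,
    atoms = data.frame(element = autodock_element(ad_type),
                       x = x, y = y, z = z, charge = charge,
                       name = nm, stringsAsFactors = FALSE),
    bonds = NULL,
    meta = list(torsdof = torsdof, autodock_type = ad_type))
}

#' Convert a PDBQT ligand to a MOL2 record
#'
#' The on-the-fly conversion pipeline used when a screening library is
#' stored in PDBQT: \code{\link{read_pdbqt}} then \code{\link{perceive_bonds}}
#' then \code{\link{assign_tripos_types}} then \code{\link{write_mol2}}.
#' Heavy-atom count, element multiset and per-atom partial charges are
#' preserved exactly; any stage failure is re-raised with the stage name.
#'
#' @param text PDBQT record as a string or character vector of lines.
#' @param path alternatively, a PDBQT file path.
#' @return a MOL2 record as a single string.
#' @export
convert_pdbqt_to_mol2 <- function(text = NULL, path = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  m <- stage("read_pdbqt", read_pdbqt(text = text, path = path))
  m <- stage("perceive_bonds", perceive_bonds(m))
  m <- stage("assign_tripos_types", assign_tripos_types(m))
  stage("write_mol2", write_mol2(m))
}
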