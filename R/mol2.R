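#' Read a Tripos MOL2 record into a molecule
#'
#' Parsing is delegated to \code{bio3d::read.mol2}; this wrapper adds the
#' structural checks a screening pipeline needs (section headers present,
#' declared atom/bond counts matching the actual record counts) and converts
#' the result into the package's \code{\link{molecule}} container.  The
#' element symbol is derived from the Tripos atom type (the token before the
#' first dot).
#'
#' @param text a single string, or character vector of lines, holding one
#'   MOL2 record.
#' @param path alternatively, a file path (exclusive with \code{text}).
#' @return a \code{\link{molecule}} with \code{type_label} populated from the
#'   MOL2 atom types and ring/rotatable bond flags unset.
#' @export
read_mol2 <- function(text = NULL, path = NULL) {
  if (is.null(text) == is.null(path)) {
    stop("supply exactly one of 'text' or 'path'", call. = FALSE)
  }
  lines <- if (!is.null(path)) readLines(path, warn = FALSE)
           else unlist(strsplit(text, "\n", fixed = TRUE))

  hdr <- grep("^@<TRIPOS>", lines)
  sect <- sub("^@<TRIPOS>", "", trimws(lines[hdr]))
  mal <- grepl("^@", lines) & !grepl("^@<TRIPOS>[A-Z_]+\\s*$", lines)
  if (any(mal)) {
    stop(sprintf("malformed MOL2 section header at line %d: '%s'",
                 which(mal)[1], lines[which(mal)[1]]), call. = FALSE)
  }
  if (!"MOLECULE" %in% sect) stop("missing @<TRIPOS>MOLECULE section", call. = FALSE)
  if (!"ATOM" %in% sect) stop("missing @<TRIPOS>ATOM section", call. = FALSE)

  mol_at <- hdr[match("MOLECULE", sect)]
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[mol_at + 2L]),
                                                 "\\s+")[[1]]))
  if (length(counts) < 1L || is.na(counts[1])) {
    stop(sprintf("unparseable counts line at line %d", mol_at + 2L), call. = FALSE)
  }
  n_at_decl <- counts[1]
  n_bd_decl <- if (length(counts) >= 2L && !is.na(counts[2])) counts[2] else 0L

  sec_lines <- function(nm) {
    i <- hdr[match(nm, sect)]
    if (is.na(i)) return(character())
    j <- hdr[hdr > i]
    end <- if (length(j)) min(j) - 1L else length(lines)
    out <- lines[seq(i + 1L, length.out = max(0L, end - i))]
    out[nzchar(trimws(out))]
  }
  if (length(sec_lines("ATOM")) != n_at_decl) {
    stop(sprintf("MOL2 declares %d atoms but ATOM section has %d records",
                 n_at_decl, length(sec_lines("ATOM"))), call. = FALSE)
  }
  if (length(sec_lines("BOND")) != n_bd_decl) {
    stop(sprintf("MOL2 declares %d bonds but BOND section has %d records",
                 n_bd_decl, length(sec_lines("BOND"))), call. = FALSE)
  }

  tf <- tempfile(fileext = ".mol2")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  raw <- suppressWarnings(bio3d::read.mol2(tf))

  atoms <- data.frame(
    element = element_from_tripos(raw$atom$elety),
    x = raw$atom$x, y = raw$atom$y, z = raw$atom$z,
    charge = ifelse(is.na(raw$atom$charge), 0, raw$atom$charge),
    type_label = raw$atom$elety,
    name = raw$atom$elena,
    stringsAsFactors = FALSE)
  bonds <- NULL
  if (!is.null(raw$bond) && nrow(raw$bond)) {
    bonds <- data.frame(a = as.integer(raw$bond$origin),
                        b = as.integer(raw$bond$target),
                        order = as.character(raw$bond$type),
                        stringsAsFactors = FALSE)
  }
  molecule(name = raw$name, atoms = atoms, bonds = bonds)
}

#' Derive the element symbol from a Tripos atom type
#'
#' \code{"C.3" -> "C"}, \code{"N.am" -> "N"}, \code{"Cl" -> "Cl"}.
#' @param type_label character vector of Tripos types.
#' @return character vector of element symbols.
#' @export
element_from_tripos <- function(type_label) {
  el <- sub("\\..*$", "", type_label)
  # normalize case: MOL2 types use e.g. "CL"/"Cl" interchangeably
  known <- names(.covalent_radius)
  fix <- !(el %in% known)
  el[fix] <- paste0(toupper(substr(el[fix], 1, 1)),
                    tolower(substr(el[fix], 2, nchar(el[fix]))))
  el
}

#' Write a molecule as a Tripos MOL2 record
#'
#' Emits \code{@<TRIPOS>MOLECULE}, \code{ATOM} and \code{BOND} sections with
#' coordinates and charges printed to four decimal places, so that a
#' write/read cycle is stable at that precision.
#'
#' @param m a \code{\link{molecule}} whose atoms all carry a
#'   \code{type_label} (run \code{\link{assign_tripos_types}} first if they
#'   do not).
#' @param path optional file path; when given the text is also written there.
#' @return the MOL2 record as a single string (invisibly when \code{path} is
#'   given).
#' @export
write_mol2 <- function(m, path = NULL) {
  validate_molecule(m)
  if (any(is.na(m$atoms$type_label))) {
    stop("atom(s) without a Tripos type_label; run assign_tripos_types() first",
         call. = FALSE)
  }
  a <- m$atoms; b <- m$bonds
  out <- c(
    "@<TRIPOS>MOLECULE",
    m$name,
    sprintf("%d %d 1 0 0", nrow(a), nrow(b)),
    "SMALL",
    "USER_CHARGES",
    "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %3d %-8s %10.4f",
            seq_len(nrow(a)), a$name, a$x, a$y, a$z, a$type_label,
            1L, "LIG1", a$charge))
  if (nrow(b)) {
    out <- c(out, "@<TRIPOS>BOND",
             sprintf("%6d %5d %5d %s", seq_len(nrow(b)), b$a, b$b, b$order))
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
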