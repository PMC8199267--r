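#' Perceive covalent bonds from interatomic distances
#'
#' A bond is created between atoms i and j when their distance does not
#' exceed \code{scale} times the sum of their covalent radii (Cordero
#' consensus values; e.g. 0.76 A for carbon, so two carbons bond below
#' 1.824 A at the default scale).  Hydrogen-hydrogen bonds are never
#' created.  Ring membership is perceived on the resulting graph.
#'
#' @param m a \code{\link{molecule}} with elements and coordinates.
#' @param scale multiplier on the radius sum; default 1.2, the standard
#'   geometric-perception heuristic.
#' @return the molecule with a populated bond table (all orders \code{"1"};
#'   aromatic orders are upgraded later by \code{\link{assign_tripos_types}}
#'   when AutoDock aromatic types are available) and \code{in_ring} flags.
#' @export
perceive_bonds <- function(m, scale = 1.2) {
  xyz <- coords(m)
  el <- m$atoms$element
  r <- covalent_radius(el)  # errors on unknown elements
  n <- nrow(xyz)
  bonds <- NULL
  if (n > 1L) {
    d <- as.matrix(stats::dist(xyz))
    thr <- outer(r, r, "+") * scale
    hit <- d <= thr & upper.tri(d)
    hh <- outer(el == "H", el == "H", "&")
    hit <- hit & !hh
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) {
      bonds <- data.frame(a = idx[, 1], b = idx[, 2], order = "1",
                          stringsAsFactors = FALSE)
    }
  }
  m$bonds <- if (is.null(bonds)) {
    data.frame(a = integer(), b = integer(), order = character(),
               in_ring = logical(), rotatable = logical(),
               stringsAsFactors = FALSE)
  } else bonds
  perceive_rings(m)
}

#' Flag ring bonds
#'
#' An edge lies in a ring iff it is not a bridge of the molecular graph.
#'
#' @param m a \code{\link{molecule}} with bonds.
#' @return the molecule with logical \code{in_ring} on every bond.
#' @export
perceive_rings <- function(m) {
  b <- m$bonds
  if (!nrow(b)) return(m)
  g <- igraph::make_graph(edges = rbind(b$a, b$b), n = n_atoms(m),
                          directed = FALSE)
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(b))
  in_ring[as.integer(br)] <- FALSE
  m$bonds$in_ring <- in_ring
  m
}

neighbor_list <- function(m) {
  n <- n_atoms(m)
  nb <- vector("list", n)
  b <- m$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$a[k]]] <- c(nb[[b$a[k]]], b$b[k])
    nb[[b$b[k]]] <- c(nb[[b$b[k]]], b$a[k])
  }
  nb
}

bond_orders_at <- function(m, i) {
  b <- m$bonds
  b$order[b$a == i | b$b == i]
}

#' Assign Tripos-style atom types
#'
#' Deterministic typing from element, connectivity and bond orders:
#' sp assignment follows the highest bond order at the atom (triple -> .1,
#' double -> .2, aromatic -> .ar, otherwise .3), with the usual special
#' cases: amide nitrogen \code{N.am} (single-bonded to a carbonyl carbon),
#' quaternary \code{N.4}, carboxylate \code{O.co2}, sulfone/sulfoxide
#' \code{S.o2}/\code{S.o}.  When the molecule came from PDBQT, AutoDock
#' aromatic types (\code{A}, \code{NA}, \code{SA} in rings) upgrade ring
#' bonds between such atoms to aromatic order first.
#'
#' @param m a \code{\link{molecule}} with bonds (and \code{in_ring} flags).
#' @return the molecule with \code{type_label} set on every atom.
#' @export
assign_tripos_types <- function(m) {
  if (!nrow(m$bonds) && n_atoms(m) > 1L) {
    stop("assign_tripos_types requires bonds; run perceive_bonds first",
         call. = FALSE)
  }
  if (any(is.na(m$bonds$in_ring))) m <- perceive_rings(m)

  # AutoDock aromatic carbons: upgrade ring bonds between aromatic-typed
  # atoms to aromatic order so sp assignment sees them.
  adt <- m$meta$autodock_type
  if (!is.null(adt) && nrow(m$bonds)) {
    arom_atom <- adt %in% c("A")
    b <- m$bonds
    up <- b$in_ring & arom_atom[b$a] & arom_atom[b$b]
    m$bonds$order[up] <- "ar"
  }

  nb <- neighbor_list(m)
  el <- m$atoms$element
  n <- n_atoms(m)
  lab <- character(n)

  max_valence <- c(H = 1, C = 4, N = 4, O = 3, S = 6, P = 5,
                   F = 1, Cl = 1, Br = 1, I = 1, B = 4)
  for (i in seq_len(n)) {
    deg <- length(nb[[i]])
    mv <- max_valence[el[i]]
    if (!is.na(mv) && deg > mv) {
      stop(sprintf("atom %d (%s) has %d bonds; valence impossible",
                   i, el[i], deg), call. = FALSE)
    }
  }

  has_order <- function(i, o) any(bond_orders_at(m, i) == o)
  carbonyl_carbon <- vapply(seq_len(n), function(i) {
    el[i] == "C" && any(vapply(nb[[i]], function(j) {
      el[j] %in% c("O", "S") &&
        any(m$bonds$order[(m$bonds$a == i & m$bonds$b == j) |
                          (m$bonds$a == j & m$bonds$b == i)] == "2")
    }, TRUE))
  }, TRUE)

  for (i in seq_len(n)) {
    e <- el[i]
    ords <- bond_orders_at(m, i)
    lab[i] <- switch(e,
      H = "H",
      C = if (any(ords == "ar")) "C.ar"
          else if (any(ords == "3")) "C.1"
          else if (any(ords == "2")) "C.2"
          else "C.3",
      N = {
        if (any(ords == "ar")) "N.ar"
        else if (any(ords == "3")) "N.1"
        else if (any(ords %in% c("am"))) "N.am"
        else if (any(ords == "2")) "N.2"
        else if (length(nb[[i]]) == 4L) "N.4"
        else if (any(vapply(nb[[i]], function(j) carbonyl_carbon[j], TRUE)))
          "N.am"
        else "N.3"
      },
      O = {
        cox <- FALSE
        if (length(nb[[i]]) == 1L) {
          cj <- nb[[i]][1]
          if (el[cj] == "C") {
            oxn <- Filter(function(j) el[j] == "O" &&
                            length(nb[[j]]) == 1L, nb[[cj]])
            cox <- length(oxn) >= 2L
          }
        }
        if (cox) "O.co2"
        else if (any(ords == "2")) "O.2"
        else "O.3"
      },
      S = {
        dbl_o <- sum(vapply(nb[[i]], function(j) {
          el[j] == "O" &&
            any(m$bonds$order[(m$bonds$a == i & m$bonds$b == j) |
                              (m$bonds$a == j & m$bonds$b == i)] == "2")
        }, TRUE))
        if (dbl_o >= 2L) "S.o2"
        else if (dbl_o == 1L) "S.o"
        else if (any(ords == "2")) "S.2"
        else "S.3"
      },
      P = "P.3",
      e)  # halogens, metals: the bare element symbol
  }
  m$atoms$type_label <- lab
  m
}

#' Detect rotatable bonds
#'
#' A bond is rotatable when it is a single (order \code{"1"}) acyclic bond
#' whose two endpoint atoms each have at least one further heavy-atom
#' neighbor (so rotating it changes the conformation), excluding amide C-N
#' bonds by default (their partial double-bond character keeps them planar).
#'
#' @param m a \code{\link{molecule}} with bonds and \code{in_ring} flags.
#' @param exclude_amide logical; drop C-N bonds at carbonyl carbons.
#' @return sorted integer vector of rotatable bond row indices; the
#'   molecule's \code{rotatable} flags can be refreshed with
#'   \code{\link{flag_rotatable_bonds}}.
#' @export
detect_rotatable_bonds <- function(m, exclude_amide = TRUE) {
  b <- m$bonds
  if (!nrow(b)) return(integer())
  if (any(is.na(b$in_ring))) {
    m <- perceive_rings(m)
    b <- m$bonds
  }
  nb <- neighbor_list(m)
  el <- m$atoms$element
  heavy_nb_excl <- function(i, j) {
    sum(el[setdiff(nb[[i]], j)] != "H")
  }
  out <- integer()
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != "1" || isTRUE(b$in_ring[k])) next
    i <- b$a[k]; j <- b$b[k]
    if (el[i] == "H" || el[j] == "H") next
    if (heavy_nb_excl(i, j) < 1L || heavy_nb_excl(j, i) < 1L) next
    if (exclude_amide) {
      # C-N where the carbon carries a double-bonded O/S (amide-like)
      ij <- c(i, j)
      cn <- el[ij] %in% c("C", "N")
      if (all(cn) && length(unique(el[ij])) == 2L) {
        ci <- ij[el[ij] == "C"]
        dbl_ox <- any(vapply(nb[[ci]], function(q) {
          el[q] %in% c("O", "S") &&
            any(b$order[(b$a == ci & b$b == q) | (b$a == q & b$b == ci)] == "2")
        }, TRUE))
        if (dbl_ox) next
      }
    }
    out <- c(out, k)
  }
  sort(out)
}

#' @rdname detect_rotatable_bonds
#' @export
flag_rotatable_bonds <- function(m, exclude_amide = TRUE) {
  if (any(is.na(m$bonds$in_ring))) m <- perceive_rings(m)
  rot <- detect_rotatable_bonds(m, exclude_amide = exclude_amide)
  m$bonds$rotatable <- seq_len(nrow(m$bonds)) %in% rot
  m
}

#' Graph (bond-count) distances between all atom pairs
#'
#' Used by the internal-clash term to exclude pairs closer than a bond
#' separation cutoff.
#'
#' @param m a \code{\link{molecule}} with bonds.
#' @return integer matrix of shortest-path bond counts (Inf if disconnected).
#' @export
bond_separation <- function(m) {
  g <- igraph::make_graph(edges = rbind(m$bonds$a, m$bonds$b),
                          n = n_atoms(m), directed = FALSE)
  igraph::distances(g)
}
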