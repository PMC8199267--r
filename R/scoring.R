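#' Piece-wise linear potential parameter set
#'
#' Four breakpoints 0 < A < B < C < D (Angstrom) define the shape: a linear
#' clash wall below A (slope \code{clash_weight} per Angstrom of
#' penetration), a linear descent from 0 at A to \code{well_depth} at B, a
#' flat well on [B, C], a linear return to 0 at D and zero beyond.  Scores
#' are dimensionless; negative is favorable.
#'
#' @param A,B,C,D breakpoints in Angstrom.
#' @param well_depth well value (<= 0).
#' @param clash_weight positive clash slope.
#' @return object of class \code{plp_params}.
#' @export
plp_params <- function(A, B, C, D, well_depth, clash_weight) {
  if (!(0 < A && A < B && B < C && C < D)) {
    stop("require 0 < A < B < C < D", call. = FALSE)
  }
  if (well_depth > 0) stop("well_depth must be <= 0", call. = FALSE)
  if (clash_weight <= 0) stop("clash_weight must be > 0", call. = FALSE)
  structure(list(A = A, B = B, C = C, D = D, well_depth = well_depth,
                 clash_weight = clash_weight), class = "plp_params")
}

#' Named scoring-function parameterizations
#'
#' Returns the full parameter set behind one of the three selectable
#' scoring functions.  The piecewise-linear functional form, the
#' heavy-atom-only pair summation, the internal clash and the Tripos-style
#' torsional term are fixed; the numeric values here are this package's own
#' parameterization (every value can be overridden via the scenario config).
#' \code{plp} and \code{plp95} differ only in their distance breakpoints
#' and well depths; \code{chemplp} adds the angle-dependent hydrogen-bond
#' term on top of the \code{plp} pair potentials.
#'
#' @param scoring_function one of \code{"plp"}, \code{"plp95"},
#'   \code{"chemplp"}.
#' @param overrides optional named list replacing individual entries
#'   (e.g. \code{list(hbond_weight = -4)}).
#' @return a list with elements \code{steric}, \code{hbond_pair}
#'   (\code{\link{plp_params}}), \code{hbond_geom} (chemplp only, else
#'   \code{NULL}), \code{torsion_table}, \code{scoring_function}.
#' @export
scoring_params <- function(scoring_function = c("chemplp", "plp", "plp95"),
                           overrides = NULL) {
  scoring_function <- match.arg(scoring_function)
  base <- switch(scoring_function,
    plp = ,
    chemplp = list(
      steric = plp_params(3.4, 3.6, 4.5, 5.5, -0.4, 20),
      hbond_pair = plp_params(2.3, 2.6, 3.1, 3.4, -2.0, 20)),
    plp95 = list(
      steric = plp_params(3.4, 3.6, 5.0, 6.0, -0.4, 20),
      hbond_pair = plp_params(2.3, 2.6, 3.4, 3.7, -2.0, 20)))
  base$hbond_geom <- if (scoring_function == "chemplp") {
    list(ideal_distance = 1.9, distance_tolerance = 0.45,
         ideal_angle = 180, angle_tolerance = 60, hbond_weight = -3.0)
  } else NULL
  base$torsion_table <- default_torsion_table()
  base$scoring_function <- scoring_function
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (nm %in% names(base$hbond_geom)) base$hbond_geom[[nm]] <- overrides[[nm]]
      else base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

# Tripos-style torsional parameters keyed by the sp labels of the two bond
# atoms; k in score units, n the periodicity, phi0 in degrees.  Generic
# sp3-sp3 fallback k = 0.2, n = 3, phi0 = 0.
default_torsion_table <- function() {
  list(
    "C.3-C.3" = list(k = 0.2, n = 3L, phi0 = 0),
    "C.3-N.3" = list(k = 0.2, n = 3L, phi0 = 0),
    "C.3-O.3" = list(k = 0.2, n = 3L, phi0 = 0),
    "C.2-C.3" = list(k = 0.1, n = 6L, phi0 = 0),
    "C.2-C.2" = list(k = 0.6, n = 2L, phi0 = 180),
    "C.ar-C.3" = list(k = 0.1, n = 6L, phi0 = 0),
    .default = list(k = 0.2, n = 3L, phi0 = 0))
}

torsion_params_for <- function(type_a, type_b, table) {
  key <- paste(sort(c(type_a, type_b)), collapse = "-")
  if (!is.null(table[[key]])) table[[key]] else table$.default
}

#' Piece-wise linear pair potential
#'
#' @param r distance(s) in Angstrom (vectorized).
#' @param p a \code{\link{plp_params}} set.
#' @return score value(s): \code{clash_weight*(A-r)} below A, linear to
#'   \code{well_depth} at B, flat to C, linear back to 0 at D, 0 beyond;
#'   continuous everywhere.
#' @export
plp_pair <- function(r, p) {
  if (!inherits(p, "plp_params")) stop("p must be plp_params", call. = FALSE)
  stopifnot(all(r >= 0))
  w <- p$well_depth
  out <- numeric(length(r))
  i <- r < p$A
  out[i] <- p$clash_weight * (p$A - r[i])
  i <- r >= p$A & r < p$B
  out[i] <- w * (r[i] - p$A) / (p$B - p$A)
  i <- r >= p$B & r <= p$C
  out[i] <- w
  i <- r > p$C & r < p$D
  out[i] <- w * (p$D - r[i]) / (p$D - p$C)
  out
}

block_ramp <- function(dev, tol) pmax(0, 1 - abs(dev) / tol)

#' Angle-dependent hydrogen-bond term
#'
#' Separable product of two linear "block" ramps: one on the deviation of
#' the H...acceptor distance from its ideal value, one on the deviation of
#' the donor-H...acceptor angle from linearity.  At ideal geometry the term
#' equals \code{hbond_weight}; it decays linearly to 0 at the tolerances.
#' Only the chemplp scoring function carries this term.
#'
#' @param donor_pos,hydrogen_pos,acceptor_pos length-3 coordinates (A).
#' @param p the \code{hbond_geom} list of a chemplp
#'   \code{\link{scoring_params}} set.
#' @return score in [\code{hbond_weight}, 0].
#' @export
hbond_term <- function(donor_pos, hydrogen_pos, acceptor_pos, p) {
  if (is.null(p)) {
    stop("hydrogen-bond term requested under a scoring function without one",
         call. = FALSE)
  }
  dv <- hydrogen_pos - donor_pos
  av <- acceptor_pos - hydrogen_pos
  dist <- sqrt(sum(av^2))
  cosang <- -sum(dv * av) / (sqrt(sum(dv^2)) * dist)
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi  # D-H...A angle, 180 = linear
  p$hbond_weight *
    block_ramp(dist - p$ideal_distance, p$distance_tolerance) *
    block_ramp(ang - p$ideal_angle, p$angle_tolerance)
}

#' Tripos-style torsional potential
#'
#' @param phi torsion angle(s) in degrees (any real; periodic).
#' @param t a record with \code{k}, \code{n}, \code{phi0}.
#' @return \code{k * (1 + cos(n*phi - phi0))}, in [0, 2k].
#' @export
torsion_energy <- function(phi, t) {
  t$k * (1 + cos(deg2rad(t$n * phi - t$phi0)))
}

#' Ligand-internal heavy-atom clash score
#'
#' Sums the repulsive branch of the pair potential
#' (\code{clash_weight*(A-r)} for r < A, else 0) over heavy-atom pairs at
#' least four bonds apart (the standard 1-4 exclusion: pairs three or fewer
#' bonds apart are constrained by the covalent geometry, not by the pose).
#'
#' @param xyz n x 3 coordinates for the ligand's atoms.
#' @param m the ligand \code{\link{molecule}} (for elements and bond graph).
#' @param p a \code{\link{plp_params}} set (the steric class).
#' @param sep optional precomputed \code{\link{bond_separation}} matrix.
#' @return non-negative clash score.
#' @export
internal_clash <- function(xyz, m, p, sep = NULL) {
  heavy <- which(m$atoms$element != "H")
  if (length(heavy) < 2L) return(0)
  if (is.null(sep)) sep <- bond_separation(m)
  tot <- 0
  for (ii in seq_along(heavy)[-length(heavy)]) {
    i <- heavy[ii]
    js <- heavy[(ii + 1L):length(heavy)]
    js <- js[sep[i, js] >= 4]
    if (!length(js)) next
    d <- sqrt(rowSums((xyz[js, , drop = FALSE] -
                         matrix(xyz[i, ], length(js), 3, byrow = TRUE))^2))
    pen <- d < p$A
    if (any(pen)) tot <- tot + sum(p$clash_weight * (p$A - d[pen]))
  }
  tot
}

# donor heavy atoms: N/O with at least one bonded hydrogen; acceptors: any
# O, plus N not of quaternary/amide type.  Returns list(donors = data.frame
# (heavy, h), acceptors = integer vector).
hbond_sites <- function(m) {
  el <- m$atoms$element
  nb <- neighbor_list(m)
  donors <- list()
  for (i in which(el %in% c("N", "O"))) {
    hs <- nb[[i]][el[nb[[i]]] == "H"]
    for (h in hs) donors[[length(donors) + 1L]] <- c(i, h)
  }
  donors <- if (length(donors)) do.call(rbind, donors) else
    matrix(integer(), ncol = 2)
  acc <- which(el == "O" |
                 (el == "N" & !(m$atoms$type_label %in% c("N.4", "N.am"))))
  list(donors = donors, acceptors = acc)
}

#' Score a ligand pose against a rigid receptor
#'
#' The docking objective f(x).  The total is the sum of four terms:
#' piece-wise linear pair potentials over all receptor-heavy/ligand-heavy
#' atom pairs (the hydrogen-bond-capable pair class uses the shorter-range
#' parameter set), the angle-dependent hydrogen-bond term (chemplp only),
#' the ligand-internal clash score, and the torsional potential over the
#' rotatable-bond dofs.  More negative totals mean stronger predicted
#' binding.
#'
#' @param receptor receptor \code{\link{molecule}} (held rigid).
#' @param ligand ligand \code{\link{molecule}} (reference conformation).
#' @param x pose dof vector, or an n_atoms x 3 coordinate matrix to score
#'   fixed coordinates directly.
#' @param params a \code{\link{scoring_params}} set.
#' @param spec the ligand's \code{\link{build_dof_spec}} (required when
#'   \code{x} is a dof vector).
#' @param cache optional precomputed invariants from
#'   \code{\link{score_cache}}; speeds up repeated calls.
#' @return object of class \code{score_breakdown}: \code{steric},
#'   \code{hbond}, \code{internal_clash}, \code{torsion}, \code{total}.
#' @export
score_pose <- function(receptor, ligand, x, params, spec = NULL,
                       cache = NULL) {
  if (is.null(cache)) cache <- score_cache(receptor, ligand, params)
  if (is.matrix(x)) {
    xyz <- x
    torsions <- NULL
  } else {
    if (is.null(spec)) stop("spec required when x is a dof vector", call. = FALSE)
    xyz <- apply_pose(ligand, x, spec)
    torsions <- if (spec$n > 6L) x[7L:spec$n] else numeric()
  }

  lig_heavy <- cache$lig_heavy
  lx <- xyz[lig_heavy, , drop = FALSE]
  d2 <- outer(rowSums(cache$rec_xyz_h^2), rowSums(lx^2), "+") -
    2 * cache$rec_xyz_h %*% t(lx)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  steric <- sum(plp_pair(d[cache$pair_is_hb], params$hbond_pair)) +
            sum(plp_pair(d[!cache$pair_is_hb], params$steric))

  hb <- 0
  if (!is.null(params$hbond_geom)) {
    geom <- params$hbond_geom
    cutoff <- geom$ideal_distance + geom$distance_tolerance
    # ligand donors -> receptor acceptors
    if (nrow(cache$lig_sites$donors)) {
      for (k in seq_len(nrow(cache$lig_sites$donors))) {
        dh <- cache$lig_sites$donors[k, ]
        hp <- xyz[dh[2], ]; dp <- xyz[dh[1], ]
        for (a in cache$rec_sites$acceptors) {
          ap <- cache$rec_xyz[a, ]
          if (sum((ap - hp)^2) > cutoff^2) next
          hb <- hb + hbond_term(dp, hp, ap, geom)
        }
      }
    }
    # receptor donors -> ligand acceptors
    if (nrow(cache$rec_sites$donors)) {
      for (k in seq_len(nrow(cache$rec_sites$donors))) {
        dh <- cache$rec_sites$donors[k, ]
        hp <- cache$rec_xyz[dh[2], ]; dp <- cache$rec_xyz[dh[1], ]
        for (a in cache$lig_sites$acceptors) {
          ap <- xyz[a, ]
          if (sum((ap - hp)^2) > cutoff^2) next
          hb <- hb + hbond_term(dp, hp, ap, geom)
        }
      }
    }
  }

  clash <- internal_clash(xyz, ligand, params$steric, sep = cache$lig_sep)

  tors <- 0
  if (!is.null(torsions) && length(torsions)) {
    for (t in seq_along(torsions)) {
      tors <- tors + torsion_energy(torsions[t], cache$torsion_params[[t]])
    }
  }

  structure(list(steric = steric, hbond = hb, internal_clash = clash,
                 torsion = tors, total = steric + hb + clash + tors),
            class = "score_breakdown")
}

#' Precompute pose-invariant scoring state
#'
#' @inheritParams score_pose
#' @return a cache list consumed by \code{\link{score_pose}}.
#' @export
score_cache <- function(receptor, ligand, params, spec = NULL) {
  rec_heavy <- which(receptor$atoms$element != "H")
  lig_heavy <- which(ligand$atoms$element != "H")
  rec_sites <- hbond_sites(receptor)
  lig_sites <- hbond_sites(ligand)
  # pair class: hbond-capable pairing when one side is a donor heavy atom or
  # acceptor and the other side an acceptor/donor (polar-polar contact)
  polar <- function(m, sites, heavy) {
    don <- unique(sites$donors[, 1])
    heavy %in% union(don, sites$acceptors)
  }
  rp <- polar(receptor, rec_sites, rec_heavy)
  lp <- polar(ligand, lig_sites, lig_heavy)
  rot <- detect_rotatable_bonds(ligand)
  tl <- ligand$atoms$type_label
  torsion_params <- lapply(rot, function(k) {
    torsion_params_for(tl[ligand$bonds$a[k]], tl[ligand$bonds$b[k]],
                       params$torsion_table)
  })
  list(rec_xyz = coords(receptor),
       rec_xyz_h = coords(receptor)[rec_heavy, , drop = FALSE],
       rec_heavy = rec_heavy, lig_heavy = lig_heavy,
       pair_is_hb = outer(rp, lp, "&"),
       rec_sites = rec_sites, lig_sites = lig_sites,
       lig_sep = bond_separation(ligand),
       torsion_params = torsion_params)
}
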