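#' Spherical docking search region
#'
#' @param center numeric length-3, Angstrom.
#' @param radius positive radius in Angstrom.  The default search region of
#'   the screening presets uses 13 A.
#' @return object of class \code{docking_sphere}.
#' @export
docking_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, is.finite(center), radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "docking_sphere")
}

#' Interval partition of one degree of freedom
#'
#' Splits [a, b] at a fixed step into the strictly increasing boundary
#' sequence a = z_0 < z_1 < ... < z_n = b used by the discretized search.
#'
#' @param a,b interval bounds.
#' @param step positive step; must divide (b - a) to within 1e-9.
#' @return object of class \code{dof_partition} with fields
#'   \code{boundaries} and \code{n_intervals}.
#' @export
build_partition <- function(a, b, step) {
  stopifnot(b > a, step > 0)
  n <- (b - a) / step
  if (abs(n - round(n)) > 1e-9) {
    stop(sprintf("step %g does not divide the interval [%g, %g]", step, a, b),
         call. = FALSE)
  }
  n <- as.integer(round(n))
  structure(list(boundaries = seq(a, b, length.out = n + 1L), n_intervals = n),
            class = "dof_partition")
}

#' Assign a continuous value to its discretization interval
#'
#' Returns the index l in 1..n with x in [z_{l-1}, z_l].  Interior boundary
#' points belong to the lower-indexed interval; x = a maps to interval 1.
#' On the unit-width partition of [0, 360] the value 1.7 falls in interval 2.
#'
#' @param x numeric value(s) within the partition bounds.
#' @param p a \code{\link{build_partition}} result.
#' @return integer interval index (vectorized over \code{x}).
#' @export
assign_interval <- function(x, p) {
  z <- p$boundaries
  if (any(x < z[1] - 1e-12 | x > z[length(z)] + 1e-12)) {
    stop("value outside partition bounds", call. = FALSE)
  }
  idx <- findInterval(x, z, left.open = TRUE)
  idx[idx == 0L] <- 1L
  idx
}

#' Characteristic (indicator) function of one interval
#'
#' chi_l(x) is 1 when x lies in interval l of the partition and 0 otherwise,
#' following the same boundary convention as \code{\link{assign_interval}}.
#'
#' @param x numeric value within bounds.
#' @param l interval index.
#' @param p a \code{\link{build_partition}} result.
#' @return 0 or 1.
#' @export
chi_indicator <- function(x, l, p) {
  as.numeric(assign_interval(x, p) == l)
}

#' Interval midpoints and representative values
#' @param p a \code{\link{build_partition}} result.
#' @param l interval index vector (default all).
#' @return numeric vector of midpoints (or upper bounds for
#'   \code{interval_upper}).
#' @export
interval_midpoint <- function(p, l = seq_len(p$n_intervals)) {
  (p$boundaries[l] + p$boundaries[l + 1L]) / 2
}

#' @rdname interval_midpoint
#' @export
interval_upper <- function(p, l = seq_len(p$n_intervals)) {
  p$boundaries[l + 1L]
}

#' Build the degree-of-freedom specification for a ligand in a sphere
#'
#' The pose of a flexible ligand has n = 3 + 3 + n_rot degrees of freedom:
#' three translations of the centroid relative to the sphere center (bounded
#' by the sphere's axis-aligned bounding box), three orientation angles
#' (Z-Y-Z Euler, each on [0, 360) degrees) and one torsion angle per
#' rotatable bond.  Rotational dofs are partitioned at \code{angular_step}
#' degrees, translations at \code{linear_step} Angstrom.
#'
#' @param ligand a \code{\link{molecule}} (rotatable bonds are detected here
#'   if not yet flagged).
#' @param sphere a \code{\link{docking_sphere}}.
#' @param angular_step degrees; must divide 360.  Default 1.
#' @param linear_step Angstrom; must divide the box edge 2*radius.  Default
#'   0.5.
#' @return object of class \code{dof_spec}: per-dof \code{bounds} (2 x n),
#'   logical \code{rotational}, list of \code{partitions}, \code{n}, plus
#'   the rotatable-bond bookkeeping needed by \code{\link{apply_pose}}.
#' @export
build_dof_spec <- function(ligand, sphere, angular_step = 1,
                           linear_step = 0.5) {
  if (360 %% angular_step != 0) {
    stop("angular_step must divide 360", call. = FALSE)
  }
  rot <- detect_rotatable_bonds(ligand)
  n <- 6L + length(rot)
  r <- sphere$radius
  bounds <- cbind(matrix(rep(c(-r, r), 3), nrow = 2),
                  matrix(rep(c(0, 360), n - 3L), nrow = 2))
  rotational <- c(rep(FALSE, 3), rep(TRUE, n - 3L))
  partitions <- lapply(seq_len(n), function(i) {
    if (rotational[i]) build_partition(0, 360, angular_step)
    else build_partition(-r, r, linear_step)
  })
  structure(list(bounds = bounds, rotational = rotational,
                 partitions = partitions, n = n,
                 rot_bonds = rot,
                 branches = torsion_branches(ligand, rot),
                 sphere = sphere),
            class = "dof_spec")
}

# For each rotatable bond, the atom set that moves when the torsion turns:
# the side of the bond with fewer heavy atoms (ties: the side holding the
# higher-indexed atom).  Returns a list of lists (axis atom indices a, b and
# moving atom indices).
torsion_branches <- function(ligand, rot_bonds) {
  b <- ligand$bonds
  el <- ligand$atoms$element
  g <- igraph::make_graph(edges = rbind(b$a, b$b), n = n_atoms(ligand),
                          directed = FALSE)
  lapply(rot_bonds, function(k) {
    i <- b$a[k]; j <- b$b[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    comp <- igraph::components(g2)$membership
    side_i <- which(comp == comp[i])
    side_j <- which(comp == comp[j])
    hi <- sum(el[side_i] != "H"); hj <- sum(el[side_j] != "H")
    mov <- if (hi < hj) list(a = j, b = i, moving = side_i)
           else if (hj < hi) list(a = i, b = j, moving = side_j)
           else if (max(side_j) > max(side_i)) list(a = i, b = j, moving = side_j)
           else list(a = j, b = i, moving = side_i)
    mov$moving <- setdiff(mov$moving, c(mov$a, mov$b))
    mov
  })
}

deg2rad <- function(d) d * pi / 180

# Rotation matrix about an arbitrary unit axis (Rodrigues), angle in degrees
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  c_ <- cos(th); s <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s, ux * uz * (1 - c_) + uy * s,
    uy * ux * (1 - c_) + uz * s, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s,
    uz * ux * (1 - c_) - uy * s, uz * uy * (1 - c_) + ux * s, c_ + uz^2 * (1 - c_)),
    nrow = 3, byrow = TRUE)
}

euler_zyz <- function(alpha, beta, gamma) {
  rz <- function(a) {
    t <- deg2rad(a)
    matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
  }
  ry <- function(a) {
    t <- deg2rad(a)
    matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, byrow = TRUE)
  }
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Apply a degree-of-freedom vector to ligand coordinates
#'
#' Torsion components rotate the smaller branch about each rotatable bond
#' (in detection order), the orientation is applied as a Z-Y-Z Euler
#' rotation about the ligand centroid, and the translation places the
#' centroid at \code{sphere$center + (x1, x2, x3)}.  All bond lengths not
#' spanning a rotatable bond are preserved exactly (rigid fragments).
#'
#' @param ligand a \code{\link{molecule}} holding the reference conformation.
#' @param x numeric vector of length \code{spec$n}: 3 translations (A),
#'   3 Euler angles (deg), then one torsion (deg) per rotatable bond.
#' @param spec a \code{\link{build_dof_spec}} result for this ligand.
#' @return n_atoms x 3 coordinate matrix in Angstrom.
#' @export
apply_pose <- function(ligand, x, spec) {
  if (length(x) != spec$n) {
    stop(sprintf("pose vector has length %d; expected %d", length(x), spec$n),
         call. = FALSE)
  }
  xyz <- coords(ligand)
  # torsions first, on the internal geometry
  if (length(spec$rot_bonds)) {
    for (t in seq_along(spec$rot_bonds)) {
      ang <- x[6L + t] %% 360
      if (ang == 0) next
      br <- spec$branches[[t]]
      p0 <- xyz[br$a, ]
      axis <- xyz[br$b, ] - p0
      R <- rotation_about_axis(axis, ang)
      mov <- br$moving  # br$b lies on the axis; rotating it is a no-op
      if (length(mov)) {
        xyz[mov, ] <- sweep(sweep(xyz[mov, , drop = FALSE], 2, p0) %*% t(R),
                            2, p0, "+")
      }
    }
  }
  ctr <- colMeans(xyz)
  R <- euler_zyz(x[4] %% 360, x[5] %% 360, x[6] %% 360)
  xyz <- sweep(xyz, 2, ctr) %*% t(R)
  sweep(xyz, 2, spec$sphere$center + x[1:3], "+")
}
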