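# ---- synthetic molecule builders ------------------------------------------
# Zig-zag heavy-atom chains with 1.5 A bonds and ~120 degree turns give
# clash-free reference conformations whose 1-3 distances (2.6 A) never
# trigger geometric bond perception.

zigzag_coords <- function(n, bond_len = 1.5) {
  xyz <- matrix(0, n, 3)
  ang <- rep(c(30, -30), length.out = max(0, n - 1)) * pi / 180
  for (i in seq_len(n - 1)) {
    xyz[i + 1, ] <- xyz[i, ] + bond_len * c(cos(ang[i]), sin(ang[i]), 0)
  }
  xyz
}

#' Template ligand library
#'
#' Hand-constructed small molecules exercising typing, torsions and
#' hydrogen bonding: alkane chains, an alcohol (donor + acceptor), an
#' amide, an ether and a single-atom apolar probe.  All are built in code
#' with clash-free reference geometry.
#'
#' @param kind one of \code{"probe"}, \code{"ethanol"}, \code{"butane"},
#'   \code{"pentanol"}, \code{"acetamide"}, \code{"ether"}.
#' @return a typed \code{\link{molecule}} with ring and rotatable flags set.
#' @export
template_ligand <- function(kind = c("ethanol", "probe", "butane",
                                     "pentanol", "acetamide", "ether")) {
  kind <- match.arg(kind)
  build_chain <- function(elements, name, hydro_on = integer(),
                          orders = NULL) {
    n <- length(elements)
    xyz <- zigzag_coords(n)
    atoms <- data.frame(element = elements,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        charge = ifelse(elements == "O", -0.4,
                                 ifelse(elements == "N", -0.3, 0.05)),
                        stringsAsFactors = FALSE)
    bonds <- if (n > 1) {
      data.frame(a = seq_len(n - 1), b = 2:n,
                 order = if (is.null(orders)) rep("1", n - 1) else orders,
                 stringsAsFactors = FALSE)
    } else NULL
    # add one hydrogen on each requested heteroatom, displaced out of plane
    for (i in hydro_on) {
      hpos <- c(xyz[i, 1], xyz[i, 2], xyz[i, 3] + 1.0)
      atoms <- rbind(atoms, data.frame(element = "H", x = hpos[1],
                                       y = hpos[2], z = hpos[3],
                                       charge = 0.2, stringsAsFactors = FALSE))
      bonds <- rbind(bonds, data.frame(a = i, b = nrow(atoms), order = "1",
                                       stringsAsFactors = FALSE))
    }
    m <- molecule(name, atoms, bonds)
    m <- perceive_rings(m)
    m <- assign_tripos_types(m)
    flag_rotatable_bonds(m)
  }
  switch(kind,
    probe = {
      m <- molecule("probe", data.frame(element = "C", x = 0, y = 0, z = 0,
                                        charge = 0, stringsAsFactors = FALSE))
      m$atoms$type_label <- "C.3"
      m
    },
    ethanol = build_chain(c("C", "C", "O"), "ethanol", hydro_on = 3L),
    butane = build_chain(c("C", "C", "C", "C"), "butane"),
    pentanol = build_chain(c("C", "C", "C", "C", "O"), "pentanol",
                           hydro_on = 5L),
    acetamide = {
      # CH3-C(=O)-NH2: chain C-C-N with a carbonyl O on the middle carbon
      xyz <- zigzag_coords(3)
      o_pos <- xyz[2, ] + c(0, -1.23, 0)
      atoms <- data.frame(
        element = c("C", "C", "N", "O", "H"),
        x = c(xyz[, 1], o_pos[1], xyz[3, 1]),
        y = c(xyz[, 2], o_pos[2], xyz[3, 2]),
        z = c(xyz[, 3], o_pos[3], xyz[3, 3] + 1.0),
        charge = c(0.05, 0.35, -0.5, -0.45, 0.25),
        stringsAsFactors = FALSE)
      bonds <- data.frame(a = c(1, 2, 2, 3), b = c(2, 3, 4, 5),
                          order = c("1", "am", "2", "1"),
                          stringsAsFactors = FALSE)
      m <- molecule("acetamide", atoms, bonds)
      m <- perceive_rings(m)
      m <- assign_tripos_types(m)
      flag_rotatable_bonds(m)
    },
    ether = build_chain(c("C", "O", "C"), "ether"))
}

#' Random small molecule (for round-trip and property tests)
#'
#' A heavy-atom chain of random length (3-8) and composition (C/N/O/S)
#' with randomized charges and slightly jittered zig-zag coordinates;
#' bonds are explicit, types assigned deterministically.
#'
#' @param seed integer seed.
#' @return a typed \code{\link{molecule}}.
#' @export
random_molecule <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  el <- c("C", sample(c("C", "C", "N", "O", "S"), n - 2, replace = TRUE), "C")
  xyz <- zigzag_coords(n) + matrix(stats::runif(3 * n, -0.05, 0.05), n, 3)
  atoms <- data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = round(stats::runif(n, -0.5, 0.5), 3),
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a = seq_len(n - 1), b = 2:n, order = "1",
                      stringsAsFactors = FALSE)
  m <- molecule(sprintf("rnd%05d", seed), atoms, bonds)
  m <- perceive_rings(m)
  assign_tripos_types(m)
}

# AutoDock type for PDBQT emission
.element_to_autodock <- function(element, is_polar_h) {
  ifelse(element == "H", ifelse(is_polar_h, "HD", "H"),
  ifelse(element == "O", "OA",
  ifelse(element == "N", "N",
  ifelse(element == "S", "SA", element))))
}

#' Write a molecule as a PDBQT record
#'
#' Emits \code{ROOT}/\code{ENDROOT} around the atom block and a
#' \code{TORSDOF} record with the molecule's rotatable-bond count.  Used by
#' the fixture generator to build PDBQT-format libraries; PDBQT stores no
#' bond table, so connectivity is left to downstream perception.
#'
#' @param m a \code{\link{molecule}}.
#' @param path optional output file.
#' @return the PDBQT text as one string (invisibly when \code{path} given).
#' @export
write_pdbqt <- function(m, path = NULL) {
  validate_molecule(m)
  a <- m$atoms
  nb <- neighbor_list(m)
  polar_h <- vapply(seq_len(nrow(a)), function(i) {
    a$element[i] == "H" && length(nb[[i]]) &&
      any(a$element[nb[[i]]] %in% c("N", "O", "S"))
  }, TRUE)
  ad <- .element_to_autodock(a$element, polar_h)
  lines <- c(
    sprintf("REMARK  Name = %s", m$name),
    "ROOT",
    sprintf("ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00    %6.3f %-2s",
            seq_len(nrow(a)), substr(a$name, 1, 4), a$x, a$y, a$z,
            a$charge, ad),
    "ENDROOT",
    sprintf("TORSDOF %d", length(detect_rotatable_bonds(m))))
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

# ---- toy receptor-ligand complexes ----------------------------------------

fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a synthetic pocket + ligand test complex
#'
#' The receptor is a spherical shell of apolar pseudo-atoms around the
#' origin (a closed "pocket") carrying one hydrogen-bond donor (N-H aimed
#' at the center) and one acceptor (carbonyl-like O).  A ligand placed at
#' the center sits in the steric well of every shell atom, so the planted
#' pose (zero dof vector) scores well below any pose displaced by 2 A or
#' more; this is verified at generation over a shell of sampled displaced
#' poses and the generator retries with the next seed on failure.
#'
#' @param pocket_atoms number of shell pseudo-atoms (default 16).
#' @param pocket_radius shell radius in Angstrom (default 5).
#' @param ligand a \code{\link{molecule}} or a \code{\link{template_ligand}}
#'   kind string (default \code{"ethanol"}).
#' @param sphere_radius docking-sphere radius (default the shell radius).
#' @param seed integer seed (jitters the shell).
#' @param scoring_function scoring function used for the planted-pose check.
#' @param verify logical; run the planted-optimum verification.
#' @return list with \code{receptor}, \code{ligand}, \code{sphere},
#'   \code{planted_score} and the seed actually used.
#' @export
make_toy_complex <- function(pocket_atoms = 16, pocket_radius = 5,
                             ligand = "ethanol", sphere_radius = pocket_radius,
                             seed = 1, scoring_function = "chemplp",
                             verify = TRUE) {
  if (is.character(ligand)) ligand <- template_ligand(ligand)
  lig <- ligand
  # center the ligand's reference conformation on its centroid
  lig <- set_coords(lig, sweep(coords(lig), 2, colMeans(coords(lig))))

  build_receptor <- function(s) {
    set.seed(s)
    shell <- fibonacci_sphere(pocket_atoms, pocket_radius)
    shell <- shell + matrix(stats::runif(length(shell), -0.2, 0.2),
                            nrow(shell), 3)
    # donor: replace the first shell atom by N, with H 1.0 A inward
    n_pos <- shell[1, ]
    h_pos <- n_pos * (1 - 1.0 / sqrt(sum(n_pos^2)))
    # acceptor: replace the second shell atom by O
    atoms <- data.frame(
      element = c("N", "O", rep("C", pocket_atoms - 2), "H"),
      x = c(n_pos[1], shell[2, 1], shell[-(1:2), 1], h_pos[1]),
      y = c(n_pos[2], shell[2, 2], shell[-(1:2), 2], h_pos[2]),
      z = c(n_pos[3], shell[2, 3], shell[-(1:2), 3], h_pos[3]),
      charge = c(-0.3, -0.4, rep(0, pocket_atoms - 2), 0.2),
      type_label = c("N.3", "O.2", rep("C.3", pocket_atoms - 2), "H"),
      stringsAsFactors = FALSE)
    molecule("toy_pocket", atoms,
             data.frame(a = 1L, b = nrow(atoms), order = "1",
                        stringsAsFactors = FALSE))
  }

  params <- scoring_params(scoring_function)
  sphere <- docking_sphere(c(0, 0, 0), sphere_radius)
  for (s in seed + 0:9) {
    receptor <- build_receptor(s)
    spec <- build_dof_spec(lig, sphere, angular_step = 60, linear_step = 1)
    cache <- score_cache(receptor, lig, params)
    planted <- score_pose(receptor, lig, rep(0, spec$n), params, spec, cache)
    if (!verify) {
      return(list(receptor = receptor, ligand = lig, sphere = sphere,
                  planted_score = planted$total, seed = s))
    }
    set.seed(s + 5000)
    ok <- planted$total < 0
    if (ok) {
      for (k in 1:40) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        shift <- dir * stats::runif(1, 2, pocket_radius)
        x <- c(shift, stats::runif(3, 0, 360), rep(0, spec$n - 6))
        disp <- score_pose(receptor, lig, x, params, spec, cache)
        if (disp$total <= planted$total) { ok <- FALSE; break }
      }
    }
    if (ok) {
      return(list(receptor = receptor, ligand = lig, sphere = sphere,
                  planted_score = planted$total, seed = s))
    }
  }
  stop("could not generate a verified toy complex in 10 attempts",
       call. = FALSE)
}

# ---- brute-force grid oracle ----------------------------------------------

#' Exhaustive grid search over the discretized pose space
#'
#' Scores the midpoint of every interval-tuple cell and returns the global
#' minimum: the oracle against which the ant-colony engine is validated.
#' Refuses grids above \code{max_cells}.
#'
#' @param receptor,ligand \code{\link{molecule}} objects.
#' @param spec the \code{\link{build_dof_spec}} (coarse partitions).
#' @param params a \code{\link{scoring_params}} set.
#' @param max_cells guard on the cell count (default 1e6).
#' @return list: \code{best_intervals}, \code{best_x} (cell midpoints),
#'   \code{best_score}, \code{n_cells}.
#' @export
brute_force_dock <- function(receptor, ligand, spec, params,
                             max_cells = 1e6) {
  ni <- vapply(spec$partitions, function(p) p$n_intervals, 1L)
  n_cells <- prod(as.numeric(ni))
  if (n_cells > max_cells) {
    stop(sprintf("grid of %g cells exceeds max_cells = %g; coarsen the partitions",
                 n_cells, max_cells), call. = FALSE)
  }
  cache <- score_cache(receptor, ligand, params)
  mids <- lapply(spec$partitions, interval_midpoint)
  grid <- as.matrix(expand.grid(lapply(ni, seq_len)))
  best_score <- Inf; best_i <- NULL
  scores <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    x <- vapply(seq_len(spec$n), function(i) mids[[i]][grid[r, i]], 0)
    scores[r] <- score_pose(receptor, ligand, x, params, spec, cache)$total
    if (scores[r] < best_score) { best_score <- scores[r]; best_i <- grid[r, ] }
  }
  list(best_intervals = as.integer(best_i),
       best_x = vapply(seq_len(spec$n), function(i) mids[[i]][best_i[i]], 0),
       best_score = best_score, n_cells = n_cells, scores = scores)
}

# ---- fixture libraries -----------------------------------------------------

#' Write a small hierarchical screening library to disk
#'
#' Emulates the meta-tranche / tranche / collection layout of large
#' screening libraries at desk scale.  In replicated mode (the default)
#' every collection holds the identical compound set, mirroring how the
#' large-scale benchmark library replicates one compound panel across all
#' collections.  A manifest of all ligand ids is written at the root and is
#' the single source of truth for the expected ligand set.
#'
#' @param h a \code{\link{library_hierarchy}} (total compounds <= 1e4).
#' @param format \code{"MOL2"} or \code{"PDBQT"}.
#' @param root output directory (created).
#' @param seed integer seed for compound variation.
#' @param replicated identical compound set in every collection.
#' @param as_tar store each collection as a .tar archive instead of a
#'   directory.
#' @return list with \code{root}, \code{manifest} (character vector of
#'   ligand ids), \code{hierarchy}.
#' @export
make_fixture_library <- function(h, format = c("MOL2", "PDBQT"),
                                 root = tempfile("library"), seed = 1,
                                 replicated = TRUE, as_tar = FALSE) {
  format <- match.arg(format)
  if (library_size(h) > 1e4) {
    stop("fixture library too large (> 1e4 compounds); use smaller level counts",
         call. = FALSE)
  }
  kinds <- c("ethanol", "butane", "pentanol", "acetamide", "ether")
  compound <- function(j, salt) {
    m <- template_ligand(kinds[(j - 1) %% length(kinds) + 1])
    set.seed(seed + 131 * j + salt)
    m$atoms$charge <- round(m$atoms$charge + stats::runif(nrow(m$atoms),
                                                          -0.02, 0.02), 4)
    m
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  ext <- tolower(format)
  manifest <- character()
  for (mi in seq_len(h$n_meta_tranches)) {
    for (ti in seq_len(h$n_tranches_per_meta)) {
      for (ci in seq_len(h$n_collections_per_tranche)) {
        cname <- sprintf("c%03d", ci)
        cdir <- file.path(root, sprintf("m%02d", mi), sprintf("t%03d", ti),
                          cname)
        dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
        salt <- if (replicated) 0L else mi * 10000L + ti * 100L + ci
        for (j in seq_len(h$n_compounds_per_collection)) {
          m <- compound(j, salt)
          lname <- sprintf("lig%03d", j)
          m$name <- lname
          fp <- file.path(cdir, paste0(lname, ".", ext))
          if (format == "MOL2") write_mol2(m, fp) else write_pdbqt(m, fp)
          manifest <- c(manifest, paste(sprintf("m%02d", mi),
                                        sprintf("t%03d", ti), cname, lname,
                                        sep = "/"))
        }
        if (as_tar) {
          old <- getwd()
          setwd(dirname(cdir))
          utils::tar(paste0(cname, ".tar"), cname)
          setwd(old)
          unlink(cdir, recursive = TRUE)
        }
      }
    }
  }
  writeLines(manifest, file.path(root, "manifest.txt"))
  list(root = root, manifest = manifest, hierarchy = h)
}

# ---- parameter-variation benchmark ----------------------------------------

#' The parameter-variation scenario grid
#'
#' Ten docking scenarios spanning the preset space: chemplp at speeds 4/2/1,
#' ant counts 10 and 50, evaporation 0.10 and 0.25, sigma 1, plus plp and
#' plp95 at speed 4.  \code{NA} means "preset default"; scenario 1 is the
#' all-defaults chemplp/speed-4 reference.
#'
#' @return data.frame with columns scenario, scoring_function, search_speed,
#'   aco_ants, aco_evap, aco_sigma.
#' @export
benchmark_grid <- function() {
  data.frame(
    scenario = 1:10,
    scoring_function = c(rep("chemplp", 8), "plp", "plp95"),
    search_speed = c(4, 2, 1, 4, 4, 4, 4, 4, 4, 4),
    aco_ants = c(NA, NA, NA, 10, 50, NA, NA, NA, NA, NA),
    aco_evap = c(NA, NA, NA, NA, NA, 0.10, 0.25, NA, NA, NA),
    aco_sigma = c(NA, NA, NA, NA, NA, NA, NA, 1, NA, NA),
    stringsAsFactors = FALSE)
}

#' Desk-scale parameter-variation benchmark
#'
#' Screens a synthetic ligand panel against a toy pocket under every
#' scenario of the grid and reports, per scenario, the mean top-N score
#' (AVE_N), the mean number of objective evaluations per ligand (the
#' hardware-independent cost measure) and the mean wall seconds per ligand
#' (informational).  Fully reproducible from \code{seed}.
#'
#' @param grid a \code{\link{benchmark_grid}}-shaped data.frame (possibly a
#'   subset of rows).
#' @param n_ligands panel size (template variations; default 12).
#' @param n_top N of AVE_N (default 10, capped at the panel size).
#' @param seed integer seed.
#' @param complex optional \code{\link{make_toy_complex}} result to reuse.
#' @param aco_overrides extra ACO settings applied to every scenario
#'   (e.g. smaller \code{iterations} for quick runs).
#' @return data.frame with one row per scenario: parameters used, ave_n,
#'   mean_evaluations, mean_dock_seconds; per-scenario score vectors in
#'   \code{attr(, "scores")}.
#' @export
run_benchmark <- function(grid = benchmark_grid(), n_ligands = 12,
                          n_top = 10, seed = 1, complex = NULL,
                          aco_overrides = NULL) {
  if (is.null(complex)) {
    complex <- make_toy_complex(seed = seed, verify = FALSE)
  }
  kinds <- c("ethanol", "butane", "pentanol", "acetamide", "ether")
  ligands <- lapply(seq_len(n_ligands), function(j) {
    m <- template_ligand(kinds[(j - 1) %% length(kinds) + 1])
    set.seed(seed + 977 * j)
    m$atoms$charge <- m$atoms$charge + stats::runif(nrow(m$atoms), -0.02, 0.02)
    m$name <- sprintf("lig%03d", j)
    m
  })
  n_top <- min(n_top, n_ligands)
  rows <- list(); all_scores <- list()
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    ov <- aco_overrides
    if (!is.na(g$aco_ants)) ov$n_ants <- as.integer(g$aco_ants)
    if (!is.na(g$aco_evap)) ov$rho <- g$aco_evap
    if (!is.na(g$aco_sigma)) ov$sigma <- g$aco_sigma
    sc <- docking_scenario(
      name = paste0("scenario", g$scenario),
      scoring_function = g$scoring_function,
      sphere = complex$sphere,
      search_speed = g$search_speed,
      aco_overrides = ov,
      angular_step = 60, linear_step = 1)
    scores <- numeric(n_ligands); evals <- numeric(n_ligands)
    secs <- numeric(n_ligands)
    for (j in seq_len(n_ligands)) {
      t0 <- Sys.time()
      res <- run_aco(complex$receptor, ligands[[j]], sc,
                     seed = ligand_seed(seed, ligands[[j]]$name))
      secs[j] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      scores[j] <- res$score
      evals[j] <- res$n_evaluations
    }
    rows[[r]] <- data.frame(
      scenario = g$scenario, scoring_function = g$scoring_function,
      search_speed = g$search_speed,
      n_ants = sc$aco$n_ants, rho = sc$aco$rho, sigma = sc$aco$sigma,
      ave_n = top_n_average(scores, n_top),
      mean_evaluations = mean(evals),
      mean_dock_seconds = mean(secs),
      stringsAsFactors = FALSE)
    all_scores[[as.character(g$scenario)]] <- scores
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scores") <- all_scores
  out
}
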