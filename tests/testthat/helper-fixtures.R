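# Shared builders for the test suite.  Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

rotation_matrix_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
}

# two-atom / n-atom carbon chains at a given spacing (no hydrogens)
carbon_chain <- function(n, spacing) {
  molecule(sprintf("chain%d", n),
           data.frame(element = rep("C", n),
                      x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
                      charge = 0, stringsAsFactors = FALSE))
}

# benzene-like ring: six aromatic carbons on a hexagon, explicit ar bonds
benzene_like <- function() {
  th <- seq(0, by = pi / 3, length.out = 6)
  atoms <- data.frame(element = "C", x = 1.4 * cos(th), y = 1.4 * sin(th),
                      z = 0, charge = 0, stringsAsFactors = FALSE)
  bonds <- data.frame(a = 1:6, b = c(2:6, 1), order = "ar",
                      stringsAsFactors = FALSE)
  m <- molecule("ring6", atoms, bonds)
  assign_tripos_types(perceive_rings(m))
}

# a quick, fully specified scenario for screening tests (small budgets)
quick_scenario_text <- function(scoring = "chemplp", speed = 4,
                                radius = 5, iterations = 5, ls = 12) {
  paste(c(sprintf("scoring_function %s", scoring),
          sprintf("search_speed %d", speed),
          "bindingsite_center 0 0 0",
          sprintf("bindingsite_radius %g", radius),
          "angular_step 60", "linear_step 1",
          sprintf("aco_iterations %d", iterations),
          sprintf("aco_ls_budget %d", ls)), collapse = "\n")
}

# write a control file + scenario configs under a fresh directory; returns
# the control file path
make_screen_setup <- function(lib_root, scen_names = c("scen1", "scen2"),
                              scorings = c("chemplp", "plp"),
                              format = "PDBQT", workers = 1, seed = 42,
                              out = "out") {
  base <- tempfile("screen")
  dir.create(base, recursive = TRUE)
  for (i in seq_along(scen_names)) {
    d <- file.path(base, "input-files", scen_names[i])
    dir.create(d, recursive = TRUE)
    writeLines(quick_scenario_text(scorings[i]), file.path(d, "config.txt"))
  }
  ctrl <- file.path(base, "control.txt")
  writeLines(c(sprintf("ligand_library_format=%s", format),
               sprintf("docking_scenario_names=%s",
                       paste(scen_names, collapse = ",")),
               sprintf("library_root=%s", lib_root),
               sprintf("output_root=%s", file.path(base, out)),
               sprintf("workers=%d", workers),
               sprintf("seed=%d", seed)), ctrl)
  ctrl
}

# the probe-in-pocket setup used for engine-vs-grid comparisons: a
# spherically symmetric one-atom ligand makes the orientation dofs inert,
# so the optimum grid cell is unique in the translation dofs
probe_grid_setup <- function(seed = 2, n_intervals = 5) {
  tc <- make_toy_complex(ligand = "probe", pocket_radius = 4, seed = seed)
  spec <- build_dof_spec(tc$ligand, tc$sphere, angular_step = 360,
                         linear_step = 2 * tc$sphere$radius / n_intervals)
  params <- scoring_params("chemplp")
  cache <- score_cache(tc$receptor, tc$ligand, params)
  obj <- function(x) {
    score_pose(tc$receptor, tc$ligand, x, params, spec, cache)$total
  }
  list(tc = tc, spec = spec, params = params, obj = obj)
}
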