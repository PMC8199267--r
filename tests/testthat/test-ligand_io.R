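test_that("MOL2 write/read round-trips molecules at written precision", {
  # fixed small case
  m <- template_ligand("ethanol")
  m2 <- read_mol2(write_mol2(m))
  expect_identical(m2$atoms$element, m$atoms$element)
  expect_identical(nrow(m2$bonds), nrow(m$bonds))
  expect_identical(paste(m2$bonds$a, m2$bonds$b),
                   paste(m$bonds$a, m$bonds$b))

  # 50 random molecules: coordinates and charges agree to the 4-decimal
  # written precision, elements and bond pairs exactly
  for (s in 1:50) {
    m <- random_molecule(s)
    m2 <- read_mol2(write_mol2(m))
    expect_identical(m2$atoms$element, m$atoms$element)
    expect_lt(max(abs(coords(m2) - coords(m))), 1e-4 + 1e-9)
    expect_lt(max(abs(m2$atoms$charge - m$atoms$charge)), 1e-4 + 1e-9)
    expect_identical(paste(m2$bonds$a, m2$bonds$b),
                     paste(m$bonds$a, m$bonds$b))
  }
})

test_that("MOL2 structural errors are reported", {
  good <- write_mol2(template_ligand("ethanol"))
  # declared 5 atoms, fewer ATOM records
  bad <- sub("\n4 3 ", "\n5 3 ", good, fixed = TRUE)
  expect_error(read_mol2(bad), "declares 5 atoms")
  # malformed section header
  bad2 <- sub("@<TRIPOS>BOND", "@<tripos>bond!", good)
  expect_error(read_mol2(bad2), "malformed")
  # single-atom, zero-bond molecule is valid and carries a "1 0" counts line
  probe <- template_ligand("probe")
  txt <- write_mol2(probe)
  expect_match(txt, "\n1 0 ", fixed = TRUE)
  expect_equal(n_atoms(read_mol2(txt)), 1L)
  # writing untyped atoms is refused with guidance
  un <- probe; un$atoms$type_label <- NA_character_
  expect_error(write_mol2(un), "assign_tripos_types")
})

test_that("emitted MOL2 is readable by an independent third-party parser", {
  obabel <- Sys.which("obabel")
  expect_true(nzchar(obabel))
  for (s in c(3, 11, 27)) {
    f <- tempfile(fileext = ".mol2")
    write_mol2(random_molecule(s), f)
    out <- system2(obabel, c("-imol2", f, "-osmi"), stdout = TRUE,
                   stderr = TRUE)
    status <- attr(out, "status")
    expect_true(is.null(status) || status == 0L)
    expect_true(any(grepl("1 molecule converted", out)))
  }
})

test_that("PDBQT parsing extracts atoms, charges and torsion metadata", {
  txt <- paste(c(
    "REMARK  Name = frag",
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.100 C",
    "ATOM      2  O1  LIG A   1       1.400   0.000   0.000  1.00  0.00    -0.400 OA",
    "ATOM      3  N1  LIG A   1       2.100   1.200   0.000  1.00  0.00    -0.350 NA",
    "ATOM      4  H1  LIG A   1       2.100   2.210   0.000  1.00  0.00     0.150 HD",
    "ENDROOT",
    "TORSDOF 3"), collapse = "\n")
  m <- read_pdbqt(txt)
  expect_equal(n_atoms(m), 4L)
  expect_equal(nrow(m$bonds), 0L)  # PDBQT has no bond records
  expect_identical(m$atoms$element, c("C", "O", "N", "H"))
  expect_equal(m$atoms$charge, c(0.1, -0.4, -0.35, 0.15))
  expect_identical(m$meta$torsdof, 3L)
  expect_error(read_pdbqt(sub("0.100 C", "0.100 XX", txt, fixed = TRUE)),
               "XX")
})

test_that("AutoDock type -> element mapping matches the reference table", {
  # hand-built lookup exercised exhaustively over the standard types
  ref <- c(H = "H", HD = "H", HS = "H", C = "C", A = "C", N = "N",
           "NA" = "N", NS = "N", O = "O", OA = "O", OS = "O", F = "F",
           MG = "Mg", P = "P", S = "S", SA = "S", CL = "Cl", CA = "Ca",
           MN = "Mn", FE = "Fe", ZN = "Zn", BR = "Br", I = "I")
  for (tk in names(ref)) {
    expect_identical(autodock_element(tk), unname(ref[tk]))
  }
  expect_error(autodock_element("QQ"), "QQ")
})

test_that("geometric bond perception follows the covalent-radius threshold", {
  # threshold for C-C: 1.2 * (0.76 + 0.76) = 1.824 A
  expect_equal(nrow(perceive_bonds(carbon_chain(2, 1.5))$bonds), 1L)
  expect_equal(nrow(perceive_bonds(carbon_chain(2, 3.0))$bonds), 0L)
  # linear chain at 1.5 A: consecutive bonds only, no 1-3 bond at 3.0 A
  m3 <- perceive_bonds(carbon_chain(3, 1.5))
  expect_equal(nrow(m3$bonds), 2L)
  # just inside / outside the 1.824 A threshold
  expect_equal(nrow(perceive_bonds(carbon_chain(2, 1.82))$bonds), 1L)
  expect_equal(nrow(perceive_bonds(carbon_chain(2, 1.83))$bonds), 0L)
  # no H-H bonds
  hh <- molecule("h2", data.frame(element = c("H", "H"), x = c(0, 0.7),
                                  y = 0, z = 0, charge = 0))
  expect_equal(nrow(perceive_bonds(hh)$bonds), 0L)
  expect_error(perceive_bonds(molecule("xx", data.frame(
    element = "C", x = 0, y = 0, z = 0, charge = 0)) |>
      (\(m) { m$atoms$element <- "Xq"; m })()), "Xq")
})

test_that("bond perception is invariant under atom reordering", {
  m <- random_molecule(5)
  mp <- perceive_bonds(molecule(m$name, m$atoms[, c("element", "x", "y", "z",
                                                    "charge")]))
  perm <- rev(seq_len(n_atoms(m)))
  at2 <- m$atoms[perm, c("element", "x", "y", "z", "charge")]
  mp2 <- perceive_bonds(molecule(m$name, at2))
  key <- function(mm, map) {
    sort(paste(pmin(map[mm$bonds$a], map[mm$bonds$b]),
               pmax(map[mm$bonds$a], map[mm$bonds$b])))
  }
  expect_identical(key(mp, seq_len(n_atoms(m))), key(mp2, order(perm)))
})

test_that("Tripos typing matches a hand-written expected table", {
  cases <- list(
    list(m = template_ligand("butane"),
         want = c("C.3", "C.3", "C.3", "C.3")),
    list(m = template_ligand("ethanol"),
         want = c("C.3", "C.3", "O.3", "H")),
    list(m = template_ligand("ether"),
         want = c("C.3", "O.3", "C.3")),
    # acetamide: carbonyl C.2 / O.2, amide nitrogen
    list(m = template_ligand("acetamide"),
         want = c("C.3", "C.2", "N.am", "O.2", "H")),
    list(m = benzene_like(), want = rep("C.ar", 6)))
  for (cs in cases) {
    expect_identical(cs$m$atoms$type_label, cs$want)
  }
  # carboxylate: two terminal oxygens on one carbon, one double bond
  carbox <- molecule("formate", data.frame(
    element = c("C", "O", "O"),
    x = c(0, 1.23, -0.6), y = c(0, 0, 1.1), z = 0,
    charge = c(0.3, -0.65, -0.65), stringsAsFactors = FALSE),
    data.frame(a = c(1, 1), b = c(2, 3), order = c("2", "1"),
               stringsAsFactors = FALSE))
  carbox <- assign_tripos_types(perceive_rings(carbox))
  expect_identical(carbox$atoms$type_label, c("C.2", "O.co2", "O.co2"))
  # quaternary nitrogen
  nq <- molecule("nq", data.frame(
    element = c("N", "C", "C", "C", "C"),
    x = c(0, 1.5, -1.5, 0, 0), y = c(0, 0, 0, 1.5, -1.5), z = 0,
    charge = c(1, 0, 0, 0, 0), stringsAsFactors = FALSE),
    data.frame(a = 1, b = 2:5, order = "1", stringsAsFactors = FALSE))
  nq <- assign_tripos_types(perceive_rings(nq))
  expect_identical(nq$atoms$type_label[1], "N.4")
  # impossible valence errors
  bad <- molecule("bad", data.frame(
    element = c("O", "C", "C", "C", "C"),
    x = c(0, 1.5, -1.5, 0, 0), y = c(0, 0, 0, 1.5, -1.5), z = 0,
    charge = 0, stringsAsFactors = FALSE),
    data.frame(a = 1, b = 2:5, order = "1", stringsAsFactors = FALSE))
  expect_error(assign_tripos_types(perceive_rings(bad)), "valence")
})

test_that("PDBQT -> MOL2 conversion conserves composition and charge", {
  for (s in 1:20) {
    m <- random_molecule(s + 100)
    pt <- write_pdbqt(m)
    mt <- convert_pdbqt_to_mol2(pt)
    m2 <- read_mol2(mt)
    expect_equal(n_heavy_atoms(m2), n_heavy_atoms(m))
    expect_identical(sort(m2$atoms$element), sort(m$atoms$element))
    expect_lt(abs(sum(m2$atoms$charge) - sum(m$atoms$charge)), 1e-3)
    # pipeline equals its parts: bond count from perceive_bonds directly
    direct <- perceive_bonds(read_pdbqt(pt))
    expect_equal(nrow(m2$bonds), nrow(direct$bonds))
  }
  # conversion is fast: a drug-sized ligand in well under a second
  t0 <- Sys.time()
  convert_pdbqt_to_mol2(write_pdbqt(template_ligand("pentanol")))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
})

test_that("rotatable-bond detection excludes terminal, ring and amide bonds", {
  ethane <- perceive_bonds(carbon_chain(2, 1.5))
  expect_length(detect_rotatable_bonds(ethane), 0L)
  expect_length(detect_rotatable_bonds(benzene_like()), 0L)
  butane <- template_ligand("butane")
  rot <- detect_rotatable_bonds(butane)
  expect_length(rot, 1L)
  expect_setequal(c(butane$bonds$a[rot], butane$bonds$b[rot]), c(2L, 3L))
  # primary amide: the C-N bond is terminal on the nitrogen side anyway
  ac <- template_ligand("acetamide")
  expect_length(detect_rotatable_bonds(ac), 0L)
  # N-methylamide: C(=O)-N single bond with heavy atoms on both sides is
  # excluded by the amide rule, kept when the rule is switched off
  nma <- local({
    xyz <- rbind(c(0, 0, 0), c(1.3, 0.75, 0), c(2.6, 0, 0), c(3.9, 0.75, 0))
    atoms <- data.frame(
      element = c("C", "C", "N", "C", "O", "H"),
      x = c(xyz[, 1], 1.3, 2.6), y = c(xyz[, 2], 1.98, 0),
      z = c(0, 0, 0, 0, 0, 1),
      charge = c(0.05, 0.35, -0.4, 0.05, -0.45, 0.25),
      stringsAsFactors = FALSE)
    bonds <- data.frame(a = c(1, 2, 3, 2, 3), b = c(2, 3, 4, 5, 6),
                        order = c("1", "1", "1", "2", "1"),
                        stringsAsFactors = FALSE)
    assign_tripos_types(perceive_rings(molecule("nma", atoms, bonds)))
  })
  expect_length(detect_rotatable_bonds(nma), 0L)
  expect_length(detect_rotatable_bonds(nma, exclude_amide = FALSE), 1L)
  # invariant under rigid transformation of coordinates
  but2 <- set_coords(butane, coords(butane) %*%
                       rotation_matrix_z(35) + 2.5)
  expect_identical(detect_rotatable_bonds(but2), rot)
})
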