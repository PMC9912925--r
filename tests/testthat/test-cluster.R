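# Cluster selection, environment validation, capping and protonation.

simple_scene <- function(extra = NULL) {
  atoms <- dplyr::bind_rows(
    atom_row("C1", 0, 0, 0),
    atom_row("C2", 1.5, 0, 0),
    atom_row("O", 0, 3.0, 0, comp_id = "HOH", chain_id = "W", seq_id = 1),
    # glycine far away
    atom_row("N", 6, 0, 0, comp_id = "GLY", chain_id = "B", seq_id = 1, is_hetatm = FALSE),
    atom_row("CA", 7.4, 0.4, 0, comp_id = "GLY", chain_id = "B", seq_id = 1, is_hetatm = FALSE),
    atom_row("C", 8.2, 1.6, 0, comp_id = "GLY", chain_id = "B", seq_id = 1, is_hetatm = FALSE),
    atom_row("O", 9.4, 1.7, 0, comp_id = "GLY", chain_id = "B", seq_id = 1, is_hetatm = FALSE),
    extra
  )
  big_p1_model(atoms)
}

test_that("the cluster takes near waters and skips distant residues", {
  m <- simple_scene()
  cl <- build_ligand_cluster(m, ligand_selector("A", "LIG", 1), radius = 3.5)
  env <- cl$atoms[cl$atoms$role == "environment", ]
  expect_equal(unique(env$comp_id), "HOH")
})

test_that("one atom inside the radius pulls in its entire residue", {
  # glycine with only its carbonyl O at 3.4 A from the ligand
  gly <- dplyr::bind_rows(
    atom_row("N", 8.2, 0, 0, comp_id = "GLY", chain_id = "B", seq_id = 1, is_hetatm = FALSE),
    atom_row("CA", 6.8, 0.4, 0, comp_id = "GLY", chain_id = "B", seq_id = 1, is_hetatm = FALSE),
    atom_row("C", 5.6, 1.2, 0, comp_id = "GLY", chain_id = "B", seq_id = 1, is_hetatm = FALSE),
    atom_row("O", 4.4, 1.2, 0, comp_id = "GLY", chain_id = "B", seq_id = 1, is_hetatm = FALSE)
  )
  m <- big_p1_model(dplyr::bind_rows(atom_row("C1", 1, 1.2, 0), gly))
  cl <- build_ligand_cluster(m, ligand_selector("A", "LIG", 1), radius = 3.5)
  env <- cl$atoms[cl$atoms$role == "environment", ]
  expect_setequal(env$name, c("N", "CA", "C", "O"))
})

test_that("selection respects the 3.49/3.51 boundary", {
  for (d in c(3.49, 3.51)) {
    m <- big_p1_model(dplyr::bind_rows(
      atom_row("C1", 0, 0, 0),
      atom_row("O", d, 0, 0, comp_id = "HOH", chain_id = "W", seq_id = 1)
    ))
    cl <- build_ligand_cluster(m, ligand_selector("A", "LIG", 1), radius = 3.5)
    n_env <- sum(cl$atoms$role == "environment")
    expect_equal(n_env, if (d < 3.5) 1L else 0L, info = sprintf("d=%.2f", d))
  }
})

test_that("clusters grow monotonically with the radius", {
  for (s in c(3, 8)) {
    fx <- generate_fixture(fixture_spec(seed = s, pocket_residues = 3, n_waters = 3))
    small <- build_ligand_cluster(fx$model, ligand_selector("A", "LIG", 1), radius = 3.5)
    large <- build_ligand_cluster(fx$model, ligand_selector("A", "LIG", 1), radius = 5.0)
    key <- function(cl) {
      a <- cl$atoms[cl$atoms$role == "environment", ]
      unique(paste(a$chain_id, a$seq_id, a$operator, a$shift_a, a$shift_b, a$shift_c))
    }
    expect_true(all(key(small) %in% key(large)))
  }
})

test_that("ambiguous or absent selectors fail loudly", {
  m <- simple_scene()
  expect_error(
    build_ligand_cluster(m, ligand_selector("A", "XXX", 1)),
    "matches no residue"
  )
})

test_that("whole-residue rule holds on generated fixtures", {
  fx <- generate_fixture(fixture_spec(seed = 4, pocket_residues = 3))
  cl <- build_ligand_cluster(fx$model, ligand_selector("A", "LIG", 1))
  a <- cl$atoms[cl$atoms$role == "environment", ]
  model_key <- qmrestraints:::.res_key(fx$model$atoms)
  for (tg in unique(paste(a$chain_id, a$seq_id, a$comp_id))) {
    rows <- a[paste(a$chain_id, a$seq_id, a$comp_id) == tg, ]
    src <- fx$model$atoms[model_key == model_key[match(
      rows$source_serial[1], fx$model$atoms$serial
    )], ]
    expect_setequal(rows$name, src$name)
  }
})

test_that("environment audit flags other ligands, metals, altlocs by distance", {
  base <- dplyr::bind_rows(atom_row("C1", 0, 0, 0), atom_row("C2", 1.5, 0, 0))
  # second ligand at 4.9 A -> flagged
  m1 <- big_p1_model(dplyr::bind_rows(
    base, atom_row("C1", -4.9, 0, 0, comp_id = "XYZ", chain_id = "C")
  ))
  r1 <- validate_environment(m1, ligand_selector("A", "LIG", 1))
  expect_true(r1$other_ligand_within_5p5)
  expect_false(r1$clean)
  # zinc at 6.0 A -> outside the radius, no flag
  m2 <- big_p1_model(dplyr::bind_rows(
    base, atom_row("ZN", -6, 0, 0, comp_id = "ZN", chain_id = "C", element = "ZN")
  ))
  r2 <- validate_environment(m2, ligand_selector("A", "LIG", 1))
  expect_false(r2$metal_within_5p5)
  # zinc at 5.4 -> flagged
  m3 <- big_p1_model(dplyr::bind_rows(
    base, atom_row("ZN", -5.4, 0, 0, comp_id = "ZN", chain_id = "C", element = "ZN")
  ))
  expect_true(validate_environment(m3, ligand_selector("A", "LIG", 1))$metal_within_5p5)
  # altloc within 5.5 -> flagged
  m4 <- big_p1_model(dplyr::bind_rows(
    base,
    atom_row("O", 0, 4, 0, comp_id = "HOH", chain_id = "W", altloc = "A"),
    atom_row("O", 0.4, 4, 0, comp_id = "HOH", chain_id = "W", altloc = "B")
  ))
  r4 <- validate_environment(m4, ligand_selector("A", "LIG", 1))
  expect_true(r4$altloc_within_5p5)
})

test_that("missing heavy atoms within 3.5 A are reported against the roster", {
  # serine missing OG, carbonyl O at 3.2 A from the ligand
  ser <- dplyr::bind_rows(
    atom_row("N", 7.0, 0, 0, comp_id = "SER", chain_id = "B", is_hetatm = FALSE),
    atom_row("CA", 5.9, 0.9, 0, comp_id = "SER", chain_id = "B", is_hetatm = FALSE),
    atom_row("C", 4.6, 0.4, 0, comp_id = "SER", chain_id = "B", is_hetatm = FALSE),
    atom_row("O", 3.2, 0.4, 0, comp_id = "SER", chain_id = "B", is_hetatm = FALSE)
    # CB and OG absent
  )
  m <- big_p1_model(dplyr::bind_rows(atom_row("C1", 0, 0.4, 0), ser))
  r <- validate_environment(m, ligand_selector("A", "LIG", 1))
  expect_true(r$missing_atoms_within_3p5)
  miss <- r$offenders[r$offenders$check == "missing_atoms_within_3p5", ]
  expect_setequal(miss$atom, c("CB", "OG"))
  expect_false(r$clean)
})

test_that("unknown components are reported, not fatal", {
  odd <- atom_row("Q1", 3.0, 0, 0, comp_id = "QQQ", chain_id = "B")
  m <- big_p1_model(dplyr::bind_rows(atom_row("C1", 0, 0, 0), odd))
  r <- validate_environment(m, ligand_selector("A", "LIG", 1))
  expect_true("QQQ" %in% r$unknown_components)
})

test_that("neutral capping puts one hydrogen per cut bond along the old vector", {
  fx <- generate_fixture(fixture_spec(seed = 6))
  cl <- build_ligand_cluster(fx$model, ligand_selector("A", "LIG", 1),
    dictionaries = list(LIG = fx$dictionary)
  )
  n_heavy <- sum(!cl$atoms$is_hydrogen)
  capped <- cap_dangling_bonds(cl, "neutral")
  caps <- capped$atoms[capped$atoms$role == "cap", ]
  expect_equal(nrow(caps), nrow(cl$cut_bonds))
  expect_true(all(caps$element == "H"))
  expect_equal(sum(!capped$atoms$is_hydrogen), n_heavy) # heavy atoms conserved
  cb <- capped$cut_bonds
  for (i in seq_len(nrow(cb))) {
    inside <- capped$atoms[match(cb$inside_serial[i], capped$atoms$serial), ]
    cap <- capped$atoms[match(cb$cap_serial[i], capped$atoms$serial), ]
    p_in <- as.numeric(inside[, c("x", "y", "z")])
    p_cap <- as.numeric(cap[, c("x", "y", "z")])
    p_out <- c(cb$outside_x[i], cb$outside_y[i], cb$outside_z[i])
    d_expect <- c(C = 1.09, N = 1.01, O = 0.96)[[inside$element]]
    expect_equal(bond_length(p_in, p_cap), d_expect, tolerance = 1e-9)
    # collinear with the former bond vector
    expect_equal(valence_angle(p_cap, p_in, p_out), 0, tolerance = 1e-6)
  }
})

test_that("capping a cut-free cluster changes nothing and double capping errors", {
  cl <- toy_cluster(tibble::tibble(name = c("C1", "C2"), x = c(0, 1.5), y = 0, z = 0))
  cl$capped <- FALSE
  capped <- cap_dangling_bonds(cl)
  expect_equal(nrow(capped$atoms), 2)
  expect_error(cap_dangling_bonds(capped), "already capped")
})

test_that("zwitterion mode builds charged termini on backbone cuts", {
  fx <- generate_fixture(fixture_spec(seed = 6))
  cl <- build_ligand_cluster(fx$model, ligand_selector("A", "LIG", 1),
    dictionaries = list(LIG = fx$dictionary)
  )
  capped <- cap_dangling_bonds(cl, "zwitterion")
  caps <- capped$atoms[capped$atoms$role == "cap", ]
  cb <- capped$cut_bonds
  c_cuts <- sum(cb$inside_name == "C" & cb$outside_name == "N")
  n_cuts <- sum(cb$inside_name == "N" & cb$outside_name == "C")
  expect_equal(sum(caps$name == "OXT"), c_cuts)
  expect_equal(sum(grepl("^HT", caps$name)), 3 * n_cuts)
  # OXT completes a carboxylate: C-OXT 1.25 A
  for (i in which(cb$inside_name == "C" & cb$outside_name == "N")) {
    inside <- capped$atoms[match(cb$inside_serial[i], capped$atoms$serial), ]
    oxt <- capped$atoms[match(cb$cap_serial[i], capped$atoms$serial), ]
    expect_equal(
      bond_length(
        as.numeric(inside[, c("x", "y", "z")]),
        as.numeric(oxt[, c("x", "y", "z")])
      ),
      1.25,
      tolerance = 1e-9
    )
  }
})

test_that("isolated waters gain two protons in the canonical geometry", {
  m <- big_p1_model(dplyr::bind_rows(
    atom_row("C1", 0, 0, 0), atom_row("C2", 1.5, 0, 0),
    atom_row("O", 0, 3.2, 0, comp_id = "HOH", chain_id = "W")
  ))
  cl <- build_ligand_cluster(m, ligand_selector("A", "LIG", 1))
  pr <- protonate_waters(cl)
  hs <- pr$atoms[pr$atoms$role == "proton", ]
  expect_equal(nrow(hs), 2)
  o <- pr$atoms[pr$atoms$comp_id == "HOH" & !pr$atoms$is_hydrogen, ]
  po <- as.numeric(o[, c("x", "y", "z")])
  p1 <- as.numeric(hs[1, c("x", "y", "z")])
  p2 <- as.numeric(hs[2, c("x", "y", "z")])
  expect_equal(bond_length(po, p1), 0.96, tolerance = 1e-9)
  expect_equal(bond_length(po, p2), 0.96, tolerance = 1e-9)
  expect_equal(valence_angle(p1, po, p2), 104.5, tolerance = 1e-6)
})

test_that("water hydrogens point towards nearby acceptors", {
  # water flanked by two carbonyl-like O acceptors
  m <- big_p1_model(dplyr::bind_rows(
    atom_row("O1", 0, 0, 0), atom_row("C2", 1.4, 0, 0),
    atom_row("O", 2.0, 2.2, 0, comp_id = "HOH", chain_id = "W"),
    atom_row("O2", 4.0, 3.0, 0, comp_id = "LIG", chain_id = "A")
  ))
  cl <- build_ligand_cluster(m, ligand_selector("A", "LIG", 1), radius = 4)
  pr <- protonate_waters(cl)
  hs <- pr$atoms[pr$atoms$role == "proton", ]
  o <- pr$atoms[pr$atoms$comp_id == "HOH" & !pr$atoms$is_hydrogen, ]
  po <- as.numeric(o[, c("x", "y", "z")])
  acc <- rbind(c(0, 0, 0), c(4.0, 3.0, 0))
  for (i in 1:2) {
    ph <- as.numeric(hs[i, c("x", "y", "z")])
    angs <- apply(acc, 1, function(pa) valence_angle(ph, po, pa))
    expect_lt(min(angs), 45)
  }
})

test_that("water protonation is idempotent and rejects over-protonated waters", {
  m <- big_p1_model(dplyr::bind_rows(
    atom_row("C1", 0, 0, 0), atom_row("C2", 1.5, 0, 0),
    atom_row("O", 0, 3.2, 0, comp_id = "HOH", chain_id = "W")
  ))
  cl <- build_ligand_cluster(m, ligand_selector("A", "LIG", 1))
  once <- protonate_waters(cl)
  twice <- protonate_waters(once)
  expect_identical(twice$atoms, once$atoms)

  # partially protonated water: the second H completes the 104.5 deg angle
  m2 <- big_p1_model(dplyr::bind_rows(
    atom_row("C1", 0, 0, 0), atom_row("C2", 1.5, 0, 0),
    atom_row("O", 0, 3.2, 0, comp_id = "HOH", chain_id = "W"),
    atom_row("H1", 0.96, 3.2, 0, comp_id = "HOH", chain_id = "W")
  ))
  cl2 <- protonate_waters(build_ligand_cluster(m2, ligand_selector("A", "LIG", 1)))
  ws <- cl2$atoms[cl2$atoms$comp_id == "HOH", ]
  expect_equal(sum(ws$is_hydrogen), 2)
  po <- as.numeric(ws[!ws$is_hydrogen, c("x", "y", "z")])
  hh <- ws[ws$is_hydrogen, ]
  expect_equal(
    valence_angle(
      as.numeric(hh[1, c("x", "y", "z")]), po,
      as.numeric(hh[2, c("x", "y", "z")])
    ),
    104.5,
    tolerance = 1e-6
  )

  m3 <- big_p1_model(dplyr::bind_rows(
    atom_row("C1", 0, 0, 0), atom_row("C2", 1.5, 0, 0),
    atom_row("O", 0, 3.2, 0, comp_id = "HOH", chain_id = "W"),
    atom_row("H1", 0.96, 3.2, 0, comp_id = "HOH", chain_id = "W"),
    atom_row("H2", -0.3, 4.1, 0, comp_id = "HOH", chain_id = "W"),
    atom_row("H3", -0.3, 2.3, 0, comp_id = "HOH", chain_id = "W")
  ))
  cl3 <- build_ligand_cluster(m3, ligand_selector("A", "LIG", 1))
  expect_error(protonate_waters(cl3), "hydrogens")
})

test_that("cluster export writes provenance remarks and re-parses", {
  fx <- generate_fixture(fixture_spec(seed = 7))
  cl <- protonate_waters(cap_dangling_bonds(
    build_ligand_cluster(fx$model, ligand_selector("A", "LIG", 1),
      dictionaries = list(LIG = fx$dictionary)
    )
  ))
  tf <- withr::local_tempfile(fileext = ".pdb")
  txt <- write_cluster_pdb(cl, tf)
  expect_true(any(grepl("REMARK 300 CUT BOND", txt)))
  again <- read_structure(tf)
  expect_equal(nrow(again$atoms), nrow(cl$atoms))
})
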