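toy_dictionary <- function() {
  restraint_dictionary(
    "TOY",
    atoms = tibble::tibble(
      name = c("C1", "C2", "O1", "N1", "C3", "H1"),
      element = c("C", "C", "O", "N", "C", "H")
    ),
    bonds = tibble::tibble(
      atom1 = c("C1", "C1", "C2"), atom2 = c("C2", "O1", "N1"),
      target = c(1.53, 1.43, 1.47), esd = c(0.02, 0.018, 0.021)
    ),
    angles = tibble::tibble(
      atom1 = "C2", atom2 = "C1", atom3 = "O1", target = 109.5, esd = 2.1
    ),
    torsions = tibble::tibble(
      id = c("t1", "t2"),
      atom1 = c("O1", "N1"), atom2 = c("C1", "C2"),
      atom3 = c("C2", "C1"), atom4 = c("N1", "H1"),
      target = c(60, 180), esd = c(30, 20), period = c(1L, 3L),
      alternatives = list(c(-60, 120.5), NULL)
    ),
    planes = tibble::tibble(
      plane_id = "plan-1", atom = c("C1", "C2", "O1", "N1"), esd = 0.02
    ),
    chirals = tibble::tibble(
      id = "chir_1", center = "C1", atom1 = "C2", atom2 = "O1", atom3 = "C3",
      sign = "positive"
    ),
    formal_charge = -1L
  )
}

test_that("a minimal two-atom component parses", {
  txt <- c(
    "data_comp_XX",
    "_chem_comp.id XX",
    "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "XX C1 C", "XX O1 O",
    "loop_",
    "_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2", "_chem_comp_bond.value_dist",
    "_chem_comp_bond.value_dist_esd",
    "XX C1 O1 1.430 0.020"
  )
  d <- parse_restraint_cif(txt)
  expect_equal(d$comp_id, "XX")
  expect_equal(nrow(d$bonds), 1)
  expect_equal(nrow(d$angles), 0)
  expect_equal(d$bonds$target, 1.43)
})

test_that("torsion period column maps through and defaults to 1", {
  txt <- c(
    "data_comp_YY",
    "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "YY A1 C", "YY A2 C", "YY A3 C", "YY A4 C",
    "loop_",
    "_chem_comp_tor.comp_id", "_chem_comp_tor.id",
    "_chem_comp_tor.atom_id_1", "_chem_comp_tor.atom_id_2",
    "_chem_comp_tor.atom_id_3", "_chem_comp_tor.atom_id_4",
    "_chem_comp_tor.value_angle", "_chem_comp_tor.value_angle_esd",
    "_chem_comp_tor.period",
    "YY t1 A1 A2 A3 A4 60.0 30.0 3"
  )
  expect_equal(parse_restraint_cif(txt)$torsions$period, 3L)
  txt2 <- txt[!grepl("period", txt)]
  txt2[grep("YY t1", txt2)] <- "YY t1 A1 A2 A3 A4 60.0 30.0"
  expect_equal(parse_restraint_cif(txt2)$torsions$period, 1L)
})

test_that("write/parse round trip preserves every field", {
  d <- toy_dictionary()
  d2 <- parse_restraint_cif(write_restraint_cif(d))
  expect_equal(d2$comp_id, d$comp_id)
  expect_equal(d2$formal_charge, -1L)
  expect_equal(d2$atoms, d$atoms)
  expect_equal(d2$bonds$target, d$bonds$target, tolerance = 5e-4)
  expect_equal(d2$bonds$esd, d$bonds$esd, tolerance = 5e-4)
  expect_equal(d2$angles$target, d$angles$target, tolerance = 5e-3)
  expect_equal(d2$torsions$target, d$torsions$target, tolerance = 5e-3)
  expect_equal(d2$torsions$period, d$torsions$period)
  expect_equal(d2$torsions$alternatives[[1]], c(-60, 120.5), tolerance = 5e-3)
  expect_null(d2$torsions$alternatives[[2]])
  expect_equal(d2$planes$atom, d$planes$atom)
  expect_equal(d2$chirals$sign, d$chirals$sign)
  # empty restraint lists still produce valid CIF
  d0 <- restraint_dictionary(
    "EMP",
    atoms = tibble::tibble(name = "C1", element = "C")
  )
  d0b <- parse_restraint_cif(write_restraint_cif(d0))
  expect_equal(nrow(d0b$bonds), 0)
})

test_that("restraints naming unknown atoms are rejected", {
  expect_error(
    restraint_dictionary(
      "BAD",
      atoms = tibble::tibble(name = "C1", element = "C"),
      bonds = tibble::tibble(atom1 = "C1", atom2 = "ZZ", target = 1.5, esd = 0.02)
    ),
    "ZZ"
  )
})

test_that("missing e.s.d.s fall back to the typical values with a warning", {
  expect_warning(
    d <- restraint_dictionary(
      "TOY",
      atoms = tibble::tibble(name = c("C1", "C2"), element = "C"),
      bonds = tibble::tibble(atom1 = "C1", atom2 = "C2", target = 1.5, esd = NA)
    ),
    "e.s.d"
  )
  expect_equal(d$bonds$esd, 0.02)
})

test_that("in-situ target generation replaces targets and keeps e.s.d.s", {
  fx <- generate_fixture(fixture_spec(seed = 3, perturbation = c(torsion = 35)))
  lig <- fx$model$atoms[fx$model$atoms$comp_id == "LIG", ]
  qmr <- generate_qmr_restraints(lig, fx$dictionary)
  # e.s.d. multisets preserved per category
  expect_equal(sort(qmr$bonds$esd), sort(fx$dictionary$bonds$esd))
  expect_equal(sort(qmr$angles$esd), sort(fx$dictionary$angles$esd))
  expect_equal(sort(qmr$torsions$esd), sort(fx$dictionary$torsions$esd))
  # torsions become unimodal
  expect_true(all(qmr$torsions$period == 1L))
  expect_true(all(vapply(qmr$torsions$alternatives, is.null, logical(1))))
  # planes/chirality/charge copied
  expect_identical(qmr$planes, fx$dictionary$planes)
  expect_identical(qmr$chirals, fx$dictionary$chirals)
  expect_identical(qmr$formal_charge, fx$dictionary$formal_charge)
  # self-consistency: measuring the same coordinates yields zero everywhere
  rep <- geometry_report(lig, qmr, include_h = TRUE)
  expect_lt(max(rep$records$abs_delta), 1e-9)
  expect_equal(rep$rmsd$rmsd, c(0, 0, 0), tolerance = 1e-9)
})

test_that("generation at the base geometry is a fixed point", {
  fx <- generate_fixture(fixture_spec(seed = 4))
  qmr <- generate_qmr_restraints(fx$ground_truth, fx$dictionary)
  expect_equal(qmr$bonds$target, fx$dictionary$bonds$target, tolerance = 1e-9)
  expect_equal(qmr$angles$target, fx$dictionary$angles$target, tolerance = 1e-9)
  expect_equal(qmr$torsions$target, fx$dictionary$torsions$target, tolerance = 1e-9)
})

test_that("an angle target moves to the measured in-situ value", {
  # base angle 109.7 deg, in-situ geometry measures 111.7 deg
  d <- restraint_dictionary(
    "TOY",
    atoms = tibble::tibble(name = c("C10", "C7", "N1"), element = c("C", "C", "N")),
    angles = tibble::tibble(
      atom1 = "C10", atom2 = "C7", atom3 = "N1", target = 109.7, esd = 2
    )
  )
  th <- 111.7 * pi / 180
  coords <- tibble::tibble(
    name = c("C10", "C7", "N1"),
    x = c(1.5, 0, 1.45 * cos(th)), y = c(0, 0, 1.45 * sin(th)), z = 0
  )
  qmr <- generate_qmr_restraints(coords, d)
  expect_equal(qmr$angles$target, 111.7, tolerance = 1e-6)
  expect_equal(qmr$angles$esd, 2)
})

test_that("generation requires every heavy roster atom", {
  fx <- generate_fixture(fixture_spec(seed = 1))
  partial <- fx$ground_truth[fx$ground_truth$name != "C3", ]
  expect_error(generate_qmr_restraints(partial, fx$dictionary), "C3")
  # absent hydrogens are tolerated: H-restraint targets are copied
  heavy <- fx$ground_truth[fx$ground_truth$element != "H", ]
  qmr <- generate_qmr_restraints(heavy, fx$dictionary)
  d <- fx$dictionary
  h_tor <- d$torsions$id[d$torsions$atom4 == "H41"]
  expect_equal(
    qmr$torsions$target[qmr$torsions$id == h_tor],
    d$torsions$target[d$torsions$id == h_tor]
  )
})
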