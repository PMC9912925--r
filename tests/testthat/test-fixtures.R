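test_that("an unperturbed fixture measures zero against its dictionary", {
  fx <- generate_fixture(fixture_spec(seed = 1))
  lig <- fx$model$atoms[fx$model$atoms$comp_id == "LIG", ]
  rep <- geometry_report(lig, fx$dictionary, include_h = TRUE)
  expect_lt(max(rep$records$abs_delta), 1e-9)
})

test_that("a pure torsion twist shows up as the torsion r.m.s.d.", {
  fx <- generate_fixture(fixture_spec(seed = 3, perturbation = c(torsion = 40)))
  lig <- fx$model$atoms[fx$model$atoms$comp_id == "LIG", ]
  g <- glance(geometry_report(lig, fx$dictionary))
  expect_equal(g$rmsd_torsions, 40, tolerance = 0.5)
  expect_lt(g$rmsd_bonds, 1e-6)
  expect_lt(g$rmsd_angles, 1e-3)
})

test_that("fixtures are byte-identical for a fixed seed", {
  spec <- fixture_spec(seed = 42, perturbation = c(bond = 0.03, torsion = 25))
  a <- generate_fixture(spec)
  b <- generate_fixture(spec)
  expect_identical(write_structure(a$model, "pdb"), write_structure(b$model, "pdb"))
  expect_identical(
    write_restraint_cif(a$dictionary),
    write_restraint_cif(b$dictionary)
  )
  c <- generate_fixture(fixture_spec(seed = 43, perturbation = c(bond = 0.03, torsion = 25)))
  expect_false(identical(write_structure(a$model, "pdb"), write_structure(c$model, "pdb")))
})

test_that("fixture knobs control ligand size, pocket and waters", {
  fx <- generate_fixture(fixture_spec(
    seed = 2, ligand_size = 10,
    pocket_residues = 3, n_waters = 4
  ))
  a <- fx$model$atoms
  expect_equal(sum(a$comp_id == "LIG" & a$element != "H"), 10)
  expect_equal(sum(a$comp_id == "HOH"), 4)
  expect_equal(length(unique(a$chain_id[a$comp_id == "GLY"])), 3)
  # the dictionary has a period-3 torsion and one with alternatives
  expect_true(any(fx$dictionary$torsions$period == 3))
  expect_true(any(lengths(fx$dictionary$torsions$alternatives) > 0))
})

test_that("the pipeline regenerates restraints the optimized geometry satisfies", {
  fx <- generate_fixture(fixture_spec(seed = 11, perturbation = c(torsion = 40)))
  res <- run_qmr_pipeline(
    fx$model, ligand_selector("A", "LIG", 1), fx$dictionary,
    max_steps = 400
  )
  expect_lt(glance(res$report_after)$rmsd_torsions, 1e-6)
  expect_equal(glance(res$report_before)$rmsd_torsions, 40, tolerance = 0.5)
  # base dictionary untouched
  expect_equal(res$report_before$records$target[res$report_before$records$kind == "torsion"],
    fx$dictionary$torsions$target[fx$dictionary$torsions$period == 1],
    tolerance = 1e-9
  )
})

test_that("builtin optimization recovers the pocket-held ground truth", {
  fx <- generate_fixture(fixture_spec(seed = 8, perturbation = c(torsion = 40)))
  res <- run_qmr_pipeline(fx$model, ligand_selector("A", "LIG", 1), fx$dictionary)
  opt_lig <- res$cluster$atoms[res$cluster$atoms$role == "ligand", ]
  g <- glance(geometry_report(opt_lig, fx$dictionary))
  expect_lt(g$rmsd_torsions, 5)
  expect_true(res$optimization$converged)
})

test_that("reruns with a warm cache reproduce the result without optimizing", {
  cache <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(seed = 13, perturbation = c(torsion = 30)))
  r1 <- run_qmr_pipeline(fx$model, ligand_selector("A", "LIG", 1), fx$dictionary,
    max_steps = 300, cache_dir = cache
  )
  r2 <- run_qmr_pipeline(fx$model, ligand_selector("A", "LIG", 1), fx$dictionary,
    max_steps = 300, cache_dir = cache
  )
  expect_true(isTRUE(r2$optimization$from_cache))
  expect_equal(r2$optimization$positions, r1$optimization$positions,
    tolerance = 1e-12
  )
  expect_equal(
    write_restraint_cif(r2$qmr_dictionary),
    write_restraint_cif(r1$qmr_dictionary)
  )
})

test_that("pipeline runs persist their intermediates", {
  out <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(seed = 3, perturbation = c(torsion = 20)))
  res <- run_qmr_pipeline(fx$model, ligand_selector("A", "LIG", 1), fx$dictionary,
    max_steps = 200, out_dir = out
  )
  expect_true(file.exists(file.path(out, "cluster.pdb")))
  expect_true(file.exists(file.path(out, "qmr_restraints.cif")))
  expect_true(file.exists(file.path(out, "summary.json")))
  d <- parse_restraint_cif(file.path(out, "qmr_restraints.cif"))
  expect_equal(d$comp_id, "LIG")
})

test_that("in-situ restraints never raise the torsion r.m.s.d. of the relaxed model", {
  for (s in c(5, 9, 14)) {
    fx <- generate_fixture(fixture_spec(
      seed = s,
      perturbation = c(angle = 4, torsion = 35)
    ))
    res <- run_qmr_pipeline(fx$model, ligand_selector("A", "LIG", 1), fx$dictionary,
      max_steps = 500
    )
    g_insitu <- glance(res$report_after)$rmsd_torsions
    g_base <- glance(res$report_optimized_vs_base)$rmsd_torsions
    expect_lte(g_insitu, g_base + 1e-9)
  }
})

test_that("pocket sterics hold the torsion the full minimizer finds", {
  # a rigid environment atom is planted where the base-target rotamer wants
  # to put C4, so the torsion must settle away from the base target; a 1-D
  # brute-force scan of the same objective over the rotatable torsion is
  # the oracle for the pocket-compatible value
  fx <- generate_fixture(fixture_spec(seed = 21, pocket_residues = 0, n_waters = 0))
  truth <- fx$ground_truth
  z <- qmrestraints:::.ligand_zmatrix(8)
  rot_about <- function(zlist, dih) {
    zlist[[4]]$dih <- dih # the rotatable torsion entry (N1)
    qmrestraints:::.build_from_zmatrix(zlist)
  }
  # blocker near the N1 position of the base rotamer (torsion 60)
  base_conf <- rot_about(z, 60)
  n1 <- as.numeric(base_conf[base_conf$name == "N1", c("x", "y", "z")])
  shift <- as.numeric(truth[1, c("x", "y", "z")]) -
    as.numeric(base_conf[1, c("x", "y", "z")])
  blocker <- atom_row("C", n1[1] + shift[1] + 0.8, n1[2] + shift[2],
    n1[3] + shift[3],
    comp_id = "ALA", chain_id = "B", is_hetatm = FALSE
  )
  atoms <- dplyr::bind_rows(
    fx$model$atoms[fx$model$atoms$comp_id == "LIG", names(blocker)], blocker
  )
  # start from a twisted rotamer so the minimizer approaches the blocker
  start <- rot_about(z, 100)
  atoms[atoms$comp_id == "LIG", c("x", "y", "z")] <-
    start[, c("x", "y", "z")] + matrix(shift, nrow(start), 3, byrow = TRUE)
  model <- big_p1_model(atoms)
  # only the atoms downstream of the rotatable bond move, so the torsion
  # itself is the escape coordinate (the pocket would otherwise have to
  # cage the whole ligand, which one blocker atom cannot)
  downstream <- c("N1", "C4", "C5", "C6", "H41", "H42", "H43")
  cl0 <- build_ligand_cluster(model, ligand_selector("A", "LIG", 1),
    dictionaries = list(LIG = fx$dictionary)
  )
  mob <- cl0$atoms$serial[cl0$atoms$name %in% downstream &
    cl0$atoms$role == "ligand"]
  res <- run_qmr_pipeline(model, ligand_selector("A", "LIG", 1), fx$dictionary,
    mobile = mob
  )
  opt_lig <- res$cluster$atoms[res$cluster$atoms$role == "ligand", ]
  xyz <- as.matrix(opt_lig[, c("x", "y", "z")])
  rownames(xyz) <- opt_lig$name
  tor_opt <- torsion_angle(xyz["C1", ], xyz["C2", ], xyz["C3", ], xyz["N1", ])

  # 1-D oracle: scan the torsion, measure the same objective
  cl <- protonate_waters(cap_dangling_bonds(build_ligand_cluster(
    model, ligand_selector("A", "LIG", 1),
    dictionaries = list(LIG = fx$dictionary)
  )))
  job <- optimization_job(cl, fx$dictionary)
  terms <- qmrestraints:::.build_objective(job)
  scan <- vapply(seq(-180, 179, by = 1), function(dih) {
    conf <- rot_about(z, dih)
    P <- as.matrix(cl$atoms[, c("x", "y", "z")])
    ord <- match(cl$atoms$name[cl$atoms$role == "ligand"], conf$name)
    P[cl$atoms$role == "ligand", ] <-
      as.matrix(conf[ord, c("x", "y", "z")]) +
      matrix(shift, length(ord), 3, byrow = TRUE)
    qmrestraints:::.objective_eval(terms, P, want_grad = FALSE)$E
  }, numeric(1))
  # the minimizer descends locally from the 100-degree start, so the
  # matching oracle is discrete downhill descent on the scanned profile
  # from the same start
  grid <- seq(-180, 179, by = 1)
  i <- which.min(abs(grid - 100))
  repeat {
    left <- if (i == 1) length(grid) else i - 1
    right <- if (i == length(grid)) 1 else i + 1
    nxt <- if (scan[left] < scan[right]) left else right
    if (scan[nxt] >= scan[i]) break
    i <- nxt
  }
  tor_oracle <- grid[i]
  expect_lt(abs(wrap_angle(tor_opt - tor_oracle)), 5)
  # and the blocker really pushed it off the base target
  expect_gt(abs(wrap_angle(tor_opt - 60)), 10)
})
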