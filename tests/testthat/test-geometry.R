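test_that("internal coordinates follow the standard conventions", {
  expect_equal(bond_length(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(valence_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  # planar cis quadruple -> 0; trans zigzag -> 180
  expect_equal(
    torsion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0
  )
  expect_equal(
    torsion_angle(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0)), 180
  )
  expect_error(
    torsion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "collinear"
  )
})

test_that("torsions agree with an independent vector-algebra formulation", {
  # oracle: project bond 1 and bond 3 onto the plane normal to bond 2 and
  # take the signed angle between the projections
  oracle <- function(p1, p2, p3, p4) {
    b2 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
    u <- (p1 - p2) - sum((p1 - p2) * b2) * b2
    v <- (p4 - p3) - sum((p4 - p3) * b2) * b2
    ang <- atan2(sum(qmrestraints:::.cross(u, v) * b2), sum(u * v)) * 180 / pi
    wrap_angle(ang)
  }
  set.seed(11)
  for (i in 1:100) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    got <- tryCatch(
      torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
      error = function(e) NA
    )
    if (is.na(got)) next
    expect_equal(got, oracle(p[1, ], p[2, ], p[3, ], p[4, ]), tolerance = 1e-9)
  }
})

test_that("signed deviations use delta = target - actual", {
  expect_equal(signed_deviation("bond", 1.419, 1.394), 0.025)
  expect_equal(signed_deviation("angle", 109.7, 117.3), -7.6)
  expect_equal(signed_deviation("torsion", 58.0, -18.7), 76.7)
  expect_equal(signed_deviation("bond", 1.5, 1.5), 0)
  expect_equal(signed_deviation("torsion", 60, 60), 0)
})

test_that("torsion deviations wrap and honor periodicity and alternatives", {
  # out-of-range targets are normalised on ingest but the printed delta
  # is still recovered through wrapping
  expect_equal(signed_deviation("torsion", wrap_angle(210.9), 143.3), 67.6,
    tolerance = 1e-9
  )
  expect_equal(wrap_angle(210.9), -149.1, tolerance = 1e-9)
  # methyl propeller: period 3 target 60 has minima at 60, 180, 300
  expect_equal(signed_deviation("torsion", 60, 175, periodicity = 3), 5)
  # aperiodic alternatives (ring pucker style)
  expect_equal(
    signed_deviation("torsion", -60, 55, periodicity = 1, alternatives = 60),
    5
  )
  # ties break towards the base target
  expect_equal(signed_deviation("torsion", 0, 90, periodicity = 2), -90)
  expect_error(signed_deviation("torsion", 0, 10, periodicity = 0), "periodicity")
})

test_that("periodicity-aware deviation equals brute-force candidate search", {
  set.seed(21)
  for (i in 1:500) {
    target <- runif(1, -180, 180)
    actual <- runif(1, -180, 180)
    p <- sample(1:6, 1)
    got <- signed_deviation("torsion", target, actual, periodicity = p)
    cands <- wrap_angle(target + (0:(p - 1)) * 360 / p)
    best <- min(abs(wrap_angle(cands - actual)))
    expect_equal(abs(got), best, tolerance = 1e-9)
    expect_lte(abs(got), 180 / p + 1e-9)
  }
})

test_that("geometry reports aggregate per-category r.m.s.d. and outliers", {
  fx <- generate_fixture(fixture_spec(seed = 1))
  truth <- fx$ground_truth
  rep0 <- geometry_report(truth, fx$dictionary)
  expect_true(all(abs(rep0$records$delta) < 1e-9))
  expect_equal(rep0$rmsd$rmsd, c(0, 0, 0), tolerance = 1e-9)

  # one-element category: rmsd equals |delta|
  d1 <- restraint_dictionary(
    "TOY",
    atoms = tibble::tibble(name = c("A1", "A2", "A3"), element = "C"),
    angles = tibble::tibble(
      atom1 = "A1", atom2 = "A2", atom3 = "A3", target = 109.7, esd = 2
    )
  )
  coords <- tibble::tibble(
    name = c("A1", "A2", "A3"),
    x = c(1, 0, cos(117.3 * pi / 180)), y = c(0, 0, sin(117.3 * pi / 180)),
    z = 0
  )
  r1 <- geometry_report(coords, d1)
  expect_equal(r1$records$delta, -7.6, tolerance = 1e-6)
  expect_equal(r1$rmsd$rmsd[r1$rmsd$kind == "angle"], 7.6, tolerance = 1e-6)
  expect_true(r1$records$is_outlier)
  # empty categories are undefined, not zero
  expect_true(is.na(r1$rmsd$rmsd[r1$rmsd$kind == "bond"]))
})

test_that("reported r.m.s.d. matches the direct formula on known deltas", {
  deltas <- c(76.7, 56.1, 48.2)
  expect_equal(sqrt(mean(deltas^2)), 61.55, tolerance = 0.01)
})

test_that("r.m.s.d. is invariant to record order and rigid-body motion", {
  fx <- generate_fixture(fixture_spec(seed = 9, perturbation = c(torsion = 25)))
  lig <- fx$model$atoms[fx$model$atoms$comp_id == "LIG", ]
  g1 <- glance(geometry_report(lig, fx$dictionary))
  # rotate + translate the coordinates
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(lig[, c("x", "y", "z")]) %*% rot
  lig2 <- lig
  lig2$x <- xyz[, 1] + 5
  lig2$y <- xyz[, 2] - 3
  lig2$z <- xyz[, 3] + 1
  g2 <- glance(geometry_report(lig2, fx$dictionary))
  expect_equal(g2$rmsd_torsions, g1$rmsd_torsions, tolerance = 1e-9)
  expect_equal(g2$rmsd_bonds, g1$rmsd_bonds, tolerance = 1e-9)
  # shuffled ligand rows
  lig3 <- lig[sample(nrow(lig)), ]
  g3 <- glance(geometry_report(lig3, fx$dictionary))
  expect_equal(g3$rmsd_angles, g1$rmsd_angles, tolerance = 1e-12)
})

test_that("hydrogen-containing restraints are excluded unless requested", {
  fx <- generate_fixture(fixture_spec(seed = 1))
  truth <- fx$ground_truth
  non_h <- geometry_report(truth, fx$dictionary, include_h = FALSE)
  with_h <- geometry_report(truth, fx$dictionary, include_h = TRUE)
  expect_false(any(non_h$records$involves_h))
  expect_gt(nrow(with_h$records), nrow(non_h$records))
  # heavy-only coordinates suffice for the default statistics
  heavy <- truth[!truth$element %in% "H", ]
  expect_silent(geometry_report(heavy, fx$dictionary, include_h = FALSE))
  expect_error(geometry_report(heavy, fx$dictionary, include_h = TRUE), "missing")
})

test_that("resolution bins follow the published layout", {
  dat <- tibble::tibble(
    resolution = c(1.39, 1.41, 2.95),
    rmsd = c(1, 2, 3),
    condition = "a"
  )
  sm <- suppressWarnings(binned_summary(dat))
  bins <- as.character(sm$bin[match(c(1, 2, 3), sm$mean)])
  expect_equal(bins[1], "(0.8,1.4]")
  expect_equal(bins[2], "(1.4,1.6]")
  expect_equal(bins[3], "(2.8,3]")
  expect_error(
    binned_summary(tibble::tibble(resolution = 3.2, rmsd = 1, condition = "a")),
    "resolutions"
  )
})

test_that("binned summaries report n, mean, s.e.m. and Welch p-values", {
  set.seed(5)
  dat <- dplyr::bind_rows(
    tibble::tibble(
      resolution = runif(40, 1.45, 1.6), rmsd = 2, condition = "base"
    ),
    tibble::tibble(
      resolution = runif(40, 1.45, 1.6), rmsd = 2, condition = "insitu"
    )
  )
  sm <- binned_summary(dat)
  row <- sm[sm$condition == "base" & sm$n > 0, ]
  expect_equal(row$mean, 2)
  expect_equal(row$sem, 0) # identical values
  # distinguishable conditions give small p in the populated bin
  dat2 <- dat
  dat2$rmsd <- ifelse(dat2$condition == "base", rnorm(80, 50, 5), rnorm(80, 15, 5))
  sm2 <- binned_summary(dat2)
  expect_lt(min(sm2$p_value, na.rm = TRUE), 1e-6)
  # single-entry bins have undefined sem/p
  dat3 <- tibble::tibble(resolution = 2.31, rmsd = 1, condition = "base")
  sm3 <- binned_summary(dat3)
  expect_true(is.na(sm3$sem))
})
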