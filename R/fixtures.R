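# Synthetic fixtures: a toy ligand with known internal coordinates (one
# rotatable torsion, one ring-pucker-like torsion carrying aperiodic
# alternative targets, one period-3 methyl torsion), a small glycine
# pocket whose middle residues contact the ligand (producing genuine
# peptide cut bonds), and waters modeled as bare O atoms. The generator is
# fully deterministic for a fixed seed, and the accompanying dictionary is
# measured from the unperturbed ground-truth geometry, so every deviation
# introduced by `perturbation` is known by construction.

#' Place an atom from internal coordinates
#'
#' Returns the position of an atom at distance `dist` from `c3`, forming
#' the given valence angle with `c2` and the given dihedral (IUPAC sign)
#' with `c1` (i.e. `torsion_angle(new, c3, c2, c1) == dihedral`).
#'
#' @param c1,c2,c3 Reference positions (dihedral, angle, bond reference).
#' @param dist Bond length (Angstrom).
#' @param angle Valence angle new-c3-c2 (degrees).
#' @param dihedral Dihedral new-c3-c2-c1 (degrees).
#' @return Length-3 position.
#' @export
place_atom <- function(c1, c2, c3, dist, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- .unit(c3 - c2)
  n <- .cross(c2 - c1, bc)
  if (.vnorm(n) < 1e-10) abort("collinear reference atoms in place_atom")
  n <- .unit(n)
  m <- .cross(n, bc)
  d2 <- c(-dist * cos(th), dist * sin(th) * cos(ph), dist * sin(th) * sin(ph))
  c3 + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Fixture specification
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param ligand_size Number of ligand heavy atoms (>= 6); extras extend an
#'   alkyl tail.
#' @param pocket_residues Number of pocket contact residues; each is the
#'   middle residue of a glycine tripeptide, so each contributes two cut
#'   peptide bonds to the cluster.
#' @param n_waters Number of waters (bare O atoms) near the ligand's polar
#'   atoms.
#' @param perturbation Named magnitudes `c(bond =, angle =, torsion =)`
#'   (Angstrom, degrees, degrees) applied to the ground-truth internal
#'   coordinates with seed-determined signs. The torsion magnitude twists
#'   each restrained rotatable bond (the rotatable and the pucker-like
#'   torsion) by exactly that amount.
#' @param space_group Space-group symbol (default P 1 with a padded box).
#' @param cell Optional explicit cell; by default a box with 20 Angstrom
#'   margins so that no symmetry image approaches the cluster.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, ligand_size = 8L, pocket_residues = 2L,
                         n_waters = 2L,
                         perturbation = c(bond = 0, angle = 0, torsion = 0),
                         space_group = "P 1", cell = NULL) {
  p <- c(bond = 0, angle = 0, torsion = 0)
  p[names(perturbation)] <- perturbation
  if (any(p < 0)) abort("perturbation magnitudes must be >= 0")
  if (ligand_size < 6) abort("ligand_size must be at least 6 heavy atoms")
  structure(
    list(
      seed = as.integer(seed), ligand_size = as.integer(ligand_size),
      pocket_residues = as.integer(pocket_residues),
      n_waters = as.integer(n_waters), perturbation = p,
      space_group = space_group, cell = cell
    ),
    class = "fixture_spec"
  )
}

# Ligand internal-coordinate table. Each row: name, element, refs
# (bond/angle/dihedral reference atoms), dist, angle, dihedral, and the
# perturbation class of each internal coordinate.
.ligand_zmatrix <- function(ligand_size) {
  z <- list(
    list(name = "C1", el = "C"),
    list(name = "C2", el = "C", r3 = "C1", dist = 1.530),
    list(name = "C3", el = "C", r3 = "C2", r2 = "C1", dist = 1.530, angle = 111.0),
    list(
      name = "N1", el = "N", r3 = "C3", r2 = "C2", r1 = "C1",
      dist = 1.470, angle = 110.0, dih = 60.0, tor_class = "rot"
    ),
    list(
      name = "O1", el = "O", r3 = "C1", r2 = "C2", r1 = "C3",
      dist = 1.430, angle = 109.5, dih = -60.0, tor_class = "puck"
    ),
    list(
      name = "C4", el = "C", r3 = "N1", r2 = "C3", r1 = "C2",
      dist = 1.470, angle = 110.0, dih = 180.0
    )
  )
  prev <- c("N1", "C3", "C2")
  extra_dih <- 60
  for (i in seq_len(ligand_size - 6)) {
    nm <- sprintf("C%d", 4 + i)
    z[[length(z) + 1L]] <- list(
      name = nm, el = "C", r3 = prev[1], r2 = prev[2], r1 = prev[3],
      dist = if (prev[1] == "N1") 1.470 else 1.530,
      angle = 111.0, dih = extra_dih
    )
    prev <- c(nm, prev[1], prev[2])
    extra_dih <- 180
  }
  z <- c(z, list(
    list(
      name = "H41", el = "H", r3 = "C4", r2 = "N1", r1 = "C3",
      dist = 1.090, angle = 109.5, dih = 60.0, tor_class = "methyl"
    ),
    list(
      name = "H42", el = "H", r3 = "C4", r2 = "N1", r1 = "C3",
      dist = 1.090, angle = 109.5, dih = 180.0
    ),
    list(
      name = "H43", el = "H", r3 = "C4", r2 = "N1", r1 = "C3",
      dist = 1.090, angle = 109.5, dih = -60.0
    ),
    list(
      name = "HO1", el = "H", r3 = "O1", r2 = "C1", r1 = "C2",
      dist = 0.960, angle = 109.5, dih = 180.0
    )
  ))
  z
}

.build_from_zmatrix <- function(z) {
  pos <- list()
  pos[[z[[1]]$name]] <- c(0, 0, 0)
  pos[[z[[2]]$name]] <- c(z[[2]]$dist, 0, 0)
  e3 <- z[[3]]
  th <- e3$angle * pi / 180
  pos[[e3$name]] <- pos[[e3$r3]] +
    e3$dist * c(-cos(th), sin(th), 0)
  for (i in seq_along(z)[-(1:3)]) {
    e <- z[[i]]
    pos[[e$name]] <- place_atom(
      pos[[e$r1]], pos[[e$r2]], pos[[e$r3]], e$dist, e$angle, e$dih
    )
  }
  nm <- vapply(z, function(e) e$name, character(1))
  el <- vapply(z, function(e) e$el, character(1))
  xyz <- do.call(rbind, pos[nm])
  tibble::tibble(
    name = nm, element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

.zmatrix_bonds <- function(z) {
  out <- list()
  for (e in z[-1]) out[[length(out) + 1L]] <- c(e$r3, e$name)
  do.call(rbind, out)
}

# Build the ligand dictionary by measuring the ground-truth geometry:
# bonds and angles enumerated from the bond graph, three designated
# torsion restraints (rotatable, pucker-like with an alternative target
# 120 degrees away, and a period-3 methyl torsion).
.fixture_dictionary <- function(z, truth) {
  xyz <- as.matrix(truth[, c("x", "y", "z")])
  rownames(xyz) <- truth$name
  bp <- .zmatrix_bonds(z)
  bonds <- tibble::tibble(
    atom1 = bp[, 1], atom2 = bp[, 2],
    target = vapply(seq_len(nrow(bp)), function(i) {
      bond_length(xyz[bp[i, 1], ], xyz[bp[i, 2], ])
    }, numeric(1)),
    esd = 0.020
  )
  adj <- split(c(bp[, 2], bp[, 1]), c(bp[, 1], bp[, 2]))
  ang <- list()
  for (center in names(adj)) {
    nb <- sort(unique(adj[[center]]))
    if (length(nb) < 2) next
    for (i in seq_len(length(nb) - 1)) {
      for (j in (i + 1):length(nb)) {
        ang[[length(ang) + 1L]] <- tibble::tibble(
          atom1 = nb[i], atom2 = center, atom3 = nb[j],
          target = valence_angle(xyz[nb[i], ], xyz[center, ], xyz[nb[j], ]),
          esd = 2.0
        )
      }
    }
  }
  angles <- dplyr::bind_rows(ang)
  tor_val <- function(a1, a2, a3, a4) {
    torsion_angle(xyz[a1, ], xyz[a2, ], xyz[a3, ], xyz[a4, ])
  }
  puck <- tor_val("O1", "C1", "C2", "C3")
  torsions <- tibble::tibble(
    id = c("tor_rot", "tor_puck", "tor_methyl"),
    atom1 = c("C1", "O1", "C3"), atom2 = c("C2", "C1", "N1"),
    atom3 = c("C3", "C2", "C4"), atom4 = c("N1", "C3", "H41"),
    target = c(tor_val("C1", "C2", "C3", "N1"), puck, tor_val("C3", "N1", "C4", "H41")),
    esd = 30,
    period = c(1L, 1L, 3L),
    alternatives = list(NULL, wrap_angle(puck + 120), NULL)
  )
  restraint_dictionary(
    "LIG",
    atoms = truth[, c("name", "element")],
    bonds = bonds, angles = angles, torsions = torsions,
    formal_charge = 0L
  )
}

# Extended glycine tripeptide backbone (N, CA, C, O per residue) built in
# a local frame.
.gly_tripeptide <- function() {
  res <- list()
  pos <- list()
  pos[["N_1"]] <- c(0, 0, 0)
  pos[["CA_1"]] <- c(1.458, 0, 0)
  th <- 111 * pi / 180
  pos[["C_1"]] <- pos[["CA_1"]] + 1.525 * c(-cos(th), sin(th), 0)
  pos[["O_1"]] <- place_atom(
    pos[["N_1"]], pos[["CA_1"]], pos[["C_1"]], 1.231, 120.8, 0
  )
  for (r in 2:3) {
    pos[[sprintf("N_%d", r)]] <- place_atom(
      pos[[sprintf("N_%d", r - 1)]], pos[[sprintf("CA_%d", r - 1)]],
      pos[[sprintf("C_%d", r - 1)]], 1.329, 116.2, 180
    )
    pos[[sprintf("CA_%d", r)]] <- place_atom(
      pos[[sprintf("CA_%d", r - 1)]], pos[[sprintf("C_%d", r - 1)]],
      pos[[sprintf("N_%d", r)]], 1.458, 121.7, 180
    )
    pos[[sprintf("C_%d", r)]] <- place_atom(
      pos[[sprintf("C_%d", r - 1)]], pos[[sprintf("N_%d", r)]],
      pos[[sprintf("CA_%d", r)]], 1.525, 111.0, 180
    )
    pos[[sprintf("O_%d", r)]] <- place_atom(
      pos[[sprintf("N_%d", r)]], pos[[sprintf("CA_%d", r)]],
      pos[[sprintf("C_%d", r)]], 1.231, 120.8, 0
    )
  }
  nm <- names(pos)
  xyz <- do.call(rbind, pos)
  tibble::tibble(
    name = sub("_\\d+$", "", nm),
    seq_id = as.integer(sub("^.*_", "", nm)),
    element = substr(sub("_\\d+$", "", nm), 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

.rotation_to <- function(from, to) {
  # rotation matrix sending unit vector `from` onto `to`
  f <- .unit(from)
  t <- .unit(to)
  v <- .cross(f, t)
  s <- .vnorm(v)
  c_ <- sum(f * t)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    p <- .perp_frame(f)$v
    return(2 * outer(p, p) - diag(3) + 2 * outer(f, f) * 0) # 180 deg flip
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

.min_interset_dist <- function(xyz_a, xyz_b) {
  min(.min_dist_to(xyz_a, xyz_b))
}

#' Generate a synthetic pocket fixture
#'
#' Produces a structure model (ligand `LIG` in chain A, glycine tripeptide
#' chains, waters as bare O), the base restraint dictionary measured from
#' the unperturbed ligand, and the ground-truth ligand coordinates. The
#' deposited-like ligand coordinates are the ground truth perturbed by the
#' magnitudes of `spec$perturbation`, so the pre-optimization deviation
#' from the dictionary is known exactly by construction.
#'
#' @param spec A [fixture_spec()].
#' @return List with `model`, `dictionary`, `ground_truth` (tibble) and
#'   `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, .generate_fixture_impl(spec))
}

.generate_fixture_impl <- function(spec) {
  z <- .ligand_zmatrix(spec$ligand_size)
  truth <- .build_from_zmatrix(z)
  dict <- .fixture_dictionary(z, truth)

  # perturb internal coordinates with seeded signs
  zp <- z
  pm <- function() sample(c(-1, 1), 1)
  for (i in seq_along(zp)) {
    e <- zp[[i]]
    if (is.null(e$r3)) next
    heavy <- e$el != "H"
    if (heavy && spec$perturbation[["bond"]] > 0) {
      zp[[i]]$dist <- e$dist + pm() * spec$perturbation[["bond"]]
    }
    if (heavy && !is.null(e$angle) && spec$perturbation[["angle"]] > 0) {
      zp[[i]]$angle <- e$angle + pm() * spec$perturbation[["angle"]]
    }
    if (!is.null(e$tor_class) && e$tor_class %in% c("rot", "puck") &&
      spec$perturbation[["torsion"]] > 0) {
      zp[[i]]$dih <- e$dih + pm() * spec$perturbation[["torsion"]]
    }
  }
  lig <- .build_from_zmatrix(zp)
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  # the pocket is built around the ground-truth conformation: the crystal
  # environment holds the in-situ geometry, and the perturbed ligand is the
  # mis-restrained deposited model sitting inside it
  truth_xyz <- as.matrix(truth[, c("x", "y", "z")])
  heavy_xyz <- truth_xyz[truth$element != "H", , drop = FALSE]
  centroid <- colMeans(heavy_xyz)

  # pocket tripeptides: middle residue in contact, chain axis tangent
  pocket <- list()
  placed_xyz <- rbind(truth_xyz, lig_xyz)
  tri <- .gly_tripeptide()
  tri_xyz <- as.matrix(tri[, c("x", "y", "z")])
  mid <- tri$seq_id == 2
  for (p in seq_len(spec$pocket_residues)) {
    az <- 2 * pi * (p - 1) / max(1, spec$pocket_residues) + stats::runif(1, 0, 0.5)
    incl <- (if (p %% 2 == 0) 1 else -1) * (0.6 + stats::runif(1, 0, 0.3))
    d_out <- c(cos(az) * cos(incl), sin(az) * cos(incl), sin(incl))
    axis <- tri_xyz[which(tri$seq_id == 3)[1], ] - tri_xyz[which(tri$seq_id == 1)[1], ]
    rot <- .rotation_to(axis, .perp_frame(d_out)$v)
    xr <- tri_xyz %*% t(rot)
    mid_centroid <- colMeans(xr[mid, , drop = FALSE])
    contact <- 3.0 + stats::runif(1, 0, 0.3)
    offset <- 5
    for (iter in 1:6) {
      cand <- xr - matrix(mid_centroid, nrow(xr), 3, byrow = TRUE) +
        matrix(centroid + offset * d_out, nrow(xr), 3, byrow = TRUE)
      md <- .min_interset_dist(cand[mid, , drop = FALSE], truth_xyz)
      if (abs(md - contact) < 0.05) break
      offset <- offset + (contact - md)
    }
    pocket[[p]] <- tibble::tibble(
      name = tri$name, seq_id = tri$seq_id, element = tri$element,
      x = cand[, 1], y = cand[, 2], z = cand[, 3],
      chain = LETTERS[1 + p]
    )
    placed_xyz <- rbind(placed_xyz, cand)
  }

  # waters near the ligand's polar atoms, away from everything placed
  waters <- list()
  polar <- truth[truth$element %in% c("O", "N"), , drop = FALSE]
  for (w in seq_len(spec$n_waters)) {
    anchor <- as.numeric(polar[(w - 1) %% nrow(polar) + 1, c("x", "y", "z")])
    base_dir <- .unit(anchor - centroid)
    fr <- .perp_frame(base_dir)
    pos <- NULL
    for (k in 0:11) {
      th <- 2 * pi * k / 12 + stats::runif(1, 0, 0.1)
      dir <- .unit(base_dir + 0.45 * (cos(th) * fr$v + sin(th) * fr$w))
      cand <- anchor + 2.85 * dir
      if (min(.min_dist_to(matrix(cand, 1, 3), placed_xyz)) > 2.5) {
        pos <- cand
        break
      }
    }
    if (is.null(pos)) pos <- anchor + 2.85 * base_dir
    waters[[w]] <- pos
    placed_xyz <- rbind(placed_xyz, matrix(pos, 1, 3))
  }

  atoms <- dplyr::bind_rows(
    tibble::tibble(
      name = lig$name, comp_id = "LIG", chain_id = "A", seq_id = 1L,
      element = lig$element, x = lig$x, y = lig$y, z = lig$z,
      is_hetatm = TRUE, b_iso = 20, occupancy = 1
    ),
    dplyr::bind_rows(lapply(pocket, function(pp) {
      tibble::tibble(
        name = pp$name, comp_id = "GLY", chain_id = pp$chain,
        seq_id = pp$seq_id, element = pp$element,
        x = pp$x, y = pp$y, z = pp$z,
        is_hetatm = FALSE, b_iso = 15, occupancy = 1
      )
    })),
    if (length(waters)) {
      wxyz <- do.call(rbind, waters)
      tibble::tibble(
        name = "O", comp_id = "HOH", chain_id = "W",
        seq_id = seq_along(waters), element = "O",
        x = wxyz[, 1], y = wxyz[, 2], z = wxyz[, 3],
        is_hetatm = TRUE, b_iso = 25, occupancy = 1
      )
    }
  )
  cell <- spec$cell
  if (is.null(cell)) {
    rng <- apply(atoms[, c("x", "y", "z")], 2, range)
    ext <- rng[2, ] - rng[1, ]
    cell <- c(ext + 40, 90, 90, 90)
    shift <- -rng[1, ] + 20
    atoms$x <- atoms$x + shift[1]
    atoms$y <- atoms$y + shift[2]
    atoms$z <- atoms$z + shift[3]
    truth$x <- truth$x + shift[1]
    truth$y <- truth$y + shift[2]
    truth$z <- truth$z + shift[3]
  }
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(
    atoms, cell,
    spacegroup = spec$space_group,
    resolution = 2.0,
    id = sprintf("fixture_seed%d", spec$seed)
  )
  list(model = model, dictionary = dict, ground_truth = truth, spec = spec)
}
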