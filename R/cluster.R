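# Ligand-cluster construction and chemical completion: select the ligand
# plus every whole residue (model-native or crystallographic symmetry
# image) with any atom inside the cutoff radius, audit the environment,
# terminate dangling bonds and protonate waters.

#' Select a ligand instance
#'
#' @param chain_id,comp_id,seq_id Chain, component code and residue number
#'   identifying one ligand copy.
#' @return Selector list used by the cluster and screening functions.
#' @export
ligand_selector <- function(chain_id, comp_id, seq_id) {
  list(chain_id = chain_id, comp_id = comp_id, seq_id = as.integer(seq_id))
}

.ligand_rows <- function(model, ligand) {
  a <- model$atoms
  hit <- a$chain_id == ligand$chain_id & a$comp_id == ligand$comp_id &
    a$seq_id == ligand$seq_id
  keys <- unique(.res_key(a[hit, , drop = FALSE]))
  if (length(keys) == 0) {
    abort(sprintf(
      "ligand selector %s/%s/%d matches no residue",
      ligand$chain_id, ligand$comp_id, ligand$seq_id
    ))
  }
  if (length(keys) > 1) {
    abort(sprintf(
      "ligand selector %s/%s/%d is ambiguous (%d residues)",
      ligand$chain_id, ligand$comp_id, ligand$seq_id, length(keys)
    ))
  }
  which(hit)
}

.apply_symop_xyz <- function(xyz, model, op_index, shift) {
  op <- model$symops[[op_index]]
  fr <- fractionalize(xyz, model$cell)
  fr <- fr %*% t(op$rot) +
    matrix(op$trans + shift, nrow(fr), 3, byrow = TRUE)
  orthogonalize(fr, model$cell)
}

.min_dist_to <- function(xyz, ref_xyz) {
  mind <- rep(Inf, nrow(xyz))
  for (s in seq_len(nrow(ref_xyz))) {
    d2 <- (xyz[, 1] - ref_xyz[s, 1])^2 + (xyz[, 2] - ref_xyz[s, 2])^2 +
      (xyz[, 3] - ref_xyz[s, 3])^2
    mind <- pmin(mind, d2)
  }
  sqrt(mind)
}

# All residue copies (native + symmetry image) with >= 1 atom within
# `radius` of the ligand. Returns a list of copies, each a list with the
# whole-residue atom tibble (positions transformed), operator and shift.
.residue_copies_within <- function(model, lig_idx, radius, symmetry = TRUE) {
  a <- model$atoms
  key <- .res_key(a)
  lig_key <- key[lig_idx[1]]
  lig_xyz <- as.matrix(a[lig_idx, c("x", "y", "z")])
  copies <- list()

  other <- which(key != lig_key)
  if (length(other)) {
    d <- .min_dist_to(as.matrix(a[other, c("x", "y", "z")]), lig_xyz)
    near_keys <- unique(key[other][d <= radius + 1e-9])
    for (k in near_keys) {
      rows <- a[key == k, , drop = FALSE]
      rows$source_serial <- rows$serial
      rows$operator <- 1L
      rows$shift_a <- 0L; rows$shift_b <- 0L; rows$shift_c <- 0L
      copies[[length(copies) + 1L]] <- list(
        atoms = rows, key = k, operator = 1L, shift = c(0L, 0L, 0L)
      )
    }
  }
  if (symmetry && length(model$symops) >= 1) {
    img <- symmetry_images_within(model, a$serial[lig_idx], radius)
    if (nrow(img)) {
      src_key <- key[match(img$source_serial, a$serial)]
      tagged <- paste(src_key, img$operator, img$shift_a, img$shift_b, img$shift_c)
      for (tg in unique(tagged)) {
        one <- img[tagged == tg, , drop = FALSE][1, ]
        k <- src_key[tagged == tg][1]
        rows <- a[key == k, , drop = FALSE]
        xyz <- .apply_symop_xyz(
          as.matrix(rows[, c("x", "y", "z")]), model,
          one$operator, c(one$shift_a, one$shift_b, one$shift_c)
        )
        rows$source_serial <- rows$serial
        rows$operator <- one$operator
        rows$shift_a <- one$shift_a; rows$shift_b <- one$shift_b
        rows$shift_c <- one$shift_c
        rows$x <- xyz[, 1]; rows$y <- xyz[, 2]; rows$z <- xyz[, 3]
        copies[[length(copies) + 1L]] <- list(
          atoms = rows, key = k, operator = one$operator,
          shift = c(one$shift_a, one$shift_b, one$shift_c)
        )
      }
    }
  }
  copies
}

#' Build the ligand cluster
#'
#' The cluster is the ligand plus every residue or water -- including
#' crystallographic symmetry images -- with at least one atom within
#' `radius` of any ligand atom, each copied in its entirety. Covalent bonds
#' leaving the cluster (typically peptide bonds of pocket residues) are
#' recorded as cut bonds for later capping.
#'
#' @param model An `xtal_model`.
#' @param ligand A [ligand_selector()].
#' @param radius Cutoff radius in Angstrom; 3.5 by default, covering
#'   hydrogen-bond and van der Waals contact distance while keeping the
#'   cluster small.
#' @param symmetry Include crystallographic symmetry images (default TRUE).
#' @param connectivity Optional precomputed [infer_connectivity()] table.
#' @param dictionaries Optional named list of restraint dictionaries used
#'   for connectivity.
#' @return Object of class `ligand_cluster`: `atoms` (tibble with `role`
#'   ligand/environment and provenance columns `source_serial`, `operator`,
#'   `shift_a/b/c`), `cut_bonds`, `radius`, `ligand`, `cell`, `model_id`.
#' @export
build_ligand_cluster <- function(model, ligand, radius = 3.5, symmetry = TRUE,
                                 connectivity = NULL, dictionaries = NULL) {
  stopifnot(inherits(model, "xtal_model"))
  if (radius <= 0) abort("radius must be positive")
  a <- model$atoms
  key <- .res_key(a)
  lig_idx <- .ligand_rows(model, ligand)
  lig_key <- key[lig_idx[1]]
  if (is.null(connectivity)) connectivity <- infer_connectivity(model, dictionaries)

  lig <- a[lig_idx, , drop = FALSE]
  lig$source_serial <- lig$serial
  lig$operator <- 1L
  lig$shift_a <- 0L; lig$shift_b <- 0L; lig$shift_c <- 0L
  lig$role <- "ligand"

  copies <- .residue_copies_within(model, lig_idx, radius, symmetry)
  env <- lapply(copies, function(cp) {
    cp$atoms$role <- "environment"
    cp$atoms
  })
  atoms <- dplyr::bind_rows(c(list(lig), env))
  atoms$serial <- seq_len(nrow(atoms))
  atoms$link_serial <- NA_integer_

  # cut bonds: model-connectivity edges leaving each residue copy
  copy_tags <- c(
    paste(lig_key, 1L, 0L, 0L, 0L),
    vapply(copies, function(cp) {
      paste(cp$key, cp$operator, cp$shift[1], cp$shift[2], cp$shift[3])
    }, character(1))
  )
  atom_tag <- paste(
    .res_key(atoms), atoms$operator, atoms$shift_a, atoms$shift_b, atoms$shift_c
  )
  cut <- list()
  ekey1 <- key[match(connectivity$serial1, a$serial)]
  ekey2 <- key[match(connectivity$serial2, a$serial)]
  all_copies <- c(
    list(list(atoms = lig, key = lig_key, operator = 1L, shift = c(0L, 0L, 0L))),
    copies
  )
  for (ci in seq_along(all_copies)) {
    cp <- all_copies[[ci]]
    leaves <- which(xor(ekey1 == cp$key, ekey2 == cp$key))
    for (e in leaves) {
      inside_src <- if (ekey1[e] == cp$key) connectivity$serial1[e] else connectivity$serial2[e]
      outside_src <- if (ekey1[e] == cp$key) connectivity$serial2[e] else connectivity$serial1[e]
      partner_key <- key[match(outside_src, a$serial)]
      partner_tag <- paste(
        partner_key, cp$operator, cp$shift[1], cp$shift[2], cp$shift[3]
      )
      if (partner_tag %in% copy_tags) next # partner copy is in the cluster
      in_row <- which(
        atoms$source_serial == inside_src & atom_tag == copy_tags[ci]
      )[1]
      oxyz <- as.numeric(a[match(outside_src, a$serial), c("x", "y", "z")])
      if (cp$operator != 1L || any(cp$shift != 0L)) {
        oxyz <- as.numeric(.apply_symop_xyz(
          matrix(oxyz, 1, 3), model, cp$operator, cp$shift
        ))
      }
      cut[[length(cut) + 1L]] <- tibble::tibble(
        inside_serial = atoms$serial[in_row],
        inside_name = atoms$name[in_row],
        inside_element = atoms$element[in_row],
        outside_source_serial = outside_src,
        outside_name = a$name[match(outside_src, a$serial)],
        outside_element = a$element[match(outside_src, a$serial)],
        outside_x = oxyz[1], outside_y = oxyz[2], outside_z = oxyz[3]
      )
    }
  }
  cut_bonds <- if (length(cut)) dplyr::bind_rows(cut) else tibble::tibble(
    inside_serial = integer(), inside_name = character(),
    inside_element = character(), outside_source_serial = integer(),
    outside_name = character(), outside_element = character(),
    outside_x = numeric(), outside_y = numeric(), outside_z = numeric()
  )
  structure(
    list(
      atoms = tibble::as_tibble(atoms), cut_bonds = cut_bonds,
      radius = radius, ligand = ligand, cell = model$cell,
      spacegroup = model$spacegroup, model_id = model$id,
      capped = FALSE
    ),
    class = "ligand_cluster"
  )
}

#' @export
print.ligand_cluster <- function(x, ...) {
  a <- x$atoms
  n_img <- length(unique(paste(
    .res_key(a), a$operator, a$shift_a, a$shift_b, a$shift_c
  )[a$role == "environment" & (a$operator != 1 | a$shift_a != 0 |
    a$shift_b != 0 | a$shift_c != 0)]))
  cat(sprintf(
    paste0(
      "<ligand_cluster %s/%s/%d @ %.1f Å: %d atoms ",
      "(%d ligand, %d environment, %d caps, %d protons), ",
      "%d symmetry-image residues, %d cut bonds>\n"
    ),
    x$ligand$chain_id, x$ligand$comp_id, x$ligand$seq_id, x$radius,
    nrow(a), sum(a$role == "ligand"), sum(a$role == "environment"),
    sum(a$role == "cap"), sum(a$role == "proton"),
    n_img, nrow(x$cut_bonds)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ligand_cluster <- function(x, ...) x$atoms

# --- environment validation ------------------------------------------------

.expected_heavy_atoms <- function(comp_id, kind, dictionaries) {
  d <- dictionaries[[comp_id]]
  if (!is.null(d)) {
    return(d$atoms$name[!d$atoms$element %in% c("H", "D")])
  }
  if (kind == "water") return("O")
  if (comp_id %in% names(.aa_heavy_atoms)) return(.aa_heavy_atoms[[comp_id]])
  NULL
}

#' Audit the environment of a ligand instance
#'
#' Applies the cluster-suitability rules: no other ligands, metals or
#' alternate conformations within 5.5 Angstrom of the ligand (measured on
#' the input model, before any hydrogen addition), and no missing atoms
#' within 3.5 Angstrom (a residue copy is incomplete when heavy atoms
#' declared by its dictionary -- or the standard amino-acid roster -- are
#' absent). Symmetry images participate in all checks.
#'
#' @inheritParams build_ligand_cluster
#' @param check_radius Radius for the ligand/metal/altloc checks (5.5).
#' @param missing_radius Radius for the missing-atom check (3.5).
#' @return Object of class `environment_report` with logical flags, an
#'   `offenders` tibble naming each offender, `unknown_components`, and
#'   `clean` (the conjunction of the four checks).
#' @export
validate_environment <- function(model, ligand, connectivity = NULL,
                                 dictionaries = NULL, check_radius = 5.5,
                                 missing_radius = 3.5) {
  stopifnot(inherits(model, "xtal_model"))
  a <- model$atoms
  key <- .res_key(a)
  lig_idx <- .ligand_rows(model, ligand)
  lig_key <- key[lig_idx[1]]
  lig_xyz <- as.matrix(a[lig_idx, c("x", "y", "z")])

  copies <- .residue_copies_within(model, lig_idx, check_radius, symmetry = TRUE)
  empty_ctx <- a[0, , drop = FALSE]
  empty_ctx$mind <- numeric()
  empty_ctx$is_image <- logical()
  ctx <- dplyr::bind_rows(c(list(empty_ctx), lapply(copies, function(cp) {
    at <- cp$atoms
    at$mind <- .min_dist_to(as.matrix(at[, c("x", "y", "z")]), lig_xyz)
    at$is_image <- cp$operator != 1L || any(cp$shift != 0L)
    at
  })))
  offenders <- list()
  register <- function(check, rows) {
    if (nrow(rows) == 0) return(FALSE)
    offenders[[length(offenders) + 1L]] <<- tibble::tibble(
      check = check,
      chain_id = rows$chain_id, comp_id = rows$comp_id, seq_id = rows$seq_id,
      atom = rows$name, distance = rows$mind,
      symmetry_image = rows$is_image
    )
    TRUE
  }
  near <- ctx[ctx$mind <= check_radius + 1e-9, , drop = FALSE]
  other_ligand <- register(
    "other_ligand_within_5p5",
    dplyr::distinct(
      near[near$kind == "ligand", , drop = FALSE],
      .data$chain_id, .data$comp_id, .data$seq_id, .data$is_image,
      .keep_all = TRUE
    )
  )
  metal <- register(
    "metal_within_5p5",
    near[is_metal_element(near$element), , drop = FALSE]
  )
  lig_alt <- a[lig_idx, , drop = FALSE][a$altloc[lig_idx] != "", , drop = FALSE]
  if (nrow(lig_alt)) {
    lig_alt$mind <- 0
    lig_alt$is_image <- FALSE
  }
  altloc <- register(
    "altloc_within_5p5",
    dplyr::bind_rows(
      near[near$altloc != "", , drop = FALSE],
      lig_alt
    )
  )

  # missing atoms within 3.5 A
  missing <- FALSE
  unknown <- character()
  for (cp in copies) {
    at <- cp$atoms
    mind <- .min_dist_to(as.matrix(at[, c("x", "y", "z")]), lig_xyz)
    if (min(mind) > missing_radius + 1e-9) next
    expected <- .expected_heavy_atoms(at$comp_id[1], at$kind[1], dictionaries)
    if (is.null(expected)) {
      unknown <- union(unknown, at$comp_id[1])
      next
    }
    absent <- setdiff(expected, at$name)
    if (length(absent)) {
      missing <- TRUE
      offenders[[length(offenders) + 1L]] <- tibble::tibble(
        check = "missing_atoms_within_3p5",
        chain_id = at$chain_id[1], comp_id = at$comp_id[1],
        seq_id = at$seq_id[1], atom = absent, distance = min(mind),
        symmetry_image = cp$operator != 1L || any(cp$shift != 0L)
      )
    }
  }
  offenders <- if (length(offenders)) dplyr::bind_rows(offenders) else tibble::tibble(
    check = character(), chain_id = character(), comp_id = character(),
    seq_id = integer(), atom = character(), distance = numeric(),
    symmetry_image = logical()
  )
  structure(
    list(
      other_ligand_within_5p5 = other_ligand,
      metal_within_5p5 = metal,
      altloc_within_5p5 = altloc,
      missing_atoms_within_3p5 = missing,
      clean = !(other_ligand || metal || altloc || missing),
      offenders = offenders,
      unknown_components = unknown,
      ligand = ligand
    ),
    class = "environment_report"
  )
}

#' @export
print.environment_report <- function(x, ...) {
  cat(sprintf(
    "<environment_report %s/%s/%d: %s>\n",
    x$ligand$chain_id, x$ligand$comp_id, x$ligand$seq_id,
    if (x$clean) "clean" else "NOT clean"
  ))
  flags <- c(
    "other_ligand_within_5p5", "metal_within_5p5",
    "altloc_within_5p5", "missing_atoms_within_3p5"
  )
  for (f in flags) cat(sprintf("  %-26s %s\n", f, if (x[[f]]) "FAIL" else "ok"))
  if (length(x$unknown_components)) {
    cat("  unknown components:", paste(x$unknown_components, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.environment_report <- function(x, ...) {
  tibble::tibble(
    other_ligand_within_5p5 = x$other_ligand_within_5p5,
    metal_within_5p5 = x$metal_within_5p5,
    altloc_within_5p5 = x$altloc_within_5p5,
    missing_atoms_within_3p5 = x$missing_atoms_within_3p5,
    clean = x$clean,
    n_unknown_components = length(x$unknown_components)
  )
}

#' @exportS3Method generics::tidy
tidy.environment_report <- function(x, ...) x$offenders

# --- capping ---------------------------------------------------------------

.hx_distance <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-9) abort("degenerate zero-length vector")
  v / n
}

.perp_frame <- function(u) {
  ref <- diag(3)[, which.min(abs(u))]
  v <- .unit(.cross(u, ref))
  w <- .cross(u, v)
  list(v = v, w = w)
}

.new_cluster_atom <- function(cluster, name, element, xyz, role, link_serial,
                              chain_id, comp_id, seq_id) {
  tibble::tibble(
    serial = max(cluster$atoms$serial) + 1L, name = name, altloc = "",
    comp_id = comp_id, chain_id = chain_id, seq_id = seq_id, icode = "",
    element = element, x = xyz[1], y = xyz[2], z = xyz[3],
    occupancy = 1, b_iso = 0, is_hetatm = TRUE,
    kind = "other", is_hydrogen = element %in% c("H", "D"),
    source_serial = NA_integer_, operator = 1L,
    shift_a = 0L, shift_b = 0L, shift_c = 0L,
    role = role, link_serial = link_serial
  )
}

#' Terminate dangling bonds of a cluster
#'
#' Neutral mode (default) replaces the lost bond partner of every cut bond
#' with a hydrogen link atom placed along the former bond vector at the
#' standard element-H distance (C-H 1.09, N-H 1.01, O-H 0.96 Angstrom).
#' Zwitterion mode instead completes backbone cuts as charged termini: a
#' cut C(=O)-N bond gains an OXT completing a carboxylate on the inside
#' carbon, a cut N-C bond gains hydrogens completing an ammonium nitrogen;
#' non-backbone cuts still receive a hydrogen link atom.
#'
#' @param cluster A [build_ligand_cluster()] result.
#' @param mode `"neutral"` or `"zwitterion"`.
#' @return The cluster with cap atoms appended (`role == "cap"`) and
#'   `cut_bonds` annotated with the capping atom serial.
#' @export
cap_dangling_bonds <- function(cluster, mode = c("neutral", "zwitterion")) {
  stopifnot(inherits(cluster, "ligand_cluster"))
  mode <- match.arg(mode)
  if (isTRUE(cluster$capped)) abort("cluster is already capped")
  cb <- cluster$cut_bonds
  cb$cap_serial <- NA_integer_
  if (nrow(cb) == 0) {
    cluster$capped <- TRUE
    cluster$cut_bonds <- cb
    return(cluster)
  }
  a <- cluster$atoms
  n_cap <- 0L
  for (i in seq_len(nrow(cb))) {
    in_row <- match(cb$inside_serial[i], cluster$atoms$serial)
    if (cluster$atoms$role[in_row] == "cap") {
      abort("internal consistency error: cut bond points at a cap atom")
    }
    p_in <- as.numeric(cluster$atoms[in_row, c("x", "y", "z")])
    p_out <- c(cb$outside_x[i], cb$outside_y[i], cb$outside_z[i])
    el <- cluster$atoms$element[in_row]
    placed <- FALSE
    if (mode == "zwitterion") {
      res_rows <- which(
        .res_key(cluster$atoms) == .res_key(cluster$atoms[in_row, , drop = FALSE]) &
          cluster$atoms$operator == cluster$atoms$operator[in_row] &
          cluster$atoms$shift_a == cluster$atoms$shift_a[in_row] &
          cluster$atoms$shift_b == cluster$atoms$shift_b[in_row] &
          cluster$atoms$shift_c == cluster$atoms$shift_c[in_row]
      )
      res <- cluster$atoms[res_rows, , drop = FALSE]
      at_in <- cluster$atoms[in_row, , drop = FALSE]
      if (at_in$name == "C" && cb$outside_name[i] == "N" &&
        all(c("CA", "O") %in% res$name)) {
        ca <- as.numeric(res[match("CA", res$name), c("x", "y", "z")])
        o <- as.numeric(res[match("O", res$name), c("x", "y", "z")])
        dir <- -(.unit(ca - p_in) + .unit(o - p_in))
        dir <- .unit(dir)
        new <- .new_cluster_atom(
          cluster, "OXT", "O", p_in + 1.25 * dir, "cap",
          at_in$serial, at_in$chain_id, at_in$comp_id, at_in$seq_id
        )
        cluster$atoms <- dplyr::bind_rows(cluster$atoms, new)
        cb$cap_serial[i] <- new$serial
        placed <- TRUE
      } else if (at_in$name == "N" && cb$outside_name[i] == "C" &&
        "CA" %in% res$name) {
        ca <- as.numeric(res[match("CA", res$name), c("x", "y", "z")])
        u <- .unit(ca - p_in)
        fr <- .perp_frame(u)
        ang <- 109.5 * pi / 180
        n_h_existing <- sum(res$is_hydrogen &
          .min_dist_to(as.matrix(res[, c("x", "y", "z")]), matrix(p_in, 1, 3)) < 1.3)
        need <- max(0L, 3L - n_h_existing)
        for (j in seq_len(need)) {
          th <- 2 * pi * (j - 1) / 3
          dir <- cos(ang) * u + sin(ang) * (cos(th) * fr$v + sin(th) * fr$w)
          new <- .new_cluster_atom(
            cluster, sprintf("HT%d", j), "H", p_in + 1.01 * dir, "cap",
            at_in$serial, at_in$chain_id, at_in$comp_id, at_in$seq_id
          )
          cluster$atoms <- dplyr::bind_rows(cluster$atoms, new)
          if (is.na(cb$cap_serial[i])) cb$cap_serial[i] <- new$serial
        }
        placed <- need > 0
      }
    }
    if (!placed) {
      d <- unname(.hx_distance[el])
      if (is.na(d)) d <- 1.0
      dir <- .unit(p_out - p_in)
      n_cap <- n_cap + 1L
      new <- .new_cluster_atom(
        cluster, sprintf("HL%d", sum(cluster$atoms$role == "cap") + 1L), "H",
        p_in + d * dir, "cap", cluster$atoms$serial[in_row], "X", "CAP", 1L
      )
      cluster$atoms <- dplyr::bind_rows(cluster$atoms, new)
      cb$cap_serial[i] <- new$serial
    }
  }
  cluster$cut_bonds <- cb
  cluster$capped <- TRUE
  cluster
}

# --- water protonation -----------------------------------------------------

.water_h_geometry <- list(oh = 0.96, hoh = 104.5)

.place_water_h <- function(o_xyz, acceptors, existing_h = NULL) {
  half <- .water_h_geometry$hoh / 2 * pi / 180
  full <- .water_h_geometry$hoh * pi / 180
  oh <- .water_h_geometry$oh
  if (!is.null(existing_h)) {
    d1 <- .unit(existing_h - o_xyz)
    if (nrow(acceptors) >= 1) {
      da <- .unit(as.numeric(acceptors[1, ]) - o_xyz)
      p <- da - sum(da * d1) * d1
      p <- if (.vnorm(p) > 1e-6) .unit(p) else .perp_frame(d1)$v
    } else {
      p <- .perp_frame(d1)$v
    }
    h2 <- cos(full) * d1 + sin(full) * p
    return(list(o_xyz + oh * h2))
  }
  if (nrow(acceptors) >= 2) {
    d1 <- .unit(as.numeric(acceptors[1, ]) - o_xyz)
    d2 <- .unit(as.numeric(acceptors[2, ]) - o_xyz)
    b <- d1 + d2
    if (.vnorm(b) < 1e-6) {
      b <- d1
      p <- .perp_frame(d1)$v
    } else {
      b <- .unit(b)
      p <- d2 - sum(d2 * b) * b
      p <- if (.vnorm(p) > 1e-6) .unit(p) else .perp_frame(b)$v
    }
    dirs <- list(cos(half) * b + sin(half) * p, cos(half) * b - sin(half) * p)
  } else if (nrow(acceptors) == 1) {
    d1 <- .unit(as.numeric(acceptors[1, ]) - o_xyz)
    p <- .perp_frame(d1)$v
    dirs <- list(d1, cos(full) * d1 + sin(full) * p)
  } else {
    dirs <- list(
      c(sin(half), 0, cos(half)),
      c(-sin(half), 0, cos(half))
    )
  }
  lapply(dirs, function(d) o_xyz + oh * d)
}

#' Protonate cluster waters
#'
#' Crystallographic waters are usually modeled as bare O atoms; each water
#' in the cluster environment is completed to O-H distances of 0.96
#' Angstrom and an H-O-H angle of 104.5 degrees. Hydrogens point towards
#' the nearest two acceptor atoms (O or N within 3.5 Angstrom), falling
#' back to a canonical frame when no acceptor exists. The operation is
#' deterministic and idempotent; a water already carrying two hydrogens is
#' left untouched and more than two is an error.
#'
#' @param cluster A [ligand_cluster()] (typically already capped).
#' @return The cluster with added hydrogens (`role == "proton"`).
#' @export
protonate_waters <- function(cluster) {
  stopifnot(inherits(cluster, "ligand_cluster"))
  a <- cluster$atoms
  copy_tag <- paste(.res_key(a), a$operator, a$shift_a, a$shift_b, a$shift_c)
  water_tags <- unique(copy_tag[a$kind == "water" & a$role %in% c("environment", "proton")])
  for (tg in water_tags) {
    rows <- which(copy_tag == tg & a$role %in% c("environment", "proton"))
    res <- cluster$atoms[rows, , drop = FALSE]
    o_row <- rows[!res$is_hydrogen][1]
    if (is.na(o_row)) next
    h_rows <- rows[res$is_hydrogen]
    if (length(h_rows) > 2) {
      abort(sprintf(
        "water %s/%d carries %d hydrogens",
        res$chain_id[1], res$seq_id[1], length(h_rows)
      ))
    }
    if (length(h_rows) == 2) next
    o_xyz <- as.numeric(cluster$atoms[o_row, c("x", "y", "z")])
    others <- cluster$atoms[-rows, , drop = FALSE]
    acc <- others[others$element %in% c("O", "N") & !others$is_hydrogen, , drop = FALSE]
    if (nrow(acc)) {
      dd <- .min_dist_to(as.matrix(acc[, c("x", "y", "z")]), matrix(o_xyz, 1, 3))
      acc <- acc[order(dd), , drop = FALSE][dd[order(dd)] <= 3.5, , drop = FALSE]
    }
    acc_xyz <- as.matrix(acc[, c("x", "y", "z")])
    existing <- if (length(h_rows) == 1) {
      as.numeric(cluster$atoms[h_rows, c("x", "y", "z")])
    } else {
      NULL
    }
    new_pos <- .place_water_h(o_xyz, acc_xyz, existing)
    used <- cluster$atoms$name[copy_tag == tg]
    for (np in new_pos) {
      nm <- setdiff(c("H1", "H2"), used)[1]
      used <- c(used, nm)
      at_o <- cluster$atoms[o_row, , drop = FALSE]
      new <- .new_cluster_atom(
        cluster, nm, "H", np, "proton", at_o$serial,
        at_o$chain_id, at_o$comp_id, at_o$seq_id
      )
      # protons belong to the water residue copy: keep provenance columns
      new$operator <- at_o$operator
      new$shift_a <- at_o$shift_a; new$shift_b <- at_o$shift_b
      new$shift_c <- at_o$shift_c
      new$kind <- "water"
      new$icode <- at_o$icode
      cluster$atoms <- dplyr::bind_rows(cluster$atoms, new)
      a <- cluster$atoms
      copy_tag <- paste(.res_key(a), a$operator, a$shift_a, a$shift_b, a$shift_c)
    }
  }
  cluster
}

# --- export ----------------------------------------------------------------

#' Convert a cluster to a standalone structure model
#'
#' @param cluster A `ligand_cluster`.
#' @return An `xtal_model` in space group P 1 with the original cell.
#' @export
cluster_to_model <- function(cluster) {
  a <- cluster$atoms
  cols <- c(
    "serial", "name", "altloc", "comp_id", "chain_id", "seq_id", "icode",
    "element", "x", "y", "z", "occupancy", "b_iso", "is_hetatm"
  )
  structure_model(
    a[, cols], cluster$cell,
    spacegroup = "P 1",
    id = sprintf("%s_cluster", cluster$model_id)
  )
}

#' Write a cluster to a PDB file with provenance remarks
#'
#' Cap and water hydrogens are distinguishable by their residue/chain
#' bookkeeping; a REMARK 300 block lists the selection radius, the
#' symmetry provenance of image residues and every cut bond.
#'
#' @param cluster A `ligand_cluster`.
#' @param file Output path.
#' @return The written lines, invisibly.
#' @export
write_cluster_pdb <- function(cluster, file) {
  a <- cluster$atoms
  rem <- c(
    sprintf(
      "REMARK 300 LIGAND CLUSTER %s/%s/%d RADIUS %.2f",
      cluster$ligand$chain_id, cluster$ligand$comp_id,
      cluster$ligand$seq_id, cluster$radius
    )
  )
  img <- a[a$operator != 1 | a$shift_a != 0 | a$shift_b != 0 | a$shift_c != 0, ]
  if (nrow(img)) {
    tags <- unique(paste(
      img$chain_id, img$comp_id, img$seq_id, img$operator,
      img$shift_a, img$shift_b, img$shift_c
    ))
    rem <- c(rem, vapply(tags, function(tg) {
      sprintf("REMARK 300 SYMMETRY IMAGE %s", tg)
    }, character(1), USE.NAMES = FALSE))
  }
  cb <- cluster$cut_bonds
  if (nrow(cb)) {
    rem <- c(rem, vapply(seq_len(nrow(cb)), function(i) {
      sprintf(
        "REMARK 300 CUT BOND %s(%d) -> %s(model %d)",
        cb$inside_name[i], cb$inside_serial[i], cb$outside_name[i],
        cb$outside_source_serial[i]
      )
    }, character(1)))
  }
  body <- write_structure(cluster_to_model(cluster), "pdb")
  txt <- c(body[1], rem, body[-1])
  writeLines(txt, file)
  invisible(txt)
}
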