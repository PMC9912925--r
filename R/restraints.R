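# Restraint dictionaries: typed bond/angle/torsion/plane/chirality
# restraints with targets, e.s.d.s, torsion periodicity and optional
# aperiodic alternative targets; monomer-library-style CIF read/write; and
# the in-situ target generation that defines QMR restraints.

.default_esd <- c(bond = 0.02, angle = 2, torsion = 30)

.empty_torsions <- function() {
  tibble::tibble(
    id = character(), atom1 = character(), atom2 = character(),
    atom3 = character(), atom4 = character(), target = numeric(),
    esd = numeric(), period = integer(), alternatives = list()
  )
}

#' Build a ligand restraint dictionary
#'
#' @param comp_id Component code, e.g. `"BER"`.
#' @param atoms Tibble with `name`, `element` (the atom roster).
#' @param bonds Tibble with `atom1`, `atom2`, `target` (Angstrom), `esd`;
#'   optional `type`.
#' @param angles Tibble with `atom1..atom3`, `target` (degrees in (0,180)),
#'   `esd`.
#' @param torsions Tibble with `id`, `atom1..atom4`, `target` (degrees),
#'   `esd`, `period` (positive integer) and an `alternatives` list column
#'   of aperiodic alternative targets (NULL for none). Targets are
#'   normalised to (-180, 180] on construction.
#' @param planes Tibble with `plane_id`, `atom`, `esd` (one row per plane
#'   member; every plane must have at least 4 atoms).
#' @param chirals Tibble with `id`, `center`, `atom1..atom3`, `sign`
#'   (`"positive"`, `"negative"` or `"both"`).
#' @param formal_charge Integer total formal charge.
#' @return Object of class `restraint_dictionary`.
#' @export
restraint_dictionary <- function(comp_id, atoms,
                                 bonds = NULL, angles = NULL, torsions = NULL,
                                 planes = NULL, chirals = NULL,
                                 formal_charge = 0L) {
  atoms <- tibble::as_tibble(atoms)
  if (anyDuplicated(atoms$name)) abort("atom roster names must be unique")
  bonds <- if (is.null(bonds)) {
    tibble::tibble(
      atom1 = character(), atom2 = character(),
      target = numeric(), esd = numeric(), type = character()
    )
  } else {
    tibble::as_tibble(bonds)
  }
  if (!"type" %in% names(bonds)) bonds$type <- rep("single", nrow(bonds))
  angles <- if (is.null(angles)) {
    tibble::tibble(
      atom1 = character(), atom2 = character(), atom3 = character(),
      target = numeric(), esd = numeric()
    )
  } else {
    tibble::as_tibble(angles)
  }
  torsions <- if (is.null(torsions)) .empty_torsions() else tibble::as_tibble(torsions)
  if (nrow(torsions)) {
    if (!"id" %in% names(torsions)) torsions$id <- sprintf("tor_%d", seq_len(nrow(torsions)))
    if (!"period" %in% names(torsions)) torsions$period <- 1L
    torsions$period <- as.integer(torsions$period)
    torsions$period[is.na(torsions$period)] <- 1L
    if (any(torsions$period < 1)) abort("torsion periodicity must be >= 1")
    if (!"alternatives" %in% names(torsions)) torsions$alternatives <- vector("list", nrow(torsions))
    torsions$target <- wrap_angle(torsions$target)
    torsions$alternatives <- lapply(torsions$alternatives, function(a) {
      if (is.null(a) || !length(a)) NULL else wrap_angle(a)
    })
  }
  planes <- if (is.null(planes)) {
    tibble::tibble(plane_id = character(), atom = character(), esd = numeric())
  } else {
    tibble::as_tibble(planes)
  }
  if (nrow(planes)) {
    sz <- table(planes$plane_id)
    if (any(sz < 4)) abort("every plane restraint needs at least 4 atoms")
  }
  chirals <- if (is.null(chirals)) {
    tibble::tibble(
      id = character(), center = character(), atom1 = character(),
      atom2 = character(), atom3 = character(), sign = character()
    )
  } else {
    tibble::as_tibble(chirals)
  }

  fix_esd <- function(df, kind) {
    if (!nrow(df)) {
      df$esd <- numeric(0)
      return(df)
    }
    bad <- is.na(df$esd) | df$esd <= 0
    if (any(bad)) {
      warn(sprintf(
        "%d %s restraint(s) lacked an e.s.d.; using the typical %s",
        sum(bad), kind,
        paste0(.default_esd[[kind]], if (kind == "bond") " A" else " deg")
      ))
      df$esd[bad] <- .default_esd[[kind]]
    }
    df
  }
  bonds <- fix_esd(bonds, "bond")
  angles <- fix_esd(angles, "angle")
  torsions <- fix_esd(torsions, "torsion")

  referenced <- unique(c(
    bonds$atom1, bonds$atom2, angles$atom1, angles$atom2, angles$atom3,
    torsions$atom1, torsions$atom2, torsions$atom3, torsions$atom4,
    planes$atom, chirals$center, chirals$atom1, chirals$atom2, chirals$atom3
  ))
  unknown <- setdiff(referenced, atoms$name)
  if (length(unknown)) {
    abort(sprintf(
      "restraints reference atoms absent from the roster: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  if (nrow(bonds) && any(bonds$target <= 0)) abort("bond targets must be positive")
  if (nrow(angles) && any(angles$target <= 0 | angles$target >= 180)) {
    abort("angle targets must lie in (0, 180)")
  }
  structure(
    list(
      comp_id = comp_id, atoms = atoms, bonds = bonds, angles = angles,
      torsions = torsions, planes = planes, chirals = chirals,
      formal_charge = as.integer(formal_charge)
    ),
    class = "restraint_dictionary"
  )
}

#' @export
print.restraint_dictionary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<restraint_dictionary %s: %d atoms, %d bonds, %d angles, ",
      "%d torsions, %d planes, %d chirals, charge %+d>\n"
    ),
    x$comp_id, nrow(x$atoms), nrow(x$bonds), nrow(x$angles),
    nrow(x$torsions), length(unique(x$planes$plane_id)), nrow(x$chirals),
    x$formal_charge
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.restraint_dictionary <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      kind = "bond",
      atoms = paste(x$bonds$atom1, x$bonds$atom2, sep = "—"),
      target = x$bonds$target, esd = x$bonds$esd, period = NA_integer_
    ),
    tibble::tibble(
      kind = "angle",
      atoms = paste(x$angles$atom1, x$angles$atom2, x$angles$atom3, sep = "—"),
      target = x$angles$target, esd = x$angles$esd, period = NA_integer_
    ),
    tibble::tibble(
      kind = "torsion",
      atoms = paste(x$torsions$atom1, x$torsions$atom2, x$torsions$atom3,
        x$torsions$atom4,
        sep = "—"
      ),
      target = x$torsions$target, esd = x$torsions$esd,
      period = x$torsions$period
    )
  )
}

# --- CIF I/O ---------------------------------------------------------------

#' Parse a monomer-library restraint dictionary from CIF text
#'
#' Reads the `_chem_comp_atom`, `_chem_comp_bond`, `_chem_comp_angle`,
#' `_chem_comp_tor`, `_chem_comp_plane_atom` and `_chem_comp_chir`
#' categories. A missing torsion period column defaults to 1. Aperiodic
#' alternative torsion targets are read from the namespaced extension loop
#' `_qmrestraints_tor_alt` (`tor_id`, `value_angle`), which the standard
#' format lacks.
#'
#' @param text CIF text (scalar or lines) or a file path.
#' @return A [restraint_dictionary()].
#' @export
parse_restraint_cif <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  blocks <- cif_parse(text)
  blk <- NULL
  for (b in blocks) {
    if (!is.null(cif_find_loop(b, "_chem_comp_atom.atom_id")) ||
      "_chem_comp.id" %in% names(b$items)) {
      blk <- b
    }
  }
  if (is.null(blk)) abort("no chem_comp data block found in restraint CIF")
  item <- function(tag) {
    if (tag %in% names(blk$items)) blk$items[[tag]] else NA_character_
  }
  comp_id <- cif_chr(item("_chem_comp.id"))
  at <- cif_find_loop(blk, "_chem_comp_atom.atom_id")
  if (is.null(at)) abort("restraint CIF lacks a _chem_comp_atom loop")
  if (is.na(comp_id)) comp_id <- cif_chr(at[["_chem_comp_atom.comp_id"]][1])
  charge <- cif_num(item("_chem_comp.formal_charge"))
  atoms <- tibble::tibble(
    name = cif_chr(at[["_chem_comp_atom.atom_id"]]),
    element = toupper(cif_chr(at[["_chem_comp_atom.type_symbol"]]))
  )
  if (!is.null(at[["_chem_comp_atom.charge"]]) && is.na(charge)) {
    charge <- sum(cif_num(at[["_chem_comp_atom.charge"]]), na.rm = TRUE)
  }
  if (is.na(charge)) charge <- 0

  bo <- cif_find_loop(blk, "_chem_comp_bond.atom_id_1")
  bonds <- if (!is.null(bo)) {
    tibble::tibble(
      atom1 = cif_chr(bo[["_chem_comp_bond.atom_id_1"]]),
      atom2 = cif_chr(bo[["_chem_comp_bond.atom_id_2"]]),
      type = cif_chr(bo[["_chem_comp_bond.type"]]) %||%
        rep("single", nrow(bo)),
      target = cif_num(bo[["_chem_comp_bond.value_dist"]]),
      esd = cif_num(bo[["_chem_comp_bond.value_dist_esd"]])
    )
  } else {
    NULL
  }
  an <- cif_find_loop(blk, "_chem_comp_angle.atom_id_1")
  angles <- if (!is.null(an)) {
    tibble::tibble(
      atom1 = cif_chr(an[["_chem_comp_angle.atom_id_1"]]),
      atom2 = cif_chr(an[["_chem_comp_angle.atom_id_2"]]),
      atom3 = cif_chr(an[["_chem_comp_angle.atom_id_3"]]),
      target = cif_num(an[["_chem_comp_angle.value_angle"]]),
      esd = cif_num(an[["_chem_comp_angle.value_angle_esd"]])
    )
  } else {
    NULL
  }
  to <- cif_find_loop(blk, "_chem_comp_tor.atom_id_1")
  torsions <- if (!is.null(to)) {
    per <- if ("_chem_comp_tor.period" %in% names(to)) {
      p <- cif_num(to[["_chem_comp_tor.period"]])
      p[is.na(p)] <- 1
      as.integer(p)
    } else {
      rep(1L, nrow(to))
    }
    tibble::tibble(
      id = cif_chr(to[["_chem_comp_tor.id"]]) %||%
        sprintf("tor_%d", seq_len(nrow(to))),
      atom1 = cif_chr(to[["_chem_comp_tor.atom_id_1"]]),
      atom2 = cif_chr(to[["_chem_comp_tor.atom_id_2"]]),
      atom3 = cif_chr(to[["_chem_comp_tor.atom_id_3"]]),
      atom4 = cif_chr(to[["_chem_comp_tor.atom_id_4"]]),
      target = cif_num(to[["_chem_comp_tor.value_angle"]]),
      esd = cif_num(to[["_chem_comp_tor.value_angle_esd"]]),
      period = per,
      alternatives = vector("list", nrow(to))
    )
  } else {
    NULL
  }
  alt <- cif_find_loop(blk, "_qmrestraints_tor_alt.tor_id")
  if (!is.null(alt) && !is.null(torsions)) {
    ids <- cif_chr(alt[["_qmrestraints_tor_alt.tor_id"]])
    vals <- cif_num(alt[["_qmrestraints_tor_alt.value_angle"]])
    for (tid in unique(ids)) {
      j <- match(tid, torsions$id)
      if (is.na(j)) {
        abort(sprintf("alternative targets name unknown torsion id '%s'", tid))
      }
      torsions$alternatives[[j]] <- vals[ids == tid]
    }
  }
  pl <- cif_find_loop(blk, "_chem_comp_plane_atom.plane_id")
  planes <- if (!is.null(pl)) {
    tibble::tibble(
      plane_id = cif_chr(pl[["_chem_comp_plane_atom.plane_id"]]),
      atom = cif_chr(pl[["_chem_comp_plane_atom.atom_id"]]),
      esd = cif_num(pl[["_chem_comp_plane_atom.dist_esd"]])
    )
  } else {
    NULL
  }
  ch <- cif_find_loop(blk, "_chem_comp_chir.atom_id_centre")
  chirals <- if (!is.null(ch)) {
    tibble::tibble(
      id = cif_chr(ch[["_chem_comp_chir.id"]]) %||%
        sprintf("chir_%d", seq_len(nrow(ch))),
      center = cif_chr(ch[["_chem_comp_chir.atom_id_centre"]]),
      atom1 = cif_chr(ch[["_chem_comp_chir.atom_id_1"]]),
      atom2 = cif_chr(ch[["_chem_comp_chir.atom_id_2"]]),
      atom3 = cif_chr(ch[["_chem_comp_chir.atom_id_3"]]),
      sign = cif_chr(ch[["_chem_comp_chir.volume_sign"]])
    )
  } else {
    NULL
  }
  restraint_dictionary(
    comp_id, atoms, bonds, angles, torsions, planes, chirals,
    formal_charge = charge
  )
}

#' Write a restraint dictionary as monomer-library-style CIF
#'
#' Bond targets are written with 3 decimals (Angstrom), angle and torsion
#' values with 2 decimals (degrees). Aperiodic alternative targets go to
#' the `_qmrestraints_tor_alt` extension loop.
#'
#' @param dictionary A [restraint_dictionary()].
#' @param file Optional output path.
#' @return Character vector of CIF lines, invisibly when `file` is given.
#' @export
write_restraint_cif <- function(dictionary, file = NULL) {
  stopifnot(inherits(dictionary, "restraint_dictionary"))
  d <- dictionary
  out <- c(
    sprintf("data_comp_%s", d$comp_id),
    "#",
    sprintf("_chem_comp.id            %s", d$comp_id),
    sprintf("_chem_comp.formal_charge %d", d$formal_charge),
    "#"
  )
  n_at <- nrow(d$atoms)
  out <- c(out, cif_format_loop(
    c(
      "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
      "_chem_comp_atom.type_symbol"
    ),
    list(rep(d$comp_id, n_at), d$atoms$name, d$atoms$element)
  ), "#")
  out <- c(out, cif_format_loop(
    c(
      "_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
      "_chem_comp_bond.atom_id_2", "_chem_comp_bond.type",
      "_chem_comp_bond.value_dist", "_chem_comp_bond.value_dist_esd"
    ),
    list(
      rep(d$comp_id, nrow(d$bonds)), d$bonds$atom1, d$bonds$atom2,
      d$bonds$type, sprintf("%.3f", d$bonds$target),
      sprintf("%.3f", d$bonds$esd)
    )
  ), "#")
  out <- c(out, cif_format_loop(
    c(
      "_chem_comp_angle.comp_id", "_chem_comp_angle.atom_id_1",
      "_chem_comp_angle.atom_id_2", "_chem_comp_angle.atom_id_3",
      "_chem_comp_angle.value_angle", "_chem_comp_angle.value_angle_esd"
    ),
    list(
      rep(d$comp_id, nrow(d$angles)), d$angles$atom1, d$angles$atom2,
      d$angles$atom3, sprintf("%.2f", d$angles$target),
      sprintf("%.2f", d$angles$esd)
    )
  ), "#")
  out <- c(out, cif_format_loop(
    c(
      "_chem_comp_tor.comp_id", "_chem_comp_tor.id",
      "_chem_comp_tor.atom_id_1", "_chem_comp_tor.atom_id_2",
      "_chem_comp_tor.atom_id_3", "_chem_comp_tor.atom_id_4",
      "_chem_comp_tor.value_angle", "_chem_comp_tor.value_angle_esd",
      "_chem_comp_tor.period"
    ),
    list(
      rep(d$comp_id, nrow(d$torsions)), d$torsions$id,
      d$torsions$atom1, d$torsions$atom2, d$torsions$atom3, d$torsions$atom4,
      sprintf("%.2f", d$torsions$target), sprintf("%.2f", d$torsions$esd),
      d$torsions$period
    )
  ), "#")
  has_alt <- vapply(d$torsions$alternatives, function(a) length(a) > 0, logical(1))
  if (any(has_alt)) {
    ids <- rep(d$torsions$id[has_alt], lengths(d$torsions$alternatives[has_alt]))
    vals <- unlist(d$torsions$alternatives[has_alt])
    out <- c(out, cif_format_loop(
      c("_qmrestraints_tor_alt.tor_id", "_qmrestraints_tor_alt.value_angle"),
      list(ids, sprintf("%.2f", vals))
    ), "#")
  }
  if (nrow(d$planes)) {
    out <- c(out, cif_format_loop(
      c(
        "_chem_comp_plane_atom.comp_id", "_chem_comp_plane_atom.plane_id",
        "_chem_comp_plane_atom.atom_id", "_chem_comp_plane_atom.dist_esd"
      ),
      list(
        rep(d$comp_id, nrow(d$planes)), d$planes$plane_id, d$planes$atom,
        sprintf("%.3f", d$planes$esd)
      )
    ), "#")
  }
  if (nrow(d$chirals)) {
    out <- c(out, cif_format_loop(
      c(
        "_chem_comp_chir.comp_id", "_chem_comp_chir.id",
        "_chem_comp_chir.atom_id_centre", "_chem_comp_chir.atom_id_1",
        "_chem_comp_chir.atom_id_2", "_chem_comp_chir.atom_id_3",
        "_chem_comp_chir.volume_sign"
      ),
      list(
        rep(d$comp_id, nrow(d$chirals)), d$chirals$id, d$chirals$center,
        d$chirals$atom1, d$chirals$atom2, d$chirals$atom3, d$chirals$sign
      )
    ), "#")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# --- QMR target generation -------------------------------------------------

#' Generate in-situ (QMR) restraints from an optimized ligand geometry
#'
#' For every bond, angle and torsion restraint of the base dictionary, the
#' target is replaced by the value measured from the supplied coordinates
#' while the e.s.d. is carried over from the base restraint. Torsions
#' become unimodal: periodicity is reset to 1 and alternative targets are
#' cleared, because the optimized in-situ value is the single known
#' minimum. Planes, chirality and the formal charge are copied unchanged.
#' Restraints whose atoms (typically hydrogens) are absent from the
#' coordinates keep their base target.
#'
#' @param coords Optimized ligand coordinates (tibble with `name`, `x`,
#'   `y`, `z`, a `ligand_cluster`, or an `xtal_model`).
#' @param base The base [restraint_dictionary()] supplying the restraint
#'   topology and e.s.d.s.
#' @return A new `restraint_dictionary` with in-situ targets.
#' @export
generate_qmr_restraints <- function(coords, base) {
  stopifnot(inherits(base, "restraint_dictionary"))
  coords <- .coords_table(coords)
  idx_of <- setNames(match(base$atoms$name, coords$name), base$atoms$name)
  heavy <- base$atoms$name[!base$atoms$element %in% c("H", "D")]
  missing_heavy <- heavy[is.na(idx_of[heavy])]
  if (length(missing_heavy)) {
    abort(sprintf(
      "coordinates lack roster atoms: %s",
      paste(missing_heavy, collapse = ", ")
    ))
  }
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  measure_if_possible <- function(kind, names_vec, base_target) {
    ii <- idx_of[names_vec]
    if (any(is.na(ii))) return(base_target)
    .measure_restraint(kind, ii, xyz)
  }
  bonds <- base$bonds
  if (nrow(bonds)) {
    bonds$target <- vapply(seq_len(nrow(bonds)), function(i) {
      measure_if_possible("bond", c(bonds$atom1[i], bonds$atom2[i]), bonds$target[i])
    }, numeric(1))
  }
  angles <- base$angles
  if (nrow(angles)) {
    angles$target <- vapply(seq_len(nrow(angles)), function(i) {
      measure_if_possible(
        "angle", c(angles$atom1[i], angles$atom2[i], angles$atom3[i]),
        angles$target[i]
      )
    }, numeric(1))
  }
  torsions <- base$torsions
  if (nrow(torsions)) {
    torsions$target <- vapply(seq_len(nrow(torsions)), function(i) {
      wrap_angle(measure_if_possible(
        "torsion",
        c(
          torsions$atom1[i], torsions$atom2[i], torsions$atom3[i],
          torsions$atom4[i]
        ),
        torsions$target[i]
      ))
    }, numeric(1))
    torsions$period <- rep(1L, nrow(torsions))
    torsions$alternatives <- vector("list", nrow(torsions))
  }
  restraint_dictionary(
    base$comp_id, base$atoms, bonds, angles, torsions,
    base$planes, base$chirals,
    formal_charge = base$formal_charge
  )
}
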