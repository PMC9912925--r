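# Shared helpers: hand-built miniature models/clusters and a mock external
# engine that echoes the deck geometry back in engine-output format.

atom_row <- function(name, x, y, z, comp_id = "LIG", chain_id = "A",
                     seq_id = 1L, element = NULL, is_hetatm = TRUE,
                     altloc = "") {
  tibble::tibble(
    name = name, comp_id = comp_id, chain_id = chain_id,
    seq_id = as.integer(seq_id), x = x, y = y, z = z,
    element = if (is.null(element)) infer_element(name) else element,
    is_hetatm = is_hetatm, altloc = altloc
  )
}

big_p1_model <- function(atoms, pad = 30) {
  rng <- apply(atoms[, c("x", "y", "z")], 2, range)
  structure_model(atoms, cell = c(rng[2, ] - rng[1, ] + 2 * pad, 90, 90, 90))
}

# A bare ligand cluster around explicit atoms (no pocket), for direct
# minimizer tests.
toy_cluster <- function(atoms, roles = "ligand", cell = c(50, 50, 50, 90, 90, 90)) {
  n <- nrow(atoms)
  at <- tibble::tibble(
    serial = seq_len(n), name = atoms$name, altloc = "",
    comp_id = "LIG", chain_id = "A", seq_id = 1L, icode = "",
    element = if ("element" %in% names(atoms)) atoms$element else infer_element(atoms$name),
    x = atoms$x, y = atoms$y, z = atoms$z,
    occupancy = 1, b_iso = 0, is_hetatm = TRUE, kind = "ligand",
    is_hydrogen = FALSE,
    source_serial = seq_len(n), operator = 1L,
    shift_a = 0L, shift_b = 0L, shift_c = 0L,
    role = rep_len(roles, n), link_serial = NA_integer_
  )
  at$is_hydrogen <- at$element %in% c("H", "D")
  structure(
    list(
      atoms = at,
      cut_bonds = tibble::tibble(
        inside_serial = integer(), inside_name = character(),
        inside_element = character(), outside_source_serial = integer(),
        outside_name = character(), outside_element = character(),
        outside_x = numeric(), outside_y = numeric(), outside_z = numeric()
      ),
      radius = 3.5, ligand = ligand_selector("A", "LIG", 1),
      cell = cell, spacegroup = "P 1", model_id = "toy", capped = TRUE
    ),
    class = "ligand_cluster"
  )
}

clean_env_report <- function() {
  structure(
    list(clean = TRUE, offenders = tibble::tibble(check = character())),
    class = "environment_report"
  )
}

# Engine mock: parses the deck written by write_external_input() and emits
# a MOPAC-flavoured output echoing the same coordinates.
echo_engine <- function(deck) {
  rows <- deck[-(1:3)]
  parts <- strsplit(trimws(rows), "\\s+")
  xyz <- do.call(rbind, lapply(parts, function(p) as.numeric(p[c(2, 4, 6)])))
  els <- vapply(parts, `[[`, character(1), 1)
  c(
    " MOCK ENGINE",
    " FINAL HEAT OF FORMATION =        -123.45600 KCAL/MOL",
    "",
    "          CARTESIAN COORDINATES",
    "",
    sprintf(
      "%6d %-2s %14.4f %14.4f %14.4f",
      seq_len(nrow(xyz)), els, xyz[, 1], xyz[, 2], xyz[, 3]
    )
  )
}

full_meta <- function(...) {
  defaults <- list(
    comp_id = "ABC", resolution = 2.0, map_cc = 0.85, non_h_atoms = 20,
    formal_charge = 0, mean_rmsd_bonds = 0.25, mean_rmsd_angles = 6,
    mean_rmsd_torsions = 40
  )
  utils::modifyList(defaults, list(...))
}
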