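# Reading and writing macromolecular models (PDB fixed-column and mmCIF
# atom_site), and a uniform tabular atom/residue/crystal data model.
#
# The model is an S3 object of class "xtal_model":
#   atoms      tibble: serial, name, altloc, comp_id, chain_id, seq_id,
#              icode, element, x, y, z, occupancy, b_iso, is_hetatm, kind,
#              is_hydrogen
#   cell       c(a, b, c, alpha, beta, gamma)
#   symops     list of fractional-space operators (identity first)
#   spacegroup Hermann-Mauguin symbol (or "" when operators were explicit)
#   resolution Angstrom (NA when unknown)
#   id         entry label

.res_key <- function(atoms) {
  paste(atoms$chain_id, atoms$seq_id, atoms$icode, atoms$comp_id, sep = "|")
}

.finalize_atoms <- function(atoms) {
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  no_el <- is.na(atoms$element) | atoms$element == ""
  if (any(no_el)) atoms$element[no_el] <- infer_element(atoms$name[no_el])
  atoms$element <- toupper(atoms$element)
  atoms$kind <- classify_residue(atoms$comp_id, atoms$is_hetatm)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))[1]
    abort(sprintf("non-finite coordinates for atom serial %s", atoms$serial[bad]))
  }
  tibble::as_tibble(atoms)
}

#' Construct a structure model from an atom table
#'
#' @param atoms Tibble/data frame with at least `name`, `comp_id`,
#'   `chain_id`, `seq_id`, `x`, `y`, `z`; missing bookkeeping columns get
#'   defaults (full occupancy, empty altloc/icode, inferred elements).
#' @param cell Unit cell `c(a, b, c, alpha, beta, gamma)`.
#' @param spacegroup Hermann-Mauguin symbol used to resolve symmetry
#'   operators from the bundled table, ignored when `symops` is given.
#' @param symops Optional explicit list of operators (`rot`, `trans`).
#' @param resolution Optional resolution in Angstrom (metadata).
#' @param id Entry label.
#' @return An object of class `xtal_model`.
#' @export
structure_model <- function(atoms, cell = c(1, 1, 1, 90, 90, 90),
                            spacegroup = "P 1", symops = NULL,
                            resolution = NA_real_, id = "model") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  defaults <- list(
    serial = seq_len(nrow(atoms)), altloc = "", icode = "",
    occupancy = 1, b_iso = 0, is_hetatm = TRUE, element = NA_character_
  )
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- rep_len(defaults[[nm]], nrow(atoms))
  }
  if (anyDuplicated(atoms$serial)) abort("atom serials must be unique")
  .cell_validate(cell)
  if (is.null(symops)) symops <- spacegroup_operators(spacegroup)
  if (!any(vapply(symops, .is_identity_op, logical(1)))) {
    symops <- c(list(list(rot = diag(3), trans = numeric(3))), symops)
  }
  out <- structure(
    list(
      atoms = .finalize_atoms(atoms),
      cell = as.numeric(cell),
      symops = symops,
      spacegroup = spacegroup,
      resolution = resolution,
      id = id
    ),
    class = "xtal_model"
  )
  out
}

#' @export
print.xtal_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "<xtal_model '%s': %d atoms, %d residues, %d symmetry ops, %s>\n",
    x$id, nrow(a), length(unique(.res_key(a))), length(x$symops),
    if (nzchar(x$spacegroup)) x$spacegroup else "explicit symmetry"
  ))
  cat(sprintf(
    "  cell: %.2f %.2f %.2f  %.1f %.1f %.1f\n",
    x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.xtal_model <- function(x, ...) x$atoms

.parse_cryst1 <- function(line) {
  cell <- c(
    as.numeric(substr(line, 7, 15)), as.numeric(substr(line, 16, 24)),
    as.numeric(substr(line, 25, 33)), as.numeric(substr(line, 34, 40)),
    as.numeric(substr(line, 41, 47)), as.numeric(substr(line, 48, 54))
  )
  sg <- trimws(substr(line, 56, 66))
  if (any(is.na(cell))) abort("malformed CRYST1 record")
  list(cell = cell, spacegroup = if (nzchar(sg)) sg else "P 1")
}

.parse_pdb_text <- function(text, fallback_cell, id) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  coord <- grepl("^(ATOM  |HETATM)", lines)
  short <- which(coord & nchar(lines) < 54)
  if (length(short)) {
    abort(sprintf("unparseable PDB record at line %d (truncated)", short[1]))
  }
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst)) {
    cc <- .parse_cryst1(cryst[1])
  } else if (!is.null(fallback_cell)) {
    cc <- list(cell = fallback_cell, spacegroup = "P 1")
  } else {
    abort("no CRYST1 record; supply fallback_cell for a P 1 box")
  }
  resol <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(m)) resol <- as.numeric(m)
  }
  if (!any(coord)) {
    atoms <- tibble::tibble(
      serial = integer(), name = character(), altloc = character(),
      comp_id = character(), chain_id = character(), seq_id = integer(),
      icode = character(), element = character(), x = numeric(),
      y = numeric(), z = numeric(), occupancy = numeric(),
      b_iso = numeric(), is_hetatm = logical()
    )
    return(structure_model(atoms, cc$cell, cc$spacegroup,
      resolution = resol, id = id
    ))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- tryCatch(
    bio3d::read.pdb(tf, verbose = FALSE),
    error = function(e) abort(sprintf("PDB parse failure: %s", conditionMessage(e)))
  )
  a <- pdb$atom
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))) {
    bad <- which(!is.finite(a$x))[1]
    abort(sprintf("unparseable coordinates in PDB record %d", bad))
  }
  atoms <- tibble::tibble(
    serial = as.integer(a$eleno),
    name = as.character(a$elety),
    altloc = ifelse(is.na(a$alt), "", as.character(a$alt)),
    comp_id = as.character(a$resid),
    chain_id = ifelse(is.na(a$chain), "", as.character(a$chain)),
    seq_id = as.integer(a$resno),
    icode = ifelse(is.na(a$insert), "", as.character(a$insert)),
    element = ifelse(is.na(a$elesy), "", toupper(as.character(a$elesy))),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_iso = ifelse(is.na(a$b), 0, a$b),
    is_hetatm = a$type == "HETATM"
  )
  structure_model(atoms, cc$cell, cc$spacegroup, resolution = resol, id = id)
}

.parse_mmcif_text <- function(text, fallback_cell, id) {
  blocks <- cif_parse(text)
  blk <- NULL
  for (b in blocks) {
    if (!is.null(cif_find_loop(b, "_atom_site.id")) ||
      !is.null(cif_find_loop(b, "_atom_site.Cartn_x"))) {
      blk <- b
      break
    }
  }
  if (is.null(blk)) {
    if (length(blocks)) blk <- blocks[[1]] else abort("empty mmCIF input")
  }
  items <- blk$items
  getit <- function(tag) if (tag %in% names(items)) items[[tag]] else NA_character_
  cell <- cif_num(c(
    getit("_cell.length_a"), getit("_cell.length_b"), getit("_cell.length_c"),
    getit("_cell.angle_alpha"), getit("_cell.angle_beta"), getit("_cell.angle_gamma")
  ))
  sg <- cif_chr(getit("_symmetry.space_group_name_H-M"))
  if (is.na(sg)) sg <- cif_chr(getit("_space_group.name_H-M_alt"))
  symops <- NULL
  oploop <- cif_find_loop(blk, "_symmetry_equiv.pos_as_xyz")
  if (is.null(oploop)) oploop <- cif_find_loop(blk, "_space_group_symop.operation_xyz")
  if (!is.null(oploop)) {
    col <- intersect(
      c("_symmetry_equiv.pos_as_xyz", "_space_group_symop.operation_xyz"),
      names(oploop)
    )[1]
    symops <- lapply(oploop[[col]], parse_symop)
  }
  if (any(is.na(cell))) {
    if (!is.null(fallback_cell)) {
      cell <- fallback_cell
      if (is.null(symops)) sg <- "P 1"
    } else {
      abort("mmCIF lacks _cell items; supply fallback_cell for a P 1 box")
    }
  }
  if (is.na(sg)) sg <- if (is.null(symops)) "P 1" else ""
  resol <- cif_num(getit("_reflns.d_resolution_high"))

  lp <- cif_find_loop(blk, "_atom_site.Cartn_x")
  if (is.null(lp)) {
    atoms <- tibble::tibble(
      serial = integer(), name = character(), altloc = character(),
      comp_id = character(), chain_id = character(), seq_id = integer(),
      icode = character(), element = character(), x = numeric(),
      y = numeric(), z = numeric(), occupancy = numeric(),
      b_iso = numeric(), is_hetatm = logical()
    )
  } else {
    pick <- function(...) {
      for (tag in c(...)) if (tag %in% names(lp)) return(lp[[tag]])
      rep(NA_character_, nrow(lp))
    }
    atoms <- tibble::tibble(
      serial = as.integer(cif_num(pick("_atom_site.id"))),
      name = cif_chr(pick("_atom_site.auth_atom_id", "_atom_site.label_atom_id")),
      altloc = cif_chr(pick("_atom_site.label_alt_id")),
      comp_id = cif_chr(pick("_atom_site.auth_comp_id", "_atom_site.label_comp_id")),
      chain_id = cif_chr(pick("_atom_site.auth_asym_id", "_atom_site.label_asym_id")),
      seq_id = as.integer(cif_num(pick("_atom_site.auth_seq_id", "_atom_site.label_seq_id"))),
      icode = cif_chr(pick("_atom_site.pdbx_PDB_ins_code")),
      element = cif_chr(pick("_atom_site.type_symbol")),
      x = cif_num(pick("_atom_site.Cartn_x")),
      y = cif_num(pick("_atom_site.Cartn_y")),
      z = cif_num(pick("_atom_site.Cartn_z")),
      occupancy = cif_num(pick("_atom_site.occupancy")),
      b_iso = cif_num(pick("_atom_site.B_iso_or_equiv")),
      is_hetatm = toupper(cif_chr(pick("_atom_site.group_PDB"))) %in% "HETATM"
    )
    atoms$occupancy[is.na(atoms$occupancy)] <- 1
    atoms$b_iso[is.na(atoms$b_iso)] <- 0
    if (any(is.na(atoms$serial))) atoms$serial <- seq_len(nrow(atoms))
  }
  structure_model(atoms, cell,
    spacegroup = sg, symops = symops,
    resolution = resol, id = id
  )
}

.guess_format <- function(file, text = NULL) {
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext %in% c("cif", "mmcif")) return("mmcif")
    if (ext %in% c("pdb", "ent")) return("pdb")
  }
  if (!is.null(text) && any(grepl("^(data_|loop_|_atom_site)", text))) return("mmcif")
  "pdb"
}

#' Parse a macromolecular model from text
#'
#' @param text Character scalar or vector of lines (PDB or mmCIF content).
#' @param format `"pdb"`, `"mmcif"`, or `"auto"`.
#' @param fallback_cell Optional cell to assume (with space group P 1) when
#'   the input lacks crystal information; without it such input is an error.
#' @param id Entry label stored on the model.
#' @return An `xtal_model`.
#' @export
parse_structure <- function(text, format = c("auto", "pdb", "mmcif"),
                            fallback_cell = NULL, id = "model") {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(NULL, text)
  switch(format,
    pdb = .parse_pdb_text(text, fallback_cell, id),
    mmcif = .parse_mmcif_text(text, fallback_cell, id)
  )
}

#' Read a macromolecular model from a file
#'
#' @inheritParams parse_structure
#' @param file Path to a `.pdb`/`.ent` or `.cif` file.
#' @return An `xtal_model`.
#' @export
read_structure <- function(file, format = c("auto", "pdb", "mmcif"),
                           fallback_cell = NULL, id = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(file)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(file))
  parse_structure(readLines(file, warn = FALSE), format, fallback_cell, id)
}

.pdb_atom_name_field <- function(name, element) {
  n <- nchar(name)
  if (n > 4) abort(sprintf("atom name '%s' exceeds the PDB 4-column field", name))
  if (n == 4 || nchar(element) == 2) {
    formatC(name, width = -4)
  } else {
    formatC(paste0(" ", name), width = -4)
  }
}

.write_pdb_text <- function(model) {
  a <- model$atoms
  if (nrow(a) > 0 && max(a$serial) > 99999) {
    abort("model has atom serials beyond 99999: PDB fixed columns cannot hold it")
  }
  if (any(nchar(a$comp_id) > 3)) {
    abort("component code longer than 3 characters cannot be written to PDB")
  }
  cryst <- sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
    model$cell[1], model$cell[2], model$cell[3],
    model$cell[4], model$cell[5], model$cell[6],
    if (nzchar(model$spacegroup)) model$spacegroup else "P 1", 1
  )
  if (nrow(a) == 0) return(c(cryst, "END"))
  recs <- vapply(seq_len(nrow(a)), function(i) {
    sprintf(
      "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (a$is_hetatm[i]) "HETATM" else "ATOM",
      a$serial[i],
      .pdb_atom_name_field(a$name[i], a$element[i]),
      a$altloc[i], a$comp_id[i], a$chain_id[i], a$seq_id[i], a$icode[i],
      a$x[i], a$y[i], a$z[i], a$occupancy[i], a$b_iso[i],
      a$element[i]
    )
  }, character(1))
  c(cryst, recs, "END")
}

.write_mmcif_text <- function(model) {
  a <- model$atoms
  hdr <- c(
    sprintf("data_%s", gsub("[^A-Za-z0-9_-]", "_", model$id)),
    "#",
    sprintf("_cell.length_a    %.4f", model$cell[1]),
    sprintf("_cell.length_b    %.4f", model$cell[2]),
    sprintf("_cell.length_c    %.4f", model$cell[3]),
    sprintf("_cell.angle_alpha %.4f", model$cell[4]),
    sprintf("_cell.angle_beta  %.4f", model$cell[5]),
    sprintf("_cell.angle_gamma %.4f", model$cell[6]),
    sprintf(
      "_symmetry.space_group_name_H-M \"%s\"",
      if (nzchar(model$spacegroup)) model$spacegroup else "P 1"
    )
  )
  if (!is.na(model$resolution)) {
    hdr <- c(hdr, sprintf("_reflns.d_resolution_high %.4f", model$resolution))
  }
  ops <- cif_format_loop(
    c("_symmetry_equiv.id", "_symmetry_equiv.pos_as_xyz"),
    list(
      seq_along(model$symops),
      vapply(model$symops, symop_to_triplet, character(1))
    )
  )
  sites <- cif_format_loop(
    c(
      "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
      "_atom_site.auth_atom_id", "_atom_site.label_alt_id",
      "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
      "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
      "_atom_site.occupancy", "_atom_site.B_iso_or_equiv"
    ),
    list(
      ifelse(a$is_hetatm, "HETATM", "ATOM"), a$serial, a$element, a$name,
      ifelse(a$altloc == "", ".", a$altloc), a$comp_id,
      ifelse(a$chain_id == "", ".", a$chain_id), a$seq_id,
      ifelse(a$icode == "", ".", a$icode),
      sprintf("%.4f", a$x), sprintf("%.4f", a$y), sprintf("%.4f", a$z),
      sprintf("%.3f", a$occupancy), sprintf("%.3f", a$b_iso)
    )
  )
  c(hdr, "#", ops, "#", sites, "#")
}

#' Serialize a structure model
#'
#' Output re-parses to an equivalent model: atom identities exactly,
#' positions to the format precision (0.001 Angstrom in both formats).
#'
#' @param model An `xtal_model`.
#' @param format `"pdb"` or `"mmcif"`.
#' @param file Optional path; when given the text is also written there.
#' @return Character vector of lines, invisibly when `file` is given.
#' @export
write_structure <- function(model, format = c("pdb", "mmcif"), file = NULL) {
  stopifnot(inherits(model, "xtal_model"))
  format <- match.arg(format)
  txt <- switch(format,
    pdb = .write_pdb_text(model),
    mmcif = .write_mmcif_text(model)
  )
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# --- connectivity ----------------------------------------------------------

# Tolerance factor on the sum of covalent radii for distance-based bonding.
.covalent_tolerance <- 1.3

.distance_bonds <- function(res_atoms) {
  n <- nrow(res_atoms)
  if (n < 2) return(NULL)
  xyz <- as.matrix(res_atoms[, c("x", "y", "z")])
  rad <- covalent_radius(res_atoms$element)
  is_h <- res_atoms$is_hydrogen
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE])^2))
  cut <- .covalent_tolerance * (rad[pairs[, 1]] + rad[pairs[, 2]])
  ok <- d <= cut & d > 0.4 & !(is_h[pairs[, 1]] & is_h[pairs[, 2]])
  # altloc compatibility: bond only same altloc or one of the pair blank
  alt1 <- res_atoms$altloc[pairs[, 1]]
  alt2 <- res_atoms$altloc[pairs[, 2]]
  ok <- ok & (alt1 == alt2 | alt1 == "" | alt2 == "")
  if (!any(ok)) return(NULL)
  sel <- which(ok)
  out <- data.frame(
    i = pairs[sel, 1], j = pairs[sel, 2], d = d[sel],
    stringsAsFactors = FALSE
  )
  # a hydrogen binds only its nearest heavy atom
  for (h in which(is_h)) {
    inv <- which((out$i == h) | (out$j == h))
    if (length(inv) > 1) {
      keep <- inv[which.min(out$d[inv])]
      out <- out[-setdiff(inv, keep), , drop = FALSE]
    }
  }
  out
}

#' Infer covalent connectivity of a model
#'
#' Intra-residue bonds come from matching restraint dictionaries when
#' supplied, otherwise from an element-pair distance rule (sum of covalent
#' radii times a 1.3 tolerance factor, hydrogens limited to their nearest
#' heavy atom). Inter-residue peptide bonds (C to N of the next residue in
#' the same chain) are added when shorter than 1.7 Angstrom.
#'
#' @param model An `xtal_model`.
#' @param dictionaries Optional named list of [restraint_dictionary()]
#'   objects keyed by component code.
#' @return Tibble with columns `serial1`, `serial2`, `order`.
#' @export
infer_connectivity <- function(model, dictionaries = NULL) {
  stopifnot(inherits(model, "xtal_model"))
  a <- model$atoms
  if (nrow(a) == 0) {
    return(tibble::tibble(serial1 = integer(), serial2 = integer(), order = character()))
  }
  key <- .res_key(a)
  edges <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    res <- a[idx, , drop = FALSE]
    dict <- dictionaries[[res$comp_id[1]]]
    if (!is.null(dict)) {
      b <- dict$bonds
      i <- match(b$atom1, res$name)
      j <- match(b$atom2, res$name)
      ok <- !is.na(i) & !is.na(j)
      if (any(ok)) {
        edges[[length(edges) + 1L]] <- data.frame(
          serial1 = res$serial[i[ok]], serial2 = res$serial[j[ok]],
          order = if (!is.null(b$type)) b$type[ok] else "single",
          stringsAsFactors = FALSE
        )
      }
    } else {
      db <- .distance_bonds(res)
      if (!is.null(db)) {
        edges[[length(edges) + 1L]] <- data.frame(
          serial1 = res$serial[db$i], serial2 = res$serial[db$j],
          order = "unknown", stringsAsFactors = FALSE
        )
      }
    }
  }
  # peptide links between consecutive residues of a chain
  ukeys <- unique(key)
  info <- a[match(ukeys, key), c("chain_id", "kind"), drop = FALSE]
  for (t in which(info$kind == "amino_acid")) {
    if (t == length(ukeys)) next
    nxt <- t + 1L
    if (info$kind[nxt] != "amino_acid") next
    if (info$chain_id[t] != info$chain_id[nxt]) next
    ci <- which(key == ukeys[t] & a$name == "C")
    ni <- which(key == ukeys[nxt] & a$name == "N")
    if (length(ci) && length(ni)) {
      d <- sqrt(sum((as.numeric(a[ci[1], c("x", "y", "z")]) -
        as.numeric(a[ni[1], c("x", "y", "z")]))^2))
      if (d < 1.7) {
        edges[[length(edges) + 1L]] <- data.frame(
          serial1 = a$serial[ci[1]], serial2 = a$serial[ni[1]],
          order = "single", stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(edges)) {
    return(tibble::tibble(serial1 = integer(), serial2 = integer(), order = character()))
  }
  out <- dplyr::bind_rows(edges)
  swap <- out$serial1 > out$serial2
  tmp <- out$serial1[swap]
  out$serial1[swap] <- out$serial2[swap]
  out$serial2[swap] <- tmp
  tibble::as_tibble(dplyr::distinct(out, .data$serial1, .data$serial2, .keep_all = TRUE))
}
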