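# Element data used across the package: covalent and van der Waals radii,
# atomic weights, metal classification, and element inference from PDB-style
# atom names. Radii are the conventional single-bond covalent radii (Cordero
# et al. style values, Angstrom); vdW radii follow Bondi.

.element_table <- local({
  tab <- tibble::tribble(
    ~element, ~covalent_r, ~vdw_r, ~weight, ~is_metal,
    "H", 0.31, 1.10, 1.008, FALSE,
    "D", 0.31, 1.10, 2.014, FALSE,
    "C", 0.76, 1.70, 12.011, FALSE,
    "N", 0.71, 1.55, 14.007, FALSE,
    "O", 0.66, 1.52, 15.999, FALSE,
    "F", 0.57, 1.47, 18.998, FALSE,
    "P", 1.07, 1.80, 30.974, FALSE,
    "S", 1.05, 1.80, 32.06, FALSE,
    "CL", 1.02, 1.75, 35.45, FALSE,
    "BR", 1.20, 1.85, 79.904, FALSE,
    "I", 1.39, 1.98, 126.904, FALSE,
    "B", 0.84, 1.92, 10.81, FALSE,
    "SE", 1.20, 1.90, 78.971, FALSE,
    "SI", 1.11, 2.10, 28.085, FALSE,
    "LI", 1.28, 1.82, 6.94, TRUE,
    "NA", 1.66, 2.27, 22.990, TRUE,
    "MG", 1.41, 1.73, 24.305, TRUE,
    "AL", 1.21, 1.84, 26.982, TRUE,
    "K", 2.03, 2.75, 39.098, TRUE,
    "CA", 1.76, 2.31, 40.078, TRUE,
    "MN", 1.39, 2.05, 54.938, TRUE,
    "FE", 1.32, 2.05, 55.845, TRUE,
    "CO", 1.26, 2.00, 58.933, TRUE,
    "NI", 1.24, 1.97, 58.693, TRUE,
    "CU", 1.32, 1.96, 63.546, TRUE,
    "ZN", 1.22, 2.01, 65.38, TRUE,
    "CD", 1.44, 2.18, 112.414, TRUE,
    "HG", 1.32, 2.23, 200.592, TRUE,
    "W", 1.62, 2.18, 183.84, TRUE,
    "MO", 1.54, 2.17, 95.95, TRUE,
    "V", 1.53, 2.07, 50.942, TRUE,
    "CR", 1.39, 2.06, 51.996, TRUE,
    "CS", 2.44, 3.43, 132.905, TRUE,
    "RB", 2.20, 3.03, 85.468, TRUE,
    "SR", 1.95, 2.49, 87.62, TRUE,
    "BA", 2.15, 2.68, 137.327, TRUE,
    "PT", 1.36, 2.13, 195.084, TRUE,
    "AU", 1.36, 2.14, 196.967, TRUE,
    "AG", 1.45, 2.11, 107.868, TRUE,
    "GA", 1.22, 1.87, 69.723, TRUE,
    "X", 0.77, 1.70, 0.0, FALSE
  )
  tab
})

.element_lookup <- function(element, column, default) {
  el <- toupper(element)
  i <- match(el, .element_table$element)
  out <- .element_table[[column]][i]
  out[is.na(i)] <- default
  out
}

covalent_radius <- function(element) .element_lookup(element, "covalent_r", 0.77)
vdw_radius <- function(element) .element_lookup(element, "vdw_r", 1.70)
atomic_weight <- function(element) .element_lookup(element, "weight", 0.0)

is_metal_element <- function(element) {
  el <- toupper(element)
  i <- match(el, .element_table$element)
  out <- .element_table$is_metal[i]
  out[is.na(i)] <- FALSE
  out
}

known_element <- function(element) toupper(element) %in% .element_table$element

#' Residue component codes recognised as water
#'
#' Common dialects used for crystallographic water in deposited models.
#' @return Character vector of component codes.
#' @export
water_synonyms <- function() c("HOH", "WAT", "H2O", "DOD")

.amino_acids <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

.nucleotides <- c(
  "A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DU", "DI"
)

# Heavy-atom rosters of the standard amino acids, used by the missing-atom
# check when no restraint dictionary is supplied for a protein residue.
.aa_heavy_atoms <- list(
  GLY = c("N", "CA", "C", "O"),
  ALA = c("N", "CA", "C", "O", "CB"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  MSE = c("N", "CA", "C", "O", "CB", "CG", "SE", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2")
)

#' Classify a residue component code
#'
#' Maps a component code to one of `amino_acid`, `nucleotide`, `water`,
#' `ligand` or `other`. Codes absent from the standard component tables are
#' called `ligand` when they arrived on a HETATM record and `other`
#' otherwise.
#'
#' @param comp_id Component code(s), e.g. `"GLY"`, `"HOH"`, `"BER"`.
#' @param is_hetatm Logical, whether the record was a HETATM; recycled.
#' @return Character vector of residue kinds.
#' @export
classify_residue <- function(comp_id, is_hetatm = TRUE) {
  cid <- toupper(comp_id)
  het <- rep_len(is_hetatm, length(cid))
  dplyr::case_when(
    cid %in% water_synonyms() ~ "water",
    cid %in% .amino_acids ~ "amino_acid",
    cid %in% .nucleotides ~ "nucleotide",
    het ~ "ligand",
    TRUE ~ "other"
  )
}

#' Infer an element symbol from a PDB-style atom name
#'
#' Legacy PDB files may omit the element column; the element is then derived
#' from the atom-name convention: the first non-digit characters of the
#' left-justified name, with two-letter symbols recognised only when they
#' name a known element (so `"CA"` in a protein residue is calcium only when
#' the name occupies the element-style columns; here we resolve plain names
#' and prefer one-letter organic elements for ambiguous cases like CA/CD).
#'
#' @param name Atom name(s), e.g. `"C20"`, `"O4"`, `"1HB"`.
#' @param prefer_single Prefer the one-letter reading of two-letter
#'   candidates (`"CA"` -> carbon); the right choice for polymer atom names.
#' @return Element symbols (uppercase).
#' @export
infer_element <- function(name, prefer_single = TRUE) {
  vapply(name, function(nm) {
    s <- gsub("[^A-Za-z]", "", toupper(nm))
    if (nchar(s) == 0) return("X")
    if (substr(s, 1, 1) == "H" || grepl("^[0-9]*H", toupper(nm))) return("H")
    two <- substr(s, 1, 2)
    one <- substr(s, 1, 1)
    if (!prefer_single && known_element(two)) return(two)
    if (known_element(one)) return(one)
    if (known_element(two)) return(two)
    "X"
  }, character(1), USE.NAMES = FALSE)
}
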