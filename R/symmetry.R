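# Unit-cell math (standard orthogonalization convention: a along x, b in
# the xy-plane) and generation of crystallographic symmetry images near a
# selection. Coordinates are Cartesian Angstrom everywhere outside this
# file; fractional coordinates exist only here.

.cell_validate <- function(cell) {
  if (length(cell) != 6 || any(!is.finite(cell))) {
    abort("cell must be six finite numbers: a, b, c, alpha, beta, gamma")
  }
  if (any(cell[1:3] <= 0)) abort("degenerate cell: non-positive axis length")
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180)) {
    abort("cell angles must lie in (0, 180) degrees")
  }
  invisible(cell)
}

#' Orthogonalization matrix of a unit cell
#'
#' @param cell Numeric vector `c(a, b, c, alpha, beta, gamma)` (Angstrom,
#'   degrees).
#' @return 3x3 matrix mapping fractional to Cartesian coordinates.
#' @export
orthogonalization_matrix <- function(cell) {
  .cell_validate(cell)
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v <= 1e-12) abort("degenerate cell: zero volume")
  m <- matrix(c(
    a, b * cg, c_ * cb,
    0, b * sg, c_ * (ca - cb * cg) / sg,
    0, 0, c_ * sqrt(v) / sg
  ), nrow = 3, byrow = TRUE)
  m
}

#' Convert Cartesian coordinates to fractional, and back
#'
#' `fractionalize()` and `orthogonalize()` are exact inverses (to machine
#' precision) under the standard crystallographic convention.
#'
#' @param xyz Numeric matrix (n x 3) or length-3 vector.
#' @param cell Unit cell `c(a, b, c, alpha, beta, gamma)`.
#' @return Matrix (n x 3) of transformed coordinates.
#' @export
fractionalize <- function(xyz, cell) {
  m <- orthogonalization_matrix(cell)
  x <- if (is.null(dim(xyz))) matrix(xyz, ncol = 3) else as.matrix(xyz)
  t(solve(m, t(x)))
}

#' @rdname fractionalize
#' @export
orthogonalize <- function(xyz, cell) {
  m <- orthogonalization_matrix(cell)
  x <- if (is.null(dim(xyz))) matrix(xyz, ncol = 3) else as.matrix(xyz)
  t(m %*% t(x))
}

# Perpendicular spacing (Angstrom) between lattice planes normal to each
# cell axis: one fractional unit along axis i advances by height[i].
.cell_heights <- function(cell) {
  f <- solve(orthogonalization_matrix(cell))
  1 / sqrt(rowSums(f^2))
}

#' Symmetry-image atoms near a selection
#'
#' Applies every symmetry operator of the model combined with lattice
#' translations over a shift box wide enough to cover `radius`, and returns
#' each image atom within `radius` of any atom of the selection. The
#' identity operator with zero lattice shift is excluded (those atoms are
#' the model itself); images that land on their own source atom (special
#' positions, within 0.1 Angstrom) are dropped.
#'
#' @param model A structure model (see [read_structure()]).
#' @param center_serials Atom serials defining the selection.
#' @param radius Cutoff radius in Angstrom (> 0).
#' @return Tibble of image atoms with provenance columns `source_serial`,
#'   `operator` (index into `model$symops`), `shift_a/b/c` (lattice shift)
#'   plus atom identity columns and Cartesian `x, y, z`.
#' @export
symmetry_images_within <- function(model, center_serials, radius) {
  stopifnot(inherits(model, "xtal_model"))
  if (!is.numeric(radius) || radius <= 0) abort("radius must be > 0")
  atoms <- model$atoms
  sel <- atoms[atoms$serial %in% center_serials, , drop = FALSE]
  if (nrow(sel) == 0) abort("empty center selection")
  cell <- model$cell
  orth <- orthogonalization_matrix(cell)
  fr_all <- fractionalize(as.matrix(atoms[, c("x", "y", "z")]), cell)
  fr_sel <- fractionalize(as.matrix(sel[, c("x", "y", "z")]), cell)
  sel_xyz <- as.matrix(sel[, c("x", "y", "z")])
  heights <- .cell_heights(cell)
  pad <- ceiling(radius / heights) + 1L

  out <- list()
  for (k in seq_along(model$symops)) {
    op <- model$symops[[k]]
    fr_img <- fr_all %*% t(op$rot) + matrix(op$trans, nrow(fr_all), 3, byrow = TRUE)
    identity_op <- .is_identity_op(op)
    # shift ranges covering all (selection, image) fractional differences
    lo <- floor(apply(fr_sel, 2, min) - apply(fr_img, 2, max)) - pad
    hi <- ceiling(apply(fr_sel, 2, max) - apply(fr_img, 2, min)) + pad
    for (sa in lo[1]:hi[1]) for (sb in lo[2]:hi[2]) for (sc in lo[3]:hi[3]) {
      if (identity_op && sa == 0 && sb == 0 && sc == 0) next
      shifted <- fr_img + matrix(c(sa, sb, sc), nrow(fr_img), 3, byrow = TRUE)
      xyz <- shifted %*% t(orth)
      # min distance of each image atom to the selection
      keep <- rep(FALSE, nrow(xyz))
      mind <- rep(Inf, nrow(xyz))
      for (s in seq_len(nrow(sel_xyz))) {
        d2 <- (xyz[, 1] - sel_xyz[s, 1])^2 + (xyz[, 2] - sel_xyz[s, 2])^2 +
          (xyz[, 3] - sel_xyz[s, 3])^2
        mind <- pmin(mind, d2)
      }
      keep <- mind <= (radius + 1e-6)^2
      if (!any(keep)) next
      # drop special positions: image coincides with its own source atom
      src <- as.matrix(atoms[keep, c("x", "y", "z")])
      dsrc <- sqrt(rowSums((xyz[keep, , drop = FALSE] - src)^2))
      keep_idx <- which(keep)[dsrc > 0.1]
      if (!length(keep_idx)) next
      img <- atoms[keep_idx, , drop = FALSE]
      img$source_serial <- img$serial
      img$operator <- k
      img$shift_a <- sa
      img$shift_b <- sb
      img$shift_c <- sc
      img$x <- xyz[keep_idx, 1]
      img$y <- xyz[keep_idx, 2]
      img$z <- xyz[keep_idx, 3]
      img$serial <- NULL
      out[[length(out) + 1L]] <- img
    }
  }
  if (!length(out)) {
    cols <- atoms[0, , drop = FALSE]
    cols$serial <- NULL
    cols$source_serial <- integer()
    cols$operator <- integer()
    cols$shift_a <- integer(); cols$shift_b <- integer(); cols$shift_c <- integer()
    return(tibble::as_tibble(cols))
  }
  tibble::as_tibble(dplyr::bind_rows(out))
}
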