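# Internal-coordinate measurement (bond, valence angle, IUPAC-signed
# torsion), periodicity-aware signed deviations, per-category r.m.s.d.
# reports with outlier flags, and resolution-binned summaries.

.vnorm <- function(v) sqrt(sum(v * v))

#' Measure internal coordinates
#'
#' `bond_length()` returns the distance between two points,
#' `valence_angle()` the 1-2-3 angle in degrees, `torsion_angle()` the
#' 1-2-3-4 dihedral in degrees with the IUPAC sign convention (clockwise
#' positive when sighting from atom 2 towards atom 3), wrapped to
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Length-3 Cartesian coordinates (Angstrom).
#' @return Numeric scalar.
#' @export
bond_length <- function(p1, p2) .vnorm(p2 - p1)

#' @rdname bond_length
#' @export
valence_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- .vnorm(u)
  nv <- .vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) abort("zero-length bond vector in angle")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' @rdname bond_length
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10) {
    abort("undefined torsion: three collinear atoms")
  }
  b2h <- b2 / .vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * b2h)
  wrap_angle(atan2(y, x) * 180 / pi)
}

.cross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Wrap an angle to (-180, 180]
#'
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  out <- x - 360 * floor(x / 360 + 0.5)
  out[out <= -180] <- out[out <= -180] + 360
  out
}

#' Signed deviation of a measured value from a restraint target
#'
#' The convention is `delta = target - actual`, matching the layout of
#' printed outlier tables (Target, Actual, Delta). For torsions the
#' deviation is computed against the nearest equivalent target: the
#' candidate set is the base target plus its periodic images
#' (`target + k * 360 / periodicity`) and any aperiodic alternative
#' targets; the candidate minimizing the absolute wrapped deviation wins,
#' with ties broken towards the earlier candidate (base target first).
#'
#' @param kind `"bond"`, `"angle"` or `"torsion"`.
#' @param target Restraint target (Angstrom or degrees).
#' @param actual Measured value.
#' @param periodicity Positive integer; only used for torsions.
#' @param alternatives Optional numeric vector of aperiodic alternative
#'   torsion targets in degrees.
#' @return Signed deviation (wrapped to (-180, 180] for torsions).
#' @export
signed_deviation <- function(kind, target, actual, periodicity = 1,
                             alternatives = NULL) {
  kind <- match.arg(kind, c("bond", "angle", "torsion"))
  if (kind != "torsion") {
    return(target - actual)
  }
  if (!is.numeric(periodicity) || periodicity < 1) {
    abort("torsion periodicity must be a positive integer")
  }
  periodicity <- as.integer(periodicity)
  cand <- wrap_angle(target + (seq_len(periodicity) - 1L) * 360 / periodicity)
  if (!is.null(alternatives) && length(alternatives)) {
    cand <- c(cand, wrap_angle(alternatives))
  }
  devs <- wrap_angle(cand - wrap_angle(actual))
  devs[which.min(abs(devs))]
}

.measure_restraint <- function(kind, idx, xyz) {
  p <- lapply(idx, function(i) xyz[i, ])
  switch(kind,
    bond = bond_length(p[[1]], p[[2]]),
    angle = valence_angle(p[[1]], p[[2]], p[[3]]),
    torsion = torsion_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  )
}

.coords_table <- function(coords) {
  if (inherits(coords, "ligand_cluster")) {
    coords <- coords$atoms[coords$atoms$role == "ligand", , drop = FALSE]
  }
  if (inherits(coords, "xtal_model")) coords <- coords$atoms
  coords <- as.data.frame(coords, stringsAsFactors = FALSE)
  if (is.null(coords$name) || is.null(coords$x)) {
    abort("coords must provide columns name, x, y, z")
  }
  coords
}

#' Geometry deviation report of coordinates against a restraint dictionary
#'
#' Measures every bond, angle and torsion restraint of `dictionary` on the
#' supplied coordinates and reports signed deviations
#' (`delta = target - actual`, torsions periodicity-aware), per-category
#' root-mean-square deviations and outlier flags.
#'
#' @param coords Atom coordinates: a tibble with `name`, `x`, `y`, `z`
#'   (e.g. the ligand rows of a cluster), an `xtal_model`, or a
#'   `ligand_cluster` (its ligand atoms are used).
#' @param dictionary A [restraint_dictionary()].
#' @param cutoffs Named outlier cutoffs, default `c(bond = 0.02, angle = 5,
#'   torsion = 30)` (Angstrom, degrees, degrees).
#' @param include_h Include restraints involving hydrogen atoms in the
#'   records and statistics; default `FALSE` (heavy-atom statistics).
#' @return Object of class `geometry_report`: list with `records` (tibble
#'   of per-restraint deviations), `rmsd` (per-category tibble), `cutoffs`,
#'   `include_h`.
#' @export
geometry_report <- function(coords, dictionary,
                            cutoffs = c(bond = 0.02, angle = 5, torsion = 30),
                            include_h = FALSE) {
  stopifnot(inherits(dictionary, "restraint_dictionary"))
  coords <- .coords_table(coords)
  roster <- dictionary$atoms
  is_h <- setNames(roster$element %in% c("H", "D"), roster$name)
  idx_of <- setNames(match(roster$name, coords$name), roster$name)
  xyz <- as.matrix(coords[, c("x", "y", "z")])

  recs <- list()
  add_rec <- function(kind, names_vec, target, period = 1L, alts = NULL) {
    hflag <- any(is_h[names_vec])
    if (!include_h && hflag) return()
    ii <- idx_of[names_vec]
    if (any(is.na(ii))) {
      abort(sprintf(
        "coordinates missing for atom(s) %s required by a %s restraint",
        paste(names_vec[is.na(ii)], collapse = ", "), kind
      ))
    }
    actual <- .measure_restraint(kind, ii, xyz)
    delta <- signed_deviation(kind, target, actual, period, alts)
    recs[[length(recs) + 1L]] <<- tibble::tibble(
      kind = kind,
      atoms = paste(names_vec, collapse = "—"),
      target = target,
      actual = if (kind == "torsion") wrap_angle(actual) else actual,
      delta = delta,
      involves_h = hflag
    )
  }
  b <- dictionary$bonds
  for (i in seq_len(nrow(b))) {
    add_rec("bond", c(b$atom1[i], b$atom2[i]), b$target[i])
  }
  an <- dictionary$angles
  for (i in seq_len(nrow(an))) {
    add_rec("angle", c(an$atom1[i], an$atom2[i], an$atom3[i]), an$target[i])
  }
  to <- dictionary$torsions
  for (i in seq_len(nrow(to))) {
    add_rec(
      "torsion", c(to$atom1[i], to$atom2[i], to$atom3[i], to$atom4[i]),
      to$target[i], to$period[i], to$alternatives[[i]]
    )
  }
  records <- if (length(recs)) dplyr::bind_rows(recs) else tibble::tibble(
    kind = character(), atoms = character(), target = numeric(),
    actual = numeric(), delta = numeric(), involves_h = logical()
  )
  records$abs_delta <- abs(records$delta)
  records$is_outlier <- records$abs_delta > cutoffs[records$kind]
  rmsd <- dplyr::summarise(
    dplyr::group_by(records, .data$kind),
    n = dplyr::n(),
    rmsd = sqrt(mean(.data$delta^2)),
    max_abs = max(.data$abs_delta),
    n_outliers = sum(.data$is_outlier),
    .groups = "drop"
  )
  for (k in c("bond", "angle", "torsion")) {
    if (!k %in% rmsd$kind) {
      rmsd <- dplyr::bind_rows(rmsd, tibble::tibble(
        kind = k, n = 0L, rmsd = NA_real_, max_abs = NA_real_, n_outliers = 0L
      ))
    }
  }
  rmsd <- rmsd[match(c("bond", "angle", "torsion"), rmsd$kind), ]
  structure(
    list(
      records = records, rmsd = rmsd, cutoffs = cutoffs,
      include_h = include_h, comp_id = dictionary$comp_id
    ),
    class = "geometry_report"
  )
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf(
    "<geometry_report %s: %d restraints measured (%s H)>\n",
    x$comp_id, nrow(x$records), if (x$include_h) "incl." else "excl."
  ))
  r <- x$rmsd
  for (i in seq_len(nrow(r))) {
    unit <- if (r$kind[i] == "bond") "Å" else "°"
    cat(sprintf(
      "  %-8s n=%3d  rmsd=%s%s  outliers=%d\n",
      r$kind[i], r$n[i],
      ifelse(is.na(r$rmsd[i]), "--", sprintf("%.3f", r$rmsd[i])), unit,
      r$n_outliers[i]
    ))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.geometry_report <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.geometry_report <- function(x, ...) {
  r <- x$rmsd
  tibble::tibble(
    comp_id = x$comp_id,
    n_bonds = r$n[r$kind == "bond"],
    n_angles = r$n[r$kind == "angle"],
    n_torsions = r$n[r$kind == "torsion"],
    rmsd_bonds = r$rmsd[r$kind == "bond"],
    rmsd_angles = r$rmsd[r$kind == "angle"],
    rmsd_torsions = r$rmsd[r$kind == "torsion"],
    n_outliers = sum(r$n_outliers),
    include_h = x$include_h
  )
}

#' Outlier table of a geometry report
#'
#' Rows whose absolute deviation exceeds the category cutoff, in the
#' Target / Actual / Delta layout used for worked examples.
#'
#' @param report A `geometry_report`.
#' @return Tibble of outlier records.
#' @export
outlier_table <- function(report) {
  stopifnot(inherits(report, "geometry_report"))
  dplyr::arrange(
    dplyr::filter(report$records, .data$is_outlier),
    .data$kind, dplyr::desc(.data$abs_delta)
  )
}

# Default resolution bin edges: a wide high-resolution bin 0.8-1.4, then
# 0.2-wide bins up to 3.0 Angstrom.
resolution_bin_edges <- function() c(0.8, seq(1.4, 3.0, by = 0.2))

#' Resolution-binned r.m.s.d. summary with s.e.m. and per-bin Welch tests
#'
#' Averages a per-ligand r.m.s.d. column in resolution bins (first bin
#' 0.8-1.4 Angstrom, then 0.2-wide bins to 3.0; right-closed intervals),
#' reporting n, mean and standard error of the mean per condition, plus a
#' Welch two-sample t-test p-value between the two conditions per bin when
#' both have at least two entries.
#'
#' @param data Tibble with columns `resolution`, `rmsd` and `condition`
#'   (two levels, e.g. baseline vs in-situ restraints).
#' @param edges Bin edges; defaults to the standard layout.
#' @return Tibble of class `qmr_binned_summary` with one row per bin and
#'   condition, and a `p_value` column repeated within bins.
#' @export
binned_summary <- function(data, edges = resolution_bin_edges()) {
  data <- tibble::as_tibble(data)
  req <- c("resolution", "rmsd", "condition")
  if (!all(req %in% names(data))) {
    abort("data must have columns resolution, rmsd, condition")
  }
  if (any(data$resolution <= min(edges) | data$resolution > max(edges))) {
    abort(sprintf(
      "resolutions must lie in (%.1f, %.1f]", min(edges), max(edges)
    ))
  }
  data$bin <- cut(data$resolution, breaks = edges, right = TRUE, dig.lab = 3)
  sm <- dplyr::summarise(
    dplyr::group_by(data, .data$bin, .data$condition),
    n = dplyr::n(),
    mean = mean(.data$rmsd),
    sem = if (dplyr::n() >= 2) sd(.data$rmsd) / sqrt(dplyr::n()) else NA_real_,
    .groups = "drop"
  )
  conds <- unique(data$condition)
  pvals <- vapply(levels(data$bin), function(b) {
    if (length(conds) != 2) return(NA_real_)
    x <- data$rmsd[data$bin == b & data$condition == conds[1]]
    y <- data$rmsd[data$bin == b & data$condition == conds[2]]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  sm$p_value <- pvals[as.character(sm$bin)]
  class(sm) <- c("qmr_binned_summary", class(sm))
  sm
}
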