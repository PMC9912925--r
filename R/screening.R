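# Test-case selection rules: reusable, auditable screening of ligand
# instances by resolution, environment cleanliness, map-model correlation,
# size, charge, geometric-strain triggers and a common-solvent exclusion
# list. Every criterion is logged with the observed value, so a verdict is
# a full audit trail, and a missing metadata field yields an indeterminate
# verdict rather than a silent pass.

.default_solvents <- c(
  "MES", "PEG", "PGE", "PG4", "EDO", "GOL", "DMS", "ACT", "FMT",
  "SO4", "PO4", "EPE", "TRS", "MPD"
)

#' Is a component a common crystallization-solution molecule?
#'
#' Membership in a user-extensible exclusion list seeded with frequent
#' buffer, cryoprotectant and precipitant components (MES, PEG fragments,
#' glycerol, sulfate, ...). Matching is case-insensitive.
#'
#' @param comp_id Component code(s).
#' @param extra Additional codes to exclude.
#' @return Logical vector.
#' @export
is_common_solvent <- function(comp_id, extra = NULL) {
  toupper(comp_id) %in% toupper(c(.default_solvents, extra))
}

#' Screen one ligand instance
#'
#' Criteria (all bounds inclusive):
#' resolution at most 3.0 Angstrom; clean environment (no other ligands,
#' metals or altlocs within 5.5 Angstrom, no missing atoms within 3.5);
#' map-model correlation at least 0.7; 8 to 40 non-hydrogen atoms; total
#' charge in \{-1, 0, +1\}; at least one geometric-strain trigger (mean
#' bond r.m.s.d. >= 0.2 Angstrom OR angle r.m.s.d. >= 5 degrees OR torsion
#' r.m.s.d. >= 30 degrees); component not a common solvent.
#'
#' @param meta Named list or one-row data frame with `comp_id`,
#'   `resolution`, `map_cc`, `non_h_atoms`, `formal_charge`,
#'   `mean_rmsd_bonds`, `mean_rmsd_angles`, `mean_rmsd_torsions`.
#' @param env An [validate_environment()] report (or NULL to leave the
#'   environment criterion indeterminate).
#' @param solvent_extra Extra component codes treated as solvent.
#' @return Object of class `screening_verdict`: tibble of per-criterion
#'   reasons with attributes `passed` (TRUE/FALSE/NA when indeterminate).
#' @export
screen_ligand <- function(meta, env = NULL, solvent_extra = NULL) {
  meta <- as.list(meta)
  get_num <- function(field) {
    v <- meta[[field]]
    if (is.null(v) || length(v) != 1 || is.na(v)) NA_real_ else as.numeric(v)
  }
  rows <- list()
  add <- function(criterion, observed, threshold, status) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      criterion = criterion,
      status = status,
      observed = as.character(observed),
      threshold = threshold
    )
  }
  judge <- function(criterion, value, threshold, ok) {
    status <- if (is.na(value)) "indeterminate" else if (ok) "pass" else "fail"
    add(criterion, if (is.na(value)) "missing" else value, threshold, status)
  }
  res <- get_num("resolution")
  judge("resolution", res, "<= 3.0 A", isTRUE(res <= 3.0))
  if (is.null(env)) {
    add("environment", "missing", "clean within 5.5/3.5 A", "indeterminate")
  } else {
    add(
      "environment",
      if (env$clean) "clean" else paste(
        unique(env$offenders$check),
        collapse = ","
      ),
      "clean within 5.5/3.5 A",
      if (env$clean) "pass" else "fail"
    )
  }
  cc <- get_num("map_cc")
  judge("map_cc", cc, ">= 0.7", isTRUE(cc >= 0.7))
  nh <- get_num("non_h_atoms")
  judge("size", nh, "8..40 non-H atoms", isTRUE(nh >= 8 && nh <= 40))
  q <- get_num("formal_charge")
  judge("charge", q, "in {-1,0,+1}", isTRUE(q %in% c(-1, 0, 1)))
  rb <- get_num("mean_rmsd_bonds")
  ra <- get_num("mean_rmsd_angles")
  rt <- get_num("mean_rmsd_torsions")
  if (all(is.na(c(rb, ra, rt)))) {
    add("rmsd_trigger", "missing", ">= 0.2 A | >= 5 deg | >= 30 deg", "indeterminate")
  } else {
    trig <- isTRUE(rb >= 0.2) || isTRUE(ra >= 5) || isTRUE(rt >= 30)
    add(
      "rmsd_trigger",
      sprintf("%.3g A / %.3g deg / %.3g deg", rb, ra, rt),
      ">= 0.2 A | >= 5 deg | >= 30 deg",
      if (trig) "pass" else "fail"
    )
  }
  comp <- meta$comp_id
  if (is.null(comp) || is.na(comp)) {
    add("solvent", "missing", "not a common solvent", "indeterminate")
  } else {
    solv <- is_common_solvent(comp, solvent_extra)
    add("solvent", comp, "not a common solvent", if (solv) "fail" else "pass")
  }
  reasons <- dplyr::bind_rows(rows)
  passed <- if (any(reasons$status == "fail")) {
    FALSE
  } else if (any(reasons$status == "indeterminate")) {
    NA
  } else {
    TRUE
  }
  structure(reasons,
    passed = passed,
    class = c("screening_verdict", class(reasons))
  )
}

#' @export
print.screening_verdict <- function(x, ...) {
  p <- attr(x, "passed")
  cat(sprintf(
    "<screening_verdict: %s>\n",
    if (isTRUE(p)) "PASS" else if (isFALSE(p)) "FAIL" else "INDETERMINATE"
  ))
  NextMethod()
}

#' @exportS3Method generics::glance
glance.screening_verdict <- function(x, ...) {
  tibble::tibble(
    passed = attr(x, "passed"),
    n_fail = sum(x$status == "fail"),
    n_indeterminate = sum(x$status == "indeterminate"),
    failed_criteria = paste(x$criterion[x$status == "fail"], collapse = ",")
  )
}

#' Screen a table of ligand instances
#'
#' Vectorized wrapper over [screen_ligand()] for metadata tables read from
#' TSV/CSV; environment reports are not consulted (that criterion stays
#' indeterminate unless `assume_clean_env = TRUE`).
#'
#' @param meta Data frame with one row per ligand instance.
#' @param assume_clean_env Treat the environment criterion as passed
#'   (useful when the table was pre-filtered).
#' @param solvent_extra Extra solvent codes.
#' @return The input tibble plus `passed` and `failed_criteria` columns.
#' @export
screen_ligand_table <- function(meta, assume_clean_env = FALSE,
                                solvent_extra = NULL) {
  meta <- tibble::as_tibble(meta)
  fake_env <- if (assume_clean_env) {
    structure(
      list(clean = TRUE, offenders = tibble::tibble(check = character())),
      class = "environment_report"
    )
  } else {
    NULL
  }
  out <- purrr::map(seq_len(nrow(meta)), function(i) {
    v <- screen_ligand(meta[i, ], env = fake_env, solvent_extra = solvent_extra)
    glance(v)
  })
  dplyr::bind_cols(meta, dplyr::bind_rows(out))
}

#' Entry-level model pre-filters
#'
#' Screens a whole model before per-ligand criteria: molecular weight
#' below 2000 kDa, no RNA/DNA residues, and at least one ligand-kind
#' residue present.
#'
#' @param model An `xtal_model`.
#' @return One-row tibble with the three predicates and `passed`.
#' @export
prefilter_model <- function(model) {
  stopifnot(inherits(model, "xtal_model"))
  a <- model$atoms
  mw <- sum(atomic_weight(a$element))
  has_na <- any(a$kind == "nucleotide")
  has_ligand <- any(a$kind == "ligand")
  tibble::tibble(
    id = model$id,
    molecular_weight_da = mw,
    weight_ok = mw < 2e6,
    no_nucleic_acid = !has_na,
    has_ligand = has_ligand,
    passed = mw < 2e6 && !has_na && has_ligand
  )
}
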