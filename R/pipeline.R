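# End-to-end orchestration: build -> validate -> cap -> protonate ->
# optimize -> generate restraints -> report, with optional persisted
# intermediates (cluster PDB, optimization cache, restraint CIF, TSV/JSON
# reports).

#' Run the full in-situ restraint-generation pipeline
#'
#' Executes, in order: environment validation, cluster construction at
#' `radius`, dangling-bond capping, water protonation, geometry
#' optimization with the requested backend, in-situ restraint generation
#' from the optimized ligand, and geometry reports. The before-report
#' measures the input (deposited-like) ligand against the base
#' dictionary; the after-report measures the optimized ligand against the
#' generated restraints; `report_optimized_vs_base` measures the optimized
#' geometry against the unchanged base targets.
#'
#' If the ligand's hydrogen count disagrees with the dictionary roster a
#' warning is issued (ligand protonation is accepted as given, never
#' invented).
#'
#' @param model An `xtal_model`.
#' @param ligand A [ligand_selector()].
#' @param base The base [restraint_dictionary()].
#' @param radius Cluster selection radius (Angstrom).
#' @param mode Capping mode, `"neutral"` or `"zwitterion"`.
#' @param backend `"builtin"` or an `"external:<engine>"` method string.
#' @param mobile Optional explicit mobile serials.
#' @param side_chains Let native side chains co-optimize.
#' @param max_steps,convergence_grad Minimizer controls.
#' @param include_h Include hydrogen-containing restraints in reports.
#' @param cutoffs Outlier cutoffs for reports.
#' @param cache_dir Optional optimization cache directory.
#' @param runner External-engine runner (see [optimize_cluster()]).
#' @param out_dir Optional directory to persist intermediates.
#' @return Object of class `qmr_result`: `qmr_dictionary`,
#'   `report_before`, `report_after`, `report_optimized_vs_base`,
#'   `environment`, `cluster`, `optimization`.
#' @export
run_qmr_pipeline <- function(model, ligand, base, radius = 3.5,
                             mode = "neutral", backend = "builtin",
                             mobile = NULL, side_chains = FALSE,
                             max_steps = 10000L, convergence_grad = 1e-2,
                             include_h = FALSE,
                             cutoffs = c(bond = 0.02, angle = 5, torsion = 30),
                             cache_dir = NULL, runner = NULL, out_dir = NULL) {
  stopifnot(inherits(model, "xtal_model"), inherits(base, "restraint_dictionary"))
  dicts <- setNames(list(base), ligand$comp_id)
  stage <- "validate"
  result <- tryCatch(
    {
      connectivity <- infer_connectivity(model, dicts)
      env <- validate_environment(model, ligand,
        connectivity = connectivity,
        dictionaries = dicts
      )
      stage <- "cluster"
      cluster <- build_ligand_cluster(
        model, ligand,
        radius = radius,
        connectivity = connectivity, dictionaries = dicts
      )
      lig_atoms <- cluster$atoms[cluster$atoms$role == "ligand", , drop = FALSE]
      n_h_model <- sum(lig_atoms$is_hydrogen)
      n_h_dict <- sum(base$atoms$element %in% c("H", "D"))
      if (n_h_model != n_h_dict) {
        warn(sprintf(
          paste0(
            "ligand %s carries %d hydrogens but the dictionary roster ",
            "declares %d; the model's protonation is used as given"
          ),
          ligand$comp_id, n_h_model, n_h_dict
        ))
      }
      stage <- "cap"
      cluster <- cap_dangling_bonds(cluster, mode)
      stage <- "protonate"
      cluster <- protonate_waters(cluster)
      stage <- "optimize"
      job <- optimization_job(
        cluster, base,
        mobile = mobile, method = backend,
        max_steps = max_steps, convergence_grad = convergence_grad,
        side_chains = side_chains
      )
      opt <- optimize_cluster(job, cache_dir = cache_dir, runner = runner)
      stage <- "restraints"
      qmr <- generate_qmr_restraints(opt$cluster, base)
      stage <- "report"
      before <- geometry_report(lig_atoms, base,
        cutoffs = cutoffs, include_h = include_h
      )
      after <- geometry_report(opt$cluster, qmr,
        cutoffs = cutoffs, include_h = include_h
      )
      opt_vs_base <- geometry_report(opt$cluster, base,
        cutoffs = cutoffs, include_h = include_h
      )
      list(
        qmr_dictionary = qmr, report_before = before, report_after = after,
        report_optimized_vs_base = opt_vs_base, environment = env,
        cluster = opt$cluster, optimization = opt, ligand = ligand
      )
    },
    error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    }
  )
  out <- structure(result, class = "qmr_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cluster_pdb(out$cluster, file.path(out_dir, "cluster.pdb"))
    write_restraint_cif(out$qmr_dictionary, file.path(out_dir, "qmr_restraints.cif"))
    utils::write.table(
      tidy(out$report_before),
      file.path(out_dir, "report_before.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    utils::write.table(
      tidy(out$report_after),
      file.path(out_dir, "report_after.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    jsonlite::write_json(
      list(
        before = glance(out$report_before),
        after = glance(out$report_after),
        optimized_vs_base = glance(out$report_optimized_vs_base),
        environment = glance(out$environment),
        optimization = glance(out$optimization)
      ),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  out
}

#' @export
print.qmr_result <- function(x, ...) {
  cat(sprintf(
    "<qmr_result %s/%s/%d>\n",
    x$ligand$chain_id, x$ligand$comp_id, x$ligand$seq_id
  ))
  g0 <- glance(x$report_before)
  g1 <- glance(x$report_after)
  cat(sprintf(
    "  before (vs base):   bond %.3f Å  angle %.2f°  torsion %.1f°\n",
    g0$rmsd_bonds, g0$rmsd_angles, g0$rmsd_torsions
  ))
  cat(sprintf(
    "  after  (vs in-situ): bond %.3f Å  angle %.2f°  torsion %.1f°\n",
    g1$rmsd_bonds, g1$rmsd_angles, g1$rmsd_torsions
  ))
  cat(sprintf(
    "  optimization: %d steps, %s; environment %s\n",
    x$optimization$n_steps,
    if (x$optimization$converged) "converged" else "not converged",
    if (x$environment$clean) "clean" else "flagged"
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.qmr_result <- function(x, ...) {
  g0 <- glance(x$report_before)
  g1 <- glance(x$report_after)
  gb <- glance(x$report_optimized_vs_base)
  tibble::tibble(
    comp_id = x$ligand$comp_id,
    rmsd_bonds_before = g0$rmsd_bonds,
    rmsd_angles_before = g0$rmsd_angles,
    rmsd_torsions_before = g0$rmsd_torsions,
    rmsd_bonds_after = g1$rmsd_bonds,
    rmsd_angles_after = g1$rmsd_angles,
    rmsd_torsions_after = g1$rmsd_torsions,
    rmsd_torsions_optimized_vs_base = gb$rmsd_torsions,
    converged = x$optimization$converged,
    environment_clean = x$environment$clean
  )
}

#' @exportS3Method generics::tidy
tidy.qmr_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$report_before), condition = "base"),
    dplyr::mutate(tidy(x$report_after), condition = "in_situ")
  )
}
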