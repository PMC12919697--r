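# End-to-end workflow: one plain-text (YAML) configuration drives a full
# experiment; every artifact is written with provenance (config hash, seed,
# package version) and identical config + seed gives byte-identical outputs.

#' Read a run configuration
#'
#' YAML file (or list) with fields: `seed`, `technique` (pbs/cover/block),
#' `phantom` (arguments of [phantom_spec()] or a `file` path to a phantom
#' archive), `beams` (list of gantry/collimator/air_gap entries),
#' `objectives` (overrides of [default_objectives()]), `robustness`
#' (`setup_mm`, `range_frac`), `optimizer` (`max_iter`, `tol`),
#' `evaluate_scenarios` (logical), `out_dir`.
#'
#' @param path YAML file path.
#' @return config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Run the full planning pipeline
#'
#' phantom -> energy layers -> leaf sequencing (per technique) -> spot
#' placement -> worst-case robust optimization -> dose -> scenario metrics.
#' Writes plan, spot table, aperture tables (collimated techniques only),
#' metric table, report and a provenance manifest into `out_dir`. Aborts
#' (after writing the feasibility report) when a block configuration fully
#' shields part of the target in every beam.
#'
#' @param config list or `run_config` (see [read_run_config()]).
#' @return (invisibly) list with the plan, metrics and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  technique <- match.arg(cfg$technique %||% "pbs",
                         c("pbs", "cover", "block"))
  if (!is.null(cfg$phantom$file)) {
    phantom <- read_phantom(cfg$phantom$file)
  } else {
    spargs <- cfg$phantom %||% list()
    phantom <- make_phantom(do.call(phantom_spec, spargs), seed = seed)
  }
  beams <- lapply(cfg$beams %||% list(list(gantry = 0)), function(bc)
    beam_config(bc$gantry %||% 0, bc$collimator %||% 0,
                air_gap_mm = bc$air_gap %||% 30))
  objectives <- do.call(default_objectives, cfg$objectives %||% list())
  rb <- cfg$robustness %||% list()
  scenarios <- generate_scenarios(rb$setup_mm %||% 2.0,
                                  rb$range_frac %||% 0.035)
  oc <- cfg$optimizer %||% list()
  plan <- make_plan(phantom, beams, technique, objectives = objectives,
                    scenarios = scenarios,
                    max_iter = oc$max_iter %||% 600, tol = oc$tol %||% 1e-5,
                    on_infeasible = "error", seed = seed)
  paths <- list(plan = file.path(out_dir, "plan.rds"),
                spots = file.path(out_dir, "spots.txt"),
                metrics = file.path(out_dir, "metrics.csv"),
                report = file.path(out_dir, "report.txt"),
                manifest = file.path(out_dir, "manifest.yaml"))
  saveRDS(plan, paths$plan)
  write_spots(plan_spot_table(plan), paths$spots)
  if (technique != "pbs") {
    for (b in seq_along(plan$states)) {
      st <- plan$states[[b]]
      paths[[paste0("apertures_beam", b)]] <-
        file.path(out_dir, sprintf("apertures_beam%d.txt", b))
      write_apertures(st$apertures,
                      vapply(st$layers, function(l) l$energy_mev,
                             numeric(1)),
                      paths[[paste0("apertures_beam", b)]])
    }
  }
  metrics <- NULL
  if (isTRUE(cfg$evaluate_scenarios %||% TRUE)) {
    metrics <- evaluate_scenarios(plan)
    write_metrics(metrics, paths$metrics)
  }
  writeLines(export_report(plan, metrics), paths$report)
  manifest <- list(package = "protonDMLC",
                   version = as.character(utils::packageVersion("protonDMLC")),
                   seed = seed, technique = technique,
                   config_hash = config_hash(cfg),
                   n_beams = length(beams),
                   n_spots = length(plan$weights),
                   optimizer_iterations = plan$optimizer$iterations)
  yaml::write_yaml(manifest, paths$manifest)
  invisible(list(plan = plan, metrics = metrics, paths = paths))
}

#' Human-readable plan report
#'
#' Summarizes the planning goals (CTV D98\% at least 95\% and D2\% at most
#' 107\% of the prescription) with PASS/FAIL flags, per-scenario worst cases
#' when a metric table is supplied, and the block-mode feasibility result.
#'
#' @param plan a `dmlc_plan`.
#' @param metrics optional table from [evaluate_scenarios()].
#' @return character vector of report lines.
#' @export
export_report <- function(plan, metrics = NULL) {
  p <- plan$objectives$prescription_gy
  roles <- vapply(plan$phantom$structures, function(s) s$role, character(1))
  ctv <- plan$phantom$structures[[which(roles == "target")[1]]]
  d98 <- dvh_metric(plan$dose, ctv, "D98%") / p * 100
  d2 <- dvh_metric(plan$dose, ctv, "D2%") / p * 100
  lines <- c(sprintf("protonDMLC plan report  (technique: %s)",
                     plan$technique),
             sprintf("prescription: %.1f Gy(RBE) in %d fractions", p,
                     plan$objectives$fractions),
             sprintf("CTV D98%% = %.1f%% of prescription (goal >= 95%%): %s",
                     d98, if (d98 >= 95) "PASS" else "FAIL"),
             sprintf("CTV D2%%  = %.1f%% of prescription (goal <= 107%%): %s",
                     d2, if (d2 <= 107) "PASS" else "FAIL"))
  if (!is.null(plan$feasibility))
    lines <- c(lines, sprintf(
      "block feasibility: %s (%d target voxel(s) shielded in every beam)",
      if (plan$feasibility$feasible) "feasible" else "INFEASIBLE",
      plan$feasibility$n_blocked))
  if (is.null(metrics) || !nrow(metrics)) {
    lines <- c(lines, "scenario table: not evaluated")
  } else {
    lines <- c(lines, "worst-case scenario metrics:")
    for (nm in unique(metrics$structure)) {
      sb <- metrics[metrics$structure == nm, ]
      lines <- c(lines, sprintf(
        "  %-12s D98 [%.1f, %.1f]  D2 [%.1f, %.1f]  Dmean [%.1f, %.1f] Gy",
        nm, min(sb$D98), max(sb$D98), min(sb$D2), max(sb$D2),
        min(sb$Dmean), max(sb$Dmean)))
    }
  }
  lines
}
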