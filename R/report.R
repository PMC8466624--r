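#' Run the full model-ensemble assessment workflow
#'
#' Orchestrates the whole analysis for one query under one or more modeling
#' scenarios, using synthetic ensembles in place of an external modeling
#' engine: for each scenario it generates the ensemble, assigns PB
#' sequences, computes the per-position frequency profile and Neq, selects
#' the best model by the synthetic quality score, and measures global RMSD,
#' region-wise RMSD (both fitting modes), CDR loop-termini distances (native
#' and best model) and Ramachandran fractions of the best model.
#'
#' @param config named list, or path to a YAML/JSON file, with fields:
#'   \describe{
#'     \item{sequence}{amino-acid string of the query;}
#'     \item{reference_pb}{PB string defining the native conformation;}
#'     \item{regions}{named list of seven FR/CDR ranges (see
#'       [region_map()]), or `"auto"` for the anchor heuristic;}
#'     \item{scenarios}{named list; each entry a list with `kappa_fr`,
#'       `kappa_cdr` (von Mises concentrations applied outside/inside CDR
#'       segments) or an explicit `kappa` vector, plus optional `n_models`
#'       (default 100), `score_noise`, `score_scale`, and optional `anchor`
#'       (a region name such as `"CDR3"`, or a `c(start, end)` range) to use
#'       the anchored-loop construction of [generate_ensemble()];}
#'     \item{seed}{integer; scenario k uses `seed + k - 1`.}
#'   }
#' @param out_dir optional directory; when given, the report tables are
#'   written there as CSV/TSV plus a JSON summary (only after the whole
#'   computation succeeded, so partial reports are never left behind).
#' @return Object of class `assessment_report`.
#' @export
assess_ensemble <- function(config, out_dir = NULL) {
  config <- .load_config(config)
  for (field in c("sequence", "reference_pb", "regions", "scenarios"))
    if (is.null(config[[field]]))
      stop("config stage: missing field '", field, "'")
  seed <- as.integer(config$seed %||% 1L)
  sequence <- config$sequence
  L <- nchar(sequence)
  regions <- tryCatch({
    if (identical(config$regions, "auto")) annotate_regions(sequence)
    else region_map(lapply(config$regions, as.integer), length = L)
  }, error = function(e) stop("regions stage: ", conditionMessage(e)))

  native <- tryCatch(
    chain_from_dihedrals(pb_string_to_dihedrals(config$reference_pb),
                         sequence),
    error = function(e) stop("reference stage: ", conditionMessage(e)))
  native_pb <- assign_pb_sequence(compute_backbone_dihedrals(native))
  cdr_names <- grep("^CDR", names(regions), value = TRUE)

  scen_names <- names(config$scenarios)
  if (is.null(scen_names) || !all(nzchar(scen_names)))
    stop("config stage: scenarios must be named")
  per_scenario <- list()
  for (k in seq_along(scen_names)) {
    nm <- scen_names[k]
    sc <- config$scenarios[[k]]
    kappa <- .scenario_kappa(sc, regions, L)
    spec <- ensemble_spec(sequence = sequence,
                          reference_pb = config$reference_pb,
                          kappa = kappa,
                          n_models = as.integer(sc$n_models %||% 100L),
                          seed = seed + k - 1L,
                          score_noise = sc$score_noise %||% 0.05,
                          score_scale = sc$score_scale %||% 1)
    anchor <- sc$anchor
    if (is.character(anchor)) {
      if (!anchor %in% names(regions))
        stop("scenario '", nm, "' stage: unknown anchor region ", anchor)
      anchor <- regions[[anchor]]
    }
    per_scenario[[nm]] <- tryCatch(
      .assess_one_scenario(spec, native, native_pb, regions, cdr_names,
                           anchor),
      error = function(e)
        stop("scenario '", nm, "' stage: ", conditionMessage(e)))
  }
  report <- structure(list(
    query = list(sequence = sequence, reference_pb = config$reference_pb,
                 native_pb = pb_string(native_pb), length = L),
    regions = regions,
    seed = seed,
    config_hash = .config_hash(config),
    scenarios = per_scenario), class = "assessment_report")
  if (!is.null(out_dir)) write_assessment_report(report, out_dir)
  report
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config stage: file not found: ", config)
    config <- if (grepl("\\.(yml|yaml)$", config)) yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config stage: config must be a list or path")
  config
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

.scenario_kappa <- function(sc, regions, L) {
  if (!is.null(sc$kappa)) return(rep_len(as.numeric(sc$kappa), L))
  kfr <- as.numeric(sc$kappa_fr %||% 500)
  kcdr <- as.numeric(sc$kappa_cdr %||% 2)
  kappa <- rep(kfr, L)
  for (nm in grep("^CDR", names(regions), value = TRUE)) {
    r <- regions[[nm]]
    kappa[r[1]:r[2]] <- kcdr
  }
  kappa
}

.assess_one_scenario <- function(spec, native, native_pb, regions,
                                 cdr_names, anchor = NULL) {
  ens <- generate_ensemble(spec, anchor = anchor)
  pbs <- ensemble_pb_strings(ens)
  profile <- pb_frequency_profile(pbs)
  neq <- neq_profile(profile)
  scores <- stats::setNames(ens$scores$score, ens$scores$model_id)
  best_id <- select_best_model(scores)
  best <- ens$models[[best_id]]
  global <- superpose_calpha(best, native)$rmsd
  termini <- lapply(stats::setNames(cdr_names, cdr_names), function(nm) {
    c(native = loop_termini_distance(native, regions[[nm]]),
      model = loop_termini_distance(best, regions[[nm]]))
  })
  list(spec = spec,
       scores = ens$scores,
       profile = profile,
       neq = neq,
       pb_best_model = pb_string(
         assign_pb_sequence(compute_backbone_dihedrals(best))),
       best_model_id = best_id,
       global_rmsd = global,
       region_rmsd_local = region_rmsd(best, native, regions, "local_fit"),
       region_rmsd_frame = region_rmsd(best, native, regions, "frame_fit"),
       cdr_termini = termini,
       ramachandran = ramachandran_fractions(
         compute_backbone_dihedrals(best)))
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("<assessment_report> %d-residue query, %d scenario(s)\n",
              x$query$length, length(x$scenarios)))
  for (nm in names(x$scenarios))
    cat(sprintf("  %s: best %s, global rmsd %.3f A\n", nm,
                x$scenarios[[nm]]$best_model_id,
                x$scenarios[[nm]]$global_rmsd))
  invisible(x)
}

#' Write an assessment report to disk
#'
#' Emits, per scenario, the per-position statistics (Neq) CSV, the PB map
#' TSV and the model score table, plus a report-level region-RMSD CSV,
#' CDR-termini CSV and a JSON summary with provenance (seed, config hash,
#' schema version). Tables carry explicit column headers.
#'
#' @param report an [assess_ensemble()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_assessment_report <- function(report, dir) {
  stopifnot(inherits(report, "assessment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$scenarios)) {
    sc <- report$scenarios[[nm]]
    utils::write.csv(data.frame(position = seq_along(sc$neq), neq = sc$neq),
                     file.path(dir, paste0("neq_", nm, ".csv")),
                     row.names = FALSE)
    write_pb_map(pb_map(sc$profile),
                 file.path(dir, paste0("pb_map_", nm, ".tsv")))
    utils::write.csv(sc$scores,
                     file.path(dir, paste0("scores_", nm, ".csv")),
                     row.names = FALSE)
  }
  rr <- do.call(rbind, lapply(names(report$scenarios), function(nm) {
    sc <- report$scenarios[[nm]]
    data.frame(scenario = nm,
               region = names(sc$region_rmsd_local),
               rmsd_local = unname(sc$region_rmsd_local),
               rmsd_frame = unname(sc$region_rmsd_frame))
  }))
  utils::write.csv(rr, file.path(dir, "region_rmsd.csv"), row.names = FALSE)
  td <- do.call(rbind, lapply(names(report$scenarios), function(nm) {
    sc <- report$scenarios[[nm]]
    do.call(rbind, lapply(names(sc$cdr_termini), function(cd)
      data.frame(scenario = nm, cdr = cd,
                 native = sc$cdr_termini[[cd]]["native"],
                 model = sc$cdr_termini[[cd]]["model"],
                 row.names = NULL)))
  }))
  utils::write.csv(td, file.path(dir, "cdr_termini.csv"), row.names = FALSE)
  summary <- list(
    schema_version = "1.0",
    seed = report$seed,
    config_hash = report$config_hash,
    query_length = report$query$length,
    regions = lapply(report$regions, as.integer),
    scenarios = lapply(report$scenarios, function(sc) list(
      best_model_id = sc$best_model_id,
      global_rmsd = sc$global_rmsd,
      ramachandran = as.list(sc$ramachandran))))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Compare two assessment reports position by position
#'
#' For every scenario name present in both reports, computes the
#' per-position signed delta-Neq and the delta-PB profile distance between
#' the two ensembles, and flags positions whose delta-PB exceeds 1 (more
#' than half the maximal profile disagreement).
#'
#' @param report_a,report_b [assess_ensemble()] results over the same query
#'   length.
#' @param flag_threshold delta-PB value above which a position is flagged
#'   (default 1).
#' @return Named list (one entry per shared scenario) of data frames with
#'   columns `position`, `delta_neq`, `delta_pb`, `flagged`.
#' @export
compare_reports <- function(report_a, report_b, flag_threshold = 1) {
  stopifnot(inherits(report_a, "assessment_report"),
            inherits(report_b, "assessment_report"))
  if (report_a$query$length != report_b$query$length)
    stop("reports cover different query lengths")
  shared <- intersect(names(report_a$scenarios), names(report_b$scenarios))
  if (!length(shared)) stop("reports share no scenario names")
  out <- lapply(stats::setNames(shared, shared), function(nm) {
    pa <- report_a$scenarios[[nm]]$profile
    pb <- report_b$scenarios[[nm]]$profile
    dpb <- delta_pb(pa, pb)
    data.frame(position = seq_along(dpb),
               delta_neq = delta_neq(pa, pb),
               delta_pb = dpb,
               flagged = !is.na(dpb) & dpb > flag_threshold)
  })
  out
}

#' All pairwise comparisons among several reports
#'
#' @param reports named list of [assess_ensemble()] results.
#' @param ... passed to [compare_reports()].
#' @return Named list with one [compare_reports()] result per unordered pair
#'   (`"A.vs.B"`).
#' @export
compare_all <- function(reports, ...) {
  if (length(reports) < 2L) stop("need at least two reports")
  nms <- names(reports) %||% paste0("report", seq_along(reports))
  out <- list()
  for (i in seq_len(length(reports) - 1L)) for (j in (i + 1L):length(reports))
    out[[paste0(nms[i], ".vs.", nms[j])]] <-
      compare_reports(reports[[i]], reports[[j]], ...)
  out
}

#' Compare scenario pairs within one report
#'
#' The within-report analogue of [compare_reports()]: delta-Neq and
#' delta-PB between every unordered pair of scenarios of a single
#' assessment, the comparison used to ask which regions two template
#' choices sample differently.
#'
#' @param report an [assess_ensemble()] result with >= 2 scenarios.
#' @param flag_threshold delta-PB flagging threshold (default 1).
#' @return Named list of data frames as in [compare_reports()].
#' @export
compare_scenarios <- function(report, flag_threshold = 1) {
  stopifnot(inherits(report, "assessment_report"))
  nms <- names(report$scenarios)
  if (length(nms) < 2L) stop("report holds fewer than two scenarios")
  out <- list()
  for (i in seq_len(length(nms) - 1L)) for (j in (i + 1L):length(nms)) {
    pa <- report$scenarios[[nms[i]]]$profile
    pb <- report$scenarios[[nms[j]]]$profile
    dpb <- delta_pb(pa, pb)
    out[[paste0(nms[i], ".vs.", nms[j])]] <-
      data.frame(position = seq_along(dpb),
                 delta_neq = delta_neq(pa, pb),
                 delta_pb = dpb,
                 flagged = !is.na(dpb) & dpb > flag_threshold)
  }
  out
}
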