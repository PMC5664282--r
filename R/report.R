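#' Report rendering and pipeline entry points
#'
#' Thin orchestration over the validation and screening modules: read
#' delimited inputs, run the calculus, write a human-readable report table
#' (mirroring the published layout: `Fc > T` / `Fc < T`, `<C_val` / `>C_val`,
#' LOD with a `<1` reporting floor, integer sensitivity) next to a
#' machine-readable full-precision export, plus a run manifest for
#' reproducibility.
#'
#' @name reporting
#' @keywords internal
NULL

#' Render a validation report table
#'
#' @param results a `validation_result` data.frame from [validate_panel()].
#' @param lod_floor LODs below this value (ug/kg) are printed as
#'   `"<floor"` (default 1, matching the published reporting floor); full
#'   precision is kept in the machine-readable export.
#' @param digits decimals for printed LODs (default 2).
#' @return data.frame with the formatted columns `fc_vs_t`, `ccbeta`,
#'   `lod`, `sensitivity` per analyte/transition.
#' @export
format_validation_report <- function(results, lod_floor = 1, digits = 2) {
  stopifnot(inherits(results, "data.frame"))
  data.frame(
    analyte = results$analyte,
    transition = results$transition_rank,
    fc_vs_t = ifelse(results$fc > results$t_value, "Fc > T", "Fc < T"),
    ccbeta = ifelse(results$ccbeta_verdict == "below_level",
                    "<C_val", ">C_val"),
    lod = ifelse(results$lod < lod_floor,
                 sprintf("<%g", lod_floor),
                 formatC(results$lod, format = "f", digits = digits)),
    sensitivity = sprintf("%d", as.integer(round(results$sensitivity_pct))),
    stringsAsFactors = FALSE)
}

write_run_manifest <- function(out_dir, inputs, seed = NULL) {
  manifest <- list(
    package = "eggscreen",
    version = as.character(utils::packageVersion("eggscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, inputs = inputs)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Run a validation over a response table and write the report files
#'
#' @param input path to a delimited response table, or a response-record
#'   data.frame.
#' @param panel panel file path or an [analyte_panel()] (default: packaged
#'   egg panel).
#' @param out_dir output directory (created if missing).
#' @param design a [validation_design()].
#' @param lod_floor,digits rendering options, see
#'   [format_validation_report()].
#' @return invisibly, a list with `results` (full precision), `report`
#'   (formatted) and `ok` (`TRUE` when every transition passed, i.e. no
#'   `above_level` verdict -- the CLI exit status).
#' @export
run_validate <- function(input, panel = default_panel(), out_dir = ".",
                         design = validation_design(), lod_floor = 1,
                         digits = 2) {
  if (is.character(panel)) panel <- load_panel(panel)
  records <- if (is.character(input)) read_response_table(input)
             else as_response_table(input)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- validate_panel(records, panel, design)
  report <- format_validation_report(results, lod_floor, digits)
  utils::write.table(report, file.path(out_dir, "validation_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(results, file.path(out_dir, "validation_results.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  write_run_manifest(out_dir, inputs = list(
    input = if (is.character(input)) input else "<data.frame>",
    panel = panel$name, n_records = nrow(records)))
  ok <- all(results$ccbeta_verdict == "below_level")
  n_fail <- sum(results$ccbeta_verdict == "above_level")
  message(sprintf("validated %d analyte/transition pairs; %d above level",
                  nrow(results), n_fail))
  invisible(list(results = results, report = report, ok = ok))
}

#' Screen study samples and write call and timeline files
#'
#' Each study sample in the manifest is classified against the
#' positive-control replicates of the same analyte and day (the batch).
#' Per-group/analyte timelines report the last noncompliant day after
#' `treatment_end_day`.
#'
#' @param records response table (path or data.frame) containing study and
#'   positive-control records.
#' @param manifest batch manifest (path or data.frame), see
#'   [as_batch_manifest()].
#' @param validation a `validation_result` data.frame (or path to the JSON
#'   export of [run_validate()]).
#' @param panel panel file path or [analyte_panel()].
#' @param treatment_end_day last day of drug administration (default 5).
#' @param out_dir output directory; `NULL` skips file output.
#' @return invisibly, list with `calls` (one row per sample/analyte) and
#'   `timelines` (per group/analyte noncompliant-day counts).
#' @export
run_screen <- function(records, manifest, validation,
                       panel = default_panel(), treatment_end_day = 5,
                       out_dir = NULL) {
  if (is.character(panel)) panel <- load_panel(panel)
  if (is.character(records)) records <- read_response_table(records)
  else records <- as_response_table(records)
  if (is.character(manifest)) manifest <- read_batch_manifest(manifest)
  else manifest <- as_batch_manifest(manifest)
  if (is.character(validation))
    validation <- as.data.frame(jsonlite::read_json(validation,
                                                    simplifyVector = TRUE))

  study <- manifest[manifest$role == "study", ]
  calls <- list()
  for (i in seq_len(nrow(study))) {
    row <- study[i, ]
    samp <- records[records$sample_id == row$sample_id &
                      records$analyte == row$analyte, ]
    pc_ids <- manifest$sample_id[manifest$role == "positive_control" &
                                   manifest$analyte == row$analyte &
                                   manifest$day == row$day]
    if (length(pc_ids) == 0L) batch_control_error(row$analyte)
    ctrl <- records[records$sample_id %in% pc_ids &
                      records$analyte == row$analyte, ]
    call <- classify_compliance(samp, ctrl, validation, panel)
    call$group <- row$group
    call$day <- row$day
    calls[[length(calls) + 1L]] <- call
  }
  calls <- do.call(rbind, calls)

  timelines <- do.call(rbind, lapply(
    split(calls, list(calls$group, calls$analyte), drop = TRUE),
    function(g) data.frame(
      group = g$group[1], analyte = g$analyte[1],
      n_compliant = sum(g$compliance == "compliant"),
      n_noncompliant = sum(g$compliance == "noncompliant"),
      n_not_detected = sum(g$compliance == "not_detected"),
      days_noncompliant_post_treatment =
        compliance_timeline(g, treatment_end_day),
      stringsAsFactors = FALSE)))
  rownames(timelines) <- NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(calls, file.path(out_dir, "screening_calls.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(timelines, file.path(out_dir, "timelines.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_run_manifest(out_dir, inputs = list(
      n_records = nrow(records), n_samples = nrow(study),
      panel = panel$name, treatment_end_day = treatment_end_day))
  }
  message(sprintf(
    "screened %d samples: %d compliant, %d noncompliant, %d not detected",
    nrow(calls), sum(calls$compliance == "compliant"),
    sum(calls$compliance == "noncompliant"),
    sum(calls$compliance == "not_detected")))
  invisible(list(calls = calls, timelines = timelines))
}

#' Generate and write a simulated study fixture
#'
#' @param drug a drug with packaged depletion defaults (see
#'   [study_fixture()]).
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @param noise_cv replicate-level concentration noise.
#' @return invisibly, the [study_fixture()] list; writes `records.tsv`,
#'   `manifest.tsv` and `depletion_series.tsv` under `out_dir`.
#' @export
run_simulate <- function(drug, out_dir = ".", seed = 1L, noise_cv = 0) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fx <- study_fixture(drug, noise_cv = noise_cv, seed = seed)
  write_response_table(fx$records, file.path(out_dir, "records.tsv"))
  write_batch_manifest(fx$manifest, file.path(out_dir, "manifest.tsv"))
  series <- simulate_depletion(depletion_defaults(drug)$config)
  utils::write.table(series, file.path(out_dir, "depletion_series.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_run_manifest(out_dir, inputs = list(drug = drug,
                                            noise_cv = noise_cv), seed = seed)
  invisible(fx)
}
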