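#' Analyte panels for multiresidue egg screening
#'
#' An analyte panel is the configuration backbone of the screening method:
#' for every antimicrobial it stores the monitored MRM transitions (precursor
#' and product m/z, declustering potential, collision energy), the expected
#' retention time, the reference relative ion intensity of each confirmatory
#' transition, the regulatory status and (where one exists) the maximum
#' residue limit (MRL) in eggs.  Levels of interest for validation and the
#' positive-control spike levels are derived from these fields, never stored.
#'
#' @name analyte_panel
#' @keywords internal
NULL

.FAMILIES <- c("tetracyclines", "aminoglycosides", "quinolones",
               "lincosamides", "beta_lactams", "sulfonamides", "macrolides")
.REG_STATUS <- c("mrl_established", "banned", "not_established",
                 "no_mrl_in_eggs")
.RANKS <- c("major", "minor1", "minor2")

panel_error <- function(msg, analyte = NULL) {
  if (!is.null(analyte)) msg <- sprintf("analyte '%s': %s", analyte, msg)
  stop(errorCondition(msg, class = c("eggscreen_panel_error", "error")))
}

validate_transition <- function(tr, analyte) {
  req <- c("rank", "precursor_mz", "product_mz", "expected_rt")
  miss <- setdiff(req, names(tr))
  if (length(miss) > 0L)
    panel_error(sprintf("transition missing field(s): %s",
                        paste(miss, collapse = ", ")), analyte)
  if (!tr$rank %in% .RANKS)
    panel_error(sprintf("unknown transition rank '%s'", tr$rank), analyte)
  if (!(tr$precursor_mz > tr$product_mz && tr$product_mz > 0))
    panel_error("requires precursor_mz > product_mz > 0", analyte)
  if (tr$expected_rt <= 0)
    panel_error("expected_rt must be positive", analyte)
  if (tr$rank == "major" && !is.null(tr$reference_relative_intensity))
    panel_error("major transition must not carry a reference relative intensity",
                analyte)
  if (!is.null(tr$reference_relative_intensity) &&
      tr$reference_relative_intensity < 0)
    panel_error("reference_relative_intensity must be >= 0", analyte)
  tr
}

validate_analyte <- function(an) {
  req <- c("name", "family", "regulatory_status", "transitions")
  miss <- setdiff(req, names(an))
  if (length(miss) > 0L)
    panel_error(sprintf("missing required field(s): %s",
                        paste(miss, collapse = ", ")),
                if (is.null(an$name)) "<unnamed>" else an$name)
  if (!an$family %in% .FAMILIES)
    panel_error(sprintf("unknown family '%s'", an$family), an$name)
  if (!an$regulatory_status %in% .REG_STATUS)
    panel_error(sprintf("unknown regulatory_status '%s'", an$regulatory_status),
                an$name)
  if (length(an$transitions) < 2L)
    panel_error("at least two MRM transitions (identification + confirmation) are required",
                an$name)
  an$transitions <- lapply(an$transitions, validate_transition, analyte = an$name)
  ranks <- vapply(an$transitions, `[[`, "", "rank")
  if (sum(ranks == "major") != 1L)
    panel_error("exactly one transition must have rank 'major'", an$name)
  if (anyDuplicated(ranks))
    panel_error("duplicate transition ranks", an$name)
  if (identical(an$regulatory_status, "mrl_established")) {
    if (is.null(an$mrl) || an$mrl <= 0)
      panel_error("mrl_established analytes need mrl > 0", an$name)
  } else if (!is.null(an$mrl)) {
    panel_error("analytes without an established MRL must not carry an mrl field",
                an$name)
  }
  if (is.null(an$combined_residue)) an$combined_residue <- FALSE
  an
}

#' Construct an analyte panel
#'
#' @param analytes list of analyte definitions, each a list with fields
#'   `name`, `family`, `regulatory_status` (one of `mrl_established`,
#'   `banned`, `not_established`, `no_mrl_in_eggs`), optional `mrl` (ug/kg,
#'   only for `mrl_established`), `combined_residue` (logical: the MRL covers
#'   parent plus epimer/metabolite), optional `level_override` (ug/kg),
#'   `extraction_route`, and `transitions`, a list of at least two transition
#'   definitions with fields `rank` (`major`, `minor1`, `minor2`),
#'   `precursor_mz`, `product_mz`, `declustering_potential`,
#'   `collision_energy`, `expected_rt` (min) and, for confirmatory
#'   transitions, `reference_relative_intensity` (% of the major response).
#' @param qualitative_default_levels named numeric vector or list giving the
#'   per-family screening level (ug/kg) used for analytes with no MRL.
#' @param name panel label.
#' @param rt_tolerance default relative retention-time window half-width.
#' @return an object of class `analyte_panel`.
#' @export
analyte_panel <- function(analytes, qualitative_default_levels,
                          name = "panel", rt_tolerance = 0.025) {
  analytes <- lapply(analytes, validate_analyte)
  nms <- vapply(analytes, `[[`, "", "name")
  if (anyDuplicated(nms))
    panel_error(sprintf("duplicate analyte name '%s'", nms[duplicated(nms)][1L]))
  names(analytes) <- nms
  defaults <- unlist(qualitative_default_levels)
  fams <- unique(vapply(analytes, `[[`, "", "family"))
  missing_fam <- setdiff(fams, names(defaults))
  if (length(missing_fam) > 0L)
    panel_error(sprintf("no qualitative default level for family(ies): %s",
                        paste(missing_fam, collapse = ", ")))
  structure(list(name = name, analytes = analytes,
                 qualitative_default_levels = defaults,
                 rt_tolerance = rt_tolerance),
            class = "analyte_panel")
}

#' Load an analyte panel from a YAML configuration file
#'
#' @param path path to a panel file; the packaged egg panel is returned by
#'   [default_panel()].
#' @return an [analyte_panel()] object.
#' @export
load_panel <- function(path) {
  if (!file.exists(path))
    panel_error(sprintf("panel file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$analytes) || is.null(raw$qualitative_default_levels))
    panel_error(sprintf("panel file %s lacks 'analytes' or 'qualitative_default_levels'",
                        path))
  analyte_panel(raw$analytes, raw$qualitative_default_levels,
                name = if (is.null(raw$name)) basename(path) else raw$name,
                rt_tolerance = if (is.null(raw$rt_tolerance)) 0.025
                               else raw$rt_tolerance)
}

#' Write an analyte panel back to YAML
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p, f))` reproduces `p`.
#'
#' @param panel an `analyte_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "analyte_panel"))
  out <- list(name = panel$name,
              rt_tolerance = panel$rt_tolerance,
              qualitative_default_levels = as.list(panel$qualitative_default_levels),
              analytes = unname(panel$analytes))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The packaged egg screening panel
#'
#' 45 antimicrobials across seven families (tetracyclines, aminoglycosides,
#' quinolones, lincosamides, beta-lactams, sulfonamides, macrolides), each
#' with its tuned MRM transitions, expected retention time, reference
#' relative ion intensity, regulatory status and egg MRL where established.
#'
#' @return an [analyte_panel()] object.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "panel_eggs.yaml", package = "eggscreen",
                         mustWork = TRUE))
}

get_analyte <- function(panel, analyte) {
  stopifnot(inherits(panel, "analyte_panel"))
  an <- panel$analytes[[analyte]]
  if (is.null(an))
    panel_error(sprintf("analyte '%s' is not in panel '%s'", analyte, panel$name))
  an
}

get_transition <- function(analyte_spec, rank) {
  ranks <- vapply(analyte_spec$transitions, `[[`, "", "rank")
  i <- match(rank, ranks)
  if (is.na(i))
    panel_error(sprintf("no transition of rank '%s'", rank), analyte_spec$name)
  analyte_spec$transitions[[i]]
}

#' Level of interest (validation concentration) for an analyte
#'
#' The concentration at which the screening method is validated: the MRL for
#' analytes with a single-residue MRL, 0.75 x MRL when the residue definition
#' combines the parent with an epimer or metabolite, an explicit per-analyte
#' override where the panel records one, and otherwise the family's
#' qualitative screening default.
#'
#' @param analyte analyte name (character) or an analyte spec from the panel.
#' @param panel an [analyte_panel()].
#' @return concentration in ug/kg.
#' @export
validation_level <- function(analyte, panel) {
  an <- if (is.character(analyte)) get_analyte(panel, analyte) else analyte
  if (!is.null(an$level_override))
    return(as.numeric(an$level_override))
  if (identical(an$regulatory_status, "mrl_established")) {
    if (isTRUE(an$combined_residue)) 0.75 * an$mrl else as.numeric(an$mrl)
  } else {
    as.numeric(panel$qualitative_default_levels[[an$family]])
  }
}

#' Positive-control spike level for an analyte
#'
#' Samples spiked at 0.75 times the validation level serve as the batch
#' positive control; study samples with responses above the control's are
#' classified noncompliant.
#'
#' @inheritParams validation_level
#' @return concentration in ug/kg.
#' @export
positive_control_level <- function(analyte, panel) {
  0.75 * validation_level(analyte, panel)
}

#' @export
print.analyte_panel <- function(x, ...) {
  fams <- vapply(x$analytes, `[[`, "", "family")
  cat(sprintf("Analyte panel '%s': %d analytes, %d families\n",
              x$name, length(x$analytes), length(unique(fams))))
  tab <- table(fams)
  for (f in names(tab)) cat(sprintf("  %-16s %d\n", f, tab[[f]]))
  invisible(x)
}

#' Tabular view of a panel
#'
#' One row per analyte with the derived validation and positive-control
#' levels alongside the stored regulatory fields.
#'
#' @param x an `analyte_panel`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a data.frame.
#' @export
as.data.frame.analyte_panel <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  rows <- lapply(x$analytes, function(an) {
    data.frame(analyte = an$name, family = an$family,
               regulatory_status = an$regulatory_status,
               mrl = if (is.null(an$mrl)) NA_real_ else an$mrl,
               combined_residue = isTRUE(an$combined_residue),
               validation_level = validation_level(an, x),
               positive_control_level = positive_control_level(an, x),
               n_transitions = length(an$transitions),
               extraction_route = if (is.null(an$extraction_route)) NA_character_
                                  else an$extraction_route,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
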