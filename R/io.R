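#' Delimited response tables and batch manifests
#'
#' The pipeline consumes already-integrated instrument output as plain
#' delimited text: one row per measured transition of one sample, with the
#' integrated response and the noise in the analyte's retention window, both
#' in the same arbitrary response units.
#'
#' @name response_io
#' @keywords internal
NULL

RESPONSE_COLS <- c("sample_id", "day", "replicate", "analyte",
                   "transition_rank", "response", "noise", "observed_rt",
                   "sample_kind")
SAMPLE_KINDS <- c("blank", "spiked", "study")

parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("eggscreen_parse_error", "error")))
}

#' Coerce and check a response-record data.frame
#'
#' @param records a data.frame with the response-record columns.
#' @return the checked data.frame (numeric columns coerced).
#' @export
as_response_table <- function(records) {
  records <- as.data.frame(records)
  miss <- setdiff(RESPONSE_COLS, names(records))
  if (length(miss) > 0L)
    parse_error(sprintf("response table missing column(s): %s",
                        paste(miss, collapse = ", ")))
  for (col in c("day", "replicate", "response", "noise", "observed_rt"))
    records[[col]] <- as.numeric(records[[col]])
  records$sample_id <- as.character(records$sample_id)
  records$analyte <- as.character(records$analyte)
  records$transition_rank <- as.character(records$transition_rank)
  records$sample_kind <- as.character(records$sample_kind)
  bad_kind <- setdiff(unique(records$sample_kind), SAMPLE_KINDS)
  if (length(bad_kind) > 0L)
    parse_error(sprintf("unknown sample_kind value(s): %s",
                        paste(bad_kind, collapse = ", ")))
  if (nrow(records) > 0L) {
    if (any(!is.finite(records$response) | records$response < 0))
      parse_error("response must be finite and >= 0")
    if (any(!is.finite(records$noise) | records$noise < 0))
      parse_error("noise must be finite and >= 0")
    if (any(!is.finite(records$day) | records$day < 0))
      parse_error("day must be finite and >= 0")
  }
  records[RESPONSE_COLS]
}

#' Read a response table from delimited text
#'
#' @param path file path; comma- or tab-delimited, with a header row naming
#'   the response-record columns.
#' @param sep field delimiter; guessed from the header line when `NULL`.
#' @return a checked response-record data.frame.
#' @export
read_response_table <- function(path, sep = NULL) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  tryCatch(as_response_table(df), error = function(e) {
    parse_error(sprintf("%s (while reading %s)", conditionMessage(e), path))
  })
}

#' Write a response table as delimited text
#'
#' @param records response-record data.frame.
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_response_table <- function(records, path, sep = "\t") {
  records <- as_response_table(records)
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

MANIFEST_COLS <- c("sample_id", "group", "day", "role", "analyte")
MANIFEST_ROLES <- c("study", "positive_control")

#' Coerce and check a batch manifest
#'
#' A manifest links study samples to the positive-control spikes measured in
#' the same batch: columns `sample_id`, `group`, `day`, `role` (`study` or
#' `positive_control`), `analyte`.
#'
#' @param manifest a data.frame.
#' @return the checked data.frame.
#' @export
as_batch_manifest <- function(manifest) {
  manifest <- as.data.frame(manifest)
  miss <- setdiff(MANIFEST_COLS, names(manifest))
  if (length(miss) > 0L)
    parse_error(sprintf("batch manifest missing column(s): %s",
                        paste(miss, collapse = ", ")))
  manifest$sample_id <- as.character(manifest$sample_id)
  manifest$group <- as.character(manifest$group)
  manifest$day <- as.numeric(manifest$day)
  manifest$role <- as.character(manifest$role)
  manifest$analyte <- as.character(manifest$analyte)
  bad <- setdiff(unique(manifest$role), MANIFEST_ROLES)
  if (length(bad) > 0L)
    parse_error(sprintf("unknown manifest role(s): %s",
                        paste(bad, collapse = ", ")))
  manifest[MANIFEST_COLS]
}

#' @rdname as_batch_manifest
#' @param path delimited-text manifest file.
#' @param sep field delimiter; guessed when `NULL`.
#' @export
read_batch_manifest <- function(path, sep = NULL) {
  if (!file.exists(path)) parse_error(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  as_batch_manifest(utils::read.delim(path, sep = sep,
                                      stringsAsFactors = FALSE))
}

#' @rdname as_batch_manifest
#' @param manifest the manifest data.frame to write.
#' @export
write_batch_manifest <- function(manifest, path, sep = "\t") {
  manifest <- as_batch_manifest(manifest)
  utils::write.table(manifest, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
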