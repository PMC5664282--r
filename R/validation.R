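#' Screening-method validation statistics
#'
#' The qualitative validation calculus works in instrument-response units and
#' asks one question per analyte and transition: is the cut-off factor Fc,
#' derived from spiked samples at the level of interest, above the T-value
#' derived from blank noise?  If so, the detection capability CCbeta lies
#' below the level of interest and the false-negative rate of the screen is
#' below 5%.
#'
#' @name validation_stats
#' @keywords internal
NULL

insufficient_data <- function(what, n, need) {
  stop(errorCondition(
    sprintf("%s needs at least %d values, got %d", what, need, n),
    class = c("eggscreen_insufficient_data", "error")))
}

#' T-value: noise-derived positivity threshold
#'
#' Mean blank noise plus `k` sample standard deviations, computed over the
#' recorded noise of blank samples in the analyte's retention window.  A
#' response above the T-value is unlikely (about 5% for `k = 1.64` under a
#' normal noise model) to come from a blank.
#'
#' @param blank_noises numeric vector of blank noise values (response units);
#'   the validation design uses 20 blanks from different batches.
#' @param k threshold multiplier (default 1.64, the one-sided 95% normal
#'   quantile as used in the screening-validation scheme).
#' @return threshold in response units.
#' @export
t_value <- function(blank_noises, k = 1.64) {
  blank_noises <- as.numeric(blank_noises)
  if (length(blank_noises) < 2L)
    insufficient_data("t_value", length(blank_noises), 2L)
  stopifnot(k > 0)
  mean(blank_noises) + k * stats::sd(blank_noises)
}

#' Cut-off factor Fc: operational detection threshold
#'
#' Mean response of samples spiked at the level of interest minus `k` sample
#' standard deviations.  The design pools 20 spiked replicates on each of
#' three days (n = 60).  A spiked sample falls below Fc with probability
#' about 5% (`k = 1.64`, normal model), so taking Fc as the positivity
#' threshold bounds the false-negative rate of the screen.
#'
#' @param spiked_responses numeric vector of spiked-sample responses.
#' @param k threshold multiplier (default 1.64).
#' @return cut-off in response units.  A negative cut-off (possible when the
#'   spread exceeds the mean) is returned as-is with attribute
#'   `flag = "low_signal"`; clamping it would silently alter sensitivity.
#' @export
cutoff_factor <- function(spiked_responses, k = 1.64) {
  spiked_responses <- as.numeric(spiked_responses)
  if (length(spiked_responses) < 2L)
    insufficient_data("cutoff_factor", length(spiked_responses), 2L)
  stopifnot(k > 0)
  fc <- mean(spiked_responses) - k * stats::sd(spiked_responses)
  if (fc < 0) attr(fc, "flag") <- "low_signal"
  fc
}

#' Signal-to-noise limit of detection
#'
#' `3 * mean_noise * spike_concentration / mean_spiked_response`: the
#' concentration whose expected response equals three times the mean blank
#' noise, assuming response proportional to concentration.
#'
#' @param mean_noise mean blank noise (response units, >= 0).
#' @param spike_concentration the known spike concentration (ug/kg, > 0).
#' @param mean_spiked_response mean response of the spiked samples (> 0).
#' @return limit of detection in ug/kg.
#' @export
lod <- function(mean_noise, spike_concentration, mean_spiked_response) {
  stopifnot(mean_noise >= 0, spike_concentration > 0)
  if (!is.finite(mean_spiked_response) || mean_spiked_response <= 0)
    stop(errorCondition(
      "LOD undefined: mean spiked response must be positive",
      class = c("eggscreen_undefined_lod", "error")))
  3 * mean_noise * spike_concentration / mean_spiked_response
}

#' Detection-capability verdict from Fc and the T-value
#'
#' `Fc > T` means the detection capability CCbeta is truly below the level of
#' interest (`below_level`, false-negative rate below 5%); `Fc <= T` means it
#' is above (`above_level`).  A tie is resolved to `above_level`: when the
#' two thresholds coincide the 5% bound is not demonstrated, and the
#' conservative call protects the consumer.
#'
#' @param fc cut-off factor (response units).
#' @param t_value T-value (response units).
#' @return `"below_level"` or `"above_level"`.
#' @export
ccbeta_verdict <- function(fc, t_value) {
  stopifnot(is.finite(fc), is.finite(t_value))
  if (fc > t_value) "below_level" else "above_level"
}

#' Screening sensitivity (positive agreement)
#'
#' Percentage of truly spiked samples whose response reaches the cut-off
#' factor.  A response exactly equal to the cut-off counts as detected.
#'
#' @param spiked_responses numeric vector of spiked-sample responses
#'   (validation design: 20).
#' @param fc cut-off factor to screen against.
#' @return percentage in `[0, 100]`.
#' @export
sensitivity <- function(spiked_responses, fc) {
  spiked_responses <- as.numeric(spiked_responses)
  if (length(spiked_responses) < 1L)
    insufficient_data("sensitivity", 0L, 1L)
  100 * sum(spiked_responses >= as.numeric(fc)) / length(spiked_responses)
}

#' Selectivity: interference flags from blank samples
#'
#' Scans blank records for signals eluting inside an analyte's retention-time
#' window with signal-to-noise above 3 -- the mechanism that compromised one
#' quinolone transition in practice, where a co-eluting extraction-solution
#' compound enhanced the signal of one transition.
#'
#' @param blank_records a response-record data.frame (see
#'   [read_response_table()]) restricted to blanks.
#' @param panel an [analyte_panel()].
#' @param rt_tolerance relative retention-time window half-width (default
#'   from the panel, typically 0.025 i.e. +/-2.5%).
#' @return data.frame with one row per interfering observation: `analyte`,
#'   `transition_rank`, `sample_id`, `observed_rt`, `snr`; zero rows when the
#'   blanks are clean.
#' @export
selectivity_check <- function(blank_records, panel, rt_tolerance = NULL) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (is.null(rt_tolerance)) rt_tolerance <- panel$rt_tolerance
  empty <- data.frame(analyte = character(), transition_rank = character(),
                      sample_id = character(), observed_rt = numeric(),
                      snr = numeric(), stringsAsFactors = FALSE)
  if (nrow(blank_records) == 0L) return(empty)
  if (!all(blank_records$sample_kind == "blank"))
    stop("selectivity_check expects blank records only")
  flags <- list()
  for (i in seq_len(nrow(blank_records))) {
    rec <- blank_records[i, ]
    an <- panel$analytes[[rec$analyte]]
    if (is.null(an)) next
    tr <- tryCatch(get_transition(an, rec$transition_rank),
                   error = function(e) NULL)
    if (is.null(tr)) next
    window <- rt_tolerance * tr$expected_rt
    in_window <- is.finite(rec$observed_rt) &&
      abs(rec$observed_rt - tr$expected_rt) <= window
    snr <- if (rec$noise > 0) rec$response / rec$noise else Inf
    if (in_window && rec$response > 0 && snr > 3) {
      flags[[length(flags) + 1L]] <- data.frame(
        analyte = rec$analyte, transition_rank = rec$transition_rank,
        sample_id = as.character(rec$sample_id),
        observed_rt = rec$observed_rt, snr = snr, stringsAsFactors = FALSE)
    }
  }
  if (length(flags) == 0L) empty else do.call(rbind, flags)
}

#' Validation design parameters
#'
#' @param n_blanks number of blank samples for the T-value (default 20).
#' @param n_spiked_fc number of spiked samples pooled across days for the
#'   cut-off factor (default 60 = 20 x 3 days).
#' @param n_spiked_sens number of spiked samples scored for sensitivity
#'   (default 20).
#' @param k threshold multiplier for both the T-value and Fc (default 1.64).
#' @return a list of class `validation_design`.
#' @export
validation_design <- function(n_blanks = 20L, n_spiked_fc = 60L,
                              n_spiked_sens = 20L, k = 1.64) {
  stopifnot(n_blanks >= 2L, n_spiked_fc >= 2L, n_spiked_sens >= 1L, k > 0)
  structure(list(n_blanks = as.integer(n_blanks),
                 n_spiked_fc = as.integer(n_spiked_fc),
                 n_spiked_sens = as.integer(n_spiked_sens), k = k),
            class = "validation_design")
}

coverage_error <- function(gaps) {
  stop(errorCondition(
    sprintf("insufficient validation coverage for: %s",
            paste(gaps, collapse = "; ")),
    class = c("eggscreen_coverage_error", "error")))
}

#' Run the full validation calculus over a response table
#'
#' For each analyte present in the records and each of its identification
#' (major) and confirmation (minor1) transitions, computes the T-value from
#' blank noise, the cut-off factor from the spiked responses pooled across
#' all days, the CCbeta verdict, the signal-to-noise LOD at the analyte's
#' validation level, and the sensitivity of the first `n_spiked_sens` spiked
#' replicates against Fc.
#'
#' @param records response-record data.frame with columns `sample_id`, `day`,
#'   `replicate`, `analyte`, `transition_rank`, `response`, `noise`,
#'   `observed_rt`, `sample_kind`.
#' @param panel an [analyte_panel()].
#' @param design a [validation_design()].
#' @param analytes analytes to validate; default all analytes present in
#'   `records`.
#' @return data.frame of class `validation_result` with one row per
#'   analyte/transition: `t_value`, `fc`, `lod`, `ccbeta_verdict`,
#'   `sensitivity_pct`, sample counts and quality `flags`.
#' @export
validate_panel <- function(records, panel, design = validation_design(),
                           analytes = NULL) {
  stopifnot(inherits(panel, "analyte_panel"),
            inherits(design, "validation_design"))
  records <- as_response_table(records)
  if (is.null(analytes)) analytes <- unique(records$analyte)
  if (nrow(records) == 0L || length(analytes) == 0L)
    coverage_error("empty record table")

  gaps <- character()
  rows <- list()
  for (a in analytes) {
    an <- get_analyte(panel, a)
    c_val <- validation_level(an, panel)
    for (rk in c("major", "minor1")) {
      sub <- records[records$analyte == a & records$transition_rank == rk, ]
      blanks <- sub[sub$sample_kind == "blank", ]
      spiked <- sub[sub$sample_kind == "spiked", ]
      if (nrow(blanks) < design$n_blanks || nrow(spiked) < design$n_spiked_fc) {
        gaps <- c(gaps, sprintf(
          "%s/%s (blanks %d/%d, spiked %d/%d)", a, rk, nrow(blanks),
          design$n_blanks, nrow(spiked), design$n_spiked_fc))
        next
      }
      tval <- t_value(blanks$noise, k = design$k)
      fc <- cutoff_factor(spiked$response, k = design$k)
      flags <- attr(fc, "flag")
      # sensitivity scored on the first day's replicates (design: 20 spiked)
      ord <- order(spiked$day, spiked$replicate)
      sens_set <- spiked$response[ord][seq_len(design$n_spiked_sens)]
      sens <- sensitivity(sens_set, as.numeric(fc))
      lod_val <- lod(mean(blanks$noise), c_val, mean(spiked$response))
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = a, transition_rank = rk,
        t_value = tval, fc = as.numeric(fc),
        lod = lod_val,
        ccbeta_verdict = ccbeta_verdict(as.numeric(fc), tval),
        sensitivity_pct = sens,
        validation_level = c_val,
        n_blanks = nrow(blanks), n_spiked_fc = nrow(spiked),
        n_spiked_sens = design$n_spiked_sens,
        flags = if (is.null(flags)) "" else paste(flags, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(gaps) > 0L) coverage_error(gaps)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validation_result", "data.frame")
  out
}
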