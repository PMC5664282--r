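#' Two-transition identification and compliance classification
#'
#' A study sample is *identified* when both MRM transitions show
#' signal-to-noise above 3, the major transition elutes at the expected
#' retention time, and the minor/major response ratio agrees with the
#' reference relative ion intensity within the tiered tolerance.  An
#' identified sample is *positive* when its major-transition response reaches
#' the validated cut-off factor, and *noncompliant* when that response also
#' exceeds the mean response of the batch positive control (a spike at 0.75
#' times the validation level).
#'
#' @name screening
#' @keywords internal
NULL

#' Tiered ion-ratio tolerance
#'
#' Relative tolerance on the minor/major ion ratio as a function of the
#' reference relative intensity, following the tiered screening convention:
#' +/-20% (relative) above 50%, +/-25% for 20-50%, +/-30% for 10-20% and
#' +/-50% at or below 10%.
#'
#' @param reference_relative_intensity reference ratio in percent of the
#'   major-transition response.
#' @return the relative tolerance as a fraction (e.g. `0.2`).
#' @export
ion_ratio_tolerance <- function(reference_relative_intensity) {
  r <- reference_relative_intensity
  stopifnot(is.finite(r), r >= 0)
  if (r > 50) 0.20 else if (r > 20) 0.25 else if (r > 10) 0.30 else 0.50
}

incomplete_sample <- function(msg) {
  stop(errorCondition(msg, class = c("eggscreen_incomplete_sample", "error")))
}

one_record <- function(records, rank) {
  sub <- records[records$transition_rank == rank, , drop = FALSE]
  if (nrow(sub) == 0L)
    incomplete_sample(sprintf(
      "sample %s / analyte %s: missing %s-transition record",
      records$sample_id[1], records$analyte[1], rank))
  sub[1L, ]
}

#' Identify an analyte in one sample
#'
#' @param sample_records response records of one sample for one analyte,
#'   covering at least the major and minor1 transitions.
#' @param panel an [analyte_panel()].
#' @param rt_tolerance relative retention-time window half-width (default
#'   taken from the panel).
#' @param ratio_tolerance_fun function mapping a reference relative intensity
#'   to a relative tolerance; defaults to the tiered [ion_ratio_tolerance()].
#' @return a list with logical `identified`, `snr_ok`, `rt_ok`,
#'   `ion_ratio_ok`, the observed `ion_ratio` (percent) and per-transition
#'   `details` (response, noise, S/N).
#' @export
identify_analyte <- function(sample_records, panel, rt_tolerance = NULL,
                             ratio_tolerance_fun = ion_ratio_tolerance) {
  sample_records <- as_response_table(sample_records)
  if (length(unique(sample_records$analyte)) != 1L)
    incomplete_sample("identify_analyte expects records for a single analyte")
  an <- get_analyte(panel, sample_records$analyte[1])
  if (is.null(rt_tolerance)) rt_tolerance <- panel$rt_tolerance
  maj <- one_record(sample_records, "major")
  min1 <- one_record(sample_records, "minor1")
  tr_maj <- get_transition(an, "major")
  tr_min <- get_transition(an, "minor1")

  snr <- function(rec) if (rec$noise > 0) rec$response / rec$noise
                       else if (rec$response > 0) Inf else 0
  snr_maj <- snr(maj)
  snr_min <- snr(min1)
  snr_ok <- snr_maj > 3 && snr_min > 3

  window <- rt_tolerance * tr_maj$expected_rt
  rt_ok <- is.finite(maj$observed_rt) &&
    abs(maj$observed_rt - tr_maj$expected_rt) <= window

  ref <- tr_min$reference_relative_intensity
  if (is.null(ref)) {
    ion_ratio <- NA_real_
    ratio_ok <- TRUE   # no reference stored: ratio criterion not applicable
  } else {
    ion_ratio <- if (maj$response > 0) 100 * min1$response / maj$response
                 else NA_real_
    tol <- ratio_tolerance_fun(ref)
    ratio_ok <- is.finite(ion_ratio) && abs(ion_ratio - ref) <= tol * ref
  }

  list(identified = snr_ok && rt_ok && ratio_ok,
       snr_ok = snr_ok, rt_ok = rt_ok, ion_ratio_ok = ratio_ok,
       ion_ratio = ion_ratio,
       details = data.frame(
         transition_rank = c("major", "minor1"),
         response = c(maj$response, min1$response),
         noise = c(maj$noise, min1$noise),
         snr = c(snr_maj, snr_min),
         observed_rt = c(maj$observed_rt, min1$observed_rt),
         stringsAsFactors = FALSE))
}

unvalidated_analyte <- function(analyte) {
  stop(errorCondition(
    sprintf("no validation result available for analyte '%s'", analyte),
    class = c("eggscreen_unvalidated_analyte", "error")))
}

fc_for <- function(validation, analyte, rank = "major") {
  i <- which(validation$analyte == analyte & validation$transition_rank == rank)
  if (length(i) == 0L) unvalidated_analyte(analyte)
  validation$fc[i[1L]]
}

#' Screen one sample for positivity
#'
#' @inheritParams identify_analyte
#' @param validation a `validation_result` data.frame from [validate_panel()]
#'   covering the analyte's major and minor1 transitions.
#' @return a list with `positive` (identified and major response at or above
#'   the major-transition cut-off factor), the `fc` used, and the
#'   identification outcome under `identification`.
#' @export
screen_sample <- function(sample_records, validation, panel,
                          rt_tolerance = NULL) {
  sample_records <- as_response_table(sample_records)
  analyte <- sample_records$analyte[1]
  fc_major <- fc_for(validation, analyte, "major")
  fc_for(validation, analyte, "minor1")  # both transitions must be validated
  ident <- identify_analyte(sample_records, panel, rt_tolerance)
  maj_resp <- ident$details$response[ident$details$transition_rank == "major"]
  list(positive = ident$identified && maj_resp >= fc_major,
       fc = fc_major, identification = ident)
}

batch_control_error <- function(analyte) {
  stop(errorCondition(
    sprintf("no positive-control records in batch for analyte '%s'", analyte),
    class = c("eggscreen_batch_control_error", "error")))
}

#' Classify one sample as compliant / noncompliant / not detected
#'
#' Implements the semiquantitative decision: a sample identified and positive
#' whose major-transition response strictly exceeds the mean major-transition
#' response of the batch positive control (spiked at 0.75 times the
#' validation level) is `noncompliant`; identified samples at or below the
#' control response are `compliant`; unidentified samples are `not_detected`.
#'
#' @inheritParams screen_sample
#' @param control_records response records of the batch positive-control
#'   replicates for the same analyte (major transition required).
#' @return a one-row data.frame (a screening call): `sample_id`, `analyte`,
#'   `identified`, `positive`, `compliance`, `ion_ratio_ok`, `rt_ok`,
#'   `response_major`, `control_mean`, `estimated_concentration` (a
#'   convenience estimate `response x control level / control response`,
#'   never used for the decision).
#' @export
classify_compliance <- function(sample_records, control_records, validation,
                                panel, rt_tolerance = NULL) {
  sample_records <- as_response_table(sample_records)
  analyte <- sample_records$analyte[1]
  control_records <- as_response_table(control_records)
  ctrl <- control_records[control_records$analyte == analyte &
                            control_records$transition_rank == "major", ]
  if (nrow(ctrl) == 0L) batch_control_error(analyte)
  control_mean <- mean(ctrl$response)

  scr <- screen_sample(sample_records, validation, panel, rt_tolerance)
  ident <- scr$identification
  maj_resp <- ident$details$response[ident$details$transition_rank == "major"]

  compliance <- if (!ident$identified) {
    "not_detected"
  } else if (scr$positive && maj_resp > control_mean) {
    "noncompliant"
  } else {
    "compliant"
  }
  est <- if (control_mean > 0)
    maj_resp * positive_control_level(analyte, panel) / control_mean
  else NA_real_
  data.frame(sample_id = sample_records$sample_id[1], analyte = analyte,
             identified = ident$identified, positive = scr$positive,
             compliance = compliance, ion_ratio_ok = ident$ion_ratio_ok,
             rt_ok = ident$rt_ok, response_major = maj_resp,
             control_mean = control_mean, estimated_concentration = est,
             stringsAsFactors = FALSE)
}

#' Days of noncompliance after the end of treatment
#'
#' Given day-indexed screening calls for one treatment group and analyte,
#' returns the largest number of days `d >= 1` after `treatment_end_day` on
#' which any call is noncompliant, or 0 when every post-treatment call is
#' compliant or not detected.
#'
#' @param daily_calls data.frame with columns `day` and `compliance`
#'   (several calls per day allowed; a day counts as noncompliant when any of
#'   its calls is).
#' @param treatment_end_day last day of drug administration.
#' @return integer count of days.
#' @export
compliance_timeline <- function(daily_calls, treatment_end_day) {
  stopifnot(all(c("day", "compliance") %in% names(daily_calls)),
            is.finite(treatment_end_day))
  post <- daily_calls[daily_calls$day > treatment_end_day, , drop = FALSE]
  nc_days <- unique(post$day[post$compliance == "noncompliant"])
  if (length(nc_days) == 0L) return(0L)
  as.integer(max(nc_days) - treatment_end_day)
}
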