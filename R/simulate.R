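#' Synthetic validation and depletion data
#'
#' Two generators stand in for the instrument and the animal study: a
#' validation simulator producing blank-noise and spiked-response tables
#' under the 20-blank / 20 x 3-day design, and a minimal linear
#' plasma-to-egg deposition model producing per-day pooled-egg residue
#' concentrations for a dosing/washout experiment.
#'
#' @name synthetic_data
#' @keywords internal
NULL

rtrunc0 <- function(n, mean, sd) pmax(0, stats::rnorm(n, mean, sd))

#' Configuration for the validation simulator
#'
#' @param noise_mean,noise_sd blank-noise distribution (response units).
#' @param spike_mean,spike_sd spiked-response distribution at the level of
#'   interest, for the major transition (response units); the minor
#'   transition is scaled by the panel's reference relative intensity.
#' @param n_blanks number of blank samples (default 20).
#' @param n_per_day,n_days spiked replicates per day and number of days
#'   (default 20 x 3).
#' @param day_effect_sd standard deviation of a shared per-day response
#'   offset (response units, default 0).
#' @param interferent optional list `list(rank =, added_mean =)` adding a
#'   co-eluting signal of the given mean response to the blanks of one
#'   transition (the mechanism that invalidated one quinolone transition:
#'   the added signal inflates blank noise, pushing the T-value above Fc).
#' @param interferent_noise_fraction fraction of the interferent response
#'   that contaminates the recorded noise (default 0.25, so blank S/N in the
#'   window rises above 3 and the interferent is also visible to the
#'   selectivity check).
#' @param seed RNG seed.
#' @return a list of class `validation_sim_config`.
#' @export
validation_sim_config <- function(noise_mean, noise_sd, spike_mean, spike_sd,
                                  n_blanks = 20L, n_per_day = 20L,
                                  n_days = 3L, day_effect_sd = 0,
                                  interferent = NULL,
                                  interferent_noise_fraction = 0.25,
                                  seed = 1L) {
  stopifnot(noise_mean >= 0, noise_sd >= 0, spike_mean >= 0, spike_sd >= 0,
            day_effect_sd >= 0, n_blanks >= 1L, n_per_day >= 1L, n_days >= 1L)
  if (!is.null(interferent))
    stopifnot(is.list(interferent),
              all(c("rank", "added_mean") %in% names(interferent)),
              interferent$added_mean >= 0)
  structure(list(noise_mean = noise_mean, noise_sd = noise_sd,
                 spike_mean = spike_mean, spike_sd = spike_sd,
                 n_blanks = as.integer(n_blanks),
                 n_per_day = as.integer(n_per_day),
                 n_days = as.integer(n_days),
                 day_effect_sd = day_effect_sd, interferent = interferent,
                 interferent_noise_fraction = interferent_noise_fraction,
                 seed = as.integer(seed)),
            class = "validation_sim_config")
}

#' Simulate a validation response table for one analyte
#'
#' Blanks carry zero-truncated normal noise; spiked samples carry
#' zero-truncated normal responses around the spike mean plus a shared
#' per-day offset.  The minor1 transition is scaled by the analyte's
#' reference relative intensity (same coefficient of variation).  Identical
#' seeds give identical tables.
#'
#' @param config a [validation_sim_config()].
#' @param panel an [analyte_panel()].
#' @param analyte analyte name.
#' @return a response-record data.frame ready for [validate_panel()].
#' @export
simulate_validation <- function(config, panel, analyte) {
  stopifnot(inherits(config, "validation_sim_config"))
  an <- get_analyte(panel, analyte)
  set.seed(config$seed)

  tr_min <- get_transition(an, "minor1")
  ref <- tr_min$reference_relative_intensity
  scale_minor <- if (is.null(ref)) 1 else ref / 100

  day_offsets <- stats::rnorm(config$n_days, 0, config$day_effect_sd)

  make_rows <- function(rank) {
    tr <- get_transition(an, rank)
    s <- if (rank == "minor1") scale_minor else 1
    interf <- !is.null(config$interferent) &&
      identical(config$interferent$rank, rank)
    add <- if (interf) config$interferent$added_mean else 0

    blank_noise <- rtrunc0(config$n_blanks, config$noise_mean, config$noise_sd)
    blanks <- data.frame(
      sample_id = sprintf("blank_%02d", seq_len(config$n_blanks)),
      day = 1, replicate = seq_len(config$n_blanks), analyte = analyte,
      transition_rank = rank,
      response = blank_noise + add,
      noise = blank_noise + config$interferent_noise_fraction * add,
      observed_rt = tr$expected_rt +
        stats::rnorm(config$n_blanks, 0, 0.005 * tr$expected_rt),
      sample_kind = "blank", stringsAsFactors = FALSE)

    spiked <- do.call(rbind, lapply(seq_len(config$n_days), function(d) {
      resp <- rtrunc0(config$n_per_day,
                      s * (config$spike_mean + day_offsets[d]),
                      s * config$spike_sd)
      data.frame(
        sample_id = sprintf("spiked_d%d_%02d", d, seq_len(config$n_per_day)),
        day = d, replicate = seq_len(config$n_per_day), analyte = analyte,
        transition_rank = rank, response = resp,
        noise = rtrunc0(config$n_per_day, config$noise_mean, config$noise_sd),
        observed_rt = tr$expected_rt +
          stats::rnorm(config$n_per_day, 0, 0.005 * tr$expected_rt),
        sample_kind = "spiked", stringsAsFactors = FALSE)
    }))
    rbind(blanks, spiked)
  }

  out <- rbind(make_rows("major"), make_rows("minor1"))
  rownames(out) <- NULL
  as_response_table(out)
}

#' Configuration for the egg-residue depletion simulator
#'
#' A deliberately minimal linear deposition model.  Plasma follows
#' first-order accumulation during dosing and exponential washout:
#' `p(t) = p(t-1) * exp(-elimination_rate) + absorption_fraction * dose(t)`.
#' Albumen, laid down over a few hours from freshly secreted protein, tracks
#' the previous day's plasma; yolk integrates plasma over its 10-day rapid
#' growth window with exponentially increasing deposition weights
#' `w_j \propto exp(yolk_growth_rate * j)` toward lay.  The pooled-egg
#' concentration mixes the two compartments by yolk mass fraction.
#'
#' @param drug analyte name the series represents.
#' @param dose_days days of medicated feed (default 5).
#' @param washout_days days after discontinuation (default 10).
#' @param absorption_fraction fraction of the daily dose reaching plasma
#'   (0-1; in this unit system the daily dose is 1, so plasma is expressed
#'   in dose units and the partition coefficients carry the scale to ug/kg).
#' @param elimination_rate first-order plasma elimination rate (per day).
#' @param albumen_partition,yolk_partition linear plasma-to-compartment
#'   transfer coefficients (ug/kg per plasma unit).
#' @param yolk_growth_rate exponential growth rate of yolk deposition weights
#'   over the 10-day maturation window (per day).
#' @param yolk_mass_fraction yolk share of pooled whole-egg mass
#'   (default 0.36).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   measurement/biological noise (0 gives the mean curve).
#' @param seed RNG seed (used only when `noise_cv > 0`).
#' @return a list of class `depletion_sim_config`.
#' @export
depletion_sim_config <- function(drug, dose_days = 5L, washout_days = 10L,
                                 absorption_fraction = 0.8,
                                 elimination_rate = 0.5,
                                 albumen_partition = 0,
                                 yolk_partition = 0,
                                 yolk_growth_rate = 0.3,
                                 yolk_mass_fraction = 0.36,
                                 noise_cv = 0, seed = 1L) {
  stopifnot(absorption_fraction >= 0, absorption_fraction <= 1,
            elimination_rate >= 0, albumen_partition >= 0,
            yolk_partition >= 0, yolk_growth_rate >= 0,
            yolk_mass_fraction > 0, yolk_mass_fraction < 1,
            noise_cv >= 0, dose_days >= 1L, washout_days >= 0L)
  structure(list(drug = drug, dose_days = as.integer(dose_days),
                 washout_days = as.integer(washout_days),
                 absorption_fraction = absorption_fraction,
                 elimination_rate = elimination_rate,
                 albumen_partition = albumen_partition,
                 yolk_partition = yolk_partition,
                 yolk_growth_rate = yolk_growth_rate,
                 yolk_mass_fraction = yolk_mass_fraction,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "depletion_sim_config")
}

YOLK_WINDOW <- 10L

#' Simulate a per-day egg residue depletion series
#'
#' @param config a [depletion_sim_config()].
#' @return data.frame of class `depletion_series` with columns `day`
#'   (0 = pre-treatment, then `dose_days + washout_days` days), `plasma`
#'   (dose units), `albumen`, `yolk` and `concentration` (ug/kg, the pooled
#'   whole-egg value, with noise if `noise_cv > 0`).
#' @export
simulate_depletion <- function(config) {
  stopifnot(inherits(config, "depletion_sim_config"))
  n_days <- config$dose_days + config$washout_days
  decay <- exp(-config$elimination_rate)

  plasma <- numeric(n_days + 1L)   # index t + 1 holds p(t); p(0) = 0
  for (t in seq_len(n_days)) {
    dose <- as.numeric(t <= config$dose_days)
    plasma[t + 1L] <- plasma[t] * decay + config$absorption_fraction * dose
  }
  p_at <- function(t) ifelse(t >= 0, plasma[t + 1L], 0)

  w <- exp(config$yolk_growth_rate * seq_len(YOLK_WINDOW))
  w <- w / sum(w)   # w[j]: weight of the day j steps into the growth window

  days <- 0:n_days
  albumen <- config$albumen_partition * vapply(days, function(t) {
    if (t >= 1) p_at(t - 1L) else 0
  }, 0)
  yolk <- config$yolk_partition * vapply(days, function(t) {
    # the yolk laid on day t grew over days t - 10 .. t - 1; w[j] weights
    # the plasma of the day that sits j steps into that window
    sum(w * vapply(seq_len(YOLK_WINDOW),
                   function(j) p_at(t - (YOLK_WINDOW - j) - 1L), 0))
  }, 0)
  conc <- config$yolk_mass_fraction * yolk +
    (1 - config$yolk_mass_fraction) * albumen

  if (config$noise_cv > 0) {
    set.seed(config$seed)
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    conc <- conc * stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog)
  }
  out <- data.frame(day = days, plasma = plasma[days + 1L],
                    albumen = albumen, yolk = yolk, concentration = conc)
  class(out) <- c("depletion_series", "data.frame")
  out
}

#' Packaged depletion defaults for the dosing-study drugs
#'
#' Mean-curve (noise-free) depletion configurations for the five feed-
#' administered drugs plus the enrofloxacin metabolite ciprofloxacin,
#' together with the linear response factor (response units per ug/kg) and
#' the constant baseline noise used when converting concentrations to
#' instrument responses.  The partition scales are calibrated so the
#' noise-free series cross their positive-control levels at the
#' post-treatment day counts observed in the residue study (enrofloxacin 9,
#' ciprofloxacin 6, doxycycline 4, lincomycin 1, oxytetracycline never,
#' neomycin undetectable).
#'
#' @param drug one of `"neomycin"`, `"enrofloxacin"`, `"ciprofloxacin"`,
#'   `"lincomycin"`, `"oxytetracycline"`, `"doxycycline"`; omit to list all.
#' @return for one drug, a list with elements `config`
#'   (a [depletion_sim_config()]), `response_factor` and `noise_floor`;
#'   otherwise the named list of all six.
#' @export
depletion_defaults <- function(drug = NULL) {
  defaults <- list(
    neomycin = list(
      config = depletion_sim_config("neomycin", absorption_fraction = 0,
                                    elimination_rate = 0.5,
                                    albumen_partition = 1, yolk_partition = 1),
      response_factor = 2, noise_floor = 2),
    enrofloxacin = list(
      config = depletion_sim_config("enrofloxacin",
                                    absorption_fraction = 0.8,
                                    elimination_rate = 0.35,
                                    albumen_partition = 1.3,
                                    yolk_partition = 52,
                                    yolk_growth_rate = 0.3),
      response_factor = 100, noise_floor = 2),
    ciprofloxacin = list(
      config = depletion_sim_config("ciprofloxacin",
                                    absorption_fraction = 0.8,
                                    elimination_rate = 0.45,
                                    albumen_partition = 0.75,
                                    yolk_partition = 33.75,
                                    yolk_growth_rate = 0.3),
      response_factor = 100, noise_floor = 2),
    lincomycin = list(
      config = depletion_sim_config("lincomycin", absorption_fraction = 0.8,
                                    elimination_rate = 1.1,
                                    albumen_partition = 80,
                                    yolk_partition = 8,
                                    yolk_growth_rate = 0.3),
      response_factor = 20, noise_floor = 2),
    oxytetracycline = list(
      config = depletion_sim_config("oxytetracycline",
                                    absorption_fraction = 0.3,
                                    elimination_rate = 0.5,
                                    albumen_partition = 120,
                                    yolk_partition = 240,
                                    yolk_growth_rate = 0.3),
      response_factor = 3, noise_floor = 2),
    doxycycline = list(
      config = depletion_sim_config("doxycycline", absorption_fraction = 0.8,
                                    elimination_rate = 0.45,
                                    albumen_partition = 110,
                                    yolk_partition = 550,
                                    yolk_growth_rate = 0.25),
      response_factor = 3, noise_floor = 2)
  )
  if (is.null(drug)) return(defaults)
  if (!drug %in% names(defaults))
    panel_error(sprintf("no packaged depletion defaults for drug '%s'", drug))
  defaults[[drug]]
}

#' Validation simulator defaults consistent with the study fixtures
#'
#' Returns a [validation_sim_config()] for one of the dosing-study drugs
#' whose spike mean equals the study fixture's response at the analyte's
#' validation level and whose relative spread (20% replicate CV plus an 8%
#' between-day effect) keeps the cut-off factor comfortably below the
#' positive-control response while holding sensitivity near 100%.
#'
#' @param drug a drug with packaged depletion defaults.
#' @param panel an [analyte_panel()].
#' @param seed RNG seed.
#' @return a [validation_sim_config()].
#' @export
validation_sim_defaults <- function(drug, panel = default_panel(), seed = 1L) {
  dd <- depletion_defaults(drug)
  spike_mean <- dd$response_factor * validation_level(drug, panel)
  validation_sim_config(
    noise_mean = dd$noise_floor, noise_sd = 0.3 * dd$noise_floor,
    spike_mean = spike_mean, spike_sd = 0.20 * spike_mean,
    day_effect_sd = 0.08 * spike_mean, seed = seed)
}

#' End-to-end study fixture for one treatment group
#'
#' Emits the response table and batch manifest of a simulated residue study:
#' an untreated control group and a treated group, each with 6 pooled-egg
#' replicates per day over a pre-treatment day (day 0) and 15 study days
#' (5 dosing + 10 washout), plus 2 positive-control replicates (spiked at
#' 0.75 x the validation level) per day.  Concentrations from the packaged
#' depletion defaults are converted to responses through the drug's linear
#' response factor; the constant baseline `noise_floor` is recorded as the
#' noise of every record.  The enrofloxacin fixture also emits its
#' metabolite ciprofloxacin, from the metabolite's own depletion defaults.
#'
#' @param drug one of the drugs covered by [depletion_defaults()] (not
#'   `"ciprofloxacin"`, which only occurs as the enrofloxacin metabolite).
#' @param panel an [analyte_panel()].
#' @param noise_cv replicate-level concentration noise (default 0: the mean
#'   curve, giving a fully deterministic fixture).
#' @param n_replicates pooled-egg replicates per group and day (default 6).
#' @param n_controls positive-control replicates per day (default 2).
#' @param seed RNG seed (used when `noise_cv > 0`).
#' @return list with `records` (response table), `manifest` (batch manifest)
#'   and `treatment_end_day` (5).
#' @export
study_fixture <- function(drug, panel = default_panel(), noise_cv = 0,
                          n_replicates = 6L, n_controls = 2L, seed = 1L) {
  valid <- setdiff(names(depletion_defaults()), "ciprofloxacin")
  if (!drug %in% valid)
    panel_error(sprintf("no packaged study fixture for drug '%s'", drug))
  analytes <- if (drug == "enrofloxacin") c("enrofloxacin", "ciprofloxacin")
              else drug
  set.seed(seed)

  records <- list()
  manifest <- list()
  add <- function(df) records[[length(records) + 1L]] <<- df
  addm <- function(df) manifest[[length(manifest) + 1L]] <<- df

  for (a in analytes) {
    dd <- depletion_defaults(a)
    cfg <- dd$config
    cfg$noise_cv <- 0                     # noise applied per replicate below
    series <- simulate_depletion(cfg)
    an <- get_analyte(panel, a)
    tr_maj <- get_transition(an, "major")
    tr_min <- get_transition(an, "minor1")
    ref <- tr_min$reference_relative_intensity
    scale_minor <- if (is.null(ref)) 1 else ref / 100
    pc_resp <- dd$response_factor * positive_control_level(a, panel)
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0

    emit <- function(group, day, rep, conc, kind, role, id) {
      if (sdlog > 0)
        conc <- conc * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      resp <- dd$response_factor * conc
      add(data.frame(
        sample_id = id, day = day, replicate = rep, analyte = a,
        transition_rank = c("major", "minor1"),
        response = c(resp, scale_minor * resp),
        noise = dd$noise_floor,
        observed_rt = c(tr_maj$expected_rt, tr_min$expected_rt),
        sample_kind = kind, stringsAsFactors = FALSE))
      addm(data.frame(sample_id = id, group = group, day = day, role = role,
                      analyte = a, stringsAsFactors = FALSE))
    }

    for (d in series$day) {
      conc_d <- series$concentration[series$day == d]
      for (r in seq_len(n_replicates)) {
        emit("control", d, r, 0, "study", "study",
             sprintf("%s_control_d%02d_r%d", a, d, r))
        emit("treated", d, r, conc_d, "study", "study",
             sprintf("%s_treated_d%02d_r%d", a, d, r))
      }
      for (r in seq_len(n_controls)) {
        id <- sprintf("%s_pc_d%02d_r%d", a, d, r)
        if (sdlog > 0) {
          conc_pc <- positive_control_level(a, panel) *
            stats::rlnorm(1, -sdlog^2 / 2, sdlog)
          resp <- dd$response_factor * conc_pc
        } else resp <- pc_resp
        add(data.frame(
          sample_id = id, day = d, replicate = r, analyte = a,
          transition_rank = c("major", "minor1"),
          response = c(resp, scale_minor * resp),
          noise = dd$noise_floor,
          observed_rt = c(tr_maj$expected_rt, tr_min$expected_rt),
          sample_kind = "spiked", stringsAsFactors = FALSE))
        addm(data.frame(sample_id = id, group = "treated", day = d,
                        role = "positive_control", analyte = a,
                        stringsAsFactors = FALSE))
      }
    }
  }
  list(records = as_response_table(do.call(rbind, records)),
       manifest = as_batch_manifest(do.call(rbind, manifest)),
       treatment_end_day = depletion_defaults(drug)$config$dose_days)
}
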