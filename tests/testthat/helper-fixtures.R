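# Shared fixtures and naive reference implementations used as independent
# oracles against the package's vectorised code paths.

tiny_panel <- function() {
  analyte_panel(
    analytes = list(
      list(name = "drug_a", family = "quinolones",
           regulatory_status = "banned", combined_residue = FALSE,
           extraction_route = "tca",
           transitions = list(
             list(rank = "major", precursor_mz = 300, product_mz = 282,
                  declustering_potential = 50, collision_energy = 30,
                  expected_rt = 5.0),
             list(rank = "minor1", precursor_mz = 300, product_mz = 250,
                  declustering_potential = 50, collision_energy = 40,
                  expected_rt = 5.0, reference_relative_intensity = 80,
                  reference_relative_intensity_sd = 5))),
      list(name = "drug_b", family = "tetracyclines",
           regulatory_status = "mrl_established", mrl = 400,
           combined_residue = TRUE, extraction_route = "tca",
           transitions = list(
             list(rank = "major", precursor_mz = 450, product_mz = 410,
                  declustering_potential = 55, collision_energy = 25,
                  expected_rt = 6.0),
             list(rank = "minor1", precursor_mz = 450, product_mz = 154,
                  declustering_potential = 55, collision_energy = 40,
                  expected_rt = 6.0, reference_relative_intensity = 25,
                  reference_relative_intensity_sd = 2)))),
    qualitative_default_levels = list(quinolones = 10, tetracyclines = 300),
    name = "tiny")
}

# one sample's records for drug_a, defaults give a clean identification
sample_records <- function(resp_major = 100, resp_minor = 80,
                           noise_major = 5, noise_minor = 5,
                           rt = 5.0, sample_id = "s1", kind = "study") {
  data.frame(sample_id = sample_id, day = 1, replicate = 1,
             analyte = "drug_a", transition_rank = c("major", "minor1"),
             response = c(resp_major, resp_minor),
             noise = c(noise_major, noise_minor),
             observed_rt = rt, sample_kind = kind,
             stringsAsFactors = FALSE)
}

control_records <- function(resp = 75, n = 2) {
  do.call(rbind, lapply(seq_len(n), function(r)
    sample_records(resp_major = resp, resp_minor = 0.8 * resp,
                   sample_id = sprintf("pc%d", r), kind = "spiked")))
}

fake_validation <- function(fc_major = 50, fc_minor = 40) {
  data.frame(analyte = "drug_a", transition_rank = c("major", "minor1"),
             t_value = c(10, 8), fc = c(fc_major, fc_minor),
             lod = 1, ccbeta_verdict = "below_level", sensitivity_pct = 100,
             stringsAsFactors = FALSE)
}

# Naive oracles: loop/closed-form re-implementations, kept deliberately
# independent of the package's code paths.
naive_mean <- function(x) sum(x) / length(x)
naive_sd <- function(x) {
  m <- naive_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
naive_t_value <- function(x, k = 1.64) naive_mean(x) + k * naive_sd(x)
naive_cutoff <- function(x, k = 1.64) naive_mean(x) - k * naive_sd(x)
naive_lod <- function(b, c, m) 3 * b * c / m
naive_sensitivity <- function(x, fc) {
  hits <- 0
  for (v in x) if (v >= fc) hits <- hits + 1
  100 * hits / length(x)
}
naive_timeline <- function(days, compliance, end) {
  last <- 0
  for (i in seq_along(days)) {
    if (days[i] > end && compliance[i] == "noncompliant")
      last <- max(last, days[i] - end)
  }
  as.integer(last)
}
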