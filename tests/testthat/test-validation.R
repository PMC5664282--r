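test_that("t_value matches hand arithmetic and degenerate cases", {
  expect_equal(t_value(rep(2, 20)), 2.0)
  expect_equal(t_value(c(1, 2, 3)), 3.64)          # mean 2, sample sd 1
  # ten 1s and ten 3s: mean 2, sd = sqrt(20/19)
  expect_equal(t_value(rep(c(1, 3), each = 10)), 2 + 1.64 * sqrt(20 / 19))
  expect_error(t_value(5), class = "eggscreen_insufficient_data")
})

test_that("cutoff_factor matches hand arithmetic and flags low signal", {
  expect_equal(cutoff_factor(rep(100, 60)), 100)
  # thirty 90s, thirty 110s: mean 100, sd = sqrt(6000/59)
  expect_equal(as.numeric(cutoff_factor(rep(c(90, 110), each = 30))),
               100 - 1.64 * sqrt(6000 / 59))
  # spread exceeding the mean drives the cut-off negative, flagged not clamped
  low <- c(0, 0, 0, 40)                            # mean 10, sd 20
  fc <- cutoff_factor(low)
  expect_lt(as.numeric(fc), 0)
  expect_identical(attr(fc, "flag"), "low_signal")
  expect_error(cutoff_factor(numeric()), class = "eggscreen_insufficient_data")
})

test_that("lod follows the 3 x noise rule and its algebraic identities", {
  expect_equal(lod(0, 10, 150), 0)                 # noiseless limit
  expect_equal(lod(5, 10, 150), 1.0)
  # when mean noise is a third of the response, LOD equals the spike level
  expect_equal(lod(50, 42, 150), 42)
  # linear in noise and concentration, inverse in response
  expect_equal(lod(10, 10, 150), 2 * lod(5, 10, 150))
  expect_equal(lod(5, 20, 150), 2 * lod(5, 10, 150))
  expect_equal(lod(5, 10, 300), lod(5, 10, 150) / 2)
  expect_error(lod(5, 10, 0), class = "eggscreen_undefined_lod")
})

test_that("CCbeta verdict compares Fc with the T-value, ties conservative", {
  expect_equal(ccbeta_verdict(120, 80), "below_level")
  expect_equal(ccbeta_verdict(50, 80), "above_level")
  expect_equal(ccbeta_verdict(80, 80), "above_level")
})

test_that("sensitivity counts detections at or above the cut-off", {
  x <- c(rep(10, 19), 1)
  expect_equal(sensitivity(x, 5), 95)
  expect_equal(sensitivity(rep(10, 20), 5), 100)
  expect_equal(sensitivity(rep(1, 20), 5), 0)
  expect_equal(sensitivity(c(5, 5, 10, 1), 5), 75)  # ties count as positive
  expect_error(sensitivity(numeric(), 5),
               class = "eggscreen_insufficient_data")
})

test_that("threshold monotonicity: spread widens T upward and Fc downward", {
  set.seed(42)
  base <- rnorm(30, 100, 5)
  wide <- mean(base) + 3 * (base - mean(base))     # same mean, triple sd
  expect_equal(mean(wide), mean(base))
  expect_gt(t_value(wide), t_value(base))
  expect_lt(as.numeric(cutoff_factor(wide)), as.numeric(cutoff_factor(base)))
  expect_gte(t_value(base), mean(base))
  expect_lte(as.numeric(cutoff_factor(base)), mean(base))
})

test_that("sensitivity is a multiple of 100/n and non-increasing in fc", {
  set.seed(7)
  for (i in 1:20) {
    x <- runif(sample(3:12, 1), 0, 100)
    fc1 <- runif(1, 0, 100)
    fc2 <- fc1 + runif(1, 0, 50)
    s1 <- sensitivity(x, fc1)
    s2 <- sensitivity(x, fc2)
    expect_gte(s1, s2)
    # s1 is an integer count of detections times 100/n
    expect_equal(s1 * length(x) / 100, round(s1 * length(x) / 100))
  }
})

test_that("selectivity flags co-eluting blank signals inside the RT window", {
  pan <- tiny_panel()
  blanks <- data.frame(
    sample_id = c("b1", "b2", "b3"), day = 1, replicate = 1:3,
    analyte = "drug_a", transition_rank = "major",
    response = c(50, 0, 50), noise = c(5, 5, 5),
    observed_rt = c(5.0, 5.0, 6.5),                # b3 elutes off-window
    sample_kind = "blank", stringsAsFactors = FALSE)
  flags <- selectivity_check(blanks, pan)
  expect_equal(nrow(flags), 1L)
  expect_equal(flags$sample_id, "b1")
  expect_equal(flags$snr, 10)
  # clean blanks produce no flags
  clean <- blanks
  clean$response <- 0
  expect_equal(nrow(selectivity_check(clean, pan)), 0L)
})

test_that("validate_panel aggregates blanks and pooled spiked days", {
  pan <- tiny_panel()
  cfg <- validation_sim_config(noise_mean = 2, noise_sd = 0.5,
                               spike_mean = 200, spike_sd = 10,
                               day_effect_sd = 5, seed = 123)
  rec <- simulate_validation(cfg, pan, "drug_a")
  res <- validate_panel(rec, pan)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$transition_rank, c("major", "minor1"))
  expect_equal(res$n_blanks, c(20L, 20L))
  expect_equal(res$n_spiked_fc, c(60L, 60L))
  # strong spike: both transitions pass, with sensitivity near 100 (the
  # cut-off sits 1.64 sd below the mean, so ~5% of replicates miss it)
  expect_true(all(res$ccbeta_verdict == "below_level"))
  expect_true(all(res$fc > 10 * res$t_value))
  expect_true(all(res$sensitivity_pct >= 85))
  # cross-check one transition against the scalar operations
  maj <- rec[rec$transition_rank == "major", ]
  expect_equal(res$t_value[res$transition_rank == "major"],
               t_value(maj$noise[maj$sample_kind == "blank"]))
  expect_equal(res$fc[res$transition_rank == "major"],
               as.numeric(cutoff_factor(maj$response[maj$sample_kind == "spiked"])))
})

test_that("validate_panel reports coverage gaps and empty input", {
  pan <- tiny_panel()
  expect_error(validate_panel(sample_records()[0, ], pan),
               class = "eggscreen_coverage_error")
  cfg <- validation_sim_config(noise_mean = 2, noise_sd = 0.5,
                               spike_mean = 200, spike_sd = 10,
                               n_per_day = 5, seed = 1)   # only 15 spiked
  rec <- simulate_validation(cfg, pan, "drug_a")
  expect_error(validate_panel(rec, pan), class = "eggscreen_coverage_error")
})
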