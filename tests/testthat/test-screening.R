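test_that("two-transition identification requires S/N, RT and ion ratio", {
  pan <- tiny_panel()
  # all criteria met: S/N {20, 16}, RT on target, ratio 80 vs reference 80
  ok <- identify_analyte(sample_records(), pan)
  expect_true(ok$identified)
  expect_true(ok$snr_ok && ok$rt_ok && ok$ion_ratio_ok)
  expect_equal(ok$ion_ratio, 80)

  # minor transition S/N at 2.5 blocks identification
  low_snr <- identify_analyte(sample_records(resp_minor = 12.5), pan)
  expect_false(low_snr$identified)

  # ratio 40 vs reference 80 falls outside the +/-20% band
  bad_ratio <- identify_analyte(sample_records(resp_minor = 40), pan)
  expect_false(bad_ratio$identified)
  expect_false(bad_ratio$ion_ratio_ok)
  expect_true(bad_ratio$snr_ok)

  # major transition off retention time
  off_rt <- identify_analyte(sample_records(rt = 5.5), pan)
  expect_false(off_rt$identified)
  expect_false(off_rt$rt_ok)

  # missing confirmation transition is an error, not a negative call
  maj_only <- sample_records()[1, ]
  expect_error(identify_analyte(maj_only, pan),
               class = "eggscreen_incomplete_sample")
})

test_that("ion-ratio tolerance tiers widen as the reference ratio falls", {
  expect_equal(ion_ratio_tolerance(80), 0.20)
  expect_equal(ion_ratio_tolerance(35), 0.25)
  expect_equal(ion_ratio_tolerance(15), 0.30)
  expect_equal(ion_ratio_tolerance(8), 0.50)
  expect_equal(ion_ratio_tolerance(50), 0.25)      # boundary goes to wider tier
})

test_that("positivity gates on identification and the major-transition Fc", {
  pan <- tiny_panel()
  val <- fake_validation(fc_major = 50)
  expect_true(screen_sample(sample_records(resp_major = 100, resp_minor = 80),
                            val, pan)$positive)
  # identified but below the cut-off
  expect_false(screen_sample(sample_records(resp_major = 40, resp_minor = 32),
                             val, pan)$positive)
  # response exactly at Fc counts as positive (consumer-protective tie)
  expect_true(screen_sample(sample_records(resp_major = 50, resp_minor = 40),
                            val, pan)$positive)
  # unidentified sample is negative regardless of response
  expect_false(screen_sample(sample_records(resp_major = 1000,
                                            resp_minor = 10),
                             val, pan)$positive)
  expect_error(screen_sample(sample_records(), fake_validation()[0, ], pan),
               class = "eggscreen_unvalidated_analyte")
})

test_that("compliance compares the sample with the batch positive control", {
  pan <- tiny_panel()
  val <- fake_validation(fc_major = 50)
  ctrl <- control_records(resp = 75)

  high <- classify_compliance(sample_records(resp_major = 150,
                                             resp_minor = 120),
                              ctrl, val, pan)
  expect_equal(high$compliance, "noncompliant")
  expect_true(high$identified && high$positive)

  low <- classify_compliance(sample_records(resp_major = 60, resp_minor = 48),
                             ctrl, val, pan)
  expect_equal(low$compliance, "compliant")

  # exactly at the control mean stays compliant (strict inequality)
  at <- classify_compliance(sample_records(resp_major = 75, resp_minor = 60),
                            ctrl, val, pan)
  expect_equal(at$compliance, "compliant")

  # nothing above S/N 3: not detected
  nd <- classify_compliance(sample_records(resp_major = 10, resp_minor = 8,
                                           noise_major = 8, noise_minor = 8),
                            ctrl, val, pan)
  expect_equal(nd$compliance, "not_detected")
  expect_false(nd$identified)

  expect_error(classify_compliance(sample_records(), ctrl[0, ], val, pan),
               class = "eggscreen_batch_control_error")
})

test_that("gating chain holds: not identified => not positive => not noncompliant", {
  pan <- tiny_panel()
  val <- fake_validation(fc_major = 50)
  ctrl <- control_records(resp = 75)
  set.seed(99)
  for (i in 1:50) {
    rec <- sample_records(resp_major = runif(1, 0, 300),
                          resp_minor = runif(1, 0, 300),
                          noise_major = runif(1, 1, 30),
                          noise_minor = runif(1, 1, 30),
                          rt = runif(1, 4.5, 5.5))
    call <- classify_compliance(rec, ctrl, val, pan)
    if (!call$identified) {
      expect_false(call$positive)
      expect_equal(call$compliance, "not_detected")
    }
    if (call$compliance == "noncompliant") {
      expect_true(call$identified && call$positive)
      expect_gt(call$response_major, call$control_mean)
    }
  }
})

test_that("compliance is monotone in the major-transition response", {
  pan <- tiny_panel()
  val <- fake_validation(fc_major = 50)
  ctrl <- control_records(resp = 75)
  rank <- c(not_detected = 0, compliant = 1, noncompliant = 2)
  responses <- seq(10, 200, by = 10)
  calls <- vapply(responses, function(r) {
    classify_compliance(sample_records(resp_major = r, resp_minor = 0.8 * r,
                                       noise_major = 2, noise_minor = 2),
                        ctrl, val, pan)$compliance
  }, "")
  expect_true(all(diff(rank[calls]) >= 0))
})

test_that("compliance_timeline equals a brute-force day scan", {
  calls <- data.frame(day = 0:15,
                      compliance = c(rep("not_detected", 2),
                                     rep("noncompliant", 12),
                                     rep("compliant", 2)))
  expect_equal(compliance_timeline(calls, 5), 8L)
  expect_equal(compliance_timeline(calls, 13), 0L)

  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    calls <- data.frame(
      day = 0:(n - 1),
      compliance = sample(c("compliant", "noncompliant", "not_detected"),
                          n, replace = TRUE))
    end <- sample(1:(n - 2), 1)
    expect_equal(compliance_timeline(calls, end),
                 naive_timeline(calls$day, calls$compliance, end))
  }
})
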