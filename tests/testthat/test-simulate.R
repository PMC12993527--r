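test_that("cohort simulation is reproducible and validates inputs", {
  a <- simulate_cohort(25, seed = 5)
  b <- simulate_cohort(25, seed = 5)
  expect_identical(a$absolute, b$absolute)
  expect_identical(a$metadata, b$metadata)
  c2 <- simulate_cohort(25, seed = 6)
  expect_false(identical(a$absolute, c2$absolute))
  expect_error(simulate_cohort(0), "positive integer")
  bad <- default_effect_config()
  bad$scenario_weights <- c(healthy = 0.5, mild = 0.5, severe = 0.5)
  expect_error(simulate_cohort(5, config = bad), "sum to 1")
  bad2 <- default_effect_config()
  bad2$baseline$sd[1] <- 0
  expect_error(simulate_cohort(5, config = bad2), "SDs must be")
})

test_that("configured group effects shift marker means by the stated delta", {
  cfg <- default_effect_config()
  cfg$effects <- data.frame(variable = "sex", level = "female",
                            marker = "AKK", delta = 1.0,
                            stringsAsFactors = FALSE)
  ch <- simulate_cohort(2000, config = cfg, seed = 41)
  f <- ch$metadata$sex == "female"
  diff_akk <- mean(ch$relative_log[f, "AKK"]) - mean(ch$relative_log[!f, "AKK"])
  sd_akk <- cfg$baseline$sd[cfg$baseline$marker == "AKK"]
  se <- sd_akk * sqrt(1 / sum(f) + 1 / sum(!f))
  expect_lt(abs(diff_akk - 1.0), 3 * se)
  # untouched marker shows no such shift
  diff_fir <- mean(ch$relative_log[f, "FIR"]) - mean(ch$relative_log[!f, "FIR"])
  sd_fir <- cfg$baseline$sd[cfg$baseline$marker == "FIR"]
  expect_lt(abs(diff_fir), 4 * sd_fir * sqrt(1 / sum(f) + 1 / sum(!f)))
})

test_that("metadata frequencies follow the configured cohort composition", {
  ch <- simulate_cohort(5000, seed = 43)
  expect_equal(mean(ch$metadata$sex == "female"), 0.7013, tolerance = 0.02)
  expect_true(all(ch$metadata$age >= 18))
  expect_true(all(ch$metadata$bmi > 0))
})

test_that("noise-free plates invert the quantification model exactly", {
  ch <- simulate_cohort(10, seed = 47)
  ex <- fixture_extraction()
  curves <- default_curves()
  plate <- simulate_plate(ch, curves, ex, ct_noise_sd = 0, seed = 47)
  # the worked calibration point: abundance 2.5e6, Cg = 5, slope -3.5, b 38
  ct <- 38 + (-3.5) * log10(2.5e6 * 0.04 * 5 * 2 / 100)
  expect_equal(ct, 24.0)
  profs <- quantify_samples(plate, curves, ex)
  ids <- ch$metadata$sample_id
  for (i in seq_along(ids)) {
    got <- profs[[ids[i]]]$absolute
    truth <- ch$absolute[i, names(got)]
    expect_lt(max(abs(got - truth) / truth), 1e-6)
  }
})

test_that("plates have two replicates per marker and censor beyond 40 cycles", {
  ch <- simulate_cohort(5, seed = 53)
  ex <- fixture_extraction()
  plate <- simulate_plate(ch, default_curves(), ex, seed = 53)
  counts <- table(plate$sample_id, plate$marker)
  expect_true(all(counts == 2))
  # a vanishingly rare organism never crosses threshold within 40 cycles
  low <- matrix(c(1e9, 0.1), 1, 2, dimnames = list("L1", c("EUB", "CAN")))
  plate_low <- simulate_plate(low, default_curves(), ex, seed = 53)
  expect_true(all(is.na(plate_low$ct[plate_low$marker == "CAN"])))
  expect_false(anyNA(plate_low$ct[plate_low$marker == "EUB"]))
  expect_error(simulate_plate(low * -1, default_curves(), ex), "positive")
})

test_that("replicate noise has the requested spread", {
  ch <- simulate_cohort(40, seed = 59)
  ex <- fixture_extraction()
  plate <- simulate_plate(ch, default_curves(), ex, ct_noise_sd = 0.25,
                          seed = 59)
  # paired duplicates: Var(ct1 - ct2) = 2 * noise_sd^2
  w <- reshape(plate, idvar = c("sample_id", "marker"),
               timevar = "replicate", direction = "wide")
  d <- w$ct.1 - w$ct.2
  expect_equal(sd(d, na.rm = TRUE), 0.25 * sqrt(2), tolerance = 0.15)
})

test_that("intended categories follow the realized generating index", {
  ch <- simulate_cohort(300, seed = 61)
  expect_identical(ch$intended_category,
                   vapply(ch$dysbiosis_value, dysbiosis_category, character(1)))
  # scenario mixing produces all three categories at the default weights
  expect_setequal(unique(ch$intended_category),
                  c("healthy", "mild", "severe"))
})

test_that("range fitting recovers generating parameters on a healthy cohort", {
  # homogeneous healthy reference population: healthy scenario, no group
  # effects, so the generating mean/SD of every marker is known exactly
  cfg <- default_effect_config(scenario_weights = c(healthy = 1, mild = 0,
                                                    severe = 0))
  cfg$effects <- cfg$effects[0, ]
  ch <- simulate_cohort(500, config = cfg, seed = 67)
  fit <- fit_tolerance_ranges(ch$relative_log)
  est <- coef(fit)
  # generating means include the healthy scenario re-centring on FAE/ECO
  gen_mean <- stats::setNames(cfg$baseline$mean, cfg$baseline$marker)
  shift <- (cfg$scenario_targets[["healthy"]] -
              (gen_mean[["FAE"]] - gen_mean[["ECO"]]))
  gen_mean["FAE"] <- gen_mean["FAE"] + shift / 2
  gen_mean["ECO"] <- gen_mean["ECO"] - shift / 2
  gen_sd <- stats::setNames(cfg$baseline$sd, cfg$baseline$marker)
  mks <- rownames(est)
  expect_lt(max(abs(est[mks, "mean"] - gen_mean[mks])), 0.05)
  expect_lt(max(abs(est[mks, "sd"] / gen_sd[mks] - 1)), 0.10)
})
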