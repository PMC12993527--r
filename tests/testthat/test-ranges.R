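test_that("limit placement follows marker class with one-decade beyond limits", {
  # frozen cohorts engineered to have exact mean/sd: for values mu +/- s,
  # mean = mu and sample sd = s * sqrt(2) / sqrt(1) ... use explicit pairs
  mk_cohort <- function(marker, mu, s) {
    # two points mu - s and mu + s have mean mu and sample sd s * sqrt(2)
    m <- matrix(c(mu - s / sqrt(2), mu + s / sqrt(2)), 2, 1,
                dimnames = list(NULL, marker))
    m
  }
  # beneficial marker, mean -2.0, sd 0.5
  fit_b <- fit_tolerance_ranges(mk_cohort("AKK", -2.0, 0.5))
  r <- fit_b$ranges
  expect_equal(r$borderline_low, -2.5)
  expect_equal(r$beyond_low, -3.5)
  expect_true(is.na(r$borderline_high) && is.na(r$beyond_high))

  # harmful marker, mean -4.0, sd 0.3
  fit_h <- fit_tolerance_ranges(mk_cohort("ECO", -4.0, 0.3))
  r <- fit_h$ranges
  expect_equal(r$borderline_high, -3.7)
  expect_equal(r$beyond_high, -2.7)
  expect_true(is.na(r$borderline_low) && is.na(r$beyond_low))

  # bidirectional marker, mean -3.0, sd 0.4
  fit_2 <- fit_tolerance_ranges(mk_cohort("CLO", -3.0, 0.4))
  r <- fit_2$ranges
  expect_equal(c(r$borderline_low, r$borderline_high), c(-3.4, -2.6))
  expect_equal(c(r$beyond_low, r$beyond_high), c(-4.4, -1.6))

  # beyond limits strictly more extreme than borderline limits
  expect_true(r$beyond_low < r$borderline_low)
  expect_true(r$beyond_high > r$borderline_high)
})

test_that("fitting uses sample SD and rejects degenerate cohorts", {
  v <- c(-2.1, -1.9, -2.4, -1.7)
  fit <- fit_tolerance_ranges(matrix(v, ncol = 1,
                                     dimnames = list(NULL, "FAE")))
  expect_equal(fit$ranges$mean, mean(v))
  expect_equal(fit$ranges$sd, sd(v))
  expect_equal(fit$cohort_n, 4)
  expect_error(fit_tolerance_ranges(matrix(-2, 1, 1,
                                           dimnames = list(NULL, "FAE"))),
               "at least 2")
  expect_error(fit_tolerance_ranges(matrix(-2, 5, 1,
                                           dimnames = list(NULL, "FAE"))),
               "degenerate")
  expect_error(fit_tolerance_ranges(matrix(rnorm(4), 2, 2,
                                           dimnames = list(NULL, c("FAE", "ZZZ")))),
               "unknown marker")
})

test_that("refitting the same cohort is deterministic", {
  set.seed(7)
  m <- matrix(rnorm(100, -2, 0.4), 50, 2,
              dimnames = list(NULL, c("AKK", "ECO")))
  expect_identical(coef(fit_tolerance_ranges(m)),
                   coef(fit_tolerance_ranges(m)))
})

test_that("classify_marker respects interval membership and boundary policy", {
  rng <- range_row(borderline_low = -2.5, beyond_low = -3.5)
  expect_equal(classify_marker(-2.2, rng), "normal")
  expect_equal(classify_marker(-3.0, rng), "borderline")
  expect_equal(classify_marker(-4.0, rng), "beyond")
  # boundary values take the less severe side
  expect_equal(classify_marker(-2.5, rng), "normal")
  expect_equal(classify_marker(-3.5, rng), "borderline")
  expect_error(classify_marker(NaN, rng), "finite")

  rng2 <- range_row(borderline_low = -3.4, beyond_low = -4.4,
                    borderline_high = -2.6, beyond_high = -1.6)
  expect_equal(classify_marker(-3.0, rng2), "normal")
  expect_equal(classify_marker(-2.0, rng2), "borderline")
  expect_equal(classify_marker(-1.0, rng2), "beyond")
  expect_equal(classify_marker(-4.6, rng2), "beyond")
})

test_that("status severity is monotone in the clinically adverse direction", {
  ben <- range_row(borderline_low = -2.5, beyond_low = -3.5)
  har <- range_row(borderline_high = -3.7, beyond_high = -2.7)
  bid <- range_row(borderline_low = -3.4, beyond_low = -4.4,
                   borderline_high = -2.6, beyond_high = -1.6)
  sev <- c(normal = 0, borderline = 1, beyond = 2)
  grid <- seq(-6, 1, by = 0.01)
  s_ben <- sev[vapply(grid, classify_marker, character(1), range = ben)]
  s_har <- sev[vapply(grid, classify_marker, character(1), range = har)]
  expect_true(all(diff(s_ben) <= 0))  # higher value never worse (beneficial)
  expect_true(all(diff(s_har) >= 0))  # higher value never better (harmful)
  # bidirectional: severity non-decreasing in |value - mean| (mean -3.0)
  d <- abs(grid + 3.0)
  s_bid <- sev[vapply(grid, classify_marker, character(1), range = bid)]
  ord <- order(d)
  expect_true(all(diff(s_bid[ord]) >= 0 | diff(d[ord]) == 0))
})

test_that("classify_profile applies below-detection policy by marker class", {
  set.seed(3)
  cohort <- matrix(rnorm(200, -2, 0.4), 50, 4,
                   dimnames = list(NULL, c("AKK", "ECO", "CLO", "FAE")))
  fit <- fit_tolerance_ranges(cohort)
  p <- make_profile(c(EUB = 1e9, AKK = NA, ECO = NA, CLO = 1e7, FAE = 1e7))
  # no EUB range fitted here -> restrict to fitted markers
  p$absolute <- p$absolute[c("AKK", "ECO", "CLO", "FAE")]
  st <- classify_profile(p, fit)
  expect_equal(unname(st["AKK"]), "beyond")   # missing beneficial = deficit
  expect_equal(unname(st["ECO"]), "normal")   # missing harmful = unremarkable
  expect_error(classify_profile(make_profile(c(EUB = 1e9, RUM = 1e7)), fit),
               "RUM")
})

test_that("profiles at the cohort mean classify normal everywhere", {
  set.seed(5)
  markers <- c("AKK", "ECO", "CLO", "FAE", "FIR", "BAC")
  cohort <- matrix(rnorm(600, -2, 0.5), 100, length(markers),
                   dimnames = list(NULL, markers))
  fit <- fit_tolerance_ranges(cohort)
  means <- coef(fit)[, "mean"]
  p <- make_profile(c(10^(means[markers] + 9), EUB = 1e9))
  p$absolute <- p$absolute[markers]  # EUB not in this fit
  st <- classify_profile(p, fit)
  expect_true(all(st == "normal"))
})

test_that("predict method returns ordered statuses for profile lists", {
  set.seed(9)
  cohort <- matrix(rnorm(300, -2, 0.4), 100, 3,
                   dimnames = list(NULL, c("AKK", "ECO", "FAE")))
  fit <- fit_tolerance_ranges(cohort)
  profs <- list(
    make_profile(c(EUB = 1e9, AKK = 1e7, ECO = 1e7, FAE = 1e7), "A"),
    make_profile(c(EUB = 1e9, AKK = 1e3, ECO = 1e7, FAE = 1e7), "B"))
  for (i in seq_along(profs))
    profs[[i]]$absolute <- profs[[i]]$absolute[c("AKK", "ECO", "FAE")]
  out <- predict(fit, profs)
  expect_s3_class(out$status, "ordered")
  expect_equal(nrow(out), 6)
  expect_equal(out$status[out$sample_id == "B" & out$marker == "AKK"],
               factor("beyond", levels = c("normal", "borderline", "beyond"),
                      ordered = TRUE))
})

test_that("EUB range is fitted on the absolute log10 scale from profiles", {
  set.seed(11)
  profs <- lapply(1:40, function(i) {
    eub <- 10^rnorm(1, 11, 0.3)
    make_profile(c(EUB = eub, FAE = eub * 10^rnorm(1, -1.3, 0.3)),
                 sample_id = paste0("S", i))
  })
  fit <- fit_tolerance_ranges(profs)
  eub_row <- fit$ranges[fit$ranges$marker == "EUB", ]
  expect_equal(eub_row$mean, 11, tolerance = 0.2)
  expect_equal(eub_row$marker_class, "total")
  expect_false(is.na(eub_row$borderline_low))  # total: low limits only
  expect_true(is.na(eub_row$borderline_high))
})

test_that("direction override flips limit placement", {
  m <- matrix(c(-2.4, -1.6, -2.2, -1.8), 4, 1, dimnames = list(NULL, "AKK"))
  fit <- fit_tolerance_ranges(m, direction = c(AKK = "high"))
  r <- fit$ranges
  expect_true(is.na(r$borderline_low))
  expect_false(is.na(r$borderline_high))
})

test_that("range JSON serialization round-trips at 12 significant digits", {
  set.seed(13)
  cohort <- matrix(rnorm(400, -2.5, 0.45), 100, 4,
                   dimnames = list(NULL, c("AKK", "ECO", "CLO", "EUB")))
  fit <- fit_tolerance_ranges(cohort)
  path <- withr::local_tempfile(fileext = ".json")
  write_ranges_json(fit, path)
  back <- read_ranges_json(path)
  for (col in c("mean", "sd", "borderline_low", "beyond_low",
                "borderline_high", "beyond_high")) {
    expect_equal(back$ranges[[col]], signif(fit$ranges[[col]], 12),
                 tolerance = 1e-12)
  }
  expect_equal(back$cohort_n, fit$cohort_n)
  # and a reread is bit-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_ranges_json(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("simulate method draws from the fitted reference model", {
  set.seed(17)
  cohort <- matrix(rnorm(1000, -2, 0.4), 500, 2,
                   dimnames = list(NULL, c("AKK", "ECO")))
  fit <- fit_tolerance_ranges(cohort)
  sims <- simulate(fit, nsim = 5000, seed = 21)
  expect_equal(dim(sims), c(5000, 2))
  expect_equal(colMeans(sims), coef(fit)[, "mean"], tolerance = 0.05)
  expect_equal(apply(sims, 2, sd), coef(fit)[, "sd"], tolerance = 0.05)
})
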