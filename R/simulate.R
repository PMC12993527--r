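#' Default effect configuration for cohort simulation
#'
#' Defines what the simulator emulates: per-marker baseline means and SDs of
#' log10 relative abundance (vs the total Eubacteria load) typical of a
#' healthy adult gut measured by a broad-group qPCR panel, a log-normal total
#' bacterial load around 10^11 copies per gram of stool, metadata category
#' frequencies matching a predominantly female adult IBS-referral cohort, and
#' group-level log10 shifts oriented by the reported clinical associations
#' (higher A. muciniphila in women; lower A. muciniphila and M. smithii with
#' diarrheal IBS; higher with constipated IBS).
#'
#' The dysbiosis scenario mixes samples whose Faecalibacterium/E. coli index
#' is re-centred on a category-typical value: healthy 1.7, mild 0.16, severe
#' -1.2 (the shift is split between FAE and ECO). Mixing weights give the
#' fraction of samples drawn from each scenario and must sum to 1; the
#' intended category of a sample is always derived from its realized
#' generating index, not the scenario it was drawn from.
#'
#' @param scenario_weights Named numeric, fractions of samples drawn from the
#'   `healthy`, `mild` and `severe` re-centrings; must sum to 1.
#' @return A list of class `effect_config` with elements `baseline`
#'   (data.frame marker/mean/sd on the log10 relative scale), `eub`
#'   (mean/sd of log10 absolute load), `effects` (data.frame
#'   variable/level/marker/delta), `scenario_targets`, `scenario_weights`,
#'   `metadata_freqs`.
#' @export
default_effect_config <- function(scenario_weights = c(healthy = 0.85,
                                                       mild = 0.11,
                                                       severe = 0.04)) {
  baseline <- data.frame(
    marker = c("AKK", "BAC", "CAN", "CLO", "ECO", "ENT", "FAE",
               "FIR", "GAM", "LAC", "MSM", "ROS", "RUM", "XIV"),
    mean = c(-2.5, -0.55, -6.0, -3.5, -3.0, -4.0, -1.3,
             -0.30, -3.5, -3.5, -4.0, -1.8, -1.8, -1.0),
    sd = c(0.45, 0.30, 0.40, 0.40, 0.40, 0.40, 0.30,
           0.25, 0.40, 0.45, 0.45, 0.35, 0.35, 0.30),
    stringsAsFactors = FALSE)
  effects <- data.frame(
    variable = c("sex", "ibs_behavior", "ibs_behavior",
                 "ibs_behavior", "ibs_behavior", "ibs_behavior"),
    level = c("female", "diarrhea", "diarrhea",
              "constipation", "constipation", "mixed"),
    marker = c("AKK", "AKK", "MSM", "AKK", "MSM", "MSM"),
    delta = c(0.40, -0.66, -0.40, 0.60, 0.75, -0.52),
    stringsAsFactors = FALSE)
  cfg <- list(
    baseline = baseline,
    eub = list(mean = 11.0, sd = 0.35),
    effects = effects,
    scenario_targets = c(healthy = 1.7, mild = 0.16, severe = -1.2),
    scenario_weights = scenario_weights,
    metadata_freqs = list(
      sex = c(female = 0.7013, male = 0.2987),
      age = c(young = 12, adult = 89, older = 27) / 128,
      bmi = c(underweight = 4, normal = 43, overweight = 14, obese = 4) / 65,
      ibs_behavior = c(none = 92, diarrhea = 30, constipation = 19,
                       mixed = 13) / 154))
  class(cfg) <- "effect_config"
  validate_effect_config(cfg)
  cfg
}

validate_effect_config <- function(config) {
  problems <- character(0)
  if (!all(c("baseline", "eub", "scenario_targets", "scenario_weights")
           %in% names(config)))
    problems <- c(problems, "missing config elements")
  if (any(config$baseline$sd <= 0))
    problems <- c(problems, "baseline SDs must be > 0")
  if (!is.null(config$eub) && config$eub$sd <= 0)
    problems <- c(problems, "EUB load SD must be > 0")
  w <- config$scenario_weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    problems <- c(problems, "scenario weights must be non-negative and sum to 1")
  if (length(problems))
    stop("invalid effect config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  invisible(config)
}

# Deterministic sub-seeds from one global seed: each simulation stage draws
# from its own stream offset so adding a stage never perturbs earlier draws.
split_seed <- function(seed, stream) {
  (as.integer(seed) * 97L + stream * 1009L) %% 2147483647L
}

#' Simulate a cohort with known ground truth
#'
#' Draws `n` samples: metadata from the configured category frequencies,
#' per-marker log10 relative abundances from Normal(baseline mean +
#' applicable group deltas + scenario shift, baseline SD), and a log-normal
#' EUB absolute load. Absolute marker abundances are the relative abundances
#' times the EUB load; markers are independent on the log scale. Each
#' sample's intended dysbiosis category is derived from its realized
#' generating index.
#'
#' @param n Number of samples (>= 1).
#' @param config An `effect_config`, see [default_effect_config()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param panel A `marker_panel`.
#' @return A list of class `simulated_cohort` with `metadata` (data.frame:
#'   sample_id, sex, age, bmi, ibs_behavior), `relative_log` (matrix samples
#'   x markers), `absolute` (matrix, copies/g, including EUB),
#'   `dysbiosis_value` and `intended_category` (per sample), `seed`.
#' @export
simulate_cohort <- function(n, config = default_effect_config(), seed = 1,
                            panel = default_panel()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  validate_effect_config(config)
  n <- as.integer(n)
  ids <- sprintf("S%04d", seq_len(n))

  # metadata stream
  set.seed(split_seed(seed, 1L))
  f <- config$metadata_freqs
  sex <- sample(names(f$sex), n, replace = TRUE, prob = f$sex)
  agegrp <- sample(names(f$age), n, replace = TRUE, prob = f$age)
  age <- ifelse(agegrp == "young", sample(18:28, n, replace = TRUE),
         ifelse(agegrp == "adult", sample(29:59, n, replace = TRUE),
                sample(60:85, n, replace = TRUE)))
  bmigrp <- sample(names(f$bmi), n, replace = TRUE, prob = f$bmi)
  bmi <- ifelse(bmigrp == "underweight", stats::runif(n, 16, 18.4),
         ifelse(bmigrp == "normal", stats::runif(n, 18.5, 24.9),
         ifelse(bmigrp == "overweight", stats::runif(n, 25, 29.9),
                stats::runif(n, 30, 40))))
  ibs <- sample(names(f$ibs_behavior), n, replace = TRUE,
                prob = f$ibs_behavior)
  metadata <- data.frame(sample_id = ids, sex = sex, age = age,
                         bmi = round(bmi, 1), ibs_behavior = ibs,
                         stringsAsFactors = FALSE)

  # abundance stream
  set.seed(split_seed(seed, 2L))
  scen <- sample(names(config$scenario_weights), n, replace = TRUE,
                 prob = config$scenario_weights)
  markers <- config$baseline$marker
  mu <- matrix(rep(config$baseline$mean, each = n), n, length(markers),
               dimnames = list(ids, markers))
  for (i in seq_len(nrow(config$effects))) {
    e <- config$effects[i, ]
    hit <- metadata[[e$variable]] == e$level
    mu[hit, e$marker] <- mu[hit, e$marker] + e$delta
  }
  # scenario re-centring of the FAE - ECO contrast, split between the two
  base_index <- config$baseline$mean[markers == "FAE"] -
    config$baseline$mean[markers == "ECO"]
  shift <- config$scenario_targets[scen] - base_index
  mu[, "FAE"] <- mu[, "FAE"] + shift / 2
  mu[, "ECO"] <- mu[, "ECO"] - shift / 2

  sds <- config$baseline$sd
  rel <- mu + matrix(stats::rnorm(n * length(markers)), n) %*% diag(sds)
  colnames(rel) <- markers
  eub_log10 <- stats::rnorm(n, config$eub$mean, config$eub$sd)
  absolute <- cbind(10^(rel + eub_log10), EUB = 10^eub_log10)

  dys <- rel[, "FAE"] - rel[, "ECO"]
  intended <- vapply(dys, dysbiosis_category, character(1))
  structure(list(metadata = metadata,
                 relative_log = rel,
                 absolute = absolute,
                 dysbiosis_value = unname(dys),
                 intended_category = unname(intended),
                 scenario = scen,
                 seed = seed),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$metadata), "samples,",
      ncol(x$absolute), "markers (seed", x$seed, ")\n")
  cat("Intended dysbiosis categories:\n")
  print(table(factor(x$intended_category,
                     levels = c("healthy", "mild", "severe"))))
  invisible(x)
}

#' Simulate a qPCR plate from generating abundances
#'
#' Inverts the quantification model: for each sample and marker,
#' `Ct = b + m * log10(A * P * Cg * Vc / Ve)` plus Gaussian noise per
#' replicate. Ct values beyond the 40-cycle run length are emitted as the
#' no-amplification sentinel (`NA`). Two replicates per marker, mirroring
#' duplicate plating.
#'
#' @param truth A `simulated_cohort` (its `absolute` matrix is the ground
#'   truth), or a numeric matrix samples x markers of copies/g including an
#'   `EUB` column.
#' @param curves A `standard_curves` covering every marker.
#' @param extraction An `extraction_params` shared by all samples.
#' @param ct_noise_sd Per-replicate Ct noise SD (>= 0). Default 0.
#' @param seed Integer seed for the noise stream.
#' @param n_replicates Replicates per marker (default 2).
#' @param max_cycles Run length; Ct above it is censored (default 40).
#' @param panel A `marker_panel` (Cg values).
#' @return Long-format data.frame `sample_id`, `marker`, `replicate`, `ct`
#'   (`NA` = no amplification), the dialect [read_ct_csv()] consumes.
#' @export
simulate_plate <- function(truth, curves, extraction, ct_noise_sd = 0,
                           seed = 1, n_replicates = 2, max_cycles = 40,
                           panel = default_panel()) {
  abundance <- if (inherits(truth, "simulated_cohort")) truth$absolute
               else as.matrix(truth)
  if (any(!is.finite(abundance)) || any(abundance <= 0))
    stop("generating abundances must be positive", call. = FALSE)
  stopifnot(inherits(extraction, "extraction_params"),
            is.numeric(ct_noise_sd), ct_noise_sd >= 0)
  markers <- colnames(abundance)
  missing_curve <- setdiff(markers, curves$marker)
  if (length(missing_curve))
    stop("no standard curve for marker(s): ",
         paste(missing_curve, collapse = ", "), call. = FALSE)
  ids <- rownames(abundance)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(abundance)))

  set.seed(split_seed(seed, 3L))
  grid <- expand.grid(replicate = seq_len(n_replicates), marker = markers,
                      sample_id = ids, stringsAsFactors = FALSE)
  grid <- grid[, c("sample_id", "marker", "replicate")]
  cg <- vapply(markers, function(mk) marker_lookup(mk, panel)$gene_copy_count,
               numeric(1))
  slope <- stats::setNames(curves$slope, curves$marker)
  icpt <- stats::setNames(curves$intercept, curves$marker)
  a <- abundance[cbind(match(grid$sample_id, ids), match(grid$marker, markers))]
  ct <- icpt[grid$marker] + slope[grid$marker] *
    log10(a * extraction$p_g * cg[grid$marker] *
            extraction$vc_ul / extraction$ve_ul)
  if (ct_noise_sd > 0) ct <- ct + stats::rnorm(length(ct), 0, ct_noise_sd)
  ct[ct > max_cycles] <- NA_real_
  grid$ct <- unname(ct)
  rownames(grid) <- NULL
  grid
}
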