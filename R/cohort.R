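#' Log-ratio of geometric means between two groups
#'
#' `ln(geomean(a)) - ln(geomean(b))`, the natural-log scale used for
#' figure-style group comparisons of abundance. Kept deliberately separate
#' from the log10 scale of marker values and clinical indices to avoid unit
#' mixing.
#'
#' @param values_a,values_b Non-empty vectors of positive abundances.
#' @return Scalar natural-log ratio of geometric means.
#' @export
group_log_ratio <- function(values_a, values_b) {
  for (v in list(values_a, values_b)) {
    if (length(v) == 0L) stop("group values must be non-empty", call. = FALSE)
    if (any(!is.finite(v)) || any(v <= 0))
      stop("group values must be positive and finite", call. = FALSE)
  }
  mean(log(values_a)) - mean(log(values_b))
}

#' Convert a natural-log ratio to a percent change
#'
#' `100 * (exp(x) - 1)`: a log-ratio of 0.05 is an approximately 5.1%
#' increase in geometric mean abundance.
#'
#' @param x Finite natural-log ratio.
#' @param digits Decimal places for reporting (default 1).
#' @return Percent change, rounded to `digits`.
#' @examples
#' logratio_to_percent(0.05)   # 5.1
#' logratio_to_percent(log(2)) # 100
#' @export
logratio_to_percent <- function(x, digits = 1) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("log-ratio must be finite", call. = FALSE)
  round(100 * (exp(x) - 1), digits)
}

#' Express an odds ratio as a fold change with direction
#'
#' An OR below 1 is reported as a `1/OR`-fold decrease, e.g. OR 0.22 is a
#' 4.54-fold decrease.
#'
#' @param odds_ratio Positive odds ratio.
#' @return List with `fold` (>= 1) and `direction`
#'   (`"increase"`, `"decrease"` or `"none"`).
#' @examples
#' or_to_fold(0.220)  # 4.54-fold decrease
#' @export
or_to_fold <- function(odds_ratio) {
  if (!is.numeric(odds_ratio) || length(odds_ratio) != 1L ||
      !is.finite(odds_ratio) || odds_ratio <= 0)
    stop("odds ratio must be a positive number", call. = FALSE)
  if (odds_ratio > 1) list(fold = odds_ratio, direction = "increase")
  else if (odds_ratio < 1) list(fold = 1 / odds_ratio, direction = "decrease")
  else list(fold = 1, direction = "none")
}

#' Age group of an adult subject
#'
#' Bins at integer-year boundaries: young 18--28, adult 29--59, older 60 and
#' above. The study population is adults only.
#'
#' @param age Age in years, >= 18. Vectorized.
#' @return Factor with levels `young`, `adult`, `older`.
#' @export
age_group <- function(age) {
  if (any(!is.finite(age)) || any(age < 18))
    stop("age outside study population (must be >= 18)", call. = FALSE)
  cut(age, breaks = c(18, 29, 60, Inf), labels = c("young", "adult", "older"),
      right = FALSE, include.lowest = TRUE)
}

#' Body-mass-index group
#'
#' Bins half-open at 18.5, 25 and 30 kg/m2: underweight < 18.5, normal
#' 18.5--24.9, overweight 25--29.9, obese >= 30.
#'
#' @param bmi BMI in kg/m2, > 0. Vectorized.
#' @return Factor with levels `underweight`, `normal`, `overweight`, `obese`.
#' @export
bmi_group <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("BMI must be positive", call. = FALSE)
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf),
      labels = c("underweight", "normal", "overweight", "obese"),
      right = FALSE)
}

#' Descriptive summary of a cohort metadata table
#'
#' Counts and percentages per category of sex, age group, BMI group and IBS
#' behavior. Missing metadata is excluded from that variable's percentage
#' denominator and reported as a missing count. Percentages are rounded only
#' for reporting: 2 decimals for sex, 1 elsewhere.
#'
#' @param metadata Data.frame with columns among `sample_id`, `sex`, `age`,
#'   `bmi`, `ibs_behavior`; `NA` or empty string = missing.
#' @return A list of class `cohort_summary`: per variable a data.frame of
#'   `level`, `n`, `percent`, plus `n_missing` attributes and `n_total`.
#' @export
cohort_summary <- function(metadata) {
  stopifnot(is.data.frame(metadata), nrow(metadata) > 0L)
  one_var <- function(x, digits) {
    x[!is.na(x) & x == ""] <- NA
    n_missing <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      out <- data.frame(level = character(0), n = integer(0),
                        percent = numeric(0))
    } else {
      tab <- table(x)
      out <- data.frame(level = names(tab), n = as.integer(tab),
                        percent = round(100 * as.integer(tab) / length(x),
                                        digits),
                        stringsAsFactors = FALSE)
    }
    attr(out, "n_missing") <- n_missing
    out
  }
  out <- list(n_total = nrow(metadata))
  if ("sex" %in% names(metadata))
    out$sex <- one_var(as.character(metadata$sex), digits = 2)
  if ("age" %in% names(metadata)) {
    ag <- rep(NA_character_, nrow(metadata))
    ok <- !is.na(metadata$age)
    ag[ok] <- as.character(age_group(metadata$age[ok]))
    out$age_group <- one_var(ag, digits = 1)
  }
  if ("bmi" %in% names(metadata)) {
    bg <- rep(NA_character_, nrow(metadata))
    ok <- !is.na(metadata$bmi)
    bg[ok] <- as.character(bmi_group(metadata$bmi[ok]))
    out$bmi_group <- one_var(bg, digits = 1)
  }
  if ("ibs_behavior" %in% names(metadata))
    out$ibs_behavior <- one_var(as.character(metadata$ibs_behavior), digits = 1)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n =", x$n_total, ")\n")
  for (nm in setdiff(names(x), "n_total")) {
    cat("\n", nm, " (missing: ", attr(x[[nm]], "n_missing"), ")\n", sep = "")
    print.data.frame(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Pearson chi-square test of association on a contingency table
#'
#' Pearson's chi-square without continuity correction, as used to test the
#' association between IBS stool-pattern subtype and phylum predominance.
#'
#' @param counts Matrix of non-negative integer counts, at least 2 x 2, with
#'   all row and column marginals positive.
#' @return List with `statistic`, `df` and `p`.
#' @examples
#' contingency_chisq(matrix(c(20, 0, 0, 20), 2))  # statistic 40, df 1
#' @export
contingency_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all row and column marginals must be positive", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic),
       df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Pairwise group comparisons of marker abundance
#'
#' For each marker, the natural-log ratio of geometric mean abundance between
#' two levels of a grouping variable, as plotted in figure-style group
#' comparisons.
#'
#' @param abundances Numeric matrix, samples x markers, of positive absolute
#'   abundances (or back-transformed relative abundances).
#' @param group Factor/character vector of length `nrow(abundances)`.
#' @param level_a,level_b The two group levels to compare (a vs b).
#' @return Data.frame of `marker`, `group_a`, `group_b`, `log_ratio`,
#'   `percent_change`, `n_a`, `n_b`.
#' @export
group_comparisons <- function(abundances, group, level_a, level_b) {
  abundances <- as.matrix(abundances)
  stopifnot(nrow(abundances) == length(group))
  ia <- which(group == level_a); ib <- which(group == level_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("both group levels must be non-empty", call. = FALSE)
  lr <- vapply(colnames(abundances), function(mk)
    group_log_ratio(abundances[ia, mk], abundances[ib, mk]), numeric(1))
  data.frame(marker = colnames(abundances),
             group_a = level_a, group_b = level_b,
             log_ratio = unname(lr),
             percent_change = logratio_to_percent(unname(lr)),
             n_a = length(ia), n_b = length(ib),
             stringsAsFactors = FALSE, row.names = NULL)
}
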