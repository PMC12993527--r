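#' Default dysbiosis-index thresholds
#'
#' Category thresholds on the log10 index scale, derived from an external
#' healthy reference cohort: `healthy` above `healthy_gt`, `severe` below
#' `severe_lt`, `mild` in between (boundary values fall in `mild`). The two
#' thresholds differ by exactly one log10 unit, matching the one-decade
#' beyond-norm convention of the tolerance ranges; this is asserted when the
#' thresholds are used.
#'
#' @return List with elements `healthy_gt` (0.66) and `severe_lt` (-0.34).
#' @export
dysbiosis_thresholds <- function() {
  list(healthy_gt = 0.66, severe_lt = -0.34)
}

index_value <- function(profile, num, den, orientation = 1) {
  stopifnot(inherits(profile, "abundance_profile"))
  a <- profile$absolute
  for (mk in c(num, den)) {
    if (!mk %in% names(a) || is.na(a[[mk]]) || a[[mk]] <= 0)
      stop("index undefined: ", mk, " abundance missing, zero or below detection",
           call. = FALSE)
  }
  orientation * (log10(a[[num]]) - log10(a[[den]]))
}

#' Firmicutes/Bacteroidetes balance index
#'
#' `log10(A_FIR) - log10(A_BAC)`: positive values mean Bacillota (Firmicutes)
#' predominance, negative values Bacteroidota (Bacteroidetes) predominance.
#' Equal to the difference of the two markers' relative log abundances (the
#' EUB denominator cancels), so it is invariant to extraction volumes and
#' stool weight.
#'
#' @param profile An `abundance_profile` with positive FIR and BAC abundances.
#' @param orientation `1` (default) for FIR minus BAC; `-1` flips the sign.
#' @return Scalar index value.
#' @export
firbac_index <- function(profile, orientation = 1) {
  index_value(profile, "FIR", "BAC", orientation)
}

#' Phylum-predominance label for a FIR/BAC index value
#'
#' @param value Finite FIR/BAC index value.
#' @return `"bacillota_predominant"` (> 0), `"bacteroidota_predominant"`
#'   (< 0) or `"balanced"` (exactly 0).
#' @export
firbac_predominance <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("index value must be a finite number", call. = FALSE)
  if (value > 0) "bacillota_predominant"
  else if (value < 0) "bacteroidota_predominant"
  else "balanced"
}

#' Dysbiosis index
#'
#' `log10(A_FAE) - log10(A_ECO)`: the log10 abundance difference between
#' Faecalibacterium prausnitzii (anti-inflammatory, beneficial) and
#' Escherichia coli (potentially pro-inflammatory). Low values indicate
#' microbial imbalance. Like the FIR/BAC index it is invariant to Ve, Vc and
#' P, which are shared by both markers within a sample.
#'
#' @param profile An `abundance_profile` with positive FAE and ECO abundances.
#' @param orientation `1` (default) for FAE minus ECO; `-1` flips the sign.
#' @return Scalar index value.
#' @export
dysbiosis_index <- function(profile, orientation = 1) {
  index_value(profile, "FAE", "ECO", orientation)
}

#' Clinical category for a dysbiosis index value
#'
#' @param value Finite dysbiosis index value.
#' @param thresholds Threshold list, see [dysbiosis_thresholds()].
#' @return `"healthy"` (value > `healthy_gt`), `"severe"`
#'   (value < `severe_lt`) or `"mild"` (in between, boundaries included).
#' @examples
#' dysbiosis_category(0.70)   # "healthy"
#' dysbiosis_category(0.00)   # "mild"
#' dysbiosis_category(-1.00)  # "severe"
#' @export
dysbiosis_category <- function(value, thresholds = dysbiosis_thresholds()) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("index value must be a finite number", call. = FALSE)
  stopifnot(is.numeric(thresholds$healthy_gt), is.numeric(thresholds$severe_lt))
  if (abs((thresholds$healthy_gt - thresholds$severe_lt) - 1) > 1e-9)
    warning("dysbiosis thresholds do not differ by one log10 unit",
            call. = FALSE)
  if (value > thresholds$healthy_gt) "healthy"
  else if (value < thresholds$severe_lt) "severe"
  else "mild"
}

#' Compute both clinical indices for a sample
#'
#' @param profile An `abundance_profile`.
#' @param thresholds Dysbiosis thresholds, see [dysbiosis_thresholds()].
#' @return A list of class `index_result` with `firbac_value`,
#'   `firbac_label`, `dysbiosis_value`, `dysbiosis_category`.
#' @export
score_profile <- function(profile, thresholds = dysbiosis_thresholds()) {
  fb <- firbac_index(profile)
  dy <- dysbiosis_index(profile)
  structure(list(sample_id = profile$sample_id,
                 firbac_value = fb,
                 firbac_label = firbac_predominance(fb),
                 dysbiosis_value = dy,
                 dysbiosis_category = dysbiosis_category(dy, thresholds)),
            class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat("Sample '", x$sample_id, "'\n", sep = "")
  cat(sprintf("  FIR/BAC index:   %8.3f  (%s)\n", x$firbac_value, x$firbac_label))
  cat(sprintf("  Dysbiosis index: %8.3f  (%s)\n", x$dysbiosis_value,
              x$dysbiosis_category))
  invisible(x)
}
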