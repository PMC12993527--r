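#' Extraction parameters for a stool sample
#'
#' Bundles the volumetric and gravimetric constants of the DNA extraction:
#' elution volume Ve (uL), volume of extract loaded into the PCR Vc (uL), and
#' the weight of the stool analytical portion P (g). The assay uses a fixed
#' 40 mg stool portion by default; Vc has no universal default and must be
#' supplied per run.
#'
#' @param ve_ul Elution volume in microlitres (> 0). Default 100.
#' @param vc_ul Loaded volume in microlitres (> 0 and <= `ve_ul`).
#' @param p_g Stool portion weight in grams (> 0). Default 0.040.
#' @return A list of class `extraction_params`.
#' @examples
#' extraction_params(ve_ul = 100, vc_ul = 2)
#' @export
extraction_params <- function(ve_ul = 100, vc_ul, p_g = 0.040) {
  if (missing(vc_ul)) stop("vc_ul (volume loaded into the PCR) is required",
                           call. = FALSE)
  stopifnot(is.numeric(ve_ul), is.numeric(vc_ul), is.numeric(p_g),
            length(ve_ul) == 1L, length(vc_ul) == 1L, length(p_g) == 1L)
  if (!is.finite(ve_ul) || ve_ul <= 0) stop("ve_ul must be > 0", call. = FALSE)
  if (!is.finite(vc_ul) || vc_ul <= 0) stop("vc_ul must be > 0", call. = FALSE)
  if (vc_ul > ve_ul) stop("vc_ul cannot exceed ve_ul", call. = FALSE)
  if (!is.finite(p_g) || p_g <= 0) stop("p_g must be > 0", call. = FALSE)
  structure(list(ve_ul = ve_ul, vc_ul = vc_ul, p_g = p_g),
            class = "extraction_params")
}

#' Per-marker qPCR standard curves
#'
#' A standard curve maps log10 template copies to threshold cycle:
#' Ct = m * log10(copies) + b. The slope must be negative (more template
#' amplifies earlier); amplification efficiency 10^(-1/m) - 1 outside
#' \[0.8, 1.2\] triggers a warning.
#'
#' @param marker Character vector of marker acronyms.
#' @param slope Curve slopes (Ct per log10 copies), all < 0.
#' @param intercept Curve intercepts (Ct at one copy).
#' @return A data.frame of class `standard_curves` with columns `marker`,
#'   `slope`, `intercept`, `efficiency`.
#' @examples
#' standard_curves("EUB", slope = -3.3219, intercept = 38)
#' @export
standard_curves <- function(marker, slope, intercept) {
  stopifnot(length(marker) == length(slope),
            length(marker) == length(intercept))
  marker <- toupper(trimws(marker))
  if (anyDuplicated(marker))
    stop("duplicate markers in standard curves", call. = FALSE)
  if (any(!is.finite(slope)) || any(slope >= 0))
    stop("standard-curve slopes must be finite and negative", call. = FALSE)
  if (any(!is.finite(intercept)))
    stop("standard-curve intercepts must be finite", call. = FALSE)
  eff <- 10^(-1 / slope) - 1
  if (any(eff <= 0 | eff >= 2))
    stop("implied amplification efficiency outside (0, 2) for: ",
         paste(marker[eff <= 0 | eff >= 2], collapse = ", "), call. = FALSE)
  out_of_spec <- eff < 0.8 | eff > 1.2
  if (any(out_of_spec))
    warning("amplification efficiency outside [0.8, 1.2] for: ",
            paste(marker[out_of_spec], collapse = ", "), call. = FALSE)
  out <- data.frame(marker = marker, slope = slope, intercept = intercept,
                    efficiency = eff, stringsAsFactors = FALSE)
  class(out) <- c("standard_curves", "data.frame")
  out
}

#' Default standard curves for the panel
#'
#' One shared calibration per marker: slope -3.3219 (100% amplification
#' efficiency) and intercept 38 Ct. Real runs supply per-marker fitted curves;
#' these defaults serve simulation and examples.
#'
#' @param panel A `marker_panel`.
#' @param slope,intercept Scalars recycled across all panel markers.
#' @return A `standard_curves` data.frame covering every panel marker.
#' @export
default_curves <- function(panel = default_panel(), slope = -3.3219,
                           intercept = 38) {
  standard_curves(panel$acronym,
                  rep_len(slope, nrow(panel)),
                  rep_len(intercept, nrow(panel)))
}

#' Mean threshold cycle over replicates
#'
#' The mean of duplicate (or more) Ct quantifications, taken on the Ct scale.
#' `NA` replicates encode no amplification: they are dropped from the mean
#' with a warning, and if every replicate failed to amplify the result is
#' `NA` (the no-amplification sentinel). Discordant duplicates
#' (range > 1 Ct) also warn, but the mean is still returned.
#'
#' @param replicates Numeric vector of Ct values; `NA` = no amplification.
#' @return Scalar mean Ct, or `NA` if no replicate amplified.
#' @examples
#' mean_ct(c(24.0, 24.4))  # 24.2
#' @export
mean_ct <- function(replicates) {
  if (length(replicates) == 0L)
    stop("at least one Ct replicate is required", call. = FALSE)
  stopifnot(is.numeric(replicates) || all(is.na(replicates)))
  ok <- !is.na(replicates)
  if (!any(ok)) return(NA_real_)
  if (any(!ok))
    warning("dropping ", sum(!ok), " no-amplification replicate(s) from mean",
            call. = FALSE)
  vals <- replicates[ok]
  if (length(vals) >= 2L && (max(vals) - min(vals)) > 1.0)
    warning("discordant replicates (Ct range ",
            format(max(vals) - min(vals), digits = 3), " > 1 cycle)",
            call. = FALSE)
  mean(vals)
}

#' Absolute abundance from a threshold cycle
#'
#' Converts a Ct value to gene copies per gram of stool:
#' \deqn{A = \frac{(V_e / V_c) \cdot 10^{(Ct - b)/m}}{P \cdot C_g}}
#' where b and m are the standard-curve intercept and slope, Ve/Vc the
#' elution/loaded volumes, P the stool portion weight and Cg the rRNA gene
#' copy count per genome of the target, which converts gene copies into
#' genome (organism) equivalents.
#'
#' @param ct Mean threshold cycle; `NA` = no amplification.
#' @param slope,intercept Standard-curve slope (< 0) and intercept.
#' @param extraction An `extraction_params` object.
#' @param cg rRNA gene copy count per genome (> 0).
#' @return Copies per gram of stool, or `NA` (below detection) when
#'   `ct` is the no-amplification sentinel.
#' @examples
#' absolute_abundance(24, slope = -3.5, intercept = 38,
#'                    extraction_params(100, 2, 0.04), cg = 5)  # 2.5e6
#' @export
absolute_abundance <- function(ct, slope, intercept, extraction, cg) {
  stopifnot(inherits(extraction, "extraction_params"))
  if (!is.numeric(cg) || length(cg) != 1L || !is.finite(cg) || cg <= 0)
    stop("cg must be a positive number", call. = FALSE)
  if (!is.numeric(slope) || !is.finite(slope) || slope >= 0)
    stop("standard-curve slope must be negative", call. = FALSE)
  if (length(ct) != 1L) stop("ct must be a scalar", call. = FALSE)
  if (is.na(ct)) return(NA_real_)  # below detection
  if (!is.finite(ct)) stop("non-finite Ct", call. = FALSE)
  (extraction$ve_ul / extraction$vc_ul) * 10^((ct - intercept) / slope) /
    (extraction$p_g * cg)
}

#' Quantify one sample's panel measurements
#'
#' Turns replicate Ct values for one sample into an abundance profile:
#' absolute abundance (copies/g stool) per marker and relative log abundance
#' log10(marker / EUB) for every non-EUB marker, normalizing out differences
#' in total microbial DNA yield. EUB must be measured and amplify, otherwise
#' normalization is impossible.
#'
#' @param measurements A data.frame with columns `marker` and `ct` (one row
#'   per replicate; `NA` ct = no amplification) for a single sample.
#' @param curves A `standard_curves` data.frame covering every measured marker.
#' @param extraction An `extraction_params` object.
#' @param panel A `marker_panel`; supplies Cg and marker classes.
#' @param sample_id Sample identifier recorded in the profile.
#' @return An object of class `abundance_profile`: a list with `sample_id`,
#'   `absolute` (named numeric, `NA` = below detection), `relative_log`
#'   (named numeric, EUB excluded), `below_detection` (character vector of
#'   censored markers) and `qc` (character vector of warnings raised).
#' @examples
#' m <- data.frame(marker = c("EUB", "EUB", "FAE", "FAE"),
#'                 ct = c(14, 14.2, 20, 20.4))
#' quantify_sample(m, default_curves(), extraction_params(100, 2), sample_id = "S1")
#' @export
quantify_sample <- function(measurements, curves, extraction,
                            panel = default_panel(), sample_id = "sample") {
  stopifnot(is.data.frame(measurements),
            all(c("marker", "ct") %in% names(measurements)))
  measurements$marker <- toupper(trimws(measurements$marker))
  unknown <- setdiff(unique(measurements$marker), panel$acronym)
  if (length(unknown))
    stop("unknown marker(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!"EUB" %in% measurements$marker)
    stop("cannot normalize: sample '", sample_id,
         "' has no EUB (total load) measurement", call. = FALSE)
  markers <- unique(measurements$marker)
  missing_curve <- setdiff(markers, curves$marker)
  if (length(missing_curve))
    stop("no standard curve for marker(s): ",
         paste(missing_curve, collapse = ", "), call. = FALSE)

  qc <- character(0)
  absolute <- stats::setNames(numeric(length(markers)), markers)
  for (mk in markers) {
    reps <- measurements$ct[measurements$marker == mk]
    ctbar <- withCallingHandlers(
      mean_ct(reps),
      warning = function(w) {
        qc <<- c(qc, paste0(mk, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    crow <- curves[curves$marker == mk, ]
    cg <- marker_lookup(mk, panel)$gene_copy_count
    absolute[mk] <- absolute_abundance(ctbar, crow$slope, crow$intercept,
                                       extraction, cg)
  }
  if (is.na(absolute[["EUB"]]) || absolute[["EUB"]] <= 0)
    stop("cannot normalize: EUB below detection in sample '", sample_id, "'",
         call. = FALSE)
  below <- names(absolute)[is.na(absolute)]
  rel_markers <- setdiff(markers[!markers %in% below], "EUB")
  relative_log <- log10(absolute[rel_markers]) - log10(absolute[["EUB"]])
  structure(list(sample_id = sample_id,
                 absolute = absolute,
                 relative_log = relative_log,
                 below_detection = below,
                 qc = qc),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("Abundance profile for sample '", x$sample_id, "'\n", sep = "")
  df <- data.frame(marker = names(x$absolute),
                   copies_per_g = unname(x$absolute),
                   relative_log10 = unname(x$relative_log[names(x$absolute)]),
                   stringsAsFactors = FALSE)
  print.data.frame(df, row.names = FALSE, digits = 4)
  if (length(x$below_detection))
    cat("Below detection:", paste(x$below_detection, collapse = ", "), "\n")
  if (length(x$qc)) cat("QC flags:", length(x$qc), "\n")
  invisible(x)
}

#' Quantify a long-format table of Ct measurements
#'
#' Batch version of [quantify_sample()]: splits a long-format table
#' (`sample_id`, `marker`, `ct`; one row per replicate) by sample and
#' quantifies each one.
#'
#' @param ct_table Long-format data.frame with columns `sample_id`, `marker`,
#'   `ct`.
#' @param curves,panel See [quantify_sample()].
#' @param extraction Either a single `extraction_params` used for every
#'   sample, or a named list keyed by sample_id.
#' @return A named list of `abundance_profile` objects.
#' @export
quantify_samples <- function(ct_table, curves, extraction,
                             panel = default_panel()) {
  stopifnot(is.data.frame(ct_table),
            all(c("sample_id", "marker", "ct") %in% names(ct_table)))
  ids <- unique(ct_table$sample_id)
  profiles <- lapply(ids, function(id) {
    ex <- if (inherits(extraction, "extraction_params")) extraction
          else extraction[[id]]
    if (is.null(ex)) stop("no extraction parameters for sample '", id, "'",
                          call. = FALSE)
    quantify_sample(ct_table[ct_table$sample_id == id, , drop = FALSE],
                    curves, ex, panel, sample_id = id)
  })
  stats::setNames(profiles, ids)
}
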