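#' Read a long-format Ct CSV
#'
#' Dialect: comma-separated, UTF-8, dot decimals, required header
#' `sample_id,marker,replicate,ct`; an empty `ct` cell is the
#' no-amplification sentinel. Unknown markers and malformed rows are rejected
#' with their line numbers.
#'
#' @param path CSV path.
#' @param panel A `marker_panel` used to validate marker acronyms.
#' @return Data.frame `sample_id`, `marker`, `replicate`, `ct` (`NA` = no
#'   amplification).
#' @export
read_ct_csv <- function(path, panel = default_panel()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ct = "character"))
  required <- c("sample_id", "marker", "replicate", "ct")
  if (!all(required %in% names(df)))
    stop("Ct CSV must have header: ", paste(required, collapse = ","),
         call. = FALSE)
  df$marker <- toupper(trimws(df$marker))
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  unknown <- !df$marker %in% panel$acronym
  if (any(unknown))
    stop("unknown marker '", df$marker[which(unknown)[1]], "' at line ",
         line_no[which(unknown)[1]], call. = FALSE)
  ct_chr <- trimws(df$ct)
  ct <- suppressWarnings(as.numeric(ct_chr))
  bad <- !is.na(ct_chr) & ct_chr != "" & is.na(ct)
  if (any(bad))
    stop("malformed ct value '", ct_chr[which(bad)[1]], "' at line ",
         line_no[which(bad)[1]], call. = FALSE)
  neg <- !is.na(ct) & ct <= 0
  if (any(neg))
    stop("non-positive ct at line ", line_no[which(neg)[1]], call. = FALSE)
  df$ct <- ct
  df
}

#' Write Ct measurements to CSV
#'
#' Inverse of [read_ct_csv()]: `NA` Ct values are written as empty cells.
#'
#' @param ct_table Data.frame with `sample_id`, `marker`, `replicate`, `ct`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(ct_table, path) {
  out <- ct_table[, c("sample_id", "marker", "replicate", "ct")]
  out$ct <- ifelse(is.na(out$ct), "", format(out$ct, digits = 12,
                                             trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read per-marker standard curves from CSV
#'
#' Columns: `marker,slope,intercept`.
#'
#' @param path CSV path.
#' @return A `standard_curves` data.frame.
#' @export
read_curves_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("marker", "slope", "intercept") %in% names(df)))
    stop("curves CSV must have header: marker,slope,intercept", call. = FALSE)
  standard_curves(df$marker, df$slope, df$intercept)
}

#' Write standard curves to CSV
#' @param curves A `standard_curves` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  utils::write.csv(curves[, c("marker", "slope", "intercept")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-sample extraction parameters from CSV
#'
#' Columns: `sample_id,ve_ul,vc_ul,p_g`; `ve_ul` defaults to 100 and `p_g`
#' to 0.040 when omitted or empty; `vc_ul` is required.
#'
#' @param path CSV path.
#' @return Named list of `extraction_params` keyed by sample_id.
#' @export
read_extraction_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "vc_ul") %in% names(df)))
    stop("extraction CSV must have at least: sample_id,vc_ul", call. = FALSE)
  if (!"ve_ul" %in% names(df)) df$ve_ul <- NA_real_
  if (!"p_g" %in% names(df)) df$p_g <- NA_real_
  out <- lapply(seq_len(nrow(df)), function(i) {
    extraction_params(
      ve_ul = if (is.na(df$ve_ul[i])) 100 else df$ve_ul[i],
      vc_ul = df$vc_ul[i],
      p_g = if (is.na(df$p_g[i])) 0.040 else df$p_g[i])
  })
  stats::setNames(out, df$sample_id)
}

#' Read a cohort metadata CSV
#'
#' Columns: `sample_id,sex,age,bmi,ibs_behavior`; empty fields are missing.
#'
#' @param path CSV path.
#' @return Data.frame with `NA` for missing fields.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"sample_id" %in% names(df))
    stop("metadata CSV must have a sample_id column", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  df
}

#' Write abundance profiles to JSON
#'
#' Per-sample maps of absolute and relative log10 abundances plus
#' below-detection and QC flags; numbers at 12 significant digits.
#'
#' @param profiles A named list of `abundance_profile` objects (or one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_json <- function(profiles, path) {
  if (inherits(profiles, "abundance_profile")) profiles <- list(profiles)
  obj <- lapply(profiles, function(p) {
    list(sample_id = p$sample_id,
         absolute = as.list(signif(p$absolute[!is.na(p$absolute)], 12)),
         relative_log = as.list(signif(p$relative_log, 12)),
         below_detection = as.list(p$below_detection),
         qc = as.list(p$qc))
  })
  names(obj) <- vapply(profiles, `[[`, character(1), "sample_id")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read abundance profiles from JSON
#'
#' @param path Path written by [write_profiles_json()].
#' @return Named list of `abundance_profile` objects.
#' @export
read_profiles_json <- function(path) {
  obj <- jsonlite::read_json(path)
  out <- lapply(obj, function(p) {
    absolute <- unlist(p$absolute)
    below <- as.character(unlist(p$below_detection))
    if (length(below)) {
      absolute <- c(absolute, stats::setNames(rep(NA_real_, length(below)),
                                              below))
    }
    structure(list(sample_id = p$sample_id,
                   absolute = absolute,
                   relative_log = if (length(p$relative_log))
                     unlist(p$relative_log) else
                       stats::setNames(numeric(0), character(0)),
                   below_detection = below,
                   qc = as.character(unlist(p$qc))),
              class = "abundance_profile")
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "sample_id"))
}
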