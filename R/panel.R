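#' The 15-marker stool qPCR panel
#'
#' Returns the default marker panel: acronym, full name, rRNA gene copy count
#' per genome (Cg), clinical marker class, and assay chemistry. The copy
#' counts for group-level markers (BAC, FIR, GAM, CLO, XIV, EUB) are averages
#' over the member species and are stored as literals; they are never
#' recomputed.
#'
#' Marker classes drive tolerance-range placement and below-detection
#' handling:
#' \describe{
#'   \item{beneficial}{deficit is clinically adverse; only low limits}
#'   \item{harmful}{excess is clinically adverse; only high limits}
#'   \item{bidirectional}{both deficit and excess adverse; limits on both sides}
#'   \item{total}{the pan-bacterial load (EUB), used as the normalization
#'     denominator; range fitted on the absolute scale}
#' }
#'
#' @return A data.frame of class `marker_panel` with one row per marker and
#'   columns `acronym`, `full_name`, `gene_copy_count`, `marker_class`,
#'   `assay_chemistry`, `is_denominator`.
#' @examples
#' panel <- default_panel()
#' nrow(panel)                         # 15
#' marker_lookup("GAM")$gene_copy_count  # 5.5
#' @export
default_panel <- function() {
  panel <- data.frame(
    acronym = c("AKK", "BAC", "CAN", "CLO", "ECO", "ENT", "FAE", "FIR",
                "GAM", "LAC", "MSM", "ROS", "RUM", "XIV", "EUB"),
    full_name = c(
      "Akkermansia muciniphila",
      "Bacteroidota (Bacteroidetes)",
      "Candida albicans",
      "Clostridium cluster I",
      "Escherichia coli",
      "Enterococcus sp.",
      "Faecalibacterium prausnitzii",
      "Bacillota (Firmicutes)",
      "Gammaproteobacteria",
      "Lactobacillus sp.",
      "Methanobrevibacter smithii",
      "Roseburia sp.",
      "Ruminococcus spp.",
      "Clostridium cluster XIV",
      "Eubacteria (total bacterial load)"),
    gene_copy_count = c(3, 5, 1, 8, 7, 4, 6, 5, 5.5, 5, 2, 5, 5, 8, 5),
    marker_class = c("beneficial", "beneficial", "harmful", "bidirectional",
                     "harmful", "harmful", "beneficial", "beneficial",
                     "harmful", "beneficial", "harmful", "beneficial",
                     "beneficial", "bidirectional", "total"),
    assay_chemistry = c("dye", "dye", "dye", "dye", "probe", "dye", "probe",
                        "dye", "dye", "dye", "dye", "dye", "dye", "dye",
                        "dye"),
    stringsAsFactors = FALSE
  )
  panel$is_denominator <- panel$acronym == "EUB"
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Look up a marker definition by acronym
#'
#' @param acronym Marker acronym (case-insensitive), e.g. `"AKK"`.
#' @param panel A `marker_panel`; defaults to [default_panel()].
#' @return A one-row data.frame with the marker's definition.
#' @examples
#' marker_lookup("eco")$gene_copy_count  # 7
#' @export
marker_lookup <- function(acronym, panel = default_panel()) {
  stopifnot(is.character(acronym), length(acronym) == 1L)
  key <- toupper(trimws(acronym))
  i <- match(key, panel$acronym)
  if (is.na(i)) {
    stop("unknown marker: '", acronym, "' (known: ",
         paste(panel$acronym, collapse = ", "), ")", call. = FALSE)
  }
  panel[i, , drop = FALSE]
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Stool microbial qPCR panel:", nrow(x), "markers\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Export a marker panel to JSON
#'
#' Schema: `{"markers": [{"acronym": ..., "cg": ..., "class": ...}, ...]}`.
#'
#' @param panel A `marker_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_json <- function(panel, path) {
  obj <- list(markers = lapply(seq_len(nrow(panel)), function(i) {
    list(acronym = panel$acronym[i],
         full_name = panel$full_name[i],
         cg = panel$gene_copy_count[i],
         class = panel$marker_class[i],
         chemistry = panel$assay_chemistry[i])
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a marker panel from JSON
#'
#' @param path Path to a JSON file written by [write_panel_json()].
#' @return A `marker_panel` data.frame.
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$markers) || length(obj$markers) == 0L)
    stop("panel JSON has no 'markers' entries", call. = FALSE)
  rows <- lapply(obj$markers, function(m) {
    data.frame(acronym = toupper(m$acronym),
               full_name = if (is.null(m$full_name)) NA_character_ else m$full_name,
               gene_copy_count = as.numeric(m$cg),
               marker_class = m$class,
               assay_chemistry = if (is.null(m$chemistry)) "dye" else m$chemistry,
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  if (anyDuplicated(panel$acronym))
    stop("duplicate marker acronyms in panel JSON", call. = FALSE)
  bad <- !panel$marker_class %in% c("beneficial", "harmful", "bidirectional", "total")
  if (any(bad))
    stop("invalid marker_class for: ", paste(panel$acronym[bad], collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(panel$gene_copy_count)) || any(panel$gene_copy_count <= 0))
    stop("gene_copy_count must be positive", call. = FALSE)
  panel$is_denominator <- panel$marker_class == "total"
  class(panel) <- c("marker_panel", "data.frame")
  panel
}
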