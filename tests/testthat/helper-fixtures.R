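# Shared fixtures: build abundance profiles directly from known abundances so
# index and classification tests do not depend on the quantification path.

make_profile <- function(absolute, sample_id = "T1") {
  absolute <- unlist(absolute)
  below <- names(absolute)[is.na(absolute)]
  rel_markers <- setdiff(names(absolute)[!is.na(absolute)], "EUB")
  rel <- if ("EUB" %in% names(absolute) && !is.na(absolute[["EUB"]]))
    log10(absolute[rel_markers]) - log10(absolute[["EUB"]])
  else stats::setNames(numeric(0), character(0))
  structure(list(sample_id = sample_id, absolute = absolute,
                 relative_log = rel, below_detection = below,
                 qc = character(0)),
            class = "abundance_profile")
}

fixture_extraction <- function() extraction_params(ve_ul = 100, vc_ul = 2,
                                                   p_g = 0.04)

# A single-marker tolerance range row for classify_marker tests.
range_row <- function(...) {
  defaults <- list(borderline_low = NA_real_, beyond_low = NA_real_,
                   borderline_high = NA_real_, beyond_high = NA_real_)
  utils::modifyList(defaults, list(...))
}
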