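#' Fit per-marker tolerance ranges on a healthy reference cohort
#'
#' The reference model of the panel: for every marker the cohort mean and
#' sample standard deviation of its relative log10 abundance (log10 absolute
#' abundance for EUB, whose relative value is identically zero) define a
#' borderline limit at one SD on the clinically adverse side of the mean, and
#' a beyond-norm limit one further log10 unit (one decade) outside it:
#' \itemize{
#'   \item beneficial and total markers: `borderline_low = mean - sd`,
#'     `beyond_low = borderline_low - 1` (deficit is adverse);
#'   \item harmful markers: `borderline_high = mean + sd`,
#'     `beyond_high = borderline_high + 1` (excess is adverse);
#'   \item bidirectional markers (CLO, XIV): limits on both sides.
#' }
#' `direction` overrides the class-derived side per marker, for sensitivity
#' analyses of the limit-placement convention.
#'
#' @param cohort A list of [abundance_profile][quantify_sample] objects, a
#'   [simulated_cohort][simulate_cohort] (its generating values plus log10
#'   EUB load), or a numeric matrix/data.frame with one row per subject and
#'   one column per marker holding relative log10 abundances (EUB column:
#'   log10 absolute abundance, copies/g).
#' @param panel A `marker_panel`; markers absent from it are rejected.
#' @param direction Optional named character vector overriding the side the
#'   limits sit on per marker: `"low"`, `"high"` or `"both"`.
#' @return An object of class `tolerance_ranges`: list with `ranges` (a
#'   data.frame of marker, marker_class, mean, sd, borderline/beyond limits),
#'   `cohort_n`, `direction` and `call`. Methods: [print.tolerance_ranges()],
#'   [summary.tolerance_ranges()], [coef.tolerance_ranges()],
#'   [predict.tolerance_ranges()], [plot.tolerance_ranges()],
#'   [simulate.tolerance_ranges()].
#' @examples
#' set.seed(1)
#' vals <- matrix(rnorm(60, -2, 0.4), 20, 3,
#'                dimnames = list(NULL, c("AKK", "ECO", "CLO")))
#' fit <- fit_tolerance_ranges(vals)
#' coef(fit)
#' @export
fit_tolerance_ranges <- function(cohort, panel = default_panel(),
                                 direction = NULL) {
  values <- cohort_value_matrix(cohort, panel)
  if (nrow(values) < 2L)
    stop("reference cohort must contain at least 2 subjects", call. = FALSE)
  markers <- colnames(values)
  unknown <- setdiff(markers, panel$acronym)
  if (length(unknown))
    stop("unknown marker(s) in cohort: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  rows <- lapply(markers, function(mk) {
    v <- values[, mk]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      stop("marker ", mk, " absent from every cohort profile", call. = FALSE)
    if (length(v) < 2L)
      stop("marker ", mk, " measured in fewer than 2 subjects", call. = FALSE)
    mu <- mean(v)
    s <- stats::sd(v)
    if (s == 0) stop("degenerate cohort: zero SD for marker ", mk,
                     call. = FALSE)
    cls <- marker_lookup(mk, panel)$marker_class
    side <- if (!is.null(direction) && mk %in% names(direction))
      match.arg(direction[[mk]], c("low", "high", "both"))
    else switch(cls, beneficial = "low", total = "low", harmful = "high",
                bidirectional = "both")
    data.frame(
      marker = mk, marker_class = cls, n = length(v), mean = mu, sd = s,
      borderline_low  = if (side %in% c("low", "both")) mu - s else NA_real_,
      beyond_low      = if (side %in% c("low", "both")) mu - s - 1 else NA_real_,
      borderline_high = if (side %in% c("high", "both")) mu + s else NA_real_,
      beyond_high     = if (side %in% c("high", "both")) mu + s + 1 else NA_real_,
      stringsAsFactors = FALSE)
  })
  ranges <- do.call(rbind, rows)
  structure(list(ranges = ranges,
                 cohort_n = nrow(values),
                 direction = direction,
                 call = match.call()),
            class = "tolerance_ranges")
}

# Coerce a cohort (list of profiles, or matrix/data.frame) into a numeric
# subjects x markers matrix of the values the ranges are fitted on:
# relative_log for ordinary markers, log10 absolute load for EUB.
cohort_value_matrix <- function(cohort, panel) {
  if (inherits(cohort, "simulated_cohort")) {
    return(cbind(cohort$relative_log,
                 EUB = log10(cohort$absolute[, "EUB"])))
  }
  if (is.matrix(cohort) || is.data.frame(cohort)) {
    m <- as.matrix(cohort)
    storage.mode(m) <- "double"
    if (is.null(colnames(m))) stop("cohort matrix needs marker column names",
                                   call. = FALSE)
    colnames(m) <- toupper(colnames(m))
    return(m)
  }
  if (is.list(cohort) && all(vapply(cohort, inherits, TRUE, "abundance_profile"))) {
    markers <- unique(unlist(lapply(cohort, function(p)
      union(names(p$relative_log), intersect("EUB", names(p$absolute))))))
    m <- matrix(NA_real_, length(cohort), length(markers),
                dimnames = list(NULL, markers))
    for (i in seq_along(cohort)) {
      p <- cohort[[i]]
      rl <- p$relative_log
      m[i, names(rl)] <- rl
      if ("EUB" %in% markers && "EUB" %in% names(p$absolute) &&
          !is.na(p$absolute[["EUB"]]))
        m[i, "EUB"] <- log10(p$absolute[["EUB"]])
    }
    return(m)
  }
  stop("cohort must be a matrix/data.frame or a list of abundance_profile objects",
       call. = FALSE)
}

#' Classify one value against a tolerance range
#'
#' `normal` inside the borderline limits (an absent limit is unbounded),
#' `borderline` outside a borderline limit but within the matching beyond
#' limit, `beyond` otherwise. A value exactly equal to a limit takes the less
#' severe status.
#'
#' @param value Relative log10 abundance (log10 absolute for EUB).
#' @param range One row of a fitted `tolerance_ranges` table (data.frame or
#'   list with the limit fields).
#' @return `"normal"`, `"borderline"` or `"beyond"`.
#' @export
classify_marker <- function(value, range) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("value must be a finite number", call. = FALSE)
  lim <- function(x) if (is.null(x) || is.na(x)) NULL else x
  bl <- lim(range$borderline_low);  byl <- lim(range$beyond_low)
  bh <- lim(range$borderline_high); byh <- lim(range$beyond_high)
  low_state <- if (is.null(bl)) "normal"
    else if (value >= bl) "normal"
    else if (!is.null(byl) && value >= byl) "borderline"
    else "beyond"
  high_state <- if (is.null(bh)) "normal"
    else if (value <= bh) "normal"
    else if (!is.null(byh) && value <= byh) "borderline"
    else "beyond"
  sev <- c(normal = 0L, borderline = 1L, beyond = 2L)
  names(which.max(sev[c(low_state, high_state)]))
}

#' Classify every marker of a profile
#'
#' Below-detection markers are classified by their clinical class: a missing
#' beneficial (or total) marker is a deficit signal (`beyond`); a missing
#' harmful marker is unremarkable (`normal`); a missing bidirectional marker
#' is treated as a deficit (`beyond`).
#'
#' @param profile An `abundance_profile`.
#' @param fit A fitted `tolerance_ranges` object.
#' @param panel A `marker_panel`.
#' @return Named character vector of statuses, one per measured marker.
#' @export
classify_profile <- function(profile, fit, panel = default_panel()) {
  stopifnot(inherits(profile, "abundance_profile"),
            inherits(fit, "tolerance_ranges"))
  markers <- names(profile$absolute)
  missing_rng <- setdiff(markers, fit$ranges$marker)
  if (length(missing_rng))
    stop("no fitted range for marker(s): ",
         paste(missing_rng, collapse = ", "), call. = FALSE)
  out <- stats::setNames(character(length(markers)), markers)
  for (mk in markers) {
    rng <- fit$ranges[fit$ranges$marker == mk, ]
    if (mk %in% profile$below_detection) {
      cls <- marker_lookup(mk, panel)$marker_class
      out[mk] <- if (cls == "harmful") "normal" else "beyond"
    } else {
      value <- if (mk == "EUB") log10(profile$absolute[["EUB"]])
               else profile$relative_log[[mk]]
      out[mk] <- classify_marker(value, rng)
    }
  }
  out
}

#' @export
print.tolerance_ranges <- function(x, ...) {
  cat("Tolerance ranges fitted on", x$cohort_n, "reference subjects\n\n")
  print.data.frame(x$ranges, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn fit_tolerance_ranges Fitted means, SDs and limits plus a count
#'   of limit sides per marker class.
#' @param object,x A `tolerance_ranges` object.
#' @param ... Unused.
#' @export
summary.tolerance_ranges <- function(object, ...) {
  r <- object$ranges
  structure(list(cohort_n = object$cohort_n,
                 ranges = r,
                 class_table = table(r$marker_class),
                 sd_range = range(r$sd)),
            class = "summary.tolerance_ranges")
}

#' @export
print.summary.tolerance_ranges <- function(x, ...) {
  cat("Tolerance-range fit:", x$cohort_n, "reference subjects,",
      nrow(x$ranges), "markers\n")
  cat("Marker classes:\n"); print(x$class_table)
  cat("Cohort SD range:", format(x$sd_range, digits = 3), "\n\n")
  print.data.frame(x$ranges, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn fit_tolerance_ranges Matrix of fitted parameters (mean, sd and
#'   the four limits), rows named by marker.
#' @export
coef.tolerance_ranges <- function(object, ...) {
  r <- object$ranges
  m <- as.matrix(r[, c("mean", "sd", "borderline_low", "beyond_low",
                       "borderline_high", "beyond_high")])
  rownames(m) <- r$marker
  m
}

#' Classify new profiles against fitted tolerance ranges
#'
#' @param object A fitted `tolerance_ranges`.
#' @param newdata An `abundance_profile` or a list of them.
#' @param panel A `marker_panel`.
#' @param ... Unused.
#' @return A long data.frame with columns `sample_id`, `marker`, `value`,
#'   `status` (`normal` < `borderline` < `beyond`).
#' @export
predict.tolerance_ranges <- function(object, newdata,
                                     panel = default_panel(), ...) {
  profiles <- if (inherits(newdata, "abundance_profile")) list(newdata)
              else newdata
  rows <- lapply(profiles, function(p) {
    st <- classify_profile(p, object, panel)
    vals <- vapply(names(st), function(mk) {
      if (mk %in% p$below_detection) NA_real_
      else if (mk == "EUB") log10(p$absolute[["EUB"]])
      else p$relative_log[[mk]]
    }, numeric(1))
    data.frame(sample_id = p$sample_id, marker = names(st),
               value = unname(vals),
               status = factor(unname(st),
                               levels = c("normal", "borderline", "beyond"),
                               ordered = TRUE),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Plot fitted tolerance ranges
#'
#' Draws, per marker, the cohort mean (point), the borderline interval
#' (thick segment) and the beyond-norm interval (thin segment) on the
#' relative log10 abundance scale.
#'
#' @param x A `tolerance_ranges` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tolerance_ranges <- function(x, ...) {
  r <- x$ranges
  n <- nrow(r)
  lo <- pmin(r$beyond_low, r$mean - r$sd - 1, na.rm = TRUE)
  hi <- pmax(r$beyond_high, r$mean + r$sd + 1, na.rm = TRUE)
  graphics::plot(NA, xlim = range(c(lo, hi), finite = TRUE),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "relative log10 abundance (EUB: log10 copies/g)",
                 ylab = "", ...)
  graphics::axis(2, at = seq_len(n), labels = r$marker, las = 1)
  for (i in seq_len(n)) {
    by_lo <- if (is.na(r$beyond_low[i])) lo[i] else r$beyond_low[i]
    by_hi <- if (is.na(r$beyond_high[i])) hi[i] else r$beyond_high[i]
    bl_lo <- if (is.na(r$borderline_low[i])) lo[i] else r$borderline_low[i]
    bl_hi <- if (is.na(r$borderline_high[i])) hi[i] else r$borderline_high[i]
    graphics::segments(by_lo, i, by_hi, i, lwd = 1, col = "grey60")
    graphics::segments(bl_lo, i, bl_hi, i, lwd = 3, col = "grey30")
    graphics::points(r$mean[i], i, pch = 19)
  }
  invisible(x)
}

#' Simulate healthy cohort values from a fitted reference model
#'
#' Draws `nsim` synthetic subjects with per-marker values from
#' `Normal(mean, sd)` as fitted; a parametric bootstrap of the reference
#' cohort on the relative log10 scale.
#'
#' @param object A fitted `tolerance_ranges`.
#' @param nsim Number of subjects to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A numeric matrix (`nsim` rows, one column per marker) suitable for
#'   refitting with [fit_tolerance_ranges()].
#' @export
simulate.tolerance_ranges <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  r <- object$ranges
  m <- vapply(seq_len(nrow(r)),
              function(i) stats::rnorm(nsim, r$mean[i], r$sd[i]),
              numeric(nsim))
  if (nsim == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- r$marker
  m
}

#' Serialize fitted tolerance ranges to JSON
#'
#' Round-trips at 12 significant digits via [read_ranges_json()].
#'
#' @param fit A `tolerance_ranges` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranges_json <- function(fit, path) {
  stopifnot(inherits(fit, "tolerance_ranges"))
  r <- fit$ranges
  sig <- function(x) if (is.na(x)) NULL else signif(x, 12)
  ranges <- stats::setNames(lapply(seq_len(nrow(r)), function(i) {
    Filter(Negate(is.null), list(
      class = r$marker_class[i],
      mean = sig(r$mean[i]), sd = sig(r$sd[i]),
      borderline_low = sig(r$borderline_low[i]),
      beyond_low = sig(r$beyond_low[i]),
      borderline_high = sig(r$borderline_high[i]),
      beyond_high = sig(r$beyond_high[i])))
  }), r$marker)
  jsonlite::write_json(list(cohort_n = fit$cohort_n, ranges = ranges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fitted tolerance ranges from JSON
#'
#' @param path Path to a JSON file written by [write_ranges_json()].
#' @return A `tolerance_ranges` object.
#' @export
read_ranges_json <- function(path) {
  obj <- jsonlite::read_json(path)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  rows <- lapply(names(obj$ranges), function(mk) {
    e <- obj$ranges[[mk]]
    data.frame(marker = mk, marker_class = e$class, n = NA_integer_,
               mean = num(e$mean), sd = num(e$sd),
               borderline_low = num(e$borderline_low),
               beyond_low = num(e$beyond_low),
               borderline_high = num(e$borderline_high),
               beyond_high = num(e$beyond_high),
               stringsAsFactors = FALSE)
  })
  structure(list(ranges = do.call(rbind, rows),
                 cohort_n = as.integer(obj$cohort_n),
                 direction = NULL, call = NULL),
            class = "tolerance_ranges")
}
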