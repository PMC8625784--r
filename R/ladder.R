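#' Fit a molecular-weight ladder model from a marker lane
#'
#' Maps relative mobility (Rf = apex migration row divided by the row of a
#' user-declared reference front, e.g. the dye front or gel end) to
#' molecular weight using a marker lane of known masses. `"loglinear"`
#' fits `log10(mw) = intercept + slope * rf` by least squares — the
#' classical Ferguson-style MW calibration. `"piecewise"` interpolates
#' log10(mw) linearly between neighbouring anchors and reproduces every
#' anchor exactly; it is the default for MW reporting since real ladders
#' are only locally log-linear.
#'
#' @param marker_peaks A [peak_table] of the marker lane's bands (or a
#'   numeric vector of apex rows), in migration order.
#' @param marker_mws Known marker masses in kDa, strictly decreasing with
#'   migration (largest protein migrates least).
#' @param front_row Migration row of the reference front; must lie beyond
#'   every marker apex.
#' @param mode `"piecewise"` (default) or `"loglinear"`.
#' @return An object of class `ladder_model` with `anchors` (data frame
#'   `mw`, `rf`), `slope`, `intercept` (of the log-linear fit, always
#'   computed for reference), and `mode`.
#' @export
fit_ladder <- function(marker_peaks, marker_mws, front_row,
                       mode = c("piecewise", "loglinear")) {
  mode <- match.arg(mode)
  apex <- if (inherits(marker_peaks, "peak_table") ||
                is.data.frame(marker_peaks)) marker_peaks$apex_row
          else as.numeric(marker_peaks)
  mws <- as.numeric(marker_mws)
  if (length(apex) != length(mws) || length(apex) < 2L)
    stop("need equal counts (>= 2) of marker peaks and marker masses")
  o <- order(apex)
  apex <- apex[o]; mws <- mws[o]
  if (any(diff(apex) <= 0))
    stop("marker apex rows must be distinct")
  if (any(diff(mws) >= 0))
    stop("marker masses must be strictly decreasing with migration")
  if (front_row <= max(apex))
    stop("front_row (", front_row, ") must lie beyond every marker apex (max ",
         max(apex), ")")
  rf <- apex / front_row
  fit <- stats::lm(log10(mws) ~ rf)
  structure(list(anchors = data.frame(mw = mws, rf = rf),
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 mode = mode,
                 front_row = front_row),
            class = "ladder_model")
}

#' @export
print.ladder_model <- function(x, ...) {
  cat("<ladder_model> ", nrow(x$anchors), " anchors, ",
      format(min(x$anchors$mw)), "-", format(max(x$anchors$mw)),
      " kDa, mode=", x$mode, "\n", sep = "")
  cat(sprintf("  log10(mw) = %.4f %+.4f * rf (log-linear reference fit)\n",
              x$intercept, x$slope))
  invisible(x)
}

#' @export
predict.ladder_model <- function(object, rf, ...) {
  if (any(!is.finite(rf)) || any(rf <= 0) || any(rf > 1))
    stop("relative mobility rf must lie in (0, 1]")
  an <- object$anchors[order(object$anchors$rf), ]
  extrap <- rf < min(an$rf) | rf > max(an$rf)
  if (object$mode == "loglinear") {
    mw <- 10^(object$intercept + object$slope * rf)
  } else {
    lg <- stats::approx(an$rf, log10(an$mw), xout = rf, rule = 2)$y
    # linear extension of the end segments in log-mass space
    k <- nrow(an)
    s1 <- (log10(an$mw[2L]) - log10(an$mw[1L])) / (an$rf[2L] - an$rf[1L])
    s2 <- (log10(an$mw[k]) - log10(an$mw[k - 1L])) / (an$rf[k] - an$rf[k - 1L])
    low <- rf < an$rf[1L]; high <- rf > an$rf[k]
    lg[low] <- log10(an$mw[1L]) + s1 * (rf[low] - an$rf[1L])
    lg[high] <- log10(an$mw[k]) + s2 * (rf[high] - an$rf[k])
    mw <- 10^lg
  }
  attr(mw, "extrapolated") <- extrap
  mw
}

#' Estimate a band's molecular weight from the ladder
#'
#' Computes the band's relative mobility `rf = apex_row / front_row` and
#' evaluates the ladder model. Queries outside the anchor Rf range are
#' answered by extending the end segment and flagged via the
#' `"extrapolated"` attribute of the result (and in pipeline reports).
#'
#' @param ladder A [fit_ladder()] model.
#' @param apex_row Band apex migration row(s), 0 < apex_row <= front_row.
#' @param front_row Reference-front row used for Rf.
#' @return Estimated molecular weight(s) in kDa, with attribute
#'   `"extrapolated"`.
#' @export
estimate_mw <- function(ladder, apex_row, front_row) {
  stopifnot(inherits(ladder, "ladder_model"))
  if (any(apex_row <= 0) || any(apex_row > front_row))
    stop("require 0 < apex_row <= front_row")
  predict(ladder, apex_row / front_row)
}
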