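#' Baseline correction of a densitogram
#'
#' Removes the slowly varying baseline under the band peaks, after which
#' peak areas can be integrated as in chromatography.
#'
#' `"valley_chords"` draws straight chords between consecutive detected
#' valleys (local minima of a lightly smoothed profile, endpoints
#' included) and subtracts them — the classic chromatographic
#' valley-to-valley baseline. `"smooth_floor"` iteratively clips the
#' profile to a local-linear smooth of itself, converging on a smooth
#' lower envelope; this is the more robust choice for crowded or diffuse
#' lanes, where valleys never return to the floor.
#'
#' @param d A raw [densitogram] (`baseline_subtracted = FALSE`).
#' @param method `"valley_chords"` or `"smooth_floor"`.
#' @param span Fraction of the profile length used as the smoothing window
#'   of `"smooth_floor"` (default 0.15) and for valley detection.
#' @param iterations Clipping iterations for `"smooth_floor"`.
#' @return A baseline-subtracted [densitogram] (values clipped at 0).
#' @export
subtract_baseline <- function(d, method = c("valley_chords", "smooth_floor"),
                              span = 0.15, iterations = 10L) {
  stopifnot(inherits(d, "densitogram"))
  method <- match.arg(method)
  if (d$baseline_subtracted)
    stop("densitogram is already baseline-subtracted")
  v <- d$values
  n <- length(v)
  if (method == "valley_chords") {
    w <- max(3L, round(0.02 * n))
    sm <- .smooth_ma(v, w)
    valleys <- .local_maxima(-sm)
    knots <- sort(unique(c(1L, valleys, n)))
    # knot levels from the smoothed profile: raw valley samples would pin
    # the chords to noise minima
    base <- stats::approx(knots, sm[knots], xout = seq_len(n), rule = 2)$y
  } else {
    w <- max(5L, round(span * n))
    y <- v
    f <- w / n
    for (i in seq_len(iterations)) {
      base <- stats::lowess(seq_len(n), y, f = f, iter = 0L)$y
      y <- pmin(y, base)
    }
    base <- stats::lowess(seq_len(n), y, f = f, iter = 0L)$y
    # the clipped fit keeps a small bump under each band; bridge the band
    # support (judged against a rolling-minimum floor) by interpolating
    # the baseline from the flanking rows
    keep <- .band_free_rows(v, max(2L * w, round(0.3 * n)))
    if (!is.null(keep) && any(!keep)) {
      ok <- which(keep)
      base[!keep] <- stats::approx(ok, base[ok], xout = which(!keep),
                                   rule = 2)$y
    }
  }
  out <- pmax(v - base, 0)
  densitogram(out, lane_id = d$lane_id, row_origin = d$row_origin,
              baseline_subtracted = TRUE, saturation = d$saturation)
}

#' Peak tables
#'
#' A data frame of integrated band peaks, one row per peak, with half-open
#' row intervals `[start_row, end_row)`.
#'
#' @param peaks Data frame with columns `lane_id`, `apex_row`, `start_row`,
#'   `end_row`, `height`, `area`, `saturated`.
#' @param profile_length Length of the densitogram(s) the peaks came from.
#' @return An object of classes `peak_table` and `data.frame`.
#' @export
peak_table <- function(peaks = NULL, profile_length = NA_integer_) {
  if (is.null(peaks) || !nrow(as.data.frame(peaks)))
    peaks <- data.frame(lane_id = integer(), apex_row = integer(),
                        start_row = integer(), end_row = integer(),
                        height = numeric(), area = numeric(),
                        saturated = logical())
  peaks <- as.data.frame(peaks)
  structure(peaks, profile_length = as.integer(profile_length),
            class = c("peak_table", "data.frame"))
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", nrow(x), " peak(s)\n", sep = "")
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

# Fraction of saturated source pixels over a peak's support; peaks with
# more than 1% saturated support are flagged, never silently quantified.
.support_saturated <- function(d, s, e) {
  if (is.null(d$saturation)) return(FALSE)
  mean(d$saturation[s:(e - 1L)]) > 0.01
}

#' Detect band peaks in a baseline-subtracted densitogram
#'
#' Finds local maxima at least `min_height_frac` of the profile maximum in
#' height and in topographic prominence (prominence suppresses noise
#' ripple on band flanks), then bounds each peak valley-to-valley: between
#' adjacent peaks at the deepest interior minimum, and on outer flanks at
#' the first local minimum after the profile falls below 5% of the peak
#' height (or the profile end). Plateau apexes report their earliest row.
#'
#' @param d A baseline-subtracted [densitogram].
#' @param min_height_frac Detection threshold as a fraction of the profile
#'   maximum (0 < frac < 1; default 0.05).
#' @param min_width_rows Minimum peak width in rows (default 3).
#' @param smooth_rows Window of the light pre-detection smoothing; defaults
#'   to `min_width_rows`.
#' @return A [peak_table]; empty when the profile is flat.
#' @export
detect_peaks <- function(d, min_height_frac = 0.05, min_width_rows = 3L,
                         smooth_rows = NULL) {
  stopifnot(inherits(d, "densitogram"))
  if (!d$baseline_subtracted)
    stop("detect_peaks requires a baseline-subtracted densitogram")
  if (!(min_height_frac > 0 && min_height_frac < 1))
    stop("min_height_frac must be in (0, 1)")
  if (is.null(smooth_rows)) smooth_rows <- min_width_rows
  v <- d$values
  n <- length(v)
  sm <- .smooth_ma(v, smooth_rows)
  vmax <- max(sm)
  if (vmax <= 0) return(peak_table(profile_length = n))
  thr <- min_height_frac * vmax
  cand <- .local_maxima(sm)
  if (!length(cand)) return(peak_table(profile_length = n))
  prom <- .prominence(sm, cand)
  apexes <- cand[sm[cand] >= thr & prom >= thr]
  if (!length(apexes)) return(peak_table(profile_length = n))

  k <- length(apexes)
  starts <- integer(k); ends <- integer(k)
  for (i in seq_len(k)) {
    a <- apexes[i]
    h <- sm[a]
    # left bound
    if (i > 1L) {
      between <- apexes[i - 1L]:a
      starts[i] <- between[which.min(sm[between])]
    } else {
      j <- a
      while (j > 1L && sm[j - 1L] > 0.05 * h) j <- j - 1L
      while (j > 1L && sm[j - 1L] < sm[j]) j <- j - 1L
      starts[i] <- j
    }
    # right bound
    if (i < k) {
      between <- a:apexes[i + 1L]
      ends[i] <- between[which.min(sm[between])]
    } else {
      j <- a
      while (j < n && sm[j + 1L] > 0.05 * h) j <- j + 1L
      while (j < n && sm[j + 1L] < sm[j]) j <- j + 1L
      ends[i] <- min(j + 1L, n)
    }
  }
  # refine apex on the raw profile within the bounds (earliest row on ties)
  apex_raw <- vapply(seq_len(k), function(i) {
    idx <- starts[i]:ends[i]
    idx[which.max(v[idx])]
  }, integer(1))
  keep <- (ends - starts) >= min_width_rows
  pk <- data.frame(
    lane_id = d$lane_id,
    apex_row = apex_raw[keep],
    start_row = starts[keep],
    end_row = ends[keep],
    height = v[apex_raw[keep]],
    area = vapply(which(keep), function(i)
      .trapz_samples(v, starts[i], ends[i]), numeric(1)),
    saturated = vapply(which(keep), function(i)
      .support_saturated(d, starts[i], ends[i]), logical(1)))
  peak_table(pk, profile_length = n)
}

#' Integrate a densitogram over a row interval
#'
#' Trapezoidal integral of the piecewise-linear interpolant of the profile
#' over the continuous row interval from `start_row` to `end_row` (capped
#' at the profile length), in row units. Exact for piecewise-linear
#' profiles and exactly additive over partitions sharing interior bounds.
#'
#' @param d A baseline-subtracted [densitogram].
#' @param start_row,end_row Half-open row interval `[start_row, end_row)`,
#'   1-based.
#' @return The peak area (arbitrary units x rows).
#' @export
integrate_peak <- function(d, start_row, end_row) {
  stopifnot(inherits(d, "densitogram"))
  n <- length(d$values)
  if (!(start_row >= 1 && start_row < end_row && end_row <= n + 1L))
    stop("integration bounds [", start_row, ", ", end_row,
         ") invalid for profile of length ", n)
  .trapz_samples(d$values, as.integer(start_row),
                 min(as.integer(end_row), n))
}

#' Integrate a manually declared band region
#'
#' For diffuse (blurred, polydisperse) bands — e.g. degradation smears —
#' automatic valley detection is unreliable; declare the bounds instead.
#' Bands not declared are simply excluded from quantification.
#'
#' @inheritParams integrate_peak
#' @return A one-row [peak_table] carrying the user bounds, the apex
#'   within them, the trapezoidal area, and the saturation flag.
#' @export
integrate_region <- function(d, start_row, end_row) {
  area <- integrate_peak(d, start_row, end_row)
  s <- as.integer(start_row); e <- min(as.integer(end_row), length(d$values))
  idx <- s:max(s, e - 1L)
  apex <- idx[which.max(d$values[idx])]
  peak_table(data.frame(lane_id = d$lane_id, apex_row = apex,
                        start_row = s, end_row = as.integer(end_row),
                        height = d$values[apex], area = area,
                        saturated = .support_saturated(d, s, max(s + 1L, e))),
             profile_length = length(d$values))
}

#' Write a peak table as CSV
#'
#' Columns: `lane_id, apex_row, start_row, end_row, height, area,
#' saturated`.
#'
#' @param pt A [peak_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(pt, path) {
  stopifnot(inherits(pt, "peak_table"))
  utils::write.csv(as.data.frame(pt)[, c("lane_id", "apex_row", "start_row",
                                         "end_row", "height", "area",
                                         "saturated")],
                   path, row.names = FALSE)
  invisible(path)
}
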