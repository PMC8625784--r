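#' Gel image objects
#'
#' A `gel_image` holds the optical signal extracted from a photographed or
#' scanned 1-D electrophoresis gel as a numeric matrix. Rows follow the
#' migration axis with the sample wells at row 1; columns follow the lane
#' axis. The signal is inverted relative to the photograph: darker stained
#' bands give larger signal values, in units of the source image's code
#' values (0 to 2^bit_depth - 1).
#'
#' @param signal Numeric matrix of non-negative optical signal.
#' @param bit_depth Integer, bit depth of the source raster (8 or 16).
#' @param saturated_mask Logical matrix of the same dimensions marking
#'   source pixels at the full-scale code value.
#' @param white_reference Luminance (code value) taken as unstained
#'   background.
#' @param mode Inversion mode used, `"linear"` or `"od"`.
#' @param source Path of the source image, if any.
#' @param flattened Logical; has the background been flattened?
#' @return An object of class `gel_image`.
#' @export
gel_image <- function(signal, bit_depth = 8L, saturated_mask = NULL,
                      white_reference = NA_real_, mode = "linear",
                      source = NA_character_, flattened = FALSE) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("gel_image signal must be finite and non-negative")
  if (is.null(saturated_mask))
    saturated_mask <- matrix(FALSE, nrow(signal), ncol(signal))
  saturated_mask <- as.matrix(saturated_mask)
  if (!identical(dim(saturated_mask), dim(signal)))
    stop("saturated_mask must have the same dimensions as signal")
  structure(
    list(signal = signal,
         n_rows = nrow(signal),
         n_cols = ncol(signal),
         bit_depth = as.integer(bit_depth),
         saturated_mask = saturated_mask,
         white_reference = white_reference,
         mode = mode,
         source = source,
         flattened = isTRUE(flattened)),
    class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  cat("<gel_image> ", x$n_rows, " rows (migration) x ", x$n_cols,
      " cols (lanes), ", x$bit_depth, "-bit, mode=", x$mode,
      if (x$flattened) ", background-flattened" else "", "\n", sep = "")
  cat("  signal range [", format(min(x$signal), digits = 4), ", ",
      format(max(x$signal), digits = 4), "], ",
      sum(x$saturated_mask), " saturated px\n", sep = "")
  invisible(x)
}

# Decode a raster file into a [0,1] luminance matrix plus bit depth and a
# per-pixel saturation mask. Alpha channels are discarded; RGB collapses
# with Rec. 601 luma weights (Coomassie quantification is monochrome).
.read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = , tiff = tiff::readTIFF(path),
           jpg = , jpeg = jpeg::readJPEG(path),
           stop("unsupported image format '", ext, "'")),
    error = function(e) stop("cannot read gel image '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ext %in% c("tif", "tiff")) {
    xi <- tryCatch(tiff::readTIFF(path, as.is = TRUE), error = function(e) NULL)
    bit <- if (!is.null(xi) && max(xi) > 255) 16L
    else if (!is.null(xi) && max(arr) > 0 &&
               abs(max(xi) / max(arr) - 65535) < 1) 16L
    else 8L
  } else if (ext == "png") {
    bit <- if (max(abs(arr * 255 - round(arr * 255))) < 1e-6) 8L else 16L
  } else bit <- 8L
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    chans <- arr[, , seq_len(min(nc, 3L)), drop = FALSE]
    sat <- apply(chans, c(1, 2), max) >= 1 - 0.5 / (2^bit - 1)
    lum <- if (dim(chans)[3L] == 3L)
      0.299 * chans[, , 1L] + 0.587 * chans[, , 2L] + 0.114 * chans[, , 3L]
    else chans[, , 1L]
  } else {
    lum <- arr
    sat <- arr >= 1 - 0.5 / (2^bit - 1)
  }
  list(luminance = lum, bit_depth = bit, saturated = sat)
}

#' Load a gel photograph as an optical-signal matrix
#'
#' Reads a PNG, TIFF or JPEG photograph of a stained gel, collapses colour
#' to luminance, and inverts it so that darker bands carry larger signal:
#' `signal = white_reference - luminance`, clipped at zero (`mode =
#' "linear"`, the default, consistent with staining intensity proportional
#' to protein amount), or the decadic optical density
#' `log10(white_reference / luminance)` (`mode = "od"`). When
#' `white_reference` is omitted it defaults to the modal luminance code
#' value, i.e. the unstained background.
#'
#' @param path Path to an 8- or 16-bit PNG/TIFF/JPEG image.
#' @param white_reference Optional background luminance in code values
#'   (0..2^bit - 1). Default: the modal code value of the image.
#' @param mode `"linear"` (default) or `"od"`.
#' @param orientation Where the sample wells are in the photograph; the
#'   image is rotated so wells end up at row 1.
#' @return A [gel_image].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(0.5, 32, 32), f)
#' img <- load_gel_image(f)
#' max(img$signal)  # flat field: zero signal everywhere
#' @export
load_gel_image <- function(path, white_reference = NULL,
                           mode = c("linear", "od"),
                           orientation = c("wells_top", "wells_bottom",
                                           "wells_left", "wells_right")) {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("cannot read gel image '", path, "': file does not exist")
  r <- .read_raster(path)
  lum <- r$luminance
  sat <- r$saturated
  rot <- switch(orientation,
                wells_top = function(m) m,
                wells_bottom = function(m) m[rev(seq_len(nrow(m))),
                                             rev(seq_len(ncol(m))), drop = FALSE],
                wells_left = function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                wells_right = function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE])
  lum <- rot(lum); sat <- rot(sat)
  if (nrow(lum) < 16L || ncol(lum) < 16L)
    stop("degenerate gel image: ", nrow(lum), "x", ncol(lum),
         " is smaller than 16x16")
  maxcode <- 2^r$bit_depth - 1
  code <- lum * maxcode
  if (is.null(white_reference)) {
    tab <- tabulate(as.integer(round(code)) + 1L, nbins = maxcode + 1L)
    white_reference <- which.max(tab) - 1
  }
  signal <- switch(mode,
                   linear = pmax(white_reference - code, 0),
                   od = pmax(log10(pmax(white_reference, 1) / pmax(code, 1)), 0))
  gel_image(signal, bit_depth = r$bit_depth, saturated_mask = sat,
            white_reference = white_reference, mode = mode, source = path)
}

#' Flatten smooth background staining and illumination gradients
#'
#' Estimates a smooth per-column background along the migration axis with a
#' moving low-quantile filter and subtracts it. Each window contributes a
#' background knot at the actual row of its low order statistic, so smooth
#' illumination gradients are removed essentially exactly (the knots lie on
#' the background curve) while bands — local maxima much narrower than the
#' window, hence never the window's low order statistic — survive.
#'
#' @param img A [gel_image].
#' @param window_rows Moving-window length in rows; default 25% of the
#'   number of rows. Must be at least 3 and less than `n_rows`.
#' @param prob Quantile used as the background level (default 0.1).
#' @return A [gel_image] with background removed (signal clipped at 0).
#' @export
flatten_background <- function(img, window_rows = NULL, prob = 0.1) {
  stopifnot(inherits(img, "gel_image"))
  if (is.null(window_rows)) window_rows <- max(3L, round(0.25 * img$n_rows))
  window_rows <- as.integer(window_rows)
  if (window_rows < 3L || window_rows >= img$n_rows)
    stop("window_rows must be in [3, n_rows): got ", window_rows)
  bg <- apply(img$signal, 2L, .rolling_low_quantile,
              window = window_rows, prob = prob)
  out <- pmax(img$signal - bg, 0)
  gel_image(out, bit_depth = img$bit_depth,
            saturated_mask = img$saturated_mask,
            white_reference = img$white_reference, mode = img$mode,
            source = img$source, flattened = TRUE)
}

#' Lane regions
#'
#' A lane is a half-open column interval `[col_start, col_end)` (1-based)
#' of the gel in which one sample migrated.
#'
#' @param lane_id Integer lane number (left to right, from 1).
#' @param col_start,col_end Half-open column interval.
#' @param role One of `"sample"`, `"calibration"`, `"marker"`, `"blank"`.
#' @return A one-row data frame of class `lane_regions`.
#' @export
lane_region <- function(lane_id, col_start, col_end, role = "sample") {
  role <- match.arg(role, c("sample", "calibration", "marker", "blank"))
  if (!(col_start >= 1 && col_start < col_end))
    stop("lane ", lane_id, ": require 1 <= col_start < col_end")
  structure(data.frame(lane_id = as.integer(lane_id),
                       col_start = as.integer(col_start),
                       col_end = as.integer(col_end),
                       role = role,
                       stringsAsFactors = FALSE),
            class = c("lane_regions", "data.frame"))
}

.as_lane_regions <- function(df) {
  structure(as.data.frame(df), class = c("lane_regions", "data.frame"))
}

#' Detect lanes from the column-wise signal profile
#'
#' Takes the column-wise mean signal, removes its robust floor (the 5th
#' percentile, i.e. the residual noise offset of blank columns),
#' log-compresses the result, smooths it, and keeps contiguous runs above
#' `threshold_frac` of the robust maximum (95th percentile) of the
#' compressed profile, numbered left to right. The log compression is what
#' lets a fixed relative threshold find both ends of a 16-fold
#' serial-dilution gel: on the raw scale the faintest lane is ~6% of the
#' brightest and no fixed fraction separates it from background. Run edges
#' are then refined on the uncompressed, unsmoothed profile so that a
#' lane's interval does not spill into background columns (which would
#' dilute the width-averaged densitogram). Touching lanes — runs with more
#' than one prominent maximum — are split at the deepest interior minimum.
#'
#' @param img A [gel_image] (background-flattened input recommended).
#' @param expected_n If given, an error is raised when the detected count
#'   differs, rather than silently merging or splitting lanes.
#' @param threshold_frac Fraction of the robust maximum of the compressed
#'   column profile above which columns belong to a lane (default 0.2).
#' @param min_width_cols Minimum lane width in columns.
#' @param smooth_cols Smoothing window for the column profile.
#' @return A `lane_regions` data frame with columns `lane_id`, `col_start`,
#'   `col_end` (half-open), `role` (all `"sample"`).
#' @export
detect_lanes <- function(img, expected_n = NULL, threshold_frac = 0.2,
                         min_width_cols = 3L, smooth_cols = NULL) {
  stopifnot(inherits(img, "gel_image"))
  if (is.null(smooth_cols)) smooth_cols <- max(3L, round(0.02 * img$n_cols))
  cm <- colMeans(img$signal)
  stat0 <- pmax(cm - stats::quantile(cm, 0.05, names = FALSE), 0)
  s95 <- stats::quantile(stat0, 0.95, names = FALSE)
  if (s95 <= 0) stop("no lanes detected: gel appears blank")
  comp_raw <- log1p(stat0 / (0.02 * s95))
  comp <- .smooth_ma(comp_raw, smooth_cols)
  robust_max <- stats::quantile(comp, 0.95, names = FALSE)
  thr <- threshold_frac * robust_max
  if (!any(comp > thr))
    stop("no lanes detected: gel appears blank")
  above <- comp > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  intervals <- list()
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1L]; b <- runs[i, 2L]
    if (b - a + 1L < min_width_cols) next
    seg <- comp[a:b]
    mx <- .local_maxima(seg)
    if (length(mx) > 1L) {
      prom <- .prominence(seg, mx)
      mx <- mx[prom >= thr]
    }
    if (length(mx) > 1L) {
      # split touching lanes only at genuine valleys: the dip must reach
      # below 70% of the lower flanking maximum (guards against plateau
      # ripple at floating-point scale)
      cuts <- integer()
      for (j in seq_len(length(mx) - 1L)) {
        between <- mx[j]:mx[j + 1L]
        v <- between[which.min(seg[between])]
        if (seg[v] < 0.7 * min(seg[mx[j]], seg[mx[j + 1L]]))
          cuts <- c(cuts, v)
      }
      bounds <- c(a, a + cuts - 1L, b + 1L)
      for (j in seq_len(length(bounds) - 1L))
        intervals[[length(intervals) + 1L]] <- c(bounds[j], bounds[j + 1L])
    } else {
      intervals[[length(intervals) + 1L]] <- c(a, b + 1L)
    }
  }
  # lanes on one gel have comparable widths: discard noise blips much
  # narrower than the widest candidate run
  if (length(intervals) > 1L) {
    widths <- vapply(intervals, function(iv) iv[2L] - iv[1L], numeric(1))
    intervals <- intervals[widths >= max(min_width_cols, 0.3 * max(widths))]
  }
  # refine edges on the uncompressed profile: keep the contiguous block
  # around the run maximum with at least half the run's median level
  intervals <- lapply(intervals, function(iv) {
    a <- iv[1L]; b <- iv[2L] - 1L
    seg <- stat0[a:b]
    lev <- 0.5 * stats::median(seg)
    pk <- a + which.max(seg) - 1L
    lo <- pk
    while (lo > a && stat0[lo - 1L] >= lev) lo <- lo - 1L
    hi <- pk
    while (hi < b && stat0[hi + 1L] >= lev) hi <- hi + 1L
    c(lo, hi + 1L)
  })
  if (!length(intervals))
    stop("no lanes detected: all candidate runs narrower than ",
         min_width_cols, " columns")
  if (!is.null(expected_n) && length(intervals) != expected_n)
    stop("lane count mismatch: detected ", length(intervals),
         " lanes but expected ", expected_n)
  out <- do.call(rbind, lapply(seq_along(intervals), function(k)
    data.frame(lane_id = k, col_start = intervals[[k]][1L],
               col_end = intervals[[k]][2L], role = "sample",
               stringsAsFactors = FALSE)))
  .as_lane_regions(out)
}

#' Densitograms
#'
#' A densitogram is one lane's optical signal versus migration distance —
#' the 1-D profile this package processes like a chromatogram.
#'
#' @param values Numeric vector of non-negative signal per migration row.
#' @param lane_id Integer lane number.
#' @param row_origin Gel row of `values[1]`.
#' @param baseline_subtracted Logical.
#' @param saturation Optional per-row fraction of saturated source pixels.
#' @return An object of class `densitogram`.
#' @export
densitogram <- function(values, lane_id = 1L, row_origin = 1L,
                        baseline_subtracted = FALSE, saturation = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("densitogram needs at least 2 rows")
  if (any(!is.finite(values))) stop("densitogram values must be finite")
  if (any(values < 0)) stop("densitogram values must be non-negative")
  structure(list(values = values,
                 lane_id = as.integer(lane_id),
                 row_origin = as.integer(row_origin),
                 baseline_subtracted = isTRUE(baseline_subtracted),
                 saturation = saturation),
            class = "densitogram")
}

#' @export
print.densitogram <- function(x, ...) {
  cat("<densitogram> lane ", x$lane_id, ", ", length(x$values), " rows, ",
      if (x$baseline_subtracted) "baseline-subtracted" else "raw",
      ", max ", format(max(x$values), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.densitogram <- function(x, ...) {
  graphics::plot(seq_along(x$values) + x$row_origin - 1L, x$values,
                 type = "l", xlab = "migration row",
                 ylab = "signal (arb. units)",
                 main = paste0("Lane ", x$lane_id), ...)
  invisible(x)
}

#' Extract a lane's densitogram
#'
#' Averages the optical signal across the lane's columns at each migration
#' row. Averaging (not summing) makes the profile invariant to the declared
#' lane width over laterally uniform bands.
#'
#' @param img A [gel_image].
#' @param lane A one-row `lane_regions` entry (or anything with
#'   `lane_id`, `col_start`, `col_end`).
#' @return A [densitogram] of length `n_rows`.
#' @export
lane_profile <- function(img, lane) {
  stopifnot(inherits(img, "gel_image"))
  cs <- lane$col_start[1L]; ce <- lane$col_end[1L]
  if (is.na(cs) || is.na(ce) || cs < 1 || ce > img$n_cols + 1L || cs >= ce)
    stop("lane columns [", cs, ", ", ce, ") outside image bounds [1, ",
         img$n_cols + 1L, ")")
  cols <- cs:(ce - 1L)
  vals <- rowMeans(img$signal[, cols, drop = FALSE])
  satf <- rowMeans(img$saturated_mask[, cols, drop = FALSE])
  densitogram(vals, lane_id = lane$lane_id[1L], row_origin = 1L,
              baseline_subtracted = FALSE, saturation = satf)
}

#' Write the signal matrix of a gel image as a 16-bit TIFF
#'
#' @param img A [gel_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_tiff <- function(img, path) {
  stopifnot(inherits(img, "gel_image"))
  maxcode <- 2^16 - 1
  m <- pmin(img$signal / maxcode, 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}
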