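# Synthetic gel photographs with exact ground truth.
#
# Bands are Gaussian along the migration axis and uniform across the lane
# width (top-hat), so every band has the closed-form densitogram area
# mass_ug * response, exactly, before noise and quantization. Band centres
# follow the mobility law rf = intercept + slope * log10(mw) relative to a
# reference front row. Illumination is a planar gradient over a light
# background; sensor noise is additive Gaussian, applied before
# quantization; the image is written dark-bands-on-light like a stained
# gel photograph.

# Default mobility law: 116 kDa at rf 0.12, 14.4 kDa at rf 0.90.
.default_mobility <- function() {
  slope <- (0.90 - 0.12) / (log10(14.4) - log10(116))
  list(slope = slope, intercept = 0.12 - slope * log10(116))
}

.mobility_rf <- function(mw, mobility) {
  mobility$intercept + mobility$slope * log10(mw)
}

.lane_layout <- function(n_lanes, lane_width = 36L, gap = 14L, margin = 18L,
                         roles = rep("sample", n_lanes)) {
  starts <- margin + (seq_len(n_lanes) - 1L) * (lane_width + gap) + 1L
  data.frame(lane_id = seq_len(n_lanes), col_start = starts,
             col_end = starts + lane_width, role = roles,
             stringsAsFactors = FALSE)
}

#' Synthetic gel specification
#'
#' Fully determines a rendered synthetic gel photograph: geometry, lanes,
#' bands, mobility law, illumination, noise, bit depth and RNG seed.
#' Rendering is bit-exact reproducible for a fixed seed.
#'
#' @param n_rows,n_cols Image size (rows = migration axis).
#' @param lanes Data frame `lane_id`, `col_start`, `col_end` (half-open),
#'   `role`.
#' @param bands Data frame with one row per band: `lane_id`, `mw` (kDa;
#'   may be NA when `center_row` is given), `center_row` (NA to place via
#'   the mobility law), `mass_ug`, `sigma_rows`, `response` (signal per
#'   µg), `kind` (`"band"` or `"smear"`), `true_alpha_pct` (NA unless a
#'   degradation series).
#' @param mobility List with `slope` and `intercept` of
#'   `rf = intercept + slope * log10(mw)`.
#' @param front_row Reference-front row (all band centres must lie above).
#' @param background Numeric `c(base, row_gradient, col_gradient)` of the
#'   illumination plane, in normalized luminance.
#' @param noise_sd Additive Gaussian sensor noise (normalized luminance).
#' @param bit_depth 8 or 16.
#' @param seed Integer RNG seed for the noise.
#' @return An object of class `synthetic_gel_spec`.
#' @export
synthetic_gel_spec <- function(n_rows, n_cols, lanes, bands,
                               mobility = .default_mobility(),
                               front_row = round(0.95 * n_rows),
                               background = c(0.88, 0, 0),
                               noise_sd = 0, bit_depth = 16L, seed = 1L) {
  lanes <- as.data.frame(lanes)
  bands <- as.data.frame(bands)
  need <- c("lane_id", "mass_ug", "sigma_rows", "response")
  if (!all(need %in% names(bands)))
    stop("bands need columns: ", paste(need, collapse = ", "))
  if (is.null(bands$mw)) bands$mw <- NA_real_
  if (is.null(bands$center_row)) bands$center_row <- NA_real_
  if (is.null(bands$kind)) bands$kind <- "band"
  if (is.null(bands$true_alpha_pct)) bands$true_alpha_pct <- NA_real_
  if (any(bands$mass_ug <= 0) || any(bands$sigma_rows <= 0) ||
        any(bands$response <= 0))
    stop("band mass_ug, sigma_rows and response must be positive")
  miss <- is.na(bands$center_row)
  if (any(miss & is.na(bands$mw)))
    stop("each band needs either mw or center_row")
  bands$center_row[miss] <-
    .mobility_rf(bands$mw[miss], mobility) * front_row
  if (!(bit_depth %in% c(8L, 16L))) stop("bit_depth must be 8 or 16")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(!(bands$lane_id %in% lanes$lane_id)))
    stop("band placed in an undeclared lane")
  if (any(bands$center_row >= front_row) || any(bands$center_row <= 1))
    stop("band centre rows must lie within (1, front_row)")
  if (any(lanes$col_start < 1) || any(lanes$col_end > n_cols + 1L))
    stop("lane columns outside the gel")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 lanes = lanes, bands = bands, mobility = mobility,
                 front_row = as.integer(front_row),
                 background = as.numeric(background),
                 noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "synthetic_gel_spec")
}

#' @export
print.synthetic_gel_spec <- function(x, ...) {
  cat("<synthetic_gel_spec> ", x$n_rows, "x", x$n_cols, ", ",
      nrow(x$lanes), " lanes, ", nrow(x$bands), " bands, ",
      x$bit_depth, "-bit, noise_sd=", format(x$noise_sd, digits = 3),
      ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Render a synthetic gel photograph
#'
#' Draws every band, adds the illumination plane and Gaussian sensor
#' noise, inverts to the dark-band-on-light photographic convention,
#' quantizes to the spec's bit depth, and (optionally) writes the image
#' (16-bit TIFF or 8-bit PNG) together with a ground-truth CSV and the
#' generating spec as a flat key-value text file.
#'
#' @param spec A [synthetic_gel_spec].
#' @param path Optional image output path (`.tif` for 16-bit, `.png` for
#'   8-bit). When given, `<path>_truth.csv` and `<path>_spec.txt` are
#'   written alongside.
#' @return A list with `luminance` (quantized, in `[0, 1]`), `truth`
#'   (data frame: `band_id`, `lane_id`, `kind`, `mw`, `center_row`,
#'   `sigma_rows`, `mass_ug`, `integrated_signal` in code-value units,
#'   `true_alpha_pct`), `path` (or NA), and `spec`.
#' @export
render_gel <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthetic_gel_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  rows <- seq_len(nr)
  sig <- matrix(0, nr, nc)
  b <- spec$bands
  for (i in seq_len(nrow(b))) {
    lane <- spec$lanes[spec$lanes$lane_id == b$lane_id[i], ]
    cols <- lane$col_start:(lane$col_end - 1L)
    amp <- b$mass_ug[i] * b$response[i] / (b$sigma_rows[i] * sqrt(2 * pi))
    prof <- amp * exp(-0.5 * ((rows - b$center_row[i]) / b$sigma_rows[i])^2)
    sig[, cols] <- sig[, cols] + prof
  }
  bg <- spec$background
  L <- outer(bg[2] * (rows - 1) / (nr - 1),
             bg[3] * (seq_len(nc) - 1) / (nc - 1), "+") + bg[1] - sig
  if (spec$noise_sd > 0)
    L <- L + .with_seed(spec$seed,
                        matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc))
  maxcode <- 2^spec$bit_depth - 1
  q <- round(pmin(pmax(L, 0), 1) * maxcode) / maxcode
  truth <- data.frame(band_id = seq_len(nrow(b)),
                      lane_id = b$lane_id, kind = b$kind, mw = b$mw,
                      center_row = b$center_row, sigma_rows = b$sigma_rows,
                      mass_ug = b$mass_ug,
                      integrated_signal = b$mass_ug * b$response * maxcode,
                      true_alpha_pct = b$true_alpha_pct,
                      stringsAsFactors = FALSE)
  out_path <- NA_character_
  if (!is.null(path)) {
    if (spec$bit_depth == 16L) tiff::writeTIFF(q, path, bits.per.sample = 16L)
    else png::writePNG(q, path)
    utils::write.csv(truth, paste0(path, "_truth.csv"), row.names = FALSE)
    .write_spec_kv(spec, paste0(path, "_spec.txt"))
    out_path <- path
  }
  list(luminance = q, truth = truth, path = out_path, spec = spec)
}

# Flat key-value serialization of a spec (one `key: value` per line;
# data-frame fields flattened as key[i].column).
.write_spec_kv <- function(spec, path) {
  lines <- c(paste0("n_rows: ", spec$n_rows),
             paste0("n_cols: ", spec$n_cols),
             paste0("front_row: ", spec$front_row),
             paste0("mobility.slope: ", format(spec$mobility$slope, digits = 12)),
             paste0("mobility.intercept: ",
                    format(spec$mobility$intercept, digits = 12)),
             paste0("background: ",
                    paste(format(spec$background, digits = 12), collapse = ",")),
             paste0("noise_sd: ", format(spec$noise_sd, digits = 12)),
             paste0("bit_depth: ", spec$bit_depth),
             paste0("seed: ", spec$seed))
  for (df_name in c("lanes", "bands")) {
    df <- spec[[df_name]]
    for (i in seq_len(nrow(df)))
      for (cn in names(df))
        lines <- c(lines, paste0(df_name, "[", i, "].", cn, ": ",
                                 format(df[[cn]][i], digits = 12)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic twofold serial-dilution calibration gel
#'
#' Lane k carries `top_conc_mg_ml * volume_ul / 2^(k-1)` µg of the
#' calibration protein; a marker lane spanning 14.4-116 kDa is appended,
#' and optionally one unknown sample lane.
#'
#' @param top_conc_mg_ml Concentration of the most concentrated
#'   calibration solution (default 0.2 mg/mL).
#' @param n_levels Number of twofold dilution levels (>= 1; >= 2 for a
#'   usable calibration).
#' @param volume_ul Loaded volume per lane (default 10 µL).
#' @param marker_mws Marker masses in kDa (top to bottom of the range).
#' @param marker_mass_ug Mass per marker band.
#' @param sample_mw Molecular weight of the calibration protein (kDa).
#' @param unknown_mass_ug Optional mass for an extra unknown sample lane.
#' @param sigma_rows Band sharpness (Gaussian sd, rows).
#' @param response Signal per µg (normalized luminance x rows).
#' @param n_rows Gel height in rows.
#' @param noise_sd,bit_depth,seed Passed to [synthetic_gel_spec()].
#' @return A [synthetic_gel_spec].
#' @examples
#' sp <- make_calibration_gel()
#' subset(sp$bands, kind == "band" & !is.na(mass_ug))$mass_ug[1:5]
#' @export
make_calibration_gel <- function(top_conc_mg_ml = 0.2, n_levels = 5L,
                                 volume_ul = 10,
                                 marker_mws = c(116, 85, 66.2, 45, 35, 25,
                                                18.4, 14.4),
                                 marker_mass_ug = 0.5, sample_mw = 68.5,
                                 unknown_mass_ug = NULL,
                                 sigma_rows = 4, response = 2.2,
                                 n_rows = 420L, noise_sd = 0,
                                 bit_depth = 16L, seed = 1L) {
  if (top_conc_mg_ml <= 0 || volume_ul <= 0 || n_levels < 1L)
    stop("top_conc_mg_ml, volume_ul must be positive and n_levels >= 1")
  masses <- top_conc_mg_ml * volume_ul / 2^(seq_len(n_levels) - 1)
  n_lanes <- n_levels + 1L + length(unknown_mass_ug)
  roles <- c(rep("calibration", n_levels), "marker",
             rep("sample", length(unknown_mass_ug)))
  lanes <- .lane_layout(n_lanes, roles = roles)
  bands <- data.frame(lane_id = seq_len(n_levels), mw = sample_mw,
                      center_row = NA_real_, mass_ug = masses,
                      sigma_rows = sigma_rows, response = response,
                      kind = "band", true_alpha_pct = NA_real_)
  marker <- data.frame(lane_id = n_levels + 1L, mw = marker_mws,
                       center_row = NA_real_, mass_ug = marker_mass_ug,
                       sigma_rows = sigma_rows, response = response,
                       kind = "band", true_alpha_pct = NA_real_)
  bands <- rbind(bands, marker)
  if (length(unknown_mass_ug))
    bands <- rbind(bands,
                   data.frame(lane_id = n_levels + 2L, mw = sample_mw,
                              center_row = NA_real_,
                              mass_ug = unknown_mass_ug,
                              sigma_rows = sigma_rows, response = response,
                              kind = "band", true_alpha_pct = NA_real_))
  n_cols <- max(lanes$col_end) + 17L
  synthetic_gel_spec(n_rows = n_rows, n_cols = n_cols, lanes = lanes,
                     bands = bands, noise_sd = noise_sd,
                     bit_depth = bit_depth, seed = seed)
}

#' Synthetic degradation-series gel
#'
#' Lane 1 is the untreated control; lane k+1 retains fraction
#' `retained_fractions[k]` of the native band's mass. With `smear = TRUE`
#' the removed mass is redistributed into a broad diffuse smear of
#' degradation products centred below the native band, conserving each
#' lane's total deposited signal exactly. The ground truth records each
#' treated lane's true degradation degree `alpha = 100 * (1 - f)` on its
#' native band.
#'
#' @param control_mass_ug Native-protein mass in the control lane.
#' @param retained_fractions Fractions of native-band mass retained after
#'   treatment, one per treated lane, each in `[0, 1]`.
#' @param smear Redistribute the lost mass into a diffuse smear?
#' @param protein_mw Native protein molecular weight (kDa).
#' @param sigma_rows Native band sharpness (rows).
#' @param smear_sigma_rows Smear breadth (rows).
#' @param response Signal per µg.
#' @param snr Signal-to-noise ratio: native control-band amplitude divided
#'   by the sensor noise sd. `Inf` for a noiseless gel.
#' @param n_rows,bit_depth,seed Passed to [synthetic_gel_spec()].
#' @return A [synthetic_gel_spec].
#' @export
make_degradation_gel <- function(control_mass_ug = 2,
                                 retained_fractions = c(0.8, 0.5, 0.2, 0.08),
                                 smear = TRUE, protein_mw = 68.5,
                                 sigma_rows = 4, smear_sigma_rows = 45,
                                 response = 2.2, snr = 50,
                                 n_rows = 420L, bit_depth = 16L, seed = 1L) {
  if (control_mass_ug <= 0) stop("control_mass_ug must be positive")
  if (any(retained_fractions < 0) || any(retained_fractions > 1))
    stop("retained_fractions must lie in [0, 1]")
  n_tr <- length(retained_fractions)
  lanes <- .lane_layout(n_tr + 1L, roles = rep("sample", n_tr + 1L))
  amp <- control_mass_ug * response / (sigma_rows * sqrt(2 * pi))
  noise_sd <- if (is.finite(snr)) amp / snr else 0
  bands <- data.frame(lane_id = 1L, mw = protein_mw, center_row = NA_real_,
                      mass_ug = control_mass_ug, sigma_rows = sigma_rows,
                      response = response, kind = "band",
                      true_alpha_pct = 0)
  for (k in seq_len(n_tr)) {
    f <- retained_fractions[k]
    if (f > 0)
      bands <- rbind(bands,
                     data.frame(lane_id = k + 1L, mw = protein_mw,
                                center_row = NA_real_,
                                mass_ug = f * control_mass_ug,
                                sigma_rows = sigma_rows, response = response,
                                kind = "band",
                                true_alpha_pct = 100 * (1 - f)))
    if (smear && f < 1)
      bands <- rbind(bands,
                     data.frame(lane_id = k + 1L, mw = protein_mw / 4,
                                center_row = NA_real_,
                                mass_ug = (1 - f) * control_mass_ug,
                                sigma_rows = smear_sigma_rows,
                                response = response, kind = "smear",
                                true_alpha_pct = 100 * (1 - f)))
  }
  n_cols <- max(lanes$col_end) + 17L
  synthetic_gel_spec(n_rows = n_rows, n_cols = n_cols, lanes = lanes,
                     bands = bands, noise_sd = noise_sd,
                     bit_depth = bit_depth, seed = seed)
}
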