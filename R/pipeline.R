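#' Read a YAML run configuration
#'
#' @param path Path to a YAML run-configuration file.
#' @return The configuration as a named list (validated lazily by
#'   [run_quantify()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config '", path, "' does not exist")
  yaml::read_yaml(path)
}

#' Write a run configuration as YAML
#'
#' @param config Named list as accepted by [run_quantify()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Defaults for every tunable pipeline parameter. Any default actually used
# is echoed into the run log: no silent defaults for quantitative knobs.
.config_defaults <- list(
  orientation = "wells_top",
  inversion_mode = "linear",
  white_reference = NULL,
  flatten = TRUE,
  window_rows = NULL,
  threshold_frac = 0.2,
  baseline_method = "smooth_floor",
  min_height_frac = 0.05,
  min_width_rows = 3L,
  weighting = "inverse_Q2",
  ladder_mode = "piecewise",
  allow_cross_gel = FALSE)

#' Validate a run configuration
#'
#' Fills defaults (recording which were used), and checks the structural
#' rules: every calibration lane declares a loaded mass, every alpha pair
#' references declared lanes, and exactly one marker lane exists when
#' molecular-weight estimation is requested.
#'
#' @param config Named list (e.g. from [read_run_config()]).
#' @param require_image Is an input image mandatory?
#' @return The validated config, with a `defaults_used` character vector
#'   attached.
#' @export
validate_run_config <- function(config, require_image = TRUE) {
  if (!is.list(config)) stop("config must be a named list")
  used <- character()
  for (nm in names(.config_defaults)) {
    if (is.null(config[[nm]])) {
      config[nm] <- list(.config_defaults[[nm]])
      used <- c(used, nm)
    }
  }
  if (require_image) {
    if (is.null(config$image))
      stop("config field 'image' is missing")
    if (!file.exists(config$image))
      stop("config field 'image': file '", config$image, "' does not exist")
  }
  lanes <- config$lanes
  if (!is.null(lanes)) {
    for (ln in lanes) {
      for (f in c("lane_id", "col_start", "col_end"))
        if (is.null(ln[[f]]))
          stop("config field 'lanes': lane entry is missing '", f, "'")
      role <- if (is.null(ln$role)) "sample" else ln$role
      if (identical(role, "calibration") && is.null(ln$mass_ug))
        stop("config field 'lanes': calibration lane ", ln$lane_id,
             " is missing its loaded mass 'mass_ug'")
    }
    ids <- vapply(lanes, function(l) as.integer(l$lane_id), integer(1))
    if (anyDuplicated(ids))
      stop("config field 'lanes': duplicated lane_id")
    roles <- vapply(lanes, function(l)
      if (is.null(l$role)) "sample" else l$role, character(1))
    if (!is.null(config$marker_mws) && sum(roles == "marker") != 1L)
      stop("config field 'marker_mws': exactly one lane with role 'marker' ",
           "is required for MW estimation (found ", sum(roles == "marker"), ")")
  } else if (is.null(config$expected_n) && require_image) {
    stop("config needs either explicit 'lanes' or 'expected_n' for detection")
  }
  if (!is.null(config$alpha_pairs)) {
    known <- if (!is.null(lanes))
      vapply(lanes, function(l) as.integer(l$lane_id), integer(1))
    else seq_len(config$expected_n %||% 0L)
    for (p in config$alpha_pairs) {
      if (is.null(p$control) || is.null(p$treated))
        stop("config field 'alpha_pairs': each pair needs 'control' and 'treated'")
      if (length(known) && !all(c(p$control, p$treated) %in% known))
        stop("config field 'alpha_pairs': pair (", p$control, ", ", p$treated,
             ") references an undeclared lane")
    }
  }
  if (!is.null(config$external_calibration) && !isTRUE(config$allow_cross_gel))
    stop("config field 'external_calibration': calibration from another gel ",
         "is refused by the same-gel policy; set allow_cross_gel: true to ",
         "override")
  if (!is.null(config$marker_mws) && is.null(config$front_row))
    stop("config field 'front_row' is required for MW estimation")
  attr(config, "defaults_used") <- used
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.lanes_from_config <- function(lanes) {
  df <- do.call(rbind, lapply(lanes, function(l)
    data.frame(lane_id = as.integer(l$lane_id),
               col_start = as.integer(l$col_start),
               col_end = as.integer(l$col_end),
               role = l$role %||% "sample",
               mass_ug = as.numeric(l$mass_ug %||% NA_real_),
               stringsAsFactors = FALSE)))
  .as_lane_regions(df[order(df$lane_id), ])
}

#' Run the full quantification pipeline
#'
#' Image -> background flattening -> lanes -> densitograms -> baseline
#' correction -> peaks -> calibration -> protein content, molecular
#' weights and degradation degrees, with CSV reports and a parameter log.
#'
#' @param config A run-config list or the path of a YAML config file. See
#'   the package vignette for the accepted fields.
#' @param output_dir Report directory; overrides `config$output_dir`. With
#'   neither set, no files are written and results are only returned.
#' @param steps Which result sections to compute: any of `"quantify"`
#'   (calibrated protein content), `"mw"`, `"alpha"`. Lane extraction and
#'   peak integration always run.
#' @return Invisibly, a list with `image`, `lanes`, `profiles`, `peaks`,
#'   `calibration`, `ladder`, `report` (quantification data frame),
#'   `alpha`, and `files` (paths written).
#' @export
run_quantify <- function(config, output_dir = NULL,
                         steps = c("quantify", "mw", "alpha")) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  steps <- match.arg(steps, several.ok = TRUE)
  img <- load_gel_image(config$image,
                        white_reference = config$white_reference,
                        mode = config$inversion_mode,
                        orientation = config$orientation)
  if (isTRUE(config$flatten))
    img <- flatten_background(img, window_rows = config$window_rows)
  lanes <- if (!is.null(config$lanes)) .lanes_from_config(config$lanes)
           else detect_lanes(img, expected_n = config$expected_n,
                             threshold_frac = config$threshold_frac)
  profiles <- lapply(seq_len(nrow(lanes)), function(i) {
    d <- lane_profile(img, lanes[i, ])
    subtract_baseline(d, method = config$baseline_method)
  })
  names(profiles) <- lanes$lane_id
  pk_list <- lapply(profiles, detect_peaks,
                    min_height_frac = config$min_height_frac,
                    min_width_rows = config$min_width_rows)
  # manual regions for diffuse bands
  if (!is.null(config$regions)) {
    for (rg in config$regions) {
      li <- as.character(rg$lane_id)
      if (is.null(profiles[[li]]))
        stop("config field 'regions': undeclared lane ", rg$lane_id)
      pk_list[[li]] <- peak_table(
        rbind(as.data.frame(pk_list[[li]]),
              as.data.frame(integrate_region(profiles[[li]],
                                             rg$start_row, rg$end_row))),
        profile_length = length(profiles[[li]]$values))
    }
  }
  peaks <- peak_table(do.call(rbind, lapply(pk_list, as.data.frame)),
                      profile_length = img$n_rows)

  # calibration (same-gel by default; external only with the override flag)
  model <- NULL
  if ("quantify" %in% steps) {
    if (!is.null(config$external_calibration)) {
      ec <- config$external_calibration
      model <- calibration_model(ec$a, ec$b)
    } else if (any(lanes$role == "calibration")) {
      cal <- lanes[lanes$role == "calibration", ]
      pts <- do.call(rbind, lapply(seq_len(nrow(cal)), function(i) {
        pt <- pk_list[[as.character(cal$lane_id[i])]]
        if (!nrow(pt)) stop("no peak found in calibration lane ",
                            cal$lane_id[i])
        data.frame(S = max(pt$area), Q = cal$mass_ug[i])
      }))
      model <- fit_calibration(pts, weighting = config$weighting)
    }
  }

  # ladder
  ladder <- NULL
  if ("mw" %in% steps && !is.null(config$marker_mws) &&
        any(lanes$role == "marker")) {
    mk <- lanes$lane_id[lanes$role == "marker"][1L]
    mpk <- pk_list[[as.character(mk)]]
    if (nrow(mpk) != length(config$marker_mws))
      stop("marker lane ", mk, ": detected ", nrow(mpk),
           " bands but ", length(config$marker_mws), " masses declared")
    ladder <- fit_ladder(mpk, config$marker_mws, config$front_row,
                         mode = config$ladder_mode)
  }

  report <- as.data.frame(peaks)
  report$role <- lanes$role[match(report$lane_id, lanes$lane_id)]
  report$predicted_Q_ug <- if (!is.null(model))
    predict_content(model, report$area) else NA_real_
  if (!is.null(ladder)) {
    mw <- estimate_mw(ladder, report$apex_row, config$front_row)
    report$estimated_mw_kDa <- as.numeric(mw)
    report$extrapolated <- attr(mw, "extrapolated")
  } else {
    report$estimated_mw_kDa <- NA_real_
    report$extrapolated <- NA
  }
  report$alpha_pct <- NA_real_

  alpha <- NULL
  if ("alpha" %in% steps && !is.null(config$alpha_pairs)) {
    alpha <- do.call(rbind, lapply(config$alpha_pairs, function(p) {
      cid <- as.character(p$control); tid <- as.character(p$treated)
      cpk <- pk_list[[cid]]
      if (!nrow(cpk)) stop("no native-protein peak in control lane ", cid)
      native <- cpk[which.max(cpk$area), ]
      St_pk <- integrate_region(profiles[[tid]], native$start_row,
                                native$end_row)
      dd <- degradation_degree(native$area, St_pk$area)
      data.frame(control_lane = as.integer(p$control),
                 treated_lane = as.integer(p$treated),
                 start_row = native$start_row, end_row = native$end_row,
                 S0 = dd$S0, St = dd$St, alpha_pct = dd$alpha_pct)
    }))
    for (i in seq_len(nrow(alpha))) {
      hit <- report$lane_id == alpha$treated_lane[i] &
        report$start_row < alpha$end_row[i] &
        report$end_row > alpha$start_row[i]
      report$alpha_pct[hit] <- alpha$alpha_pct[i]
    }
  }

  files <- character()
  out <- output_dir %||% config$output_dir
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    dens <- do.call(rbind, lapply(profiles, function(d)
      data.frame(lane_id = d$lane_id, row = seq_along(d$values),
                 value = d$values)))
    files <- c(
      densitograms = .write_report(dens, file.path(out, "densitograms.csv")),
      peaks = write_peak_table(peaks, file.path(out, "peaks.csv")),
      quantification = .write_report(report,
                                     file.path(out, "quantification.csv")))
    if (!is.null(model) && !is.null(model$points)) {
      caldf <- model$points
      caldf$fitted <- model$fitted
      caldf$residual <- model$residuals
      caldf$a <- model$a; caldf$b <- model$b
      caldf$weighting <- model$weighting
      caldf$relative_deviation_pct <- model$relative_deviation_pct
      files["calibration"] <- .write_report(caldf,
                                            file.path(out, "calibration.csv"))
    }
    if (!is.null(alpha))
      files["alpha"] <- .write_report(alpha, file.path(out, "alpha.csv"))
    files["log"] <- .write_run_log(config, file.path(out, "run_log.txt"))
  }
  invisible(list(image = img, lanes = lanes, profiles = profiles,
                 peaks = peaks, calibration = model, ladder = ladder,
                 report = report, alpha = alpha, files = files))
}

.write_report <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.write_run_log <- function(config, path) {
  used <- attr(config, "defaults_used") %||% character()
  flat <- function(x, prefix = "") {
    out <- character()
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- paste0(prefix, nm)
      if (is.list(v)) out <- c(out, flat(v, paste0(key, ".")))
      else out <- c(out, paste0(key, " = ",
                                paste(format(v), collapse = ", "),
                                if (nm %in% used) "   [default]" else ""))
    }
    out
  }
  writeLines(c(paste0("# gelquant ", utils::packageVersion("gelquant"),
                      " run log"),
               paste0("# ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
               flat(config)), path)
  path
}

#' Render a synthetic gel from a simulation config
#'
#' Delegates to the synthetic-gel generator. The config (a list or YAML
#' path) selects `preset: calibration` ([make_calibration_gel()]) or
#' `preset: degradation` ([make_degradation_gel()]); any further fields
#' are passed to the preset as arguments.
#'
#' @param config List or YAML path with a `preset` field plus preset
#'   arguments.
#' @param path Image output path (`.tif` 16-bit / `.png` 8-bit); ground
#'   truth and spec are written alongside.
#' @return The [render_gel()] result, invisibly.
#' @export
run_simulate <- function(config, path) {
  if (is.character(config)) config <- read_run_config(config)
  preset <- config$preset
  if (is.null(preset) ||
        !preset %in% c("calibration", "degradation"))
    stop("simulation config needs preset: 'calibration' or 'degradation'")
  args <- config[setdiff(names(config), "preset")]
  spec <- switch(preset,
                 calibration = do.call(make_calibration_gel, args),
                 degradation = do.call(make_degradation_gel, args))
  invisible(render_gel(spec, path = path))
}
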