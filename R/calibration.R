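#' Fit the quadratic-through-origin mass-vs-area calibration
#'
#' Fits `Q = a*S^2 + b*S` (no intercept) by weighted least squares, where
#' `Q` is the loaded protein mass in micrograms and `S` the integrated
#' band peak area in arbitrary units, using serial-dilution lanes run on
#' the same gel as the unknowns. The curve passes through the origin by
#' construction: zero area is zero protein.
#'
#' The default weighting, `"inverse_Q2"`, minimises relative rather than
#' absolute residuals. A twofold serial dilution spans a 16-fold mass
#' range, and with unit weights the top lane dominates the fit; inverse-Q²
#' weights give every dilution level equal say in relative terms.
#'
#' The model's `relative_deviation_pct` summarises calibration quality as
#' the mean (or maximum) absolute relative residual in percent.
#'
#' @param points Data frame (or list coercible to one) with columns `S`
#'   (area, >= 0) and `Q` (mass in µg, > 0); at least 3 points with
#'   distinct `S`.
#' @param weighting `"inverse_Q2"` (default), `"inverse_Q"`, or `"none"`.
#' @param deviation `"mean"` (default) or `"max"` — the summary used for
#'   `relative_deviation_pct`.
#' @return An object of class `gel_calibration` with elements `a`, `b`,
#'   `weighting`, `relative_deviation_pct`, `points`, `fitted`,
#'   `residuals`.
#' @seealso [predict_content()], [invert_calibration()],
#'   [calibration_model()] for a model with externally given
#'   coefficients.
#' @examples
#' pts <- data.frame(S = c(200, 500, 900, 1300),
#'                   Q = 2e-6 * c(200, 500, 900, 1300)^2 +
#'                       3e-4 * c(200, 500, 900, 1300))
#' fit <- fit_calibration(pts)
#' coef(fit)
#' @export
fit_calibration <- function(points,
                            weighting = c("inverse_Q2", "inverse_Q", "none"),
                            deviation = c("mean", "max")) {
  weighting <- match.arg(weighting)
  deviation <- match.arg(deviation)
  points <- as.data.frame(points)
  if (!all(c("S", "Q") %in% names(points)))
    stop("calibration points need columns 'S' and 'Q'")
  S <- as.numeric(points$S); Q <- as.numeric(points$Q)
  if (any(!is.finite(S)) || any(!is.finite(Q)) || any(S < 0) || any(Q <= 0))
    stop("calibration points require S >= 0 and Q > 0")
  if (length(unique(S)) < 3L)
    stop("calibration fit needs at least 3 points with distinct areas")
  w <- switch(weighting, none = rep(1, length(S)),
              inverse_Q = 1 / Q, inverse_Q2 = 1 / Q^2)
  sw <- sqrt(w)
  X <- cbind(S2 = S^2, S1 = S)
  beta <- tryCatch(qr.solve(X * sw, Q * sw),
                   error = function(e) stop("degenerate calibration system: ",
                                            conditionMessage(e), call. = FALSE))
  a <- unname(beta[1L]); b <- unname(beta[2L])
  fitted <- a * S^2 + b * S
  rel <- abs(fitted - Q) / Q * 100
  structure(list(a = a, b = b, weighting = weighting, deviation = deviation,
                 relative_deviation_pct = if (deviation == "mean") mean(rel)
                                          else max(rel),
                 points = data.frame(S = S, Q = Q, weight = w),
                 fitted = fitted, residuals = Q - fitted),
            class = "gel_calibration")
}

#' Calibration model from given coefficients
#'
#' Builds a `gel_calibration` directly from known coefficients `a` and
#' `b` of `Q = a*S^2 + b*S`, e.g. a previously reported calibration
#' equation, for forward evaluation with [predict_content()].
#'
#' @param a Quadratic coefficient (µg per squared area unit).
#' @param b Linear coefficient (µg per area unit).
#' @return A `gel_calibration` object without fit diagnostics.
#' @export
calibration_model <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  structure(list(a = a, b = b, weighting = "given", deviation = NA_character_,
                 relative_deviation_pct = NA_real_,
                 points = NULL, fitted = NULL, residuals = NULL),
            class = "gel_calibration")
}

#' @export
print.gel_calibration <- function(x, ...) {
  cat("Quadratic-through-origin calibration  Q = a*S^2 + b*S\n")
  cat(sprintf("  a = %.6g ug/area^2,  b = %.6g ug/area  (weighting: %s)\n",
              x$a, x$b, x$weighting))
  if (!is.na(x$relative_deviation_pct))
    cat(sprintf("  relative deviation (%s): %.2f%%  on %d points\n",
                x$deviation, x$relative_deviation_pct, nrow(x$points)))
  invisible(x)
}

#' @export
coef.gel_calibration <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
residuals.gel_calibration <- function(object, ...) object$residuals

#' @export
predict.gel_calibration <- function(object, S, ...) {
  predict_content(object, S)
}

#' @export
summary.gel_calibration <- function(object, ...) {
  print(object)
  if (!is.null(object$points)) {
    df <- object$points
    df$fitted <- object$fitted
    df$residual <- object$residuals
    df$rel_residual_pct <- abs(df$residual) / df$Q * 100
    cat("\nPer-point residuals:\n")
    print(df, row.names = FALSE, digits = 5)
  }
  invisible(object)
}

#' @export
plot.gel_calibration <- function(x, ...) {
  if (is.null(x$points)) {
    smax <- invert_calibration(x, 2)
  } else smax <- max(x$points$S)
  s <- seq(0, smax * 1.05, length.out = 200)
  graphics::plot(s, x$a * s^2 + x$b * s, type = "l",
                 xlab = "peak area S (arb. units)",
                 ylab = "protein mass Q (ug)",
                 main = "Calibration: mass vs peak area", ...)
  if (!is.null(x$points))
    graphics::points(x$points$S, x$points$Q, pch = 19)
  invisible(x)
}

#' Predict protein content from a peak area
#'
#' Evaluates the calibration polynomial `Q = a*S^2 + b*S` at area `S`.
#'
#' @param model A `gel_calibration`.
#' @param S Peak area(s), >= 0.
#' @return Protein mass(es) in µg.
#' @export
predict_content <- function(model, S) {
  stopifnot(inherits(model, "gel_calibration"))
  if (any(!is.finite(S)) || any(S < 0))
    stop("peak area S must be finite and non-negative")
  model$a * S^2 + model$b * S
}

#' Invert the calibration: area corresponding to a given mass
#'
#' Solves `a*S^2 + b*S - Q = 0` for its unique non-negative root — reading
#' a mass back onto the calibration plot's abscissa.
#'
#' @param model A `gel_calibration` with `a >= 0`, `b >= 0`, not both 0.
#' @param Q Protein mass in µg, >= 0.
#' @return The non-negative peak area.
#' @export
invert_calibration <- function(model, Q) {
  stopifnot(inherits(model, "gel_calibration"))
  if (any(!is.finite(Q)) || any(Q < 0)) stop("Q must be finite and >= 0")
  a <- model$a; b <- model$b
  if (a < 0 || b < 0 || (a == 0 && b == 0))
    stop("inversion requires a >= 0, b >= 0 and not both zero")
  if (a == 0) return(Q / b)
  (-b + sqrt(b^2 + 4 * a * Q)) / (2 * a)
}
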