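#' Degradation degree of a protein after treatment
#'
#' The degradation degree is the fractional loss of the native-protein
#' band's peak area, in percent:
#' `alpha = (S0 - St) / S0 * 100`,
#' where `S0` is the native band's area before treatment and `St` its area
#' after treatment of duration t. Because alpha is a ratio of areas it is
#' unit-free: any common scaling of `S0` and `St` cancels.
#'
#' `St > S0` (apparent gain, e.g. integration or loading artefacts) yields
#' a negative alpha with a warning rather than an error.
#'
#' @param S0 Native-band peak area before treatment (> 0).
#' @param St Native-band peak area after treatment (>= 0).
#' @return An object of class `degradation_result` with elements `S0`,
#'   `St`, `alpha_pct`.
#' @examples
#' degradation_degree(1288, 103.04)  # 92% degraded
#' @export
degradation_degree <- function(S0, St) {
  if (!is.finite(S0) || S0 <= 0)
    stop("S0 must be a positive finite area")
  if (!is.finite(St) || St < 0)
    stop("St must be a non-negative finite area")
  if (St > S0)
    warning("St > S0: apparent gain in native-band area; alpha is negative")
  structure(list(S0 = S0, St = St,
                 alpha_pct = (S0 - St) / S0 * 100),
            class = "degradation_result")
}

#' @export
print.degradation_result <- function(x, ...) {
  cat(sprintf("Degradation degree: alpha = %.1f%%  (S0 = %.4g, St = %.4g)\n",
              x$alpha_pct, x$S0, x$St))
  invisible(x)
}
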