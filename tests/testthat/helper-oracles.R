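# Independent oracles and small fixture builders, kept deliberately
# separate from the implementation paths they check.

# Dense Riemann-sum integral of a function over [s, e] (midpoint rule).
riemann_integral <- function(fun, s, e, n = 2e5) {
  x <- seq(s, e, length.out = n + 1)
  mid <- (x[-1] + x[-length(x)]) / 2
  sum(fun(mid)) * (e - s) / n
}

# Closed-form area of a Gaussian peak of amplitude A and sd sigma.
gauss_area <- function(A, sigma) A * sigma * sqrt(2 * pi)

# Explicit normal-equations solve of Q ~ a S^2 + b S with weights w,
# written independently of the package's QR-based solver.
calib_normal_equations <- function(S, Q, w = rep(1, length(S))) {
  X <- cbind(S^2, S)
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% Q)
  c(a = beta[1], b = beta[2])
}

# A densitogram holding given values, marked baseline-subtracted.
flat_densitogram <- function(values, lane_id = 1L) {
  densitogram(values, lane_id = lane_id, baseline_subtracted = TRUE)
}

# Gaussian profile sampled on rows 1..n.
gauss_profile <- function(n, center, sigma, A) {
  A * exp(-0.5 * ((seq_len(n) - center) / sigma)^2)
}

# Write a gel_image-like luminance matrix to a temp PNG and return its path.
write_temp_png <- function(lum) {
  f <- tempfile(fileext = ".png")
  png::writePNG(lum, f)
  f
}
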