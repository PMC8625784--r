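# Internal numerical helpers shared across modules.

# Moving average with edge-truncated (partial) windows; exact for constants,
# and exact for straight lines in the interior.
.smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L || length(x) < 2L) return(x)
  n <- length(x)
  h <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Rolling low-quantile background track along one column.
#
# A centre-registered moving quantile of a trending background is biased
# by (q - 0.5)*window*slope. Here each window contributes a knot at the
# ACTUAL ROW of its q-th order statistic, with that row's value: on any
# monotone background the knot lies exactly on the background curve, and
# band rows (high order statistics) are never selected, so bands do not
# inflate the estimate. Knots are interpolated linearly, with linear
# extension of the end segments beyond the first/last knot.
.rolling_low_quantile <- function(x, window, prob) {
  keep <- .band_free_rows(x, window)
  if (is.null(keep)) return(.rlq_pass(x, window, prob))
  .rlq_pass(x, window, prob, keep = keep)
}

# Rows that belong to the background rather than a band, judged against a
# rolling-minimum floor (whose knots a band cannot contaminate, being high
# order statistics). Without this mask, a window whose low-value end
# coincides with a band flank absorbs the flank into its low quantile.
.band_free_rows <- function(x, window) {
  floor1 <- .rlq_pass(x, window, 0)
  dev <- x - floor1
  dev <- dev - stats::median(dev)
  sc <- stats::mad(dev)
  keep <- dev <= 3.5 * sc + 1e-9 * max(abs(x), 1)
  if (mean(keep) < 0.5) NULL else keep
}

.rlq_pass <- function(x, window, prob, keep = NULL) {
  n <- length(x)
  h <- max(1L, window %/% 2L)
  step <- max(1L, h %/% 5L)
  centers <- sort(unique(c(seq(1L, n, by = step), n)))
  lo <- pmax(1L, centers - h)
  hi <- pmin(n, centers + h)
  pos <- numeric(0)
  qv <- numeric(0)
  for (i in seq_along(centers)) {
    idx <- lo[i]:hi[i]
    if (!is.null(keep)) idx <- idx[keep[idx]]
    if (length(idx) < 3L) next
    k <- max(1L, round(prob * length(idx)))
    ord <- order(x[idx])[k]
    pos <- c(pos, idx[ord])
    qv <- c(qv, x[idx[ord]])
  }
  if (!length(pos)) return(rep(min(x), n))
  o <- order(pos, qv)
  pos <- pos[o]; qv <- qv[o]
  keep <- !duplicated(pos)
  pos <- pos[keep]; qv <- qv[keep]
  if (length(pos) < 2L) return(rep(qv[1L], n))
  bg <- stats::approx(pos, qv, xout = seq_len(n), rule = 2)$y
  s1 <- (qv[2L] - qv[1L]) / (pos[2L] - pos[1L])
  m <- length(pos)
  s2 <- (qv[m] - qv[m - 1L]) / (pos[m] - pos[m - 1L])
  left <- which(seq_len(n) < pos[1L])
  if (length(left)) bg[left] <- qv[1L] + s1 * (left - pos[1L])
  right <- which(seq_len(n) > pos[m])
  if (length(right)) bg[right] <- qv[m] + s2 * (right - pos[m])
  bg
}

# Trapezoidal integral of the piecewise-linear interpolant of v over the
# continuous row interval [s, e], s and e integer sample indices.
.trapz_samples <- function(v, s, e) {
  if (e <= s) return(0)
  idx <- s:(e - 1L)
  sum((v[idx] + v[idx + 1L]) / 2)
}

# Evaluate code with a temporary RNG state seeded by `seed`.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Local maxima of a vector; plateaus report their earliest row. Endpoints
# qualify when the single neighbouring run is lower.
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 2L) return(integer())
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer()
  for (i in seq_len(k)) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == k || r$values[i + 1L] < r$values[i]
    if (left_ok && right_ok && k > 1L) out <- c(out, starts[i])
  }
  out
}

# Topographic prominence of each peak index: height above the higher of the
# two minima separating it from the nearest higher ground on either side.
.prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    hp <- v[p]
    lmin <- hp
    i <- p
    while (i > 1L) {
      i <- i - 1L
      if (v[i] > hp) break
      if (v[i] < lmin) lmin <- v[i]
    }
    if (i == 1L && v[1L] <= hp && v[1L] < lmin) lmin <- v[1L]
    rmin <- hp
    i <- p
    n <- length(v)
    while (i < n) {
      i <- i + 1L
      if (v[i] > hp) break
      if (v[i] < rmin) rmin <- v[i]
    }
    if (i == n && v[n] <= hp && v[n] < rmin) rmin <- v[n]
    hp - max(lmin, rmin)
  }, numeric(1))
}
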