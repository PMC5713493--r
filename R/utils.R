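# Internal helpers shared across modules.

#' @keywords internal
clamp1 <- function(x) pmin(1, pmax(-1, x))

#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to (-pi, pi]
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Remove 2*pi discontinuities from an angle series
#' @keywords internal
unwrap_angle <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  jumps <- round(d / (2 * pi))
  x - c(0, cumsum(jumps)) * 2 * pi
}

#' Evaluate code with a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Centered linear convolution with reflected edge padding
#'
#' Returns a series aligned with `x`: for a filter whose mass is centred, a
#' feature at sample k of `x` stays at sample k of the output.
#' @keywords internal
conv_centered <- function(x, f) {
  n <- length(x)
  lf <- length(f)
  pad <- lf
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1):n]))
  yfull <- stats::convolve(xp, rev(f), type = "open")
  c0 <- pad + floor((lf - 1) / 2)
  yfull[(c0 + 1):(c0 + n)]
}

#' Centered moving average (odd width)
#' @keywords internal
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  conv_centered(x, rep(1 / width, width))
}

#' Cumulative trapezoidal integral of each column of `y` over `t`
#' @keywords internal
cumtrapz_cols <- function(t, y) {
  y <- as.matrix(y)
  dt <- diff(t)
  inc <- (y[-1, , drop = FALSE] + y[-nrow(y), , drop = FALSE]) / 2 * dt
  out <- rbind(0, apply(inc, 2, cumsum))
  dimnames(out) <- NULL
  out
}

#' Row-wise Euclidean norm of a 3-column matrix
#' @keywords internal
row_norm <- function(m) sqrt(rowSums(as.matrix(m)^2))

#' Nearest-sample index of time `time` in sample grid `t`
#' @keywords internal
nearest_index <- function(t, time) {
  idx <- findInterval(time, t, all.inside = TRUE)
  idx_hi <- pmin(idx + 1L, length(t))
  ifelse(abs(t[idx_hi] - time) < abs(t[idx] - time), idx_hi, idx)
}

#' Logical run-length morphological closing (fill FALSE gaps <= gap_max)
#' @keywords internal
mask_close <- function(mask, gap_max) {
  if (gap_max <= 0 || !any(mask)) return(mask)
  r <- rle(mask)
  n <- length(r$values)
  for (i in seq_len(n)) {
    if (!r$values[i] && r$lengths[i] <= gap_max && i > 1 && i < n) {
      r$values[i] <- TRUE
    }
  }
  inverse.rle(r)
}

#' Logical run-length morphological opening (drop TRUE runs < min_len)
#' @keywords internal
mask_open <- function(mask, min_len) {
  if (min_len <= 1 || !any(mask)) return(mask)
  r <- rle(mask)
  r$values[r$values & r$lengths < min_len] <- FALSE
  inverse.rle(r)
}

#' Half-open [start, end) sample intervals of TRUE runs in a logical mask
#' @keywords internal
mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

#' @keywords internal
intervals_to_mask <- function(intervals, n) {
  mask <- logical(n)
  for (i in seq_len(nrow(intervals))) {
    mask[intervals[i, 1]:(intervals[i, 2] - 1L)] <- TRUE
  }
  mask
}

#' Evaluate a polynomial (coefficients in increasing degree) and derivatives
#' @keywords internal
polyval_inc <- function(coef, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coef))) y <- y * x + coef[k]
  y
}

#' @keywords internal
polyderiv_inc <- function(coef) {
  if (length(coef) <= 1) return(0)
  coef[-1] * seq_len(length(coef) - 1)
}
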