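# Minimal IIR toolbox: Butterworth low/high-pass design (bilinear transform),
# an RBJ-cookbook biquad notch, and forward-backward (zero-phase) application.
# Orders used in this package never exceed 4, so direct polynomial transfer
# functions are numerically safe.

# polynomial coefficients (descending powers) from roots, real part taken
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

#' Digital Butterworth coefficients
#'
#' @param n filter order.
#' @param w cutoff as a fraction of the Nyquist frequency (0 < w < 1).
#' @param type `"low"` or `"high"`.
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1).
#' @keywords internal
#' @noRd
butter_design <- function(n, w, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, w > 0, w < 1)
  wa <- tan(pi * w / 2)                       # prewarped analog cutoff (T = 2)
  k <- seq_len(n)
  pa <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit-circle LHP prototype
  p <- if (type == "low") wa * pa else wa / pa
  pz <- (1 + p) / (1 - p)                     # bilinear transform
  a <- poly_from_roots(pz)
  zz <- if (type == "low") rep(-1, n) else rep(1, n)
  b <- poly_from_roots(zz)
  # unity gain at DC (low-pass) / Nyquist (high-pass)
  g <- if (type == "low") sum(a) / sum(b)
  else sum(a * (-1)^(seq_along(a) - 1)) / sum(b * (-1)^(seq_along(b) - 1))
  list(b = b * g, a = a)
}

# RBJ biquad notch at f0 Hz, quality q, sampling rate fs
notch_design <- function(f0, q, fs) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  list(
    b = c(1, -2 * cos(w0), 1) / a0,
    a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0)
  )
}

# direct-form IIR via stats::filter (MA convolution then AR recursion)
iir_filter <- function(b, a, x) {
  v <- stats::filter(c(rep(0, length(b) - 1), x), b,
                     method = "convolution", sides = 1)
  v <- v[-seq_len(length(b) - 1)]
  if (length(a) > 1) v <- stats::filter(v, -a[-1], method = "recursive")
  as.numeric(v)
}

# zero-phase filtering: odd-reflection padding, forward and reverse passes
filtfilt_zp <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (n < 2) return(x)
  if (is.null(pad)) pad <- min(n - 1, 1000L)
  front <- 2 * x[1] - x[seq(pad + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(front, x, back)
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[seq(pad + 1, pad + n)]
}

# single-pass variant (phase not compensated), same padding for transients
filt_forward <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (n < 2) return(x)
  if (is.null(pad)) pad <- min(n - 1, 1000L)
  front <- 2 * x[1] - x[seq(pad + 1, 2)]
  xp <- c(front, x)
  y <- iir_filter(b, a, xp)
  y[seq(pad + 1, pad + n)]
}

# centred moving average over an odd window, edges padded by replication
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  h <- (width - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[
    seq(h + 1L, h + length(x))]
}
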