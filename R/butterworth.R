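#' Butterworth filter design as second-order sections
#'
#' Designs a digital Butterworth low-pass or band-pass filter by the
#' standard analog-prototype route: prototype poles on the unit circle,
#' frequency prewarping, low-pass/band-pass transformation, and the
#' bilinear transform. The result is returned as a cascade of biquad
#' sections rather than a single transfer function, which keeps the
#' order-10 low-pass at 0.01 Hz numerically sane.
#'
#' For `type = "low"` the `order` is the filter order (number of poles).
#' For `type = "band"` the `order` is the total order; the underlying
#' low-pass prototype has `order/2` poles, matching the usual convention
#' in which an "8th-order band-pass" has an order-4 prototype and the
#' magnitude response `1 / sqrt(1 + ((f^2 - f0^2) / (f * bw))^(2 * order/2))`.
#'
#' @param order filter order (even).
#' @param cutoff cutoff frequency in Hz (low-pass) or length-2 band edges
#'   in Hz (band-pass).
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"band"`.
#' @return numeric matrix with one row per biquad and columns
#'   `b0, b1, b2, a1, a2` (`a0 = 1`).
#' @examples
#' sos <- butter_sos(4, 1, fs = 100, type = "low")
#' @export
butter_sos <- function(order, cutoff, fs, type = c("low", "band")) {
  type <- match.arg(type)
  if (order < 2 || order %% 2 != 0)
    stop("`order` must be a positive even integer")
  if (fs <= 0) stop("`fs` must be positive")

  if (type == "low") {
    if (length(cutoff) != 1 || cutoff <= 0 || cutoff >= fs / 2)
      stop("low-pass `cutoff` must be a single frequency in (0, fs/2)")
    n <- order
    k <- seq_len(n)
    proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left half-plane
    wc <- 2 * fs * tan(pi * cutoff / fs)               # prewarped rad/s
    s_poles <- proto * wc
    z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
    pos <- z_poles[Im(z_poles) > 0]
    sos <- t(vapply(pos, function(p) {
      a1 <- -2 * Re(p)
      a2 <- Mod(p)^2
      g <- (1 + a1 + a2) / 4                            # unit DC gain
      c(g, 2 * g, g, a1, a2)
    }, numeric(5)))
  } else {
    if (length(cutoff) != 2 || any(cutoff <= 0) || cutoff[1] >= cutoff[2] ||
        cutoff[2] >= fs / 2)
      stop("band-pass `cutoff` must be increasing band edges in (0, fs/2)")
    m <- order / 2                                      # prototype order
    k <- seq_len(m)
    proto <- exp(1i * pi * (2 * k + m - 1) / (2 * m))
    w1 <- 2 * fs * tan(pi * cutoff[1] / fs)
    w2 <- 2 * fs * tan(pi * cutoff[2] / fs)
    w0 <- sqrt(w1 * w2)
    bw <- w2 - w1
    # low-pass -> band-pass: each prototype pole p maps to the two roots of
    # s^2 - (p * bw) s + w0^2 = 0
    s_poles <- unlist(lapply(proto, function(p) {
      disc <- sqrt(as.complex((p * bw)^2 - 4 * w0^2))
      c((p * bw + disc) / 2, (p * bw - disc) / 2)
    }))
    z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
    pos <- z_poles[Im(z_poles) > 0]
    if (length(pos) != m)
      stop("internal error: band-pass pole pairing failed")
    # digital frequency of the (warped) analog centre
    z0 <- exp(1i * 2 * atan(w0 / (2 * fs)))
    sos <- t(vapply(pos, function(p) {
      a1 <- -2 * Re(p)
      a2 <- Mod(p)^2
      # zeros at z = 1 and z = -1; normalise to unit gain at the centre
      h0 <- (1 - z0^2) / (1 + a1 * z0 + a2 * z0^2)
      g <- 1 / Mod(h0)
      c(g, 0, -g, a1, a2)
    }, numeric(5)))
  }
  colnames(sos) <- c("b0", "b1", "b2", "a1", "a2")
  sos
}

#' Zero-phase filtering through a second-order-section cascade
#'
#' Applies the cascade forward and backward (MATLAB/scipy `filtfilt`
#' style), so the effective magnitude response is squared and the phase
#' response is zero - cycle landmarks are not shifted in time. Start-up
#' transients are handled two ways: each biquad is initialised at the
#' steady state of a step with the first sample's value (constants pass
#' exactly), and the signal is extended by odd reflection over `padlen`
#' samples at each end before filtering.
#'
#' @param x numeric signal.
#' @param sos section matrix from [butter_sos()].
#' @param padlen reflection padding length in samples; default
#'   `min(length(x) - 1, 3 * fs_like)` where `fs_like = 100` is a neutral
#'   choice - pass an explicit value for very short signals.
#' @return filtered signal, same length as `x`.
#' @export
sosfiltfilt <- function(x, sos, padlen = NULL) {
  n <- length(x)
  if (n < 4) stop("signal too short to filter (need at least 4 samples)")
  padlen <- padlen %||% min(n - 1, 300L)
  padlen <- min(padlen, n - 1)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    xe <- c(pre, x, post)
  } else {
    xe <- x
  }
  y <- sosfilt_cpp(xe, sos)
  y <- rev(sosfilt_cpp(rev(y), sos))
  y[seq(padlen + 1, padlen + n)]
}
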