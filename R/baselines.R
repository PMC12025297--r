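#' Temporal low-pass baseline filter
#'
#' Zero-phase Butterworth low-pass applied along time to each channel
#' independently (forward-backward filtering, so no group delay biases the
#' comparison). The cutoff is given in breaths per minute, the clinical
#' convention for respiratory band edges: `cutoff_bpm = 60` is 1 Hz.
#'
#' @param v an [voltage_matrix()] recording.
#' @param order Butterworth order (default 3).
#' @param cutoff_bpm cutoff frequency in cycles per minute (default 60); the
#'   equivalent in Hz must be below the Nyquist rate `frame_rate / 2`.
#' @return Filtered `eit_voltage`.
#' @export
lowpass_filter <- function(v, order = 3L, cutoff_bpm = 60) {
  stopifnot_voltage(v)
  if (order < 1L) stop("`order` must be >= 1")
  f_hz <- cutoff_bpm / 60
  nyq <- v$frame_rate / 2
  if (f_hz <= 0 || f_hz >= nyq)
    stop(sprintf("cutoff %.3g Hz must lie in (0, Nyquist = %.3g Hz)", f_hz, nyq))
  bf <- signal::butter(order, f_hz / nyq, type = "low")
  # normalize to exactly unit DC gain (butter()'s coefficients are only
  # accurate to ~1e-6 there, which would bias every channel's baseline)
  bf$b <- bf$b * (sum(bf$a) / sum(bf$b))
  n <- ncol(v$data)
  # odd-reflection padding long enough for the filter's slowest pole to decay
  # below 1e-12, so the forward-backward pass carries no start-up transient
  p_max <- max(abs(polyroot(rev(bf$a))))
  pad <- min(n - 1L, max(3L * order, ceiling(log(1e-12) / log(p_max))))
  out <- t(apply(v$data, 1L, function(ch) {
    left <- 2 * ch[1L] - ch[(pad + 1L):2L]
    right <- 2 * ch[n] - ch[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(left, ch, right))
    y[pad + seq_len(n)]
  }))
  voltage_matrix(out, v$frame_rate, v$n_electrodes, v$protocol_id)
}

#' Temporal median baseline filter
#'
#' Running median along time, per channel, with reflected edges. A median
#' window suppresses isolated spikes narrower than half the window but passes
#' wider spike blocks through (windows fully inside a wide contaminated block
#' see only contaminated samples), which is the failure mode that motivates
#' the low-rank/sparse decomposition.
#'
#' @param v an [voltage_matrix()] recording.
#' @param order nominal filter order (default 20). A centered median needs odd
#'   support, so the window length is `order` if odd, else `order + 1`.
#' @return Filtered `eit_voltage`.
#' @export
median_filter <- function(v, order = 20L) {
  stopifnot_voltage(v)
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be >= 1")
  if (order > ncol(v$data)) stop("`order` exceeds the recording length")
  k <- if (order %% 2L == 1L) order else order + 1L
  if (k > ncol(v$data)) k <- k - 2L
  if (k < 1L) k <- 1L
  half <- (k - 1L) %/% 2L
  out <- t(apply(v$data, 1L, function(ch) {
    if (half == 0L) return(ch)
    padded <- c(rev(ch[seq_len(half) + 1L]),        # reflect, excluding edge
                ch,
                rev(ch[length(ch) - seq_len(half)]))
    stats::runmed(padded, k, endrule = "keep")[half + seq_along(ch)]
  }))
  voltage_matrix(out, v$frame_rate, v$n_electrodes, v$protocol_id)
}
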