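#' Spike contamination specification
#'
#' Describes one episode of spike-like noise: a set of channels, an inclusive
#' frame window, and a multiplicative magnitude. Affected entries are
#' multiplied by `magnitude`, mimicking electrode-contact and movement
#' artifacts whose amplitude is several times the respiratory signal. Channel
#' and frame indices are 1-based.
#'
#' @param channels non-empty integer vector of channel indices.
#' @param frame_window length-2 integer vector `(start, end)`, inclusive.
#' @param magnitude multiplicative factor, >= 1 (1 = no contamination).
#' @return An object of class `spike_spec`.
#' @export
spike_spec <- function(channels, frame_window, magnitude) {
  channels <- unique(as.integer(channels))
  if (length(channels) == 0L) stop("`channels` must be non-empty")
  if (any(channels < 1L)) stop("channel indices are 1-based")
  frame_window <- as.integer(frame_window)
  if (length(frame_window) != 2L || frame_window[1] > frame_window[2])
    stop("`frame_window` must be (start, end) with start <= end")
  if (frame_window[1] < 1L) stop("frame indices are 1-based")
  if (magnitude < 1) stop("`magnitude` must be >= 1")
  structure(list(channels = channels, frame_window = frame_window,
                 magnitude = as.numeric(magnitude)),
            class = "spike_spec")
}

#' @export
print.spike_spec <- function(x, ...) {
  cat(sprintf("Spike spec: %d channel(s), frames %d-%d, x%g\n",
              length(x$channels), x$frame_window[1], x$frame_window[2],
              x$magnitude))
  invisible(x)
}

#' Inject spike-like noise into a recording
#'
#' Multiplies the entries selected by a [spike_spec()] by its magnitude;
#' everything else is returned bit-identically.
#'
#' @param v an [voltage_matrix()] object.
#' @param spec a [spike_spec()].
#' @return A new `eit_voltage` with the contaminated entries.
#' @export
inject_spikes <- function(v, spec) {
  stopifnot_voltage(v)
  if (!inherits(spec, "spike_spec")) stop("expected a `spike_spec`")
  if (any(spec$channels > nrow(v$data)))
    stop("spike channels exceed the recording's channel count")
  if (spec$frame_window[2] > ncol(v$data))
    stop("spike frame window exceeds the recording length")
  out <- v$data
  fr <- spec$frame_window[1]:spec$frame_window[2]
  out[spec$channels, fr] <- out[spec$channels, fr] * spec$magnitude
  voltage_matrix(out, v$frame_rate, v$n_electrodes, v$protocol_id)
}

#' Spike-injection protocol sweeps
#'
#' The three simulation protocols probing robustness to spike magnitude,
#' temporal width, and channel extent:
#' \describe{
#'   \item{`"magnitude"`}{19 specs: channel 35, frame 299, multipliers
#'     1, 2, ..., 10, 20, 30, ..., 100.}
#'   \item{`"width"`}{11 specs: channel 35, magnitude 50, consecutive widths
#'     5, 10, 20, 30, ..., 100 frames starting at frame 299.}
#'   \item{`"channels"`}{14 specs: frames 300-350, magnitude 50, channels
#'     1..k for k in 5, 10, 20, ..., 100, 150, 190, 192.}
#' }
#'
#' @param kind one of `"magnitude"`, `"width"`, `"channels"`.
#' @return A list of [spike_spec()] objects (19, 11 or 14 items).
#' @export
protocol_sweep <- function(kind = c("magnitude", "width", "channels")) {
  kind <- match.arg(kind)
  switch(kind,
    magnitude = lapply(c(1:10, seq(20, 100, by = 10)), function(m)
      spike_spec(35L, c(299L, 299L), m)),
    width = lapply(c(5L, seq(10L, 100L, by = 10L)), function(w)
      spike_spec(35L, c(299L, 299L + w - 1L), 50)),
    channels = lapply(c(5L, seq(10L, 100L, by = 10L), 150L, 190L, 192L),
      function(k) spike_spec(seq_len(k), c(300L, 350L), 50))
  )
}

#' Heterogeneous-lung contamination case
#'
#' The stress case used to compare RPCA against baseline filters: a phantom
#' whose left lung is split into two sub-regions with different conductivity
#' scalings, contaminated on 50 randomly selected channels over a 61-frame
#' window with multiplicative magnitude 27.
#'
#' @param seed integer seed for the random channel draw (default 42; the
#'   original draw is unpublished, so any fixed seed defines the case).
#' @param start_frame first contaminated frame (default 290, keeping the
#'   61-frame window inside a 600-frame recording and overlapping the frames
#'   probed by the other protocols).
#' @param style phantom style passed to [make_phantom()].
#' @return List with `phantom` (heterogeneous-left [make_phantom()]) and
#'   `spec` (the [spike_spec()]).
#' @export
heterogeneous_case <- function(seed = 42L, start_frame = 290L,
                               style = "thorax") {
  set.seed(as.integer(seed))
  channels <- sort(sample.int(192L, 50L))
  list(
    phantom = make_phantom(style, heterogeneous_left = TRUE),
    spec = spike_spec(channels, c(start_frame, start_frame + 60L), 27))
}
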