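#' Synthetic normalized breathing waveform
#'
#' A periodic raised-cosine surrogate for the normalized lung-conductivity
#' modulation used to drive the simulator:
#' `w(t) = 1 - depth * (1 - cos(2 * pi * rate_bpm / 60 * t)) / 2`,
#' so `w` starts each cycle at 1 (end-expiration, maximal lung conductivity =
#' inspiration start) and dips to `1 - depth` at mid-cycle (end-inspiration:
#' air lowers tissue conductivity). Optional small cycle-to-cycle jitter
#' perturbs each cycle's depth to mimic natural breath-to-breath variability.
#'
#' @param n_frames number of frames (>= one full cycle).
#' @param frame_rate frames per second (default 20).
#' @param rate_bpm breathing rate in breaths per minute, in \[6, 60\]
#'   (default 15, i.e. an 80-frame cycle at 20 fps).
#' @param depth peak-to-trough fractional conductivity swing in (0, 1)
#'   (default 0.5).
#' @param jitter relative SD of the per-cycle depth perturbation (default 0 =
#'   strictly periodic).
#' @param seed integer seed for the jitter draw.
#' @return An object of class `eit_breathing`: list with `values` (in
#'   `[1 - depth, 1]`, and in (0, 1]) and `frame_rate`.
#' @export
synth_breathing <- function(n_frames, frame_rate = 20, rate_bpm = 15,
                            depth = 0.5, jitter = 0, seed = 1L) {
  if (rate_bpm < 6 || rate_bpm > 60) stop("`rate_bpm` must lie in [6, 60]")
  if (depth <= 0 || depth >= 1) stop("`depth` must lie in (0, 1)")
  f <- rate_bpm / 60                      # Hz
  period_frames <- frame_rate / f
  if (n_frames < period_frames)
    stop("`n_frames` must cover at least one breathing cycle (",
         ceiling(period_frames), " frames)")
  t <- (seq_len(n_frames) - 1L) / frame_rate
  phase <- (1 - cos(2 * pi * f * t)) / 2  # 0 at cycle start, 1 at mid-cycle
  d <- rep(depth, n_frames)
  if (jitter > 0) {
    cycle <- floor(t * f)
    set.seed(as.integer(seed))
    per_cycle <- depth * (1 + jitter * stats::rnorm(max(cycle) + 1L))
    per_cycle <- pmin(pmax(per_cycle, 0.05), 0.95)
    d <- per_cycle[cycle + 1L]
  }
  values <- 1 - d * phase
  structure(list(values = values, frame_rate = frame_rate,
                 rate_bpm = rate_bpm, depth = depth),
            class = "eit_breathing")
}

#' @export
print.eit_breathing <- function(x, ...) {
  cat(sprintf("Breathing waveform: %d frames at %g fps, %g bpm, depth %g\n",
              length(x$values), x$frame_rate, x$rate_bpm, x$depth))
  invisible(x)
}
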