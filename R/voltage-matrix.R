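#' EIT boundary-voltage matrix
#'
#' Container for a thoracic EIT recording: a real matrix with one row per
#' measurement channel and one column per time frame, plus acquisition
#' metadata. For a 16-electrode system driven with opposite (diametral)
#' current excitation and adjacent voltage measurement, each of the 16 drive
#' switches yields 12 voltage readings, so a frame holds
#' `16 * (16 - 4) = 192` values and the matrix has 192 rows.
#'
#' @param data numeric matrix, channels x frames. All entries must be finite
#'   and at least two frames are required.
#' @param frame_rate acquisition rate in frames per second (> 0).
#' @param n_electrodes number of boundary electrodes (only 16 is supported).
#' @param protocol_id label of the excitation/measurement scheme. The default
#'   `"opposite-adjacent"` enforces 192 rows; `"adjacent-adjacent"` allows the
#'   208-row layout of adjacent-drive systems.
#'
#' @return An object of class `eit_voltage`: a list with elements `data`,
#'   `frame_rate`, `n_electrodes`, `protocol_id`.
#' @export
voltage_matrix <- function(data, frame_rate, n_electrodes = 16L,
                           protocol_id = "opposite-adjacent") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x frames)")
  if (any(!is.finite(data)))
    stop("voltage matrix contains non-finite entries (NaN/Inf)")
  if (ncol(data) < 2L)
    stop("a recording needs at least 2 frames")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a positive scalar (frames per second)")
  n_electrodes <- as.integer(n_electrodes)
  if (n_electrodes != 16L)
    stop("only 16-electrode systems are supported")
  expected <- switch(protocol_id,
    "opposite-adjacent" = n_electrodes * (n_electrodes - 4L),  # 192
    "adjacent-adjacent" = 208L,
    stop("unknown protocol_id: ", protocol_id)
  )
  if (nrow(data) != expected)
    stop(sprintf("protocol '%s' expects %d channel rows, got %d",
                 protocol_id, expected, nrow(data)))
  structure(
    list(data = unname(data), frame_rate = as.numeric(frame_rate),
         n_electrodes = n_electrodes, protocol_id = protocol_id),
    class = "eit_voltage")
}

#' @export
print.eit_voltage <- function(x, ...) {
  cat(sprintf("EIT voltage matrix: %d channels x %d frames at %g fps (%s, %d electrodes)\n",
              nrow(x$data), ncol(x$data), x$frame_rate, x$protocol_id,
              x$n_electrodes))
  invisible(x)
}

#' @export
dim.eit_voltage <- function(x) dim(x$data)

n_frames <- function(v) ncol(v$data)

stopifnot_voltage <- function(v) {
  if (!inherits(v, "eit_voltage")) stop("expected an `eit_voltage` object")
  invisible(v)
}

#' Channel map for opposite excitation / adjacent measurement
#'
#' Enumerates the 192 measurement channels of the 16-electrode scheme.
#' The excitation pair rotates a full circle through 16 switches; under drive
#' pair `i` the current enters electrode `i` and leaves the diametrically
#' opposite electrode `i + 8` (mod 16). For each drive pair, the 12 adjacent
#' electrode pairs that do not contain a driving electrode are read out, in
#' ascending order of their first electrode. Channel order is drive-pair-major:
#' channels 1-12 belong to drive pair 1, channels 13-24 to drive pair 2, and
#' so on.
#'
#' @param n_electrodes number of electrodes (16 only).
#' @return A data frame with one row per channel: `channel`, `drive_a`,
#'   `drive_b` (current in/out electrodes), `meas_c`, `meas_d` (the measured
#'   adjacent pair; the reported voltage is `U[meas_c] - U[meas_d]`).
#'   Electrode and channel indices are 1-based.
#' @export
channel_map <- function(n_electrodes = 16L) {
  n_electrodes <- as.integer(n_electrodes)
  if (n_electrodes != 16L) stop("only 16-electrode systems are supported")
  rows <- vector("list", n_electrodes)
  ch <- 0L
  for (i in seq_len(n_electrodes)) {
    a <- i
    b <- ((i + 7L) %% n_electrodes) + 1L   # opposite electrode
    kept <- list()
    for (c in seq_len(n_electrodes)) {
      d <- (c %% n_electrodes) + 1L        # adjacent neighbour
      if (c %in% c(a, b) || d %in% c(a, b)) next
      kept[[length(kept) + 1L]] <- c(c, d)
    }
    stopifnot(length(kept) == n_electrodes - 4L)
    rows[[i]] <- data.frame(
      channel = ch + seq_along(kept),
      drive_a = a, drive_b = b,
      meas_c = vapply(kept, `[`, integer(1), 1L),
      meas_d = vapply(kept, `[`, integer(1), 2L))
    ch <- ch + length(kept)
  }
  do.call(rbind, rows)
}

#' Read a boundary-voltage matrix from disk
#'
#' Two on-disk dialects are supported: a headerless CSV with channels as rows,
#' and a raw little-endian double array (`.bin`) accompanied by a JSON sidecar
#' `<path>.json` holding `{"frame_rate":, "n_electrodes":, "protocol":, "dim":}`.
#'
#' @param path file to read (`.csv` or `.bin`).
#' @param frame_rate frames per second; required for CSV, ignored for the
#'   binary container (taken from the sidecar).
#' @return An [voltage_matrix()] object.
#' @export
load_voltage_matrix <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.bin$", path)) {
    meta_path <- paste0(path, ".json")
    if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    n <- prod(meta$dim)
    x <- readBin(path, "double", n = n, size = 8L, endian = "little")
    if (length(x) != n) stop("binary container truncated: ", path)
    m <- matrix(x, nrow = meta$dim[1], ncol = meta$dim[2])
    return(voltage_matrix(m, meta$frame_rate,
                          n_electrodes = meta$n_electrodes,
                          protocol_id = meta$protocol))
  }
  m <- tryCatch(
    as.matrix(utils::read.csv(path, header = FALSE)),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  storage.mode(m) <- "double"
  if (any(!is.finite(m)))
    stop("parse error: non-finite values (NaN/Inf) in ", path)
  if (!nrow(m) %in% c(192L, 208L))
    stop("protocol error: expected 192 or 208 channel rows, got ", nrow(m))
  protocol <- if (nrow(m) == 192L) "opposite-adjacent" else "adjacent-adjacent"
  if (is.null(frame_rate)) stop("`frame_rate` is required for CSV input")
  voltage_matrix(m, frame_rate, protocol_id = protocol)
}

#' Write a boundary-voltage matrix to disk
#'
#' @param v an [voltage_matrix()] object.
#' @param path destination; `.csv` writes headerless CSV, `.bin` writes a raw
#'   little-endian double array plus a `<path>.json` sidecar.
#' @return `path`, invisibly.
#' @export
write_voltage_matrix <- function(v, path) {
  stopifnot_voltage(v)
  if (grepl("\\.bin$", path)) {
    writeBin(as.vector(v$data), path, size = 8L, endian = "little")
    jsonlite::write_json(
      list(frame_rate = v$frame_rate, n_electrodes = v$n_electrodes,
           protocol = v$protocol_id, dim = dim(v$data)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(v$data, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Singular spectrum of a recording
#'
#' The channels of a thoracic EIT recording all observe the same respiratory
#' conductivity modulation, so the data matrix is approximately low rank: on
#' real recordings the first singular value carries the vast majority of the
#' total singular-value sum. This function quantifies that by returning the
#' singular values and each value's fraction of the total.
#'
#' @param v an [voltage_matrix()] object or a plain numeric matrix.
#' @return A list of class `eit_spectrum` with `singular_values`
#'   (non-increasing) and `energy_fractions` (sums to 1).
#' @export
singular_spectrum <- function(v) {
  m <- if (inherits(v, "eit_voltage")) v$data else v
  if (!is.matrix(m) || !is.numeric(m) || any(!is.finite(m)))
    stop("expected a finite numeric matrix")
  s <- svd(m, nu = 0, nv = 0)$d
  structure(list(singular_values = s, energy_fractions = s / sum(s)),
            class = "eit_spectrum")
}

#' @export
print.eit_spectrum <- function(x, ...) {
  cat(sprintf("Singular spectrum: %d values; first carries %.1f%% of the total sum\n",
              length(x$singular_values), 100 * x$energy_fractions[1]))
  invisible(x)
}

#' Saturate channels driven by poorly contacting electrodes
#'
#' When an electrode loses skin contact, measurements taken while that
#' electrode drives current are meaningless and typically rail at the
#' amplifier's saturation level, while other frames' readings collapse. To
#' preserve the low-rank structure that robust PCA relies on, every channel
#' whose drive pair contains a flagged electrode is overwritten, over all
#' frames, with a constant saturation level.
#'
#' @param v an [voltage_matrix()] object.
#' @param bad_electrodes integer vector of 1-based electrode ids in 1..16.
#' @param saturation_level constant written into the affected rows; must
#'   exceed `max(abs(v$data))`. Default: `10 * max(abs(v$data))`.
#' @return A new `eit_voltage` with the affected rows replaced.
#' @export
saturate_bad_electrodes <- function(v, bad_electrodes,
                                    saturation_level = NULL) {
  stopifnot_voltage(v)
  bad_electrodes <- unique(as.integer(bad_electrodes))
  if (length(bad_electrodes) == 0L) return(v)
  if (any(bad_electrodes < 1L | bad_electrodes > v$n_electrodes))
    stop("electrode ids must lie in 1..", v$n_electrodes)
  if (is.null(saturation_level)) saturation_level <- 10 * max(abs(v$data))
  cm <- channel_map(v$n_electrodes)
  hit <- cm$channel[cm$drive_a %in% bad_electrodes |
                      cm$drive_b %in% bad_electrodes]
  # the level must dominate every reading that stays in the data (so that
  # repeating the replacement at the same level is a no-op)
  peak <- max(abs(v$data[-hit, , drop = FALSE]))
  if (saturation_level <= peak)
    stop("`saturation_level` must exceed the remaining channels' max |voltage| = ",
         signif(peak, 6))
  out <- v$data
  out[hit, ] <- saturation_level
  voltage_matrix(out, v$frame_rate, v$n_electrodes, v$protocol_id)
}

#' Global respiratory waveform of a recording
#'
#' Sum of the voltages over all channels at each frame; on a breathing subject
#' this traces the respiratory cycle (boundary voltages rise as lung
#' conductivity falls during inspiration).
#'
#' @param v an [voltage_matrix()] object.
#' @return Numeric vector of length `n_frames`.
#' @export
sum_waveform <- function(v) {
  stopifnot_voltage(v)
  colSums(v$data)
}
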