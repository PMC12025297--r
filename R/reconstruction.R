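#' Train a GREIT-style linear reconstruction model
#'
#' Builds the linear map from 192-channel difference-voltage vectors to 32 x 32
#' pixel images following the GREIT construction: simulate many small
#' conductivity targets across the domain of a homogeneous phantom, pair each
#' simulated difference signal with a desired image (a Gaussian point-spread
#' blob at the target position), and solve the regularized regression
#' `R = X Y' (Y Y' + alpha * mean(diag(Y Y')) I)^-1`. Target signals come from
#' the forward model's conductivity Jacobian, so training is deterministic
#' given the phantom and parameters.
#'
#' Polarity: targets are conductivity *decreases*, paired with positive
#' desired blobs, so reconstructed ventilation signal (air entering the lungs
#' lowers conductivity relative to an inspiration-start reference) appears
#' positive.
#'
#' Image orientation: the subject's ventral side is the top image row, the
#' subject's right is the left image column.
#'
#' @param phantom an [make_phantom()] object (trained on its homogeneous
#'   background state).
#' @param target_radius radius of training targets as a fraction of the domain
#'   radius (default 0.05).
#' @param psf_sd standard deviation of the desired Gaussian point-spread, as a
#'   fraction of the domain radius (default 0.1).
#' @param noise_alpha Tikhonov weight relative to the mean diagonal of `Y Y'`
#'   (default 0.02); plays the role of GREIT's noise-figure weighting.
#' @param grid_margin training targets are pixel centers within this fraction
#'   of the boundary ellipse (default 0.92).
#' @return An object of class `eit_recon_model`: list with `matrix`
#'   (1024 x 192), `mask` (32 x 32 logical, in-body pixels), `pixel_x`,
#'   `pixel_y` (pixel-center coordinate grids), `phantom_ref`, and the
#'   training parameters.
#' @export
build_reconstructor <- function(phantom, target_radius = 0.05, psf_sd = 0.1,
                                noise_alpha = 0.02, grid_margin = 0.92) {
  if (!inherits(phantom, "eit_phantom")) stop("expected an `eit_phantom`")
  a <- phantom$bounds[1]; b <- phantom$bounds[2]

  # pixel-center coordinates; row 1 = ventral (+y), col 1 = subject right (-x)
  xs <- seq(-a, a, length.out = 65L)[seq(2L, 64L, by = 2L)]
  ys <- seq(b, -b, length.out = 65L)[seq(2L, 64L, by = 2L)]
  px <- matrix(xs, 32L, 32L, byrow = TRUE)   # [row, col] -> x
  py <- matrix(ys, 32L, 32L, byrow = FALSE)  # [row, col] -> y
  mask <- (px / a)^2 + (py / b)^2 <= 1

  sig_hom <- c("0" = phantom$background_conductivity,
               "1" = phantom$background_conductivity,
               "2" = phantom$background_conductivity,
               "3" = phantom$background_conductivity)
  J <- forward_jacobian(phantom, sig_hom)
  geom <- mesh_geometry(phantom)
  ecx <- (phantom$nodes[phantom$tris[, 1], 1] + phantom$nodes[phantom$tris[, 2], 1] +
          phantom$nodes[phantom$tris[, 3], 1]) / 3
  ecy <- (phantom$nodes[phantom$tris[, 1], 2] + phantom$nodes[phantom$tris[, 2], 2] +
          phantom$nodes[phantom$tris[, 3], 2]) / 3

  inside <- (px / (grid_margin * a))^2 + (py / (grid_margin * b))^2 <= 1
  tx <- px[inside]; ty <- py[inside]
  n_t <- length(tx)
  rt <- target_radius                      # in domain-radius units
  sdp <- psf_sd

  Y <- matrix(0, nrow(J), n_t)
  X <- matrix(0, 1024L, n_t)
  pxv <- as.vector(px); pyv <- as.vector(py); mv <- as.vector(mask)
  for (k in seq_len(n_t)) {
    # small conductivity decrease: Gaussian-weighted element blob
    d2 <- ((ecx - tx[k]) / a)^2 + ((ecy - ty[k]) / b)^2
    w <- geom$area * exp(-d2 / (2 * rt^2))
    Y[, k] <- -J %*% w
    g <- exp(-(((pxv - tx[k]) / a)^2 + ((pyv - ty[k]) / b)^2) / (2 * sdp^2))
    g[!mv] <- 0
    X[, k] <- g
  }

  YY <- Y %*% t(Y)
  reg <- noise_alpha * mean(diag(YY))
  R <- X %*% t(Y) %*% solve(YY + reg * diag(nrow(YY)))
  R[!mv, ] <- 0

  structure(list(matrix = R, mask = mask, pixel_x = px, pixel_y = py,
                 phantom_ref = phantom, target_radius = target_radius,
                 psf_sd = psf_sd, noise_alpha = noise_alpha),
            class = "eit_recon_model")
}

#' @export
print.eit_recon_model <- function(x, ...) {
  cat(sprintf("GREIT-style reconstructor: 192 channels -> 32x32 (%d in-body pixels)\n",
              sum(x$mask)))
  invisible(x)
}

#' Reconstruct one difference image
#'
#' Applies the reconstruction matrix to a 192-length difference-voltage
#' vector and returns the masked 32 x 32 image.
#'
#' @param model an [build_reconstructor()] model.
#' @param dv numeric vector of length 192 (frame voltages minus reference
#'   voltages).
#' @return 32 x 32 numeric matrix; out-of-body pixels are exactly 0.
#' @export
reconstruct_frame <- function(model, dv) {
  if (!inherits(model, "eit_recon_model")) stop("expected an `eit_recon_model`")
  if (length(dv) != ncol(model$matrix))
    stop("difference vector must have length ", ncol(model$matrix))
  img <- matrix(model$matrix %*% as.numeric(dv), 32L, 32L)
  img[!model$mask] <- 0
  img
}

#' Reconstruct a time series of difference images
#'
#' Subtracts the reference frame's voltages from every frame and reconstructs
#' each difference vector. The reference should be an inspiration-start
#' (end-expiration) frame; see [pick_reference_frame()].
#'
#' @param model an [build_reconstructor()] model.
#' @param v an [voltage_matrix()] recording.
#' @param reference_frame 1-based frame index used as the reference.
#' @return An object of class `eit_image_series`: list with `images` (array
#'   32 x 32 x n_frames), `mask`, `reference_frame`, `frame_rate`.
#' @export
reconstruct_series <- function(model, v, reference_frame) {
  if (!inherits(model, "eit_recon_model")) stop("expected an `eit_recon_model`")
  stopifnot_voltage(v)
  reference_frame <- as.integer(reference_frame)
  if (reference_frame < 1L || reference_frame > ncol(v$data))
    stop("`reference_frame` outside the recording")
  dv <- v$data - v$data[, reference_frame]
  pix <- model$matrix %*% dv              # 1024 x T
  pix[!as.vector(model$mask), ] <- 0
  structure(list(images = array(pix, c(32L, 32L, ncol(dv))),
                 mask = model$mask, reference_frame = reference_frame,
                 frame_rate = v$frame_rate),
            class = "eit_image_series")
}

#' @export
print.eit_image_series <- function(x, ...) {
  cat(sprintf("EIT image series: %d frames of 32x32 (reference frame %d)\n",
              dim(x$images)[3], x$reference_frame))
  invisible(x)
}

#' Functional EIT image (standard-deviation method)
#'
#' Summarizes a time series of difference images into one functional image by
#' taking each pixel's standard deviation over time; ventilated regions, whose
#' pixel values oscillate with breathing, light up. Population (divide-by-n)
#' SD by default.
#'
#' @param series an [reconstruct_series()] object (>= 2 frames).
#' @param sample_sd use the divide-by-(n-1) sample SD instead.
#' @return 32 x 32 non-negative matrix, zero outside the body mask.
#' @export
feit_image <- function(series, sample_sd = FALSE) {
  if (!inherits(series, "eit_image_series")) stop("expected an `eit_image_series`")
  n <- dim(series$images)[3]
  if (n < 2L) stop("need at least 2 frames")
  m <- matrix(series$images, 1024L, n)    # pixels x time
  mu <- rowMeans(m)
  ss <- rowSums((m - mu)^2)
  img <- matrix(sqrt(ss / if (sample_sd) (n - 1L) else n), 32L, 32L)
  img[!series$mask] <- 0
  img
}

#' Pick the inspiration-start reference frame
#'
#' Locates the local minima of the recording's summed voltage waveform (lung
#' conductivity is maximal at end-expiration, which makes the boundary-voltage
#' sum minimal, marking the start of inspiration) and returns the one closest
#' to `near_frame`, tie-breaking to the earlier frame.
#'
#' @param v an [voltage_matrix()] recording spanning more than one breathing
#'   cycle.
#' @param near_frame 1-based frame index to search around.
#' @return The chosen frame index.
#' @export
pick_reference_frame <- function(v, near_frame) {
  stopifnot_voltage(v)
  s <- sum_waveform(v)
  n <- length(s)
  if (near_frame < 1L || near_frame > n) stop("`near_frame` outside recording")
  i <- 2:(n - 1L)
  minima <- i[s[i] < s[i - 1L] & s[i] <= s[i + 1L]]
  if (length(minima) == 0L)
    stop("no breathing cycle found: the summed waveform has no interior local minimum")
  d <- abs(minima - near_frame)
  minima[which(d == min(d))[1L]]          # earlier frame wins ties
}
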