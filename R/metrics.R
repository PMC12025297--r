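as_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || any(!is.finite(img)))
    stop("expected a finite numeric image matrix")
  img
}

#' Image correlation coefficient
#'
#' Pearson correlation between two reconstructed images, computed over all
#' pixels (means subtracted over the full grid). Used to score a processed
#' image against the clean ground truth.
#'
#' @param a,b numeric image matrices of identical shape; each must have at
#'   least one varying pixel.
#' @return Correlation in \[-1, 1\].
#' @export
image_correlation <- function(a, b) {
  a <- as_image(a); b <- as_image(b)
  if (!all(dim(a) == dim(b))) stop("images must have identical shape")
  da <- a - mean(a); db <- b - mean(b)
  va <- sum(da^2); vb <- sum(db^2)
  if (va == 0 || vb == 0)
    stop("correlation undefined: an image has zero pixel variance")
  sum(da * db) / sqrt(va * vb)
}

#' Image error
#'
#' Deviation of a test image from a reference image: the square root of the
#' summed squared pixel differences, normalized by the summed absolute
#' reference pixel values,
#' \deqn{\mathrm{Img_{err}} = \frac{\sqrt{\sum_i (test_i - ref_i)^2}}{\sum_i |ref_i|}.}
#' The numerator is the root of the total (not mean) squared error; the ratio
#' is invariant to rescaling both images together.
#'
#' @param test,ref numeric image matrices of identical shape; `ref` must not
#'   be identically zero.
#' @return Non-negative error.
#' @export
image_error <- function(test, ref) {
  test <- as_image(test); ref <- as_image(ref)
  if (!all(dim(test) == dim(ref))) stop("images must have identical shape")
  denom <- sum(abs(ref))
  if (denom == 0) stop("reference image is identically zero")
  sqrt(sum((test - ref)^2)) / denom
}

#' Center of ventilation
#'
#' Amplitude-weighted mean pixel position along the ventral-dorsal axis, as a
#' percentage of thoracic depth: 0% = all ventilation at the ventral edge
#' (top image row), 100% = at the dorsal edge. Pixel distances are normalized
#' by the grid extent (`nrow - 1`), so a uniform image scores 50%.
#'
#' @param img numeric image matrix with positive total; top row = ventral.
#' @return CoV in \[0, 100\] (percent).
#' @export
center_of_ventilation <- function(img) {
  img <- as_image(img)
  tot <- sum(img)
  if (tot <= 0) stop("CoV undefined: image total must be positive")
  l <- (row(img) - 1) / (nrow(img) - 1)   # 0 at ventral edge, 1 at dorsal
  sum(l * img) / tot * 100
}

#' Global inhomogeneity index
#'
#' Heterogeneity of the ventilation distribution: summed absolute deviation of
#' every pixel from the median pixel value, normalized by the total pixel sum.
#' By default all pixels of the grid enter the sums (set `roi` to restrict to
#' a lung region of interest, the common clinical variant).
#'
#' @param img numeric image matrix with positive total.
#' @param roi optional logical matrix selecting the pixels entering the sums.
#' @return Non-negative GI.
#' @export
global_inhomogeneity <- function(img, roi = NULL) {
  img <- as_image(img)
  x <- if (is.null(roi)) as.vector(img) else img[roi]
  tot <- sum(x)
  if (tot <= 0) stop("GI undefined: image total must be positive")
  sum(abs(x - stats::median(x))) / tot
}

#' Ventral/dorsal and right/left ventilation ratios
#'
#' Ratios of summed pixel amplitude between image halves under the documented
#' orientation (ventral = top rows 1-16, dorsal = bottom rows 17-32; subject
#' right = left columns 1-16, subject left = right columns 17-32).
#'
#' @param img numeric image matrix (32 x 32 or any even-sized grid).
#' @return Named list `vtod`, `rtol`.
#' @export
region_ratios <- function(img) {
  img <- as_image(img)
  hr <- nrow(img) %/% 2L; hc <- ncol(img) %/% 2L
  ventral <- sum(img[seq_len(hr), ]); dorsal <- sum(img[(hr + 1L):nrow(img), ])
  right <- sum(img[, seq_len(hc)]); left <- sum(img[, (hc + 1L):ncol(img)])
  if (dorsal <= 0) stop("VtoD undefined: dorsal sum must be positive")
  if (left <= 0) stop("RtoL undefined: left sum must be positive")
  list(vtod = ventral / dorsal, rtol = right / left)
}

#' Score an image against a reference
#'
#' Computes the two image-quality metrics and the four clinical ventilation
#' indices for a test image, plus the absolute index errors against the
#' reference image's indices.
#'
#' @param test,ref numeric image matrices of identical shape.
#' @return An object of class `eit_index_report`: list with `img_corr`,
#'   `img_err`, `cov`, `gi`, `vtod`, `rtol` for the test image, and `deltas`
#'   (named numeric: absolute CoV/GI/VtoD/RtoL differences vs. the reference).
#' @export
index_report <- function(test, ref) {
  rr_t <- region_ratios(test); rr_r <- region_ratios(ref)
  rep_t <- list(
    img_corr = image_correlation(test, ref),
    img_err = image_error(test, ref),
    cov = center_of_ventilation(test),
    gi = global_inhomogeneity(test),
    vtod = rr_t$vtod, rtol = rr_t$rtol)
  ref_idx <- c(cov = center_of_ventilation(ref),
               gi = global_inhomogeneity(ref),
               vtod = rr_r$vtod, rtol = rr_r$rtol)
  rep_t$deltas <- abs(c(cov = rep_t$cov, gi = rep_t$gi,
                        vtod = rep_t$vtod, rtol = rep_t$rtol) - ref_idx)
  structure(rep_t, class = "eit_index_report")
}

#' @export
print.eit_index_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Image vs reference: corr = %.4f, error = %.4g\n",
    "  CoV = %.2f%% (err %.3g), GI = %.3f (err %.3g)\n",
    "  VtoD = %.3f (err %.3g), RtoL = %.3f (err %.3g)\n"),
    x$img_corr, x$img_err, x$cov, x$deltas["cov"], x$gi, x$deltas["gi"],
    x$vtod, x$deltas["vtod"], x$rtol, x$deltas["rtol"]))
  invisible(x)
}

#' Absolute index errors between two reports
#'
#' @param test,ref [index_report()] objects (or any lists carrying `cov`,
#'   `gi`, `vtod`, `rtol`).
#' @return Named numeric vector of absolute differences.
#' @export
index_errors <- function(test, ref) {
  nm <- c("cov", "gi", "vtod", "rtol")
  abs(unlist(test[nm]) - unlist(ref[nm]))
}

#' Two-sample comparison of metric groups
#'
#' Independent-samples t-test (equal-variance by default; set
#' `welch = TRUE` for the unequal-variance variant) comparing a metric before
#' and after processing across cases.
#'
#' @param before,after numeric vectors (each length >= 2).
#' @param welch use the Welch t-test.
#' @return List with `t_statistic`, `p_value`, `df`.
#' @export
compare_groups <- function(before, after, welch = FALSE) {
  if (length(before) < 2L || length(after) < 2L)
    stop("each group needs at least 2 observations")
  ht <- stats::t.test(before, after, var.equal = !welch)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
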