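test_that("image correlation matches a longhand Pearson computation", {
  a <- det_matrix(32, 32, seed = 40)
  b <- det_matrix(32, 32, seed = 41)
  expect_equal(image_correlation(a, a), 1, tolerance = 1e-12)
  expect_equal(image_correlation(a, -a), -1, tolerance = 1e-12)

  av <- as.vector(a); bv <- as.vector(b)
  ref <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(image_correlation(a, b), ref, tolerance = 1e-12)
  expect_equal(image_correlation(a, b), cor(av, bv), tolerance = 1e-12)

  # affine positive rescaling leaves it unchanged
  expect_equal(image_correlation(2.7 * a + 3, b), image_correlation(a, b),
               tolerance = 1e-12)
  expect_error(image_correlation(a, matrix(1, 32, 32)), "zero pixel variance")
})

test_that("image error is the printed root-total-square over summed-absolute ratio", {
  a <- det_matrix(32, 32, seed = 42)
  expect_equal(image_error(a, a), 0)

  ref <- matrix(0, 32, 32); ref[5, 5] <- 1
  test <- matrix(0, 32, 32); test[5, 5] <- 2
  expect_equal(image_error(test, ref), 1)       # sqrt((2-1)^2) / |1|

  b <- abs(det_matrix(32, 32, seed = 43)) + 0.1
  longhand <- sqrt(sum((a - b)^2)) / sum(abs(b))
  expect_equal(image_error(a, b), longhand, tolerance = 1e-12)
  # scale invariance of the ratio
  expect_equal(image_error(2 * a, 2 * b), image_error(a, b), tolerance = 1e-12)
  expect_error(image_error(a, matrix(0, 32, 32)), "identically zero")
})

test_that("center of ventilation is a ventral-referenced percentage", {
  expect_equal(center_of_ventilation(matrix(1, 32, 32)), 50)

  ventral_only <- matrix(0, 32, 32); ventral_only[1, ] <- 1
  expect_equal(center_of_ventilation(ventral_only), 0)
  dorsal_only <- matrix(0, 32, 32); dorsal_only[32, ] <- 1
  expect_equal(center_of_ventilation(dorsal_only), 100)

  split <- matrix(0, 32, 32); split[1, ] <- 1; split[32, ] <- 1
  expect_equal(center_of_ventilation(split), 50)

  img <- abs(det_matrix(32, 32, seed = 44))
  l <- (row(img) - 1) / 31
  expect_equal(center_of_ventilation(img), 100 * sum(l * img) / sum(img),
               tolerance = 1e-12)
  expect_true(center_of_ventilation(img) >= 0 &&
                center_of_ventilation(img) <= 100)
  expect_error(center_of_ventilation(matrix(0, 32, 32)), "positive")
})

test_that("global inhomogeneity matches its defining ratio", {
  expect_equal(global_inhomogeneity(matrix(3, 32, 32)), 0)

  img <- matrix(1, 32, 32)
  roi <- matrix(FALSE, 32, 32); roi[1, 1:2] <- TRUE
  img[1, 1] <- 0; img[1, 2] <- 2
  expect_equal(global_inhomogeneity(img, roi = roi), 1)  # (1 + 1) / 2

  x <- abs(det_matrix(32, 32, seed = 45))
  ref <- sum(abs(x - median(x))) / sum(x)
  expect_equal(global_inhomogeneity(x), ref, tolerance = 1e-12)
  expect_equal(global_inhomogeneity(5 * x), global_inhomogeneity(x),
               tolerance = 1e-12)
})

test_that("region ratios split the grid at the documented halves", {
  expect_equal(region_ratios(matrix(1, 32, 32)), list(vtod = 1, rtol = 1))

  img <- matrix(0, 32, 32)
  img[1:16, 1:16] <- 2      # ventral-right quadrant
  img[17:32, 1:16] <- 1     # dorsal-right
  img[1:16, 17:32] <- 4     # ventral-left
  img[17:32, 17:32] <- 8    # dorsal-left
  rr <- region_ratios(img)
  expect_equal(rr$vtod, (2 + 4) / (1 + 8))
  expect_equal(rr$rtol, (2 + 1) / (4 + 8))

  bad <- matrix(0, 32, 32); bad[1:16, 1:16] <- 1
  expect_error(region_ratios(bad), "VtoD undefined")
})

test_that("index reports and errors are symmetric absolute differences", {
  a <- abs(det_matrix(32, 32, seed = 46)) + 0.01
  b <- abs(det_matrix(32, 32, seed = 47)) + 0.01
  rep_ab <- index_report(a, b)
  expect_equal(unname(rep_ab$deltas["cov"]),
               abs(center_of_ventilation(a) - center_of_ventilation(b)),
               tolerance = 1e-12)
  expect_true(all(rep_ab$deltas >= 0))

  same <- index_report(a, a)
  expect_equal(unname(same$deltas), rep(0, 4))
  expect_equal(same$img_corr, 1, tolerance = 1e-12)
  expect_equal(same$img_err, 0)

  e1 <- index_errors(index_report(a, b), index_report(b, a))
  e2 <- index_errors(index_report(b, a), index_report(a, b))
  expect_equal(unname(e1), unname(e2), tolerance = 1e-12)
})

test_that("metric conventions have not drifted (frozen regression values)", {
  # deterministic fixture image: smooth ventral-weighted ramp plus a blob
  img <- outer(32:1, 1:32, function(r, c) r / 32 + 0.5 * exp(-((r - 20)^2 + (c - 10)^2) / 40))
  ref <- outer(32:1, 1:32, function(r, c) r / 32)
  expect_equal(image_correlation(img, ref), 0.9467811502372, tolerance = 1e-10)
  expect_equal(image_error(img, ref), 0.0075013694211, tolerance = 1e-10)
  expect_equal(center_of_ventilation(img), 33.9071906998986, tolerance = 1e-10)
  expect_equal(global_inhomogeneity(img), 0.5077723721460, tolerance = 1e-10)
  rr <- region_ratios(img)
  expect_equal(rr$vtod, 2.9473603681868, tolerance = 1e-10)
  expect_equal(rr$rtol, 1.1955860164629, tolerance = 1e-10)
})

test_that("group comparison reproduces the classic pooled t-test", {
  g1 <- c(5.1, 4.9, 5.4, 5.0, 5.2)
  g2 <- c(4.6, 4.4, 4.9, 4.5, 4.7)
  res <- compare_groups(g1, g2)
  # longhand pooled two-sample t statistic
  sp2 <- (4 * var(g1) + 4 * var(g2)) / 8
  t_ref <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(res$t_statistic, t_ref, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pt(-abs(t_ref), df = 8), tolerance = 1e-6)

  # identical groups: t = 0, p = 1
  res0 <- compare_groups(g1, g1)
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 1)

  # antisymmetry
  swapped <- compare_groups(g2, g1)
  expect_equal(swapped$t_statistic, -res$t_statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)

  welch <- compare_groups(g1, g2, welch = TRUE)
  expect_lt(welch$df, 8 + 1e-9)
  expect_error(compare_groups(1, g2), "at least 2")
})
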