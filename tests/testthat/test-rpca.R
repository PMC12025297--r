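test_that("svt matches hand-computed and reference results", {
  x <- det_matrix(10, 14, seed = 2)
  expect_equal(svt(x, 0), x, tolerance = 1e-10)

  # diagonal case by hand: singular values are the diagonal entries
  expect_equal(svt(diag(c(3, 1)), 2), diag(c(1, 0)), tolerance = 1e-12)

  # full shrinkage
  s1 <- max(svd(x)$d)
  expect_equal(svt(x, s1 + 1), matrix(0, 10, 14), tolerance = 1e-12)

  # against a plain-SVD reference at a mid-range threshold, both orientations
  for (xx in list(x, t(x))) {
    sv <- svd(xx)
    tau <- sv$d[4]
    d <- pmax(sv$d - tau, 0); keep <- d > 0
    ref <- sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
    expect_equal(svt(xx, tau), ref, tolerance = 1e-10)
    # nuclear norm does not increase
    expect_lte(sum(svd(svt(xx, tau))$d), sum(sv$d))
  }
  expect_error(svt(matrix(c(1, NA, 1, 1), 2), 1), "finite")
  expect_error(svt(x, -1), "non-negative")
})

test_that("soft thresholding applies the entrywise shrinkage formula", {
  expect_equal(soft_threshold(matrix(c(5, -0.5), 1), 1), matrix(c(4, 0), 1))
  x <- det_matrix(6, 6, seed = 3)
  expect_identical(soft_threshold(x, 0), x)
  expect_equal(soft_threshold(0, 5), 0)              # sign(0) = 0
  for (tau in c(0.1, 1, 10))
    expect_lte(sum(abs(soft_threshold(x, tau))), sum(abs(x)))
  # matches the formula evaluated longhand
  tau <- 0.7
  ref <- ifelse(abs(x) > tau, sign(x) * (abs(x) - tau), 0)
  expect_equal(soft_threshold(x, tau), ref, tolerance = 1e-15)
})

test_that("rpca handles degenerate and clean inputs", {
  z <- matrix(0, 5, 8)
  fit <- rpca(z)
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 1L)
  expect_equal(fit$L, z)
  expect_equal(fit$S, z)

  # clean rank-1 input: essentially nothing ends up in S. At this generic
  # 50 x 200 size the size-adaptive sparsity weight is the appropriate one
  # (the fixed 0.01 default is calibrated to 192-channel recordings, where
  # the l1 cost of absorbing the signal into S is several times the nuclear
  # cost of keeping it in L; at 50 x 200 the two are near-equal).
  d <- outer(0.2 * sin(1:50 / 4), 0.3 * cos(1:200 / 9))
  fit <- suppressWarnings(rpca(d, lam = candes_lambda(d), max_iter = 2000))
  expect_lt(sqrt(sum(fit$S^2)) / sqrt(sum(d^2)), 1e-4)
  expect_lt(sqrt(sum((fit$L - d)^2)) / sqrt(sum(d^2)), 1e-3)

  expect_error(rpca(matrix(1, 1, 5)), "2 x 2")
  expect_error(rpca(matrix(c(1, Inf, 1, 1), 2)), "finite")
  expect_error(rpca(matrix(1, 3, 3), lam = 0), "positive")
})

test_that("rpca separates sparse corruption from a low-rank matrix", {
  prob <- lr_plus_spikes(m = 50, n = 200, r = 2, frac = 0, seed = 4)
  d <- prob$L0
  d[cbind(c(3, 17, 25, 40, 11), c(8, 90, 150, 60, 199))] <-
    d[cbind(c(3, 17, 25, 40, 11), c(8, 90, 150, 60, 199))] * 50
  fit <- suppressWarnings(rpca(d, lam = candes_lambda(d), max_iter = 4000))
  big <- which(abs(fit$S) > 0.1 * max(abs(d)))
  expect_setequal(big,
    (c(8, 90, 150, 60, 199) - 1) * 50 + c(3, 17, 25, 40, 11))
  expect_lt(sqrt(sum((fit$L - prob$L0)^2)) / sqrt(sum(prob$L0^2)), 1e-3)

  # decomposition identity within the stopping tolerance regime
  res <- d - fit$L - fit$S
  expect_equal(res, residuals(fit), tolerance = 1e-12)
  expect_lt(sqrt(sum(res^2)) / max(1, sqrt(sum(d^2))), 1e-5)

  # residual trace is recorded each iteration and is eventually tiny
  expect_identical(length(fit$residual_trace), fit$n_iter)

  # objective no worse than the trivial splits
  obj <- function(L, S)
    sum(svd(L, nu = 0, nv = 0)$d) + candes_lambda(d) * sum(abs(S))
  expect_lte(obj(fit$L, fit$S), obj(d, matrix(0, 50, 200)))
  expect_lte(obj(fit$L, fit$S), obj(matrix(0, 50, 200), d))
})

test_that("a huge sparsity weight forces S to zero and L to D", {
  d <- lr_plus_spikes(m = 30, n = 60, r = 2, frac = 0.02, seed = 5)$d
  fit <- suppressWarnings(rpca(d, lam = 1e6, max_iter = 500))
  expect_equal(max(abs(fit$S)), 0)
  expect_lt(max(abs(fit$L - d)), 1e-4 * max(abs(d)))
})

test_that("rpca S3 methods expose the fit", {
  d <- lr_plus_spikes(m = 20, n = 30, r = 1, frac = 0.02, seed = 6)$d
  fit <- suppressWarnings(rpca(d, max_iter = 300))
  expect_identical(fitted(fit), fit$L)
  expect_output(print(fit), "Robust PCA")
  sm <- summary(fit)
  expect_output(print(sm), "objective")
  expect_equal(sm$objective,
               sum(svd(fit$L)$d) + 0.01 * sum(abs(fit$S)), tolerance = 1e-8)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("candes_lambda follows the 1/sqrt(max dim) convention", {
  expect_equal(candes_lambda(matrix(0, 100, 300)), 1 / sqrt(300))
  expect_equal(candes_lambda(voltage_matrix(matrix(1, 192, 600), 20)),
               1 / sqrt(600))
})

test_that("rpca_denoise wraps a recording and returns matched metadata", {
  set.seed(8)
  base <- outer(0.2 + 0.05 * sin(1:192 / 5), 1 + 0.1 * cos(1:120 / 7))
  v <- voltage_matrix(base, frame_rate = 20)
  vc <- inject_spikes(v, spike_spec(35L, c(60L, 60L), 50))
  den <- suppressWarnings(rpca_denoise(vc, max_iter = 3000))
  expect_s3_class(den$clean, "eit_voltage")
  expect_identical(den$clean$frame_rate, 20)
  # the spike lands in S at the right position
  expect_gt(abs(den$spikes$data[35, 60]), 0.9 * abs(vc$data[35, 60] - base[35, 60]))
  off <- den$spikes$data; off[35, 60] <- 0
  expect_lt(max(abs(off)), 0.05 * abs(den$spikes$data[35, 60]))
  # and the clean part stays near the uncorrupted recording
  expect_lt(sqrt(sum((den$clean$data - base)^2)) / sqrt(sum(base^2)), 1e-3)
})
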