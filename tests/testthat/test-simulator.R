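test_that("breathing waveform is a raised cosine with the stated period and range", {
  b <- synth_breathing(600, frame_rate = 20, rate_bpm = 15, depth = 0.5)
  expect_true(all(b$values > 0 & b$values <= 1))
  expect_equal(min(b$values), 0.5, tolerance = 1e-12)   # 1 - depth
  expect_equal(max(b$values), 1, tolerance = 1e-12)
  # 15 bpm at 20 fps: cycle maxima exactly 80 frames apart
  peaks <- which(b$values > 1 - 1e-9)
  expect_equal(unique(diff(peaks)), 80L)

  # near-zero depth: essentially constant at 1
  b0 <- synth_breathing(200, depth = 1e-9)
  expect_equal(b0$values, rep(1, 200), tolerance = 1e-8)

  # jitter is reproducible and stays in range
  b1 <- synth_breathing(400, jitter = 0.1, seed = 7)
  b2 <- synth_breathing(400, jitter = 0.1, seed = 7)
  expect_identical(b1$values, b2$values)
  expect_true(all(b1$values > 0 & b1$values <= 1))

  expect_error(synth_breathing(600, rate_bpm = 80), "6, 60")
  expect_error(synth_breathing(600, depth = 1.5), "0, 1")
  expect_error(synth_breathing(10, rate_bpm = 15), "one breathing cycle")
})

test_that("phantom meshes partition into labeled regions with aligned electrodes", {
  for (ph in list(make_phantom("circular"), make_phantom("thorax"))) {
    expect_true(all(ph$region %in% 0:2))
    expect_true(all(c(1, 2) %in% ph$region))    # both lungs present
    expect_identical(length(ph$region), nrow(ph$tris))
    expect_identical(length(ph$electrode_edges), 16L)
  }
  het <- make_phantom("thorax", heterogeneous_left = TRUE)
  expect_true(all(c(1, 2, 3) %in% het$region))

  # circular phantom: electrodes equispaced on the unit circle
  ph <- make_phantom("circular")
  expect_equal(sort(ph$electrode_angles %% (2 * pi)),
               sort(2 * pi * (0:15) / 16), tolerance = 1e-12)
  for (e in ph$electrode_edges) {
    r <- sqrt(rowSums(ph$nodes[as.vector(e), ]^2))
    expect_equal(r, rep(1, length(r)), tolerance = 1e-12)
  }
})

test_that("forward model is time-invariant, linear in current, and reciprocal", {
  ph <- small_phantom()
  const <- structure(list(values = rep(0.8, 5), frame_rate = 20),
                     class = "eit_breathing")
  v <- forward_voltages(ph, const)
  expect_lt(max(abs(v$data - v$data[, 1])), 1e-10 * max(v$data))

  v2 <- forward_voltages(ph, const, current_mA = 2)
  expect_equal(v2$data, 2 * v$data, tolerance = 1e-10)

  # reciprocity on the homogeneous disc: drive (a,b), measure (c,d) equals
  # drive (c,d), measure (a,b)
  sig <- c("0" = 1, "1" = 1, "2" = 1)
  set.seed(11)
  for (i in 1:20) {
    pr <- sample(16L, 4L)
    I1 <- matrix(0, 16, 1); I1[pr[1]] <- 1e-3; I1[pr[2]] <- -1e-3
    I2 <- matrix(0, 16, 1); I2[pr[3]] <- 1e-3; I2[pr[4]] <- -1e-3
    U1 <- electrode_potentials(ph, sig, I1)
    U2 <- electrode_potentials(ph, sig, I2)
    m1 <- U1[pr[3]] - U1[pr[4]]
    m2 <- U2[pr[1]] - U2[pr[2]]
    expect_equal(m1, m2, tolerance = 1e-6 * max(abs(U1)))
  }
})

test_that("summed voltage waveform tracks breathing inversely", {
  setup <- shared_setup()
  expect_lt(cor(sum_waveform(setup$clean), setup$breathing$values), -0.9)
})

test_that("spike injection changes exactly the masked entries", {
  v <- voltage_matrix(matrix(abs(det_matrix(192, 40, seed = 5)) + 0.5, 192, 40), 20)

  expect_identical(inject_spikes(v, spike_spec(35, c(10, 10), 1))$data, v$data)

  out <- inject_spikes(v, spike_spec(35, c(10, 10), 50))
  diffmask <- out$data != v$data
  expect_identical(which(diffmask), which(row(v$data) == 35 & col(v$data) == 10))
  expect_equal(out$data[35, 10], 50 * v$data[35, 10])

  sp <- spike_spec(c(3, 7, 100), c(5, 12), 27)
  out <- inject_spikes(v, sp)
  expect_identical(sum(out$data != v$data), 3L * 8L)
  expect_identical(out$data[-c(3, 7, 100), ], v$data[-c(3, 7, 100), ])

  expect_error(inject_spikes(v, spike_spec(35, c(39, 41), 2)), "exceeds")
  expect_error(inject_spikes(v, spike_spec(250, c(1, 2), 2)), "exceed")
  expect_error(spike_spec(integer(0), c(1, 2), 2), "non-empty")
  expect_error(spike_spec(1, c(5, 2), 2), "start <= end")
  expect_error(spike_spec(1, c(1, 2), 0.5), ">= 1")
})

test_that("protocol sweeps enumerate the published injection lists", {
  mag <- protocol_sweep("magnitude")
  expect_length(mag, 19L)
  expect_equal(vapply(mag, function(s) s$magnitude, numeric(1)),
               c(1:10, seq(20, 100, 10)))
  expect_true(all(vapply(mag, function(s)
    identical(s$channels, 35L) && identical(s$frame_window, c(299L, 299L)),
    logical(1))))

  wid <- protocol_sweep("width")
  expect_length(wid, 11L)
  expect_true(all(vapply(wid, function(s) s$magnitude == 50, logical(1))))
  expect_equal(vapply(wid, function(s) diff(s$frame_window) + 1L, integer(1)),
               c(5L, seq(10L, 100L, 10L)))
  expect_true(all(vapply(wid, function(s) s$frame_window[1] == 299L, logical(1))))

  ch <- protocol_sweep("channels")
  expect_length(ch, 14L)
  expect_equal(vapply(ch, function(s) length(s$channels), integer(1)),
               c(5L, seq(10L, 100L, 10L), 150L, 190L, 192L))
  expect_true(all(vapply(ch, function(s)
    identical(s$frame_window, c(300L, 350L)) && s$magnitude == 50 &&
      identical(s$channels, seq_len(length(s$channels))), logical(1))))
})

test_that("the heterogeneous stress case is reproducible and in bounds", {
  hc1 <- heterogeneous_case(seed = 42)
  hc2 <- heterogeneous_case(seed = 42)
  expect_identical(hc1$spec$channels, hc2$spec$channels)
  expect_length(hc1$spec$channels, 50L)
  expect_true(all(hc1$spec$channels %in% 1:192))
  expect_equal(hc1$spec$magnitude, 27)
  expect_identical(diff(hc1$spec$frame_window) + 1L, 61L)
  expect_true(hc1$phantom$heterogeneous_left)
  expect_false(identical(heterogeneous_case(seed = 1)$spec$channels,
                         hc1$spec$channels))
})
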