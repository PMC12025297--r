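# Shared fixtures, all built in code.

# A small, fast phantom for physics tests (480 elements).
small_phantom <- function(style = "circular", heterogeneous_left = FALSE) {
  make_phantom(style, heterogeneous_left = heterogeneous_left,
               n_rings = 8L, n_theta = 32L)
}

# A valid 192-row recording with prescribed per-frame column sums:
# row 1 carries the target waveform, the rest a positive constant.
recording_with_sum <- function(sums, frame_rate = 20) {
  n <- length(sums)
  m <- matrix(1, 192L, n)
  m[1L, ] <- sums - 191
  voltage_matrix(m, frame_rate)
}

# Deterministic pseudo-random matrix (no RNG state side effects).
det_matrix <- function(nr, nc, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}

# Low-rank + sparse-corruption test problem at a voltage-like scale.
lr_plus_spikes <- function(m = 100L, n = 300L, r = 2L, frac = 0.02,
                           mag = 50, seed = 1L) {
  set.seed(seed)
  U <- matrix(rnorm(m * r, sd = 0.3), m, r)
  V <- matrix(rnorm(n * r, sd = 0.3), n, r)
  L0 <- U %*% t(V)
  n_c <- ceiling(frac * m * n)
  idx <- sample.int(m * n, n_c)
  S0 <- numeric(m * n)
  S0[idx] <- sample(c(-1, 1), n_c, TRUE) * mag * mean(abs(L0))
  S0 <- matrix(S0, m, n)
  list(d = L0 + S0, L0 = L0, S0 = S0, idx = idx)
}

# One shared full-scale simulation for the expensive pipeline tests:
# built lazily, once per test run.
.shared <- new.env(parent = emptyenv())
shared_setup <- function() {
  if (is.null(.shared$setup)) .shared$setup <- sweep_setup(seed = 1L)
  .shared$setup
}

# The three protocol sweeps, run once and reused by the acceptance blocks.
shared_sweeps <- function() {
  if (is.null(.shared$sweeps)) {
    s <- shared_setup()
    .shared$sweeps <- list(
      mag = run_magnitude_sweep(1L, setup = s),
      wid = run_width_sweep(1L, setup = s),
      chan = run_channel_sweep(1L, setup = s))
  }
  .shared$sweeps
}
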