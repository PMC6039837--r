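make_run <- function(data, fs = 200) as_run(data, fs_hz = fs)

sine_run <- function(freqs, fs = 200, dur = 6, delays = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  data <- t(mapply(function(f, d) sin(2 * pi * f * (t - d)), freqs, delays))
  as_run(data, fs_hz = fs)
}

test_that("epoch segmentation follows the floor rule", {
  fs <- 100
  run300 <- make_run(matrix(rnorm(2 * 300 * fs), 2), fs)
  expect_length(segment_epochs(run300, 3), 100)

  run3 <- make_run(matrix(rnorm(2 * 3 * fs), 2), fs)
  expect_length(segment_epochs(run3, 3), 1)

  run59 <- make_run(matrix(rnorm(2 * 590), 2), fs)  # 5.9 s
  eps <- segment_epochs(run59, 3)
  expect_length(eps, 1)
  expect_equal(ncol(eps[[1]]), 300)

  run2 <- make_run(matrix(rnorm(2 * 200), 2), fs)
  expect_error(segment_epochs(run2, 3), "shorter")
})

test_that("run constructor validates input", {
  expect_error(as_run(matrix(1:10, 1), 100), "2 channels")
  m <- matrix(rnorm(20), 2); m[1, 3] <- NaN
  expect_error(as_run(m, 100), "finite")
  expect_error(as_run(matrix(rnorm(20), 2), -1), "positive")
})

test_that("bin phase of a sinusoid has constant slope 2*pi*f", {
  fs <- 200; f <- 6
  run <- sine_run(c(f, f), fs = fs)
  ph <- bin_phase(run$data, fs, f)
  interior <- 150:1000
  slopes <- diff(ph[1, interior])
  slopes <- (slopes + pi) %% (2 * pi) - pi
  expect_equal(mean(slopes) * fs / (2 * pi), f, tolerance = 1e-6)
  expect_lt(stats::sd(slopes) * fs / (2 * pi), 1e-6)
})

test_that("delayed sinusoid gives the closed-form constant phase lag", {
  fs <- 200; f <- 10; dt <- 0.012
  run <- sine_run(c(f, f), fs = fs, delays = c(0, dt))
  ph <- bin_phase(run$data, fs, f)
  d <- ph[1, 150:1000] - ph[2, 150:1000]
  d <- (d + pi) %% (2 * pi) - pi
  expect_equal(mean(d), 2 * pi * f * dt, tolerance = 1e-6)
  expect_lt(stats::sd(d), 1e-6)
  # and the PLV of a constant lag is 1
  expect_equal(plv_pair(ph[1, 150:1000], ph[2, 150:1000]), 1,
               tolerance = 1e-9)
})

test_that("white-noise phases cover the circle and bin edges are rejected", {
  set.seed(1)
  run <- make_run(matrix(rnorm(2 * 1200), 2), fs = 200)
  ph <- bin_phase(run$data, 200, 10)
  expect_true(all(ph > -pi & ph <= pi))
  expect_gt(diff(range(ph)), 5.5)  # spans most of (-pi, pi]
  expect_error(bin_phase(run$data, 200, 100), "Nyquist")
  expect_error(bin_phase(run$data, 200, 0), "Nyquist")
})

test_that("plv_pair reproduces hand-computed phasor means", {
  expect_equal(plv_pair(seq(0, 5, by = 0.1) + 0.7, seq(0, 5, by = 0.1)), 1.0)
  expect_equal(plv_pair(c(0, pi, 0, pi), c(0, 0, 0, 0)), 0.0,
               tolerance = 1e-12)
  expect_equal(plv_pair(c(0, pi / 2), c(0, 0)), sqrt(2) / 2)
  expect_error(plv_pair(numeric(0), numeric(0)), "empty")
  expect_error(plv_pair(1:3, 1:4), "mismatch")
})

test_that("plv is invariant to a constant phase offset", {
  set.seed(2)
  a <- cumsum(rnorm(500, 0.2, 0.1)); b <- cumsum(rnorm(500, 0.2, 0.1))
  expect_equal(plv_pair(a + 1.3, b), plv_pair(a, b))
  expect_equal(plv_pair(a, b - 2.2), plv_pair(a, b))
})

test_that("band matrix of identical channels is 1 off-diagonal", {
  fs <- 120
  set.seed(3)
  x <- rnorm(9 * fs)
  run <- as_run(rbind(x, x, x), fs_hz = fs)
  bc <- band_plv_matrix(run, "theta")
  off <- bc$matrix[upper.tri(bc$matrix)]
  expect_equal(off, rep(1, 3), tolerance = 1e-9)
  expect_equal(diag(bc$matrix), rep(0, 3), ignore_attr = TRUE)
  expect_equal(bc$n_epochs_used, 3)
})

test_that("independent white-noise channels match a Monte-Carlo phase oracle", {
  # For white Gaussian input the phase of a 1-Hz band is the phase of a
  # band-restricted complex Gaussian process, which the oracle simulates
  # directly in the frequency domain -- exact in distribution, sharing no
  # code with the estimator.
  fs <- 120; dur <- 60
  set.seed(7)
  run <- as_run(matrix(rnorm(4 * dur * fs), 4), fs_hz = fs)
  bc <- band_plv_matrix(run, "theta")
  off <- bc$matrix[upper.tri(bc$matrix)]
  est <- mean(off)
  expect_true(all(off < 0.9))        # far below locking
  expect_equal(bc$n_epochs_used, 20)

  epn <- 3 * fs; trim <- round(0.25 * fs)
  sim_phase <- function(f0) {
    freq <- (0:(epn - 1)) / epn * fs
    sel <- freq >= f0 - 0.5 & freq <= f0 + 0.5 & freq > 0 & freq < fs / 2
    spec <- complex(real = rnorm(epn), imaginary = rnorm(epn)) * sel
    Arg(stats::fft(spec, inverse = TRUE))
  }
  set.seed(42)
  sims <- replicate(400, {
    p1 <- sim_phase(5); p2 <- sim_phase(5)
    idx <- (trim + 1):(epn - trim)
    Mod(mean(exp(1i * (p1[idx] - p2[idx]))))
  })
  # est averages 20 epochs x 4 bins x 6 (correlated) pairs; allow ~2 SE with
  # a conservative effective-sample count of epochs x bins x 2
  se_est <- stats::sd(sims) / sqrt(20 * 4 * 2)
  expect_lt(abs(est - mean(sims)), 2 * se_est + 2 * stats::sd(sims) / sqrt(400))
})

test_that("band matrix is invariant to channel permutation", {
  prof <- coupling_profile(5, 2, within = 0.5, global = 0.1,
                           run_length_s = 9, fs_hz = 120)
  run <- generate_run(prof, seed = 4)
  bc <- band_plv_matrix(run, "alpha")
  perm <- c(3, 1, 5, 2, 4)
  run_p <- as_run(run$data[perm, ], fs_hz = run$fs_hz,
                  channel_names = run$channel_names[perm])
  bc_p <- band_plv_matrix(run_p, "alpha")
  expect_equal(unname(bc_p$matrix), unname(bc$matrix[perm, perm]),
               tolerance = 1e-12)
})

test_that("estimator averages per-epoch PLV, not pooled samples", {
  # two segments with opposite constant lags: per-epoch PLV is 1 in each
  # epoch (mean 1), pooling the samples would cancel the phasors
  fs <- 120; t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  f <- 6
  seg1 <- rbind(sin(2 * pi * f * t), sin(2 * pi * f * t + pi / 2))
  seg2 <- rbind(sin(2 * pi * f * t), sin(2 * pi * f * t - pi / 2))
  run <- as_run(cbind(seg1, seg2), fs_hz = fs)
  bc <- band_plv_matrix(run, "theta", bins = f)
  expect_equal(bc$matrix[1, 2], 1, tolerance = 0.05)
  # pooled-sample estimator would be ~|mean(exp(+i pi/2)) + exp(-i pi/2)| ~ 0
  ph <- bin_phase(run$data, fs, f)
  pooled <- plv_pair(ph[1, ], ph[2, ])
  expect_lt(pooled, 0.2)
})

test_that("bands own the documented bins and empty bands error", {
  expect_equal(band_bins("theta"), 4:7)
  expect_equal(band_bins("alpha"), 8:11)
  expect_equal(band_bins("beta"), 12:28)
  expect_length(c(band_bins("theta"), band_bins("alpha"), band_bins("beta")),
                25)
  expect_error(band_bins("theta", bins = 20:28), "no assigned bins")
})

test_that("connectivity matrices round-trip through TSV", {
  prof <- coupling_profile(4, 2, within = 0.4, global = 0.1,
                           run_length_s = 6, fs_hz = 120)
  run <- generate_run(prof, seed = 8)
  bc <- band_plv_matrix(run, "theta")
  path <- tempfile(fileext = ".tsv")
  write_connectivity(bc, path)
  back <- read_connectivity(path, band = "theta")
  expect_equal(back$matrix, bc$matrix, tolerance = 1e-12)
  unlink(path)
})
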