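test_that("Slepian tapers are orthonormal and band-concentrated", {
  tp <- dpss_tapers(200, nw = 4, k = 7)
  expect_equal(dim(tp), c(200, 7))
  expect_equal(crossprod(tp), diag(7), tolerance = 1e-8)
  # first taper concentrates its energy inside the design band
  spec <- abs(fft(c(tp[, 1], rep(0, 1800))))^2
  inband <- sum(spec[1:41]) + sum(spec[1961:2000])  # |f| <= 4/200 of fs
  expect_gt(inband / sum(spec), 0.99)
})

test_that("auto-spectrum of a pure sinusoid peaks at its frequency bin", {
  fs <- 250; tt <- (0:499) / fs
  data <- array(0, dim = c(2, 1, 500))
  data[1, 1, ] <- sin(2 * pi * 10 * tt)
  data[2, 1, ] <- sin(2 * pi * 10 * tt + 1)
  ts <- node_timeseries(data, fs = fs)
  cs <- multitaper_cross_spectra(ts)
  expect_equal(cs$freqs[which.max(auto_spectrum(cs, 1))], 10)
})

test_that("identical channels have an exactly real cross-spectrum", {
  set.seed(1)
  x <- array(rnorm(5 * 1 * 500), dim = c(5, 1, 500))
  data <- array(0, dim = c(5, 2, 500))
  data[, 1, ] <- x[, 1, ]
  data[, 2, ] <- x[, 1, ]
  cs <- multitaper_cross_spectra(node_timeseries(data, fs = 250))
  expect_true(all(Im(cross_spectrum(cs, 1, 2)) == 0))
  expect_true(all(wpli(cs)$wpli == 0))
})

test_that("white noise gives an approximately flat auto-spectrum", {
  set.seed(2)
  data <- array(rnorm(200 * 1 * 500), dim = c(200, 1, 500))
  cs <- multitaper_cross_spectra(node_timeseries(data, fs = 250))
  s <- auto_spectrum(cs, 1)
  expect_lt(max(s) / min(s), 3)
})

test_that("wPLI reproduces its closed forms on constructed cross-spectra", {
  # observations with Im(S_12) = {+1, +1, -1}: |mean|/mean|.| = 1/3
  coefs <- array(complex(real = 0), dim = c(1, 2, 3))
  coefs[1, 1, ] <- c(1, 1, 1)
  coefs[1, 2, ] <- c(-1i, -1i, 1i)
  w <- wpli(cross_spectra_from_coefs(coefs))
  expect_equal(w$wpli[1, 1, 2], 1 / 3)

  # all Im the same sign -> exactly 1
  coefs[1, 2, ] <- c(-1i, -2i, -3i)
  expect_equal(wpli(cross_spectra_from_coefs(coefs))$wpli[1, 1, 2], 1)

  # zero imaginary part -> 0 under the 0/0 convention
  coefs[1, 2, ] <- c(2, 3, 4)
  expect_equal(wpli(cross_spectra_from_coefs(coefs))$wpli[1, 1, 2], 0)
})

test_that("wPLI from simulated oscillators matches phase-lag expectations", {
  ts <- simulate_coupled_oscillators(
    2, list(list(i = 1, j = 2, freq_Hz = 10, phase_lag_rad = pi / 2, snr = Inf)),
    n_trials = 20, fs = 250, duration_s = 2, seed = 2)
  w <- wpli(multitaper_cross_spectra(ts))
  bin10 <- which(w$freqs == 10)
  expect_gt(w$wpli[bin10, 1, 2], 0.999)

  ts0 <- simulate_coupled_oscillators(
    2, list(list(i = 1, j = 2, freq_Hz = 10, phase_lag_rad = 0, snr = Inf)),
    n_trials = 20, fs = 250, duration_s = 2, seed = 3)
  w0 <- wpli(multitaper_cross_spectra(ts0))
  expect_equal(w0$wpli[bin10, 1, 2], 0)
})

test_that("wPLI is invariant to positive channel rescaling and stays in [0, 1]", {
  set.seed(5)
  coefs <- array(complex(real = rnorm(3 * 4 * 10), imaginary = rnorm(3 * 4 * 10)),
                 dim = c(3, 4, 10))
  w1 <- wpli(cross_spectra_from_coefs(coefs))$wpli
  coefs2 <- coefs
  coefs2[, 2, ] <- 7.3 * coefs2[, 2, ]
  w2 <- wpli(cross_spectra_from_coefs(coefs2))$wpli
  expect_equal(w1, w2, tolerance = 1e-12)
  expect_true(all(w1 >= 0 & w1 <= 1))
  # symmetric with a zero diagonal
  expect_equal(w1, aperm(w1, c(1, 3, 2)))
  expect_true(all(vapply(1:4, function(i) all(w1[, i, i] == 0), logical(1))))
})

test_that("wPLI agrees with an explicit-loop transcription of the formula", {
  set.seed(6)
  coefs <- array(complex(real = rnorm(2 * 4 * 10), imaginary = rnorm(2 * 4 * 10)),
                 dim = c(2, 4, 10))
  w <- wpli(cross_spectra_from_coefs(coefs))$wpli
  expect_equal(w, wpli_oracle(coefs), tolerance = 1e-12)
})

test_that("L2 aggregation across bins follows the Euclidean norm", {
  W2 <- array(0, dim = c(2, 3, 3))
  W2[1, 1, 2] <- W2[1, 2, 1] <- 0.3
  W2[2, 1, 2] <- W2[2, 2, 1] <- 0.4
  sc <- structure(list(wpli = W2, freqs = c(1, 2),
                       node_coords = matrix(rnorm(9), 3, 3)),
                  class = "spectral_connectivity")
  conn <- aggregate_l2(sc)
  expect_equal(conn$W[1, 2], 0.5)
  expect_equal(conn$n_bins_aggregated, 2)

  # single bin: identity; all-ones over n bins: sqrt(n)
  sc1 <- sc; sc1$wpli <- W2[1, , , drop = FALSE]; sc1$freqs <- 1
  expect_equal(aggregate_l2(sc1)$W, W2[1, , ])
  scn <- sc
  scn$wpli <- array(rep(1 - diag(3), each = 200), dim = c(200, 3, 3))
  scn$freqs <- seq(0.5, 100, 0.5)
  expect_equal(aggregate_l2(scn)$W[1, 2], sqrt(200))
})

test_that("mean node distance matches hand values and a brute-force loop", {
  expect_equal(mean_node_distance(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(mean_node_distance(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               4 / 3)
  set.seed(7)
  coords <- matrix(rnorm(30), 10, 3)
  acc <- 0; np <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    acc <- acc + sqrt(sum((coords[i, ] - coords[j, ])^2)); np <- np + 1
  }
  expect_equal(mean_node_distance(coords), acc / np)
  expect_error(mean_node_distance(matrix(0, 1, 3)), "2 nodes")
})

test_that("cross-spectra preconditions are enforced", {
  data <- array(rnorm(2 * 2 * 500), dim = c(2, 2, 500))
  ts <- node_timeseries(data, fs = 250)
  expect_error(multitaper_cross_spectra(ts, fmax = 130), "Nyquist")
  one_trial <- node_timeseries(array(rnorm(1 * 2 * 500), c(1, 2, 500)), fs = 250)
  expect_error(multitaper_cross_spectra(one_trial), "2 trials")
})
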