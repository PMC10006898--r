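test_that("RSS attenuation line has the pinned endpoints and domain", {
  head <- default_head()
  expect_identical(rss_coefficient(0, head), 1.0)
  expect_equal(rss_coefficient(2 * head$radius_cm, head), 0.01)
  expect_equal(rss_coefficient(10, head), 0.505)
  # monotone decreasing and bounded on the legal domain
  d <- seq(0, 20, by = 0.5)
  rho <- rss_coefficient(d, head)
  expect_true(all(diff(rho) < 0))
  expect_true(all(rho >= 0.01 - 1e-12 & rho <= 1))
  expect_error(rss_coefficient(-1, head), "outside")
  expect_error(rss_coefficient(21, head), "outside")
})

test_that("conductivity draws respect bounds, mean, and fixed-per-recording rule", {
  degenerate <- head_model(conductivity = c(0.5, 0.5))
  expect_true(all(sample_conductivity(degenerate, 10, 3, seed = 1) == 0.5))
  besa <- head_model(conductivity = c(0.2, 0.4))
  z <- sample_conductivity(besa, 200, 5, seed = 2)
  expect_true(all(z >= 0.2 & z <= 0.4))
  big <- sample_conductivity(default_head(), 1000, 100, seed = 3)
  se <- stats::sd(big) / sqrt(length(big))
  expect_lt(abs(mean(big) - 0.5), 3 * se)
  # same seed -> identical draws (held fixed for a recording)
  expect_identical(z, sample_conductivity(besa, 200, 5, seed = 2))
})

test_that("gain matrix rows follow the inverse-square law construction", {
  head <- default_head()
  sens <- sensor_array(rbind(c(0, 0, 10)), radius_cm = 10)
  g <- gain_matrix(c(0, 0, 5), sens, conductivities = 1 / (4 * pi))
  expect_equal(as.numeric(g), c(0, 0, 0.04))
  g0 <- gain_matrix(c(0, 0, 0), sens, conductivities = 1 / (4 * pi))
  expect_equal(as.numeric(g0), c(0, 0, 0.01))
  # linearity in 1/zeta
  g2 <- gain_matrix(c(0, 0, 5), sens, conductivities = 2 / (4 * pi))
  expect_equal(2 * as.numeric(g2), as.numeric(g))
  expect_error(gain_matrix(c(0, 0, 10), sens, 0.5), "coincides")

  # doubling source-sensor distance along a fixed direction scales |g| by 1/4
  ga <- gain_matrix(c(0, 0, 8), sens, 0.5)
  gb <- gain_matrix(c(0, 0, 6), sens, 0.5)
  expect_equal(sqrt(sum(gb^2)) / sqrt(sum(ga^2)), 1 / 4, tolerance = 1e-12)
})

test_that("simulation: zero-noise exactness, linearity, superposition, determinism", {
  head <- default_head()
  sens <- sample_uniform_sensors(head, 24, seed = 5)
  d1 <- random_dipole(1)
  d2 <- random_dipole(2)

  rec0 <- simulate_recording(list(d1), sens, head, 5, noise_model(sigma = 0),
                             seed = 9)
  expect_true(all(rec0$signals == rec0$truth$noiseless))

  # scaling strength scales the noiseless signal exactly
  d1b <- dipole(d1$location, d1$orientation, 3 * d1$strength)
  rec0b <- simulate_recording(list(d1b), sens, head, 5, noise_model(sigma = 0),
                              seed = 9)
  expect_equal(rec0b$truth$noiseless, 3 * rec0$truth$noiseless)

  # superposition under identical conductivity draws: simulate A and B jointly,
  # then reconstruct each dipole's share from the stored draws
  recAB <- simulate_recording(list(d1, d2), sens, head, 5,
                              noise_model(sigma = 0), seed = 9)
  share <- function(rec, i) {
    p <- rec$truth$param[i, , drop = FALSE]
    predict_signals(p, rec$sensors, rec$head,
                    zeta = rec$truth$zeta[, i, drop = FALSE])
  }
  expect_equal(share(recAB, 1) + share(recAB, 2), recAB$truth$noiseless,
               tolerance = 1e-12)

  # bit-identical under identical seeds
  r1 <- simulate_recording(list(d1), sens, head, 50,
                           noise_model(target_snr = 20), seed = 4)
  r2 <- simulate_recording(list(d1), sens, head, 50,
                           noise_model(target_snr = 20), seed = 4)
  expect_identical(r1$signals, r2$signals)

  # zero-strength dipole: pure noise with the requested sigma
  d0 <- dipole(d1$location, d1$orientation, 0)
  recn <- simulate_recording(list(d0), sens, head, 2000,
                             noise_model(sigma = 0.3), seed = 8)
  expect_equal(stats::sd(as.vector(recn$signals)), 0.3, tolerance = 0.02)
  expect_equal(snr_of(recn), 0)

  expect_warning(
    simulate_recording(list(), sens, head, 3, noise_model(sigma = 1), seed = 1),
    "pure noise")
  expect_error(
    simulate_recording(list(d0), sens, head, 3, noise_model(target_snr = 20),
                       seed = 1), "undefined")
})

test_that("realized SNR is close to target and degenerates sensibly", {
  head <- default_head()
  sens <- sample_uniform_sensors(head, 36, seed = 6)
  d <- random_dipole(3)
  rec <- simulate_recording(list(d), sens, head, 500,
                            noise_model(target_snr = 20), seed = 10)
  s <- snr_of(rec)
  expect_gt(s, 16); expect_lt(s, 24)
  rec0 <- simulate_recording(list(d), sens, head, 10, noise_model(sigma = 0),
                             seed = 1)
  expect_identical(snr_of(rec0), Inf)
  rec$truth <- NULL
  expect_error(snr_of(rec), "unavailable|no generating truth")
})

test_that("noise model validates its arguments", {
  expect_error(noise_model(), "exactly one")
  expect_error(noise_model(sigma = 1, target_snr = 2), "exactly one")
  expect_error(noise_model(sigma = -1), ">= 0")
  expect_error(noise_model(target_snr = 0), "> 0")
})
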