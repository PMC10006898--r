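test_that("prediction is consistent with the generator and linear in strength", {
  head <- default_head()
  sens <- sample_uniform_sensors(head, 20, seed = 2)
  d <- random_dipole(4)
  rec <- simulate_recording(list(d), sens, head, 10, noise_model(sigma = 0),
                            seed = 3)
  p <- rec$truth$param
  pred <- predict_signals(p, sens, head, zeta = rec$truth$zeta)
  expect_equal(pred, rec$truth$noiseless, tolerance = 1e-14)
  p0 <- p; p0[, "s"] <- 0
  expect_equal(predict_signals(p0, sens, head, rec$truth$zeta), rep(0, 20),
               ignore_attr = TRUE)
  p2 <- p; p2[, "s"] <- 2 * p[, "s"]
  expect_equal(predict_signals(p2, sens, head, rec$truth$zeta), 2 * pred)
})

test_that("the residual cost has its defining values and symmetries", {
  head <- default_head()
  sens <- sample_uniform_sensors(head, 20, seed = 2)
  d <- random_dipole(4)
  rec <- simulate_recording(list(d), sens, head, 10, noise_model(sigma = 0),
                            seed = 3)
  cfg <- solver_config(mode = "clairvoyant")
  expect_equal(fit_cost(rec$truth$param, rec, cfg), 0)

  # single sensor, single sample, residual 2 -> J = 1/2 * 2^2 = 2
  one <- rec
  one$signals <- rec$signals[1, 1, drop = FALSE] + 2
  one$sensors <- sensor_array(rec$sensors$positions[1, , drop = FALSE],
                              radius_cm = head$radius_cm)
  one$truth$zeta <- rec$truth$zeta[1, , drop = FALSE]
  one$n_samples <- 1L
  expect_equal(fit_cost(rec$truth$param, one, cfg), 2)

  # relabeling sensors leaves J unchanged when W = I
  perm <- withr::with_seed(1, sample(20))
  shuf <- rec
  shuf$signals <- rec$signals[perm, , drop = FALSE]
  shuf$sensors <- sensor_array(rec$sensors$positions[perm, , drop = FALSE],
                               radius_cm = head$radius_cm)
  shuf$truth$zeta <- rec$truth$zeta[perm, , drop = FALSE]
  guess <- perturb_parameters(rec$truth$param, head, seed = 5)
  expect_equal(fit_cost(guess, shuf, cfg), fit_cost(guess, rec, cfg))
})

test_that("localization error matches hand-computed distances and matching", {
  # mm-scale examples, computed directly from the distance formula
  expect_equal(
    localization_error(c(9.11, 32.07, 38.54), c(9.13, 32.06, 38.52)),
    sqrt(0.02^2 + 0.01^2 + 0.02^2), ignore_attr = TRUE)
  expect_equal(
    round(localization_error(c(-15.01, -29.78, 59.42), c(-34, -17, 69)), 2),
    24.81, ignore_attr = TRUE)
  expect_equal(localization_error(c(1, 2, 3), c(1, 2, 3)), 0,
               ignore_attr = TRUE)
  expect_error(localization_error(rbind(c(1, 2, 3), c(4, 5, 6)), c(1, 2, 3)),
               "different dipole counts")
  # estimates in permuted order are re-matched by total distance
  truth <- rbind(c(2, 0, 5), c(-2, 0, 5))
  est <- rbind(c(-2, 0.1, 5), c(2.1, 0, 5))
  err <- localization_error(truth, est)
  expect_equal(attr(err, "order"), c(2L, 1L), ignore_attr = TRUE)
  expect_equal(as.numeric(err), c(0.1, 0.1), tolerance = 1e-12)
})

test_that("noiseless single-dipole fits recover the truth exactly", {
  head <- default_head()
  worst_loc <- 0
  for (seed in 1:20) {
    d <- random_dipole(seed)
    sens <- sample_uniform_sensors(head, 36, seed = 100 + seed)
    rec <- simulate_recording(list(d), sens, head, 5, noise_model(sigma = 0),
                              seed = 200 + seed)
    ig <- perturb_parameters(rec$truth$param, head, seed = 300 + seed,
                             offset_cm = 0.5)
    fit <- fit_dipoles(rec, 1, solver_config(mode = "clairvoyant",
                                             initial_guess = ig,
                                             multistart = 1))
    loc_err <- localization_error(rec$truth$param, fit$estimate)
    worst_loc <- max(worst_loc, loc_err)
    expect_lt(loc_err, 1e-3)
    expect_true(all(abs(fit$estimate[, 4:6] - rec$truth$param[, 4:6]) < 1e-4))
    expect_lt(abs(fit$estimate[, 7] - d$strength), 1e-4)
    expect_lte(fit$constraint_residuals, 1e-6)
  }
})

test_that("fits satisfy the unit-norm constraint and report monotone cost", {
  head <- default_head()
  for (seed in c(1, 2, 3)) {
    d <- random_dipole(seed + 40)
    sens <- sample_uniform_sensors(head, 30, seed = seed)
    rec <- simulate_recording(list(d), sens, head, 100,
                              noise_model(target_snr = 20), seed = seed + 7)
    fit <- fit_dipoles(rec, 1, solver_config(multistart = 4, seed = seed))
    expect_true(all(fit$constraint_residuals <= 1e-6))
    tr <- fit$cost_trace
    expect_true(all(diff(tr) <= 1e-8 * (1 + tr[-length(tr)])))
    expect_gte(fit$final_cost, 0)
  }
})

test_that("solver matches the independent grid-search oracle", {
  head <- default_head()
  for (seed in c(5, 17)) {
    d <- random_dipole(seed)
    sens <- sample_uniform_sensors(head, 36, seed = seed + 50)
    rec <- simulate_recording(list(d), sens, head, 150,
                              noise_model(target_snr = 50), seed = seed + 60)
    orc <- oracle_single_dipole(rec, mode = "clairvoyant")
    fit <- fit_dipoles(rec, 1, solver_config(mode = "clairvoyant",
                                             multistart = 4, seed = 1))
    expect_lt(euclidean_distance(orc$location, fit$estimate[, 1:3]),
              max(orc$grid_resolution, 0.05))
  }
})

test_that("conductivity mismatch, not noise, dominates expected-mode error", {
  fx <- make_fixture("table2", seed = 1)
  rec <- simulate_recording(list(fx$dipoles[[1]]), fx$sensors, fx$head, 250,
                            noise_model(target_snr = 20), seed = 1001)
  err_mm <- sapply(c("clairvoyant", "expected"), function(mode) {
    f <- fit_dipoles(rec, 1, solver_config(mode = mode, multistart = 4))
    10 * f$localization_error_cm
  })
  expect_lt(err_mm[["clairvoyant"]], 0.5)
  expect_gt(err_mm[["expected"]], 10 * err_mm[["clairvoyant"]])
})

test_that("solver input validation and under-determination warnings work", {
  head <- default_head()
  d <- random_dipole(9)
  sens <- sample_uniform_sensors(head, 5, seed = 1)
  rec <- simulate_recording(list(d), sens, head, 20,
                            noise_model(target_snr = 20), seed = 2)
  expect_warning(fit_dipoles(rec, 1, solver_config(multistart = 2)),
                 "under-determined")
  sens2 <- sample_uniform_sensors(head, 12, seed = 1)
  rec2 <- simulate_recording(list(d), sens2, head, 20,
                             noise_model(target_snr = 20), seed = 2)
  bad <- solver_config(initial_guess = c(12, 0, 1, 0, 0, 1, 0.1))
  expect_error(fit_dipoles(rec2, 1, bad), "inside the hemisphere")
  suppressWarnings(
    expect_error(fit_dipoles(rec2, 2,
                             solver_config(mode = "clairvoyant",
                                           initial_guess = rbind(rep(0.5, 7),
                                                                 rep(0.4, 7)))),
                 "conductivity draws"))
})
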