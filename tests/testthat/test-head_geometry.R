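test_that("spherical -> Cartesian matches the defining identities", {
  expect_equal(drop(spherical_to_cartesian(10, 0, 0)), c(x = 0, y = 0, z = 10))
  expect_equal(drop(spherical_to_cartesian(10, pi / 2, 0)),
               c(x = 10, y = 0, z = 0), tolerance = 1e-12)
  # location recovered from its printed Cartesian coordinates
  r <- sqrt(2.25^2 + 0.82^2 + 6.58^2)
  p <- drop(spherical_to_cartesian(r, acos(6.58 / r), atan2(0.82, 2.25)))
  expect_equal(unname(p), c(2.25, 0.82, 6.58), tolerance = 1e-12)
  expect_error(spherical_to_cartesian(10, pi, 0), "theta")
  expect_error(spherical_to_cartesian(10, 0.1, -0.2), "phi")
  expect_error(spherical_to_cartesian(-1, 0.1, 0.2), "nonnegative")
})

test_that("Cartesian -> spherical inverts exactly and rejects z < 0", {
  expect_equal(drop(cartesian_to_spherical(c(0, 0, 10))),
               c(r = 10, theta = 0, phi = 0))
  expect_equal(drop(cartesian_to_spherical(c(10, 0, 0))),
               c(r = 10, theta = pi / 2, phi = 0))
  expect_equal(drop(cartesian_to_spherical(c(2.25, 0.82, 6.58)))[["r"]],
               sqrt(2.25^2 + 0.82^2 + 6.58^2))
  expect_error(cartesian_to_spherical(c(1, 1, -0.5)), "below the hemisphere")
})

test_that("coordinate round trip is identity to 1e-12 relative", {
  pts <- withr::with_seed(11, {
    n <- 1000
    cbind(r = runif(n, 0.01, 10), theta = runif(n, 0, pi / 2),
          phi = runif(n, 0, 2 * pi - 1e-9))
  })
  xyz <- spherical_to_cartesian(pts[, "r"], pts[, "theta"], pts[, "phi"])
  back <- cartesian_to_spherical(xyz)
  expect_equal(back[, "r"], pts[, "r"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back[, "theta"], pts[, "theta"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back[, "phi"], pts[, "phi"], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("uniform sensor sampling is on-scalp, reproducible, area-uniform", {
  head <- default_head()
  s <- sample_uniform_sensors(head, 128, seed = 7)
  expect_equal(s$m, 128L)
  expect_true(all(s$positions[, 3] >= 0))
  expect_equal(sqrt(rowSums(s$positions^2)), rep(10, 128),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(s$positions,
                   sample_uniform_sensors(head, 128, seed = 7)$positions)
  one <- sample_uniform_sensors(head, 1, seed = 0)
  expect_equal(sqrt(sum(one$positions^2)), 10)
  expect_error(sample_uniform_sensors(head, 0, seed = 1), "positive count")

  # E[z] = radius/2 for area-uniform sampling on the hemisphere
  big <- sample_uniform_sensors(head, 1e5, seed = 3)
  z <- big$positions[, 3]
  se <- stats::sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z) - 5), 3 * se)

  # chi-square over equal-area bins (cos(theta) x phi)
  sph <- cartesian_to_spherical(sample_uniform_sensors(head, 1e4, seed = 9)$positions)
  bins <- table(cut(cos(sph[, "theta"]), seq(0, 1, by = 0.2)),
                cut(sph[, "phi"], seq(0, 2 * pi, length.out = 9)))
  chi <- stats::chisq.test(as.vector(bins))
  expect_gt(chi$p.value, 0.001)
})

test_that("standard montage loads, projects radially, and validates input", {
  head85 <- head_model(radius_cm = 8.5)
  mont <- load_standard_montage("biosemi64", head85)
  expect_equal(mont$m, 64L)
  expect_equal(sqrt(rowSums(mont$positions^2)), rep(8.5, 64),
               tolerance = 1e-9, ignore_attr = TRUE)
  mont10 <- load_standard_montage("biosemi64", default_head())
  # same directions, rescaled norms
  expect_equal(mont10$positions / 10, mont$positions / 8.5, tolerance = 1e-12)

  f <- tempfile(fileext = ".txt")
  writeLines(c("# unit-sphere directions", "A 1 0 0", "B 0 1 0",
               "C 0 0 1"), f)
  cust <- load_standard_montage(f, default_head())
  expect_equal(sqrt(rowSums(cust$positions^2)), rep(10, 3),
               ignore_attr = TRUE)
  expect_error(load_standard_montage("no-such-montage", default_head()),
               "unknown montage")
  writeLines(c("A 1 0", "B 0 1 0 0 9"), f)
  expect_error(load_standard_montage(f, default_head()), "malformed")
})

test_that("euclidean distance is symmetric and matches direct arithmetic", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(0, 0, 10)), 10)
  expect_equal(euclidean_distance(c(2.25, 0.82, 6.58), c(2.25, 0.82, 6.58)), 0)
  d <- sqrt(2.25^2 + 0.82^2 + (10 - 6.58)^2)
  expect_equal(euclidean_distance(c(2.25, 0.82, 6.58), c(0, 0, 10)), d)
  expect_equal(euclidean_distance(c(0, 0, 10), c(2.25, 0.82, 6.58)), d)
})

test_that("sensor arrays reject off-scalp or duplicate positions", {
  expect_error(sensor_array(rbind(c(1, 0, 0), c(0, 1, 0)), radius_cm = 10),
               "on the scalp")
  p <- rbind(c(10, 0, 0), c(10, 0, 0))
  expect_error(sensor_array(p, radius_cm = 10), "distinct")
})
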