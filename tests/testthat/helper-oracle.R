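# Shared helpers: small scenario builders and an independent grid-search
# oracle for single-dipole fits.

default_head <- function() head_model(radius_cm = 10, conductivity = c(0.1, 0.9))

# a random interior dipole, seeded
random_dipole <- function(seed, head = default_head()) {
  withr::with_seed(seed, {
    repeat {
      loc <- stats::runif(3, -0.6, 0.6) * head$radius_cm
      loc[3] <- abs(loc[3])
      r <- sqrt(sum(loc^2))
      if (r > 0.2 * head$radius_cm && r < 0.8 * head$radius_cm && loc[3] > 0.1)
        break
    }
    mu <- stats::rnorm(3)
    dipole(loc, mu, strength = stats::runif(1, 0.1, 0.5), normalize = TRUE)
  })
}

# Independent oracle: dense location grid; at each node the moment s*mu is the
# exact solution of an ordinary linear least squares (lm.fit) against the
# sensor means; the best node is refined on a shrinking local grid. No code
# shared with the package's optimizer.
oracle_single_dipole <- function(recording, mode = "clairvoyant",
                                 n_grid = 5, n_refine = 6) {
  head <- recording$head
  sens <- recording$sensors
  zeta <- if (mode == "clairvoyant") recording$truth$zeta[, 1] else
    rep((head$conductivity_low + head$conductivity_high) / 2, sens$m)
  fbar <- rowMeans(recording$signals)
  cost_at <- function(loc) {
    u <- sweep(sens$positions, 2, loc)
    d <- sqrt(rowSums(u^2))
    if (any(d < 1e-6) || loc[3] < 0 ||
        sum(loc^2) >= (0.97 * head$radius_cm)^2) return(list(cost = Inf))
    rho <- head$beta - head$alpha * d
    A <- (rho / (4 * pi * zeta * d^3)) * u
    fit <- stats::lm.fit(A, fbar)
    list(cost = sum(fit$residuals^2), v = fit$coefficients)
  }
  lim <- 0.9 * head$radius_cm
  ctr <- c(0, 0, lim / 2)
  hw <- lim
  best <- list(cost = Inf, loc = ctr)
  for (round in seq_len(n_refine)) {
    gx <- seq(ctr[1] - hw, ctr[1] + hw, length.out = n_grid)
    gy <- seq(ctr[2] - hw, ctr[2] + hw, length.out = n_grid)
    gz <- seq(max(0, ctr[3] - hw), ctr[3] + hw, length.out = n_grid)
    for (x in gx) for (y in gy) for (z in gz) {
      res <- cost_at(c(x, y, z))
      if (res$cost < best$cost) best <- list(cost = res$cost, loc = c(x, y, z),
                                             v = res$v)
    }
    ctr <- best$loc
    hw <- hw * 2.2 / (n_grid - 1)   # shrink around the incumbent
  }
  s <- sqrt(sum(best$v^2))
  list(location = best$loc, strength = s,
       orientation = if (s > 0) best$v / s else c(0, 0, 1),
       cost = best$cost, grid_resolution = hw)
}
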