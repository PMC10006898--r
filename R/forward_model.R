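#' Equivalent current dipole
#'
#' A dipole is parameterized by its location inside the head (cm, head
#' frame), a unit orientation vector and a nonnegative strength magnitude.
#' Strength units are carried as an opaque tag (conventionally "A.cm"); no
#' dimensional conversion is attempted anywhere in the package.
#'
#' @param location Length-3 numeric, head-frame cm; must be strictly inside
#'   the hemisphere when later combined with a head model.
#' @param orientation Length-3 numeric; must have unit norm (tolerance 1e-9)
#'   unless `normalize = TRUE`, in which case it is rescaled.
#' @param strength Nonnegative scalar magnitude.
#' @param normalize Rescale `orientation` to unit norm instead of erroring.
#' @return Object of class `dipole`.
#' @export
dipole <- function(location, orientation, strength, normalize = FALSE) {
  location <- as.numeric(location); orientation <- as.numeric(orientation)
  stopifnot(length(location) == 3L, length(orientation) == 3L,
            is.numeric(strength), length(strength) == 1L)
  if (strength < 0) stop("strength must be nonnegative", call. = FALSE)
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop("orientation must be a nonzero vector", call. = FALSE)
  if (normalize) {
    orientation <- orientation / nrm
  } else if (abs(nrm - 1) > 1e-9) {
    stop("orientation must be unit norm (use normalize = TRUE to rescale)",
         call. = FALSE)
  }
  structure(list(location = location, orientation = orientation,
                 strength = as.numeric(strength)),
            class = "dipole")
}

# stack a list of dipoles into an n x 7 parameter matrix
dipoles_to_matrix <- function(dipoles) {
  if (inherits(dipoles, "dipole")) dipoles <- list(dipoles)
  out <- t(vapply(dipoles, function(d)
    c(d$location, d$orientation, d$strength), numeric(7)))
  colnames(out) <- param_names()
  out
}

param_names <- function() c("lx", "ly", "lz", "mux", "muy", "muz", "s")

check_dipoles_inside <- function(param, head, margin = 1) {
  loc <- param[, 1:3, drop = FALSE]
  r <- sqrt(rowSums(loc^2))
  if (any(r >= head$radius_cm * margin) || any(loc[, 3] < 0))
    stop("dipole locations must lie strictly inside the hemisphere",
         call. = FALSE)
  invisible(TRUE)
}

#' Distance-based received-signal-strength attenuation
#'
#' The linear attenuation line `rho(d) = beta - alpha * d` with endpoints
#' pinned by the head model: full pickup (`rho = 1`) for a source directly
#' under the electrode and 1% pickup (`rho = 0.01`) at the full head
#' diameter. Distances outside `[0, 2 * radius]` are geometrically impossible
#' and raise a domain error.
#'
#' @param d Source-sensor distance(s), cm.
#' @param head A [head_model()].
#' @return Attenuation coefficient(s) in `[0.01, 1]`.
#' @export
rss_coefficient <- function(d, head) {
  stopifnot(inherits(head, "head_model"), is.numeric(d))
  if (any(d < 0 | d > 2 * head$radius_cm + 1e-12))
    stop("distance outside [0, 2*radius]", call. = FALSE)
  head$beta - head$alpha * d
}

#' Per-path conductivity draws
#'
#' One effective conductivity is drawn per (sensor, dipole) path, i.i.d.
#' uniform between the head model's bounds, and held fixed for the whole
#' recording: the tissue between a given source and a given electrode does
#' not change from sample to sample, only the measurement noise does.
#'
#' @param head A [head_model()].
#' @param m Number of sensors.
#' @param n_dipoles Number of dipoles.
#' @param seed Integer seed.
#' @return m x n_dipoles numeric matrix of draws.
#' @export
sample_conductivity <- function(head, m, n_dipoles, seed) {
  stopifnot(inherits(head, "head_model"), m >= 1, n_dipoles >= 1)
  withr::with_seed(as.integer(seed), {
    matrix(stats::runif(m * n_dipoles, head$conductivity_low,
                        head$conductivity_high),
           nrow = m, ncol = n_dipoles)
  })
}

#' Gain (lead-field) matrix of one dipole
#'
#' Row j maps the dipole's moment vector to the potential at sensor j via
#' the inverse-square field: `g_j = (w_j - l) / (4 * pi * zeta_j * d_j^3)`,
#' where `d_j` is the source-sensor distance and `zeta_j` the conductivity
#' of that path.
#'
#' @param dipole_loc Length-3 dipole location (cm), strictly inside the head.
#' @param sensors A [sensor_array()].
#' @param conductivities Length-m vector of per-path conductivities (a scalar
#'   is recycled).
#' @return m x 3 matrix with attributes `distances` and `conductivities`.
#' @export
gain_matrix <- function(dipole_loc, sensors, conductivities) {
  stopifnot(inherits(sensors, "sensor_array"))
  loc <- as.numeric(dipole_loc)
  stopifnot(length(loc) == 3L)
  zeta <- rep_len(as.numeric(conductivities), sensors$m)
  if (any(zeta <= 0)) stop("conductivities must be positive", call. = FALSE)
  u <- sweep(sensors$positions, 2, loc)           # w_j - l
  d <- sqrt(rowSums(u^2))
  if (any(d < 1e-9))
    stop("dipole coincides with a sensor (zero source-sensor distance)",
         call. = FALSE)
  g <- u / (4 * pi * zeta * d^3)
  attr(g, "distances") <- d
  attr(g, "conductivities") <- zeta
  g
}

# Noiseless sensor means for a stack of dipoles (n x 7 matrix), with given
# per-path conductivities (m x n). RSS attenuation is evaluated on the
# candidate geometry. Shared by the simulator and the solver.
forward_means <- function(param, sensors, head, zeta) {
  m <- sensors$m
  n <- nrow(param)
  mu_sig <- numeric(m)
  for (i in seq_len(n)) {
    g <- gain_matrix(param[i, 1:3], sensors, zeta[, i])
    d <- attr(g, "distances")
    rho <- rss_coefficient(pmin(d, 2 * head$radius_cm), head)
    mu_sig <- mu_sig + rho * param[i, 7] * drop(g %*% param[i, 4:6])
  }
  mu_sig
}

#' Measurement noise model
#'
#' Gaussian white noise, homoscedastic across sensors and samples
#' (covariance `sigma^2 * I`). Specify either the standard deviation directly
#' or a target signal-to-noise ratio (noiseless signal power over noise
#' power, averaged across sensors), from which `sigma` is derived for the
#' specific scenario at simulation time.
#'
#' @param sigma Noise standard deviation (microvolt); `sigma = 0` yields a
#'   noiseless recording.
#' @param target_snr Dimensionless power ratio; exactly one of `sigma`,
#'   `target_snr` must be given.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma = NULL, target_snr = NULL) {
  if (is.null(sigma) == is.null(target_snr))
    stop("specify exactly one of sigma or target_snr", call. = FALSE)
  if (!is.null(sigma) && (!is.numeric(sigma) || sigma < 0))
    stop("sigma must be >= 0", call. = FALSE)
  if (!is.null(target_snr) && (!is.numeric(target_snr) || target_snr <= 0))
    stop("target_snr must be > 0", call. = FALSE)
  structure(list(kind = "gaussian-white", sigma = sigma,
                 target_snr = target_snr),
            class = "noise_model")
}

#' Simulate a multichannel EEG-like recording
#'
#' Builds the noiseless sensor means by superposing all dipoles' attenuated,
#' conductivity-scaled inverse-square contributions, then adds independent
#' Gaussian noise to each of the `n_samples` columns. Dipoles are fixed in
#' location, orientation and strength over the whole recording: the per-path
#' conductivity and attenuation are drawn/evaluated once, so only the noise
#' varies across samples.
#'
#' @param dipoles A `dipole`, list of `dipole`s, or n x 7 parameter matrix
#'   (columns lx, ly, lz, mux, muy, muz, s).
#' @param sensors A [sensor_array()].
#' @param head A [head_model()].
#' @param n_samples Number of time samples (columns), >= 1.
#' @param noise A [noise_model()].
#' @param seed Integer seed governing conductivity draws and noise.
#' @return Object of class `eeg_recording`: `signals` (m x N matrix, one row
#'   per sensor), `sensors`, `head`, `n_samples`, `seed`, and `truth` (the
#'   generating parameters, conductivity and attenuation draws, noiseless
#'   means, and realized `sigma`).
#' @export
simulate_recording <- function(dipoles, sensors, head, n_samples,
                               noise = noise_model(target_snr = 20),
                               seed = 1L) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(head, "head_model"),
            inherits(noise, "noise_model"))
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (is.matrix(dipoles)) param <- dipoles else param <- dipoles_to_matrix(dipoles)
  n <- nrow(param)
  all_noise <- n == 0L
  if (all_noise) {
    warning("no dipoles supplied: recording is pure noise", call. = FALSE)
    if (is.null(noise$sigma))
      stop("target_snr is undefined for a source-free recording", call. = FALSE)
  } else {
    colnames(param) <- param_names()
    check_dipoles_inside(param, head)
  }
  seed <- as.integer(seed)

  zeta <- if (all_noise) matrix(numeric(0), sensors$m, 0) else
    sample_conductivity(head, sensors$m, n, seed = seed)
  mu_sig <- if (all_noise) numeric(sensors$m) else
    forward_means(param, sensors, head, zeta)

  sigma <- noise$sigma
  if (is.null(sigma)) {
    p_sig <- mean(mu_sig^2)
    if (p_sig == 0)
      stop("target_snr is undefined when the noiseless signal is zero",
           call. = FALSE)
    sigma <- sqrt(p_sig / noise$target_snr)
  }
  noise_mat <- withr::with_seed(seed + 1L, {
    matrix(stats::rnorm(sensors$m * n_samples, sd = sigma),
           nrow = sensors$m, ncol = n_samples)
  })
  signals <- mu_sig + noise_mat
  dimnames(signals) <- list(sensors$labels, NULL)

  rho <- if (all_noise) NULL else {
    d <- vapply(seq_len(n), function(i)
      euclidean_distance(sensors$positions, param[i, 1:3]), numeric(sensors$m))
    rss_coefficient(pmin(d, 2 * head$radius_cm), head)
  }
  structure(list(
    signals = signals, sensors = sensors, head = head,
    n_samples = n_samples, seed = seed, sample_rate = NA_real_,
    truth = list(param = if (all_noise) NULL else param,
                 zeta = zeta, rho = rho, noiseless = mu_sig,
                 sigma = sigma, target_snr = noise$target_snr)
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d sensors x %d samples", nrow(x$signals),
              ncol(x$signals)))
  if (!is.null(x$truth$param))
    cat(sprintf(" (synthetic, %d dipole%s)", nrow(x$truth$param),
                if (nrow(x$truth$param) == 1) "" else "s"))
  cat("\n")
  invisible(x)
}

#' Realized signal-to-noise ratio of a synthetic recording
#'
#' Mean over sensors of (noiseless signal power) / (empirical noise power).
#' Requires the generating truth (only synthetic recordings know their
#' noiseless component). A noiseless recording returns `Inf`; a source-free
#' one returns 0.
#'
#' @param recording An [simulate_recording()] result with truth attached.
#' @return Scalar SNR (power ratio).
#' @export
snr_of <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  tr <- recording$truth
  if (is.null(tr) || is.null(tr$noiseless))
    stop("SNR unavailable: recording carries no generating truth", call. = FALSE)
  noise <- recording$signals - tr$noiseless
  p_noise <- rowMeans(noise^2)
  p_sig <- tr$noiseless^2
  if (all(p_noise == 0)) return(Inf)
  mean(p_sig / p_noise)
}
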