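#' Hemispherical head model
#'
#' Constructs the head model used by both the forward simulator and the
#' inverse solver: a hemisphere of radius `radius_cm` whose flat face lies in
#' the z = 0 plane. Dipoles live strictly inside the hemisphere; electrodes
#' sit on the curved scalp surface. Signal conduction through the head is
#' summarized by two ingredients stored here: (i) the bounds of the uniform
#' distribution from which the per-path conductivity is drawn, and (ii) the
#' coefficients `alpha`, `beta` of the linear received-signal-strength (RSS)
#' attenuation line `rho(d) = -alpha * d + beta`. The endpoints are pinned so
#' that a dipole directly under a sensor is picked up at full strength
#' (`rho(0) = 1`) while a source a full head diameter away contributes only
#' 1% (`rho(2 * radius) = 0.01`), hence `beta = 1` and
#' `alpha = 0.99 / (2 * radius)`.
#'
#' @param radius_cm Head (hemisphere) radius in cm. Default 10 cm; use 8.5
#'   for the 85 mm head matched to the standard 64-channel montage.
#' @param conductivity Length-2 numeric, lower and upper bound of the uniform
#'   per-path conductivity distribution (dimensionless effective units).
#' @return An object of class `head_model`: a list with `radius_cm`,
#'   `conductivity_low`, `conductivity_high`, `alpha`, `beta`.
#' @examples
#' head <- head_model()
#' rss_coefficient(0, head)    # 1.0
#' rss_coefficient(20, head)   # 0.01
#' @export
head_model <- function(radius_cm = 10, conductivity = c(0.1, 0.9)) {
  stopifnot(is.numeric(radius_cm), length(radius_cm) == 1L, radius_cm > 0,
            is.numeric(conductivity), length(conductivity) == 2L)
  lo <- conductivity[1]; hi <- conductivity[2]
  if (!(lo > 0 && lo <= hi))
    stop("conductivity bounds must satisfy 0 < low <= high", call. = FALSE)
  structure(list(
    radius_cm         = as.numeric(radius_cm),
    conductivity_low  = as.numeric(lo),
    conductivity_high = as.numeric(hi),
    beta              = 1.0,
    alpha             = 0.99 / (2 * radius_cm)
  ), class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("Hemispherical head model: radius %.2f cm\n", x$radius_cm))
  cat(sprintf("  conductivity ~ U(%.3g, %.3g)\n",
              x$conductivity_low, x$conductivity_high))
  cat(sprintf("  RSS attenuation rho(d) = %.4g - %.4g d  (rho(0)=1, rho(2r)=0.01)\n",
              x$beta, x$alpha))
  invisible(x)
}

#' Spherical to Cartesian coordinates
#'
#' Head-frame convention: +x through the right ear, +y through the nasion,
#' +z up. The polar angle `theta` is measured from the +z axis and is
#' restricted to the upper hemisphere (`[0, pi/2]`; the rim is included so
#' that electrodes may sit on the equator), `phi` is the azimuth in
#' `[0, 2*pi)`.
#'
#' @param r Radial distance(s), same length unit throughout (cm).
#' @param theta Polar angle(s) in `[0, pi/2]`.
#' @param phi Azimuth(s) in `[0, 2*pi)`.
#' @return Numeric matrix with columns `x`, `y`, `z` (one row per point).
#' @seealso [cartesian_to_spherical()]
#' @export
spherical_to_cartesian <- function(r, theta, phi) {
  stopifnot(is.numeric(r), is.numeric(theta), is.numeric(phi))
  n <- max(length(r), length(theta), length(phi))
  r <- rep_len(r, n); theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  if (any(r < 0)) stop("r must be nonnegative", call. = FALSE)
  if (any(theta < 0 | theta > pi / 2 + 1e-12))
    stop("theta out of range [0, pi/2]", call. = FALSE)
  if (any(phi < 0 | phi >= 2 * pi))
    stop("phi out of range [0, 2*pi)", call. = FALSE)
  cbind(x = r * sin(theta) * cos(phi),
        y = r * sin(theta) * sin(phi),
        z = r * cos(theta))
}

#' Cartesian to spherical coordinates
#'
#' Inverse of [spherical_to_cartesian()]. Points must lie in the upper
#' half-space (`z >= 0`); anything below the hemisphere base is a domain
#' error. At the pole (`x = y = 0`) the azimuth is reported as 0.
#'
#' @param xyz Numeric matrix (n x 3) or length-3 vector of head-frame
#'   coordinates.
#' @return Numeric matrix with columns `r`, `theta`, `phi`.
#' @export
cartesian_to_spherical <- function(xyz) {
  xyz <- as_xyz_matrix(xyz)
  if (any(xyz[, 3] < -1e-12))
    stop("z < 0: point lies below the hemisphere base", call. = FALSE)
  r <- sqrt(rowSums(xyz^2))
  theta <- ifelse(r > 0, acos(pmin(1, pmax(-1, xyz[, 3] / r))), 0)
  phi <- atan2(xyz[, 2], xyz[, 1])
  phi <- ifelse(phi < 0, phi + 2 * pi, phi)
  phi[xyz[, 1] == 0 & xyz[, 2] == 0] <- 0
  cbind(r = r, theta = theta, phi = phi)
}

as_xyz_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3, byrow = TRUE)
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("positions must have 3 columns (x, y, z)", call. = FALSE)
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y", "z")
  p
}

#' Electrode array on the scalp
#'
#' Light container for an ordered set of electrode positions on the scalp
#' sphere. Positions are validated to lie on the sphere of the stated radius
#' (relative tolerance 1e-6) and to be pairwise distinct.
#'
#' @param positions n x 3 matrix of head-frame coordinates (cm).
#' @param radius_cm Scalp sphere radius the positions must satisfy.
#' @param labels Optional character vector of channel labels.
#' @param montage_name Label describing the layout provenance.
#' @param seed Integer seed used to generate the layout, or `NA`.
#' @return Object of class `sensor_array` with elements `positions`,
#'   `labels`, `montage_name`, `radius_cm`, `seed`, `m`.
#' @export
sensor_array <- function(positions, radius_cm, labels = NULL,
                         montage_name = "custom", seed = NA_integer_) {
  positions <- as_xyz_matrix(positions)
  m <- nrow(positions)
  if (m < 1L) stop("need at least one sensor", call. = FALSE)
  norms <- sqrt(rowSums(positions^2))
  if (any(abs(norms - radius_cm) > 1e-6 * radius_cm))
    stop("sensor positions must lie on the scalp sphere (|w| = radius)",
         call. = FALSE)
  if (anyDuplicated(round(positions, 9)))
    stop("sensor positions must be distinct", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("S%03d", seq_len(m))
  rownames(positions) <- labels
  structure(list(positions = positions, labels = labels,
                 montage_name = montage_name, radius_cm = radius_cm,
                 seed = seed, m = m),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("Sensor array '%s': %d electrodes on a %.2f cm scalp sphere\n",
              x$montage_name, x$m, x$radius_cm))
  invisible(x)
}

#' Uniform random electrode placement on the scalp hemisphere
#'
#' Draws `m` electrode positions uniformly with respect to surface area on
#' the scalp hemisphere: azimuth `phi ~ U[0, 2*pi)` and `cos(theta) ~ U(0, 1)`
#' (area-uniform, not uniform in the polar angle). Reproducible under a fixed
#' seed; the global RNG state is left untouched.
#'
#' @param head A [head_model()].
#' @param m Number of electrodes (>= 1).
#' @param seed Integer seed.
#' @return A [sensor_array()] with `montage_name = "uniform-random"`.
#' @export
sample_uniform_sensors <- function(head, m, seed) {
  stopifnot(inherits(head, "head_model"))
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("m must be a positive count", call. = FALSE)
  m <- as.integer(m)
  pts <- withr::with_seed(as.integer(seed), {
    cost <- stats::runif(m)          # cos(theta) area-uniform on hemisphere
    phi  <- stats::runif(m, 0, 2 * pi)
    sint <- sqrt(pmax(0, 1 - cost^2))
    head$radius_cm * cbind(sint * cos(phi), sint * sin(phi), cost)
  })
  sensor_array(pts, radius_cm = head$radius_cm,
               montage_name = "uniform-random", seed = as.integer(seed))
}

#' Standard electrode montages
#'
#' Loads a named standard layout (currently `"biosemi64"`, the idealized
#' spherical BioSemi 64-channel 10-20-family positions bundled with the
#' package as unit-sphere directions) or a user position file, and projects
#' each electrode radially onto the scalp sphere of the given head.
#'
#' The position file format is plain text, one electrode per line,
#' `label x y z`, whitespace- or tab-separated, with optional `#` comment
#' lines. Coordinates are taken as cm in the head frame unless a comment
#' line containing `unit-sphere` (or `units: unit`) declares unit-vector
#' form; in either case directions are preserved and radii are rescaled to
#' the head radius.
#'
#' @param name Montage label (`"biosemi64"`) or path to a position file.
#' @param head A [head_model()] providing the scalp radius.
#' @return A [sensor_array()].
#' @export
load_standard_montage <- function(name, head) {
  stopifnot(inherits(head, "head_model"), is.character(name), length(name) == 1L)
  if (identical(tolower(name), "biosemi64")) {
    path <- system.file("extdata", "biosemi64_unit_sphere.tsv",
                        package = "dipolefit", mustWork = TRUE)
    montage <- "biosemi64"
  } else if (file.exists(name)) {
    path <- name
    montage <- basename(name)
  } else {
    stop(sprintf("unknown montage '%s' (not a known label or a readable file)",
                 name), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  # tolerate a single header line of column names
  if (length(body) && grepl("^\\s*label\\b", body[1], ignore.case = TRUE))
    body <- body[-1]
  if (!length(body)) stop("montage file contains no positions", call. = FALSE)
  fields <- strsplit(trimws(body), "[\t ,]+")
  if (any(lengths(fields) != 4L))
    stop(sprintf("malformed montage line %d: expected 'label x y z'",
                 which(lengths(fields) != 4L)[1]), call. = FALSE)
  labels <- vapply(fields, `[`, "", 1L)
  xyz <- t(vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(v)) stop(sprintf("non-numeric coordinate for electrode '%s'",
                               f[1]), call. = FALSE)
    v
  }, numeric(3)))
  norms <- sqrt(rowSums(xyz^2))
  if (any(norms == 0)) stop("zero-length electrode direction", call. = FALSE)
  xyz <- xyz * (head$radius_cm / norms)    # radial projection onto the scalp
  sensor_array(xyz, radius_cm = head$radius_cm, labels = labels,
               montage_name = montage)
}

#' Euclidean source-sensor distance
#'
#' @param a,b Length-3 vectors or n x 3 matrices of head-frame coordinates;
#'   rows are recycled to the longer of the two.
#' @return Numeric vector of Euclidean distances.
#' @export
euclidean_distance <- function(a, b) {
  a <- as_xyz_matrix(a); b <- as_xyz_matrix(b)
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  sqrt(rowSums((a - b)^2))
}
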