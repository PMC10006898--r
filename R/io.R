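#' Write / read a recording as CSV plus JSON sidecar
#'
#' The native on-disk form of a recording is a pair (plus a sensor position
#' file): `<prefix>_signals.csv` with one row per sensor (first column the
#' sensor label, remaining columns the samples, serialized with 17
#' significant digits so the round trip is bit-exact), and
#' `<prefix>_meta.json` carrying the head configuration, seeds and -- for
#' synthetic data -- the generating truth (dipole parameters, conductivity
#' and attenuation draws, noiseless means, noise sigma).
#' `<prefix>_sensors.txt` stores the electrode positions in the plain-text
#' format of [load_standard_montage()].
#'
#' @param recording An `eeg_recording`.
#' @param prefix Output path prefix.
#' @return `write_recording` invisibly returns the three file paths;
#'   `read_recording` returns the reconstructed `eeg_recording`.
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "eeg_recording"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- recording_paths(prefix)
  sig <- recording$signals
  lines <- c(paste(c("sensor", sprintf("t%d", seq_len(ncol(sig)))),
                   collapse = ","),
             vapply(seq_len(nrow(sig)), function(j)
               paste(c(recording$sensors$labels[j],
                       sprintf("%.17g", sig[j, ])), collapse = ","), ""))
  writeLines(lines, paths$signals)
  write_sensor_file(recording$sensors, paths$sensors)
  head <- recording$head
  meta <- list(
    format = "dipolefit-recording-v1",
    head = list(radius_cm = head$radius_cm,
                conductivity = c(head$conductivity_low, head$conductivity_high)),
    n_sensors = recording$sensors$m,
    n_samples = recording$n_samples,
    montage = recording$sensors$montage_name,
    seed = recording$seed,
    units = list(signals = "uV", length = "cm", strength = "A.cm"),
    truth = recording$truth
  )
  jsonlite::write_json(meta, paths$meta, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(unlist(paths))
}

recording_paths <- function(prefix) list(
  signals = paste0(prefix, "_signals.csv"),
  meta    = paste0(prefix, "_meta.json"),
  sensors = paste0(prefix, "_sensors.txt"))

#' @rdname write_recording
#' @param prefix Path prefix used when writing.
#' @export
read_recording <- function(prefix) {
  paths <- recording_paths(prefix)
  for (p in unlist(paths[c("signals", "meta")]))
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
  meta <- jsonlite::read_json(paths$meta, simplifyVector = TRUE)
  head <- head_model(radius_cm = meta$head$radius_cm,
                     conductivity = meta$head$conductivity)
  sensors <- load_standard_montage(paths$sensors, head)
  sensors$montage_name <- meta$montage %||% sensors$montage_name
  lines <- readLines(paths$signals)
  cells <- strsplit(lines, ",", fixed = TRUE)
  hdr <- cells[[1]]
  body <- cells[-1]
  if (length(body) != sensors$m)
    stop(sprintf("signals CSV has %d sensor rows but sensor file has %d",
                 length(body), sensors$m), call. = FALSE)
  n_col <- length(hdr) - 1L
  sig <- matrix(NA_real_, length(body), n_col)
  labels <- character(length(body))
  for (j in seq_along(body)) {
    row <- body[[j]]
    if (length(row) != n_col + 1L)
      stop(sprintf("signals CSV row %d has %d fields, expected %d",
                   j + 1L, length(row), n_col + 1L), call. = FALSE)
    labels[j] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in signals CSV at row %d, column %d",
                   j + 1L, which(is.na(v))[1] + 1L), call. = FALSE)
    sig[j, ] <- v
  }
  sensors$labels <- labels
  rownames(sensors$positions) <- labels
  dimnames(sig) <- list(labels, NULL)
  truth <- meta$truth
  if (!is.null(truth) && !is.null(truth$param)) {
    truth$param <- matrix(unlist(truth$param), ncol = 7,
                          dimnames = list(NULL, param_names()))
    truth$zeta <- matrix(unlist(truth$zeta), nrow = sensors$m)
    truth$rho <- matrix(unlist(truth$rho), nrow = sensors$m)
    truth$noiseless <- as.numeric(truth$noiseless)
  }
  structure(list(signals = sig, sensors = sensors, head = head,
                 n_samples = ncol(sig), seed = meta$seed,
                 sample_rate = NA_real_, truth = truth),
            class = "eeg_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write electrode positions to a plain-text file
#'
#' One electrode per line, `label x y z`, coordinates in cm in the head
#' frame; readable back with [load_standard_montage()].
#'
#' @param sensors A [sensor_array()].
#' @param path Output path.
#' @export
write_sensor_file <- function(sensors, path) {
  stopifnot(inherits(sensors, "sensor_array"))
  p <- sensors$positions
  lines <- c("# electrode positions, head frame, cm",
             sprintf("# montage: %s; radius_cm: %.10g", sensors$montage_name,
                     sensors$radius_cm),
             "label\tx\ty\tz",
             vapply(seq_len(sensors$m), function(j)
               paste(c(sensors$labels[j], sprintf("%.17g", p[j, ])),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Validates the schema (unknown keys are rejected), applies defaults, and
#' returns the fully resolved configuration -- head model, sensor montage
#' specification, dipoles (explicit parameter rows or a fixture tag),
#' simulation settings, solver settings, and optionally a sweep section.
#'
#' Recognized keys:
#' \preformatted{
#' head:       radius_cm, conductivity (length-2)
#' sensors:    montage ("uniform-random" | "biosemi64" | path), count, seed
#' dipoles:    "table1" | "table2" | list of 7-value rows
#'             (lx, ly, lz, mux, muy, muz, s)
#' simulation: n_samples, target_snr, sigma, seed
#' solver:     mode, max_iterations, gradient_tolerance,
#'             constraint_tolerance, multistart, seed, s_max,
#'             initial_guess (list of 7-value rows)
#' sweep:      sensor_counts, sample_counts, n_repeats, target_snr,
#'             sigma, joint, base_seed, mode
#' }
#'
#' @param path YAML file path.
#' @return Named list with elements `head`, `sensors_spec`, `dipoles`,
#'   `initial_guess`, `simulation`, `solver`, `sweep`, `resolved` (the fully
#'   resolved config list suitable for echoing).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- list(
    head = c("radius_cm", "conductivity"),
    sensors = c("montage", "count", "seed"),
    dipoles = NULL,
    simulation = c("n_samples", "target_snr", "sigma", "seed"),
    solver = c("mode", "max_iterations", "gradient_tolerance",
               "constraint_tolerance", "multistart", "seed", "s_max",
               "initial_guess"),
    sweep = c("sensor_counts", "sample_counts", "n_repeats", "target_snr",
              "sigma", "joint", "base_seed", "mode"))
  bad <- setdiff(names(cfg), names(allowed))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in intersect(names(cfg), c("head", "sensors", "simulation",
                                      "solver", "sweep"))) {
    extra <- setdiff(names(cfg[[sec]]), allowed[[sec]])
    if (length(extra))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  hd <- cfg$head %||% list()
  head <- head_model(radius_cm = hd$radius_cm %||% 10,
                     conductivity = unlist(hd$conductivity %||% c(0.1, 0.9)))
  sn <- cfg$sensors %||% list()
  sensors_spec <- list(montage = sn$montage %||% "uniform-random",
                       count = as.integer(sn$count %||% 36L),
                       seed = as.integer(sn$seed %||% 1L))
  dipoles <- cfg$dipoles %||% "table1"
  if (!is.character(dipoles)) {
    dipoles <- do.call(rbind, lapply(dipoles, function(r) {
      v <- as.numeric(unlist(r))
      if (length(v) != 7) stop("each dipole row needs 7 values", call. = FALSE)
      v
    }))
    colnames(dipoles) <- param_names()
  }
  sim <- cfg$simulation %||% list()
  simulation <- list(n_samples = as.integer(sim$n_samples %||% 250L),
                     target_snr = sim$target_snr,
                     sigma = sim$sigma,
                     seed = as.integer(sim$seed %||% 1L))
  if (is.null(simulation$target_snr) && is.null(simulation$sigma))
    simulation$target_snr <- 20
  sv <- cfg$solver %||% list()
  ig <- sv$initial_guess
  if (!is.null(ig)) {
    ig <- do.call(rbind, lapply(ig, function(r) as.numeric(unlist(r))))
    if (ncol(ig) != 7) stop("solver initial_guess rows need 7 values",
                            call. = FALSE)
  }
  solver <- solver_config(
    mode = sv$mode %||% "expected",
    initial_guess = ig,
    max_iterations = sv$max_iterations %||% 500L,
    gradient_tolerance = sv$gradient_tolerance %||% 1e-8,
    constraint_tolerance = sv$constraint_tolerance %||% 1e-6,
    multistart = sv$multistart %||% 8L,
    seed = sv$seed %||% 1L,
    s_max = sv$s_max %||% 10)
  sweep <- NULL
  if (!is.null(cfg$sweep)) {
    sw <- cfg$sweep
    sweep <- sweep_config(
      sensor_counts = as.integer(unlist(sw$sensor_counts)),
      sample_counts = as.integer(unlist(sw$sample_counts)),
      n_repeats = as.integer(sw$n_repeats %||% 20L),
      head = head, target_snr = sw$target_snr %||% 20,
      sigma = sw$sigma, joint = isTRUE(sw$joint),
      base_seed = as.integer(sw$base_seed %||% 1L),
      mode = sw$mode %||% "expected")
  }
  resolved <- list(head = list(radius_cm = head$radius_cm,
                               conductivity = c(head$conductivity_low,
                                                head$conductivity_high)),
                   sensors = sensors_spec,
                   dipoles = if (is.character(dipoles)) dipoles else
                     rows_as_list(dipoles),
                   simulation = simulation,
                   solver = list(mode = solver$mode,
                                 multistart = solver$multistart,
                                 seed = solver$seed))
  list(head = head, sensors_spec = sensors_spec, dipoles = dipoles,
       initial_guess = ig, simulation = simulation, solver = solver,
       sweep = sweep, resolved = resolved)
}

resolve_sensors <- function(spec, head) {
  if (identical(spec$montage, "uniform-random"))
    sample_uniform_sensors(head, spec$count, seed = spec$seed)
  else
    load_standard_montage(spec$montage, head)
}
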