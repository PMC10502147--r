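# Flat key = value run configuration files with an explicit schema version.
# Unknown keys are errors: silent unit typos in hand-edited files are the
# main failure mode this guards against, so every key carries its unit
# suffix and the vocabulary is closed.

config_schema <- list(
  schema_version = "int",
  tag            = "chr",
  # acoustic field
  n0             = "num",
  delta_n        = "num",
  freq_hz        = "num",
  v_us_m_s       = "num",
  # medium
  sigma_t_per_m  = "num",
  albedo         = "num",
  g              = "num",
  length_m       = "num",
  n_external     = "num",
  # source
  source         = "chr",     # collimated | lens
  beam_diameter_m = "num",
  focus_depth_m  = "num",
  flux_au        = "num",
  # detector
  det_radius_m   = "numvec",
  # temporal
  time_mode      = "chr",     # uniform | fixed | duty | peak
  t_fixed_s      = "num",
  duty_fraction  = "num",
  # run controls
  step_ds_m      = "num",
  kill_radius_m  = "num",
  max_events     = "int",
  order_max      = "int",
  n_photons      = "int",
  seed           = "int",
  # sweep axes
  f_list_hz      = "numvec",
  delta_n_list   = "numvec",
  out_dir        = "chr")

config_defaults <- function() {
  list(schema_version = 1L, tag = "run",
       n0 = 1.3333, delta_n = 0, freq_hz = 1e6, v_us_m_s = 1500,
       sigma_t_per_m = 0, albedo = 0.99, g = 0.9, length_m = 30e-3,
       n_external = 1,
       source = "collimated", beam_diameter_m = 500e-6,
       focus_depth_m = 30e-3, flux_au = 7.5e4,
       det_radius_m = 100e-6,
       time_mode = "uniform", t_fixed_s = 0, duty_fraction = 0.1,
       step_ds_m = NA_real_, kill_radius_m = NA_real_,
       max_events = 10000L, order_max = 10L,
       n_photons = 10000L, seed = 1L,
       f_list_hz = numeric(), delta_n_list = numeric(),
       out_dir = ".")
}

#' Build a run configuration
#'
#' Named arguments override the package defaults (the standard transparent /
#' turbid slab setup: 500 um beam of 7.5e4 a.u. flux, 30 mm slab, 100 um
#' target disk, uniform phase sampling). Unknown keys are rejected. A unit
#' sanity lint warns when the implied optical depth exceeds 1000 mean free
#' paths, the signature of an extinction coefficient entered in 1/mm where
#' 1/m is expected.
#'
#' @param ... Configuration keys, see \code{sonotrace:::config_schema}.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration values must be named", call. = FALSE)
  unknown <- setdiff(names(over), names(config_schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(config_defaults(), over)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!identical(as.integer(cfg$schema_version), 1L))
    stop("unsupported schema_version: ", cfg$schema_version, call. = FALSE)
  if (!cfg$source %in% c("collimated", "lens"))
    stop("source must be 'collimated' or 'lens'", call. = FALSE)
  if (!cfg$time_mode %in% c("uniform", "fixed", "duty", "peak"))
    stop("time_mode must be uniform, fixed, duty or peak", call. = FALSE)
  depth <- cfg$length_m * cfg$sigma_t_per_m
  if (is.finite(depth) && depth > 1000)
    warning(sprintf(paste0("optical depth is %.3g MFP (> 1000): check that ",
                           "sigma_t_per_m is in 1/m, not 1/mm"), depth))
  structure(cfg, class = "run_config")
}

#' Read / write run configuration files
#'
#' Plain-text files of \code{key = value} lines (comments start with #).
#' Values may be numbers, comma-separated numeric lists, or strings. Unknown
#' keys and unsupported schema versions are errors.
#'
#' @param path File path.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse configuration line: ", ln, call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    type <- config_schema[[key]]
    if (is.null(type))
      stop("unknown configuration key: ", key, call. = FALSE)
    over[[key]] <- suppressWarnings(switch(type,
      int = as.integer(val),
      num = as.numeric(val),
      numvec = as.numeric(trimws(strsplit(val, ",")[[1]])),
      chr = val))
    if (type %in% c("int", "num", "numvec") && any(is.na(over[[key]])))
      stop("non-numeric value for key ", key, ": ", val, call. = FALSE)
  }
  do.call(run_config, over)
}

#' @rdname read_run_config
#' @param cfg A \code{run_config}.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  fmt <- function(key) {
    v <- cfg[[key]]
    if (length(v) == 0L || (length(v) == 1L && is.na(v))) return(NULL)
    val <- if (is.numeric(v)) paste(format(v, digits = 15, scientific = TRUE,
                                           trim = TRUE), collapse = ", ")
           else as.character(v)
    sprintf("%s = %s", key, val)
  }
  out <- unlist(lapply(names(config_schema), fmt))
  writeLines(out, path)
  invisible(path)
}

#' Build the scene described by a run configuration
#'
#' @param cfg A [run_config()].
#' @param delta_n,freq_hz,sigma_t_per_m Optional overrides (used by sweeps).
#' @return A [scene()].
#' @export
config_to_scene <- function(cfg, delta_n = NULL, freq_hz = NULL,
                            sigma_t_per_m = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dn <- if (is.null(delta_n)) cfg$delta_n else delta_n
  f <- if (is.null(freq_hz)) cfg$freq_hz else freq_hz
  st <- if (is.null(sigma_t_per_m)) cfg$sigma_t_per_m else sigma_t_per_m
  prof <- acoustic_profile(cfg$n0, dn, f, cfg$v_us_m_s)
  opt <- medium_optics(st, cfg$albedo, cfg$g, cfg$length_m, cfg$n_external)
  src <- if (cfg$source == "lens")
    lens_source(cfg$focus_depth_m, cfg$beam_diameter_m, cfg$flux_au)
  else beam_source(cfg$beam_diameter_m, cfg$flux_au)
  tm <- time_spec(cfg$time_mode, cfg$t_fixed_s, cfg$duty_fraction)
  scene(prof, opt, beam_or_lens(src), detector_spec(cfg$det_radius_m), tm)
}

# identity helper kept for clarity at call sites
beam_or_lens <- function(src) src

# run controls from a config (NA means package default)
config_controls <- function(cfg) {
  list(step_ds = if (is.na(cfg$step_ds_m)) NULL else cfg$step_ds_m,
       kill_radius = if (is.na(cfg$kill_radius_m)) NULL else cfg$kill_radius_m,
       max_events = cfg$max_events, order_max = cfg$order_max)
}
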