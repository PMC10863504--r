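## Run configuration: YAML files validated against a documented schema with
## defaults, plus structured logging.

config_defaults <- function() {
  list(
    seed = 1L,
    scale = "test",                  # "test" or "full"
    fiber = list(preset = "m3cf",
                 cladding_diameter = NULL, pulp_diameter = NULL,
                 na_multimode = NULL, corelet_rings = NULL,
                 corelet_pitch = NULL, corelet_core_diameter = NULL,
                 corelet_na = NULL, wavelength = NULL),
    calibration = list(input_grid_n = 201L, window_factor = 1.1,
                       carrier = c(0.125, 0.125), iris_fraction = 0.6,
                       photons = NULL, prune_threshold = 0.1),
    imaging = list(grid_n = 352L, pitch = 0.7, working_distance = 15,
                   photons = 1e4, dark_rate = 0),
    mating = list(offset_sd = 0.3, axial_gap = 0.5, rotation = 0,
                  bore_clearance = 3),
    phantom = list(kind = "beads", n = 10, diameter = 6,
                   field_diameter = 230)
  )
}

merge_validate <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      hf_stop(sprintf("unknown configuration key `%s`", full),
              "holofiber_config_error")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        hf_stop(sprintf("configuration key `%s` must be a section", full),
                "holofiber_config_error")
      defaults[[key]] <- merge_validate(user[[key]], defaults[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, validates it against the documented schema
#' (unknown keys are rejected, naming the offending key), applies defaults,
#' resolves the fiber preset, and echoes the resolved values to the log.
#'
#' @param path path to a YAML configuration file.
#' @param quiet suppress the configuration echo.
#' @return a validated configuration list of class `holofiber_config`, with
#'   `$fiber` resolved to a [fiber_spec()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("fiber:\n  preset: m3cf\nseed: 7", f)
#' cfg <- load_config(f, quiet = TRUE)
#' cfg$fiber$pulp_diameter
load_config <- function(path, quiet = FALSE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    hf_stop(sprintf("configuration file not found: %s", path),
            "holofiber_config_error")
  user <- tryCatch(yaml::read_yaml(path), error = function(e)
    hf_stop(sprintf("cannot parse configuration: %s", conditionMessage(e)),
            "holofiber_config_error"))
  if (is.null(user)) user <- list()
  cfg <- merge_validate(user, config_defaults())
  if (!cfg$scale %in% c("test", "full"))
    hf_stop("configuration key `scale` must be \"test\" or \"full\"",
            "holofiber_config_error")
  ## resolve fiber: preset fields overridden by any explicit values
  preset <- fiber_preset(cfg$fiber$preset)
  for (key in setdiff(names(cfg$fiber), "preset"))
    if (!is.null(cfg$fiber[[key]])) preset[[key]] <- cfg$fiber[[key]]
  cfg$fiber <- do.call(fiber_spec, c(preset[setdiff(names(preset), "label")],
                                     list(label = preset$label)))
  class(cfg) <- "holofiber_config"
  if (!quiet) {
    hf_log("config", file = path, seed = cfg$seed, scale = cfg$scale,
           fiber = cfg$fiber$label)
  }
  cfg
}

#' Structured log line
#'
#' Writes `timestamp stage key=value ...` to `stderr`.
#'
#' @param stage pipeline stage label.
#' @param ... named values.
#' @export
hf_log <- function(stage, ...) {
  kv <- list(...)
  msg <- paste(vapply(names(kv), function(k)
    sprintf("%s=%s", k, format(kv[[k]])[1]), character(1)), collapse = " ")
  message(sprintf("%s %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg))
}
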