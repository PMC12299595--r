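.configDefaults <- function() {
  list(
    polynomial_order = 12L,          # WASSR fit order
    interpolation_resolution_ppm = 0.01,
    analysis_offset_ppm = 3.5,       # amide resonance
    max_shift_ppm = 0.5,             # |B0| validity bound
    alpha = 0.05,
    noise_sd = 0.005,                # phantom noise, fraction of S0
    between_subject_sd = 0.0025,     # cohort amide-amplitude jitter
    n_per_group = 7L,
    groups = c("CTRL", "LPS05", "LPS10"),
    grid_shape = c(32L, 32L),
    b0_amplitude_ppm = 0.15,
    seed = 1L,
    outdir = NULL,
    write_maps = FALSE
  )
}

#' Pipeline configuration
#'
#' Assembles the processing parameters shared across the pipeline stages.
#' Unspecified values take the defaults: 12th-order WASSR polynomial,
#' 0.01 ppm interpolation resolution, 3.5 ppm analysis offset, 0.5 ppm
#' maximum valid shift, alpha 0.05.
#'
#' @param ... named overrides of the default keys; unknown keys are an
#'   error.
#' @return validated list of class `cest_config`.
#' @export
pipelineConfig <- function(...) {
  cfg <- .configDefaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("all configuration overrides must be named")
    }
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  if (cfg$polynomial_order < 1) stop("polynomial_order must be >= 1")
  if (cfg$interpolation_resolution_ppm <= 0) {
    stop("interpolation_resolution_ppm must be > 0")
  }
  if (cfg$max_shift_ppm <= 0) stop("max_shift_ppm must be > 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  structure(cfg, class = "cest_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads a config file, validates its keys against the known set (unknown
#' keys are rejected rather than silently ignored) and fills unset keys
#' with the package defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `cest_config` list, as from [pipelineConfig()].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("malformed YAML config: ",
                                      conditionMessage(e)))
  } else if (ext == "json") {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) stop("malformed JSON config: ",
                                      conditionMessage(e)))
  } else {
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  }
  if (is.null(vals)) vals <- list()
  do.call(pipelineConfig, vals)
}
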