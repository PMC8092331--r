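#' Pipeline configuration
#'
#' One nested list drives every stage: the master seed, the Dirichlet
#' concentration `alpha` (one component per blending function), blend
#' parameters, chroma thresholds, the augmentation stack, the standard
#' width, and the certainty bands for refinement. Every field has a
#' default, so an empty config (or empty YAML file) is valid.
#'
#' @param overrides Named list of fields to override (nested lists are
#'   merged recursively).
#' @return A validated config list of class `"pipeline_config"`.
#' @examples
#' cfg <- default_config(list(seed = 42, alpha = c(2, 1, 1)))
#' cfg$standard_width
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    alpha = c(1.0, 1.0, 1.0),
    standard_width = 640L,
    blend = list(erosion_kernel = 3L, blur_kernel = 5L, pyramid_levels = 4L),
    chroma = list(hue_low = 80, hue_high = 160, min_saturation = 0.25,
                  min_value = 0.15, n_instruments = 1L,
                  grabcut_iterations = 5L, sure_fg_erosion = 5L),
    bands = list(low = 0.2, high = 0.8),
    augment = augment_config()
  )
  cfg <- modify_deep(cfg, overrides)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Load a YAML configuration file
#'
#' Missing fields fall back to [default_config()] values; an empty file is
#' a valid configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return A `"pipeline_config"` list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  from_file <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    from_file <- yaml::read_yaml(path)
    if (is.null(from_file)) from_file <- list()
  }
  default_config(modify_deep(from_file, overrides))
}

validate_config <- function(cfg) {
  if (any(cfg$alpha <= 0)) stopf("all Dirichlet alpha components must be > 0")
  if (cfg$standard_width < 64) stopf("standard_width must be >= 64")
  b <- cfg$bands
  if (!(b$low >= 0 && b$low < b$high && b$high <= 1))
    stopf("certainty bands must satisfy 0 <= low < high <= 1")
  bl <- cfg$blend
  if (!is_odd(bl$erosion_kernel) || !is_odd(bl$blur_kernel) ||
      bl$erosion_kernel < 1 || bl$blur_kernel < 1)
    stopf("blend kernels must be odd and >= 1")
  if (bl$pyramid_levels < 1) stopf("pyramid_levels must be >= 1")
  ch <- cfg$chroma
  if (!(ch$hue_low >= 0 && ch$hue_low < ch$hue_high && ch$hue_high <= 360))
    stopf("chroma hue band must satisfy 0 <= low < high <= 360")
  if (ch$n_instruments < 1) stopf("n_instruments must be >= 1")
  invisible(cfg)
}

# Recursive list merge: values in `upd` override `base`; nested named lists
# merge field-by-field.
modify_deep <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
        !is.null(names(upd[[nm]]))) {
      base[[nm]] <- modify_deep(base[[nm]], upd[[nm]])
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

# Stable digest of the effective configuration (for run reports).
config_digest <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", hash_string(s))
}
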