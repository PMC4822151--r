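# YAML run configuration: one file collects every tunable of an analysis run
# so the run is reproducible from the manifest alone.

config_defaults <- function() {
  list(
    voxel_size = c(0.5, 0.5, 0.5),
    channels = list(DAPI = 1L, WGA = 2L),
    seed = 1L,
    qc = list(max_flatness_cv = 0.10, max_saturated_fraction = 1e-3,
              min_noise_margin = 3, drop_fraction = 0.5, smooth_window = 3L),
    nuclei = list(smooth_sigma = 0.5, split_depth = 1.0,
                  min_nucleus_volume = 20, measure_dilation = 1.0),
    cells = list(membrane_ridge_threshold = NULL, boundary_level = NULL,
                 merge_threshold = NULL,
                 merge_interface_quantile = NULL,
                 min_cytoplasm_shell_fraction = 0.5,
                 membrane_coverage_floor = 0.7,
                 max_growth_distance = 30, fill_holes = TRUE,
                 smooth_sigma = 0.35),
    ploidy = list(log2_tolerance = 0.35, max_class = 8L,
                  require_qc_pass = TRUE, min_control_n = 30L,
                  control_genome_copies = 1))
}

check_scalar <- function(val, key, kind = c("number", "positive", "nonneg",
                                            "flag", "count")) {
  kind <- match.arg(kind)
  bad <- switch(kind,
    number = !is.numeric(val) || length(val) != 1 || !is.finite(val),
    positive = !is.numeric(val) || length(val) != 1 || !is.finite(val) ||
      val <= 0,
    nonneg = !is.numeric(val) || length(val) != 1 || !is.finite(val) ||
      val < 0,
    flag = !is.logical(val) || length(val) != 1 || is.na(val),
    count = !is.numeric(val) || length(val) != 1 || !is.finite(val) ||
      val < 0 || val != round(val))
  if (bad)
    stop_named("invalid_config", "config key '%s' is invalid (%s required)",
               key, kind)
  invisible(val)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, merges it over package defaults, and validates every
#' key. Unknown keys and out-of-range values are rejected with the
#' offending key named, so typos fail loudly rather than being silently
#' ignored.
#'
#' @param path YAML file; `NULL` returns the defaults
#' @return validated config list
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_named("unreadable_file", "config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop_named("invalid_config", "config must be a mapping")
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop_named("invalid_config", "unknown config key(s): %s",
                 paste(unknown, collapse = ", "))
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && !is.null(names(cfg[[k]]))) {
        sub_unknown <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(sub_unknown))
          stop_named("invalid_config", "unknown config key(s): %s",
                     paste(paste0(k, ".", sub_unknown), collapse = ", "))
        for (s in names(user[[k]])) cfg[[k]][[s]] <- user[[k]][[s]]
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  vs <- cfg$voxel_size
  if (!is.numeric(vs) || length(vs) != 3 || any(!is.finite(vs)) ||
      any(vs <= 0))
    stop_named("invalid_config",
               "config key 'voxel_size' must be 3 positive numbers (z, y, x)")
  if (!is.list(cfg$channels) || length(cfg$channels) < 1 ||
      is.null(names(cfg$channels)) || any(names(cfg$channels) == ""))
    stop_named("invalid_config",
               "config key 'channels' must be a named mapping of page indices")
  check_scalar(cfg$seed, "seed", "count")

  check_scalar(cfg$qc$max_flatness_cv, "qc.max_flatness_cv", "positive")
  check_scalar(cfg$qc$max_saturated_fraction, "qc.max_saturated_fraction",
               "nonneg")
  check_scalar(cfg$qc$min_noise_margin, "qc.min_noise_margin", "positive")
  check_scalar(cfg$qc$drop_fraction, "qc.drop_fraction", "positive")
  if (cfg$qc$drop_fraction >= 1)
    stop_named("invalid_config", "config key 'qc.drop_fraction' must be < 1")
  check_scalar(cfg$qc$smooth_window, "qc.smooth_window", "count")

  check_scalar(cfg$nuclei$smooth_sigma, "nuclei.smooth_sigma", "nonneg")
  check_scalar(cfg$nuclei$split_depth, "nuclei.split_depth", "positive")
  check_scalar(cfg$nuclei$min_nucleus_volume, "nuclei.min_nucleus_volume",
               "nonneg")
  check_scalar(cfg$nuclei$measure_dilation, "nuclei.measure_dilation",
               "nonneg")

  for (k in c("membrane_ridge_threshold", "boundary_level", "merge_threshold",
              "merge_interface_quantile"))
    if (!is.null(cfg$cells[[k]]))
      check_scalar(cfg$cells[[k]], paste0("cells.", k), "nonneg")
  if (!is.null(cfg$cells$merge_interface_quantile) &&
      cfg$cells$merge_interface_quantile > 1)
    stop_named("invalid_config",
               "config key 'cells.merge_interface_quantile' must be in [0, 1]")
  check_scalar(cfg$cells$min_cytoplasm_shell_fraction,
               "cells.min_cytoplasm_shell_fraction", "nonneg")
  check_scalar(cfg$cells$membrane_coverage_floor,
               "cells.membrane_coverage_floor", "nonneg")
  check_scalar(cfg$cells$max_growth_distance, "cells.max_growth_distance",
               "positive")
  check_scalar(cfg$cells$fill_holes, "cells.fill_holes", "flag")
  check_scalar(cfg$cells$smooth_sigma, "cells.smooth_sigma", "nonneg")

  check_scalar(cfg$ploidy$log2_tolerance, "ploidy.log2_tolerance", "positive")
  if (cfg$ploidy$log2_tolerance >= 0.5)
    stop_named("invalid_config",
               "config key 'ploidy.log2_tolerance' must be < 0.5")
  check_scalar(cfg$ploidy$max_class, "ploidy.max_class", "count")
  check_scalar(cfg$ploidy$require_qc_pass, "ploidy.require_qc_pass", "flag")
  check_scalar(cfg$ploidy$min_control_n, "ploidy.min_control_n", "count")
  check_scalar(cfg$ploidy$control_genome_copies,
               "ploidy.control_genome_copies", "positive")
  cfg
}
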