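# Acquisition quality control for quantitative ploidy densitometry. A usable
# stack has a flat nuclear-channel mean-intensity profile through the tissue
# core with a terminal drop-off where the section ends, essentially no
# saturated voxels, and core signal well above the background level.

#' QC thresholds
#'
#' Operational defaults turning "flat", "not close to saturation" and "above
#' the noise floor" into testable criteria. All configurable.
#'
#' @param max_flatness_cv maximum coefficient of variation of smoothed plane
#'   means over the tissue core
#' @param max_saturated_fraction maximum fraction of voxels at the saturation
#'   limit
#' @param min_noise_margin minimum ratio of the lowest core plane mean to the
#'   background level (histogram mode)
#' @param drop_fraction a trailing plane belongs to the drop-off when its
#'   smoothed mean falls below `drop_fraction` times the core level (75th
#'   percentile of smoothed plane means)
#' @param smooth_window moving-mean window (planes) applied to the profile
#' @return a `qc_params` list
#' @export
qc_params <- function(max_flatness_cv = 0.10,
                      max_saturated_fraction = 1e-3,
                      min_noise_margin = 3,
                      drop_fraction = 0.5,
                      smooth_window = 3L) {
  stopifnot(max_flatness_cv > 0, max_saturated_fraction >= 0,
            max_saturated_fraction <= 1, min_noise_margin >= 0,
            drop_fraction > 0, drop_fraction < 1, smooth_window >= 1)
  structure(list(max_flatness_cv = max_flatness_cv,
                 max_saturated_fraction = max_saturated_fraction,
                 min_noise_margin = min_noise_margin,
                 drop_fraction = drop_fraction,
                 smooth_window = as.integer(smooth_window)),
            class = "qc_params")
}

#' Per-plane mean intensity profile of a channel
#'
#' @param stack a `ZStack`
#' @param channel channel name (typically `"DAPI"`)
#' @return an `IntensityProfile` data.frame with columns `plane`, `depth_um`
#'   (distance from the first plane) and `mean_intensity`
#' @export
compute_profile <- function(stack, channel = "DAPI") {
  ch <- get_channel(stack, channel)
  nzp <- dim(ch)[1]
  mu <- rowMeans(matrix(ch, nrow = nzp))
  structure(data.frame(plane = seq_len(nzp),
                       depth_um = (seq_len(nzp) - 1) * stack$voxel_size[1],
                       mean_intensity = mu),
            channel = channel, class = c("IntensityProfile", "data.frame"))
}

# centred moving mean, shrinking window at the ends
moving_mean <- function(x, w) {
  if (w <= 1 || length(x) < 2) return(x)
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Assess a nuclear-channel profile against the QC criteria
#'
#' The terminal drop-off is the maximal suffix of the smoothed profile whose
#' values fall below `drop_fraction` times the core level (the 75th
#' percentile of smoothed plane means); the core is every plane before it.
#' `flatness_cv` is the CV of smoothed core plane means, `saturated_fraction`
#' the fraction of channel voxels at the saturation limit, and
#' `noise_floor_margin` the ratio of the minimum smoothed core plane mean to
#' the background level (mode of the intensity histogram). The report passes
#' when all three criteria pass.
#'
#' @param profile an `IntensityProfile` from [compute_profile()]
#' @param stack the `ZStack` the profile was computed from
#' @param params a [qc_params()]
#' @param saturation_limit intensity treated as saturated; defaults to
#'   `2^bit_depth - 1`
#' @return a `QCReport` list with the measured quantities, per-criterion
#'   flags, the thresholds used, and an overall `pass` flag
#' @export
assess_dapi_profile <- function(profile, stack, params = qc_params(),
                                saturation_limit = NULL) {
  channel <- attr(profile, "channel") %||% "DAPI"
  ch <- get_channel(stack, channel)
  if (nrow(profile) != dim(ch)[1])
    stop_named("geometry_mismatch",
               "profile has %d planes but the stack has %d",
               nrow(profile), dim(ch)[1])
  if (is.null(saturation_limit)) saturation_limit <- 2^stack$bit_depth - 1

  p <- moving_mean(profile$mean_intensity, params$smooth_window)
  n <- length(p)
  core_level <- unname(quantile(p, 0.75, names = FALSE))
  tau <- params$drop_fraction * core_level
  below <- p < tau
  # maximal suffix below tau
  drop_start <- NA_integer_
  if (n > 1 && below[n]) {
    s <- n
    while (s > 1 && below[s - 1]) s <- s - 1
    if (s > 1) drop_start <- s
  }
  core <- if (is.na(drop_start)) seq_len(n) else seq_len(drop_start - 1)

  flatness_cv <- if (length(core) > 1 && mean(p[core]) > 0)
    stats::sd(p[core]) / mean(p[core]) else 0
  saturated_fraction <- mean(ch >= saturation_limit)
  background_level <- histogram_mode(ch)
  noise_floor_margin <- if (background_level > 0)
    min(p[core]) / background_level else Inf

  flags <- list(
    flatness = flatness_cv <= params$max_flatness_cv,
    saturation = saturated_fraction <= params$max_saturated_fraction,
    noise_floor = noise_floor_margin >= params$min_noise_margin)

  structure(list(
    channel = channel,
    flatness_cv = flatness_cv,
    dropoff_start = drop_start,
    saturated_fraction = saturated_fraction,
    background_level = background_level,
    noise_floor_margin = noise_floor_margin,
    criteria = flags,
    pass = all(unlist(flags)),
    params = params,
    saturation_limit = saturation_limit), class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QC report (%s): %s\n", x$channel,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  flatness CV over core: %.4f (max %.4f) %s\n", x$flatness_cv,
              x$params$max_flatness_cv, if (x$criteria$flatness) "ok" else "FAIL"))
  cat(sprintf("  saturated fraction:    %.2e (max %.2e) %s\n",
              x$saturated_fraction, x$params$max_saturated_fraction,
              if (x$criteria$saturation) "ok" else "FAIL"))
  cat(sprintf("  noise-floor margin:    %.2f (min %.2f) %s\n",
              x$noise_floor_margin, x$params$min_noise_margin,
              if (x$criteria$noise_floor) "ok" else "FAIL"))
  if (!is.na(x$dropoff_start))
    cat(sprintf("  terminal drop-off from plane %d\n", x$dropoff_start))
  invisible(x)
}

#' Serialise a QC report to JSON (thresholds included)
#' @param report a `QCReport`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_qc_report <- function(report, path) {
  out <- report
  out$dropoff_start <- if (is.na(out$dropoff_start)) NULL else out$dropoff_start
  class(out) <- NULL
  out$params <- unclass(out$params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
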