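# Core containers: a two-channel 3D stack and an integer label volume,
# both carrying voxel geometry. Arrays are indexed [z, y, x]; voxel sizes
# are (z, y, x) extents in micrometres.

#' Construct a ZStack
#'
#' A `ZStack` holds one or more named 3D intensity channels of identical
#' shape (typically `"DAPI"` for the nuclear stain and `"WGA"` for the
#' membrane stain), the voxel extents in micrometres, the nominal bit depth,
#' and free-text provenance.
#'
#' @param channels named list of 3D numeric arrays with identical dimensions,
#'   indexed `[z, y, x]`
#' @param voxel_size numeric length-3, voxel extents (z, y, x) in micrometres
#' @param bit_depth bits per sample (saturation at `2^bit_depth - 1`)
#' @param provenance free text identifying the source acquisition
#' @return an object of class `ZStack`
#' @export
zstack <- function(channels, voxel_size, bit_depth = 16L, provenance = "") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_named("invalid_stack", "channels must be a named list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop_named("invalid_stack", "every channel must be a 3D array")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop_named("invalid_stack", "all channels must share the same shape")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop_named("invalid_voxel_size",
               "voxel_size must be 3 strictly positive extents (z, y, x) in um")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop_named("invalid_stack", "intensities must be non-negative")
  structure(list(channels = channels,
                 voxel_size = setNames(voxel_size, c("z", "y", "x")),
                 bit_depth = as.integer(bit_depth),
                 provenance = provenance),
            class = "ZStack")
}

#' Extract a channel array from a ZStack
#' @param stack a `ZStack`
#' @param channel channel name
#' @return the 3D intensity array
#' @export
get_channel <- function(stack, channel) {
  if (!channel %in% names(stack$channels))
    stop_named("unknown_channel", "channel '%s' not present (have: %s)",
               channel, paste(names(stack$channels), collapse = ", "))
  stack$channels[[channel]]
}

#' @export
print.ZStack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("ZStack: %d x %d x %d voxels (z,y,x), channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size (um): %.3g x %.3g x %.3g, %d-bit\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$bit_depth))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Construct a LabelVolume
#'
#' Integer-labelled 3D volume (0 = background) geometrically registered to a
#' `ZStack`.
#'
#' @param labels 3D array of non-negative integers
#' @param voxel_size voxel extents (z, y, x) in micrometres
#' @param kind `"nuclei"` or `"cells"`
#' @return an object of class `LabelVolume`
#' @export
label_volume <- function(labels, voxel_size, kind = c("nuclei", "cells")) {
  kind <- match.arg(kind)
  if (length(dim(labels)) != 3L)
    stop_named("invalid_labels", "labels must be a 3D array")
  if (any(labels < 0))
    stop_named("invalid_labels", "labels must be non-negative integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_named("invalid_voxel_size",
               "voxel_size must be 3 strictly positive extents (z, y, x) in um")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 voxel_size = setNames(voxel_size, c("z", "y", "x")),
                 kind = kind),
            class = "LabelVolume")
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("LabelVolume (%s): %d x %d x %d voxels, %d labels\n",
              x$kind, d[1], d[2], d[3], max(x$labels)))
  invisible(x)
}

# geometry compatibility check used by operations pairing stacks and labels
check_same_geometry <- function(a, b) {
  da <- if (inherits(a, "ZStack")) dim(a$channels[[1]]) else dim(a$labels)
  db <- if (inherits(b, "ZStack")) dim(b$channels[[1]]) else dim(b$labels)
  if (!identical(as.integer(da), as.integer(db)) ||
      max(abs(a$voxel_size - b$voxel_size)) > 1e-9)
    stop_named("geometry_mismatch",
               "inputs are not registered to the same stack geometry")
  invisible(TRUE)
}
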