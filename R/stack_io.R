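# Reading and writing image stacks, label volumes and per-object tables.
# Stacks are multi-page TIFF, pages ordered z-major with the channel index
# varying fastest; geometry metadata (voxel size, channel names, bit depth)
# travels in a JSON sidecar `<path>.meta.json` written alongside. Foreign
# plain TIFFs are read by supplying `channel_map` and `voxel_size` explicitly.

meta_path <- function(path) paste0(path, ".meta.json")

#' Write a ZStack to multi-page TIFF (+ JSON geometry sidecar)
#'
#' Intensities are quantised to the stack's bit depth; round-trips through
#' [read_stack()] are lossless for integer-valued stacks within that depth.
#'
#' @param stack a `ZStack`
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path) {
  dm <- dim(stack$channels[[1]])
  maxv <- 2^stack$bit_depth - 1
  pages <- vector("list", dm[1] * length(stack$channels))
  k <- 0L
  for (z in seq_len(dm[1]))
    for (ch in stack$channels) {
      k <- k + 1L
      pages[[k]] <- pmin(ch[z, , ], maxv) / maxv
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(list(
    type = "ZStack",
    shape = dm,
    channels = names(stack$channels),
    voxel_size_um = unname(stack$voxel_size),
    bit_depth = stack$bit_depth,
    provenance = stack$provenance
  ), meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ZStack from multi-page TIFF
#'
#' Geometry comes from the JSON sidecar written by [write_stack()] when
#' present; explicit arguments override it. For foreign TIFFs without a
#' sidecar both `channel_map` and `voxel_size` are required.
#'
#' @param path TIFF path
#' @param channel_map named list/vector mapping channel names to the channel
#'   slot within each z-position (e.g. `list(DAPI = 1, WGA = 2)`); pages are
#'   assumed z-major with channel varying fastest
#' @param voxel_size voxel extents (z, y, x) in um; overrides the sidecar
#' @param bit_depth bits per sample (default from sidecar, else 16)
#' @return a `ZStack`
#' @export
read_stack <- function(path, channel_map = NULL, voxel_size = NULL,
                       bit_depth = NULL) {
  if (!file.exists(path))
    stop_named("unreadable_file", "cannot read stack: '%s' does not exist", path)
  meta <- if (file.exists(meta_path(path)))
    jsonlite::read_json(meta_path(path), simplifyVector = TRUE) else NULL
  if (is.null(channel_map) && !is.null(meta))
    channel_map <- setNames(as.list(seq_along(meta$channels)), meta$channels)
  if (is.null(channel_map))
    stop_named("missing_channel_map",
               "no metadata sidecar found; supply channel_map explicitly")
  if (is.null(voxel_size) && !is.null(meta)) voxel_size <- meta$voxel_size_um
  if (is.null(voxel_size))
    stop_named("missing_voxel_size",
               "voxel_size metadata missing for '%s' and no override given", path)
  if (is.null(bit_depth)) bit_depth <- meta$bit_depth %||% 16L

  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nc <- max(unlist(channel_map))
  if (length(pages) %% nc != 0)
    stop_named("missing_channel",
               "page count %d is not a multiple of the %d mapped channels",
               length(pages), nc)
  nzp <- length(pages) %/% nc
  dmp <- dim(pages[[1]])
  channels <- lapply(channel_map, function(ci) {
    arr <- array(0, c(nzp, dmp[1], dmp[2]))
    for (z in seq_len(nzp)) arr[z, , ] <- pages[[(z - 1) * nc + ci]]
    arr
  })
  zstack(channels, voxel_size, bit_depth = bit_depth, provenance = path)
}

#' Write a LabelVolume to multi-page TIFF (+ JSON sidecar)
#' @param labels a `LabelVolume`
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_labels <- function(labels, path) {
  mx <- max(labels$labels)
  if (mx > 65535)
    stop_named("label_overflow", "label ids exceed 16-bit range (%d)", mx)
  dm <- dim(labels$labels)
  pages <- lapply(seq_len(dm[1]), function(z) labels$labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(list(
    type = "LabelVolume", kind = labels$kind, shape = dm,
    voxel_size_um = unname(labels$voxel_size)
  ), meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a LabelVolume written by [write_labels()]
#' @param path TIFF path
#' @param voxel_size,kind overrides for foreign files without a sidecar
#' @return a `LabelVolume`
#' @export
read_labels <- function(path, voxel_size = NULL, kind = NULL) {
  if (!file.exists(path))
    stop_named("unreadable_file", "cannot read labels: '%s' does not exist", path)
  meta <- if (file.exists(meta_path(path)))
    jsonlite::read_json(meta_path(path), simplifyVector = TRUE) else NULL
  if (is.null(voxel_size)) voxel_size <- meta$voxel_size_um
  if (is.null(voxel_size))
    stop_named("missing_voxel_size",
               "voxel_size metadata missing for '%s' and no override given", path)
  if (is.null(kind)) kind <- meta$kind %||% "cells"
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  arr <- array(0L, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  label_volume(arr, voxel_size, kind)
}

#' Write a records table to CSV
#'
#' Comma-separated, UTF-8, header row, "." decimal separator; an empty record
#' list yields a header-only file.
#'
#' @param records a data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a records table written by [write_table()]
#' @param path CSV path
#' @return a data.frame
#' @export
read_table <- function(path) {
  if (!file.exists(path))
    stop_named("unreadable_file", "cannot read table: '%s' does not exist", path)
  read.csv(path, fileEncoding = "UTF-8")
}
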