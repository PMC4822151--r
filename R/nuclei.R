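# 3D nucleus segmentation and densitometry on the nuclear channel.
# Foreground by global Otsu threshold of the Gaussian-smoothed channel,
# connected components (26-connectivity), touching nuclei split by watershed
# on the negated anisotropic distance transform seeded at h-maxima, and
# per-nucleus background-corrected integrated intensity -- the densitometric
# quantity the ploidy calibration consumes.

#' Nucleus segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing sigma in um (physical units,
#'   honoured per axis for anisotropic voxels)
#' @param split_depth minimum depth (um) of a distance-transform maximum for
#'   it to seed a split of touching nuclei (h-maxima height)
#' @param min_nucleus_volume smallest retained component, um^3
#' @param measure_dilation distance (um) each nucleus label is grown (into
#'   unclaimed background, nearest-nucleus wins) for the integrated-intensity
#'   measurement only. The segmentation mask erodes object edges slightly,
#'   and edge voxels hold real signal; densitometry must capture it or dim
#'   nuclei are penalised more than bright ones. Morphology (volume,
#'   centroid) always uses the undilated label.
#' @return a `nuclei_params` list
#' @export
nuclei_params <- function(smooth_sigma = 0.5, split_depth = 1.0,
                          min_nucleus_volume = 20, measure_dilation = 1.0) {
  stopifnot(smooth_sigma >= 0, split_depth > 0, min_nucleus_volume >= 0,
            measure_dilation >= 0)
  structure(list(smooth_sigma = smooth_sigma, split_depth = split_depth,
                 min_nucleus_volume = min_nucleus_volume,
                 measure_dilation = measure_dilation),
            class = "nuclei_params")
}

#' Estimate the background level of a channel
#'
#' Mode of the binned intensity histogram -- the dominant (background) value.
#' Integrated intensities are corrected by this level so they reflect stain
#' content rather than detector offset.
#'
#' @param stack a `ZStack`
#' @param channel channel name
#' @param n_bins histogram bins
#' @return background intensity level
#' @export
estimate_background <- function(stack, channel = "DAPI", n_bins = 256L) {
  histogram_mode(get_channel(stack, channel), n_bins)
}

blur_stack_channel <- function(ch, voxel_size, sigma_um) {
  if (sigma_um <= 0) return(ch)
  blur3d_cpp(as.numeric(ch), dim(ch), sigma_um / voxel_size)
}

# seeds for splitting: connected regions of regional maxima of the h-maxima
# transform of the distance map, restricted to the foreground
split_seeds <- function(dist, fg, dm, h) {
  hmax <- grey_reconstruct3d_cpp(dist - h, dist, dm)
  eps <- 1e-3
  rec <- grey_reconstruct3d_cpp(hmax - eps, hmax, dm)
  rmax <- (hmax - rec) > eps / 2 & fg
  cc_label3d_cpp(rmax, dm, 26L)
}

#' Segment nuclei in 3D and measure per-nucleus records
#'
#' @param stack a `ZStack` with the nuclear channel
#' @param params a [nuclei_params()]
#' @param channel nuclear channel name
#' @param background background level; estimated with
#'   [estimate_background()] when `NULL`
#' @return list with `labels` (a nuclei `LabelVolume`), `records` (one row
#'   per nucleus: id, centroid um, voxel_count, volume um^3,
#'   `integrated_intensity` = sum of `max(intensity - background, 0)` over
#'   the component, `touches_border`, `owning_cell` (NA until cells are
#'   segmented), `ploidy_class` "unset"), and `background`
#' @export
segment_nuclei <- function(stack, params = nuclei_params(), channel = "DAPI",
                           background = NULL) {
  ch <- get_channel(stack, channel)
  dm <- dim(ch)
  vox <- stack$voxel_size
  if (is.null(background)) background <- estimate_background(stack, channel)

  sm <- blur_stack_channel(ch, vox, params$smooth_sigma)
  thr <- otsu_threshold(sm)
  fg <- sm > thr
  empty <- function() list(
    labels = label_volume(array(0L, dm), vox, "nuclei"),
    records = data.frame(id = integer(0), centroid_z = numeric(0),
                         centroid_y = numeric(0), centroid_x = numeric(0),
                         voxel_count = integer(0), volume_um3 = numeric(0),
                         integrated_intensity = numeric(0),
                         touches_border = logical(0),
                         owning_cell = integer(0),
                         ploidy_class = character(0)),
    background = background, threshold = thr)
  if (!any(fg)) return(empty())

  dist <- edt3d_cpp(!fg, dm, vox)      # distance of each voxel to background
  seeds <- split_seeds(dist, fg, dm, params$split_depth)
  lab <- watershed3d_cpp(-dist, seeds, fg, dm)
  # components that contained no seed (possible for very shallow objects)
  leftover <- fg & lab == 0L
  if (any(leftover)) {
    extra <- cc_label3d_cpp(leftover, dm, 26L)
    lab[leftover] <- extra[leftover] + max(lab)
  }

  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * prod(vox) >= params$min_nucleus_volume)
  if (length(keep) == 0) return(empty())
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  lab_arr <- array(0L, dm)
  pos <- lab > 0L
  lab_arr[pos] <- remap[lab[pos]]

  cen <- label_centroids_um(lab_arr, vox)
  counts <- tabulate(lab_arr[lab_arr > 0L], nbins = length(keep))
  corrected <- pmax(ch - background, 0)
  mlab <- lab_arr
  if (params$measure_dilation > 0) {
    # grow labels by the measurement dilation, nearest nucleus winning, so
    # edge signal excluded by the foreground mask is still integrated
    ddist <- edt3d_cpp(lab_arr > 0L, dm, vox)
    mlab <- watershed3d_cpp(ddist, lab_arr,
                            ddist <= params$measure_dilation, dm)
  }
  ii <- rowsum(corrected[mlab > 0L], mlab[mlab > 0L])
  border_ids <- labels_touching_border(lab_arr)

  records <- data.frame(
    id = seq_along(keep),
    centroid_z = cen[, "z"], centroid_y = cen[, "y"], centroid_x = cen[, "x"],
    voxel_count = counts,
    volume_um3 = counts * prod(vox),
    integrated_intensity = as.numeric(ii),
    touches_border = seq_along(keep) %in% border_ids,
    owning_cell = NA_integer_,
    ploidy_class = "unset")
  rownames(records) <- NULL
  list(labels = label_volume(lab_arr, vox, "nuclei"), records = records,
       background = background, threshold = thr)
}
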