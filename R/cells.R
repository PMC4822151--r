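# Cardiomyocyte delineation: nuclear seeds grown to the limits of the
# membrane staining by marker-controlled watershed on the smoothed membrane
# channel, followed by interface-based region merging (which yields
# multinucleated cells), optional 3D hole filling, and the exclusion rules
# (border contact, nuclei without surrounding cytoplasm, incomplete
# membrane, manual edits).

#' Cell segmentation parameters
#'
#' @param membrane_ridge_threshold absolute membrane intensity above which a
#'   voxel is treated as membrane (a growth barrier); `NULL` selects it
#'   automatically by global Otsu on the smoothed membrane channel
#' @param boundary_level intensity at which the cell boundary is placed
#'   (the edge of the growth mask). `NULL` selects the half-maximum
#'   criterion: the midpoint between the image base level (histogram mode)
#'   and the membrane ridge peak (95th percentile of above-ridge-threshold
#'   voxels). Half-maximum edge placement keeps the measured boundary at
#'   the true membrane edge independent of the smoothing width, which a
#'   plain foreground threshold does not.
#' @param merge_threshold interface mean intensity below which two adjacent
#'   regions are merged into one (multinucleated) cell; defaults to the
#'   ridge threshold -- true membranes lie at or above it, cytoplasmic
#'   watershed partitions below
#' @param merge_interface_quantile optional alternative merge rule: merge
#'   interfaces below this quantile of all interface mean intensities
#' @param min_cytoplasm_shell_fraction minimum fraction of a nucleus's
#'   1-voxel dilation shell that must lie in its cell for the nucleus to
#'   count as "surrounded by cytoplasm"
#' @param membrane_coverage_floor minimum fraction of a cell's surface that
#'   must face above-threshold membrane signal
#' @param max_growth_distance maximum seed growth distance, um
#' @param fill_holes make each cell cavity-free in 3D
#' @param smooth_sigma Gaussian smoothing sigma for the membrane channel, um
#' @return a `segmentation_params` list
#' @export
segmentation_params <- function(membrane_ridge_threshold = NULL,
                                boundary_level = NULL,
                                merge_threshold = NULL,
                                merge_interface_quantile = NULL,
                                min_cytoplasm_shell_fraction = 0.5,
                                membrane_coverage_floor = 0.7,
                                max_growth_distance = 30,
                                fill_holes = TRUE,
                                smooth_sigma = 0.35) {
  stopifnot(min_cytoplasm_shell_fraction >= 0, min_cytoplasm_shell_fraction <= 1,
            membrane_coverage_floor >= 0, membrane_coverage_floor <= 1,
            max_growth_distance > 0, smooth_sigma >= 0)
  if (!is.null(merge_interface_quantile))
    stopifnot(merge_interface_quantile >= 0, merge_interface_quantile <= 1)
  structure(list(membrane_ridge_threshold = membrane_ridge_threshold,
                 boundary_level = boundary_level,
                 merge_threshold = merge_threshold,
                 merge_interface_quantile = merge_interface_quantile,
                 min_cytoplasm_shell_fraction = min_cytoplasm_shell_fraction,
                 membrane_coverage_floor = membrane_coverage_floor,
                 max_growth_distance = max_growth_distance,
                 fill_holes = isTRUE(fill_holes),
                 smooth_sigma = smooth_sigma),
            class = "segmentation_params")
}

#' Brightness inversion of a channel
#'
#' Returns `max(channel) - intensity` per voxel (bright cytoplasm, dark
#' membranes), the preprocessing some analysis suites prefer. Involutive when
#' re-applied with the same maximum.
#'
#' @param stack a `ZStack`
#' @param channel channel name
#' @param max_intensity maximum used for the inversion; defaults to the
#'   channel maximum
#' @return the inverted 3D array
#' @export
invert_brightness <- function(stack, channel = "WGA", max_intensity = NULL) {
  ch <- get_channel(stack, channel)
  if (is.null(max_intensity)) max_intensity <- max(ch)
  max_intensity - ch
}

# union-find for region merging
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Segment cells by membrane-limited seeded growth
#'
#' Seeds (one per nucleus) grow over sub-threshold voxels within
#' `max_growth_distance` of any seed, flooding the smoothed membrane channel
#' in intensity order so fronts meet at membrane ridges. Adjacent regions
#' whose shared interface shows sub-threshold mean membrane intensity are
#' merged (binucleated cells arise here). Optionally, each cell is made
#' cavity-free in 3D. Nuclei are assigned to cells by centroid containment.
#'
#' @param stack a `ZStack` with the membrane channel
#' @param nuclei result of [segment_nuclei()] (or a list with `labels` and
#'   `records`)
#' @param params a [segmentation_params()]
#' @param channel membrane channel name
#' @return list with `labels` (cells `LabelVolume`), `cells` (one row per
#'   cell: id, voxel_count, volume um^3, nucleus_ids, nuclearity,
#'   touches_border, membrane_coverage, excluded, exclusion_reason,
#'   ploidy_label), `nuclei` (records with `owning_cell` filled in), and the
#'   thresholds used
#' @export
segment_cells <- function(stack, nuclei, params = segmentation_params(),
                          channel = "WGA") {
  check_same_geometry(stack, nuclei$labels)
  ch <- get_channel(stack, channel)
  dm <- dim(ch)
  vox <- stack$voxel_size
  seeds <- nuclei$labels$labels
  nrec <- nuclei$records

  if (nrow(nrec) == 0 || max(seeds) == 0) {
    res <- cell_result(array(0L, dm), vox, nrec, NULL, NA_real_, NA_real_)
    res$nucleus_labels <- nuclei$labels
    return(res)
  }

  sm <- blur_stack_channel(ch, vox, params$smooth_sigma)
  thr <- params$membrane_ridge_threshold %||% otsu_threshold(sm)
  bl <- params$boundary_level %||% {
    above <- sm[sm > thr]
    if (length(above))
      (histogram_mode(sm) + unname(quantile(above, 0.95))) / 2
    else thr
  }

  seed_dist <- edt3d_cpp(seeds > 0L, dm, vox)
  mask <- (sm < bl & seed_dist <= params$max_growth_distance) | seeds > 0L
  lab <- watershed3d_cpp(sm, seeds, mask, dm)

  # region merging across sub-threshold interfaces
  inter <- interface_means3d_cpp(lab, sm, dm)
  merge_thr <- params$merge_threshold %||% {
    if (!is.null(params$merge_interface_quantile) && nrow(inter) > 0)
      unname(quantile(inter$mean_intensity, params$merge_interface_quantile))
    else thr
  }
  if (nrow(inter) > 0) {
    parent <- seq_len(max(lab))
    for (k in seq_len(nrow(inter))) {
      if (inter$mean_intensity[k] < merge_thr) {
        ra <- uf_find(parent, inter$a[k])
        rb <- uf_find(parent, inter$b[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), 1L)
    # compact to consecutive ids in order of first appearance (root id order)
    ids <- sort(unique(roots))
    remap <- integer(length(parent))
    remap[ids] <- seq_along(ids)
    pos <- lab > 0L
    lab[pos] <- remap[roots[lab[pos]]]
  }

  if (params$fill_holes && max(lab) > 0)
    lab <- fill_holes_all(lab, dm)

  res <- cell_result(lab, vox, nrec, sm_above = sm >= bl, thr, merge_thr)
  res$boundary_level <- bl
  res$nucleus_labels <- nuclei$labels
  res
}

# assemble cell records from a label array
cell_result <- function(lab, vox, nrec, sm_above, thr, merge_thr) {
  dm <- dim(lab)
  K <- max(lab)
  empty_cells <- data.frame(id = integer(0), voxel_count = integer(0),
                            volume_um3 = numeric(0), nucleus_ids = character(0),
                            nuclearity = integer(0), touches_border = logical(0),
                            membrane_coverage = numeric(0), excluded = logical(0),
                            exclusion_reason = character(0),
                            ploidy_label = character(0))
  if (K == 0)
    return(list(labels = label_volume(array(as.integer(lab), dm), vox, "cells"),
                cells = empty_cells, nuclei = nrec,
                ridge_threshold = thr, merge_threshold = merge_thr))

  counts <- tabulate(lab[lab > 0L], nbins = K)
  # nucleus -> cell by centroid containment
  own <- rep(NA_integer_, nrow(nrec))
  if (nrow(nrec) > 0) {
    iz <- pmin(pmax(ceiling(nrec$centroid_z / vox[1]), 1L), dm[1])
    iy <- pmin(pmax(ceiling(nrec$centroid_y / vox[2]), 1L), dm[2])
    ix <- pmin(pmax(ceiling(nrec$centroid_x / vox[3]), 1L), dm[3])
    lin <- iz + dm[1] * (iy - 1L) + dm[1] * dm[2] * (ix - 1L)
    o <- lab[lin]
    own[o > 0L] <- o[o > 0L]
  }
  nrec$owning_cell <- own
  nuc_ids <- lapply(seq_len(K), function(k) nrec$id[!is.na(own) & own == k])

  cov <- if (!is.null(sm_above) && length(sm_above) == prod(dm)) {
    sc <- surface_coverage3d_cpp(as.integer(lab), as.logical(sm_above), dm, K)
    ifelse(sc$boundary_faces > 0, sc$covered_faces / sc$boundary_faces, 0)
  } else rep(NA_real_, K)

  border_ids <- labels_touching_border(array(as.integer(lab), dm))
  cells <- data.frame(
    id = seq_len(K),
    voxel_count = counts,
    volume_um3 = counts * prod(vox),
    nucleus_ids = vapply(nuc_ids, paste, "", collapse = ";"),
    nuclearity = vapply(nuc_ids, length, 1L),
    touches_border = seq_len(K) %in% border_ids,
    membrane_coverage = cov,
    excluded = FALSE,
    exclusion_reason = NA_character_,
    ploidy_label = "unset")
  list(labels = label_volume(array(as.integer(lab), dm), vox, "cells"),
       cells = cells, nuclei = nrec,
       ridge_threshold = thr, merge_threshold = merge_thr)
}

# fill internal cavities of every cell label (vectorised over the volume):
# background components (26-connectivity) not reaching the stack exterior are
# absorbed into the unique cell label enclosing them.
fill_holes_all <- function(lab, dm) {
  bg <- lab == 0L
  comp <- cc_label3d_cpp(bg, dm, 26L)
  border <- unique(c(comp[1, , ], comp[dm[1], , ], comp[, 1, ], comp[, dm[2], ],
                     comp[, , 1], comp[, , dm[3]]))
  enclosed <- setdiff(unique(comp[comp > 0L]), border)
  for (e in enclosed) {
    idx <- which(comp == e)
    # absorb into the adjacent cell; sample one boundary neighbour
    z <- ((idx[1] - 1) %% dm[1]) + 1
    r <- (idx[1] - 1) %/% dm[1]
    y <- (r %% dm[2]) + 1
    x <- (r %/% dm[2]) + 1
    nb <- c(if (z > 1) lab[z - 1, y, x], if (z < dm[1]) lab[z + 1, y, x],
            if (y > 1) lab[z, y - 1, x], if (y < dm[2]) lab[z, y + 1, x],
            if (x > 1) lab[z, y, x - 1], if (x < dm[3]) lab[z, y, x + 1])
    nb <- nb[nb > 0L]
    if (length(nb)) lab[idx] <- nb[1]
  }
  lab
}

#' Fill internal holes of one cell
#'
#' Absorbs background cavities that are not 26-connected to the stack
#' exterior within the cell's bounding region. Surface indentations open to
#' the exterior are untouched; the operation never decreases the cell's
#' volume.
#'
#' @param labels a cells `LabelVolume`
#' @param cell_id the cell to fill
#' @return the updated `LabelVolume`
#' @export
fill_holes_3d <- function(labels, cell_id) {
  lab <- labels$labels
  dm <- dim(lab)
  sel <- which(lab == cell_id)
  if (length(sel) == 0)
    stop_named("unknown_cell", "cell id %s not present", cell_id)
  z <- ((sel - 1) %% dm[1]) + 1
  r <- (sel - 1) %/% dm[1]
  y <- (r %% dm[2]) + 1
  x <- (r %/% dm[2]) + 1
  lo <- pmax(c(min(z), min(y), min(x)) - 1L, 1L)
  hi <- pmin(c(max(z), max(y), max(x)) + 1L, dm)
  sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dms <- dim(sub)
  notcell <- sub != cell_id
  comp <- cc_label3d_cpp(notcell, dms, 26L)
  dim(comp) <- dms
  border <- unique(c(comp[1, , ], comp[dms[1], , ], comp[, 1, ],
                     comp[, dms[2], ], comp[, , 1], comp[, , dms[3]]))
  enclosed <- setdiff(unique(comp[comp > 0L]), border)
  for (e in enclosed) {
    idx <- which(comp == e & sub == 0L)  # only absorb background voxels
    sub[idx] <- as.integer(cell_id)
  }
  lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  labels$labels <- lab
  labels
}

#' Apply the exclusion rules to segmented cells
#'
#' Flags, in order of precedence: cells touching any stack face (`border`, an
#' automated proxy for partial or incomplete cells); cells none of whose
#' nuclei are surrounded by cytoplasm -- a nucleus qualifies when at least
#' `min_cytoplasm_shell_fraction` of its 1-voxel dilation shell lies inside
#' the same cell's label (`no_cytoplasm_nucleus`); cells with membrane
#' coverage below the floor (`incomplete_membrane`); ids listed in
#' `manual_exclude` (`manual`). Cells without any nucleus are excluded as
#' `no_cytoplasm_nucleus`. Nothing is dropped; reasons are recorded.
#'
#' @param seg result of [segment_cells()] (or [segment_from_mask()])
#' @param params a [segmentation_params()]
#' @param manual_exclude integer ids from a curation edit list
#' @return `seg` with `cells$excluded`/`exclusion_reason` set and a
#'   `cytoplasm_ok` column added to the nucleus records
#' @export
apply_exclusions <- function(seg, params = segmentation_params(),
                             manual_exclude = integer(0)) {
  cells <- seg$cells
  nrec <- seg$nuclei
  if (nrow(cells) == 0) return(seg)
  dm <- dim(seg$labels$labels)

  if (is.null(seg$nucleus_labels))
    stop_named("missing_labels", "nucleus labels required for exclusions")
  own <- ifelse(is.na(nrec$owning_cell), 0L, as.integer(nrec$owning_cell))
  if (nrow(nrec) > 0) {
    sh <- nucleus_shell_counts_cpp(seg$nucleus_labels$labels,
                                   seg$labels$labels, dm, own)
    frac <- ifelse(sh$shell_voxels > 0, sh$shell_in_cell / sh$shell_voxels, 0)
    nrec$cytoplasm_ok <- frac >= params$min_cytoplasm_shell_fraction &
      !is.na(nrec$owning_cell)
  }

  reason <- rep(NA_character_, nrow(cells))
  reason[cells$membrane_coverage < params$membrane_coverage_floor &
           !is.na(cells$membrane_coverage)] <- "incomplete_membrane"
  ok_by_cell <- vapply(cells$id, function(k) {
    mine <- nrec$cytoplasm_ok[!is.na(nrec$owning_cell) & nrec$owning_cell == k]
    length(mine) > 0 && any(mine)
  }, logical(1))
  reason[!ok_by_cell] <- "no_cytoplasm_nucleus"
  reason[cells$touches_border] <- "border"
  reason[cells$id %in% manual_exclude & is.na(reason)] <- "manual"

  cells$exclusion_reason <- reason
  cells$excluded <- !is.na(reason)
  seg$cells <- cells
  seg$nuclei <- nrec
  seg
}

#' Split a cell by re-seeded watershed
#'
#' Re-runs the watershed restricted to the cell's voxels using the supplied
#' seed points (physical um coordinates), used to correct abnormal seed
#' growth. The children exactly partition the parent (voxel conservation).
#'
#' @param labels a cells `LabelVolume`
#' @param cell_id cell to split
#' @param seed_points matrix of seed coordinates (rows; columns z, y, x in
#'   um); at least two, all inside the cell
#' @param elevation optional 3D array to flood (e.g. the smoothed membrane
#'   channel); defaults to distance from the seeds, giving a nearest-seed
#'   partition
#' @return the updated `LabelVolume`; children take the parent's id and
#'   `max(labels) + 1, ...`
#' @export
split_cell <- function(labels, cell_id, seed_points, elevation = NULL) {
  lab <- labels$labels
  dm <- dim(lab)
  vox <- labels$voxel_size
  if (!any(lab == cell_id))
    stop_named("unknown_cell", "cell id %s not present", cell_id)
  seed_points <- rbind(seed_points)
  if (nrow(seed_points) < 2)
    stop_named("too_few_seeds", "at least two seed points are required")
  iz <- pmin(pmax(ceiling(seed_points[, 1] / vox[1]), 1L), dm[1])
  iy <- pmin(pmax(ceiling(seed_points[, 2] / vox[2]), 1L), dm[2])
  ix <- pmin(pmax(ceiling(seed_points[, 3] / vox[3]), 1L), dm[3])
  lin <- iz + dm[1] * (iy - 1L) + dm[1] * dm[2] * (ix - 1L)
  if (any(lab[lin] != cell_id))
    stop_named("seed_outside_cell", "all seed points must lie inside cell %s",
               cell_id)
  newids <- c(as.integer(cell_id), max(lab) + seq_len(nrow(seed_points) - 1L))
  seeds <- array(0L, dm)
  seeds[lin] <- newids
  mask <- lab == cell_id
  if (is.null(elevation)) elevation <- edt3d_cpp(seeds > 0L, dm, vox)
  child <- watershed3d_cpp(as.numeric(elevation), seeds, mask, dm)
  lab[mask] <- child[mask]
  labels$labels <- lab
  labels
}

#' Merge cell labels into one
#'
#' Relabels all listed cells to the first id; the inverse of [split_cell()].
#'
#' @param labels a cells `LabelVolume`
#' @param ids integer ids to merge; the result carries `ids[1]`
#' @return the updated `LabelVolume`
#' @export
merge_cells <- function(labels, ids) {
  stopifnot(length(ids) >= 2)
  lab <- labels$labels
  lab[lab %in% ids[-1]] <- as.integer(ids[1])
  labels$labels <- lab
  labels
}

#' Segment cells from an externally supplied binary mask
#'
#' Connected components of the mask become cells (replacing membrane-channel
#' growth, e.g. for masks produced by a pixel classifier); nuclei are
#' assigned by centroid containment; downstream records are identical in
#' form to [segment_cells()] output. Membrane coverage is not defined for
#' mask input and is reported as `NA`.
#'
#' @param mask a `LabelVolume` (any non-zero voxel is cell) or 3D array
#' @param nuclei result of [segment_nuclei()]
#' @param voxel_size required when `mask` is a bare array
#' @return as [segment_cells()]
#' @export
segment_from_mask <- function(mask, nuclei, voxel_size = NULL) {
  if (inherits(mask, "LabelVolume")) {
    arr <- mask$labels
    voxel_size <- mask$voxel_size
  } else {
    arr <- mask
    if (is.null(voxel_size))
      stop_named("missing_voxel_size", "voxel_size required for a bare mask array")
  }
  dm <- dim(arr)
  if (!identical(as.integer(dm), as.integer(dim(nuclei$labels$labels))))
    stop_named("geometry_mismatch", "mask and nucleus labels differ in shape")
  lab <- cc_label3d_cpp(arr > 0, dm, 26L)
  dim(lab) <- dm
  res <- cell_result(lab, as.numeric(voxel_size), nuclei$records,
                     sm_above = NULL, thr = NA_real_, merge_thr = NA_real_)
  res$nucleus_labels <- nuclei$labels
  res
}
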