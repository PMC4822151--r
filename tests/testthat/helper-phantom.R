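# Shared fixtures (built once per session) and matching helpers.

fixture_env <- new.env(parent = emptyenv())

# a small but fully featured phantom: 4 cells, both nuclearities possible
small_phantom <- function() {
  if (is.null(fixture_env$small))
    fixture_env$small <- generate_phantom(
      phantom_spec(shape = c(40L, 192L, 192L), n_cells = 4L, seed = 21L))
  fixture_env$small
}

small_nuclei <- function() {
  if (is.null(fixture_env$nuc))
    fixture_env$nuc <- segment_nuclei(small_phantom()$stack)
  fixture_env$nuc
}

small_segmentation <- function() {
  if (is.null(fixture_env$seg)) {
    seg <- segment_cells(small_phantom()$stack, small_nuclei())
    fixture_env$seg <- apply_exclusions(seg)
  }
  fixture_env$seg
}

# the label found under each truth centroid (columns centroid_z/y/x in um)
labels_at_centroids <- function(truth_df, labels) {
  dm <- dim(labels$labels)
  vox <- labels$voxel_size
  iz <- pmin(pmax(ceiling(truth_df$centroid_z / vox[1]), 1L), dm[1])
  iy <- pmin(pmax(ceiling(truth_df$centroid_y / vox[2]), 1L), dm[2])
  ix <- pmin(pmax(ceiling(truth_df$centroid_x / vox[3]), 1L), dm[3])
  labels$labels[cbind(iz, iy, ix)]
}
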