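test_that("nucleus segmentation recovers every nucleus in a sparse field", {
  sp <- phantom_spec(shape = c(32L, 128L, 128L), n_cells = 20L, seed = 13L)
  fld <- generate_nuclei_field(sp)
  nuc <- segment_nuclei(fld$stack)
  expect_equal(nrow(nuc$records), 20)
  # one segmented label directly under each true centroid, all distinct
  ids <- labels_at_centroids(fld$truth$nuclei, nuc$labels)
  expect_true(all(ids > 0))
  expect_equal(length(unique(ids)), 20)
  # volumes are approximate (a global threshold sits at a class-dependent
  # fraction of each nucleus's peak); the calibrated quantity is the
  # integrated intensity, tested tightly below
  at <- match(ids, nuc$records$id)
  verr <- nuc$records$voxel_count[at] / fld$truth$nuclei$voxel_count - 1
  expect_lt(max(abs(verr)), 0.5)
})

test_that("integrated intensity tracks truth within a few percent", {
  sp <- phantom_spec(shape = c(32L, 128L, 128L), n_cells = 20L, seed = 14L)
  fld <- generate_nuclei_field(sp)
  nuc <- segment_nuclei(fld$stack)
  ids <- labels_at_centroids(fld$truth$nuclei, nuc$labels)
  at <- match(ids, nuc$records$id)
  ratio <- nuc$records$integrated_intensity[at] / fld$truth$nuclei$true_intensity
  expect_lt(max(abs(ratio - 1)), 0.05)
  # and the 2x ploidy structure survives measurement
  cls <- fld$truth$nuclei$ploidy_class
  if (all(c("2n", "4n") %in% cls)) {
    m2 <- median(nuc$records$integrated_intensity[at][cls == "2n"])
    m4 <- median(nuc$records$integrated_intensity[at][cls == "4n"])
    expect_equal(m4 / m2, 2, tolerance = 0.1)
  }
})

test_that("touching nuclei are split by the distance-transform watershed", {
  dm <- c(24L, 48L, 48L)
  vox <- c(0.5, 0.5, 0.5)
  dapi <- array(100, dm)
  # two spheres of radius 3 um with centres 5 um apart: one connected
  # component with a necked waist between the lobes
  centers <- list(c(6, 12, 9.5), c(6, 12, 14.5))
  for (C in centers) {
    zi <- rep(seq_len(dm[1]), times = dm[2] * dm[3])
    yi <- rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3])
    xi <- rep(seq_len(dm[3]), each = dm[1] * dm[2])
    d2 <- ((zi - 0.5) * vox[1] - C[1])^2 + ((yi - 0.5) * vox[2] - C[2])^2 +
      ((xi - 0.5) * vox[3] - C[3])^2
    dapi[d2 <= 9] <- 4000
  }
  st <- zstack(list(DAPI = dapi), vox)
  # the saddle between these lobes is ~0.5 um below the lobe maxima
  nuc <- segment_nuclei(st, nuclei_params(split_depth = 0.5))
  expect_equal(nrow(nuc$records), 2)
  expect_equal(sort(nuc$records$centroid_x), c(9.5, 14.5), tolerance = 0.05)
})

test_that("minimum volume filter and border flag behave", {
  sp <- phantom_spec(shape = c(24L, 96L, 96L), n_cells = 8L, seed = 15L)
  fld <- generate_nuclei_field(sp)
  # an aggressive volume floor removes everything
  nuc <- segment_nuclei(fld$stack,
                        nuclei_params(min_nucleus_volume = 1e6))
  expect_equal(nrow(nuc$records), 0)
  expect_equal(max(nuc$labels$labels), 0)
  # lattice fields keep a margin, so nothing touches the border
  nuc2 <- segment_nuclei(fld$stack)
  expect_false(any(nuc2$records$touches_border))
  expect_true(all(nuc2$records$ploidy_class == "unset"))
})

test_that("background estimate matches the generator's background level", {
  fld <- small_phantom()
  bg <- estimate_background(fld$stack, "DAPI")
  expect_equal(bg, 100, tolerance = 0.1)
})
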