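test_that("phantom_spec validates fields", {
  expect_s3_class(phantom_spec(), "PhantomSpec")
  expect_error(phantom_spec(n_cells = -1), class = "invalid_spec")
  expect_error(phantom_spec(voxel_size = c(0.5, 0, 0.5)),
               class = "invalid_spec")
  expect_error(phantom_spec(nuclearity_probs = c("1" = 0.4, "2" = 0.4)),
               class = "invalid_spec")
  # length is tip-to-tip, so it must exceed the diameter
  expect_error(phantom_spec(cell_length_range = c(8, 10),
                            cell_diameter_range = c(9, 12)),
               class = "invalid_spec")
})

test_that("phantom generation is deterministic for a given seed", {
  sp <- phantom_spec(shape = c(40L, 160L, 160L), n_cells = 2L, seed = 5L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- generate_phantom(phantom_spec(shape = c(40L, 160L, 160L), n_cells = 2L,
                                     seed = 6L))
  expect_false(identical(a$stack$channels$DAPI, c$stack$channels$DAPI))
})

test_that("ground truth tables are consistent with the label volumes", {
  ph <- small_phantom()
  tr <- ph$truth
  expect_equal(nrow(tr$cells), 4)
  # per-cell voxel counts match the label volume exactly
  counts <- tabulate(tr$cell_labels$labels[tr$cell_labels$labels > 0],
                     nbins = nrow(tr$cells))
  expect_equal(tr$cells$voxel_count, counts)
  expect_equal(tr$cells$volume_um3, counts * voxel_volume(tr$cell_labels))
  # every nucleus lies inside its own cell
  for (i in seq_len(nrow(tr$nuclei))) {
    sel <- tr$nucleus_labels$labels == tr$nuclei$nucleus_id[i]
    expect_true(all(tr$cell_labels$labels[sel] == tr$nuclei$cell_id[i]))
  }
  # nuclearity matches the nucleus table
  per_cell <- table(factor(tr$nuclei$cell_id, levels = tr$cells$cell_id))
  expect_equal(tr$cells$nuclearity, as.integer(per_cell))
  # membrane shells must not overlap: no cell voxel may belong to two cells
  expect_true(all(tr$cells$voxel_count > 0))
})

test_that("nuclei-only fields honour count, class mix and intensity scaling", {
  sp <- phantom_spec(shape = c(32L, 128L, 128L), n_cells = 25L, seed = 9L)
  fld <- generate_nuclei_field(sp)
  expect_equal(nrow(fld$truth$nuclei), 25)
  expect_equal(nrow(fld$truth$cells), 0)
  expect_setequal(unique(fld$truth$nuclei$ploidy_class), c("2n", "4n"))
  i2 <- fld$truth$nuclei$true_intensity[fld$truth$nuclei$ploidy_class == "2n"]
  expect_true(all(abs(i2 / sp$reference_2n_intensity - 1) < 0.3))

  ctl <- generate_control_field(sp, control_genome_copies = 1)
  expect_equal(nrow(ctl$truth$nuclei), 25)
  ic <- ctl$truth$nuclei$true_intensity
  expect_true(all(abs(ic / (sp$reference_2n_intensity / 2) - 1) < 0.3))
  expect_error(generate_control_field(sp, control_genome_copies = 0),
               class = "invalid_control")
})

test_that("z attenuation multiplies plane means exponentially", {
  ph <- small_phantom()
  att <- apply_z_attenuation(ph$stack, 0.05)
  p0 <- compute_profile(ph$stack)$mean_intensity
  p1 <- compute_profile(att)$mean_intensity
  depth <- compute_profile(ph$stack)$depth_um
  expect_equal(p1, p0 * exp(-0.05 * depth), tolerance = 1e-12)
  expect_identical(apply_z_attenuation(ph$stack, 0)$channels,
                   ph$stack$channels)
  expect_error(apply_z_attenuation(ph$stack, -1),
               class = "invalid_coefficient")
})
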