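test_that("stack TIFF round-trip is lossless with sidecar metadata", {
  ph <- small_phantom()
  p <- withr::local_tempfile(fileext = ".tif")
  write_stack(ph$stack, p)
  expect_true(file.exists(paste0(p, ".meta.json")))
  s2 <- read_stack(p)
  expect_equal(names(s2$channels), c("DAPI", "WGA"))
  expect_identical(round(s2$channels$DAPI), round(ph$stack$channels$DAPI))
  expect_identical(round(s2$channels$WGA), round(ph$stack$channels$WGA))
  expect_equal(unname(s2$voxel_size), unname(ph$stack$voxel_size))
  expect_equal(s2$bit_depth, 16L)
})

test_that("foreign TIFFs require explicit channel map and voxel size", {
  ph <- small_phantom()
  p <- withr::local_tempfile(fileext = ".tif")
  write_stack(ph$stack, p)
  file.remove(paste0(p, ".meta.json"))
  expect_error(read_stack(p), class = "missing_channel_map")
  expect_error(read_stack(p, channel_map = list(DAPI = 1, WGA = 2)),
               class = "missing_voxel_size")
  s2 <- read_stack(p, channel_map = list(DAPI = 1, WGA = 2),
                   voxel_size = c(0.5, 0.5, 0.5))
  expect_identical(round(s2$channels$DAPI), round(ph$stack$channels$DAPI))
  expect_error(read_stack(p, channel_map = list(A = 1, B = 2, C = 3),
                          voxel_size = c(0.5, 0.5, 0.5)),
               class = "missing_channel")
  expect_error(read_stack("no/such/file.tif"), class = "unreadable_file")
})

test_that("label volume round-trip preserves ids and kind", {
  ph <- small_phantom()
  p <- withr::local_tempfile(fileext = ".tif")
  write_labels(ph$truth$cell_labels, p)
  l2 <- read_labels(p)
  expect_identical(l2$labels, ph$truth$cell_labels$labels)
  expect_identical(l2$kind, "cells")
  big <- label_volume(array(70000L, c(2, 2, 2)), c(1, 1, 1), "cells")
  expect_error(write_labels(big, p), class = "label_overflow")
})

test_that("records tables round-trip through CSV", {
  ph <- small_phantom()
  p <- withr::local_tempfile(fileext = ".csv")
  write_table(ph$truth$cells, p)
  t2 <- read_table(p)
  expect_equal(t2$cell_id, ph$truth$cells$cell_id)
  expect_equal(t2$volume_um3, ph$truth$cells$volume_um3)
  expect_error(read_table("no/such.csv"), class = "unreadable_file")
})
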