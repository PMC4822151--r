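test_that("cells are recovered with correct nuclearity and accurate volume", {
  ph <- small_phantom()
  seg <- small_segmentation()
  tr <- ph$truth$cells
  ids <- labels_at_centroids(tr, seg$labels)
  expect_true(all(ids > 0))
  expect_equal(length(unique(ids)), nrow(tr))
  at <- match(ids, seg$cells$id)
  expect_equal(seg$cells$nuclearity[at], tr$nuclearity)
  verr <- seg$cells$volume_um3[at] / tr$volume_um3 - 1
  expect_lt(max(abs(verr)), 0.10)
  # nothing retained beyond the true cells, nothing excluded
  expect_equal(sum(!seg$cells$excluded), nrow(tr))
  # nucleus ownership is mutual: each cell's nuclei point back at it
  for (k in seq_len(nrow(seg$cells))) {
    mine <- seg$nuclei$id[!is.na(seg$nuclei$owning_cell) &
                            seg$nuclei$owning_cell == seg$cells$id[k]]
    expect_setequal(strsplit(seg$cells$nucleus_ids[k], ";")[[1]],
                    as.character(mine))
  }
})

test_that("membrane coverage is near-complete for intact phantom cells", {
  seg <- small_segmentation()
  expect_true(all(seg$cells$membrane_coverage > 0.9))
})

test_that("border-touching cells are excluded automatically", {
  ph <- small_phantom()
  # crop the stack through the farthest cell so it hits the new border
  cut <- ceiling(max(ph$truth$cells$centroid_y) / ph$stack$voxel_size[2])
  ch <- lapply(ph$stack$channels, function(a) a[, 1:cut, , drop = FALSE])
  st <- zstack(ch, ph$stack$voxel_size)
  nuc <- segment_nuclei(st)
  seg <- apply_exclusions(segment_cells(st, nuc))
  expect_true(any(seg$cells$touches_border))
  expect_true(all(seg$cells$excluded[seg$cells$touches_border]))
  expect_true(all(seg$cells$exclusion_reason[seg$cells$touches_border] ==
                    "border"))
})

test_that("manual exclusion is recorded without overriding automatic reasons", {
  ph <- small_phantom()
  seg <- segment_cells(ph$stack, small_nuclei())
  keep <- seg$cells$id[1]
  seg2 <- apply_exclusions(seg, manual_exclude = keep)
  expect_true(seg2$cells$excluded[seg2$cells$id == keep])
  expect_equal(seg2$cells$exclusion_reason[seg2$cells$id == keep], "manual")
})

test_that("fill_holes_3d restores carved cavities exactly (volume accounting)", {
  ph <- small_phantom()
  lab <- ph$truth$cell_labels
  cid <- ph$truth$cells$cell_id[which.max(ph$truth$cells$voxel_count)]
  sel <- which(lab$labels == cid)
  dm <- dim(lab$labels)
  z <- ((sel - 1) %% dm[1]) + 1
  r <- (sel - 1) %/% dm[1]
  y <- (r %% dm[2]) + 1
  x <- (r %/% dm[2]) + 1
  # carve a 3x3x3 cavity around the cell voxel nearest the centroid
  # (guaranteed deep interior for a capsule of radius >= 4 um)
  near <- which.min((z - mean(z))^2 + (y - mean(y))^2 + (x - mean(x))^2)
  cz <- z[near]; cy <- y[near]; cx <- x[near]
  block <- as.vector(outer(outer((cz - 1):(cz + 1),
                                 dm[1] * ((cy - 2):cy), `+`),
                           dm[1] * dm[2] * ((cx - 2):cx), `+`))
  expect_true(all(block %in% sel))
  carved <- lab
  carved$labels[(cz - 1):(cz + 1), (cy - 1):(cy + 1), (cx - 1):(cx + 1)] <- 0L
  n_carved <- length(sel) - sum(carved$labels == cid)
  expect_equal(n_carved, 27)
  filled <- fill_holes_3d(carved, cid)
  # accounting: exactly the carved voxels come back, nothing else changes
  expect_equal(sum(filled$labels == cid), length(sel))
  expect_identical(which(filled$labels == cid), sel)
  other <- lab$labels != cid
  expect_identical(filled$labels[other], lab$labels[other])
  # idempotent and never shrinking
  again <- fill_holes_3d(filled, cid)
  expect_identical(again$labels, filled$labels)
  expect_error(fill_holes_3d(lab, 999L), class = "unknown_cell")
})

test_that("split_cell partitions the parent exactly and merge undoes it", {
  ph <- small_phantom()
  lab <- ph$truth$cell_labels
  cid <- ph$truth$cells$cell_id[1]
  tr_n <- ph$truth$nuclei
  cen <- ph$truth$cells[1, ]
  before <- which(lab$labels == cid)
  # seed points: two points along the cell, derived from its own voxels
  dm <- dim(lab$labels)
  x <- ((before - 1) %/% (dm[1] * dm[2])) + 1
  i1 <- before[which.min(x)]
  i2 <- before[which.max(x)]
  to_um <- function(i) {
    z <- ((i - 1) %% dm[1]) + 1
    r <- (i - 1) %/% dm[1]
    c(z - 0.5, (r %% dm[2]) + 0.5, (r %/% dm[2]) + 0.5) * lab$voxel_size
  }
  pts <- rbind(to_um(i1), to_um(i2))
  sp <- split_cell(lab, cid, pts)
  kids <- sort(unique(sp$labels[before]))
  expect_length(kids, 2)
  expect_true(cid %in% kids)
  # conservation: children exactly partition the parent
  expect_equal(sum(sp$labels %in% kids), length(before))
  expect_identical(which(sp$labels %in% kids), before)
  # all other labels untouched
  expect_identical(sp$labels[-before], lab$labels[-before])
  merged <- merge_cells(sp, kids)
  expect_identical(merged$labels, lab$labels)

  expect_error(split_cell(lab, 999L, pts), class = "unknown_cell")
  expect_error(split_cell(lab, cid, pts[1, , drop = FALSE]),
               class = "too_few_seeds")
  expect_error(split_cell(lab, cid, rbind(c(1, 1, 1), c(2, 2, 2))),
               class = "seed_outside_cell")
})

test_that("segment_from_mask matches truth-mask cells and flags NA coverage", {
  ph <- small_phantom()
  nuc <- small_nuclei()
  res <- segment_from_mask(ph$truth$cell_labels, nuc)
  expect_equal(nrow(res$cells), nrow(ph$truth$cells))
  ids <- labels_at_centroids(ph$truth$cells, res$labels)
  at <- match(ids, res$cells$id)
  expect_equal(res$cells$voxel_count[at], ph$truth$cells$voxel_count)
  expect_true(all(is.na(res$cells$membrane_coverage)))
  # exclusions still work: NA coverage must not trip the membrane rule
  res2 <- apply_exclusions(res)
  expect_false(any(res2$cells$exclusion_reason %in% "incomplete_membrane"))
})

test_that("invert_brightness is involutive", {
  ph <- small_phantom()
  inv <- invert_brightness(ph$stack, "WGA")
  mx <- max(get_channel(ph$stack, "WGA"))
  back <- mx - inv
  expect_identical(back, get_channel(ph$stack, "WGA"))
})
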