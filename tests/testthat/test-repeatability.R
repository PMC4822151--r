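test_that("matching pairs identical runs perfectly", {
  lab <- small_phantom()$truth$cell_labels
  m <- match_cells(lab, lab)
  expect_equal(nrow(m$pairs), nrow(small_phantom()$truth$cells))
  expect_equal(m$pairs$id1, m$pairs$id2)
  expect_equal(m$pairs$jaccard, rep(1, nrow(m$pairs)))
  expect_length(m$unmatched1, 0)
  expect_length(m$unmatched2, 0)
})

test_that("greedy matching equals brute-force optimal on permuted labels", {
  lab <- small_phantom()$truth$cell_labels
  # run 2: permute ids and erode each cell by dropping every voxel in the
  # first occupied plane of its bounding box (a deterministic perturbation)
  K <- max(lab$labels)
  perm <- rev(seq_len(K))
  lab2 <- lab
  lab2$labels[lab$labels > 0] <- perm[lab$labels[lab$labels > 0]]
  first_z <- vapply(seq_len(K), function(k)
    min(which(apply(lab2$labels == k, 1, any))), 1L)
  for (k in seq_len(K))
    lab2$labels[first_z[k], , ][lab2$labels[first_z[k], , ] == k] <- 0L

  m <- match_cells(lab, lab2)
  expect_equal(nrow(m$pairs), K)
  # brute force over all assignments, maximising total overlap
  ov <- matrix(0, K, K)
  both <- lab$labels > 0 & lab2$labels > 0
  tt <- table(lab$labels[both], lab2$labels[both])
  ov[as.matrix(expand.grid(as.integer(rownames(tt)),
                           as.integer(colnames(tt))))] <- as.vector(tt)
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ]
  scores <- apply(perms, 1, function(p) sum(ov[cbind(seq_len(K), p)]))
  best <- perms[which.max(scores), ]
  got <- m$pairs$id2[order(m$pairs$id1)]
  expect_equal(got, unname(best[sort(m$pairs$id1)]))
})

test_that("low-Jaccard pairs are rejected as unmatched", {
  dm <- c(4L, 8L, 8L)
  a <- array(0L, dm); b <- array(0L, dm)
  a[, 1:4, 1:4] <- 1L
  b[, 4, 4] <- 1L        # overlaps 4 voxels of 64: Jaccard 1/16
  l1 <- label_volume(a, c(1, 1, 1), "cells")
  l2 <- label_volume(b, c(1, 1, 1), "cells")
  m <- match_cells(l1, l2, min_jaccard = 0.25)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$unmatched1, 1L)
  expect_equal(m$unmatched2, 1L)
  expect_error(volume_difference_stats(m, 1, 1), class = "no_pairs")
})

test_that("identical runs give exactly 0 +/- 0 percent difference", {
  lab <- small_phantom()$truth$cell_labels
  v <- small_phantom()$truth$cells$volume_um3
  r <- volume_difference_stats(match_cells(lab, lab), v, v)
  expect_identical(r$mean_percent_difference, 0)
  expect_identical(r$sd_percent_difference, 0)
  expect_false(r$exceeds_threshold)
})

test_that("a uniform 10% inflation gives the closed-form 9.52%", {
  lab <- small_phantom()$truth$cell_labels
  v <- small_phantom()$truth$cells$volume_um3
  r <- volume_difference_stats(match_cells(lab, lab), v, v * 1.1)
  # 100 * |1 - 1.1| / 1.05
  expect_equal(r$mean_percent_difference, 100 * 0.1 / 1.05)
  expect_equal(r$sd_percent_difference, 0, tolerance = 1e-9)
  # symmetric denominator: order invariant
  r2 <- volume_difference_stats(match_cells(lab, lab), v * 1.1, v)
  expect_equal(r2$mean_percent_difference, r$mean_percent_difference)
})
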