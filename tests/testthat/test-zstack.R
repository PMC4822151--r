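test_that("zstack validates channels and geometry", {
  a <- array(1, c(2, 3, 4))
  s <- zstack(list(DAPI = a, WGA = a), c(0.5, 0.5, 0.5))
  expect_s3_class(s, "ZStack")
  expect_equal(unname(s$voxel_size), c(0.5, 0.5, 0.5))
  expect_equal(voxel_volume(s), 0.125)
  expect_identical(get_channel(s, "WGA"), a)

  expect_error(zstack(list(a, a), c(0.5, 0.5, 0.5)), class = "invalid_stack")
  expect_error(zstack(list(DAPI = a, WGA = array(1, c(2, 3, 5))),
                      c(0.5, 0.5, 0.5)), class = "invalid_stack")
  expect_error(zstack(list(DAPI = -a), c(0.5, 0.5, 0.5)),
               class = "invalid_stack")
  expect_error(zstack(list(DAPI = a), c(0.5, 0.5)),
               class = "invalid_voxel_size")
  expect_error(get_channel(s, "GFP"), class = "unknown_channel")
})

test_that("label_volume validates input", {
  l <- label_volume(array(0L, c(2, 2, 2)), c(1, 1, 1), "cells")
  expect_s3_class(l, "LabelVolume")
  expect_identical(l$kind, "cells")
  expect_error(label_volume(array(-1L, c(2, 2, 2)), c(1, 1, 1)),
               class = "invalid_labels")
  expect_error(label_volume(matrix(0L, 2, 2), c(1, 1, 1)),
               class = "invalid_labels")
})

test_that("otsu threshold separates two well-separated modes", {
  set.seed(2)
  x <- c(rnorm(5000, 100, 10), rnorm(1000, 1000, 50))
  thr <- otsu_threshold(x)
  # with an empty valley the maximiser has a plateau; any threshold in it
  # separates the two classes exactly
  expect_lt(abs(sum(x > thr) - 1000), 5)
  expect_gt(thr, 130)
  expect_lt(thr, 900)
  expect_equal(otsu_threshold(rep(5, 10)), 5)
})
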