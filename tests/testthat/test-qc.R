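# QC module tests use a small dense nuclei slab whose depth profile is
# statistically uniform, the regime the criteria are written for.
qc_field <- function(...) {
  generate_tissue_field(phantom_spec(shape = c(48L, 128L, 128L),
                                     n_cells = 500L, seed = 31L, ...))
}

test_that("a clean uniform stack passes all QC criteria", {
  fld <- qc_field()
  rep <- assess_dapi_profile(compute_profile(fld$stack), fld$stack)
  expect_s3_class(rep, "QCReport")
  expect_true(rep$pass)
  expect_true(all(unlist(rep$criteria)))
  expect_true(is.na(rep$dropoff_start))
  expect_gt(rep$noise_floor_margin, 3)
})

test_that("depth attenuation inflates flatness CV and is detected", {
  fld <- qc_field()
  r0 <- assess_dapi_profile(compute_profile(fld$stack), fld$stack)
  att <- apply_z_attenuation(fld$stack, 0.1)
  r1 <- assess_dapi_profile(compute_profile(att), att)
  expect_gt(r1$flatness_cv, r0$flatness_cv)
  expect_false(r1$criteria$flatness)
  expect_false(r1$pass)
})

test_that("saturation is detected and fails the stack", {
  fld <- qc_field(reference_2n_intensity = 5e8)
  rep <- assess_dapi_profile(compute_profile(fld$stack), fld$stack)
  expect_gt(rep$saturated_fraction, 0.001)
  expect_false(rep$criteria$saturation)
  expect_false(rep$pass)
})

test_that("the terminal drop-off is located and excluded from the core", {
  fld <- qc_field()
  st <- fld$stack
  nzp <- dim(st$channels$DAPI)[1]
  # kill the last 10 planes, emulating the section ending inside the stack
  fade <- c(rep(1, nzp - 10), rep(0.05, 10))
  st$channels <- lapply(st$channels, function(ch) array(ch * fade, dim(ch)))
  rep <- assess_dapi_profile(compute_profile(st), st)
  expect_false(is.na(rep$dropoff_start))
  expect_true(rep$dropoff_start >= nzp - 11 && rep$dropoff_start <= nzp - 8)
  # excluding the drop-off rescues most of the flatness: the core CV is far
  # below the CV of the whole smoothed profile (the moving mean leaves one
  # transition plane in the core, so it is not exactly the clean-stack CV)
  p <- compute_profile(st)$mean_intensity
  full_cv <- sd(p) / mean(p)
  expect_lt(rep$flatness_cv, 0.25 * full_cv)
})

test_that("QC report serialises to JSON with thresholds", {
  fld <- qc_field()
  rep <- assess_dapi_profile(compute_profile(fld$stack), fld$stack)
  p <- withr::local_tempfile(fileext = ".json")
  write_qc_report(rep, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$pass, rep$pass)
  expect_equal(j$flatness_cv, rep$flatness_cv)
  expect_equal(j$params$max_flatness_cv, rep$params$max_flatness_cv)
})

test_that("profile/stack geometry mismatch errors", {
  fld <- qc_field()
  pr <- compute_profile(fld$stack)
  other <- zstack(list(DAPI = array(1, c(4, 4, 4))), c(1, 1, 1))
  expect_error(assess_dapi_profile(pr, other), class = "geometry_mismatch")
})
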