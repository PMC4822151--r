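test_that("calibration computes the diploid reference from controls", {
  set.seed(1)
  ctl <- rlnorm(200, log(5e5), 0.05)   # haploid control intensities
  cal <- calibrate_ploidy(ctl, control_genome_copies = 1)
  expect_s3_class(cal, "PloidyCalibration")
  expect_equal(cal$reference_2n_intensity, median(ctl) * 2)
  expect_equal(cal$control_n, 200)
  # diploid control: no doubling
  cal2 <- calibrate_ploidy(ctl, control_genome_copies = 2)
  expect_equal(cal2$reference_2n_intensity, median(ctl))
  expect_error(calibrate_ploidy(ctl[1:5]), class = "too_few_controls")
  expect_error(calibrate_ploidy(ctl, control_genome_copies = -1),
               class = "invalid_control")
})

test_that("classification follows the log2-ratio window exactly", {
  cal <- structure(list(reference_2n_intensity = 1000),
                   class = "PloidyCalibration")
  pp <- ploidy_params(log2_tolerance = 0.35)
  expect_equal(classify_ploidy(c(1000, 2000, 4000), cal, pp),
               c("2n", "4n", "8n"))
  # window edges: 2^0.35 and just beyond
  expect_equal(classify_ploidy(1000 * 2^0.349, cal, pp), "2n")
  expect_equal(classify_ploidy(1000 * 2^0.351, cal, pp), "unclassified")
  # below 2n and above max_class are rejected, as are non-positive values
  expect_equal(classify_ploidy(c(400, 16000, 0, -5), cal, pp),
               rep("unclassified", 4))
  # data frame input fills ploidy_class in place
  df <- data.frame(id = 1:2, integrated_intensity = c(1000, 2050))
  out <- classify_ploidy(df, cal, pp)
  expect_equal(out$ploidy_class, c("2n", "4n"))
})

test_that("classification refuses a failed QC unless overridden", {
  cal <- structure(list(reference_2n_intensity = 1000),
                   class = "PloidyCalibration")
  bad_qc <- structure(list(pass = FALSE), class = "QCReport")
  expect_error(classify_ploidy(1000, cal, qc_report = bad_qc),
               class = "qc_failed")
  pp <- ploidy_params(require_qc_pass = FALSE)
  expect_equal(classify_ploidy(1000, cal, pp, qc_report = bad_qc), "2n")
})

test_that("cell-level ploidy labels cover all cases", {
  expect_equal(cell_ploidy_label("2n"), "2n")
  expect_equal(cell_ploidy_label(c("2n", "2n")), "2*2n")
  expect_equal(cell_ploidy_label(c("4n", "4n", "4n")), "3*4n")
  expect_equal(cell_ploidy_label(c("2n", "4n")), "mixed")
  expect_equal(cell_ploidy_label(c("2n", "unclassified")), "unclassified")
  expect_equal(cell_ploidy_label(character(0)), "unclassified")
})

test_that("end-to-end densitometry on synthetic fields is exact", {
  sp <- phantom_spec(shape = c(32L, 192L, 192L), n_cells = 40L, seed = 33L)
  fld <- generate_nuclei_field(sp)
  ctl <- generate_control_field(
    phantom_spec(shape = c(32L, 192L, 192L), n_cells = 40L, seed = 34L),
    control_genome_copies = 1)
  nuc <- segment_nuclei(fld$stack)
  cn <- segment_nuclei(ctl$stack)
  cal <- calibrate_ploidy(cn$records)
  expect_lt(abs(cal$reference_2n_intensity / sp$reference_2n_intensity - 1),
            0.05)
  cls <- classify_ploidy(nuc$records, cal)
  ids <- labels_at_centroids(fld$truth$nuclei, nuc$labels)
  at <- match(ids, cls$id)
  expect_equal(cls$ploidy_class[at], fld$truth$nuclei$ploidy_class)
})
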