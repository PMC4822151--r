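# End-to-end analysis of one stack: QC -> nuclei -> cells -> exclusions ->
# (optionally) ploidy -> cell table, with a JSON manifest recording
# everything needed to reproduce the run.

#' Run the full analysis pipeline on one stack
#'
#' Steps: nuclear-channel QC, nucleus segmentation, membrane-guided cell
#' segmentation, exclusion rules, ploidy classification (skipped with a
#' warning when QC failed and `ploidy.require_qc_pass` is set), and the
#' retained-cell table. All randomness is driven by `config$seed` (the
#' pipeline itself is deterministic; the seed is recorded for provenance).
#'
#' @param stack a `ZStack` (or a path readable by [read_stack()])
#' @param config validated config from [load_config()]
#' @param control_stack optional control `ZStack` (or path) of known genome
#'   copy number for ploidy calibration; without it ploidy is skipped
#' @param manual_exclude integer cell ids to exclude by manual review
#' @return a `PipelineResult` list: `qc`, `nuclei`, `segmentation`, `cells`
#'   (retained-cell table), `calibration` (or NULL), `manifest`
#' @export
run_pipeline <- function(stack, config = load_config(), control_stack = NULL,
                         manual_exclude = integer(0)) {
  input_path <- NULL
  if (is.character(stack)) {
    input_path <- stack
    stack <- read_stack(stack)
  }
  if (is.character(control_stack)) control_stack <- read_stack(control_stack)

  qc <- assess_dapi_profile(compute_profile(stack),
                            stack,
                            params = do.call(qc_params, config$qc))

  nuc <- segment_nuclei(stack, do.call(nuclei_params, config$nuclei))
  seg <- segment_cells(stack, nuc, do.call(segmentation_params, config$cells))
  seg <- apply_exclusions(seg, do.call(segmentation_params, config$cells),
                          manual_exclude = manual_exclude)

  calibration <- NULL
  pp <- ploidy_params(log2_tolerance = config$ploidy$log2_tolerance,
                      max_class = config$ploidy$max_class,
                      require_qc_pass = config$ploidy$require_qc_pass,
                      min_control_n = config$ploidy$min_control_n)
  if (!is.null(control_stack)) {
    if (!qc$pass && pp$require_qc_pass) {
      warning("stack failed nuclear-channel QC; ploidy classification skipped",
              call. = FALSE)
    } else {
      ctrl <- segment_nuclei(control_stack,
                             do.call(nuclei_params, config$nuclei))
      calibration <- calibrate_ploidy(
        ctrl$records[!ctrl$records$touches_border, ],
        control_genome_copies = config$ploidy$control_genome_copies,
        min_control_n = pp$min_control_n)
      seg$nuclei <- classify_ploidy(seg$nuclei, calibration, pp,
                                    qc_report = qc)
      seg <- label_cell_ploidy(seg)
    }
  }

  cells <- seg$cells[!seg$cells$excluded, , drop = FALSE]
  manifest <- list(
    package_version = as.character(utils::packageVersion("cardiomorph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = if (!is.null(input_path))
      list(path = input_path, md5 = unname(tools::md5sum(input_path)))
      else list(path = NA, md5 = NA),
    seed = config$seed,
    config = config,
    qc_pass = qc$pass,
    n_nuclei = nrow(nuc$records),
    n_cells_total = nrow(seg$cells),
    n_cells_retained = nrow(cells))

  structure(list(qc = qc, nuclei = nuc, segmentation = seg, cells = cells,
                 calibration = calibration, manifest = manifest),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("Pipeline result: QC %s; %d nuclei; %d cells (%d retained)\n",
              if (x$qc$pass) "pass" else "FAIL",
              x$manifest$n_nuclei, x$manifest$n_cells_total,
              x$manifest$n_cells_retained))
  if (!is.null(x$calibration)) print(x$calibration)
  invisible(x)
}

#' Write the run manifest as JSON
#'
#' @param result a `PipelineResult`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_manifest <- function(result, path) {
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
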