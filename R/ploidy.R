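# Ploidy densitometry: a control field of nuclei of known genome copy number
# (e.g. a haploid sperm smear imaged with identical settings) calibrates the
# diploid reference integrated intensity; every nucleus is then classified by
# the log2 ratio of its background-corrected integrated intensity to that
# reference. The whole procedure is scale-invariant, so it is robust to any
# global gain shared by sample and control.

#' Ploidy classification parameters
#'
#' @param log2_tolerance half-width of the acceptance window around each
#'   class on the log2 intensity-ratio scale; must be < 0.5 so classes never
#'   overlap. The default 0.35 keeps 2n and 4n separable up to roughly 15%
#'   intensity CV.
#' @param max_class highest ploidy considered, as genome copies (8 = "8n")
#' @param require_qc_pass refuse to classify when the stack failed nuclear-
#'   channel QC (signal intensity is crucial to densitometry); overridable
#' @param min_control_n minimum number of control nuclei for calibration
#' @return a `ploidy_params` list
#' @export
ploidy_params <- function(log2_tolerance = 0.35, max_class = 8L,
                          require_qc_pass = TRUE, min_control_n = 30L) {
  stopifnot(log2_tolerance > 0, log2_tolerance < 0.5, max_class >= 2)
  structure(list(log2_tolerance = log2_tolerance,
                 max_class = as.integer(max_class),
                 require_qc_pass = isTRUE(require_qc_pass),
                 min_control_n = as.integer(min_control_n)),
            class = "ploidy_params")
}

#' Calibrate the diploid reference intensity from a control field
#'
#' `reference_2n_intensity = median(control intensities) * 2 / copies`.
#' The median is used because control preparations contain debris and
#' clumps; the robust CV (MAD/median) is recorded as a calibration quality
#' measure.
#'
#' @param control_nuclei nucleus records from [segment_nuclei()] run on the
#'   control stack (acquired with identical settings -- recorded in
#'   `source`), or a numeric vector of integrated intensities
#' @param control_genome_copies genome copies per control nucleus (1 for a
#'   haploid sperm-like control)
#' @param min_control_n minimum control nuclei required
#' @param source provenance text
#' @return a `PloidyCalibration` list
#' @export
calibrate_ploidy <- function(control_nuclei, control_genome_copies = 1,
                             min_control_n = 30L, source = "") {
  if (!is.finite(control_genome_copies) || control_genome_copies <= 0)
    stop_named("invalid_control", "control_genome_copies must be positive")
  ii <- if (is.data.frame(control_nuclei)) control_nuclei$integrated_intensity
        else as.numeric(control_nuclei)
  ii <- ii[is.finite(ii) & ii > 0]
  if (length(ii) < min_control_n)
    stop_named("too_few_controls",
               "calibration needs >= %d control nuclei, got %d",
               min_control_n, length(ii))
  med <- median(ii)
  structure(list(reference_2n_intensity = med * 2 / control_genome_copies,
                 control_genome_copies = control_genome_copies,
                 control_n = length(ii),
                 control_cv = mad(ii) / med,
                 source = source),
            class = "PloidyCalibration")
}

#' @export
print.PloidyCalibration <- function(x, ...) {
  cat(sprintf("Ploidy calibration: 2n reference = %.4g (from %d control nuclei, %g genome copies, robust CV %.3f)\n",
              x$reference_2n_intensity, x$control_n, x$control_genome_copies,
              x$control_cv))
  invisible(x)
}

#' Classify nuclear ploidy from integrated intensity
#'
#' For the ratio `ratio = intensity / reference_2n_intensity`, the candidate class is
#' `k = round(log2(ratio))`; the nucleus is `2n * 2^k` when
#' `|log2(ratio) - k| <= log2_tolerance` and the class does not exceed
#' `max_class`, otherwise `"unclassified"` (S-phase intermediates and
#' outliers are not interpolated). Non-positive intensities are
#' `"unclassified"`.
#'
#' @param intensity numeric vector of background-corrected integrated
#'   intensities (or a nucleus records data.frame)
#' @param cal a `PloidyCalibration`
#' @param params a [ploidy_params()]
#' @param qc_report optional `QCReport` for the sample stack; with
#'   `require_qc_pass` set, classification refuses to run on a failed QC
#' @return character vector of classes (`"2n"`, `"4n"`, ..., or
#'   `"unclassified"`); or the records with `ploidy_class` filled in when a
#'   data.frame was given
#' @export
classify_ploidy <- function(intensity, cal, params = ploidy_params(),
                            qc_report = NULL) {
  if (params$require_qc_pass && !is.null(qc_report) && !isTRUE(qc_report$pass))
    stop_named("qc_failed",
               "stack failed nuclear-channel QC; pass require_qc_pass = FALSE to override")
  records <- NULL
  if (is.data.frame(intensity)) {
    records <- intensity
    intensity <- records$integrated_intensity
  }
  r <- intensity / cal$reference_2n_intensity
  lg <- rep(NA_real_, length(r))
  lg[r > 0] <- log2(r[r > 0])
  k <- round(lg)
  kmax <- log2(params$max_class / 2)
  ok <- !is.na(lg) & abs(lg - k) <= params$log2_tolerance & k >= 0 & k <= kmax
  cls <- ifelse(ok, paste0(2 * 2^k, "n"), "unclassified")
  if (!is.null(records)) {
    records$ploidy_class <- cls
    return(records)
  }
  cls
}

#' Cell-level ploidy label
#'
#' Mononucleated cells carry their nucleus's class (`"2n"`, `"4n"`, ...);
#' multinucleated cells with all nuclei in one class carry `"m*c"` (e.g.
#' `"2*2n"` for a binucleated cell with two diploid nuclei); cells with any
#' unclassified nucleus are `"unclassified"`, and discordant classified
#' nuclei give `"mixed"`.
#'
#' @param nucleus_classes character vector of the cell's nucleus classes
#' @return the cell label string
#' @export
cell_ploidy_label <- function(nucleus_classes) {
  m <- length(nucleus_classes)
  if (m == 0) return("unclassified")
  if (any(nucleus_classes %in% c("unclassified", "unset", NA)))
    return("unclassified")
  if (length(unique(nucleus_classes)) > 1) return("mixed")
  if (m == 1) nucleus_classes[1] else paste0(m, "*", nucleus_classes[1])
}

#' Attach cell ploidy labels to segmented cells
#'
#' @param seg result of [segment_cells()] whose nucleus records carry
#'   `ploidy_class` (see [classify_ploidy()])
#' @return `seg` with `cells$ploidy_label` filled in
#' @export
label_cell_ploidy <- function(seg) {
  nrec <- seg$nuclei
  seg$cells$ploidy_label <- vapply(seg$cells$id, function(k)
    cell_ploidy_label(nrec$ploidy_class[!is.na(nrec$owning_cell) &
                                          nrec$owning_cell == k]),
    character(1))
  seg
}
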