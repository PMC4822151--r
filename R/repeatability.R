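# Measurement repeatability: match cells between two analysis runs of the
# same stack by label overlap and summarise per-cell percent volume
# differences. A fully deterministic re-run yields exactly 0%; nonzero
# values isolate the contribution of manual curation and acquisition
# variation.

#' Match cells between two runs by maximum label overlap
#'
#' Greedy matching on voxel overlap: pairs are taken in decreasing overlap,
#' each cell used at most once; pairs with Jaccard below `min_jaccard` are
#' rejected as unmatched.
#'
#' @param labels1,labels2 cells `LabelVolume`s from the two runs (same
#'   geometry)
#' @param min_jaccard minimum Jaccard index for an accepted pair
#' @return list with `pairs` (data.frame: id1, id2, overlap, jaccard),
#'   `unmatched1`, `unmatched2`
#' @export
match_cells <- function(labels1, labels2, min_jaccard = 0.25) {
  check_same_geometry(labels1, labels2)
  l1 <- as.integer(labels1$labels)
  l2 <- as.integer(labels2$labels)
  n1 <- max(l1); n2 <- max(l2)
  sz1 <- tabulate(l1[l1 > 0L], nbins = max(n1, 1))
  sz2 <- tabulate(l2[l2 > 0L], nbins = max(n2, 1))
  both <- l1 > 0L & l2 > 0L
  if (any(both)) {
    key <- (l1[both] - 1) * as.double(n2) + l2[both]
    tab <- table(key)
    k <- as.numeric(names(tab))
    ov <- data.frame(id1 = as.integer((k - 1) %/% n2) + 1L,
                     id2 = as.integer((k - 1) %% n2) + 1L,
                     overlap = as.integer(tab))
    ov$jaccard <- ov$overlap / (sz1[ov$id1] + sz2[ov$id2] - ov$overlap)
    ov <- ov[order(-ov$overlap, ov$id1, ov$id2), ]
  } else {
    ov <- data.frame(id1 = integer(0), id2 = integer(0),
                     overlap = integer(0), jaccard = numeric(0))
  }
  used1 <- logical(n1); used2 <- logical(n2)
  keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    if (used1[ov$id1[i]] || used2[ov$id2[i]] || ov$jaccard[i] < min_jaccard)
      next
    keep[i] <- TRUE
    used1[ov$id1[i]] <- TRUE
    used2[ov$id2[i]] <- TRUE
  }
  pairs <- ov[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched1 = setdiff(which(sz1 > 0), pairs$id1),
       unmatched2 = setdiff(which(sz2 > 0), pairs$id2))
}

#' Repeatability statistics over matched cell pairs
#'
#' Per-pair percent difference uses the symmetric mean denominator,
#' `100 * |V1 - V2| / ((V1 + V2) / 2)`, so the report is invariant to run
#' order. Mean and sample SD are reported over matched pairs; a mean above
#' `warn_threshold` (the "<5-10% is achievable and acceptable" guidance) is
#' flagged.
#'
#' @param matches result of [match_cells()]
#' @param volumes1,volumes2 per-cell volumes (um^3) indexed by cell id for
#'   the two runs
#' @param warn_threshold percent mean difference above which the report is
#'   flagged
#' @return a `RepeatabilityReport` list
#' @export
volume_difference_stats <- function(matches, volumes1, volumes2,
                                    warn_threshold = 10) {
  pairs <- matches$pairs
  if (nrow(pairs) == 0)
    stop_named("no_pairs", "no matched pairs to compare")
  v1 <- volumes1[pairs$id1]
  v2 <- volumes2[pairs$id2]
  pct <- 100 * abs(v1 - v2) / ((v1 + v2) / 2)
  structure(list(
    n_matched = nrow(pairs),
    n_unmatched_run1 = length(matches$unmatched1),
    n_unmatched_run2 = length(matches$unmatched2),
    percent_differences = pct,
    mean_percent_difference = mean(pct),
    sd_percent_difference = if (length(pct) > 1) stats::sd(pct) else 0,
    warn_threshold = warn_threshold,
    exceeds_threshold = mean(pct) > warn_threshold),
    class = "RepeatabilityReport")
}

#' @export
print.RepeatabilityReport <- function(x, ...) {
  cat(sprintf("Repeatability: %.2f +/- %.2f%% (mean +/- SD) over %d matched cells\n",
              x$mean_percent_difference, x$sd_percent_difference, x$n_matched))
  cat(sprintf("  unmatched: %d (run 1), %d (run 2)%s\n", x$n_unmatched_run1,
              x$n_unmatched_run2,
              if (x$exceeds_threshold)
                sprintf("; WARNING: mean exceeds %g%%", x$warn_threshold) else ""))
  invisible(x)
}
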