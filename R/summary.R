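# Group summaries: per-region, per-nuclearity aggregates across animals.
# The animal is the experimental unit: percentages and mean volumes are
# computed per animal first, then summarised as mean +/- SD across animals.
# Whether published tables report SD or SEM is often unstated; the
# dispersion convention used here is recorded in the output metadata.

nuclearity_class <- function(n) {
  ifelse(n <= 1, "mono", ifelse(n == 2, "bi", "multi"))
}

#' Summarise retained cells per group
#'
#' @param cells data.frame of retained cells with columns `animal`,
#'   `nuclearity`, `volume_um3`, optionally `ploidy_label`, plus any grouping
#'   columns (e.g. `region`)
#' @param group_cols character vector of grouping columns (default
#'   `"region"`; may be empty for a single group)
#' @param animal_col column identifying the experimental unit
#' @return a `GroupSummary` list: `nuclearity` (per group x nuclearity
#'   class: percentage and volume mean +/- SD across animals, n_animals,
#'   n_cells, single-animal flag), `ploidy` (per group x nuclearity class x
#'   ploidy label: percentage mean +/- SD across animals), and `meta`
#'   (dispersion convention)
#' @export
summarize_cells <- function(cells, group_cols = "region",
                            animal_col = "animal") {
  stopifnot(is.data.frame(cells))
  need <- c(animal_col, "nuclearity", "volume_um3", group_cols)
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop_named("missing_column", "cells table lacks column(s): %s",
               paste(miss, collapse = ", "))
  if ("excluded" %in% names(cells)) cells <- cells[!cells$excluded, ]

  cells$.nucl <- nuclearity_class(cells$nuclearity)
  grp_of <- function(df) {
    if (length(group_cols) == 0) rep("all", nrow(df))
    else do.call(paste, c(df[group_cols], sep = " / "))
  }
  cells$.grp <- grp_of(cells)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0

  nucl_rows <- list()
  ploidy_rows <- list()
  for (g in unique(cells$.grp)) {
    sub <- cells[cells$.grp == g, ]
    animals <- unique(sub[[animal_col]])
    n_anim <- length(animals)
    for (cl in c("mono", "bi", "multi")) {
      if (!any(sub$.nucl == cl) && cl == "multi") next
      pct <- vapply(animals, function(a) {
        s <- sub[sub[[animal_col]] == a, ]
        100 * mean(s$.nucl == cl)
      }, numeric(1))
      vols <- vapply(animals, function(a) {
        s <- sub[sub[[animal_col]] == a & sub$.nucl == cl, ]
        if (nrow(s)) mean(s$volume_um3) else NA_real_
      }, numeric(1))
      vols_ok <- vols[!is.na(vols)]
      nucl_rows[[length(nucl_rows) + 1]] <- data.frame(
        group = g, nuclearity_class = cl,
        n_animals = n_anim,
        n_cells = sum(sub$.nucl == cl),
        pct_mean = mean(pct), pct_sd = sd0(pct),
        volume_mean = if (length(vols_ok)) mean(vols_ok) else NA_real_,
        volume_sd = if (length(vols_ok)) sd0(vols_ok) else NA_real_,
        single_animal = n_anim == 1)
      if ("ploidy_label" %in% names(sub) && any(sub$.nucl == cl)) {
        labs <- unique(sub$ploidy_label[sub$.nucl == cl])
        for (pl in labs) {
          pp <- vapply(animals, function(a) {
            s <- sub[sub[[animal_col]] == a & sub$.nucl == cl, ]
            if (nrow(s)) 100 * mean(s$ploidy_label == pl) else NA_real_
          }, numeric(1))
          pp <- pp[!is.na(pp)]
          ploidy_rows[[length(ploidy_rows) + 1]] <- data.frame(
            group = g, nuclearity_class = cl, ploidy_label = pl,
            pct_mean = mean(pp), pct_sd = sd0(pp))
        }
      }
    }
  }
  structure(list(
    nuclearity = do.call(rbind, nucl_rows),
    ploidy = if (length(ploidy_rows)) do.call(rbind, ploidy_rows) else NULL,
    meta = list(dispersion = "SD across animals (sample SD, n-1)",
                unit = "animal")), class = "GroupSummary")
}

#' @export
print.GroupSummary <- function(x, ...) {
  cat("Group summary (per-animal means, mean +/- SD across animals)\n")
  df <- x$nuclearity
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    cat(sprintf("  %s | %-5s: %5.1f +/- %4.1f%% of cells, volume %s +/- %s um^3 (n=%d animals, %d cells)%s\n",
                r$group, r$nuclearity_class, r$pct_mean, r$pct_sd,
                format(round(r$volume_mean), big.mark = ","),
                format(round(r$volume_sd), big.mark = ","),
                r$n_animals, r$n_cells,
                if (r$single_animal) " [single animal]" else ""))
  }
  invisible(x)
}

#' Percent volume difference between binucleated and mononucleated cells
#'
#' `100 * (mean_binucleated - mean_mononucleated) / mean_mononucleated`,
#' reported to 3 significant figures -- the "binucleated cardiomyocytes were
#' X% larger" statistic.
#'
#' @param mean_binucleated_volume,mean_mononucleated_volume mean volumes in
#'   um^3; the mononucleated mean must be positive
#' @return the percentage, 3 significant figures
#' @export
percent_volume_difference <- function(mean_binucleated_volume,
                                      mean_mononucleated_volume) {
  if (any(!is.finite(mean_mononucleated_volume)) ||
      any(mean_mononucleated_volume <= 0))
    stop_named("invalid_volume", "mononucleated mean volume must be positive")
  if (any(!is.finite(mean_binucleated_volume)) ||
      any(mean_binucleated_volume <= 0))
    stop_named("invalid_volume", "binucleated mean volume must be positive")
  signif(100 * (mean_binucleated_volume - mean_mononucleated_volume) /
           mean_mononucleated_volume, 3)
}
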