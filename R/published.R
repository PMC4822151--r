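# Published reference values: mean mono- and binucleated cardiomyocyte
# volumes by species, age and ventricular region, from prior direct 3D
# measurements in thick sections. Shipped so users can benchmark their own
# groups against the literature with the same statistic.

#' Published group mean cardiomyocyte volumes
#'
#' Mean volumes (um^3) of mono- and binucleated cardiomyocytes for several
#' species/age/region groups, with the percent-larger value as published
#' (3 significant figures).
#'
#' @return data.frame with columns `species`, `age`, `region`,
#'   `mono_volume_um3`, `bi_volume_um3`, `published_percent_larger`
#' @export
published_group_volumes <- function() {
  utils::read.csv(system.file("extdata", "published_group_volumes.csv",
                              package = "cardiomorph", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
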