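#' Regional brain atlas table
#'
#' Returns the atlas used throughout the package: 19 cortical and 7
#' subcortical grey-matter regions whose volumes enter the progression model,
#' plus total cerebellar volume. Each region carries its lobe grouping and
#' the typical bilateral volume and between-subject residual spread (in ml)
#' used by the synthetic cohort generator.
#'
#' @param include_cerebellum logical; keep the cerebellum row? Cerebellar
#'   volume is tabulated in the source cohort but is not part of the default
#'   modeled region set, so the default is `FALSE`.
#' @return A data.frame with columns `region`, `lobe`
#'   (`cortical`/`subcortical`/`cerebellum`), `base_volume_ml`,
#'   `residual_sd_ml`.
#' @export
#' @examples
#' table(region_table()$lobe)
region_table <- function(include_cerebellum = FALSE) {
  path <- system.file("extdata", "regions.csv", package = "sustainz",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!include_cerebellum) tab <- tab[tab$lobe != "cerebellum", , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Default modeled region subset
#'
#' The six regions used by the default synthetic cohort and its progression
#' model: three with early involvement in the temporal-led pattern
#' (hippocampus, amygdala, temporal pole), two shared early regions
#' (lateral temporal cortex, anterior insula) and one frontal region
#' (orbitofrontal cortex) leading the frontotemporal pattern. With three
#' z-score thresholds per region this yields an 18-event model, large enough
#' to express two distinct orderings while staying tractable.
#'
#' @return character vector of region names (a subset of
#'   `region_table()$region`).
#' @export
default_model_regions <- function() {
  c("hippocampus", "amygdala", "temporal_pole",
    "lateral_temporal_cortex", "anterior_insula_cortex",
    "orbitofrontal_cortex")
}
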