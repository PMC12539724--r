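#' Published regional cover-crop acreage ledger (2013-2019)
#'
#' Yearly government-subsidized, voluntary, and total cover-crop acreage for
#' the Arkansas Mississippi Alluvial Plain study region, transcribed from the
#' published per-year accounting table, together with the published SOC
#' tonnage columns (`*_soc_published`) for golden-file comparison. The
#' acreage columns are inputs to [soc_table()] and [adoption_trends()]; the
#' published SOC columns are never used in computation.
#'
#' @return data frame with columns `year`, `government_acres`,
#'   `government_soc_published`, `voluntary_acres`,
#'   `voluntary_soc_published`, `total_acres`, `total_soc_published`.
#' @export
published_acreage <- function() {
  path <- system.file("extdata", "map_cover_crop_acreage.csv",
                      package = "covertrace", mustWork = TRUE)
  utils::read.csv(path)
}
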