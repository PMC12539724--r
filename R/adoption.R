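#' County-level cover-crop acreage
#'
#' Zonal accounting: per county, the number of positive cover pixels times
#' the per-pixel acreage. Counties present in the zone raster but without a
#' single positive pixel get an explicit zero row.
#'
#' @param cover binary `grid_raster` (1 = cover crop; nodata excluded).
#' @param zones co-registered integer county-zone `grid_raster`.
#' @param year optional calendar year stamped on the rows.
#' @param polygons optional county polygon list; ids in the raster but not in
#'   the polygon set raise a consistency warning.
#' @return data frame `county_id, year, acres`.
#' @export
zonal_cover_acres <- function(cover, zones, year = NA_integer_,
                              polygons = NULL) {
  stop_if_grid_mismatch(cover, zones, what = "cover and zone rasters")
  ppx <- pixel_acres(cover)
  zv <- as.vector(zones$values)
  cv <- as.vector(cover$values)
  ids <- sort(unique(zv[!is.na(zv)]))
  if (!is.null(polygons)) {
    poly_ids <- vapply(polygons, function(p) p$county_id, numeric(1))
    missing_ids <- setdiff(ids, poly_ids)
    if (length(missing_ids)) {
      warning("zone id(s) absent from polygon set: ",
              paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }
  pos <- !is.na(cv) & cv == 1 & !is.na(zv)
  counts <- table(factor(zv[pos], levels = ids))
  data.frame(county_id = as.integer(ids), year = as.integer(year),
             acres = as.numeric(counts) * ppx, stringsAsFactors = FALSE)
}

#' Decompose total adoption into government and voluntary acreage
#'
#' Row-wise exact subtraction `voluntary = total - government` on
#' `(county, year)` keys. Government rows missing for a key are treated as 0
#' with a warning; negative voluntary acreage (model under-prediction against
#' the subsidy ledger) is retained and flagged, never clamped.
#'
#' @param total data frame `county_id, year, acres` (or `total_acres`) of
#'   model-predicted acreage.
#' @param government data frame `county_id, year, government_acres` (or
#'   `acres`).
#' @return a county ledger: `county_id, year, total_acres, government_acres,
#'   voluntary_acres, negative_voluntary`.
#' @export
compute_voluntary <- function(total, government) {
  norm <- function(df, col) {
    if (!col %in% names(df) && "acres" %in% names(df)) {
      names(df)[names(df) == "acres"] <- col
    }
    if (!all(c("county_id", "year", col) %in% names(df))) {
      stop("ledger needs county_id, year and an acreage column",
           call. = FALSE)
    }
    df[c("county_id", "year", col)]
  }
  total <- norm(total, "total_acres")
  government <- norm(government, "government_acres")
  key <- function(df) paste(df$county_id, df$year)
  if (anyDuplicated(key(total)) || anyDuplicated(key(government))) {
    stop("ledger error: duplicate (county, year) keys", call. = FALSE)
  }
  m <- merge(total, government, by = c("county_id", "year"), all.x = TRUE)
  if (anyNA(m$government_acres)) {
    warning(sum(is.na(m$government_acres)),
            " (county, year) key(s) missing from the government ledger; ",
            "treated as 0", call. = FALSE)
    m$government_acres[is.na(m$government_acres)] <- 0
  }
  m$voluntary_acres <- m$total_acres - m$government_acres
  m$negative_voluntary <- m$voluntary_acres < 0
  m <- m[order(m$county_id, m$year), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("county_ledger", "data.frame")
  m
}

#' Adoption trend summary
#'
#' Yearly totals by funding source, the percent change of the voluntary
#' series from the first to the last year, and cumulative acre-years.
#'
#' @param ledger a county ledger (from [compute_voluntary()]), or any data
#'   frame with `year, total_acres, government_acres, voluntary_acres`.
#' @return list: `yearly` (data frame of yearly sums), `voluntary_change_acres`,
#'   `voluntary_change_pct`, `cumulative` (named acre-year sums).
#' @export
adoption_trends <- function(ledger) {
  need <- c("year", "total_acres", "government_acres", "voluntary_acres")
  stopifnot(all(need %in% names(ledger)))
  years <- sort(unique(ledger$year))
  if (length(years) < 2) stop("need at least 2 years", call. = FALSE)
  agg <- function(col) {
    vapply(years, function(y) sum(ledger[[col]][ledger$year == y]),
           numeric(1))
  }
  yearly <- data.frame(year = years,
                       total_acres = agg("total_acres"),
                       government_acres = agg("government_acres"),
                       voluntary_acres = agg("voluntary_acres"))
  v <- yearly$voluntary_acres
  if (v[1] == 0) {
    stop("undefined percent change: first-year voluntary total is 0",
         call. = FALSE)
  }
  list(
    yearly = yearly,
    voluntary_change_acres = v[length(v)] - v[1],
    voluntary_change_pct = 100 * (v[length(v)] - v[1]) / v[1],
    cumulative = c(total = sum(yearly$total_acres),
                   government = sum(yearly$government_acres),
                   voluntary = sum(yearly$voluntary_acres))
  )
}

#' Correlation between government and voluntary acreage
#'
#' Pearson product-moment correlation with a two-sided p-value from the
#' t transform, either across county-year rows or on yearly sums.
#'
#' @param ledger a county ledger.
#' @param level `"county_year"` (default) or `"yearly"`.
#' @return list `r`, `p`, `n`.
#' @export
funding_correlation <- function(ledger,
                                level = c("county_year", "yearly")) {
  level <- match.arg(level)
  if (level == "yearly") {
    ledger <- adoption_trends(ledger)$yearly
  }
  g <- ledger$government_acres
  v <- ledger$voluntary_acres
  n <- length(g)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(g) == 0 || stats::sd(v) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- stats::cor(g, v)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}
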