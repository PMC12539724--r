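# Pattern labels use an en dash, e.g. "Soybean – CC – Soybean", so tables
# can be compared verbatim against published rotation tables.
PATTERN_SEP <- " – "

#' Wrap a binary cover raster as a categorical layer
#'
#' Turns a 0/1 cover raster into a two-class categorical raster with legend
#' `None`/`CC`, so it can enter [combine_rasters()] like any class raster.
#'
#' @param cover binary `grid_raster` (1 = cover crop).
#' @return categorical `grid_raster` with legend `c("None", "CC")`.
#' @export
cover_as_class <- function(cover) {
  v <- cover$values + 1L
  storage.mode(v) <- "integer"
  grid_raster(v, pixel_size_m = cover$pixel_size_m,
              xll = cover$xll, yll = cover$yll, legend = c("None", "CC"))
}

#' Pixel-wise combination of categorical rasters
#'
#' Cross-tabulates 2 or 3 co-registered categorical rasters: every unique
#' tuple of values becomes a distinct pattern. A pixel with nodata in any
#' input is excluded from both the pattern raster and the table (numerator
#' and denominator alike). The table is sorted by area descending, ties
#' broken lexicographically by pattern label.
#'
#' @param rasters list of 2-3 categorical `grid_raster`s, each with a legend.
#' @param sep label separator (default `" – "`).
#' @return list with `raster` (pattern-id `grid_raster`, legend = pattern
#'   labels) and `table` (data frame `label, pixels, acres, pct`), plus
#'   `total_acres`, the accountable area.
#' @export
combine_rasters <- function(rasters, sep = PATTERN_SEP) {
  if (!is.list(rasters) || length(rasters) < 2 || length(rasters) > 3) {
    stop("combine takes 2 or 3 rasters", call. = FALSE)
  }
  do.call(stop_if_grid_mismatch, unname(rasters))
  if (any(vapply(rasters, function(r) is.null(r$legend), logical(1)))) {
    stop("every input raster needs a legend (see cover_as_class())",
         call. = FALSE)
  }
  labs <- lapply(rasters, function(r) r$legend[as.vector(r$values)])
  valid <- Reduce(`&`, lapply(labs, function(l) !is.na(l)))
  ref <- rasters[[1]]
  ppx <- pixel_acres(ref)

  if (!any(valid)) {
    empty <- data.frame(label = character(0), pixels = integer(0),
                        acres = numeric(0), pct = numeric(0))
    out <- grid_raster(matrix(NA_integer_, nrow(ref$values),
                              ncol(ref$values)),
                       ref$pixel_size_m, ref$xll, ref$yll)
    return(list(raster = out, table = empty, total_acres = 0))
  }

  key <- do.call(paste, c(lapply(labs, function(l) l[valid]), sep = sep))
  tab <- table(key)
  df <- data.frame(label = names(tab), pixels = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$acres <- df$pixels * ppx
  df$pct <- 100 * df$pixels / sum(df$pixels)
  df <- df[order(-df$acres, df$label), , drop = FALSE]
  rownames(df) <- NULL

  ids <- match(key, df$label)
  m <- matrix(NA_integer_, nrow(ref$values), ncol(ref$values))
  m[valid] <- ids
  pr <- grid_raster(m, ref$pixel_size_m, ref$xll, ref$yll, legend = df$label)
  list(raster = pr, table = df, total_acres = sum(df$acres))
}

#' Count the distinct sequence patterns a combine can produce
#'
#' `k` crop classes crossed with `s` cover states gives `k * s` two-layer
#' patterns; adding a following-year crop layer with `k2` classes gives
#' `k * s * k2` (7 x 2 = 14; 7 x 2 x 7 = 98; 133 x 2 x 133 = 35,378).
#'
#' @param n_classes crop classes in year t.
#' @param n_states cover states (2: with/without).
#' @param n_classes_after optional crop classes in year t+1.
#' @return integer pattern count.
#' @export
enumerate_patterns <- function(n_classes, n_states, n_classes_after = NULL) {
  stopifnot(n_classes >= 1, n_states >= 1)
  out <- n_classes * n_states
  if (!is.null(n_classes_after)) {
    stopifnot(n_classes_after >= 1)
    out <- out * n_classes_after
  }
  as.integer(out)
}

#' Select the top patterns by area
#'
#' @param table a pattern table from [combine_rasters()].
#' @param k rows to keep (`Inf` for all); ties by area break
#'   lexicographically on the label.
#' @return the first `k` rows.
#' @export
top_patterns <- function(table, k = 15) {
  table <- table[order(-table$acres, table$label), , drop = FALSE]
  utils::head(table, k)
}

#' Yearly crop-sequence report
#'
#' For each year `t` emits the three analyses: cash crop before a winter
#' cover (`crop_t` x `cc_t`, 14 patterns with 7 classes), cash crop following
#' a winter cover (`cc_t` x `crop_(t+1)`), and the bracketing sequence
#' (`crop_t` x `cc_t` x `crop_(t+1)`, 98 patterns). The winter between `t`
#' and `t+1` is indexed by `t`. Years whose `t+1` crop raster is missing are
#' reported only in the first analysis, with a warning.
#'
#' @param class_rasters named list (by year) of categorical crop rasters.
#' @param cover_rasters named list (by year) of binary cover rasters, already
#'   restricted to cultivated pixels.
#' @param top_k rows kept per year-table (`Inf` = all).
#' @return list of three tidy data frames (`before`, `after`, `full`), each
#'   with columns `year, label, pixels, acres, pct`.
#' @export
rotation_report <- function(class_rasters, cover_rasters, top_k = Inf) {
  years <- sort(as.integer(names(class_rasters)))
  before <- after <- full <- list()
  for (y in years) {
    yc <- as.character(y)
    if (is.null(cover_rasters[[yc]])) next
    cc <- cover_as_class(cover_rasters[[yc]])
    tb <- combine_rasters(list(class_rasters[[yc]], cc))$table
    before[[yc]] <- cbind(year = y, top_patterns(tb, top_k))

    nxt <- as.character(y + 1L)
    if (is.null(class_rasters[[nxt]])) {
      warning(sprintf(
        "no crop raster for %s: after/full sequences truncated at %d",
        nxt, y), call. = FALSE)
      next
    }
    ta <- combine_rasters(list(cc, class_rasters[[nxt]]))$table
    after[[yc]] <- cbind(year = y, top_patterns(ta, top_k))
    tf <- combine_rasters(list(class_rasters[[yc]], cc,
                               class_rasters[[nxt]]))$table
    full[[yc]] <- cbind(year = y, top_patterns(tf, top_k))
  }
  bind <- function(l) {
    if (!length(l)) return(NULL)
    out <- do.call(rbind, l)
    rownames(out) <- NULL
    out
  }
  list(before = bind(before), after = bind(after), full = bind(full))
}
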