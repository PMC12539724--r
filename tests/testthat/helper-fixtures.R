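# Shared fixtures and independent oracles.

# A small scene config used across module tests.
small_scene_config <- function(seed = 11, ...) {
  scene_config(n_rows = 40, n_cols = 40, years = 2013:2015,
               n_counties = 3, n_truth_points = 150, seed = seed, ...)
}

# Near-noiseless NDVI separation: covered pixels ~0.7, bare ~0.1.
noiseless_ndvi <- function() {
  list(cover = c(mean = 0.7, sd = 1e-6), bare = c(mean = 0.1, sd = 1e-6))
}

# Independent cross-tabulation oracle: explicit nested loop over pixels,
# no vectorised table() on keys, mirroring a hand tally.
oracle_crosstab <- function(rasters, sep = " – ") {
  d <- dim(rasters[[1]]$values)
  counts <- list()
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      labs <- character(length(rasters))
      ok <- TRUE
      for (k in seq_along(rasters)) {
        v <- rasters[[k]]$values[i, j]
        if (is.na(v)) { ok <- FALSE; break }
        labs[k] <- rasters[[k]]$legend[v]
      }
      if (!ok) next
      key <- paste(labs, collapse = sep)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  if (!length(counts)) {
    return(data.frame(label = character(0), pixels = integer(0)))
  }
  df <- data.frame(label = names(counts),
                   pixels = unlist(counts, use.names = FALSE),
                   stringsAsFactors = FALSE)
  ppx <- pixel_acres(rasters[[1]])
  df$acres <- df$pixels * ppx
  df$pct <- 100 * df$pixels / sum(df$pixels)
  df <- df[order(-df$acres, df$label), , drop = FALSE]
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random categorical raster with the given legend.
random_class_raster <- function(nr, nc, legend, px = 30, na_frac = 0) {
  v <- matrix(sample(seq_along(legend), nr * nc, replace = TRUE), nr, nc)
  if (na_frac > 0) {
    v[sample(length(v), round(na_frac * length(v)))] <- NA_integer_
  }
  storage.mode(v) <- "integer"
  grid_raster(v, pixel_size_m = px, legend = legend)
}
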