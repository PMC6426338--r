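#' Read and write grids as plain text
#'
#' Two portable text formats are supported: ESRI ASCII grid (\code{.asc}, one
#' header block then a row-major matrix, masked cells as \code{NODATA_value})
#' and CSV triples of \code{lon, lat, value} at cell centers (masked cells
#' omitted). Both round-trip the grid geometry exactly for regular grids.
#'
#' @param g a \code{geogrid}.
#' @param path file path.
#' @param digits significant digits written (ASCII grid only).
#' @return \code{read_grid_ascii} / \code{read_grid_csv} return a
#'   \code{geogrid}; the writers return \code{path} invisibly.
#' @name grid_text_io
NULL

#' @rdname grid_text_io
#' @export
write_grid_ascii <- function(g, path, digits = 10) {
  if (!inherits(g, "geogrid")) stop("'g' must be a geogrid")
  nodata <- -9999
  v <- ifelse(g$mask, g$values, nodata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_lon),
    sprintf("nrows %d", g$n_lat),
    sprintf("xllcorner %.10g", g$origin_lon),
    sprintf("yllcorner %.10g", g$origin_lat - g$n_lat * g$res),
    sprintf("cellsize %.10g", g$res),
    sprintf("NODATA_value %d", nodata)
  ), con)
  for (i in seq_len(g$n_lat))
    writeLines(paste(format(v[i, ], digits = digits, trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' @rdname grid_text_io
#' @export
read_grid_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  nrows <- as.integer(hdr$nrows); ncols <- as.integer(hdr$ncols)
  vals <- matrix(scan(text = lines[i:(i + nrows - 1L)], quiet = TRUE),
                 nrow = nrows, ncol = ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  mask <- vals != nodata & !is.na(vals)
  vals[!mask] <- NA_real_
  geogrid(vals,
          origin_lon = hdr$xllcorner,
          origin_lat = hdr$yllcorner + nrows * hdr$cellsize,
          res = hdr$cellsize, mask = mask)
}

#' @rdname grid_text_io
#' @export
write_grid_csv <- function(g, path) {
  utils::write.csv(as.data.frame(g), path, row.names = FALSE)
  invisible(path)
}

#' @rdname grid_text_io
#' @export
read_grid_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("lon", "lat", "value") %in% names(d)))
    stop("CSV must have columns lon, lat, value")
  lons <- sort(unique(d$lon)); lats <- sort(unique(d$lat), decreasing = TRUE)
  res_candidates <- c(diff(lons), -diff(lats))
  res <- min(res_candidates[res_candidates > 0])
  # rebuild a regular grid spanning the observed centers
  n_lon <- as.integer(round((max(lons) - min(lons)) / res)) + 1L
  n_lat <- as.integer(round((max(lats) - min(lats)) / res)) + 1L
  origin_lon <- min(lons) - res / 2
  origin_lat <- max(lats) + res / 2
  vals <- matrix(NA_real_, n_lat, n_lon)
  i <- as.integer(round((origin_lat - d$lat) / res + 0.5))
  j <- as.integer(round((d$lon - origin_lon) / res + 0.5))
  vals[cbind(i, j)] <- d$value
  geogrid(vals, origin_lon, origin_lat, res)
}
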