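#' Construct a georeferenced grid
#'
#' A \code{geogrid} is the common raster currency of the package: a 2-D field of
#' values on a regular lat/lon grid with a per-cell validity mask. Rows run
#' north to south from the grid's northwest corner, columns west to east
#' (row-major, 0-based window indexing downstream). Coordinates refer to cell
#' centers: cell (i, j) (1-based matrix indices) has center
#' \code{lon = origin_lon + (j - 0.5) * res}, \code{lat = origin_lat - (i - 0.5) * res}.
#'
#' @param values numeric matrix (rows = latitude bands from north, cols = longitude).
#' @param origin_lon,origin_lat degrees of the northwest cell \emph{corner}.
#' @param res cell size in degrees (the analysis grid uses 0.05).
#' @param mask logical matrix, \code{TRUE} = valid. Defaults to non-\code{NA} values.
#' @return An object of class \code{geogrid}.
#' @export
geogrid <- function(values, origin_lon = 0, origin_lat = 0, res = 0.05,
                    mask = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (any(dim(values) == 0L)) stop("empty grid")
  if (!is.numeric(res) || length(res) != 1L || res <= 0) stop("'res' must be a positive scalar")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values))) stop("'values' and 'mask' must have identical shape")
  mask <- mask & !is.na(values)
  storage.mode(values) <- "double"
  structure(
    list(values = values, mask = mask,
         origin_lon = as.numeric(origin_lon), origin_lat = as.numeric(origin_lat),
         res = as.numeric(res), n_lat = nrow(values), n_lon = ncol(values)),
    class = "geogrid"
  )
}

#' @export
print.geogrid <- function(x, ...) {
  cat(sprintf("geogrid: %d x %d cells at %g deg, NW corner (%g, %g)\n",
              x$n_lat, x$n_lon, x$res, x$origin_lon, x$origin_lat))
  v <- x$values[x$mask]
  if (length(v)) {
    cat(sprintf("  valid cells: %d / %d, range [%g, %g]\n",
                length(v), length(x$values), min(v), max(v)))
  } else cat("  no valid cells\n")
  invisible(x)
}

#' Cell-center longitudes / latitudes of a geogrid
#' @param g a \code{geogrid}.
#' @return numeric vector of cell-center coordinates (lon west to east;
#'   lat north to south, matching matrix rows).
#' @export
grid_lons <- function(g) g$origin_lon + (seq_len(g$n_lon) - 0.5) * g$res

#' @rdname grid_lons
#' @export
grid_lats <- function(g) g$origin_lat - (seq_len(g$n_lat) - 0.5) * g$res

same_geometry <- function(a, b, tol = 1e-9) {
  a$n_lat == b$n_lat && a$n_lon == b$n_lon &&
    abs(a$res - b$res) < tol &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol
}

stopifnot_same_geometry <- function(a, b) {
  if (!same_geometry(a, b)) stop("grids do not share one geometry")
  invisible(TRUE)
}

#' Convert a geogrid to (lon, lat, value) triples
#'
#' @param x a \code{geogrid}.
#' @param row.names,optional unused, for S3 compatibility.
#' @param valid_only drop masked cells (default \code{TRUE}).
#' @param ... unused.
#' @return data.frame with columns \code{lon}, \code{lat}, \code{value}.
#' @export
as.data.frame.geogrid <- function(x, row.names = NULL, optional = FALSE,
                                  valid_only = TRUE, ...) {
  lon <- rep(grid_lons(x), each = x$n_lat)
  lat <- rep(grid_lats(x), times = x$n_lon)
  d <- data.frame(lon = lon, lat = lat, value = as.vector(x$values))
  if (valid_only) d <- d[as.vector(x$mask), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Block-average a fine grid onto a coarser grid
#'
#' Each coarse cell is the arithmetic mean of the \emph{valid} fine cells in its
#' \code{factor x factor} block; a coarse cell with no valid fine cell is
#' masked. This is the upscaling convention used to bring 30-m tree-cover maps
#' to the 0.05-degree analysis grid.
#'
#' @param fine a \code{geogrid}.
#' @param factor positive integer block size.
#' @param allow_partial permit edge blocks when \code{factor} does not divide
#'   the fine dimensions (default \code{FALSE}).
#' @return a \code{geogrid} at \code{factor}-times coarser resolution.
#' @export
upscale_mean <- function(fine, factor, allow_partial = FALSE) {
  if (!inherits(fine, "geogrid")) stop("'fine' must be a geogrid")
  if (length(factor) != 1L || is.na(factor) || factor < 1 || factor != round(factor))
    stop("'factor' must be a positive integer")
  factor <- as.integer(factor)
  if (!allow_partial && (fine$n_lat %% factor || fine$n_lon %% factor))
    stop("'factor' does not divide the grid dimensions (set allow_partial = TRUE)")
  n_lat <- ceiling(fine$n_lat / factor)
  n_lon <- ceiling(fine$n_lon / factor)
  bi <- (seq_len(fine$n_lat) - 1L) %/% factor + 1L
  bj <- (seq_len(fine$n_lon) - 1L) %/% factor + 1L
  idx <- factor(paste(bi[row(fine$values)], bj[col(fine$values)]),
                levels = paste(rep(seq_len(n_lat), times = n_lon),
                               rep(seq_len(n_lon), each = n_lat)))
  v <- ifelse(fine$mask, fine$values, NA_real_)
  sums <- tapply(v, idx, function(z) sum(z, na.rm = TRUE))
  cnts <- tapply(v, idx, function(z) sum(!is.na(z)))
  cnts[is.na(cnts)] <- 0
  vals <- matrix(ifelse(cnts > 0, sums / cnts, NA_real_), n_lat, n_lon)
  geogrid(vals, fine$origin_lon, fine$origin_lat, fine$res * factor,
          mask = matrix(cnts > 0, n_lat, n_lon))
}

#' Bilinear resampling onto a target grid
#'
#' Each target cell center takes the bilinear interpolation of the four
#' surrounding source cell centers. Target cells outside the source's
#' cell-center envelope, or adjacent to any masked source cell, are masked
#' (conservative propagation: no value is invented next to missing data).
#'
#' @param src a \code{geogrid}.
#' @param target a \code{geogrid} (its values are ignored) or a list with
#'   \code{origin_lon}, \code{origin_lat}, \code{res}, \code{n_lat}, \code{n_lon}.
#' @return a \code{geogrid} with the target geometry.
#' @export
resample_bilinear <- function(src, target) {
  if (!inherits(src, "geogrid")) stop("'src' must be a geogrid")
  if (src$n_lat < 2L || src$n_lon < 2L)
    stop("degenerate source axis: bilinear resampling needs at least 2 cells per axis")
  tg <- target
  out_lon <- tg$origin_lon + (seq_len(tg$n_lon) - 0.5) * tg$res
  out_lat <- tg$origin_lat - (seq_len(tg$n_lat) - 0.5) * tg$res
  src_lon <- grid_lons(src)
  src_lat <- grid_lats(src)   # decreasing
  vals <- matrix(NA_real_, tg$n_lat, tg$n_lon)
  ok <- matrix(FALSE, tg$n_lat, tg$n_lon)
  # index of the source cell-center at or west / at or north of each target
  # center; boundary centers are clamped into the last interior interval
  j0 <- pmin(findInterval(out_lon, src_lon), src$n_lon - 1L)
  i0 <- pmin(findInterval(-out_lat, -src_lat), src$n_lat - 1L)
  for (i in seq_len(tg$n_lat)) {
    ri <- i0[i]   # northern row: src_lat[ri] >= out_lat[i] >= src_lat[ri + 1]
    if (ri < 1L || out_lat[i] > src_lat[1L] || out_lat[i] < src_lat[src$n_lat]) next
    fy <- (src_lat[ri] - out_lat[i]) / (src_lat[ri] - src_lat[ri + 1L])
    for (j in seq_len(tg$n_lon)) {
      cj <- j0[j]
      if (cj < 1L || out_lon[j] < src_lon[1L] || out_lon[j] > src_lon[src$n_lon]) next
      if (!(src$mask[ri, cj] && src$mask[ri, cj + 1L] &&
            src$mask[ri + 1L, cj] && src$mask[ri + 1L, cj + 1L])) next
      fx <- (out_lon[j] - src_lon[cj]) / (src_lon[cj + 1L] - src_lon[cj])
      v <- (1 - fy) * ((1 - fx) * src$values[ri, cj] + fx * src$values[ri, cj + 1L]) +
        fy * ((1 - fx) * src$values[ri + 1L, cj] + fx * src$values[ri + 1L, cj + 1L])
      vals[i, j] <- v
      ok[i, j] <- TRUE
    }
  }
  geogrid(vals, tg$origin_lon, tg$origin_lat, tg$res, mask = ok)
}

#' Quality-control rule for a climate variable
#'
#' Encodes the per-product screening defaults: LST retained only where the
#' estimated emissivity error is at most 0.02 and the LST error at most 2 K;
#' white-sky albedo retained for quality flags 0, 1 or 2; coarse ET retained
#' only where all 36 fine subpixels contained data.
#'
#' @param variable one of \code{"LST"}, \code{"ET"}, \code{"albedo"}.
#' @param max_emissivity_error,max_lst_error LST thresholds.
#' @param allowed_flags albedo quality flags accepted.
#' @param required_subpixels complete fine-pixel count required per ET cell.
#' @return an object of class \code{qc_rule}.
#' @export
qc_rule <- function(variable = c("LST", "ET", "albedo"),
                    max_emissivity_error = 0.02, max_lst_error = 2,
                    allowed_flags = c(0, 1, 2), required_subpixels = 36) {
  variable <- match.arg(variable)
  structure(list(variable = variable,
                 max_emissivity_error = max_emissivity_error,
                 max_lst_error = max_lst_error,
                 allowed_flags = allowed_flags,
                 required_subpixels = required_subpixels),
            class = "qc_rule")
}

#' Apply a quality-control rule to a grid
#'
#' Cells failing the rule are masked; no value is altered. The operation only
#' grows the mask and is idempotent.
#'
#' @param values a \code{geogrid} of the variable being screened.
#' @param qc_layers named list of co-registered \code{geogrid} QC layers:
#'   LST needs \code{emissivity_error} and \code{lst_error}; albedo needs
#'   \code{flag}; ET needs \code{subpixel_count}.
#' @param rule a \code{qc_rule}.
#' @return a \code{geogrid} with the same values and a possibly larger mask.
#' @export
apply_qc <- function(values, qc_layers, rule) {
  if (!inherits(rule, "qc_rule")) stop("'rule' must be a qc_rule")
  need <- switch(rule$variable,
                 LST = c("emissivity_error", "lst_error"),
                 albedo = "flag",
                 ET = "subpixel_count")
  if (!all(need %in% names(qc_layers)))
    stop("missing qc layer(s) for ", rule$variable, ": ",
         paste(setdiff(need, names(qc_layers)), collapse = ", "))
  for (nm in need) stopifnot_same_geometry(values, qc_layers[[nm]])
  pass <- switch(
    rule$variable,
    LST = (qc_layers$emissivity_error$values <= rule$max_emissivity_error) &
      (qc_layers$lst_error$values <= rule$max_lst_error) &
      qc_layers$emissivity_error$mask & qc_layers$lst_error$mask,
    albedo = matrix(qc_layers$flag$values %in% rule$allowed_flags,
                    values$n_lat, values$n_lon) & qc_layers$flag$mask,
    ET = (qc_layers$subpixel_count$values >= rule$required_subpixels) &
      qc_layers$subpixel_count$mask
  )
  pass[is.na(pass)] <- FALSE
  geogrid(values$values, values$origin_lon, values$origin_lat, values$res,
          mask = values$mask & pass)
}

# masked-aware cellwise mean of a list of geogrids; a cell is valid if at least
# `min_valid` layers are valid there (require_all = TRUE demands all layers)
mean_grid <- function(grids, require_all = FALSE, min_valid = 1L) {
  g1 <- grids[[1L]]
  for (g in grids[-1L]) stopifnot_same_geometry(g1, g)
  acc <- matrix(0, g1$n_lat, g1$n_lon)
  cnt <- matrix(0L, g1$n_lat, g1$n_lon)
  for (g in grids) {
    v <- ifelse(g$mask, g$values, 0)
    acc <- acc + v
    cnt <- cnt + g$mask
  }
  ok <- if (require_all) cnt == length(grids) else cnt >= min_valid
  vals <- ifelse(ok, acc / pmax(cnt, 1L), NA_real_)
  geogrid(vals, g1$origin_lon, g1$origin_lat, g1$res, mask = ok)
}

#' Hierarchical temporal averaging to an annual grid
#'
#' Collapses a stack of co-registered grids to a single annual mean using
#' hierarchical arithmetic means (mean of means, not a pooled mean — the two
#' differ when counts are unequal across months):
#' \describe{
#'   \item{\code{monthly_to_annual}}{\code{stack} is a list of monthly grids.}
#'   \item{\code{day_night_then_annual}}{\code{stack} is a list of months, each
#'     a list with \code{day} and \code{night} grids; day and night are averaged
#'     (unweighted) per month, then across months.}
#'   \item{\code{eightday_to_monthly_to_annual}}{\code{stack} is a list of
#'     months, each a list of 8-day composite grids; composites are averaged
#'     per month, then across months.}
#' }
#'
#' @param stack list structured per \code{mode}.
#' @param mode averaging mode.
#' @param require_all if \code{TRUE}, a cell must be valid in every layer at
#'   each level; default is any-valid within a month and at least one valid
#'   month per cell.
#' @return annual \code{geogrid}.
#' @export
temporal_average <- function(stack,
                             mode = c("monthly_to_annual", "day_night_then_annual",
                                      "eightday_to_monthly_to_annual"),
                             require_all = FALSE) {
  mode <- match.arg(mode)
  if (length(stack) == 0L) stop("empty stack")
  monthly <- switch(
    mode,
    monthly_to_annual = stack,
    day_night_then_annual = lapply(stack, function(m) {
      if (!all(c("day", "night") %in% names(m))) stop("each month needs 'day' and 'night' grids")
      mean_grid(list(m$day, m$night), require_all = require_all)
    }),
    eightday_to_monthly_to_annual = lapply(stack, function(m) {
      if (length(m) == 0L) stop("empty month in 8-day stack")
      mean_grid(m, require_all = require_all)
    })
  )
  mean_grid(monthly, require_all = require_all)
}
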