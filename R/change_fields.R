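#' Decadal change between two epochs of a variable
#'
#' Per-cell later minus earlier; a cell is masked wherever either epoch is
#' masked. Forest change uses the 2010 and 2000 cover epochs; climate changes
#' use 2011 and 2001 (the cause is taken to precede the consequence), with a
#' same-epoch mode available simply by passing matching epochs.
#'
#' @param later,earlier \code{geogrid}s on identical geometry.
#' @return a \code{geogrid} of changes.
#' @export
decadal_change <- function(later, earlier) {
  stopifnot_same_geometry(later, earlier)
  ok <- later$mask & earlier$mask
  vals <- ifelse(ok, later$values - earlier$values, NA_real_)
  geogrid(vals, later$origin_lon, later$origin_lat, later$res, mask = ok)
}

#' Latitudinal region of a cell
#'
#' Tropical is |lat| <= 20, temperate 20 < |lat| <= 50, boreal |lat| > 50.
#' Boundary latitudes (exactly 20 or 50 degrees) are assigned to the
#' equatorward class; the classification is symmetric about the equator.
#'
#' @param lat latitude(s) in degrees, in [-90, 90].
#' @param tropical_max,temperate_max boundary latitudes (degrees).
#' @return factor with levels \code{tropical}, \code{temperate}, \code{boreal}.
#' @export
classify_region <- function(lat, tropical_max = 20, temperate_max = 50) {
  if (any(is.na(lat)) || any(abs(lat) > 90)) stop("latitude out of range [-90, 90]")
  a <- abs(lat)
  out <- ifelse(a <= tropical_max, "tropical",
                ifelse(a <= temperate_max, "temperate", "boreal"))
  factor(out, levels = c("tropical", "temperate", "boreal"))
}

#' Bundle the four decadal change layers
#'
#' @param dF forest-cover change grid (percentage points, in [-100, 100]).
#' @param dLST LST change grid (deg C).
#' @param dET ET change grid (mm/month).
#' @param dAlbedo white-sky albedo change grid (percentage points).
#' @param epochs optional named list of epoch labels per variable.
#' @return an object of class \code{change_layer}.
#' @export
change_layer <- function(dF, dLST = NULL, dET = NULL, dAlbedo = NULL,
                         epochs = list(forest = c("2000", "2010"),
                                       climate = c("2001", "2011"))) {
  for (g in list(dLST, dET, dAlbedo))
    if (!is.null(g)) stopifnot_same_geometry(dF, g)
  v <- dF$values[dF$mask]
  if (length(v) && (min(v) < -100 || max(v) > 100))
    stop("dF outside [-100, 100]")
  structure(list(dF = dF, dLST = dLST, dET = dET, dAlbedo = dAlbedo,
                 epochs = epochs),
            class = "change_layer")
}
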