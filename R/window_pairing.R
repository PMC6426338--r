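#' Search-window specification
#'
#' Windows of \code{size_lon x size_lat} cells tile the grid with strides
#' derived from the stated overlap (5 - 3 = 2 cells in longitude, 3 - 1 = 2 in
#' latitude). Within a window the focal cell is the valid cell with the largest
#' absolute forest change above \code{focal_thresh}; the reference cell is the
#' valid cell with the smallest absolute forest change below \code{ref_thresh}.
#'
#' @param size_lon,size_lat window extent in cells (defaults 5 x 3).
#' @param stride_lon,stride_lat window stride in cells (defaults 2 x 2).
#' @param focal_thresh,ref_thresh absolute forest-change thresholds in
#'   percentage points (defaults 15 and 5).
#' @return an object of class \code{window_spec}.
#' @export
window_spec <- function(size_lon = 5L, size_lat = 3L,
                        stride_lon = 2L, stride_lat = 2L,
                        focal_thresh = 15, ref_thresh = 5) {
  if (stride_lon < 1L || stride_lon > size_lon ||
      stride_lat < 1L || stride_lat > size_lat)
    stop("strides must satisfy 1 <= stride <= size per axis")
  if (!(ref_thresh > 0 && ref_thresh < focal_thresh && focal_thresh <= 100))
    stop("thresholds must satisfy 0 < ref_thresh < focal_thresh <= 100")
  structure(list(size_lon = as.integer(size_lon), size_lat = as.integer(size_lat),
                 stride_lon = as.integer(stride_lon), stride_lat = as.integer(stride_lat),
                 focal_thresh = focal_thresh, ref_thresh = ref_thresh),
            class = "window_spec")
}

#' Tile a grid geometry into search windows
#'
#' Windows start at 0-based offsets \code{(r * stride_lat, c * stride_lon)} for
#' all non-negative r, c such that the window fits entirely inside the grid, and
#' are emitted in row-major order from the northwest. Windows that would
#' overhang the domain edge are dropped, not padded.
#'
#' @param n_lat,n_lon grid dimensions in cells.
#' @param spec a \code{window_spec}.
#' @return data.frame with \code{window_id} and 0-based \code{row0}, \code{col0}.
#' @export
tile_windows <- function(n_lat, n_lon, spec = window_spec()) {
  if (n_lat < spec$size_lat || n_lon < spec$size_lon)
    stop("grid smaller than one window")
  r0 <- seq.int(0L, n_lat - spec$size_lat, by = spec$stride_lat)
  c0 <- seq.int(0L, n_lon - spec$size_lon, by = spec$stride_lon)
  data.frame(window_id = seq_len(length(r0) * length(c0)),
             row0 = rep(r0, each = length(c0)),
             col0 = rep(c0, times = length(r0)))
}

#' Select the focal/reference cell pair of one window
#'
#' The focal cell maximizes |dF| among valid cells with |dF| strictly above the
#' focal threshold; the reference minimizes |dF| among valid cells with |dF|
#' strictly below the reference threshold. If either candidate set is empty no
#' pair is produced. Ties are broken by row-major order (first wins).
#'
#' @param dF_win numeric matrix of forest changes in the window.
#' @param mask_win logical validity matrix.
#' @param spec a \code{window_spec}.
#' @return list with 1-based local indices \code{focal = c(i, j)} and
#'   \code{ref = c(i, j)}, or \code{NULL} when no pair exists.
#' @export
select_pair <- function(dF_win, mask_win = NULL, spec = window_spec()) {
  if (is.null(mask_win)) mask_win <- !is.na(dF_win)
  a <- abs(dF_win)
  a[!mask_win | is.na(dF_win)] <- NA_real_
  # row-major rank for deterministic tie-breaking
  rm_rank <- (row(dF_win) - 1L) * ncol(dF_win) + col(dF_win)
  foc_ok <- !is.na(a) & a > spec$focal_thresh
  ref_ok <- !is.na(a) & a < spec$ref_thresh
  if (!any(foc_ok) || !any(ref_ok)) return(NULL)
  pick <- function(ok, maximize) {
    v <- a[ok]
    best <- if (maximize) max(v) else min(v)
    cand <- which(ok & a == best)
    cand[which.min(rm_rank[cand])]
  }
  fi <- pick(foc_ok, TRUE)
  ri <- pick(ref_ok, FALSE)
  if (fi == ri) return(NULL)  # cannot happen with valid thresholds, kept defensive
  list(focal = c((fi - 1L) %% nrow(dF_win) + 1L, (fi - 1L) %/% nrow(dF_win) + 1L),
       ref   = c((ri - 1L) %% nrow(dF_win) + 1L, (ri - 1L) %/% nrow(dF_win) + 1L))
}

std_value <- function(g, i, j) {
  if (is.null(g)) return(NA_real_)
  if (g$mask[i, j]) g$values[i, j] else NA_real_
}

#' Extract standardized changes for a selected pair
#'
#' For each variable, the standardized change is the focal-cell change minus
#' the reference-cell change; it is absent (\code{NA}) whenever either cell is
#' masked for that variable, so pairs enter different analyses in different
#' numbers. Forest change must be valid at both cells (guaranteed by
#' selection); region is taken from the focal cell's latitude and the category
#' from the sign of the standardized forest change.
#'
#' @param pair list with grid-level 1-based \code{focal = c(i, j)},
#'   \code{ref = c(i, j)}.
#' @param change a \code{change_layer}.
#' @param window_id integer id.
#' @return one-row data.frame (a \code{CellPair} record).
#' @export
standardize_changes <- function(pair, change, window_id = NA_integer_) {
  f <- pair$focal; r <- pair$ref
  g <- change$dF
  if (f[1] < 1 || f[1] > g$n_lat || f[2] < 1 || f[2] > g$n_lon ||
      r[1] < 1 || r[1] > g$n_lat || r[2] < 1 || r[2] > g$n_lon)
    stop("pair index out of bounds")
  lons <- grid_lons(g); lats <- grid_lats(g)
  vals <- lapply(list(dF = change$dF, dLST = change$dLST,
                      dET = change$dET, dAlbedo = change$dAlbedo),
                 function(x) c(foc = std_value(x, f[1], f[2]),
                               ref = std_value(x, r[1], r[2])))
  std <- vapply(vals, function(v) v[["foc"]] - v[["ref"]], numeric(1))
  d <- data.frame(
    window_id = window_id,
    focal_row = f[1], focal_col = f[2], ref_row = r[1], ref_col = r[2],
    focal_lon = lons[f[2]], focal_lat = lats[f[1]],
    ref_lon = lons[r[2]], ref_lat = lats[r[1]],
    dF_foc = vals$dF[["foc"]], dF_ref = vals$dF[["ref"]], dF_std = std[["dF"]],
    dLST_foc = vals$dLST[["foc"]], dLST_ref = vals$dLST[["ref"]], dLST_std = std[["dLST"]],
    dET_foc = vals$dET[["foc"]], dET_ref = vals$dET[["ref"]], dET_std = std[["dET"]],
    dAlbedo_foc = vals$dAlbedo[["foc"]], dAlbedo_ref = vals$dAlbedo[["ref"]],
    dAlbedo_std = std[["dAlbedo"]]
  )
  d$region <- as.character(classify_region(d$focal_lat))
  d$category <- ifelse(d$dF_std > 0, "forestation", "deforestation")
  d
}

#' Drop repeated pairs, keeping the first window occurrence
#'
#' Overlapping windows can select the same (focal, reference) cell pair; among
#' pairs sharing identical grid indices only the one from the earliest window
#' (row-major scan order) is retained.
#'
#' @param pairs data.frame of pairs ordered by \code{window_id}.
#' @return data.frame of unique pairs.
#' @export
dedupe_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  pairs <- pairs[order(pairs$window_id), , drop = FALSE]
  key <- paste(pairs$focal_row, pairs$focal_col, pairs$ref_row, pairs$ref_col)
  out <- pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full window search over a change layer
#'
#' Tiles the grid, selects at most one focal/reference pair per window,
#' extracts standardized changes for every variable, and removes duplicate
#' pairs arising from window overlap.
#'
#' @param change a \code{change_layer}.
#' @param spec a \code{window_spec}.
#' @return data.frame of unique \code{CellPair} records.
#' @export
find_pairs <- function(change, spec = window_spec()) {
  g <- change$dF
  wins <- tile_windows(g$n_lat, g$n_lon, spec)
  rows <- vector("list", nrow(wins))
  for (k in seq_len(nrow(wins))) {
    r0 <- wins$row0[k]; c0 <- wins$col0[k]
    ri <- (r0 + 1L):(r0 + spec$size_lat)
    ci <- (c0 + 1L):(c0 + spec$size_lon)
    sel <- select_pair(g$values[ri, ci, drop = FALSE],
                       g$mask[ri, ci, drop = FALSE], spec)
    if (is.null(sel)) next
    rows[[k]] <- standardize_changes(
      list(focal = c(r0 + sel$focal[1], c0 + sel$focal[2]),
           ref = c(r0 + sel$ref[1], c0 + sel$ref[2])),
      change, window_id = wins$window_id[k])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- standardize_changes(list(focal = c(1, 1), ref = c(1, 2)),
                               change_layer(geogrid(matrix(0, 1, 2))))[0, ]
    return(out)
  }
  dedupe_pairs(do.call(rbind, rows))
}

#' Restrict pairs to a band of absolute standardized forest change
#'
#' Keeps pairs with \code{low < |dF_std| < high} (strict inequalities). The
#' comparative deforestation-vs-forestation analysis uses the band around 50
#' percent, i.e. (40, 60).
#'
#' @param pairs data.frame of pairs.
#' @param low,high band limits in percentage points, \code{low < high}.
#' @return filtered data.frame.
#' @export
subset_by_change <- function(pairs, low = 40, high = 60) {
  if (!(low < high)) stop("'low' must be < 'high'")
  a <- abs(pairs$dF_std)
  out <- pairs[!is.na(a) & a > low & a < high, , drop = FALSE]
  rownames(out) <- NULL
  out
}
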