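#' Project LST change from a scenario forest-change raster
#'
#' Applies the fitted total standardized effect to a forest-change scenario:
#' per cell, \code{dLST_pred = total_std * (dF / sd_dF) * sd_dLST} degrees C.
#' For a linear recursive path model this equals full propagation of dF through
#' every causal pathway. Cells masked in the scenario stay masked; the
#' projection is exactly linear in dF and no clipping is applied outside the
#' observed forest-change range. The output records the stationarity caveat:
#' the fitted forest-albedo-ET-LST relationships are assumed to hold over the
#' scenario horizon.
#'
#' @param scenario a \code{geogrid} of scenario forest change (percentage
#'   points over the horizon, e.g. 2050 minus 2010), or a list with fields
#'   \code{dF} (geogrid) and \code{label}.
#' @param decomposition an \code{effects_decomposition} (or a single numeric
#'   total standardized effect).
#' @param sd_dF,sd_dLST sample SDs of standardized forest change (%) and LST
#'   change (deg C) from the fitted pairs, both positive.
#' @return an object of class \code{projection_result}: \code{dLST_pred}
#'   (geogrid), \code{summary} (mean, min, max over valid cells),
#'   \code{label}, \code{total_std} and the SDs used, plus an
#'   \code{assumption} note.
#' @export
project_dlst <- function(scenario, decomposition, sd_dF, sd_dLST) {
  if (sd_dF <= 0 || sd_dLST <= 0) stop("standard deviations must be positive")
  total_std <- if (inherits(decomposition, "effects_decomposition"))
    decomposition$total else as.numeric(decomposition)
  if (!is.finite(total_std)) stop("total effect must be finite")
  label <- NA_character_
  dF <- scenario
  if (!inherits(scenario, "geogrid")) {
    dF <- scenario$dF
    if (!is.null(scenario$label)) label <- scenario$label
  }
  v <- dF$values[dF$mask]
  if (length(v) && (min(v) < -100 || max(v) > 100))
    stop("scenario dF outside [-100, 100]")
  vals <- ifelse(dF$mask, total_std * (dF$values / sd_dF) * sd_dLST, NA_real_)
  pred <- geogrid(vals, dF$origin_lon, dF$origin_lat, dF$res, mask = dF$mask)
  out <- list(dLST_pred = pred,
              summary = summarize_projection(pred),
              label = label, total_std = total_std,
              sd_dF = sd_dF, sd_dLST = sd_dLST,
              assumption = paste("Assumes the fitted relationships between",
                                 "forest change, albedo, ET and LST remain",
                                 "unchanged over the scenario horizon."))
  class(out) <- "projection_result"
  out
}

#' Summarize a projected LST-change field
#'
#' @param result a \code{projection_result} or a \code{geogrid}.
#' @return named numeric vector \code{c(mean, min, max)} over valid cells.
#' @export
summarize_projection <- function(result) {
  g <- if (inherits(result, "projection_result")) result$dLST_pred else result
  v <- g$values[g$mask]
  if (length(v) == 0L) stop("fully masked raster: nothing to summarize")
  c(mean = mean(v), min = min(v), max = max(v))
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("scenario projection%s: total_std = %+.3f, sd_dF = %g%%, sd_dLST = %g C\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$total_std, x$sd_dF, x$sd_dLST))
  s <- x$summary
  s[s == 0] <- 0   # avoid printing negative zero
  cat(sprintf("  predicted dLST over valid cells: mean %+.3f C, range [%+.3f, %+.3f] C\n",
              s[["mean"]], s[["min"]], s[["max"]]))
  invisible(x)
}
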