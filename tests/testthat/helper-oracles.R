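# Independent oracles used across tests. These deliberately re-derive results
# with naive loops / closed forms, never through the package's own code paths.

# blockwise means by direct enumeration
oracle_block_means <- function(vals, mask, factor) {
  nl <- nrow(vals) %/% factor
  nc <- ncol(vals) %/% factor
  out <- matrix(NA_real_, nl, nc)
  for (i in seq_len(nl)) for (j in seq_len(nc)) {
    ri <- ((i - 1) * factor + 1):(i * factor)
    ci <- ((j - 1) * factor + 1):(j * factor)
    v <- vals[ri, ci][mask[ri, ci]]
    if (length(v)) out[i, j] <- mean(v)
  }
  out
}

# textbook bilinear interpolation at a point from 4 surrounding cell centers
oracle_bilinear_point <- function(src_vals, src_lon, src_lat, lon, lat) {
  j <- max(which(src_lon <= lon)); i <- max(which(src_lat >= lat))
  if (j >= length(src_lon)) j <- length(src_lon) - 1
  if (i >= length(src_lat)) i <- length(src_lat) - 1
  fx <- (lon - src_lon[j]) / (src_lon[j + 1] - src_lon[j])
  fy <- (src_lat[i] - lat) / (src_lat[i] - src_lat[i + 1])
  (1 - fy) * ((1 - fx) * src_vals[i, j] + fx * src_vals[i, j + 1]) +
    fy * ((1 - fx) * src_vals[i + 1, j] + fx * src_vals[i + 1, j + 1])
}

# exhaustive window-pairing enumeration: tile origins, candidate scans with
# row-major tie-breaks, then a duplicate scan keeping the first occurrence
oracle_pairs <- function(dF, mask, size_lat = 3, size_lon = 5,
                         stride_lat = 2, stride_lon = 2,
                         focal_thresh = 15, ref_thresh = 5) {
  found <- list()
  wid <- 0
  for (r0 in seq(0, nrow(dF) - size_lat, by = stride_lat)) {
    for (c0 in seq(0, ncol(dF) - size_lon, by = stride_lon)) {
      wid <- wid + 1
      best_f <- NULL; best_r <- NULL
      for (i in (r0 + 1):(r0 + size_lat)) for (j in (c0 + 1):(c0 + size_lon)) {
        if (!mask[i, j]) next
        a <- abs(dF[i, j])
        if (a > focal_thresh && (is.null(best_f) || a > best_f$a))
          best_f <- list(i = i, j = j, a = a)
        if (a < ref_thresh && (is.null(best_r) || a < best_r$a))
          best_r <- list(i = i, j = j, a = a)
      }
      if (!is.null(best_f) && !is.null(best_r))
        found[[length(found) + 1]] <- c(wid, best_f$i, best_f$j, best_r$i, best_r$j)
    }
  }
  if (!length(found)) return(matrix(numeric(0), 0, 5))
  m <- do.call(rbind, found)
  key <- paste(m[, 2], m[, 3], m[, 4], m[, 5])
  m[!duplicated(key), , drop = FALSE]
}

# closed-form GLS estimator with a fully known covariance
oracle_gls_beta <- function(y, X, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# simulate y with exponential spatial correlation at given coords
sim_spatial_y <- function(X, beta, coords, range, sigma) {
  V <- exp(-as.matrix(dist(coords)) / range)
  drop(X %*% beta) + sigma * drop(t(chol(V)) %*% rnorm(nrow(X)))
}

random_dF_grid <- function(n_lat, n_lon, mask_frac = 0.1) {
  vals <- matrix(runif(n_lat * n_lon, -100, 100), n_lat, n_lon)
  # concentrate some cells into the reference band so pairs exist
  low <- matrix(runif(n_lat * n_lon) < 0.4, n_lat, n_lon)
  vals[low] <- runif(sum(low), -5, 5)
  mask <- matrix(runif(n_lat * n_lon) >= mask_frac, n_lat, n_lon)
  list(vals = vals, mask = mask)
}
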