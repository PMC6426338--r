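#' Parameters for the synthetic forest-climate generator
#'
#' Defines seeded synthetic landscapes and pair-level datasets with the causal
#' structure the analysis assumes: decadal forest change on clustered patches
#' drives changes in albedo, ET and LST through a linear recursive system on
#' the standardized scale, with independent cell noise, optional spatially
#' correlated noise, a smooth regional background trend, and per-cell QC flags.
#'
#' The structural coefficients are expressed on the standardized scale. The
#' defaults give a standardized total effect of forest change on LST of about
#' -0.64, the regime reported for Brazilian pair data; per-equation noise SDs
#' default to the values that give every variable unit population variance on
#' the standardized scale (so the implied population R-squared per equation is
#' simply the explained variance).
#'
#' @param n_lat,n_lon grid size in cells.
#' @param res cell size in degrees.
#' @param origin_lon,origin_lat northwest corner of the landscape.
#' @param change_patch_rate fraction of cells with |dF| > 15.
#' @param forestation_fraction fraction of change patches with positive sign.
#' @param s_FA,s_FE,s_AE,s_FL,s_AL,s_EL standardized structural coefficients
#'   (dF->dAlbedo, dF->dET, dAlbedo->dET, dF->dLST direct, dAlbedo->dLST,
#'   dET->dLST).
#' @param noise_sd optional named vector \code{c(dAlbedo=, dET=, dLST=)} of
#'   structural-equation noise SDs on the standardized scale; \code{NULL}
#'   (default) picks the unit-variance values.
#' @param window_sd SD of the window-level background shared by the focal and
#'   reference member of a pair (standardized scale; cancels in differencing
#'   but drives the window random effect).
#' @param spatial_family,spatial_range family and range (degrees) of the
#'   spatially correlated noise component in landscapes.
#' @param spatial_noise_share share of cell-noise variance that is spatially
#'   correlated rather than independent (landscapes only).
#' @param background_trend_amplitude amplitude (standardized units) of the
#'   smooth regional trend added to every climate change field.
#' @param trend_scale wavelength of the background trend in degrees.
#' @param native_sd nominal SDs used to express the generated standardized
#'   climate changes in native units (deg C, mm/month, %).
#' @param qc_fail_rate per-cell probability that a variable fails QC.
#' @param seed integer seed; identical parameters and seed give identical
#'   output.
#' @return an object of class \code{synthetic_params}.
#' @export
synthetic_params <- function(n_lat = 60L, n_lon = 60L, res = 0.05,
                             origin_lon = -60, origin_lat = -10,
                             change_patch_rate = 0.05,
                             forestation_fraction = 0.5,
                             s_FA = -0.4, s_FE = 0.5, s_AE = -0.12,
                             s_FL = -0.23, s_AL = 0.2, s_EL = -0.6,
                             noise_sd = NULL, window_sd = 0.5,
                             spatial_family = "gaussian", spatial_range = 0.1,
                             spatial_noise_share = 0.25,
                             background_trend_amplitude = 2, trend_scale = 10,
                             native_sd = c(dAlbedo = 1.2, dET = 6, dLST = 0.57),
                             qc_fail_rate = 0.02, seed = 1L) {
  stopifnot(n_lat >= 1, n_lon >= 1, res > 0,
            change_patch_rate >= 0, change_patch_rate <= 1,
            forestation_fraction >= 0, forestation_fraction <= 1,
            qc_fail_rate >= 0, qc_fail_rate <= 1, window_sd >= 0,
            spatial_noise_share >= 0, spatial_noise_share <= 1)
  coefs <- c(s_FA = s_FA, s_FE = s_FE, s_AE = s_AE,
             s_FL = s_FL, s_AL = s_AL, s_EL = s_EL)
  if (any(!is.finite(coefs))) stop("structural coefficients must be finite")
  mom <- implied_moments(coefs)
  if (is.null(noise_sd)) noise_sd <- mom$noise_sd
  if (any(noise_sd < 0)) stop("noise SDs must be non-negative")
  p <- list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon), res = res,
            origin_lon = origin_lon, origin_lat = origin_lat,
            change_patch_rate = change_patch_rate,
            forestation_fraction = forestation_fraction,
            coefs = coefs, noise_sd = noise_sd, window_sd = window_sd,
            spatial_family = spatial_family, spatial_range = spatial_range,
            spatial_noise_share = spatial_noise_share,
            background_trend_amplitude = background_trend_amplitude,
            trend_scale = trend_scale, native_sd = native_sd,
            qc_fail_rate = qc_fail_rate, seed = as.integer(seed),
            moments = mom)
  class(p) <- "synthetic_params"
  p
}

#' Population moments implied by the structural coefficients
#'
#' Propagates unit-variance forest change through the linear system to obtain
#' the explained variance (population R-squared, under unit-variance scaling)
#' of each endogenous equation, the noise SDs that make every variable unit
#' variance, and the total standardized effect of dF on dLST (which equals the
#' population simple-regression slope of dLST on dF by path tracing).
#'
#' @param coefs named vector with \code{s_FA}, \code{s_FE}, \code{s_AE},
#'   \code{s_FL}, \code{s_AL}, \code{s_EL}.
#' @return list with \code{r2} (per equation), \code{noise_sd}, \code{total},
#'   and the model-implied covariance matrix \code{Sigma} of (dF, dAlbedo,
#'   dET, dLST) under unit variances.
#' @export
implied_moments <- function(coefs) {
  cf <- as.list(coefs)
  expl_A <- cf$s_FA^2
  cov_FA <- cf$s_FA
  expl_E <- cf$s_FE^2 + cf$s_AE^2 + 2 * cf$s_FE * cf$s_AE * cov_FA
  cov_FE <- cf$s_FE + cf$s_AE * cov_FA
  cov_AE <- cf$s_FE * cov_FA + cf$s_AE
  S3 <- matrix(c(1, cov_FA, cov_FE,
                 cov_FA, 1, cov_AE,
                 cov_FE, cov_AE, 1), 3, 3)
  b <- c(cf$s_FL, cf$s_AL, cf$s_EL)
  expl_L <- drop(t(b) %*% S3 %*% b)
  if (expl_A >= 1 || expl_E >= 1 || expl_L >= 1)
    stop("coefficients imply explained variance >= 1; no unit-variance noise exists")
  total <- cf$s_FL + cf$s_FA * cf$s_AL + cf$s_FE * cf$s_EL +
    cf$s_FA * cf$s_AE * cf$s_EL
  cov_FL <- drop(S3[1, ] %*% b)
  cov_AL <- drop(S3[2, ] %*% b)
  cov_EL <- drop(S3[3, ] %*% b)
  Sigma <- rbind(cbind(S3, c(cov_FL, cov_AL, cov_EL)),
                 c(cov_FL, cov_AL, cov_EL, 1))
  dimnames(Sigma) <- rep(list(c("dF", "dAlbedo", "dET", "dLST")), 2)
  list(r2 = c(dAlbedo = expl_A, dET = expl_E, dLST = expl_L),
       noise_sd = c(dAlbedo = sqrt(1 - expl_A), dET = sqrt(1 - expl_E),
                    dLST = sqrt(1 - expl_L)),
       total = total, Sigma = Sigma)
}

# analytic mean/SD of pair-level dF_std under the generator's mixture:
# focal dF = sign * U(15, 100), reference dF = U(-5, 5)
dF_std_moments <- function(forestation_fraction) {
  f <- forestation_fraction
  m_mag <- (15 + 100) / 2
  m2_mag <- (15^2 + 15 * 100 + 100^2) / 3
  mu <- (2 * f - 1) * m_mag
  v <- m2_mag - mu^2 + 100 / 12
  c(mean = mu, sd = sqrt(v))
}

#' Draw pair-level data directly from the structural model
#'
#' Bypasses rasters: standardized forest change is drawn from the
#' focal-minus-reference mixture (focal magnitudes uniform on 15-100 percent
#' with sign set by the forestation fraction; reference changes uniform on
#' -5..5), and the three climate changes follow the structural equations with
#' independent noise, for both the focal and the reference member of each pair
#' (which also share a window-level background, so the paired mixed model is
#' exercisable). Focal coordinates are uniform over the stated ranges; the
#' reference cell sits within window reach of its focal cell.
#'
#' @param params a \code{synthetic_params}.
#' @param n_pairs number of pairs (>= 1).
#' @param lat_range,lon_range sampling ranges for focal coordinates (degrees).
#' @return data.frame in the same layout as \code{\link{find_pairs}} output,
#'   with attribute \code{"truth"} recording the generator's coefficients,
#'   implied R-squared and total effect.
#' @export
generate_pairs <- function(params, n_pairs,
                           lat_range = c(-60, 60), lon_range = c(-180, 180)) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  set.seed(params$seed)
  n <- as.integer(n_pairs)
  cf <- as.list(params$coefs)
  ns <- params$noise_sd
  sgn <- ifelse(stats::runif(n) < params$forestation_fraction, 1, -1)
  dF_foc <- sgn * stats::runif(n, 15, 100)
  dF_ref <- stats::runif(n, -5, 5)
  sd_pop <- dF_std_moments(params$forestation_fraction)[["sd"]]
  Fz_foc <- dF_foc / sd_pop
  Fz_ref <- dF_ref / sd_pop
  half <- function(sd) stats::rnorm(n, 0, sd / sqrt(2))
  bg <- function() stats::rnorm(n, 0, params$window_sd)
  b_A <- bg(); b_E <- bg(); b_L <- bg()
  A_foc <- b_A + cf$s_FA * Fz_foc + half(ns[["dAlbedo"]])
  A_ref <- b_A + cf$s_FA * Fz_ref + half(ns[["dAlbedo"]])
  E_foc <- b_E + cf$s_FE * Fz_foc + cf$s_AE * (A_foc - b_A) + half(ns[["dET"]])
  E_ref <- b_E + cf$s_FE * Fz_ref + cf$s_AE * (A_ref - b_A) + half(ns[["dET"]])
  L_foc <- b_L + cf$s_FL * Fz_foc + cf$s_AL * (A_foc - b_A) +
    cf$s_EL * (E_foc - b_E) + half(ns[["dLST"]])
  L_ref <- b_L + cf$s_FL * Fz_ref + cf$s_AL * (A_ref - b_A) +
    cf$s_EL * (E_ref - b_E) + half(ns[["dLST"]])
  nat <- params$native_sd
  focal_lon <- stats::runif(n, lon_range[1], lon_range[2])
  focal_lat <- stats::runif(n, lat_range[1], lat_range[2])
  ref_lon <- focal_lon + stats::runif(n, -2, 2) * params$res
  ref_lat <- focal_lat + stats::runif(n, -1, 1) * params$res
  d <- data.frame(
    window_id = seq_len(n),
    focal_row = NA_integer_, focal_col = NA_integer_,
    ref_row = NA_integer_, ref_col = NA_integer_,
    focal_lon = focal_lon, focal_lat = focal_lat,
    ref_lon = ref_lon, ref_lat = ref_lat,
    dF_foc = dF_foc, dF_ref = dF_ref, dF_std = dF_foc - dF_ref,
    dLST_foc = L_foc * nat[["dLST"]], dLST_ref = L_ref * nat[["dLST"]],
    dLST_std = (L_foc - L_ref) * nat[["dLST"]],
    dET_foc = E_foc * nat[["dET"]], dET_ref = E_ref * nat[["dET"]],
    dET_std = (E_foc - E_ref) * nat[["dET"]],
    dAlbedo_foc = A_foc * nat[["dAlbedo"]], dAlbedo_ref = A_ref * nat[["dAlbedo"]],
    dAlbedo_std = (A_foc - A_ref) * nat[["dAlbedo"]]
  )
  d$region <- as.character(classify_region(d$focal_lat))
  d$category <- ifelse(d$dF_std > 0, "forestation", "deforestation")
  attr(d, "truth") <- list(coefs = params$coefs, r2 = params$moments$r2,
                           total = params$moments$total,
                           noise_sd = ns, dF_sd = sd_pop)
  d
}

# separable gaussian kernel smoother with edge renormalization
smooth_field <- function(n_lat, n_lon, sigma_cells) {
  z <- matrix(stats::rnorm(n_lat * n_lon), n_lat, n_lon)
  band <- function(n) {
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sigma_cells)
    K / rowSums(K)
  }
  s <- band(n_lat) %*% z %*% t(band(n_lon))
  s / stats::sd(as.vector(s))
}

#' Generate a full synthetic landscape
#'
#' Produces two forest-cover epochs, two epochs of each climate variable and
#' QC layers on one grid. Forest change is concentrated on clustered square
#' patches of side 1-3 cells (magnitude uniform 15-100 percent, sign by the
#' forestation fraction); elsewhere it is uniform on -5..5. Climate changes
#' follow the structural equations cell-by-cell on the standardized scale,
#' plus independent and spatially correlated noise and a shared smooth
#' regional background trend; the second epoch of every variable is the first
#' epoch plus its change field. QC failures are drawn independently per cell
#' at the stated rate.
#'
#' @param params a \code{synthetic_params}.
#' @return list with \code{forest} (t1, t2 geogrids), \code{climate} (per
#'   variable: t1, t2), \code{qc} (layers per variable), and \code{truth}.
#' @export
generate_landscape <- function(params) {
  if (params$n_lat < 3 || params$n_lon < 5) stop("degenerate grid: smaller than one window")
  set.seed(params$seed)
  nl <- params$n_lat; nc <- params$n_lon
  mk <- function(v) geogrid(matrix(v, nl, nc), params$origin_lon,
                            params$origin_lat, params$res)
  cf <- as.list(params$coefs)
  ns <- params$noise_sd

  # --- forest change on clustered patches ---
  dF <- matrix(stats::runif(nl * nc, -5, 5), nl, nc)
  p_center <- params$change_patch_rate / mean(c(1, 4, 9))  # E[side^2] for side 1..3
  centers <- which(matrix(stats::runif(nl * nc) < p_center, nl, nc))
  for (idx in centers) {
    i <- (idx - 1L) %% nl + 1L; j <- (idx - 1L) %/% nl + 1L
    side <- sample.int(3L, 1L)
    mag <- stats::runif(1, 15, 100) *
      (if (stats::runif(1) < params$forestation_fraction) 1 else -1)
    ii <- i:min(nl, i + side - 1L); jj <- j:min(nc, j + side - 1L)
    dF[ii, jj] <- mag
  }
  forest_t1 <- 100 * stats::plogis(smooth_field(nl, nc, 3))
  chg <- abs(dF) > 5
  lo <- pmax(0, -dF[chg]); hi <- pmin(100, 100 - dF[chg])
  forest_t1[chg] <- lo + stats::runif(sum(chg)) * (hi - lo)
  forest_t1 <- pmin(pmax(forest_t1, pmax(0, -dF)), pmin(100, 100 - dF))
  forest_t2 <- forest_t1 + dF

  # --- climate changes from the structural system (standardized scale) ---
  sd_pop <- dF_std_moments(params$forestation_fraction)[["sd"]]
  Fz <- dF / sd_pop
  w <- params$spatial_noise_share
  cell_noise <- function(sd_v) {
    iid <- matrix(stats::rnorm(nl * nc), nl, nc)
    sp <- smooth_field(nl, nc, max(params$spatial_range / params$res / 2, 1))
    (sqrt(1 - w) * iid + sqrt(w) * sp) * sd_v / sqrt(2)
  }
  lon_c <- params$origin_lon + (seq_len(nc) - 0.5) * params$res
  lat_c <- params$origin_lat - (seq_len(nl) - 0.5) * params$res
  trend <- params$background_trend_amplitude *
    outer(sin(2 * pi * lat_c / params$trend_scale),
          cos(2 * pi * lon_c / params$trend_scale), "+") / 2
  A <- cf$s_FA * Fz + cell_noise(ns[["dAlbedo"]])
  E <- cf$s_FE * Fz + cf$s_AE * A + cell_noise(ns[["dET"]])
  L <- cf$s_FL * Fz + cf$s_AL * A + cf$s_EL * E + cell_noise(ns[["dLST"]])
  nat <- params$native_sd
  dAlb <- (A + trend) * nat[["dAlbedo"]]
  dET <- (E + trend) * nat[["dET"]]
  dLST <- (L + trend) * nat[["dLST"]]

  base_field <- function(amp, center) center + amp * smooth_field(nl, nc, 5)
  lst_t1 <- base_field(2, 22); et_t1 <- base_field(10, 80); alb_t1 <- base_field(2, 15)

  # --- QC layers ---
  fail <- function() matrix(stats::runif(nl * nc) < params$qc_fail_rate, nl, nc)
  f_lst <- fail(); f_alb <- fail(); f_et <- fail()
  qc <- list(
    LST = list(emissivity_error = mk(ifelse(f_lst, 0.03, 0.01)),
               lst_error = mk(ifelse(f_lst, 3, 1))),
    albedo = list(flag = mk(ifelse(f_alb, 3, sample(0:2, nl * nc, TRUE)))),
    ET = list(subpixel_count = mk(ifelse(f_et, 35, 36)))
  )
  list(
    forest = list(t1 = mk(forest_t1), t2 = mk(forest_t2)),
    climate = list(
      LST = list(t1 = mk(lst_t1), t2 = mk(lst_t1 + dLST)),
      ET = list(t1 = mk(et_t1), t2 = mk(et_t1 + dET)),
      albedo = list(t1 = mk(alb_t1), t2 = mk(alb_t1 + dAlb))
    ),
    qc = qc,
    truth = list(coefs = params$coefs, r2 = params$moments$r2,
                 total = params$moments$total, dF = mk(dF), dF_sd = sd_pop)
  )
}

#' Build the analysis change layer from a synthetic landscape
#'
#' Applies the per-variable QC rules to both epochs of each climate variable,
#' then differences epochs (later minus earlier) for all four variables.
#'
#' @param landscape output of \code{\link{generate_landscape}}.
#' @return a \code{change_layer}.
#' @export
landscape_change_layer <- function(landscape) {
  rules <- list(LST = qc_rule("LST"), ET = qc_rule("ET"), albedo = qc_rule("albedo"))
  chg <- lapply(names(rules), function(v) {
    t1 <- apply_qc(landscape$climate[[v]]$t1, landscape$qc[[v]], rules[[v]])
    t2 <- apply_qc(landscape$climate[[v]]$t2, landscape$qc[[v]], rules[[v]])
    decadal_change(t2, t1)
  })
  names(chg) <- names(rules)
  change_layer(dF = decadal_change(landscape$forest$t2, landscape$forest$t1),
               dLST = chg$LST, dET = chg$ET, dAlbedo = chg$albedo)
}
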