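#' Parametric spatial correlation structures
#'
#' Isotropic residual correlation as a function of inter-observation distance,
#' measured as Euclidean distance in raw (longitude, latitude) degrees. The
#' five parametric families plus an independence structure are supported; all
#' equal 1 at zero distance, are non-increasing in distance, and take values in
#' [0, 1]. No nugget term is used.
#'
#' @param family one of \code{"exponential"}, \code{"gaussian"},
#'   \code{"rational_quadratic"}, \code{"spherical"}, \code{"linear"},
#'   \code{"independence"}.
#' @param range positive range parameter in degrees (ignored for independence).
#' @return an object of class \code{cor_structure}.
#' @export
cor_structure <- function(family = c("exponential", "gaussian", "rational_quadratic",
                                     "spherical", "linear", "independence"),
                          range = NULL) {
  family <- match.arg(family)
  if (family != "independence") {
    if (!is.null(range) && (!is.numeric(range) || range <= 0))
      stop("'range' must be positive")
  } else range <- NULL
  structure(list(family = family, range = range), class = "cor_structure")
}

#' @export
print.cor_structure <- function(x, ...) {
  cat("spatial correlation:", x$family,
      if (!is.null(x$range)) sprintf("(range = %.4g deg)", x$range) else "", "\n")
  invisible(x)
}

#' Evaluate a correlation structure at given distances
#'
#' @param structure a \code{cor_structure} with its range set (except
#'   independence).
#' @param d non-negative distance(s) in degrees.
#' @return correlation value(s) in [0, 1].
#' @export
correlation_value <- function(structure, d) {
  if (any(d < 0)) stop("negative distance")
  fam <- structure$family
  if (fam == "independence") return(as.numeric(d == 0))
  r <- structure$range
  if (is.null(r) || r <= 0) stop("non-positive or missing range")
  h <- d / r
  switch(fam,
         exponential = exp(-h),
         gaussian = exp(-h^2),
         rational_quadratic = 1 / (1 + h^2),
         spherical = ifelse(h < 1, 1 - 1.5 * h + 0.5 * h^3, 0),
         linear = ifelse(h < 1, 1 - h, 0))
}

#' Observation correlation matrix (up to residual scale)
#'
#' Builds \code{V = variance_ratio * B + C}, where \code{B} indicates pairs of
#' observations sharing a search window (the window random intercept, expressed
#' as a ratio of window variance to residual variance) and
#' \code{C[i, j] = correlation_value(structure, d_ij)} with Euclidean distance
#' in degrees. A small diagonal jitter is added (and recorded) if the Cholesky
#' factorization fails, which can occur for the gaussian family with
#' near-duplicate coordinates.
#'
#' @param coords two-column matrix or data.frame of (lon, lat).
#' @param structure a \code{cor_structure}.
#' @param variance_ratio non-negative window-to-residual variance ratio, or
#'   \code{NULL} for no random effect.
#' @param window_ids grouping vector (required with \code{variance_ratio}).
#' @return list with matrix \code{V} and the \code{jitter} applied (0 if none).
#' @export
build_covariance <- function(coords, structure, variance_ratio = NULL,
                             window_ids = NULL) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("coords must be finite")
  n <- nrow(coords)
  if (structure$family == "independence") {
    V <- diag(n)
  } else {
    d <- as.matrix(stats::dist(coords))
    V <- matrix(correlation_value(structure, d), n, n)
  }
  if (!is.null(variance_ratio)) {
    if (is.null(window_ids)) stop("'window_ids' required with a variance ratio")
    if (variance_ratio < 0) stop("'variance_ratio' must be non-negative")
    B <- outer(window_ids, window_ids, "==") * 1
    V <- V + variance_ratio * B
  }
  list(V = V, jitter = 0)
}

# Cholesky with escalating jitter; returns list(U, logdet, jitter)
chol_jitter <- function(V) {
  jit <- 0
  for (k in 0:6) {
    U <- tryCatch(chol(if (jit > 0) V + diag(jit, nrow(V)) else V),
                  error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, logdet = 2 * sum(log(diag(U))), jitter = jit))
    jit <- if (jit == 0) 1e-10 else jit * 100
  }
  stop("covariance matrix not positive definite even after jitter")
}

# Profiled GLS given a correlation matrix V (unit-ish diagonal):
# beta and sigma2 profile out analytically; returns both ML and REML logLik.
gls_profile <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  ch <- chol_jitter(V)
  Ut <- t(ch$U)
  Xw <- forwardsolve(Ut, X)
  colnames(Xw) <- colnames(X)
  yw <- forwardsolve(Ut, y)
  qrX <- qr(Xw)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(qrX, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-12)
    stop("whitened design is ill-conditioned at these correlation parameters")
  sigma2_ml <- rss / n
  sigma2_reml <- rss / (n - p)
  ll_ml <- -0.5 * (n * log(2 * pi) + ch$logdet + n * log(sigma2_ml) + n)
  ll_reml <- -0.5 * ((n - p) * log(2 * pi) + ch$logdet +
                       determinant(XtX, logarithm = TRUE)$modulus[1] +
                       (n - p) * log(sigma2_reml) + (n - p))
  list(beta = drop(beta), rss = rss, sigma2_ml = sigma2_ml,
       sigma2_reml = sigma2_reml, ll_ml = ll_ml, ll_reml = ll_reml,
       XtX = XtX, jitter = ch$jitter)
}

#' Fit a linear model by generalized least squares with spatial correlation
#'
#' The fixed-effect coefficients and residual variance are profiled out in
#' closed form given the correlation parameters; the range (and, with a window
#' random effect, the window-to-residual variance ratio) is found by numerical
#' optimization of the ML or REML log-likelihood on the log scale (bounded
#' search, three deterministic starts in the 2-D case, objective tolerance
#' 1e-10). Coefficient standard errors use the REML residual variance at the
#' selected parameters; 95% intervals are estimate +/- 1.96 SE and p-values use
#' a t reference with n - p residual degrees of freedom unless overridden.
#'
#' @param formula model formula evaluated in \code{data}.
#' @param data data.frame of observations.
#' @param coords two-column (lon, lat) matrix/data.frame, one row per
#'   observation.
#' @param structure a \code{cor_structure}; if its range is \code{NULL} it is
#'   estimated.
#' @param method \code{"REML"} (default, for reported coefficients) or
#'   \code{"ML"} (for AICc comparison across structures).
#' @param window_ids optional grouping vector adding a window random intercept.
#' @param variance_ratio optional fixed variance ratio (estimated when
#'   \code{window_ids} is given and this is \code{NULL}).
#' @param V optional fixed, fully known observation covariance matrix (up to
#'   scale); overrides \code{structure} and the random effect.
#' @param df_resid residual degrees of freedom for p-values (default n - p).
#' @return an object of class \code{gls_fit}.
#' @export
fit_gls <- function(formula, data, coords = NULL,
                    structure = cor_structure("independence"),
                    method = c("REML", "ML"),
                    window_ids = NULL, variance_ratio = NULL, V = NULL,
                    df_resid = NULL) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  spatial <- is.null(V) && structure$family != "independence"
  if ((spatial || !is.null(window_ids)) && is.null(V)) {
    if (is.null(coords)) stop("'coords' required for spatial structures")
    coords <- as.matrix(coords)
    if (nrow(coords) != n) stop("coords must have one row per observation")
    if (spatial && anyDuplicated(coords))
      stop("duplicated coordinates: nugget-free spatial correlation requires ",
           "distinct locations (drop or aggregate tied observations)")
  }
  est_range <- spatial && is.null(structure$range)
  est_vr <- is.null(V) && !is.null(window_ids) && is.null(variance_ratio)
  obj_of <- function(fit) if (method == "REML") fit$ll_reml else fit$ll_ml

  D <- NULL
  if (spatial) D <- as.matrix(stats::dist(coords))
  B <- NULL
  if (!is.null(window_ids) && is.null(V)) B <- outer(window_ids, window_ids, "==") * 1

  make_V <- function(range, vr) {
    Vm <- if (spatial) {
      s <- structure; s$range <- range
      matrix(correlation_value(s, D), n, n)
    } else diag(n)
    if (!is.null(B) && !is.null(vr)) Vm <- Vm + vr * B
    Vm
  }

  range_hat <- structure$range
  vr_hat <- variance_ratio
  convergence <- TRUE

  if (!is.null(V)) {
    fit <- gls_profile(y, X, V)
  } else if (!est_range && !est_vr) {
    fit <- gls_profile(y, X, make_V(range_hat, vr_hat))
  } else {
    dpos <- if (spatial) { dv <- D[upper.tri(D)]; dv[dv > 0] } else numeric(0)
    lr_lo <- if (length(dpos)) log(max(min(dpos) / 100, 1e-8)) else -8
    lr_hi <- if (length(dpos)) log(max(dpos) * 10) else 8
    lv_lo <- log(1e-8); lv_hi <- log(1e6)
    neg_obj <- function(par) {
      rg <- if (est_range) exp(par[["lr"]]) else range_hat
      vr <- if (est_vr) exp(par[["lv"]]) else vr_hat
      f <- tryCatch(gls_profile(y, X, make_V(rg, vr)), error = function(e) NULL)
      if (is.null(f)) return(1e10)
      -obj_of(f)
    }
    if (est_range && est_vr) {
      starts <- list(c(lr = stats::median(c(lr_lo, lr_hi)), lv = 0),
                     c(lr = lr_lo + 0.25 * (lr_hi - lr_lo), lv = log(0.1)),
                     c(lr = lr_lo + 0.75 * (lr_hi - lr_lo), lv = log(10)))
      best <- NULL
      for (s0 in starts) {
        o <- stats::optim(s0, neg_obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 2000))
        if (is.null(best) || o$value < best$value) best <- o
      }
      convergence <- best$convergence == 0
      range_hat <- exp(best$par[["lr"]]); vr_hat <- exp(best$par[["lv"]])
    } else if (est_range) {
      # profile likelihood in the range can be multimodal: bracket the global
      # optimum on a deterministic coarse grid before the local refinement
      grid <- seq(lr_lo, lr_hi, length.out = 25)
      gv <- vapply(grid, function(lr) neg_obj(c(lr = lr)), numeric(1))
      i <- which.min(gv)
      o <- stats::optimize(function(lr) neg_obj(c(lr = lr)),
                           interval = c(grid[max(1, i - 1)], grid[min(25, i + 1)]),
                           tol = 1e-10)
      range_hat <- exp(o$minimum)
    } else {
      grid <- seq(lv_lo, lv_hi, length.out = 25)
      gv <- vapply(grid, function(lv) neg_obj(c(lv = lv)), numeric(1))
      i <- which.min(gv)
      o <- stats::optimize(function(lv) neg_obj(c(lv = lv)),
                           interval = c(grid[max(1, i - 1)], grid[min(25, i + 1)]),
                           tol = 1e-10)
      vr_hat <- exp(o$minimum)
    }
    fit <- gls_profile(y, X, make_V(range_hat, vr_hat))
  }

  se <- sqrt(fit$sigma2_reml * diag(solve(fit$XtX)))
  names(se) <- names(fit$beta)
  if (is.null(df_resid)) df_resid <- n - p
  tval <- fit$beta / se
  pval <- 2 * stats::pt(abs(tval), df = df_resid, lower.tail = FALSE)
  ci <- cbind(lower = fit$beta - 1.96 * se, upper = fit$beta + 1.96 * se)
  k <- p + 1 + (if (is.null(V) && spatial) 1 else 0) +
    (if (is.null(V) && !is.null(window_ids)) 1 else 0)
  fitted_vals <- drop(X %*% fit$beta)
  out <- list(
    coefficients = fit$beta, se = se, t = tval, p = pval, ci95 = ci,
    df_resid = df_resid,
    logLik_ml = fit$ll_ml, logLik_reml = fit$ll_reml,
    sigma2 = fit$sigma2_reml, n = n, k = k,
    structure = if (is.null(V)) cor_structure(structure$family,
                                              if (structure$family != "independence") range_hat) else NULL,
    variance_ratio = vr_hat,
    fitted = fitted_vals, residuals = y - fitted_vals,
    y = y, method = method, converged = convergence, jitter = fit$jitter,
    formula = formula
  )
  class(out) <- "gls_fit"
  if (!convergence) warning("optimizer did not fully converge; inspect fit$converged")
  out
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("GLS fit (%s), n = %d, k = %d\n", x$method, x$n, x$k))
  if (!is.null(x$structure)) print(x$structure)
  if (!is.null(x$variance_ratio))
    cat(sprintf("window/residual variance ratio: %.4g\n", x$variance_ratio))
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p)
  print(tab, digits = 4)
  cat(sprintf("logLik: ML %.3f, REML %.3f; sigma2 %.4g\n",
              x$logLik_ml, x$logLik_reml, x$sigma2))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' \code{AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)}.
#'
#' @param log_likelihood model log-likelihood.
#' @param k number of estimated parameters (fixed effects + correlation/variance
#'   parameters + residual variance).
#' @param n number of observations, must exceed \code{k + 1}.
#' @return AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Paired focal/reference mixed model for one variable
#'
#' Expands pairs into two observations per window (the reference-cell change
#' and the focal-cell change), and fits cell type (focal vs reference) as the
#' fixed effect with a window random intercept and, optionally, residual
#' spatial correlation at each observation's own coordinates. The cell-type
#' coefficient estimates the effect of forest change on the variable. Under the
#' independence structure this model is exactly equivalent to a paired t-test
#' on the within-window differences (the cell-type p-value uses
#' \code{n_windows - 1} degrees of freedom accordingly).
#'
#' @param pairs data.frame of pairs (from \code{\link{find_pairs}} or
#'   \code{\link{generate_pairs}}) with \code{<variable>_foc} / \code{_ref}
#'   columns and coordinates.
#' @param variable one of \code{"dLST"}, \code{"dET"}, \code{"dAlbedo"},
#'   \code{"dF"}.
#' @param structure a \code{cor_structure}.
#' @param method \code{"REML"} (default) or \code{"ML"}.
#' @param min_windows minimum number of complete windows required.
#' @return a \code{gls_fit}; the effect of interest is the
#'   \code{cell_typefocal} coefficient.
#' @export
fit_paired_model <- function(pairs, variable = c("dLST", "dET", "dAlbedo", "dF"),
                             structure = cor_structure("independence"),
                             method = c("REML", "ML"), min_windows = 10L) {
  variable <- match.arg(variable)
  method <- match.arg(method)
  foc <- pairs[[paste0(variable, "_foc")]]
  ref <- pairs[[paste0(variable, "_ref")]]
  ok <- !is.na(foc) & !is.na(ref)
  m <- sum(ok)
  if (m < min_windows) stop("fewer than ", min_windows, " complete windows for ", variable)
  pr <- pairs[ok, , drop = FALSE]
  long <- data.frame(
    y = c(ref[ok], foc[ok]),
    cell_type = factor(rep(c("reference", "focal"), each = m),
                       levels = c("reference", "focal")),
    window = rep(seq_len(m), 2)
  )
  coords <- rbind(cbind(pr$ref_lon, pr$ref_lat), cbind(pr$focal_lon, pr$focal_lat))
  fit_gls(y ~ cell_type, long, coords = coords, structure = structure,
          method = method, window_ids = long$window, df_resid = m - 1)
}

#' Fit candidate correlation structures and rank them by AICc
#'
#' Each candidate is fitted with identical fixed effects by maximum likelihood
#' (so AICc values are comparable across correlation structures), ranked by
#' AICc ascending with a stable sort, and the top-ranked fit flagged.
#' Candidates that fail to converge are dropped with a warning; an error is
#' raised only if all fail.
#'
#' @param formula,data,coords,window_ids as in \code{\link{fit_gls}}.
#' @param families character vector of structure families to compare (an
#'   independence candidate is the no-structure comparison model).
#' @param method likelihood used for the AICc ranking (default \code{"ML"}).
#' @return list with \code{table} (family, range, logLik, k, AICc, delta_AICc),
#'   \code{fits}, and \code{best} (the top-ranked \code{gls_fit}).
#' @export
select_structure <- function(formula, data, coords,
                             families = c("rational_quadratic", "exponential",
                                          "gaussian", "spherical", "linear",
                                          "independence"),
                             window_ids = NULL, method = "ML") {
  if (length(families) < 2L) stop("need at least 2 candidate structures")
  fits <- vector("list", length(families))
  for (i in seq_along(families)) {
    fits[[i]] <- tryCatch(
      fit_gls(formula, data, coords = coords,
              structure = cor_structure(families[i]),
              method = method, window_ids = window_ids),
      error = function(e) { warning("candidate '", families[i], "' failed: ",
                                    conditionMessage(e)); NULL })
  }
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) stop("all candidate structures failed to fit")
  fits <- fits[keep]; fams <- families[keep]
  ll <- vapply(fits, function(f)
    if (method == "ML") f$logLik_ml else f$logLik_reml, numeric(1))
  kk <- vapply(fits, function(f) f$k, numeric(1))
  nn <- vapply(fits, function(f) f$n, numeric(1))
  ic <- mapply(aicc, ll, kk, nn)
  tab <- data.frame(family = fams,
                    range = vapply(fits, function(f)
                      if (is.null(f$structure$range)) NA_real_ else f$structure$range,
                      numeric(1)),
                    logLik = ll, k = kk, AICc = ic)
  ord <- order(tab$AICc)          # stable: ties keep input order
  tab <- tab[ord, , drop = FALSE]
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  rownames(tab) <- NULL
  list(table = tab, fits = fits[ord], best = fits[[ord[1]]])
}
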