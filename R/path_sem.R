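#' Specification of the forest-climate path model
#'
#' The causal diagram links decadal forest change (dF, exogenous) to local LST
#' change through surface albedo and evapotranspiration: dLST depends on dF,
#' dAlbedo and dET; dAlbedo depends on dF; dET depends on dF and dAlbedo. Any
#' recursive (acyclic) system over these variables can be specified; each
#' endogenous variable has exactly one equation.
#'
#' @param equations list of formulas, one per endogenous variable.
#' @return an object of class \code{path_spec} with the equation list, the
#'   directed edge table, variables in topological order, and the exogenous set.
#' @export
path_spec <- function(equations = list(dAlbedo ~ dF,
                                       dET ~ dF + dAlbedo,
                                       dLST ~ dF + dAlbedo + dET)) {
  responses <- vapply(equations, function(f) as.character(f[[2]]), character(1))
  if (anyDuplicated(responses)) stop("each endogenous variable needs exactly one equation")
  edges <- do.call(rbind, lapply(equations, function(f) {
    preds <- all.vars(f[[3]])
    data.frame(from = preds, to = as.character(f[[2]]))
  }))
  vars <- unique(c(edges$from, edges$to))
  exogenous <- setdiff(vars, responses)
  order <- topo_order(vars, edges)   # errors on cycles
  structure(list(equations = equations, responses = responses, edges = edges,
                 variables = order, exogenous = exogenous),
            class = "path_spec")
}

topo_order <- function(vars, edges) {
  out <- character(0)
  remaining <- sort(vars)            # deterministic: name order among sources
  ed <- edges
  while (length(remaining)) {
    src <- remaining[!(remaining %in% ed$to)]
    if (length(src) == 0L) stop("equation graph is not a DAG (cycle detected)")
    v <- src[1L]
    out <- c(out, v)
    remaining <- setdiff(remaining, v)
    ed <- ed[ed$from != v, , drop = FALSE]
  }
  out
}

parents_of <- function(spec, v) sort(spec$edges$from[spec$edges$to == v])

#' Standardize a regression coefficient
#'
#' @param raw raw coefficient (response units per predictor unit).
#' @param sd_predictor,sd_response sample standard deviations, both positive.
#' @return the standardized coefficient \code{raw * sd_predictor / sd_response}.
#' @export
standardize_coefficient <- function(raw, sd_predictor, sd_response) {
  if (sd_predictor <= 0 || sd_response <= 0) stop("standard deviations must be positive")
  raw * sd_predictor / sd_response
}

#' Coefficient of determination of a fitted component model
#'
#' Primary definition: \code{1 - RSS/TSS} on raw residuals. The squared
#' correlation between fitted and observed values is also returned, as the two
#' can differ for GLS fits.
#'
#' @param fit a \code{gls_fit}.
#' @return list with \code{r2} (1 - RSS/TSS) and \code{r2_cor}.
#' @export
r_squared <- function(fit) {
  tss <- sum((fit$y - mean(fit$y))^2)
  if (tss == 0) stop("zero total sum of squares")
  r2 <- 1 - sum(fit$residuals^2) / tss
  r2_cor <- if (stats::sd(fit$fitted) > 0) stats::cor(fit$fitted, fit$y)^2 else 0
  list(r2 = r2, r2_cor = r2_cor)
}

#' Fit the path model to pair-level data
#'
#' Each component equation is fitted by \code{\link{fit_gls}} on the subset of
#' pairs with all model variables present (the path-analysis subset), using the
#' given spatial correlation structure anchored at the focal cell's
#' coordinates. Because the correlation families carry no nugget, tied
#' locations are inadmissible: when the window search retains one focal cell
#' with several references, only the earliest-window pair enters this
#' analysis. Standardized coefficients use the sample SDs of that subset.
#' Links with p > 0.05 are flagged non-significant for display but retained in
#' all effect arithmetic.
#'
#' @param pairs data.frame with \code{dF_std}, \code{dAlbedo_std},
#'   \code{dET_std}, \code{dLST_std}, \code{focal_lon}, \code{focal_lat}.
#' @param spec a \code{path_spec}.
#' @param structure a \code{cor_structure} (the rational quadratic family is
#'   the default used for reported path models).
#' @param method \code{"REML"} (default) or \code{"ML"}.
#' @param min_n minimum number of complete pairs.
#' @return an object of class \code{path_fit}: component fits, a link table
#'   (from, to, raw, standardized, se, p, significant), per-equation R2,
#'   sample SDs, and the analysis subset size.
#' @export
fit_path_model <- function(pairs, spec = path_spec(),
                           structure = cor_structure("rational_quadratic"),
                           method = c("REML", "ML"), min_n = 30L) {
  method <- match.arg(method)
  std_cols <- paste0(spec$variables, "_std")
  missing_cols <- setdiff(std_cols, names(pairs))
  if (length(missing_cols)) stop("pairs lack columns: ", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(pairs[, std_cols, drop = FALSE])
  d <- pairs[cc, , drop = FALSE]
  # one observation per location: a focal cell retained with several
  # references would enter a nugget-free spatial likelihood as perfectly
  # correlated replicates, so only its earliest-window pair is analyzed
  d <- d[!duplicated(cbind(d$focal_lon, d$focal_lat)), , drop = FALSE]
  if (nrow(d) < min_n) stop("fewer than ", min_n, " complete pairs")
  dat <- d[, std_cols, drop = FALSE]
  names(dat) <- spec$variables
  coords <- cbind(d$focal_lon, d$focal_lat)
  sds <- vapply(dat, stats::sd, numeric(1))
  fits <- list(); links <- list(); r2 <- list()
  for (i in seq_along(spec$equations)) {
    f <- spec$equations[[i]]
    resp <- spec$responses[i]
    fit <- fit_gls(f, dat, coords = coords, structure = structure, method = method)
    fits[[resp]] <- fit
    r2[[resp]] <- r_squared(fit)$r2
    preds <- all.vars(f[[3]])
    links[[resp]] <- data.frame(
      from = preds, to = resp,
      raw = unname(fit$coefficients[preds]),
      standardized = vapply(preds, function(pv)
        standardize_coefficient(fit$coefficients[[pv]], sds[[pv]], sds[[resp]]),
        numeric(1)),
      se = unname(fit$se[preds]),
      p = unname(fit$p[preds])
    )
  }
  link_table <- do.call(rbind, links)
  link_table$significant <- link_table$p <= 0.05
  rownames(link_table) <- NULL
  out <- list(spec = spec, component_fits = fits, links = link_table,
              r2 = unlist(r2), sds = sds, n = nrow(dat),
              structure = structure)
  class(out) <- "path_fit"
  out
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("path model fit: n = %d complete pairs, structure = %s\n",
              x$n, x$structure$family))
  tab <- x$links
  tab$standardized <- round(tab$standardized, 3)
  tab$raw <- signif(tab$raw, 4)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("R2:", paste(sprintf("%s %.3f", names(x$r2), x$r2), collapse = ", "), "\n")
  invisible(x)
}

link_coef <- function(model, from, to) {
  i <- which(model$links$from == from & model$links$to == to)
  if (length(i) != 1L) stop("missing link coefficient ", from, " -> ", to)
  model$links$standardized[i]
}

#' Decompose the effect of forest change on LST
#'
#' On the standardized scale, the direct effect is the dF -> dLST link; the
#' three indirect effects are the products of standardized coefficients along
#' dF -> dAlbedo -> dLST, dF -> dET -> dLST, and dF -> dAlbedo -> dET -> dLST;
#' the total effect is the direct effect plus the sum of the indirect effects
#' (an exact identity of the decomposition). Non-significant links are
#' retained in the arithmetic.
#'
#' @param model a \code{path_fit} of the full forest-climate diagram.
#' @return an object of class \code{effects_decomposition} with fields
#'   \code{direct}, \code{indirect} (named vector over the three pathways),
#'   \code{indirect_total} and \code{total}.
#' @export
effects_decomposition <- function(model) {
  a_FA <- link_coef(model, "dF", "dAlbedo")
  a_FE <- link_coef(model, "dF", "dET")
  a_AE <- link_coef(model, "dAlbedo", "dET")
  a_FL <- link_coef(model, "dF", "dLST")
  a_AL <- link_coef(model, "dAlbedo", "dLST")
  a_EL <- link_coef(model, "dET", "dLST")
  indirect <- c("dF->dAlbedo->dLST" = a_FA * a_AL,
                "dF->dET->dLST" = a_FE * a_EL,
                "dF->dAlbedo->dET->dLST" = a_FA * a_AE * a_EL)
  out <- list(direct = a_FL, indirect = indirect,
              indirect_total = sum(indirect),
              total = a_FL + sum(indirect))
  class(out) <- "effects_decomposition"
  out
}

#' @export
print.effects_decomposition <- function(x, ...) {
  cat(sprintf("standardized effects of dF on dLST:\n  direct   %+.3f\n", x$direct))
  for (nm in names(x$indirect)) cat(sprintf("  %-24s %+.3f\n", nm, x$indirect[[nm]]))
  cat(sprintf("  indirect (sum) %+.3f\n  total    %+.3f\n", x$indirect_total, x$total))
  invisible(x)
}

#' Convert a standardized total effect to degrees Celsius
#'
#' A change of \code{delta_in_sd_units} standard deviations of forest cover
#' shifts LST by \code{total_std * delta_in_sd_units} standard deviations of
#' LST change, i.e. \code{|total_std| * sd_dLST * delta} degrees C, signed by
#' the total effect.
#'
#' @param total_std total standardized effect of dF on dLST.
#' @param sd_dF sample SD of standardized forest change (%; kept for the
#'   record: the per-SD answer does not depend on it).
#' @param sd_dLST sample SD of standardized LST change (deg C), positive.
#' @param delta_in_sd_units forest-cover change expressed in SDs of dF.
#' @return LST change in degrees C.
#' @export
unstandardized_effect <- function(total_std, sd_dF, sd_dLST, delta_in_sd_units = 1) {
  if (sd_dF <= 0 || sd_dLST <= 0) stop("standard deviations must be positive")
  sign(total_std) * abs(total_std) * sd_dLST * delta_in_sd_units
}

#' d-separation basis set of a (pruned) path model
#'
#' For every ordered pair of non-adjacent variables (the earlier variable in
#' the causal ordering first), the basis claims independence of the pair
#' conditional on the union of both variables' parents. The saturated
#' forest-climate diagram has no missing links, hence an empty basis and no
#' testable global fit. Claims are returned in a deterministic order (by
#' response, then claim variable name).
#'
#' @param spec a \code{path_spec}.
#' @return data.frame with columns \code{response}, \code{claim_var},
#'   \code{conditioning} (comma-joined, possibly empty).
#' @export
dsep_basis <- function(spec) {
  vars <- spec$variables             # topological order
  claims <- list()
  adj <- paste(spec$edges$from, spec$edges$to)
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i >= j) next
    u <- vars[i]; v <- vars[j]       # u precedes v causally
    if (paste(u, v) %in% adj || paste(v, u) %in% adj) next
    cond <- sort(union(parents_of(spec, u), parents_of(spec, v)))
    claims[[length(claims) + 1L]] <- data.frame(
      response = v, claim_var = u,
      conditioning = paste(cond, collapse = ","))
  }
  if (length(claims) == 0L)
    return(data.frame(response = character(0), claim_var = character(0),
                      conditioning = character(0)))
  out <- do.call(rbind, claims)
  out <- out[order(out$response, out$claim_var), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test the d-separation claims of a pruned model on pair data
#'
#' Each claim is tested by regressing the claim's response on its conditioning
#' set plus the claimed-independent variable with the same GLS correlation
#' structure used for the component models, and reading the added predictor's
#' p-value.
#'
#' @param pairs pair-level data (as for \code{\link{fit_path_model}}).
#' @param spec a pruned \code{path_spec}.
#' @param structure a \code{cor_structure}.
#' @return data.frame of claims with a \code{p} column.
#' @export
dsep_tests <- function(pairs, spec, structure = cor_structure("independence")) {
  basis <- dsep_basis(spec)
  if (nrow(basis) == 0L) return(cbind(basis, p = numeric(0)))
  all_vars <- unique(c(spec$variables,
                       unlist(strsplit(basis$conditioning, ","))))
  std_cols <- paste0(all_vars, "_std")
  cc <- stats::complete.cases(pairs[, std_cols, drop = FALSE])
  d <- pairs[cc, , drop = FALSE]
  d <- d[!duplicated(cbind(d$focal_lon, d$focal_lat)), , drop = FALSE]
  dat <- d[, std_cols, drop = FALSE]
  names(dat) <- all_vars
  coords <- cbind(d$focal_lon, d$focal_lat)
  basis$p <- NA_real_
  for (i in seq_len(nrow(basis))) {
    cond <- strsplit(basis$conditioning[i], ",")[[1]]
    cond <- cond[nzchar(cond)]
    rhs <- paste(c(cond, basis$claim_var[i]), collapse = " + ")
    if (!nzchar(rhs)) rhs <- basis$claim_var[i]
    f <- stats::as.formula(paste(basis$response[i], "~", rhs))
    fit <- fit_gls(f, dat, coords = coords, structure = structure)
    basis$p[i] <- fit$p[[basis$claim_var[i]]]
  }
  basis
}

#' Fisher's C statistic over a d-separation basis
#'
#' \code{C = -2 sum(log p_i)} over the k independence-claim p-values, referred
#' to a chi-squared distribution with 2k degrees of freedom. A significant C
#' (small p) indicates that at least one missing link matters.
#'
#' @param p_values claim p-values in (0, 1].
#' @return list with \code{C}, \code{df} and \code{p}.
#' @export
fishers_c <- function(p_values) {
  if (length(p_values) < 1L) stop("need at least one claim p-value")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  if (any(p_values == 0)) {
    warning("p-value of 0: Fisher's C is infinite")
    return(list(C = Inf, df = 2L * length(p_values), p = 0))
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df, p = stats::pchisq(C, df, lower.tail = FALSE))
}

#' Serialize a fitted path model to JSON
#'
#' Writes the link table (from, to, raw, standardized, p), per-equation R2,
#' sample SDs and the effects decomposition.
#'
#' @param model a \code{path_fit}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_path_model_json <- function(model, path) {
  dec <- effects_decomposition(model)
  obj <- list(
    n = model$n,
    structure = model$structure$family,
    links = model$links,
    r2 = as.list(model$r2),
    sds = as.list(model$sds),
    effects = list(direct = dec$direct, indirect = as.list(dec$indirect),
                   total = dec$total),
    note = paste("Projection with these coefficients assumes the fitted",
                 "forest-albedo-ET-LST relationships remain unchanged.")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
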