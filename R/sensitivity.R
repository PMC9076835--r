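# One-at-a-time sensitivity of the holding angle and first-order
# propagation of parameter covariation into predicted correlations.

model_parameter_names <- function() {
  c("D", "H", "R", "H_pod", "H_side", "W_side", "W_vasc", "D_cavity",
    "d_vasc", "s_cort", "s_pod", "s_side", "s_vasc",
    "rho_cort", "rho_pod", "rho_side", "nu")
}

get_param <- function(geometry, materials, name) {
  if (name %in% names(geometry)) return(geometry[[name]])
  switch(name,
    s_cort = materials$s[["cortex"]], s_pod = materials$s[["podium"]],
    s_side = materials$s[["side"]], s_vasc = materials$s[["vasculature"]],
    rho_cort = materials$rho[["cortex"]], rho_pod = materials$rho[["podium"]],
    rho_side = materials$rho[["side"]], nu = materials$nu,
    stop("unknown parameter: ", name, call. = FALSE))
}

set_param <- function(geometry, materials, name, value) {
  if (name %in% names(geometry)) {
    gl <- unclass(geometry)
    gl[[name]] <- value
    geometry <- do.call(geometry_params, gl)
  } else {
    if (name == "nu") materials$nu <- value
    else if (startsWith(name, "s_")) {
      reg <- switch(name, s_cort = "cortex", s_pod = "podium",
                    s_side = "side", s_vasc = "vasculature")
      if (value <= 0 || value >= 1) stop("swelling factor out of (0,1)")
      materials$s[[reg]] <- value
    } else if (startsWith(name, "rho_")) {
      reg <- switch(name, rho_cort = "cortex", rho_pod = "podium",
                    rho_side = "side")
      if (value <= 0) stop("density must be positive")
      materials$rho[[reg]] <- value
    } else stop("unknown parameter: ", name, call. = FALSE)
  }
  list(geometry = geometry, materials = materials)
}

theta_of <- function(geometry, materials, target_edge) {
  st <- solve_actuator(geometry, materials, target_edge = target_edge)
  st$theta
}

#' One-at-a-time sensitivity of the holding angle
#'
#' Varies each parameter about its reference value while keeping all
#' others fixed and reports the dimensionless sensitivity
#' `S = (dtheta/theta_ref) / (dp/p_ref)` from central differences at
#' `p_ref (1 +/- rel_step)`. Parameters whose perturbed geometry is
#' invalid are recorded as failed and do not stop the others.
#'
#' @param geometry a [geometry_params()] object.
#' @param materials a [material_params()] object.
#' @param parameters character vector of parameter names (defaults to
#'   all geometric, swelling, density and Poisson parameters).
#' @param rel_step relative step in (0, 0.2].
#' @param target_edge mesh resolution (um) for every solve.
#' @return data frame of class `sensitivity_result`: `parameter`,
#'   `value` (reference), `theta_minus`, `theta_plus`, `sensitivity`,
#'   `error` (NA or the failure message); attributes `theta_ref` and
#'   `rel_step`.
#' @export
oat_sensitivity <- function(geometry = geometry_params(),
                            materials = material_params(),
                            parameters = model_parameter_names(),
                            rel_step = 0.05, target_edge = 6) {
  if (rel_step <= 0 || rel_step > 0.2)
    stop("rel_step must lie in (0, 0.2]", call. = FALSE)
  theta_ref <- theta_of(geometry, materials, target_edge)
  if (abs(theta_ref) < 1e-9)
    stop("theta_ref is zero; relative sensitivity undefined", call. = FALSE)
  rows <- lapply(parameters, function(nm) {
    p0 <- get_param(geometry, materials, nm)
    res <- tryCatch({
      up <- set_param(geometry, materials, nm, p0 * (1 + rel_step))
      dn <- set_param(geometry, materials, nm, p0 * (1 - rel_step))
      tp <- theta_of(up$geometry, up$materials, target_edge)
      tm <- theta_of(dn$geometry, dn$materials, target_edge)
      p0 <- unname(p0)
      data.frame(parameter = nm, value = p0, theta_minus = tm,
                 theta_plus = tp,
                 sensitivity = ((tp - tm) / theta_ref) / (2 * rel_step),
                 error = NA_character_)
    }, error = function(e)
      data.frame(parameter = nm, value = p0, theta_minus = NA_real_,
                 theta_plus = NA_real_, sensitivity = NA_real_,
                 error = conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "theta_ref") <- theta_ref
  attr(out, "rel_step") <- rel_step
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' Sweep the holding angle along one parameter
#'
#' @param parameter parameter name.
#' @param rel_changes vector of relative changes (e.g. `seq(-0.2, 0.2,
#'   0.05)`); 0 is the reference point.
#' @inheritParams oat_sensitivity
#' @return data frame `rel_change`, `value`, `theta` (NA where the
#'   perturbed geometry is invalid).
#' @export
theta_sweep <- function(parameter, rel_changes = seq(-0.2, 0.2, by = 0.05),
                        geometry = geometry_params(),
                        materials = material_params(), target_edge = 6) {
  p0 <- get_param(geometry, materials, parameter)
  th <- vapply(rel_changes, function(r) {
    tryCatch({
      mod <- set_param(geometry, materials, parameter, p0 * (1 + r))
      theta_of(mod$geometry, mod$materials, target_edge)
    }, error = function(e) NA_real_)
  }, numeric(1))
  data.frame(rel_change = rel_changes, value = p0 * (1 + rel_changes),
             theta = th)
}

#' Covariation structure of model parameters
#'
#' @param parameters character vector of parameter names.
#' @param cv per-parameter coefficient of variation (> 0).
#' @param corr correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite) in the order of `parameters`.
#' @return object of class `parameter_covariation`.
#' @export
parameter_covariation <- function(parameters, cv, corr) {
  k <- length(parameters)
  stopifnot(length(cv) == k, is.matrix(corr), all(dim(corr) == k))
  if (any(!is.finite(cv)) || any(cv < 0))
    stop("coefficients of variation must be non-negative", call. = FALSE)
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix must be positive semi-definite", call. = FALSE)
  structure(list(parameters = parameters, cv = setNames(cv, parameters),
                 corr = `dimnames<-`(corr, list(parameters, parameters))),
            class = "parameter_covariation")
}

#' Predicted correlation between the holding angle and each parameter
#'
#' First-order (delta-method) propagation: with gradient
#' `g_j = S_j * theta_ref / p_j` and spread `sigma_j = CV_j * p_j`,
#' `cov(theta, p_i) = sum_j g_j sigma_j sigma_i rho_ij`,
#' `var(theta) = sum_jk g_j g_k sigma_j sigma_k rho_jk`, and
#' `corr(theta, p_i) = cov(theta, p_i) / (sqrt(var(theta)) sigma_i)`.
#'
#' @param sens a `sensitivity_result` from [oat_sensitivity()] covering
#'   every parameter in `cov`.
#' @param cov a [parameter_covariation()] object.
#' @return data frame `parameter`, `sensitivity`, `predicted_correlation`
#'   (all values in `[-1, 1]`).
#' @export
predict_correlations <- function(sens, cov) {
  stopifnot(inherits(sens, "sensitivity_result"),
            inherits(cov, "parameter_covariation"))
  idx <- match(cov$parameters, sens$parameter)
  if (anyNA(idx))
    stop("sensitivities missing for: ",
         paste(cov$parameters[is.na(idx)], collapse = ", "), call. = FALSE)
  S <- sens$sensitivity[idx]
  if (anyNA(S))
    stop("sensitivity is NA for: ",
         paste(cov$parameters[is.na(S)], collapse = ", "), call. = FALSE)
  p <- sens$value[idx]
  theta_ref <- attr(sens, "theta_ref")
  g <- S * theta_ref / p
  sig <- cov$cv * p
  if (any(sig <= 0))
    stop("degenerate propagation: zero spread for ",
         paste(cov$parameters[sig <= 0], collapse = ", "), call. = FALSE)
  rho <- cov$corr
  cth <- as.numeric(rho %*% (g * sig)) * sig      # cov(theta, p_i)
  vth <- as.numeric((g * sig) %*% rho %*% (g * sig))
  if (vth <= 0)
    stop("degenerate propagation: var(theta) is zero", call. = FALSE)
  r <- cth / (sqrt(vth) * sig)
  data.frame(parameter = cov$parameters, sensitivity = S,
             predicted_correlation = pmin(1, pmax(-1, r)))
}

#' Example covariation of the geometric parameters
#'
#' A plausible positive-definite covariation structure for the nine
#' geometric parameters, standing in for unpublished specimen
#' covariation: sizes co-vary through an overall size factor (stronger
#' among the overall dimensions), with moderate CVs.
#'
#' @return a [parameter_covariation()] object.
#' @export
example_geometry_covariation <- function() {
  pars <- c("D", "H", "R", "H_pod", "H_side", "W_side", "W_vasc",
            "D_cavity", "d_vasc")
  # one-factor structure: corr_ij = l_i * l_j, loadings by how strongly
  # each length tracks overall plate size
  l <- c(D = 0.9, H = 0.85, R = 0.7, H_pod = 0.5, H_side = 0.6,
         W_side = 0.55, W_vasc = 0.45, D_cavity = 0.5, d_vasc = 0.4)
  corr <- outer(l, l)
  diag(corr) <- 1
  cv <- c(D = 0.08, H = 0.09, R = 0.10, H_pod = 0.12, H_side = 0.10,
          W_side = 0.12, W_vasc = 0.12, D_cavity = 0.15, d_vasc = 0.15)
  parameter_covariation(pars, cv[pars], corr[pars, pars])
}
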