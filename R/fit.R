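# Calibration of the four intrinsic swelling factors against regional
# expansion targets. The mesh and the stiffness factorization depend
# only on geometry and densities, so they are built once; each objective
# evaluation is a single forward/backward substitution with a new
# eigenstrain load.

#' Regional expansion targets
#'
#' @param region character vector of region names (all four of podium,
#'   vasculature, side, cortex must be present).
#' @param ratio target area change as wet/dry expansion ratio.
#' @param sd optional standard deviation of each target; when supplied
#'   the fit is inverse-variance weighted.
#' @return data frame of class `expansion_targets`.
#' @export
expansion_targets <- function(region, ratio, sd = NULL) {
  region <- as.character(region)
  need <- c("podium", "vasculature", "side", "cortex")
  if (!setequal(region, need))
    stop("targets must name exactly the four regions: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("target ratios must be positive", call. = FALSE)
  out <- data.frame(region = region, ratio = ratio,
                    sd = if (is.null(sd)) NA_real_ else sd)
  class(out) <- c("expansion_targets", class(out))
  out
}

#' Fit the intrinsic swelling factors to regional expansion targets
#'
#' Minimizes the (optionally inverse-variance weighted) sum of squared
#' differences between the model's regional wet/dry expansion ratios and
#' the targets, over the four swelling factors, using Nelder-Mead on a
#' logistic-transformed scale with restarts from jittered initial
#' points.
#'
#' @param geometry a [geometry_params()] object.
#' @param materials a [material_params()] object supplying densities,
#'   Poisson ratio and modulus scale; its swelling factors are ignored
#'   except as defaults for `initial_s`.
#' @param targets an [expansion_targets()] data frame.
#' @param initial_s named numeric vector of starting swelling factors
#'   (names: podium, vasculature, side, cortex).
#' @param bounds length-2 numeric, box bounds for every factor.
#' @param target_edge mesh resolution (um) used during the fit.
#' @param restarts number of jittered restarts beyond the first.
#' @param jitter_sd standard deviation of the logit-scale jitter.
#' @param seed seed for the jitter.
#' @param maxit Nelder-Mead iteration budget per start.
#' @return list of class `swelling_fit`: `$s` (fitted factors), `$value`
#'   (objective at the optimum), `$initial_value`, `$convergence` (0 =
#'   converged), `$starts` (per-start results), `$materials` (materials
#'   with fitted factors inserted).
#' @export
fit_swelling_factors <- function(geometry, materials, targets,
                                 initial_s = materials$s,
                                 bounds = c(0.01, 0.95),
                                 target_edge = 8, restarts = 2,
                                 jitter_sd = 0.3, seed = 1L,
                                 maxit = 400) {
  stopifnot(inherits(targets, "expansion_targets"))
  if (bounds[1] <= 0 || bounds[2] >= 1 || bounds[1] >= bounds[2])
    stop("bounds must satisfy 0 < lower < upper < 1", call. = FALSE)
  regs <- c("podium", "vasculature", "side", "cortex")
  s0 <- initial_s[regs]
  if (anyNA(s0)) stop("initial_s must name all four regions", call. = FALSE)
  tg <- setNames(targets$ratio, targets$region)[regs]
  w <- if (all(is.finite(targets$sd)) && all(targets$sd > 0))
    setNames(1 / targets$sd^2, targets$region)[regs] else rep(1, 4)

  dom <- build_reference_geometry(geometry)
  mesh <- mesh_domain(dom, target_edge = target_edge)
  problem <- swelling_problem(mesh, materials)
  op <- dehydration_operator(problem)
  wet <- tri_signed_areas(mesh$nodes, mesh$triangles)
  aw <- tapply(wet, mesh$region, sum, default = NA_real_)[regs]
  tri <- mesh$triangles
  regf <- mesh$region

  model_ratio <- function(s) {
    U <- operator_solve(op, s[regs])
    dry <- tri_signed_areas(mesh$nodes + U, tri)
    ad <- tapply(dry, regf, sum, default = NA_real_)[regs]
    aw / ad   # wet/dry expansion
  }
  lo <- bounds[1]; hi <- bounds[2]
  to_z <- function(s) stats::qlogis((s - lo) / (hi - lo))
  to_s <- function(z) lo + (hi - lo) * stats::plogis(z)
  obj_z <- function(z) {
    r <- model_ratio(setNames(to_s(z), regs))
    sum(w * (r - tg)^2)
  }

  z0 <- to_z(pmin(pmax(s0, lo + 1e-6), hi - 1e-6))
  f0 <- obj_z(z0)
  set.seed(seed)
  starts <- c(list(z0), lapply(seq_len(restarts), function(i)
    z0 + rnorm(4, sd = jitter_sd)))
  runs <- lapply(starts, function(z) {
    optim(z, obj_z, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-10))
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  if (best$convergence != 0)
    warning("optimizer did not report convergence within the iteration budget")
  s_hat <- setNames(to_s(best$par), regs)
  if (any(s_hat < lo + 1e-4 | s_hat > hi - 1e-4))
    warning("fitted swelling factor at a box bound")
  mat_hat <- materials
  mat_hat$s <- s_hat[names(materials$s)]
  structure(list(s = s_hat, value = best$value, initial_value = f0,
                 convergence = best$convergence,
                 starts = data.frame(start = seq_along(vals), value = vals),
                 materials = mat_hat),
            class = "swelling_fit")
}

#' @export
print.swelling_fit <- function(x, ...) {
  cat("Swelling-factor fit\n  fitted s:\n")
  print(round(x$s, 4))
  cat(sprintf("  objective %.4g (initial %.4g), convergence %d\n",
              x$value, x$initial_value, x$convergence))
  invisible(x)
}
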