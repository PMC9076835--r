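# Seeded generators for every input the pipeline consumes: reference
# configurations, deformed landmark sets with known regional area
# factors, Sneddon-form force curves with baseline tilt and adhesion
# dips, and correlated geometric-parameter samples.

#' Reference configuration of the actuator model
#'
#' @return list with `geometry` (the measured hydrated geometry) and
#'   `materials` (measured densities, estimated Poisson ratio and fitted
#'   swelling factors).
#' @examples
#' cfg <- reference_config()
#' cfg$geometry$D       # 491
#' cfg$materials$s      # fitted swelling factors
#' @export
reference_config <- function() {
  list(geometry = geometry_params(), materials = material_params())
}

#' Default landmark layout for synthetic deformation data
#'
#' A rectangular sample outline partitioned into full-height vertical
#' strips: podium, cortex, vasculature, cortex, side (left to right).
#' Only the named regions carry polygons; the unnamed strips default to
#' cortex under the 40% overlap rule. The strip arrangement lets the
#' paired deformation field control the local area factor exactly (see
#' [generate_landmarks()]).
#'
#' @param width,height outline size (um).
#' @return list with `outline`, `regions` (vertex matrices) and the
#'   strip `breaks` used by the deformation field.
#' @export
default_landmark_layout <- function(width = 760, height = 240) {
  breaks <- width * c(0, 150, 300, 460, 610, 760) / 760
  strip <- function(a, b) cbind(c(a, b, b, a), c(0, 0, height, height))
  outline <- strip(0, width)
  regions <- list(podium = strip(breaks[1], breaks[2]),
                  vasculature = strip(breaks[3], breaks[4]),
                  side = strip(breaks[5], breaks[6]))
  list(outline = outline, regions = regions, breaks = breaks)
}

#' Specification of a synthetic landmark deformation
#'
#' @param area_factors named vector of target wet/dry area factors per
#'   region (any of podium, vasculature, side, cortex).
#' @param blend_length smooth blending length (um) between the
#'   region-wise affine maps.
#' @param noise_sd isotropic Gaussian annotation noise SD (um) added to
#'   the wet positions.
#' @param spacing landmark grid spacing (um).
#' @param seed integer seed.
#' @return object of class `deformation_spec`.
#' @export
deformation_spec <- function(area_factors = c(cortex = 1.8, vasculature = 1.3,
                                              podium = 1.6, side = 1.9),
                             blend_length = 10, noise_sd = 0,
                             spacing = 20, seed = 1L) {
  if (any(area_factors <= 0)) stop("area factors must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  structure(list(area_factors = area_factors, blend_length = blend_length,
                 noise_sd = noise_sd, spacing = spacing,
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

#' Generate a synthetic paired landmark set
#'
#' Dry landmarks are scattered on a jittered grid over the layout
#' outline; wet positions come from a smooth deformation field whose
#' local area factor is controlled exactly: with strip-wise factors
#' `f(x)` (Gaussian-smoothed across strip boundaries over the blend
#' length), the map is `x' = int_0^x sqrt(f(u)) du`,
#' `y' = y * sqrt(f(x))`, whose Jacobian determinant equals `f(x)`
#' everywhere - including inside the blend zones - and is positive, so
#' the synthetic field never folds. Optional isotropic Gaussian
#' annotation noise is added to the wet positions. The generator is a
#' pure function of the spec (including its seed).
#'
#' @param spec a [deformation_spec()].
#' @param layout a layout as from [default_landmark_layout()].
#' @return list: `landmarks` (a [landmark_set()]) and `truth` (the
#'   per-region area factors used).
#' @export
generate_landmarks <- function(spec = deformation_spec(),
                               layout = default_landmark_layout()) {
  stopifnot(inherits(spec, "deformation_spec"))
  set.seed(spec$seed)
  out <- layout$outline
  bb <- apply(out, 2, range)
  sp <- spec$spacing
  gx <- seq(bb[1, 1] + sp / 2, bb[2, 1] - sp / 4, by = sp)
  gy <- seq(bb[1, 2] + sp / 2, bb[2, 2] - sp / 4, by = sp)
  g <- as.matrix(expand.grid(gx, gy))
  jit <- matrix(runif(length(g), -0.25 * sp, 0.25 * sp), ncol = 2)
  # keep the outermost rows/columns exactly on their grid lines so the
  # triangulation hull carries no near-degenerate sliver triangles
  interior <- g[, 1] > min(gx) & g[, 1] < max(gx) &
    g[, 2] > min(gy) & g[, 2] < max(gy)
  g <- g + jit * as.numeric(interior)
  keep <- point_in_polygon(g[, 1], g[, 2], out) &
    dist_to_polygon(g[, 1], g[, 2], out) > 0.2 * sp
  dry <- g[keep, , drop = FALSE]
  dimnames(dry) <- NULL

  factors <- spec$area_factors
  if (!"cortex" %in% names(factors)) factors[["cortex"]] <- 1
  br <- layout$breaks
  strip_of <- c("podium", "cortex", "vasculature", "cortex", "side")
  fs <- vapply(strip_of, function(nm) {
    f <- unname(factors[nm]); if (length(f) == 0 || is.na(f)) 1 else f
  }, numeric(1))

  # strip-wise area factor, Gaussian-smoothed on a fine x grid
  xg <- seq(bb[1, 1] - 3 * spec$blend_length,
            bb[2, 1] + 3 * spec$blend_length, length.out = 4096)
  fraw <- fs[pmin(findInterval(xg, br[-1]) + 1L, length(fs))]
  if (spec$blend_length > 0) {
    dx <- xg[2] - xg[1]
    kw <- dnorm(seq(-4 * spec$blend_length, 4 * spec$blend_length, by = dx),
                sd = spec$blend_length)
    kw <- kw / sum(kw)
    fsm <- stats::filter(fraw, kw, sides = 2)
    fsm[is.na(fsm)] <- fraw[is.na(fsm)]
  } else fsm <- fraw
  lam <- sqrt(as.numeric(fsm))          # local x-stretch
  xmap_g <- cumsum(lam) * (xg[2] - xg[1])
  xmap_g <- xmap_g - approx(xg, xmap_g, xout = 0)$y  # anchor x' = 0 at x = 0
  map_pt <- function(P) {
    l <- approx(xg, lam, P[, 1], rule = 2)$y
    xp <- approx(xg, xmap_g, P[, 1], rule = 2)$y
    unname(cbind(xp, P[, 2] * l))
  }
  wet <- map_pt(dry)
  if (spec$noise_sd > 0)
    wet <- wet + matrix(rnorm(length(wet), 0, spec$noise_sd), ncol = 2)

  # reference landmark: upper-central, near the podium/cavity junction
  cen <- polygon_centroid(out)
  ref <- which.min((dry[, 1] - cen[1])^2 +
                     (dry[, 2] - max(dry[, 2]) * 0.95)^2)
  ids <- seq_len(nrow(dry))
  wet_outline <- map_pt(out)
  lm <- landmark_set(id = ids, dry = dry, wet = wet, reference_id = ids[ref],
                     outline_dry = out, outline_wet = wet_outline,
                     regions = layout$regions)
  list(landmarks = lm, truth = factors)
}

#' Specification of a synthetic AFM force curve
#'
#' @param E true effective Young's modulus (Pa).
#' @param contact contact height (m) on the approach axis.
#' @param spring_constant cantilever spring constant (N/m).
#' @param trigger_force trigger force (N).
#' @param baseline_offset,baseline_slope linear baseline added to the
#'   whole curve (N and N/m).
#' @param adhesion magnitude of the pull-off dip on the final
#'   retraction (N).
#' @param noise_sd relative multiplicative force noise SD.
#' @param z_range piezo ramp length (m).
#' @param n_points samples per segment.
#' @param alpha,nu Sneddon constants of the generating model.
#' @param region,sample labels carried to the curve.
#' @param seed integer seed.
#' @return object of class `curve_spec`.
#' @export
curve_spec <- function(E = 5e9, contact = 1.0e-6, spring_constant = 40,
                       trigger_force = 3e-6, baseline_offset = 2e-8,
                       baseline_slope = 5e-3, adhesion = 5e-8,
                       noise_sd = 0, z_range = 2e-6, n_points = 2000,
                       alpha = 18 * pi / 180, nu = 0.5,
                       region = NA_character_, sample = NA_character_,
                       seed = 1L) {
  if (E < 0) stop("E must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "curve_spec")
}

# elastic Sneddon response at piezo height h (approach convention):
# solves F = A * ((h - h0) - F/k)^2 on the contact side
sneddon_force <- function(h, h0, A, k) {
  u <- pmax(h - h0, 0)
  if (A <= 0) return(rep(0, length(h)))
  # quadratic in deflection d: A d^2 - (2Au + k) d + A u^2 = 0
  b <- 2 * A * u + k
  d <- (b - sqrt(pmax(b^2 - 4 * A^2 * u^2, 0))) / (2 * A)
  k * d
}

#' Generate a synthetic 7-segment AFM force curve
#'
#' Two extension-retraction cycles, a third extension, a constant-force
#' pause and a final retraction; the contact branch follows the Sneddon
#' conical-indenter law with the spec's modulus, a linear baseline is
#' added, the final retraction carries an adhesion dip just off contact,
#' and multiplicative Gaussian noise is applied. Pure function of the
#' spec including its seed.
#'
#' @param spec a [curve_spec()].
#' @return list: `curve` (a [force_curve()]) and `truth` (the spec).
#' @export
generate_force_curve <- function(spec = curve_spec()) {
  stopifnot(inherits(spec, "curve_spec"))
  set.seed(spec$seed)
  A <- sneddon_prefactor(spec$E, spec$alpha, spec$nu)
  k <- spec$spring_constant
  h0 <- spec$contact
  hmin <- h0 - spec$z_range
  # height at which the trigger force is reached (invert the response)
  hmax <- if (spec$E > 0) {
    FT <- spec$trigger_force
    h0 + sqrt(FT / A) + FT / k
  } else h0 + spec$z_range / 2
  ramp <- function(a, b) seq(a, b, length.out = spec$n_points)
  segs <- list(extend1 = ramp(hmin, hmax), retract1 = ramp(hmax, hmin),
               extend2 = ramp(hmin, hmax), retract2 = ramp(hmax, hmin),
               extend3 = ramp(hmin, hmax),
               pause = rep(hmax, spec$n_points %/% 4),
               retract_final = ramp(hmax, hmin))
  h <- unlist(segs, use.names = FALSE)
  lab <- rep(names(segs), vapply(segs, length, integer(1)))
  f <- sneddon_force(h, h0, A, k)
  # adhesion dip on the final retraction, just on the non-contact side
  if (spec$adhesion > 0) {
    sel <- lab == "retract_final"
    width <- 0.02 * spec$z_range
    centre <- h0 - 4 * width   # strictly on the non-contact side
    f[sel] <- f[sel] - spec$adhesion *
      exp(-(h[sel] - centre)^2 / (2 * width^2))
  }
  if (spec$noise_sd > 0)
    f <- f * (1 + rnorm(length(f), 0, spec$noise_sd))
  f <- f + spec$baseline_offset + spec$baseline_slope * h
  cv <- force_curve(h, f, lab, spring_constant = k,
                    trigger_force = spec$trigger_force,
                    region = spec$region, sample = spec$sample)
  list(curve = cv, truth = spec)
}

#' Sample correlated geometric parameters
#'
#' Multivariate-normal draws around the reference (Table-scale) means
#' with the requested coefficients of variation and correlation matrix,
#' truncated to valid geometries by resampling (which preserves the
#' correlation structure among accepted draws, at the cost of a small
#' documented bias at large CVs).
#'
#' @param n number of samples.
#' @param cov a [parameter_covariation()] over geometric parameter
#'   names.
#' @param means named vector of means (defaults to the reference
#'   geometry).
#' @param seed integer seed.
#' @param max_tries resampling budget multiplier.
#' @return data frame of `n` valid parameter rows.
#' @export
generate_geometry_sample <- function(n, cov = example_geometry_covariation(),
                                     means = unlist(unclass(geometry_params())),
                                     seed = 1L, max_tries = 50) {
  stopifnot(inherits(cov, "parameter_covariation"))
  set.seed(as.integer(seed))
  mu <- means[cov$parameters]
  if (anyNA(mu)) stop("means missing for some parameters", call. = FALSE)
  sig <- cov$cv * mu
  Sigma <- outer(sig, sig) * cov$corr
  ok_row <- function(x) {
    !inherits(tryCatch(do.call(geometry_params, as.list(x)),
                       error = function(e) e), "error")
  }
  got <- matrix(numeric(0), ncol = length(mu))
  tries <- 0
  while (nrow(got) < n && tries < max_tries) {
    m <- max(n - nrow(got), 16L)
    draw <- MASS::mvrnorm(m, mu = mu, Sigma = Sigma)
    if (m == 1) draw <- matrix(draw, nrow = 1)
    colnames(draw) <- names(mu)
    keep <- apply(draw, 1, function(x) all(x > 0) && ok_row(x))
    got <- rbind(got, draw[keep, , drop = FALSE])
    tries <- tries + 1
  }
  if (nrow(got) < n)
    stop("could not generate enough valid geometries; reduce the CVs",
         call. = FALSE)
  out <- as.data.frame(got[seq_len(n), , drop = FALSE])
  names(out) <- names(mu)
  out
}
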