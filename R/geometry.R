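# Parametric longitudinal-section geometry of the apical plate.
#
# Coordinate convention: origin at the intersection of the symmetry axis
# with the base of the plate, x radial, y up, lengths in micrometres. The
# canonical representation is the right half (x >= 0); the full domain is
# obtained by mirroring.
#
# Construction. The plate is an envelope of width D whose flat upper
# shoulder sits at height H - H_pod and is capped by the floral podium:
# the circular segment of radius R and sagitta H_pod whose apex reaches
# H. The central cavity is a trapezoid that widens upward from basal
# width D_cavity to the underside of the podium; the vasculature runs as
# straight bands of basal width W_vasc parallel to the cavity flanks,
# from the base up and outward to the side regions. The side regions
# (W_side x H_side) occupy the upper outer flanks where the pappus hairs
# attach, so the bands end against their inner corners, consistent with
# the vascular bundles supplying the hairs. The cortex forms the lower
# bulges outboard of the bands. The podium rests on the band tops over a
# seat of width W_vasc/2 at each end of its chord; at the measured
# reference values the chord end and the parallel-band top coincide to
# within a fraction of a micrometre, and the computed mechanics are
# insensitive to the seat width.

#' Geometry parameters of the hydrated apical plate
#'
#' The nine lengths (micrometres) that fully determine the 2D section
#' model of the hydrated (stress-free) apical plate, plus the prescribed
#' wet-to-dry displacement of the vascular base.
#'
#' @param D apical-plate diameter.
#' @param H apical-plate height (apex of the podium segment).
#' @param R radius of curvature of the floral podium.
#' @param H_pod height of the floral podium (sagitta of its circular
#'   segment).
#' @param H_side height of the side regions.
#' @param W_side width of the side regions.
#' @param W_vasc width of the vascular bands at the base.
#' @param D_cavity diameter of the central cavity at the base.
#' @param d_vasc prescribed inward displacement of the vascular base on
#'   dehydration.
#' @return object of class `geometry_params`.
#' @examples
#' geometry_params() # hydrated reference measurements
#' @export
geometry_params <- function(D = 491.0, H = 240.0, R = 363.0, H_pod = 38.8,
                            H_side = 91.4, W_side = 47.6, W_vasc = 34.3,
                            D_cavity = 74.8, d_vasc = 15.3) {
  p <- list(D = D, H = H, R = R, H_pod = H_pod, H_side = H_side,
            W_side = W_side, W_vasc = W_vasc, D_cavity = D_cavity,
            d_vasc = d_vasc)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid geometry: all parameters must be finite and strictly positive",
         call. = FALSE)
  if (p$D_cavity + 2 * p$W_vasc >= p$D)
    stop("invalid geometry: D_cavity + 2*W_vasc must be < D", call. = FALSE)
  if (p$H_pod + p$H_side >= p$H)
    stop("invalid geometry: H_pod + H_side must be < H", call. = FALSE)
  if (p$d_vasc >= p$D / 2)
    stop("invalid geometry: d_vasc must be < D/2", call. = FALSE)
  if (p$H_pod >= 2 * p$R)
    stop("invalid geometry: podium sagitta H_pod must be < 2*R", call. = FALSE)
  xc <- chord_halfwidth(p)
  if (xc >= p$D / 2 - p$W_side)
    stop("invalid geometry: the podium chord sqrt(H_pod*(2R - H_pod)) must ",
         "end inboard of the side region (D/2 - W_side)", call. = FALSE)
  if (xc - p$W_vasc / 2 <= p$D_cavity / 2)
    stop("invalid geometry: the cavity roof (podium chord minus the band ",
         "seat) must lie outboard of the cavity base", call. = FALSE)
  structure(p, class = "geometry_params")
}

# half-width of the podium chord at y = H - H_pod
chord_halfwidth <- function(p) sqrt(p$H_pod * (2 * p$R - p$H_pod))

#' @export
print.geometry_params <- function(x, ...) {
  cat("Apical-plate geometry (um):\n")
  print(unlist(x))
  invisible(x)
}

#' Describe a geometric perturbation of the reference section
#'
#' `fill_cavity_horizontal` and `fill_cavity_vertical` replace cavity
#' space with cortex material, shrinking the cavity toward the symmetry
#' axis (horizontal, magnitude in micrometres of basal half-width
#' removed) or toward the base (vertical, micrometres of roof height
#' removed). `trim_corner_vertical` removes cortex from below the lower
#' bulges, raising the base of the cortex outboard of the vasculature by
#' the magnitude. `move_corner_horizontal` moves the lower outer corners
#' radially (signed; positive adds cortex material).
#'
#' @param kind one of `"fill_cavity_horizontal"`, `"fill_cavity_vertical"`,
#'   `"trim_corner_vertical"`, `"move_corner_horizontal"`.
#' @param magnitude perturbation magnitude in micrometres.
#' @return object of class `geometry_perturbation`.
#' @export
geometry_perturbation <- function(kind = c("fill_cavity_horizontal",
                                           "fill_cavity_vertical",
                                           "trim_corner_vertical",
                                           "move_corner_horizontal"),
                                  magnitude) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L, is.finite(magnitude))
  structure(list(kind = kind, magnitude = magnitude),
            class = "geometry_perturbation")
}

#' Admissible magnitude range of a perturbation kind
#'
#' @param params a [geometry_params()] object.
#' @param kind perturbation kind (see [geometry_perturbation()]).
#' @return numeric length-2 vector, the closed admissible interval (um).
#' @export
perturbation_range <- function(params, kind) {
  p <- params
  ytop <- p$H - p$H_pod
  switch(kind,
    fill_cavity_horizontal = c(0, p$D_cavity / 2),
    fill_cavity_vertical   = c(0, ytop),
    trim_corner_vertical   = c(0, ytop - p$H_side - 1e-6),
    move_corner_horizontal = c(-(p$D / 2 - p$D_cavity / 2 - p$W_vasc) + 1e-6,
                               p$D / 2)
  )
}

#' Build the hydrated reference section of the apical plate
#'
#' Constructs the four-region planar domain (right half, mirror-symmetric
#' about x = 0) from the geometry parameters. The podium arc is
#' polygonized at resolution `arc_seg`.
#'
#' @param params a [geometry_params()] object.
#' @param arc_seg approximate chord length (um) used to polygonize the
#'   podium arc.
#' @return object of class `planar_domain` with half-domain region
#'   polygons (`$regions`, each a list of vertex matrices), the cavity
#'   polygon (`$cavity`, `NULL` when degenerate), the half outline
#'   (`$outline`) and the holding-angle landmark points
#'   (`$theta_landmarks`).
#' @examples
#' dom <- build_reference_geometry(geometry_params())
#' range(dom$outline[, 1]) # 0 .. D/2
#' @export
build_reference_geometry <- function(params, arc_seg = 2) {
  build_domain(params, perturbation = NULL, arc_seg = arc_seg)
}

#' Apply a geometric perturbation to the reference section
#'
#' @param params a [geometry_params()] object.
#' @param p a [geometry_perturbation()] object.
#' @param arc_seg arc polygonization resolution (um).
#' @return a perturbed `planar_domain`.
#' @export
apply_geometry_perturbation <- function(params, p, arc_seg = 2) {
  stopifnot(inherits(p, "geometry_perturbation"))
  rng <- perturbation_range(params, p$kind)
  if (p$magnitude < rng[1] || p$magnitude > rng[2])
    stop(sprintf("perturbation magnitude %.3g outside admissible range [%.3g, %.3g] for %s",
                 p$magnitude, rng[1], rng[2], p$kind), call. = FALSE)
  build_domain(params, perturbation = p, arc_seg = arc_seg)
}

rev_rows <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

clean_poly <- function(poly) {
  keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-9)
  poly <- poly[keep, , drop = FALSE]
  n <- nrow(poly)
  if (n > 1 && sum(abs(poly[1, ] - poly[n, ])) < 1e-9)
    poly <- poly[-n, , drop = FALSE]
  poly
}

# Shared constructor: builds all half-domain polygons, applying the
# optional perturbation consistently to regions, cavity and outline.
build_domain <- function(params, perturbation = NULL, arc_seg = 2) {
  stopifnot(inherits(params, "geometry_params"))
  p <- params
  D <- p$D; H <- p$H; R <- p$R
  ytop <- H - p$H_pod             # shoulder height / podium chord level
  xc <- chord_halfwidth(p)        # podium chord half-width
  xcav <- p$D_cavity / 2          # cavity basal half-width
  xvout <- xcav + p$W_vasc        # outer edge of vasculature at the base
  xs <- D / 2 - p$W_side          # inner edge of the side region
  xb <- xc - p$W_vasc / 2         # end of the cavity roof (podium seat)
  ysb <- ytop - p$H_side          # bottom of the side region

  # podium arc from (xc, ytop) up to the apex (0, H); circle centre (0, H - R)
  tmax <- asin(min(1, xc / R))
  nt <- max(8L, ceiling(R * tmax / arc_seg))
  tt <- seq(tmax, 0, length.out = nt + 1L)
  arc <- cbind(R * sin(tt), (H - R) + R * cos(tt))

  podium <- clean_poly(rbind(c(0, ytop), c(xc, ytop), arc[-1, , drop = FALSE]))
  side <- rbind(c(xs, ysb), c(D / 2, ysb), c(D / 2, ytop), c(xs, ytop))
  vasc <- rbind(c(xcav, 0), c(xvout, 0), c(xs, ytop), c(xb, ytop))

  # defaults, possibly modified by the perturbation
  cavity <- rbind(c(0, 0), c(xcav, 0), c(xb, ytop), c(0, ytop))
  cortex_extra <- list()
  corner_pts <- rbind(c(D / 2, 0))  # path replacing the lower outer corner
  base_start <- c(xvout, 0)         # where the cortex base begins
  trim_pts <- NULL                  # extra outline vertex for the trim cut

  kind <- if (is.null(perturbation)) "none" else perturbation$kind
  m <- if (is.null(perturbation)) 0 else perturbation$magnitude

  # path along the unperturbed cavity boundary: base corner -> flank ->
  # roof -> axis top
  cav_path <- cavity[-1, , drop = FALSE]
  if (kind == "fill_cavity_horizontal" && m > 0) {
    f <- (xcav - m) / xcav
    if (f <= 1e-9) {
      cortex_extra <- list(clean_poly(cavity))
      cavity <- NULL
    } else {
      new_path <- cbind(cav_path[, 1] * f, cav_path[, 2])
      cortex_extra <- list(clean_poly(rbind(cav_path, rev_rows(new_path))))
      cavity <- clean_poly(rbind(c(0, 0), new_path))
    }
  } else if (kind == "fill_cavity_vertical" && m > 0) {
    f <- (ytop - m) / ytop
    if (f <= 1e-9) {
      cortex_extra <- list(clean_poly(cavity))
      cavity <- NULL
    } else {
      new_path <- cbind(cav_path[, 1], cav_path[, 2] * f)
      cortex_extra <- list(clean_poly(rbind(cav_path, rev_rows(new_path))))
      cavity <- clean_poly(rbind(c(0, 0), new_path))
    }
  } else if (kind == "trim_corner_vertical" && m > 0) {
    # raise the cortex base outboard of the vasculature to height m; the
    # cut follows the slanted outer edge of the vascular band
    tfrac <- m / ytop
    xm <- xvout + (xs - xvout) * tfrac
    base_start <- c(xm, m)
    corner_pts <- rbind(c(D / 2, m))
    trim_pts <- c(xvout, 0)
  } else if (kind == "move_corner_horizontal" && m != 0) {
    corner_pts <- rbind(c(D / 2 + m, 0))
  }

  cortex_main <- clean_poly(rbind(base_start, corner_pts, c(D / 2, ysb),
                                  c(xs, ysb), c(xs, ytop)))
  regions <- list(podium = list(podium),
                  vasculature = list(vasc),
                  side = list(side),
                  cortex = c(list(cortex_main), cortex_extra))

  # half outline: base, corner path, rim, shoulder, podium arc, axis,
  # cavity roof + flank back to the base
  hole_path <- if (is.null(cavity)) rbind(c(0, 0)) else
    rev_rows(cavity[-1, , drop = FALSE])
  outline <- clean_poly(rbind(
    if (is.null(trim_pts)) NULL else rbind(trim_pts),
    base_start, corner_pts, c(D / 2, ysb), c(D / 2, ytop), c(xc, ytop),
    arc[-1, , drop = FALSE], c(0, ytop), hole_path))

  structure(list(params = params, perturbation = perturbation,
                 regions = regions, cavity = cavity, outline = outline,
                 ytop = ytop, chord_halfwidth = xc,
                 theta_landmarks = rbind(upper = c(D / 2, ytop),
                                         lower = c(D / 2, ysb))),
            class = "planar_domain")
}

#' Region areas of a planar domain
#'
#' Shoelace areas of the region polygons. Half-domain areas are doubled
#' so the result refers to the full mirror-symmetric section.
#'
#' @param domain a `planar_domain`.
#' @return named numeric vector (um^2) with one entry per region plus
#'   `cavity`.
#' @export
domain_region_areas <- function(domain) {
  a <- vapply(domain$regions, function(polys)
    sum(vapply(polys, polygon_area, numeric(1))), numeric(1))
  cav <- if (is.null(domain$cavity)) 0 else polygon_area(domain$cavity)
  2 * c(a, cavity = cav)
}

#' @export
print.planar_domain <- function(x, ...) {
  cat("Apical-plate planar domain (right half, um)\n")
  if (!is.null(x$perturbation))
    cat(sprintf("  perturbation: %s (%.3g um)\n",
                x$perturbation$kind, x$perturbation$magnitude))
  a <- domain_region_areas(x)
  cat("  full-section region areas (um^2):\n")
  print(round(a, 1))
  invisible(x)
}

#' @export
plot.planar_domain <- function(x, full = TRUE, cols = NULL, ...) {
  polys <- x$regions
  if (is.null(cols))
    cols <- c(podium = "#4477AA", vasculature = "#CCBB44",
              side = "#228833", cortex = "#EE7733")
  xl <- if (full) c(-x$params$D / 2, x$params$D / 2) else c(0, x$params$D / 2)
  plot(NA, xlim = xl, ylim = c(0, x$params$H), asp = 1,
       xlab = "x (um)", ylab = "y (um)", ...)
  for (nm in names(polys)) for (p in polys[[nm]]) {
    polygon(p[, 1], p[, 2], col = cols[[nm]], border = "grey30")
    if (full) polygon(-p[, 1], p[, 2], col = cols[[nm]], border = "grey30")
  }
  invisible(x)
}
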