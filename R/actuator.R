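# Dry-state post-processing: holding angle, regional area changes, and
# the displacement field relative to the centre of the floral podium.

#' Build the dry actuator state from a solved dehydration problem
#'
#' @param problem a [swelling_problem()].
#' @param field the `displacement_field` returned by
#'   [solve_dehydration()] for that problem.
#' @return object of class `actuator_state`: `$dry_nodes`, `$theta`
#'   (degrees), `$area_change` (per-region dry/wet ratio and wet/dry
#'   expansion), `$rel_displacement` (nodal displacement relative to the
#'   podium-centre reference point), plus the mesh and problem.
#' @export
actuator_state <- function(problem, field) {
  mesh <- problem$mesh
  U <- unclass(field)
  dry <- mesh$nodes + U

  # reference point: node closest to the centre of the floral podium
  pod <- mesh$domain$regions$podium[[1]]
  cen <- polygon_centroid(pod)
  cen[1] <- 0 # mirror symmetry: the podium centre sits on the axis
  ref <- which.min((mesh$nodes[, 1] - cen[1])^2 + (mesh$nodes[, 2] - cen[2])^2)
  rel <- sweep(U, 2, U[ref, ])

  st <- structure(list(dry_nodes = dry, mesh = mesh, problem = problem,
                       displacement = U, rel_displacement = rel,
                       ref_node = ref,
                       area_change = regional_area_change(mesh, field)),
                  class = "actuator_state")
  st$theta <- compute_holding_angle(st, mesh$domain)
  st
}

#' Holding angle of the dry configuration
#'
#' The angle between the vertical and the line from the upper corner of
#' the apical plate to the lowest point of the side region's lateral
#' edge, both identified on the wet domain and advected to the dry
#' state; positive when the line tilts outward from the vertical.
#'
#' @param state an `actuator_state` (or a list with `$mesh` and
#'   `$dry_nodes`).
#' @param domain the `planar_domain` carrying the landmark points
#'   (defaults to the mesh's domain).
#' @return theta in degrees.
#' @export
compute_holding_angle <- function(state, domain = state$mesh$domain) {
  lm <- domain$theta_landmarks
  nd <- state$mesh$nodes
  up <- which.min((nd[, 1] - lm["upper", 1])^2 + (nd[, 2] - lm["upper", 2])^2)
  lo <- which.min((nd[, 1] - lm["lower", 1])^2 + (nd[, 2] - lm["lower", 2])^2)
  v <- state$dry_nodes[up, ] - state$dry_nodes[lo, ]
  if (sqrt(sum(v^2)) < 1e-9)
    stop("degenerate angle: landmark points coincide in the dry state",
         call. = FALSE)
  unname(atan2(v[1], v[2]) * 180 / pi)
}

#' Regional area change between wet and dry configurations
#'
#' @param mesh a `tri_mesh`.
#' @param field a `displacement_field` on that mesh.
#' @return data frame per region: `dry_wet` (summed dry area / summed
#'   wet area) and `wet_dry` (its reciprocal, the expansion convention
#'   used for the measured targets).
#' @export
regional_area_change <- function(mesh, field) {
  wet <- tri_signed_areas(mesh$nodes, mesh$triangles)
  dry <- tri_signed_areas(mesh$nodes + unclass(field), mesh$triangles)
  aw <- tapply(wet, mesh$region, sum, default = NA_real_)
  ad <- tapply(dry, mesh$region, sum, default = NA_real_)
  r <- as.numeric(ad / aw)
  data.frame(region = names(aw), dry_wet = r, wet_dry = 1 / r,
             row.names = NULL)
}

#' Build, solve and post-process an actuator model in one call
#'
#' Convenience wrapper: constructs the (optionally perturbed) geometry,
#' meshes it, solves the dehydration problem and returns the dry state.
#'
#' @param geometry a [geometry_params()] object.
#' @param materials a [material_params()] object.
#' @param target_edge mesh resolution (um).
#' @param half_model solve on the half section with symmetry conditions?
#' @param perturbation optional [geometry_perturbation()].
#' @param domain optional pre-built `planar_domain` (overrides
#'   `geometry`/`perturbation`).
#' @return an `actuator_state`.
#' @examples
#' \donttest{
#' st <- solve_actuator(target_edge = 8)
#' st$theta
#' }
#' @export
solve_actuator <- function(geometry = geometry_params(),
                           materials = material_params(),
                           target_edge = 4, half_model = TRUE,
                           perturbation = NULL, domain = NULL) {
  if (is.null(domain)) {
    domain <- if (is.null(perturbation)) build_reference_geometry(geometry)
    else apply_geometry_perturbation(geometry, perturbation)
  }
  mesh <- mesh_domain(domain, target_edge = target_edge,
                      half_model = half_model)
  pr <- swelling_problem(mesh, materials)
  actuator_state(pr, solve_dehydration(pr))
}

#' @export
print.actuator_state <- function(x, ...) {
  cat(sprintf("Actuator dry state: holding angle theta = %.2f deg\n", x$theta))
  cat("Regional area changes:\n")
  print(transform(x$area_change,
                  dry_wet = round(dry_wet, 3), wet_dry = round(wet_dry, 3)))
  invisible(x)
}

#' @export
plot.actuator_state <- function(x, what = c("dry", "wet"), ...) {
  what <- match.arg(what)
  nd <- if (what == "dry") x$dry_nodes else x$mesh$nodes
  cols <- c(podium = "#4477AA", vasculature = "#CCBB44",
            side = "#228833", cortex = "#EE7733")
  plot(NA, xlim = range(nd[, 1]), ylim = range(nd[, 2]), asp = 1,
       xlab = "x (um)", ylab = "y (um)", ...)
  for (i in seq_len(nrow(x$mesh$triangles))) {
    v <- x$mesh$triangles[i, ]
    polygon(nd[v, 1], nd[v, 2],
            col = cols[[as.character(x$mesh$region[i])]],
            border = NA)
  }
  invisible(x)
}

#' Write the dry-state summary of an actuator solve
#'
#' Exports the per-node displacement table, the per-element stress table
#' and a JSON record with theta and the regional area changes.
#'
#' @param state an `actuator_state`.
#' @param stem output path stem.
#' @return invisibly, the file paths written.
#' @export
write_actuator_result <- function(state, stem) {
  fdisp <- paste0(stem, "_displacement.csv")
  fstress <- paste0(stem, "_stress.csv")
  fjson <- paste0(stem, "_result.json")
  write.csv(data.frame(node = seq_len(nrow(state$mesh$nodes)),
                       x_wet = state$mesh$nodes[, 1],
                       y_wet = state$mesh$nodes[, 2],
                       ux = state$displacement[, 1],
                       uy = state$displacement[, 2]),
            fdisp, row.names = FALSE)
  write.csv(compute_stress(state$problem, state$displacement),
            fstress, row.names = FALSE)
  rec <- list(theta_deg = state$theta,
              area_change = state$area_change)
  jsonlite::write_json(rec, fjson, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(fdisp, fstress, fjson))
}
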