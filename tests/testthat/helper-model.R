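# Shared fixtures. Reference solves at coarse resolution are cached so
# the suite meshes and factorizes each configuration only once.

.cache <- new.env(parent = emptyenv())

ref_domain <- function() {
  if (is.null(.cache$dom))
    .cache$dom <- build_reference_geometry(geometry_params())
  .cache$dom
}

ref_mesh <- function(h = 8) {
  key <- paste0("mesh", h)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- mesh_domain(ref_domain(), target_edge = h)
  .cache[[key]]
}

ref_state <- function(h = 8) {
  key <- paste0("state", h)
  if (is.null(.cache[[key]])) {
    pr <- swelling_problem(ref_mesh(h), material_params())
    .cache[[key]] <- actuator_state(pr, solve_dehydration(pr))
  }
  .cache[[key]]
}

# solve a substitution scenario on the cached mesh
scenario_theta <- function(mapping, h = 8) {
  mat <- substitute_materials(material_params(), mapping)
  pr <- swelling_problem(ref_mesh(h), mat)
  st <- actuator_state(pr, suppressWarnings(solve_dehydration(pr)))
  st$theta
}

# structured rectangular test mesh (single- or two-region) built from
# the package's own Delaunay kernel
rect_mesh <- function(width = 60, height = 120, h = 10,
                      region_of = function(x, y) "cortex", seed = 1) {
  xs <- seq(0, width, by = h)
  ys <- seq(0, height, by = h)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  set.seed(seed)
  interior <- g[, 1] > 0 & g[, 1] < width & g[, 2] > 0 & g[, 2] < height
  g <- g + matrix(runif(length(g), -0.2 * h, 0.2 * h), ncol = 2) *
    as.numeric(interior)
  tri <- delaunay(g)
  cen <- cbind((g[tri[, 1], 1] + g[tri[, 2], 1] + g[tri[, 3], 1]) / 3,
               (g[tri[, 1], 2] + g[tri[, 2], 2] + g[tri[, 3], 2]) / 3)
  reg <- mapply(region_of, cen[, 1], cen[, 2])
  structure(list(nodes = g, triangles = tri,
                 region = factor(reg, levels = c("podium", "vasculature",
                                                 "side", "cortex")),
                 node_sets = list(vasc_base = integer(0), axis = integer(0),
                                  boundary = integer(0)),
                 target_edge = h, half_model = TRUE, domain = NULL),
            class = "tri_mesh")
}

# minimal pin that removes rigid-body modes without constraining strain:
# fix one corner fully and the vertical displacement of another
minimal_pins <- function(mesh) {
  n1 <- which.min(rowSums(mesh$nodes^2))
  n2 <- which.min((mesh$nodes[, 1] - max(mesh$nodes[, 1]))^2 + mesh$nodes[, 2]^2)
  rbind(data.frame(node = n1, dof = "x", value = 0),
        data.frame(node = n1, dof = "y", value = 0),
        data.frame(node = n2, dof = "y", value = 0))
}
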