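# Conforming triangular meshing of the planar domain.
#
# Strategy: all region-polygon edges (the planar straight-line graph of
# the section) are subdivided at the target edge length; interior nodes
# are laid out region-by-region on a hexagonal grid with a small
# deterministic jitter (which breaks the exact cocircularity of regular
# point lattices); the combined point set is Delaunay-triangulated and
# each triangle is assigned to the region containing its centroid.
# Because boundary chains are sampled at least as densely as the
# interior, the Delaunay triangulation recovers the straight region
# boundaries and the classification yields a conforming, tagged mesh.

round_key <- function(x, y) paste(round(x, 6), round(y, 6))

# deterministic pseudo-random in [0,1) from lattice indices
lattice_hash <- function(i, j) {
  v <- sin(i * 12.9898 + j * 78.233) * 43758.5453
  v - floor(v)
}

subdivide_edges <- function(polys, h) {
  seen <- new.env(hash = TRUE)
  pts <- list()
  for (poly in polys) {
    n <- nrow(poly)
    j <- n
    for (i in seq_len(n)) {
      a <- poly[j, ]; b <- poly[i, ]
      key <- paste(sort(c(round_key(a[1], a[2]), round_key(b[1], b[2]))),
                   collapse = "|")
      j <- i
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      L <- sqrt(sum((b - a)^2))
      if (L < 1e-9) next
      k <- max(1L, ceiling(L / h))
      t <- seq(0, 1, length.out = k + 1L)
      pts[[length(pts) + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                                       a[2] + t * (b[2] - a[2]))
    }
  }
  do.call(rbind, pts)
}

interior_points <- function(poly, h, clearance = 0.55) {
  bb <- apply(poly, 2, range)
  dy <- h * sqrt(3) / 2
  ys <- seq(bb[1, 2] + dy / 2, bb[2, 2], by = dy)
  if (length(ys) == 0) return(NULL)
  out <- list()
  for (r in seq_along(ys)) {
    off <- if (r %% 2 == 0) h / 2 else 0
    xs <- seq(bb[1, 1] + h / 2 + off, bb[2, 1], by = h)
    if (length(xs) == 0) next
    ii <- seq_along(xs)
    jx <- 0.24 * h * (lattice_hash(ii, r) - 0.5)
    jy <- 0.24 * h * (lattice_hash(ii + 1000, r) - 0.5)
    out[[r]] <- cbind(xs + jx, ys[r] + jy)
  }
  p <- do.call(rbind, out)
  keep <- point_in_polygon(p[, 1], p[, 2], poly) &
    dist_to_polygon(p[, 1], p[, 2], poly) >= clearance * h
  p[keep, , drop = FALSE]
}

#' Mesh a planar apical-plate domain
#'
#' Produces a conforming triangular mesh with per-triangle region tags
#' and marked node sets for the vascular base, the symmetry axis and the
#' free surface.
#'
#' @param domain a `planar_domain` from [build_reference_geometry()] or
#'   [apply_geometry_perturbation()].
#' @param target_edge target element edge length (um); must be positive.
#'   The default 4 um (about W_vasc/8) keeps the holding angle converged
#'   to well under 0.2 degrees relative to further refinement.
#' @param half_model mesh only the right half with the symmetry axis
#'   marked (the default solve configuration) or the mirrored full
#'   section.
#' @return object of class `tri_mesh`: `$nodes` (n x 2, um), `$triangles`
#'   (m x 3 indices, CCW), `$region` (factor per triangle), `$node_sets`
#'   (list: `vasc_base`, `axis`, `boundary`), `$target_edge`,
#'   `$half_model`.
#' @export
mesh_domain <- function(domain, target_edge = 4, half_model = TRUE) {
  stopifnot(inherits(domain, "planar_domain"))
  if (!is.numeric(target_edge) || target_edge <= 0)
    stop("target_edge must be positive")
  h <- target_edge

  all_polys <- unlist(domain$regions, recursive = FALSE)
  bpts <- subdivide_edges(all_polys, h)
  ipts <- do.call(rbind, lapply(all_polys, interior_points, h = h))
  pts <- rbind(bpts, ipts)

  # deduplicate (shared edges contribute their nodes twice)
  key <- round_key(pts[, 1], pts[, 2])
  pts <- pts[!duplicated(key), , drop = FALSE]
  # snap near-zero coordinates so the axis is exact
  pts[abs(pts[, 1]) < 1e-7, 1] <- 0
  pts[abs(pts[, 2]) < 1e-7, 2] <- 0

  tri <- delaunay(pts)
  cen <- cbind((pts[tri[, 1], 1] + pts[tri[, 2], 1] + pts[tri[, 3], 1]) / 3,
               (pts[tri[, 1], 2] + pts[tri[, 2], 2] + pts[tri[, 3], 2]) / 3)

  lab <- rep(NA_character_, nrow(tri))
  for (nm in c("podium", "vasculature", "side")) {
    for (poly in domain$regions[[nm]]) {
      hit <- is.na(lab) & point_in_polygon(cen[, 1], cen[, 2], poly)
      lab[hit] <- nm
    }
  }
  in_out <- point_in_polygon(cen[, 1], cen[, 2], domain$outline)
  in_cav <- if (is.null(domain$cavity)) rep(FALSE, nrow(tri)) else
    point_in_polygon(cen[, 1], cen[, 2], domain$cavity)
  lab[is.na(lab) & in_out & !in_cav] <- "cortex"
  keep <- !is.na(lab)
  tri <- tri[keep, , drop = FALSE]
  lab <- lab[keep]

  # drop nodes not referenced by any kept triangle
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(pts)); remap[used] <- seq_along(used)
  nodes <- pts[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)

  if (!half_model) {
    mir <- nodes[, 1] > 1e-9
    n0 <- nrow(nodes)
    map_m <- integer(n0)
    map_m[!mir] <- which(!mir)
    map_m[mir] <- n0 + seq_len(sum(mir))
    nodes <- rbind(nodes, cbind(-nodes[mir, 1], nodes[mir, 2]))
    tri_m <- cbind(map_m[tri[, 1]], map_m[tri[, 3]], map_m[tri[, 2]])
    tri <- rbind(tri, tri_m)
    lab <- c(lab, lab)
  }

  a <- tri_signed_areas(nodes, tri)
  bad <- a <= 0
  if (any(bad)) {
    tri <- tri[!bad, , drop = FALSE]  # drop exact slivers (area ~ 0)
    lab <- lab[!bad]
  }

  # boundary = edges used exactly once
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  single <- names(which(table(ekey) == 1L))
  bnodes <- sort(unique(as.vector(e[ekey %in% single, , drop = FALSE])))

  p <- domain$params
  xcav <- p$D_cavity / 2
  vb <- which(abs(nodes[, 2]) < 1e-6 &
                abs(nodes[, 1]) >= xcav - 1e-6 &
                abs(nodes[, 1]) <= xcav + p$W_vasc + 1e-6)
  ax <- which(abs(nodes[, 1]) < 1e-6)

  structure(list(nodes = nodes, triangles = tri,
                 region = factor(lab, levels = c("podium", "vasculature",
                                                 "side", "cortex")),
                 node_sets = list(vasc_base = vb, axis = ax,
                                  boundary = bnodes),
                 target_edge = h, half_model = half_model,
                 domain = domain),
            class = "tri_mesh")
}

tri_signed_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Per-region mesh areas
#'
#' @param mesh a `tri_mesh`.
#' @return named numeric vector of summed triangle areas per region
#'   (um^2), on the meshed half or full section as built.
#' @export
mesh_region_areas <- function(mesh) {
  a <- tri_signed_areas(mesh$nodes, mesh$triangles)
  tapply(a, mesh$region, sum, default = 0)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d nodes, %d triangles (%s model, target edge %.2g um)\n",
              nrow(x$nodes), nrow(x$triangles),
              if (x$half_model) "half" else "full", x$target_edge))
  print(round(mesh_region_areas(x), 1))
  invisible(x)
}

#' @export
plot.tri_mesh <- function(x, cols = NULL, ...) {
  if (is.null(cols))
    cols <- c(podium = "#4477AA", vasculature = "#CCBB44",
              side = "#228833", cortex = "#EE7733")
  plot(NA, xlim = range(x$nodes[, 1]), ylim = range(x$nodes[, 2]), asp = 1,
       xlab = "x (um)", ylab = "y (um)", ...)
  for (i in seq_len(nrow(x$triangles))) {
    v <- x$triangles[i, ]
    polygon(x$nodes[v, 1], x$nodes[v, 2],
            col = cols[[as.character(x$region[i])]], border = "grey60",
            lwd = 0.3)
  }
  invisible(x)
}

#' Export a mesh as plain-text node/element tables
#'
#' Writes `<stem>_nodes.csv` (node, x, y) and `<stem>_elements.csv`
#' (element, n1, n2, n3, region), a minimal unstructured-mesh
#' interchange that any mesh tool can ingest.
#'
#' @param mesh a `tri_mesh`.
#' @param stem output path stem.
#' @return invisibly, the two file paths.
#' @export
write_mesh <- function(mesh, stem) {
  fn <- paste0(stem, "_nodes.csv")
  fe <- paste0(stem, "_elements.csv")
  write.csv(data.frame(node = seq_len(nrow(mesh$nodes)),
                       x = mesh$nodes[, 1], y = mesh$nodes[, 2]),
            fn, row.names = FALSE)
  write.csv(data.frame(element = seq_len(nrow(mesh$triangles)),
                       n1 = mesh$triangles[, 1], n2 = mesh$triangles[, 2],
                       n3 = mesh$triangles[, 3],
                       region = as.character(mesh$region)),
            fe, row.names = FALSE)
  invisible(c(fn, fe))
}
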