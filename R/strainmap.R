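# Landmark-based quantification of tissue deformation between paired
# dry and wet images: relative displacement, Delaunay area-change maps
# with neighbour smoothing, principal strain directions, region
# assignment by polygon overlap, and shape circularity.

#' Paired dry/wet landmark set
#'
#' @param id landmark identifiers (unique).
#' @param dry,wet n x 2 coordinate matrices, paired row-by-row with `id`.
#' @param reference_id id of the reference landmark (near the centre, at
#'   the junction between floral podium and central cavity).
#' @param outline_dry simple polygon enclosing the dry sample.
#' @param outline_wet optional wet outline (not used by the mapping
#'   itself, carried for plotting).
#' @param regions named list of simple convex polygons on the dry image
#'   (podium, vasculature, side, cavity as available); triangles not
#'   assigned to any of these become cortex.
#' @param pixel_size scalar, micrometres per input unit; coordinates are
#'   stored in micrometres.
#' @param y_down set to `TRUE` for image pixel coordinates with the y
#'   axis pointing down; they are flipped to the internal y-up
#'   convention.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(id, dry, wet, reference_id, outline_dry,
                         outline_wet = NULL, regions = list(),
                         pixel_size = 1, y_down = FALSE) {
  dry <- as.matrix(dry); wet <- as.matrix(wet)
  if (anyDuplicated(id)) stop("landmark ids must be unique", call. = FALSE)
  if (nrow(dry) != length(id) || nrow(wet) != length(id))
    stop("validation error: unpaired landmarks - dry/wet rows must match ids",
         call. = FALSE)
  if (!reference_id %in% id)
    stop("reference landmark id not present", call. = FALSE)
  tf <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m) * pixel_size
    if (y_down) m[, 2] <- -m[, 2]
    m
  }
  structure(list(id = id, dry = tf(dry), wet = tf(wet),
                 reference_id = reference_id,
                 outline_dry = tf(outline_dry), outline_wet = tf(outline_wet),
                 regions = lapply(regions, tf)),
            class = "landmark_set")
}

#' Landmark displacement relative to the reference landmark
#'
#' Wet-minus-dry displacement of each landmark, minus that of the
#' reference landmark (whose own relative displacement is therefore the
#' zero vector).
#'
#' @param lm a [landmark_set()].
#' @return n x 2 matrix of relative displacements (um), rownames = ids.
#' @export
relative_displacement <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  u <- lm$wet - lm$dry
  ref <- which(lm$id == lm$reference_id)
  u <- sweep(u, 2, u[ref, ])
  rownames(u) <- lm$id
  colnames(u) <- c("ux", "uy")
  u
}

#' Delaunay triangulation of the dry landmarks
#'
#' Builds the Delaunay triangulation on the dry positions and excludes
#' triangles that are not fully enclosed by the dry outline.
#'
#' @param lm a [landmark_set()].
#' @return object of class `strain_map`: a data frame with one row per
#'   triangle (`v1`, `v2`, `v3` as row indices into the landmark set,
#'   `included`, `reason`) plus the landmark set as an attribute.
#' @export
triangulate_dry <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  tri <- delaunay(lm$dry)
  inc <- rep(TRUE, nrow(tri))
  reason <- rep(NA_character_, nrow(tri))
  if (!is.null(lm$outline_dry)) {
    for (i in seq_len(nrow(tri))) {
      if (!triangle_in_polygon(lm$dry[tri[i, ], , drop = FALSE],
                               lm$outline_dry)) {
        inc[i] <- FALSE
        reason[i] <- "outside-outline"
      }
    }
  }
  out <- data.frame(v1 = tri[, 1], v2 = tri[, 2], v3 = tri[, 3],
                    included = inc, reason = reason)
  attr(out, "landmarks") <- lm
  class(out) <- c("strain_map", class(out))
  out
}

tri_coords <- function(map, lm, which = c("dry", "wet")) {
  which <- match.arg(which)
  xy <- lm[[which]]
  idx <- as.matrix(map[, c("v1", "v2", "v3")])
  list(x = matrix(xy[idx, 1], ncol = 3), y = matrix(xy[idx, 2], ncol = 3))
}

signed_area_cols <- function(cx, cy) {
  ((cx[, 2] - cx[, 1]) * (cy[, 3] - cy[, 1]) -
     (cx[, 3] - cx[, 1]) * (cy[, 2] - cy[, 1])) / 2
}

#' Per-triangle area change (wet area / dry area)
#'
#' Computes the raw area ratio of every included triangle and flags as
#' invalid those whose wet image inverts its orientation or overlaps the
#' interior of another wet triangle (physically impossible for a
#' connected cellular structure; such triangles are omitted from the
#' analysis).
#'
#' @param map a `strain_map` from [triangulate_dry()].
#' @param overlap_tol fraction of a triangle's own wet area above which
#'   an intersection with another wet triangle counts as overlap.
#' @return the map with columns `ratio`, `valid`, `reason` filled.
#' @export
area_change <- function(map, overlap_tol = 1e-6) {
  lm <- attr(map, "landmarks")
  d <- tri_coords(map, lm, "dry")
  w <- tri_coords(map, lm, "wet")
  a_dry <- signed_area_cols(d$x, d$y)
  a_wet <- signed_area_cols(w$x, w$y)
  ratio <- ifelse(abs(a_dry) > 1e-12, a_wet / a_dry, NA_real_)
  valid <- map$included
  reason <- map$reason
  deg <- valid & (!is.finite(ratio) | abs(a_dry) <= 1e-12)
  reason[deg] <- "degenerate-dry"
  valid[deg] <- FALSE
  inv <- valid & ratio <= 0
  reason[inv] <- "wet-overlap"   # inversion implies overlap in a connected sheet
  valid[inv] <- FALSE

  # pairwise overlap among remaining wet images (bbox prefilter)
  cand <- which(valid)
  if (length(cand) > 1) {
    bx1 <- apply(w$x, 1, min); bx2 <- apply(w$x, 1, max)
    by1 <- apply(w$y, 1, min); by2 <- apply(w$y, 1, max)
    polys <- lapply(seq_len(nrow(map)), function(i)
      cbind(w$x[i, ], w$y[i, ]))
    bad <- logical(nrow(map))
    for (ii in seq_along(cand)) {
      i <- cand[ii]
      for (jj in seq_len(ii - 1L)) {
        j <- cand[jj]
        if (bx1[i] > bx2[j] || bx2[i] < bx1[j] ||
            by1[i] > by2[j] || by2[i] < by1[j]) next
        ov <- intersection_area_convex(polys[[i]], polys[[j]])
        if (ov > overlap_tol * min(abs(a_wet[i]), abs(a_wet[j]))) {
          bad[i] <- TRUE; bad[j] <- TRUE
        }
      }
    }
    reason[bad] <- "wet-overlap"
    valid[bad] <- FALSE
  }
  map$ratio <- abs(ratio)
  map$ratio[!map$included] <- NA_real_
  map$valid <- valid
  map$reason <- reason
  map
}

# edge-adjacency list over a subset of triangles
edge_neighbours <- function(map, subset) {
  idx <- as.matrix(map[, c("v1", "v2", "v3")])
  m <- nrow(idx)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- rbind(cbind(1:m, ekey(idx[, 1], idx[, 2])),
                cbind(1:m, ekey(idx[, 2], idx[, 3])),
                cbind(1:m, ekey(idx[, 3], idx[, 1])))
  keys <- keys[as.integer(keys[, 1]) %in% subset, , drop = FALSE]
  split(as.integer(keys[, 1]), keys[, 2])
}

#' Neighbour-smooth the area-change field
#'
#' Replaces each valid triangle's ratio by the arithmetic mean of its
#' own ratio and those of its edge-adjacent valid neighbours (one pass).
#' Invalid triangles neither receive nor contribute values.
#'
#' @param map a `strain_map` with `ratio` computed.
#' @return the map with a `smoothed` column.
#' @export
smooth_area_change <- function(map) {
  stopifnot("ratio" %in% names(map))
  valid <- which(map$valid)
  nb <- vector("list", nrow(map))
  for (grp in edge_neighbours(map, valid)) {
    if (length(grp) == 2) {
      nb[[grp[1]]] <- c(nb[[grp[1]]], grp[2])
      nb[[grp[2]]] <- c(nb[[grp[2]]], grp[1])
    }
  }
  sm <- rep(NA_real_, nrow(map))
  for (i in valid)
    sm[i] <- mean(map$ratio[c(i, nb[[i]])])
  map$smoothed <- sm
  map
}

#' Principal stretches and directions per triangle
#'
#' From the affine map taking each dry triangle to its wet image,
#' computes the deformation gradient F; principal stretches are the
#' singular values of F and principal directions the corresponding right
#' singular vectors (dry-frame directions). The display scaling used in
#' figures is applied only at render time, never here.
#'
#' @param map a `strain_map` with validity flags.
#' @return the map with `stretch1 >= stretch2` and `angle` (radians,
#'   direction of the major principal stretch in the dry frame).
#' @export
principal_strain <- function(map) {
  lm <- attr(map, "landmarks")
  d <- tri_coords(map, lm, "dry")
  w <- tri_coords(map, lm, "wet")
  n <- nrow(map)
  s1 <- s2 <- ang <- rep(NA_real_, n)
  for (i in which(map$valid)) {
    Dm <- cbind(c(d$x[i, 2] - d$x[i, 1], d$y[i, 2] - d$y[i, 1]),
                c(d$x[i, 3] - d$x[i, 1], d$y[i, 3] - d$y[i, 1]))
    Wm <- cbind(c(w$x[i, 2] - w$x[i, 1], w$y[i, 2] - w$y[i, 1]),
                c(w$x[i, 3] - w$x[i, 1], w$y[i, 3] - w$y[i, 1]))
    Fm <- Wm %*% solve(Dm)
    sv <- svd(Fm)
    s1[i] <- sv$d[1]; s2[i] <- sv$d[2]
    ang[i] <- atan2(sv$v[2, 1], sv$v[1, 1])
  }
  map$stretch1 <- s1
  map$stretch2 <- s2
  map$angle <- ang
  map
}

#' Assign triangles to tissue regions by polygon overlap
#'
#' A triangle is assigned to the region whose (convex) polygon covers at
#' least `overlap_threshold` of its dry area; all other triangles are
#' designated cortex. When several regions reach the threshold the
#' largest overlap wins; exact ties are broken by the fixed priority
#' podium > vasculature > side > cavity.
#'
#' @param map a `strain_map`.
#' @param overlap_threshold minimum covered fraction (default 0.40).
#' @return the map with a `region` column.
#' @export
assign_regions <- function(map, overlap_threshold = 0.40) {
  lm <- attr(map, "landmarks")
  regions <- lm$regions
  prio <- c("podium", "vasculature", "side", "cavity")
  nms <- names(regions)
  for (nm in nms)
    if (!is_convex_polygon(regions[[nm]]))
      stop("region polygon '", nm, "' must be convex", call. = FALSE)
  d <- tri_coords(map, lm, "dry")
  lab <- rep("cortex", nrow(map))
  for (i in seq_len(nrow(map))) {
    tri_xy <- cbind(d$x[i, ], d$y[i, ])
    a <- abs(signed_area_cols(d$x[i, , drop = FALSE], d$y[i, , drop = FALSE]))
    if (a <= 1e-12) next
    frac <- vapply(nms, function(nm)
      intersection_area_convex(tri_xy, regions[[nm]]) / a, numeric(1))
    if (length(frac) && sum(frac) > 1 + 1e-6)
      warning("region polygons overlap on triangle ", i,
              "; assigning the largest overlap")
    ok <- which(frac >= overlap_threshold - 1e-12)
    if (length(ok)) {
      best <- ok[frac[ok] == max(frac[ok])]
      if (length(best) > 1)
        best <- best[order(match(nms[best], prio))][1]
      lab[i] <- nms[best]
    }
  }
  map$region <- lab
  map
}

#' Shape circularity
#'
#' `4 * pi * Area / Perimeter^2`: 1 for a perfect circle, approaching 0
#' for elongated shapes.
#'
#' @param polygon simple polygon (two-column vertex matrix, >= 3 rows).
#' @return dimensionless circularity in (0, 1] up to discretization.
#' @examples
#' circularity(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))) # pi/4 for a square
#' @export
circularity <- function(polygon) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  if (n < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  # reject self-intersection (non-adjacent edges properly crossing)
  for (i in seq_len(n)) {
    a1 <- polygon[i, ]; a2 <- polygon[if (i == n) 1 else i + 1, ]
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (i == n && j == 1)) next
      b1 <- polygon[j, ]; b2 <- polygon[if (j == n) 1 else j + 1, ]
      if (segments_cross(a1, a2, b1, b2))
        stop("polygon is self-intersecting", call. = FALSE)
    }
  }
  4 * pi * polygon_area(polygon) / polygon_perimeter(polygon)^2
}

#' Mean smoothed area change per region
#'
#' Arithmetic mean of the smoothed ratios over valid triangles of each
#' region; these are the expansion targets consumed by the
#' swelling-factor fit. Regions with no valid triangle yield NA.
#'
#' @param map a `strain_map` with `smoothed` and `region` columns.
#' @return data frame `region`, `mean_ratio`, `n_triangles`.
#' @export
regional_mean_area_change <- function(map) {
  stopifnot(all(c("smoothed", "region") %in% names(map)))
  ok <- map$valid & !is.na(map$smoothed)
  regs <- sort(unique(map$region))
  data.frame(
    region = regs,
    mean_ratio = vapply(regs, function(r) {
      v <- map$smoothed[ok & map$region == r]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    n_triangles = vapply(regs, function(r)
      sum(ok & map$region == r), numeric(1)),
    row.names = NULL)
}

#' Run the full landmark strain-mapping pipeline
#'
#' Triangulation, area change, smoothing, principal strain and region
#' assignment in sequence.
#'
#' @param lm a [landmark_set()].
#' @param overlap_threshold region-assignment threshold.
#' @return a fully populated `strain_map`.
#' @export
strainmap_run <- function(lm, overlap_threshold = 0.40) {
  map <- triangulate_dry(lm)
  map <- area_change(map)
  map <- smooth_area_change(map)
  map <- principal_strain(map)
  assign_regions(map, overlap_threshold)
}

#' Write per-triangle and per-region strain-map tables
#'
#' @param map a populated `strain_map`.
#' @param stem output path stem.
#' @return invisibly, the file paths written.
#' @export
write_strain_map <- function(map, stem) {
  f1 <- paste0(stem, "_triangles.csv")
  f2 <- paste0(stem, "_regions.csv")
  write.csv(as.data.frame(map), f1, row.names = FALSE)
  write.csv(regional_mean_area_change(map), f2, row.names = FALSE)
  invisible(c(f1, f2))
}
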