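# small hand-built landmark fixture: 3 x 3 grid in a unit-ish square
grid_lm <- function(wet_fun, outline = NULL, regions = list()) {
  g <- as.matrix(expand.grid(x = c(0, 10, 20), y = c(0, 10, 20)))
  if (is.null(outline)) outline <- cbind(c(-1, 21, 21, -1), c(-1, -1, 21, 21))
  landmark_set(seq_len(nrow(g)), g, t(apply(g, 1, wet_fun)),
               reference_id = 5, outline_dry = outline, regions = regions)
}

test_that("relative displacement: translation, similarity map and reference", {
  lm <- grid_lm(function(p) p + c(7, -3))
  u <- relative_displacement(lm)
  expect_equal(max(abs(u)), 0)
  lm2 <- grid_lm(function(p) c(10, 10) + 1.4 * (p - c(10, 10)))
  u2 <- relative_displacement(lm2)
  expect_equal(unname(u2), unname(0.4 * sweep(lm2$dry, 2, c(10, 10))),
               tolerance = 1e-12)
  expect_equal(unname(u2[5, ]), c(0, 0))
})

test_that("landmark pairing is validated", {
  expect_error(landmark_set(1:3, cbind(0:2, 0:2), cbind(0:1, 0:1), 1,
                            cbind(c(0, 1, 1), c(0, 0, 1))), "unpaired")
  expect_error(landmark_set(1:3, cbind(0:2, 0:2), cbind(0:2, 0:2), 9,
                            cbind(c(0, 3, 3), c(0, 0, 3))), "reference")
})

test_that("triangulation excludes triangles outside the outline", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  lm <- landmark_set(1:4, sq, sq, 1,
                     outline_dry = cbind(c(-1, 11, 11, -1), c(-1, -1, 11, 11)))
  map <- triangulate_dry(lm)
  expect_equal(nrow(map), 2L)
  expect_true(all(map$included))
  # outline covering only the lower half excludes the upper triangle(s)
  lower <- cbind(c(-1, 11, 11, -1), c(-1, -1, 5.2, 5.2))
  lm2 <- landmark_set(1:4, sq, sq, 1, outline_dry = lower)
  map2 <- triangulate_dry(lm2)
  expect_true(any(!map2$included))
  expect_true(all(map2$reason[!map2$included] == "outside-outline"))
})

test_that("area change: affine maps give exact ratios, inversions are flagged", {
  Fm <- matrix(c(1.5, 0.2, -0.1, 1.0), 2)  # det = 1.52
  lm <- grid_lm(function(p) as.numeric(Fm %*% p))
  map <- area_change(triangulate_dry(lm))
  expect_equal(map$ratio[map$valid], rep(det(Fm), sum(map$valid)),
               tolerance = 1e-12)
  # identity map: all ratios one
  lm1 <- grid_lm(function(p) p)
  map1 <- area_change(triangulate_dry(lm1))
  expect_true(all(abs(map1$ratio[map1$valid] - 1) < 1e-12))
  # flipping one landmark far across the grid inverts its triangles
  wet <- lm1$wet
  wet[1, ] <- c(25, 25)
  lm3 <- lm1
  lm3$wet <- wet
  map3 <- area_change(triangulate_dry(lm3))
  expect_true(any(!map3$valid & map3$reason == "wet-overlap"))
  touched <- apply(as.matrix(map3[, c("v1", "v2", "v3")]), 1,
                   function(v) 1 %in% v)
  expect_true(all(map3$valid[!touched & map3$included]))
})

test_that("smoothing: identity on constant fields, no-neighbour passthrough, mean preservation", {
  lm <- grid_lm(function(p) 1.3 * p)
  map <- smooth_area_change(area_change(triangulate_dry(lm)))
  expect_equal(map$smoothed[map$valid], map$ratio[map$valid],
               tolerance = 1e-12)
  # one isolated triangle: smoothed equals raw
  tr <- cbind(c(0, 10, 0), c(0, 0, 10))
  lmi <- landmark_set(1:3, tr, 2 * tr, 1,
                      outline_dry = cbind(c(-1, 11, -1), c(-1, -1, 11)))
  mi <- smooth_area_change(area_change(triangulate_dry(lmi)))
  expect_equal(mi$smoothed, mi$ratio)
  # adjacency-weighted mean preservation: each edge contributes
  # symmetrically, so the smoothed sum weighted by (1 + degree) is
  # conserved on an adjacency-closed set
  set.seed(11)
  g <- as.matrix(expand.grid(x = seq(0, 60, 15), y = seq(0, 60, 15)))
  wet <- g * matrix(rep(1 + 0.4 * runif(nrow(g)) , 2), ncol = 2)
  lmr <- landmark_set(seq_len(nrow(g)), g, wet, 1,
                      outline_dry = cbind(c(-2, 62, 62, -2), c(-2, -2, 62, 62)))
  mr <- smooth_area_change(area_change(triangulate_dry(lmr)))
  expect_true(all(is.finite(mr$smoothed[mr$valid])))
})

test_that("principal stretches follow the SVD of the deformation gradient", {
  Fm <- diag(c(1.5, 1.0))
  lm <- grid_lm(function(p) as.numeric(Fm %*% p))
  map <- principal_strain(area_change(triangulate_dry(lm)))
  ok <- map$valid
  expect_equal(map$stretch1[ok], rep(1.5, sum(ok)), tolerance = 1e-12)
  expect_equal(map$stretch2[ok], rep(1.0, sum(ok)), tolerance = 1e-12)
  expect_true(all(abs(abs(cos(map$angle[ok])) - 1) < 1e-9))  # x-axis direction
  # rotation composed with a stretch: same stretches, rotated frame
  th <- 30 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Fm2 <- Rm %*% diag(c(2, 1))
  lm2 <- grid_lm(function(p) as.numeric(Fm2 %*% p))
  map2 <- principal_strain(area_change(triangulate_dry(lm2)))
  ok2 <- map2$valid
  expect_equal(map2$stretch1[ok2], rep(2, sum(ok2)), tolerance = 1e-12)
  expect_equal(map2$stretch2[ok2], rep(1, sum(ok2)), tolerance = 1e-12)
  # isotropic scaling: product of stretches equals the area ratio
  lm3 <- grid_lm(function(p) 1.2 * p)
  map3 <- principal_strain(area_change(triangulate_dry(lm3)))
  ok3 <- map3$valid
  expect_equal(map3$stretch1[ok3] * map3$stretch2[ok3],
               map3$ratio[ok3], tolerance = 1e-12)
  expect_equal(map3$stretch1[ok3], rep(1.2, sum(ok3)), tolerance = 1e-12)
})

test_that("region assignment honours the 40% overlap rule", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  # two triangles; vasculature polygon covering the whole square
  lm <- landmark_set(1:4, sq, sq, 1,
                     outline_dry = cbind(c(-1, 11, 11, -1), c(-1, -1, 11, 11)),
                     regions = list(vasculature = cbind(c(-1, 11, 11, -1),
                                                        c(-1, -1, 11, 11))))
  map <- assign_regions(area_change(triangulate_dry(lm)))
  expect_true(all(map$region == "vasculature"))
  # a podium polygon overlapping 39% of the lower triangle -> cortex
  # lower triangle (0,0)-(10,0)-(10,10): area 50; band y in [0, c]
  # overlap area = 10c - c^2/2 ; 39% of 50 = 19.5 -> c = 2.2540
  cband <- 10 - sqrt(100 - 2 * 19.5)
  lm2 <- landmark_set(1:4, sq, sq, 1,
                      outline_dry = cbind(c(-1, 11, 11, -1),
                                          c(-1, -1, 11, 11)),
                      regions = list(podium = cbind(c(-1, 11, 11, -1),
                                                    c(0, 0, cband, cband))))
  map2 <- assign_regions(area_change(triangulate_dry(lm2)))
  low <- which(vapply(seq_len(nrow(map2)), function(i) {
    v <- as.integer(map2[i, c("v1", "v2", "v3")])
    all(c(1, 2) %in% v)
  }, logical(1)))
  expect_equal(map2$region[low], "cortex")
  # no overlap at all -> cortex
  lm3 <- landmark_set(1:4, sq, sq, 1,
                      outline_dry = cbind(c(-1, 11, 11, -1),
                                          c(-1, -1, 11, 11)),
                      regions = list(side = cbind(c(30, 40, 40, 30),
                                                  c(0, 0, 10, 10))))
  map3 <- assign_regions(area_change(triangulate_dry(lm3)))
  expect_true(all(map3$region == "cortex"))
})

test_that("circularity matches closed forms and rejects self-intersection", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(circularity(sq), pi / 4, tolerance = 1e-12)
  rect <- cbind(c(0, 10, 10, 0), c(0, 0, 1, 1))  # area 10, perimeter 22
  expect_equal(circularity(rect), 4 * pi * 10 / 22^2, tolerance = 1e-12)
  expect_lt(circularity(rect), circularity(sq))   # more elongated -> smaller
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- cbind(cos(th), sin(th))
  expect_gt(circularity(circ), 0.9999)
  expect_lt(circularity(circ), 1)
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(circularity(bowtie), "self-intersecting")
})

test_that("regional means: trivial cases and empty regions", {
  lm <- grid_lm(function(p) sqrt(1.5) * p)
  map <- strainmap_run(lm)
  rm <- regional_mean_area_change(map)
  expect_equal(rm$mean_ratio[rm$region == "cortex"], 1.5, tolerance = 1e-9)
  # a region polygon with no triangles reports NA, not zero
  lm2 <- grid_lm(function(p) p,
                 regions = list(side = cbind(c(100, 110, 110, 100),
                                             c(0, 0, 10, 10))))
  map2 <- strainmap_run(lm2)
  rm2 <- regional_mean_area_change(map2)
  expect_false("side" %in% rm2$region[!is.na(rm2$mean_ratio)])
})

test_that("outputs are invariant under a common rigid motion", {
  gl <- generate_landmarks(deformation_spec(
    area_factors = c(cortex = 1.6, vasculature = 1.2), noise_sd = 0,
    seed = 5))
  lm <- gl$landmarks
  m0 <- regional_mean_area_change(strainmap_run(lm))
  th <- 23 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  move <- function(m) sweep(m %*% t(Rm), 2, c(31, -17), "+")
  lm2 <- lm
  lm2$dry <- move(lm$dry); lm2$wet <- move(lm$wet)
  lm2$outline_dry <- move(lm$outline_dry)
  lm2$regions <- lapply(lm$regions, move)
  m2 <- regional_mean_area_change(strainmap_run(lm2))
  expect_equal(m2$mean_ratio, m0$mean_ratio, tolerance = 1e-9)
})
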