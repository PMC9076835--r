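test_that("parameter validation names the violated constraint", {
  expect_error(geometry_params(D = -1), "strictly positive")
  expect_error(geometry_params(D_cavity = 450), "D_cavity")
  expect_error(geometry_params(H_pod = 160, H_side = 91.4), "H_pod \\+ H_side")
  expect_error(geometry_params(d_vasc = 300), "d_vasc")
  expect_error(geometry_params(W_side = 130), "inboard of the side region")
})

test_that("reference section has the measured bounding box and closed areas", {
  dom <- ref_domain()
  p <- dom$params
  expect_equal(diff(range(dom$outline[, 1])) * 2, p$D, tolerance = 1e-9)
  expect_equal(max(dom$outline[, 2]), p$H, tolerance = 1e-9)
  # shoelace closure: regions + cavity tile the outline exactly
  a <- domain_region_areas(dom)
  expect_equal(sum(a[c("podium", "vasculature", "side", "cortex")]) +
                 a[["cavity"]],
               2 * polygon_area(dom$outline) + a[["cavity"]],
               tolerance = 1e-9)
  expect_equal(sum(a[c("podium", "vasculature", "side", "cortex")]),
               2 * polygon_area(dom$outline), tolerance = 1e-9)
})

test_that("geometry construction is deterministic", {
  d1 <- build_reference_geometry(geometry_params())
  d2 <- build_reference_geometry(geometry_params())
  expect_identical(d1$outline, d2$outline)
  expect_identical(d1$regions, d2$regions)
})

test_that("zero-magnitude perturbations are the identity", {
  for (kind in c("fill_cavity_horizontal", "fill_cavity_vertical",
                 "trim_corner_vertical")) {
    dom <- apply_geometry_perturbation(geometry_params(),
                                       geometry_perturbation(kind, 0))
    expect_equal(dom$regions, ref_domain()$regions, tolerance = 1e-12,
                 info = kind)
    expect_equal(dom$outline, ref_domain()$outline, tolerance = 1e-12)
  }
  dom <- apply_geometry_perturbation(
    geometry_params(), geometry_perturbation("move_corner_horizontal", 0))
  expect_equal(dom$regions, ref_domain()$regions, tolerance = 1e-12)
})

test_that("out-of-range magnitudes report the admissible interval", {
  p <- geometry_params()
  expect_error(apply_geometry_perturbation(
    p, geometry_perturbation("fill_cavity_horizontal", p$D_cavity)),
    "admissible range")
  expect_error(apply_geometry_perturbation(
    p, geometry_perturbation("fill_cavity_vertical", -3)),
    "admissible range")
})

test_that("full horizontal fill removes the cavity and conserves area", {
  p <- geometry_params()
  dom <- apply_geometry_perturbation(
    p, geometry_perturbation("fill_cavity_horizontal", p$D_cavity / 2))
  expect_null(dom$cavity)
  a_ref <- domain_region_areas(ref_domain())
  a <- domain_region_areas(dom)
  expect_equal(a[["cavity"]], 0)
  # cavity space became cortex, everything else untouched
  expect_equal(a[["cortex"]], a_ref[["cortex"]] + a_ref[["cavity"]],
               tolerance = 1e-9)
  expect_equal(a[["vasculature"]], a_ref[["vasculature"]], tolerance = 1e-9)
})

test_that("partial fills conserve total tissue + cavity area", {
  p <- geometry_params()
  a_ref <- domain_region_areas(ref_domain())
  for (pert in list(geometry_perturbation("fill_cavity_horizontal", 15),
                    geometry_perturbation("fill_cavity_vertical", 60))) {
    a <- domain_region_areas(apply_geometry_perturbation(p, pert))
    expect_equal(a[["cortex"]] + a[["cavity"]],
                 a_ref[["cortex"]] + a_ref[["cavity"]], tolerance = 1e-9)
    expect_lt(a[["cavity"]], a_ref[["cavity"]])
  }
})

test_that("corner trim removes exactly the shoelace area of the cut", {
  p <- geometry_params()
  m <- 25
  dom <- apply_geometry_perturbation(
    p, geometry_perturbation("trim_corner_vertical", m))
  a_ref <- domain_region_areas(ref_domain())
  a <- domain_region_areas(dom)
  # removed piece: between the base, the band's outer edge and y = m
  ytop <- p$H - p$H_pod
  xvout <- p$D_cavity / 2 + p$W_vasc
  xs <- p$D / 2 - p$W_side
  xm <- xvout + (xs - xvout) * m / ytop
  cut <- rbind(c(xvout, 0), c(p$D / 2, 0), c(p$D / 2, m), c(xm, m))
  expect_equal(a_ref[["cortex"]] - a[["cortex"]], 2 * polygon_area(cut),
               tolerance = 1e-9)
})

test_that("horizontal corner moves add or remove the expected cortex area", {
  p <- geometry_params()
  a_ref <- domain_region_areas(ref_domain())
  for (m in c(-30, 30)) {
    a <- domain_region_areas(apply_geometry_perturbation(
      p, geometry_perturbation("move_corner_horizontal", m)))
    ysb <- p$H - p$H_pod - p$H_side
    expect_equal(a[["cortex"]] - a_ref[["cortex"]], 2 * m * ysb / 2,
                 tolerance = 1e-9, info = paste("m =", m))
  }
})
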