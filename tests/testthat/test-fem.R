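test_that("patch test: linear boundary displacement reproduces constant strain", {
  mesh <- rect_mesh(60, 60, h = 12)
  mat <- material_params(s_cort = 1e-9, s_pod = 1e-9, s_side = 1e-9,
                         s_vasc = 1e-9)
  # boundary = edges used once
  e <- rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3],
             mesh$triangles[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  bn <- sort(unique(as.vector(e[ekey %in% names(which(table(ekey) == 1L)), ])))
  A <- matrix(c(0.003, 0.001, -0.002, 0.004), 2)  # linear field u = A x
  ub <- mesh$nodes[bn, ] %*% t(A)
  d <- rbind(data.frame(node = bn, dof = "x", value = ub[, 1]),
             data.frame(node = bn, dof = "y", value = ub[, 2]))
  pr <- swelling_problem(mesh, mat, dirichlet = d)
  U <- solve_dehydration(pr)
  expect_equal(unclass(U), mesh$nodes %*% t(A), tolerance = 1e-9,
               ignore_attr = TRUE)
  st <- compute_stress(pr, U)
  expect_lt(diff(range(st$sxx)), 1e-9)
  expect_lt(diff(range(st$sxy)), 1e-9)
})

test_that("compatible uniform swelling is stress-free and scales the mesh", {
  mesh <- ref_mesh(8)
  s <- 0.4
  mat <- material_params(s_cort = s, s_pod = s, s_side = s, s_vasc = s)
  e <- 1 - sqrt(1 - s)
  vb <- mesh$node_sets$vasc_base
  d <- rbind(data.frame(node = vb, dof = "x", value = -e * mesh$nodes[vb, 1]),
             data.frame(node = vb, dof = "y", value = 0),
             data.frame(node = setdiff(mesh$node_sets$axis, vb), dof = "x",
                        value = 0))
  pr <- swelling_problem(mesh, mat, dirichlet = d)
  U <- solve_dehydration(pr)
  st <- compute_stress(pr, U)
  expect_lt(max(abs(c(st$sxx, st$syy, st$sxy))), 1e-6 * mat$E_vasc)
  # dry geometry = wet scaled by sqrt(1 - s); ratios exactly 1 - s
  rc <- regional_area_change(mesh, U)
  expect_equal(rc$dry_wet, rep(1 - s, 4), tolerance = 1e-6)
})

test_that("an isolated free region shrinks by exactly its swelling factor", {
  mesh <- rect_mesh(80, 120, h = 12)
  mat <- material_params(s_cort = 0.37)
  pr <- swelling_problem(mesh, mat, dirichlet = minimal_pins(mesh))
  U <- solve_dehydration(pr)
  rc <- regional_area_change(mesh, U)
  expect_equal(rc$dry_wet[rc$region == "cortex"], 1 - 0.37, tolerance = 1e-9)
})

test_that("displacements are invariant to the global modulus scale", {
  mesh <- ref_mesh(8)
  pr1 <- swelling_problem(mesh, material_params(E_vasc = 1))
  pr2 <- swelling_problem(mesh, material_params(E_vasc = 73.2))
  U1 <- solve_dehydration(pr1)
  U2 <- solve_dehydration(pr2)
  expect_equal(unclass(U1), unclass(U2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the discrete solution minimizes the energy functional", {
  mesh <- ref_mesh(10)
  pr <- swelling_problem(mesh, material_params())
  U <- suppressWarnings(solve_dehydration(pr))
  e0 <- pappus:::fem_energy(pr, U)
  fixed_nodes <- pr$dirichlet$node
  set.seed(3)
  for (k in 1:5) {
    V <- matrix(rnorm(length(U), sd = 0.5), ncol = 2)
    V[fixed_nodes, ] <- 0
    expect_gt(pappus:::fem_energy(pr, unclass(U) + V), e0)
  }
})

test_that("full-domain solve is mirror symmetric and agrees with the half model", {
  dom <- ref_domain()
  full <- mesh_domain(dom, 8, half_model = FALSE)
  pr <- swelling_problem(full, material_params())
  U <- suppressWarnings(solve_dehydration(pr))
  st_full <- actuator_state(pr, U)
  # pair nodes with their mirror images
  key <- paste(round(full$nodes[, 1], 6), round(full$nodes[, 2], 6))
  mkey <- paste(round(-full$nodes[, 1], 6), round(full$nodes[, 2], 6))
  m <- match(mkey, key)
  ok <- !is.na(m)
  expect_gt(mean(ok), 0.99)
  expect_lt(max(abs(U[ok, 1] + U[m[ok], 1])), 1e-6)
  expect_lt(max(abs(U[ok, 2] - U[m[ok], 2])), 1e-6)
  expect_lt(abs(st_full$theta - ref_state(8)$theta), 0.3)
})

test_that("holding angle: identity and rigid-rotation oracles", {
  st <- ref_state(8)
  # identity deformation reproduces the wet (vertical) line
  st0 <- st
  st0$dry_nodes <- st$mesh$nodes
  expect_equal(compute_holding_angle(st0), 0, tolerance = 1e-9)
  # tilting the dry state 10 degrees further outward (clockwise on the
  # right half) about the podium centre adds exactly 10 degrees
  pod <- st$mesh$domain$regions$podium[[1]]
  cen <- pappus:::polygon_centroid(pod)
  th <- -10 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  at <- st
  at$dry_nodes <- sweep(sweep(st$dry_nodes, 2, cen) %*% t(Rm), 2, cen, "+")
  expect_equal(compute_holding_angle(at), st$theta + 10, tolerance = 1e-9)
})

test_that("single fully-clamped element feels minus C : eigenstrain", {
  nodes <- rbind(c(0, 0), c(10, 0), c(0, 10))
  mesh <- structure(list(nodes = nodes, triangles = matrix(1:3, 1),
                         region = factor("cortex",
                                         levels = c("podium", "vasculature",
                                                    "side", "cortex")),
                         node_sets = list(vasc_base = integer(0),
                                          axis = integer(0),
                                          boundary = 1:3),
                         target_edge = 10, half_model = TRUE, domain = NULL),
                    class = "tri_mesh")
  mat <- material_params(s_cort = 0.3)
  d <- rbind(data.frame(node = 1:3, dof = "x", value = 0),
             data.frame(node = 1:3, dof = "y", value = 0))
  pr <- swelling_problem(mesh, mat, dirichlet = d)
  U <- solve_dehydration(pr)
  st <- compute_stress(pr, U)
  e <- sqrt(1 - 0.3) - 1
  E <- mat$E_vasc * mat$rho[["cortex"]]
  nu <- mat$nu
  kap <- E / ((1 + nu) * (1 - 2 * nu))
  expect_equal(st$sxx, -kap * e, tolerance = 1e-12)  # d11*e + d12*e = kap*e
  expect_equal(st$syy, -kap * e, tolerance = 1e-12)
  expect_equal(st$sxy, 0, tolerance = 1e-12)
})

test_that("reference stress pattern: vasculature axially compressed, flanks in tension", {
  st <- ref_state(8)
  sig <- compute_stress(st$problem, st$displacement)
  p <- geometry_params()
  v <- c(p$D / 2 - p$W_side - p$D_cavity / 2, p$H - p$H_pod)
  v <- v / sqrt(sum(v^2))  # vascular band axis
  ax <- sig$sxx * v[1]^2 + 2 * sig$sxy * v[1] * v[2] + sig$syy * v[2]^2
  expect_lt(median(ax[sig$region == "vasculature"]), 0)
  expect_gt(mean(ax[sig$region == "vasculature"] < 0), 0.8)
  expect_gt(median(ax[sig$region == "side"]), 0)
  expect_gt(median(ax[sig$region == "cortex"]), 0)
})

test_that("reference regional expansions rank the vasculature lowest", {
  rc <- ref_state(8)$area_change
  vasc <- rc$wet_dry[rc$region == "vasculature"]
  expect_true(all(vasc < rc$wet_dry[rc$region != "vasculature"]))
})

test_that("lower cortex displaces more radially than the vasculature", {
  st <- ref_state(8)
  mesh <- st$mesh
  tri <- mesh$triangles
  node_region <- rep(NA_character_, nrow(mesh$nodes))
  for (r in levels(mesh$region)) {
    node_region[unique(as.vector(tri[mesh$region == r, ]))] <- r
  }
  low_cort <- which(node_region == "cortex" & mesh$nodes[, 2] < 60)
  vasc <- which(node_region == "vasculature")
  rad <- abs(st$rel_displacement[, 1])
  expect_gt(mean(rad[low_cort]), mean(rad[vasc]))
})

test_that("material substitution validates and composes correctly", {
  m0 <- material_params()
  expect_identical(substitute_materials(m0, c(podium = "podium")), m0)
  ms <- substitute_materials(m0, c(vasculature = "side", podium = "side"))
  expect_equal(ms$s[["vasculature"]], m0$s[["side"]])
  expect_equal(ms$rho[["podium"]], m0$rho[["side"]])
  expect_equal(ms$s[["cortex"]], m0$s[["cortex"]])
  expect_error(substitute_materials(m0, c(pith = "side")), "region names")
})
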