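# Plane-strain linear elasticity with region-wise isotropic eigenstrain,
# discretized with linear (constant-strain) triangles. The hydrated mesh
# is the stress-free reference configuration; dehydration imposes the
# eigenstrain eps* = (sqrt(1 - s_region) - 1) * I in-plane (no
# out-of-plane eigenstrain), which reproduces the isolated-region area
# ratio 1 - s exactly for a free region. The discrete problem minimizes
# 1/2 u'Ku - f'u subject to Dirichlet data; K is assembled sparsely and
# factorized once per stiffness distribution, so repeated solves with
# different swelling factors (as in the fit) reuse the factorization.

dof_x <- function(node) 2L * node - 1L
dof_y <- function(node) 2L * node

# Geometric element quantities shared by assembly and stress recovery.
element_geometry <- function(mesh) {
  tri <- mesh$triangles
  nd <- mesh$nodes
  x <- matrix(nd[tri, 1], ncol = 3)
  y <- matrix(nd[tri, 2], ncol = 3)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  A <- ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
          (x[, 3] - x[, 1]) * (y[, 2] - y[, 1])) / 2
  list(b = b, cc = cc, A = A)
}

plane_strain_moduli <- function(E, nu) {
  kap <- E / ((1 + nu) * (1 - 2 * nu))
  list(d11 = kap * (1 - nu), d12 = kap * nu, d33 = kap * (1 - 2 * nu) / 2,
       kap = kap)
}

# Assemble the global stiffness matrix and the per-region unit-eigenstrain
# load vectors. Returns an environment-free list.
assemble_system <- function(mesh, materials) {
  g <- element_geometry(mesh)
  b <- g$b; cc <- g$cc; A <- g$A
  if (any(A <= 0)) stop("mesh contains non-positively oriented triangles")
  reg <- as.character(mesh$region)
  E <- region_modulus(materials)[reg]
  mod <- plane_strain_moduli(E, materials$nu)
  d11 <- mod$d11; d12 <- mod$d12; d33 <- mod$d33

  tri <- mesh$triangles
  m <- nrow(tri)
  nn <- nrow(mesh$nodes)
  ii <- jj <- xx <- vector("list", 36L)
  k <- 0L
  inv4A <- 1 / (4 * A)
  for (i in 1:3) for (j in 1:3) {
    bi <- b[, i]; ci <- cc[, i]; bj <- b[, j]; cj <- cc[, j]
    kxx <- (d11 * bi * bj + d33 * ci * cj) * inv4A
    kxy <- (d12 * bi * cj + d33 * ci * bj) * inv4A
    kyx <- (d12 * ci * bj + d33 * bi * cj) * inv4A
    kyy <- (d11 * ci * cj + d33 * bi * bj) * inv4A
    ni <- tri[, i]; nj <- tri[, j]
    k <- k + 1L; ii[[k]] <- dof_x(ni); jj[[k]] <- dof_x(nj); xx[[k]] <- kxx
    k <- k + 1L; ii[[k]] <- dof_x(ni); jj[[k]] <- dof_y(nj); xx[[k]] <- kxy
    k <- k + 1L; ii[[k]] <- dof_y(ni); jj[[k]] <- dof_x(nj); xx[[k]] <- kyx
    k <- k + 1L; ii[[k]] <- dof_y(ni); jj[[k]] <- dof_y(nj); xx[[k]] <- kyy
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(2L * nn, 2L * nn))

  # load vector for a unit in-plane eigenstrain on each region:
  # f_i = kappa * (b_i, c_i) / 2 per element (D:eps* = kappa*(1,1,0) at e=1)
  regions <- levels(mesh$region)
  Funit <- matrix(0, 2L * nn, length(regions),
                  dimnames = list(NULL, regions))
  for (r in regions) {
    sel <- reg == r
    if (!any(sel)) next
    f <- numeric(2L * nn)
    for (i in 1:3) {
      fx <- mod$kap[sel] * b[sel, i] / 2
      fy <- mod$kap[sel] * cc[sel, i] / 2
      idx <- dof_x(tri[sel, i])
      idy <- dof_y(tri[sel, i])
      f <- f + tabulate2(idx, fx, 2L * nn) + tabulate2(idy, fy, 2L * nn)
    }
    Funit[, r] <- f
  }
  list(K = K, Funit = Funit, geom = g, mod = mod, nn = nn)
}

# sum values into a dense vector by index
tabulate2 <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Standard dehydration Dirichlet data: vascular-base nodes move
# horizontally toward the axis by d_vasc (vertical displacement fixed at
# zero); axis nodes (half model) have zero horizontal displacement.
standard_dirichlet <- function(mesh, d_vasc) {
  vb <- mesh$node_sets$vasc_base
  ax <- setdiff(mesh$node_sets$axis, vb)
  d <- rbind(
    data.frame(node = vb, dof = "x",
               value = -sign(mesh$nodes[vb, 1]) * d_vasc),
    data.frame(node = vb, dof = "y", value = 0),
    if (length(ax)) data.frame(node = ax, dof = "x", value = 0)
  )
  d[!duplicated(paste(d$node, d$dof)), , drop = FALSE]
}

#' Define a dehydration (swelling) problem
#'
#' Bundles a tagged mesh, material parameters and boundary conditions.
#' By default the vascular-base nodes are displaced horizontally toward
#' the symmetry axis by `d_vasc` with vertical displacement fixed, and
#' axis nodes (half model) carry the symmetry condition.
#'
#' @param mesh a `tri_mesh`.
#' @param materials a [material_params()] object.
#' @param d_vasc prescribed inward vascular-base displacement (um);
#'   defaults to the value stored in the meshed geometry.
#' @param dirichlet optional replacement boundary conditions: a data
#'   frame with columns `node`, `dof` (`"x"`/`"y"`), `value`. When given,
#'   it is used instead of the standard conditions.
#' @return object of class `swelling_problem`.
#' @export
swelling_problem <- function(mesh, materials,
                             d_vasc = mesh$domain$params$d_vasc,
                             dirichlet = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(materials, "material_params"))
  if (is.null(dirichlet)) {
    if (length(mesh$node_sets$vasc_base) == 0)
      stop("mesh has no vascular-base nodes to constrain", call. = FALSE)
    dirichlet <- standard_dirichlet(mesh, d_vasc)
  }
  if (nrow(dirichlet) < 3)
    stop("insufficient constraints: rigid-body modes are not fixed",
         call. = FALSE)
  structure(list(mesh = mesh, materials = materials, d_vasc = d_vasc,
                 dirichlet = dirichlet),
            class = "swelling_problem")
}

# Factorized operator for repeated solves with varying swelling factors.
dehydration_operator <- function(problem) {
  mesh <- problem$mesh
  sys <- assemble_system(mesh, problem$materials)
  nd <- 2L * sys$nn
  fixed <- ifelse(problem$dirichlet$dof == "x",
                  dof_x(problem$dirichlet$node), dof_y(problem$dirichlet$node))
  uc <- problem$dirichlet$value
  free <- setdiff(seq_len(nd), fixed)
  Kff <- sys$K[free, free, drop = FALSE]
  Kfc_uc <- as.numeric(sys$K[free, fixed, drop = FALSE] %*% uc)
  fact <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
    error = function(e)
      stop("singular system: insufficient constraints leave rigid-body modes",
           call. = FALSE))
  list(sys = sys, fact = fact, free = free, fixed = fixed, uc = uc,
       Kfc_uc = Kfc_uc, nd = nd, mesh = mesh, problem = problem)
}

operator_solve <- function(op, s) {
  e <- sqrt(1 - s) - 1  # isotropic in-plane eigenstrain per region
  f <- as.numeric(op$sys$Funit[, names(s), drop = FALSE] %*% e)
  rhs <- f[op$free] - op$Kfc_uc
  uf <- as.numeric(Matrix::solve(op$fact, rhs))
  u <- numeric(op$nd)
  u[op$free] <- uf
  u[op$fixed] <- op$uc
  U <- cbind(u[seq(1, op$nd, by = 2)], u[seq(2, op$nd, by = 2)])
  colnames(U) <- c("ux", "uy")
  U
}

#' Solve the dehydration problem
#'
#' Minimizes the plane-strain elastic energy with region-wise isotropic
#' eigenstrain `sqrt(1 - s) - 1` and the problem's Dirichlet data, and
#' returns the wet-to-dry displacement field. Warns if any triangle of
#' the dry configuration is inverted.
#'
#' @param problem a [swelling_problem()].
#' @return a `displacement_field`: n x 2 matrix of nodal displacements
#'   (um) with the problem attached as an attribute.
#' @export
solve_dehydration <- function(problem) {
  op <- dehydration_operator(problem)
  U <- operator_solve(op, problem$materials$s)
  dry <- op$mesh$nodes + U
  if (any(tri_signed_areas(dry, op$mesh$triangles) <= 0)) {
    bad <- which(tri_signed_areas(dry, op$mesh$triangles) <= 0)
    warning(sprintf("non-physical deformation: %d inverted dry triangle(s), e.g. %s",
                    length(bad), paste(head(bad, 5), collapse = ", ")))
  }
  structure(U, class = c("displacement_field", "matrix"),
            problem = problem)
}

#' Element stresses from a displacement field
#'
#' Hooke's law on the elastic strain (total minus eigenstrain) per
#' constant-strain triangle, plus the out-of-plane plane-strain
#' component and in-plane principal values/directions.
#'
#' @param problem the [swelling_problem()] the field solves.
#' @param field a `displacement_field` (or plain n x 2 matrix).
#' @return data frame with one row per element: `sxx`, `syy`, `sxy`,
#'   `szz`, principal values `s1 >= s2`, principal angle `angle`
#'   (radians from +x), and the region label. Units of `E_vasc`.
#' @export
compute_stress <- function(problem, field) {
  mesh <- problem$mesh
  g <- element_geometry(mesh)
  tri <- mesh$triangles
  U <- unclass(field)
  ux <- matrix(U[tri, 1], ncol = 3)
  uy <- matrix(U[tri, 2], ncol = 3)
  inv2A <- 1 / (2 * g$A)
  exx <- rowSums(g$b * ux) * inv2A
  eyy <- rowSums(g$cc * uy) * inv2A
  gxy <- (rowSums(g$cc * ux) + rowSums(g$b * uy)) * inv2A
  reg <- as.character(mesh$region)
  s <- problem$materials$s[reg]
  estar <- sqrt(1 - s) - 1
  E <- region_modulus(problem$materials)[reg]
  mod <- plane_strain_moduli(E, problem$materials$nu)
  ex <- exx - estar; ey <- eyy - estar
  sxx <- mod$d11 * ex + mod$d12 * ey
  syy <- mod$d12 * ex + mod$d11 * ey
  sxy <- mod$d33 * gxy
  szz <- mod$kap * problem$materials$nu * (ex + ey)
  cen <- (sxx + syy) / 2
  rad <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  data.frame(sxx = sxx, syy = syy, sxy = sxy, szz = szz,
             s1 = cen + rad, s2 = cen - rad,
             angle = 0.5 * atan2(2 * sxy, sxx - syy),
             region = reg)
}

# Discrete energy functional J(u) = 1/2 u'Ku - f'u of an admissible field
# (used to verify that the solution minimizes energy).
fem_energy <- function(problem, field) {
  sys <- assemble_system(problem$mesh, problem$materials)
  e <- sqrt(1 - problem$materials$s) - 1
  f <- as.numeric(sys$Funit[, names(e), drop = FALSE] %*% e)
  u <- as.numeric(t(unclass(field)))  # interleave ux, uy
  0.5 * sum(u * as.numeric(sys$K %*% u)) - sum(f * u)
}
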