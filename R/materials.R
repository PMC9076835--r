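#' Material parameters of the four tissue regions
#'
#' Region stiffness is proportional to the measured density of cell-wall
#' material: `E_region = E_vasc * rho_region/rho_vasc`. All regions share
#' one Poisson ratio. The intrinsic swelling factor `s` of a region is
#' the fraction of area it would lose on dehydration if detached from
#' its neighbours; the defaults are the fitted reference values.
#'
#' @param rho_cort,rho_pod,rho_side density of cortex / floral podium /
#'   side tissue relative to the vasculature (dimensionless).
#' @param nu Poisson ratio shared by all regions.
#' @param s_cort,s_pod,s_side,s_vasc intrinsic swelling factors in (0, 1).
#' @param E_vasc reference modulus scale of the vasculature (arbitrary
#'   units; the dehydration problem is displacement- and
#'   eigenstrain-driven, so results do not depend on it).
#' @return object of class `material_params`.
#' @export
material_params <- function(rho_cort = 0.76, rho_pod = 1.16, rho_side = 1.04,
                            nu = 0.29, s_cort = 0.46, s_pod = 0.44,
                            s_side = 0.57, s_vasc = 0.24, E_vasc = 1) {
  rho <- c(podium = rho_pod, vasculature = 1, side = rho_side,
           cort = rho_cort)
  names(rho)[4] <- "cortex"
  s <- c(podium = s_pod, vasculature = s_vasc, side = s_side,
         cortex = s_cort)
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("densities must be positive", call. = FALSE)
  if (!is.finite(nu) || nu <= 0 || nu >= 0.5)
    stop("Poisson ratio must lie in (0, 0.5)", call. = FALSE)
  if (any(!is.finite(s)) || any(s <= 0) || any(s >= 1))
    stop("swelling factors must lie in (0, 1)", call. = FALSE)
  if (!is.finite(E_vasc) || E_vasc <= 0)
    stop("E_vasc must be positive", call. = FALSE)
  structure(list(rho = rho, nu = nu, s = s, E_vasc = E_vasc),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Apical-plate material parameters\n")
  cat("  relative density (vs vasculature):\n"); print(round(x$rho, 3))
  cat("  swelling factors s:\n"); print(round(x$s, 3))
  cat(sprintf("  Poisson ratio %.3g, modulus scale E_vasc %.3g\n",
              x$nu, x$E_vasc))
  invisible(x)
}

region_modulus <- function(materials) materials$E_vasc * materials$rho

#' Substitute tissue types between regions
#'
#' Gives each recipient region the donor region's relative density
#' (hence modulus) and intrinsic swelling factor, emulating hypothetical
#' actuators built from alternative tissue arrangements.
#'
#' @param materials a [material_params()] object.
#' @param mapping named character vector, `recipient = donor`, e.g.
#'   `c(vasculature = "side", podium = "side")`.
#' @return a new `material_params` object.
#' @examples
#' substitute_materials(material_params(), c(podium = "vasculature"))
#' @export
substitute_materials <- function(materials, mapping) {
  stopifnot(inherits(materials, "material_params"))
  regions <- names(materials$s)
  if (length(mapping) == 0) return(materials)
  if (is.null(names(mapping)) ||
      !all(names(mapping) %in% regions) || !all(mapping %in% regions))
    stop("mapping must be recipient = donor with region names among: ",
         paste(regions, collapse = ", "), call. = FALSE)
  out <- materials
  # donors read from the original set, so simultaneous swaps are well defined
  for (rec in names(mapping)) {
    don <- mapping[[rec]]
    out$rho[rec] <- materials$rho[don]
    out$s[rec] <- materials$s[don]
  }
  out
}
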