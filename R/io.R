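# Plain-text configuration and data interchange: YAML configs mirroring
# the measured-parameter tables, CSV targets and landmark files.

#' Write geometry and material parameters to a YAML config
#'
#' @param geometry a [geometry_params()] object.
#' @param materials a [material_params()] object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_config <- function(geometry, materials, path) {
  cfg <- list(
    geometry = as.list(unclass(geometry)),
    materials = list(rho_cort = unname(materials$rho[["cortex"]]),
                     rho_pod = unname(materials$rho[["podium"]]),
                     rho_side = unname(materials$rho[["side"]]),
                     nu = materials$nu,
                     s_cort = unname(materials$s[["cortex"]]),
                     s_pod = unname(materials$s[["podium"]]),
                     s_side = unname(materials$s[["side"]]),
                     s_vasc = unname(materials$s[["vasculature"]]),
                     E_vasc = materials$E_vasc))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read geometry and material parameters from a YAML config
#'
#' @param path config file written by [write_config()] (or hand-written
#'   with the same keys; missing material keys fall back to defaults).
#' @return list with `geometry` and `materials`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geometry <- do.call(geometry_params, cfg$geometry)
  materials <- do.call(material_params, cfg$materials)
  list(geometry = geometry, materials = materials)
}

#' Read expansion targets from CSV
#'
#' Expects columns `region`, `ratio` and optionally `sd`.
#'
#' @param path CSV file.
#' @return an [expansion_targets()] data frame.
#' @export
read_targets <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  expansion_targets(df$region, df$ratio,
                    sd = if ("sd" %in% names(df)) df$sd else NULL)
}

#' Write expansion targets to CSV
#'
#' @param targets an [expansion_targets()] data frame.
#' @param path CSV file.
#' @return invisibly, `path`.
#' @export
write_targets <- function(targets, path) {
  write.csv(targets, path, row.names = FALSE)
  invisible(path)
}

#' Read a paired landmark table from CSV
#'
#' Expects columns `id`, `x_dry`, `y_dry`, `x_wet`, `y_wet`.
#'
#' @param path CSV file.
#' @param reference_id reference landmark id.
#' @param outline_dry,regions,pixel_size,y_down passed to
#'   [landmark_set()].
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path, reference_id, outline_dry,
                           regions = list(), pixel_size = 1,
                           y_down = FALSE) {
  df <- read.csv(path)
  landmark_set(df$id, cbind(df$x_dry, df$y_dry), cbind(df$x_wet, df$y_wet),
               reference_id = reference_id, outline_dry = outline_dry,
               regions = regions, pixel_size = pixel_size, y_down = y_down)
}

#' Read AFM force curves from a manifest
#'
#' The manifest CSV has columns `file`, `region`, `sample`,
#' `spring_constant`, `trigger_force`; each referenced file is a CSV
#' with columns `height`, `force`, `segment` (SI units).
#'
#' @param manifest path to the manifest CSV.
#' @param dir directory the curve files live in (default: the
#'   manifest's directory).
#' @return list of [force_curve()] objects.
#' @export
read_force_curves <- function(manifest, dir = dirname(manifest)) {
  mf <- read.csv(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(mf)), function(i) {
    df <- read.csv(file.path(dir, mf$file[i]))
    force_curve(df$height, df$force, df$segment,
                spring_constant = mf$spring_constant[i],
                trigger_force = mf$trigger_force[i],
                region = mf$region[i], sample = mf$sample[i])
  })
}
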