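# Pulsation: thick-walled-cylinder (Lame) mechanics of the vessel wall.
#
# The artificial artery is modelled as an isotropic, single-layer thick-walled
# cylinder with negligible external pressure. All quantities are differential,
# relative to the diastolic baseline: a transmural pressure change dp produces
# stress changes
#   sigma_r    = -dp
#   sigma_hoop =  dp (ri^2 + ro^2) / (ro^2 - ri^2)
#   sigma_z    = 2 nu dp ri^2 / (ro^2 - ri^2)
# at the interior surface; Hooke's law gives the hoop strain and u = eps * ri
# the radial displacement. Units: radii/displacement um, pressure kPa,
# modulus MPa.

#' Vessel-wall geometry and elastic constants
#'
#' @param r_inner_um inner radius, micrometres.
#' @param r_outer_um outer radius, micrometres; must exceed `r_inner_um`.
#' @param youngs_modulus_mpa Young's modulus of the wall, MPa (constant — the
#'   strain-dependent incremental modulus of real arteries is deliberately
#'   not modelled).
#' @param poisson_ratio dimensionless in \[0, 0.5\]; default 0.5, the
#'   incompressible-elastomer limit appropriate for PDMS and soft tissue.
#' @return Object of class `vessel_geometry`.
#' @examples
#' vessel_geometry(500, 750, 1) # 1-mm artery channel, 0.25-mm wall
#' @export
vessel_geometry <- function(r_inner_um, r_outer_um, youngs_modulus_mpa,
                            poisson_ratio = 0.5) {
  assert_num(r_inner_um, "r_inner_um", len = 1)
  assert_num(r_outer_um, "r_outer_um", len = 1)
  assert_num(youngs_modulus_mpa, "youngs_modulus_mpa", len = 1)
  assert_num(poisson_ratio, "poisson_ratio", len = 1)
  if (r_inner_um <= 0) stop_invalid("r_inner_um must be > 0")
  if (r_outer_um <= r_inner_um)
    stop_invalid("r_outer_um must exceed r_inner_um (degenerate geometry)")
  if (youngs_modulus_mpa <= 0) stop_invalid("youngs_modulus_mpa must be > 0")
  if (poisson_ratio < 0 || poisson_ratio > 0.5)
    stop_invalid("poisson_ratio must lie in [0, 0.5]")
  structure(list(r_inner_um = r_inner_um, r_outer_um = r_outer_um,
                 youngs_modulus_mpa = youngs_modulus_mpa,
                 poisson_ratio = poisson_ratio),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("Vessel geometry: ri = %g um, ro = %g um (wall %g um)\n",
              x$r_inner_um, x$r_outer_um, x$r_outer_um - x$r_inner_um))
  cat(sprintf("  E = %g MPa, nu = %g\n", x$youngs_modulus_mpa, x$poisson_ratio))
  invisible(x)
}

#' Lamé stress state at the interior wall surface
#'
#' Differential radial, hoop and axial (plane) stresses for a transmural
#' pressure change, plus the hoop strain from Hooke's law
#' \eqn{\epsilon_\psi = [\sigma_\psi - \nu(\sigma_r + \sigma_z)]/E}.
#'
#' @param geom a [vessel_geometry()].
#' @param delta_p_kpa transmural pressure change, kPa (scalar or vector).
#' @return list of class `cylinder_stress_state` with `sigma_r_kpa`,
#'   `sigma_hoop_kpa`, `sigma_z_kpa` (kPa) and `strain_hoop`
#'   (dimensionless), each the length of `delta_p_kpa`.
#' @examples
#' cylinder_stresses(vessel_geometry(500, 750, 1), 1)
#' @export
cylinder_stresses <- function(geom, delta_p_kpa) {
  stopifnot(inherits(geom, "vessel_geometry"))
  assert_num(delta_p_kpa, "delta_p_kpa")
  ri2 <- geom$r_inner_um^2
  ro2 <- geom$r_outer_um^2
  denom <- ro2 - ri2
  nu <- geom$poisson_ratio
  sigma_r <- -delta_p_kpa
  sigma_hoop <- delta_p_kpa * (ri2 + ro2) / denom
  sigma_z <- 2 * nu * delta_p_kpa * ri2 / denom
  # E in MPa -> kPa for strain
  strain_hoop <- (sigma_hoop - nu * (sigma_r + sigma_z)) /
    (geom$youngs_modulus_mpa * 1000)
  structure(list(sigma_r_kpa = sigma_r, sigma_hoop_kpa = sigma_hoop,
                 sigma_z_kpa = sigma_z, strain_hoop = strain_hoop),
            class = "cylinder_stress_state")
}

#' Radial displacement of the interior wall surface
#'
#' Closed form
#' \deqn{u = \frac{r_i \Delta p}{E}\left[\frac{r_i^2+r_o^2}{r_o^2-r_i^2}
#'   + \nu\left(1 - \frac{2\nu r_i^2}{r_o^2-r_i^2}\right)\right],}
#' linear in the pressure change and in \eqn{1/E}. Equals the hoop strain
#' from [cylinder_stresses()] times the inner radius.
#'
#' @inheritParams cylinder_stresses
#' @return radial displacement in micrometres, same length as `delta_p_kpa`.
#' @examples
#' radial_displacement(vessel_geometry(500, 750, 1), 1) # 1.35 um
#' @export
radial_displacement <- function(geom, delta_p_kpa) {
  stopifnot(inherits(geom, "vessel_geometry"))
  assert_num(delta_p_kpa, "delta_p_kpa")
  ri2 <- geom$r_inner_um^2
  ro2 <- geom$r_outer_um^2
  denom <- ro2 - ri2
  nu <- geom$poisson_ratio
  bracket <- (ri2 + ro2) / denom + nu * (1 - 2 * nu * ri2 / denom)
  # kPa / (MPa) = 1e-3 strain
  geom$r_inner_um * (delta_p_kpa / (geom$youngs_modulus_mpa * 1000)) * bracket
}

#' Transmural pressure waveform
#'
#' One (or more) cardiac cycles of transmural pressure change relative to the
#' diastolic baseline, on a uniform time grid.
#'
#' @param time_s numeric, seconds, strictly increasing, uniform step.
#' @param delta_p_kpa numeric, kPa, same length. If `unit = "mmHg"` the
#'   values are converted on construction (1 mmHg = 0.133322 kPa).
#' @param unit `"kPa"` (default) or `"mmHg"`.
#' @return Object of class `pressure_waveform` (data frame with `time_s`,
#'   `delta_p_kpa`).
#' @export
pressure_waveform <- function(time_s, delta_p_kpa, unit = c("kPa", "mmHg")) {
  unit <- match.arg(unit)
  assert_num(time_s, "time_s")
  assert_num(delta_p_kpa, "delta_p_kpa", len = length(time_s))
  check_uniform_grid(time_s)
  if (unit == "mmHg") delta_p_kpa <- convert_pressure(delta_p_kpa, "mmHg", "kPa")
  structure(data.frame(time_s = time_s, delta_p_kpa = delta_p_kpa),
            class = c("pressure_waveform", "data.frame"))
}

#' Radial-displacement waveform
#'
#' @param time_s numeric, seconds, uniform grid.
#' @param u_um radial displacement at the interior wall surface, micrometres.
#' @return Object of class `displacement_waveform` (data frame with
#'   `time_s`, `u_um`).
#' @export
displacement_waveform_obj <- function(time_s, u_um) {
  assert_num(time_s, "time_s")
  assert_num(u_um, "u_um", len = length(time_s))
  check_uniform_grid(time_s)
  structure(data.frame(time_s = time_s, u_um = u_um),
            class = c("displacement_waveform", "data.frame"))
}

#' Convert a pressure waveform to a displacement waveform
#'
#' Pointwise application of [radial_displacement()]; the time grid is
#' preserved.
#'
#' @param geom a [vessel_geometry()].
#' @param pw a [pressure_waveform()].
#' @return a `displacement_waveform`.
#' @export
displacement_waveform <- function(geom, pw) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (!inherits(pw, "pressure_waveform"))
    stop_invalid("`pw` must be a pressure_waveform")
  if (nrow(pw) == 0L) stop_invalid("pressure waveform is empty")
  displacement_waveform_obj(pw$time_s, radial_displacement(geom, pw$delta_p_kpa))
}

#' Read / write waveform CSVs
#'
#' `read_pressure_csv()` expects columns `time_s` and either `delta_p_kpa`
#' or `pressure_mmhg` (converted with 0.133322 kPa/mmHg).
#' `write_waveform_csv()` writes any of the waveform data frames with their
#' unit-bearing column names.
#'
#' @param path CSV file path.
#' @return `read_pressure_csv()` returns a [pressure_waveform()].
#' @export
read_pressure_csv <- function(path) {
  d <- read.csv(path)
  if (!"time_s" %in% names(d)) stop_invalid("CSV needs a `time_s` column: ", path)
  if ("delta_p_kpa" %in% names(d)) {
    pressure_waveform(d$time_s, d$delta_p_kpa)
  } else if ("pressure_mmhg" %in% names(d)) {
    pressure_waveform(d$time_s, d$pressure_mmhg, unit = "mmHg")
  } else {
    stop_invalid("CSV needs `delta_p_kpa` or `pressure_mmhg`: ", path)
  }
}

#' @rdname read_pressure_csv
#' @param wf a waveform data frame.
#' @export
write_waveform_csv <- function(wf, path) {
  write.csv(as.data.frame(wf), path, row.names = FALSE)
  invisible(path)
}

#' Write / read vessel geometry as JSON
#'
#' @param geom a [vessel_geometry()].
#' @param path JSON file path.
#' @export
write_vessel_geometry_json <- function(geom, path) {
  stopifnot(inherits(geom, "vessel_geometry"))
  jsonlite::write_json(unclass(geom), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vessel_geometry_json
#' @export
read_vessel_geometry_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vessel_geometry(x$r_inner_um, x$r_outer_um, x$youngs_modulus_mpa,
                  x$poisson_ratio %||% 0.5)
}
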