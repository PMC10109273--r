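# Mechanics: Young's modulus from tensile data and curing-agent calibration.
#
# PDMS stiffness is tuned by the base : curing-agent mixing ratio. The modulus
# is the slope of the stress-strain curve in the linear-elastic region
# (strain 0 to 0.05), and modulus vs curing-agent concentration is itself
# linear, so a two-step linear calibration maps a target vessel modulus to a
# formulation.

#' Tensile stress–strain curve
#'
#' Container for a uniaxial tensile test. Strain is stored as a dimensionless
#' fraction (5% elongation is 0.05), stress in MPa.
#'
#' @param strain numeric, dimensionless fraction, strictly increasing,
#'   `strain[1] >= 0`.
#' @param stress_mpa numeric, MPa, same length as `strain`.
#' @return An object of class `stress_strain_curve` (a data frame with
#'   columns `strain`, `stress_mpa`).
#' @seealso [fit_youngs_modulus()], [gen_stress_strain()]
#' @export
stress_strain_curve <- function(strain, stress_mpa) {
  assert_num(strain, "strain")
  assert_num(stress_mpa, "stress_mpa", len = length(strain))
  if (length(strain) < 2L) stop_invalid("need at least 2 points")
  if (strain[1] < 0) stop_invalid("strain must start at >= 0")
  if (any(diff(strain) <= 0)) stop_invalid("strain must be strictly increasing")
  structure(data.frame(strain = strain, stress_mpa = stress_mpa),
            class = c("stress_strain_curve", "data.frame"))
}

#' Young's modulus from the linear-elastic region
#'
#' Ordinary-least-squares slope of stress vs strain restricted to the
#' linear-elastic strain window (default 0–0.05, i.e. 0%–5% elongation),
#' following Hooke's law \eqn{\sigma = E \epsilon}.
#'
#' @param curve a [stress_strain_curve()].
#' @param strain_window length-2 numeric, inclusive strain interval used for
#'   the fit. Default `c(0, 0.05)`.
#' @return Young's modulus in MPa (OLS slope with free intercept).
#' @examples
#' cv <- stress_strain_curve(seq(0, 0.05, by = 0.005),
#'                           0.5 * seq(0, 0.05, by = 0.005))
#' fit_youngs_modulus(cv) # 0.5
#' @export
fit_youngs_modulus <- function(curve, strain_window = c(0, 0.05)) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  assert_num(strain_window, "strain_window", len = 2)
  if (strain_window[1] >= strain_window[2])
    stop_invalid("strain_window must be an increasing interval")
  in_win <- curve$strain >= strain_window[1] & curve$strain <= strain_window[2]
  if (sum(in_win) < 3L)
    stop_invalid("fewer than 3 points in strain window [",
                 strain_window[1], ", ", strain_window[2], "]")
  fit <- lm(stress_mpa ~ strain, data = curve[in_win, , drop = FALSE])
  unname(coef(fit)[["strain"]])
}

#' Linear calibration of Young's modulus vs curing-agent concentration
#'
#' @param slope MPa per % curing agent.
#' @param intercept MPa.
#' @param r_squared coefficient of determination of the generating fit,
#'   `NA` when constructed from printed coefficients.
#' @param valid_range length-2 numeric, the concentration interval (%) the
#'   calibration was fitted on; inversions outside it warn.
#' @return Object of class `elastic_calibration`.
#' @examples
#' # calibration line for plain PDMS
#' elastic_calibration(slope = 0.18, intercept = -0.39)
#' @export
elastic_calibration <- function(slope, intercept, r_squared = NA_real_,
                                valid_range = c(NA_real_, NA_real_)) {
  assert_num(slope, "slope", len = 1)
  assert_num(intercept, "intercept", len = 1)
  if (!all(is.na(valid_range))) {
    assert_num(valid_range, "valid_range", len = 2)
    if (valid_range[1] < 0) stop_invalid("valid_range lower bound must be >= 0")
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop_invalid("r_squared must lie in [0, 1]")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, valid_range = valid_range),
            class = "elastic_calibration")
}

#' @export
print.elastic_calibration <- function(x, ...) {
  cat(sprintf("Elastic calibration: E = %.4g MPa/%% * c %+.4g MPa\n",
              x$slope, x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  if (!all(is.na(x$valid_range)))
    cat(sprintf("  fitted on c in [%.3g, %.3g] %%\n",
                x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Fit the modulus vs curing-agent calibration line
#'
#' OLS with free intercept of Young's modulus (MPa) on curing-agent
#' concentration (%).
#'
#' @param concentration_pct numeric, % curing agent.
#' @param modulus_mpa numeric, MPa, same length.
#' @return An [elastic_calibration()] with `r_squared` and
#'   `valid_range = range(concentration_pct)`.
#' @examples
#' fit_elastic_calibration(c(2.5, 10), c(0.05, 1.42))
#' @export
fit_elastic_calibration <- function(concentration_pct, modulus_mpa) {
  assert_num(concentration_pct, "concentration_pct")
  assert_num(modulus_mpa, "modulus_mpa", len = length(concentration_pct))
  if (length(unique(concentration_pct)) < 2L)
    stop_degenerate("all concentrations identical; calibration line is undetermined")
  fit <- lm(modulus_mpa ~ concentration_pct)
  r2 <- if (length(concentration_pct) > 2L || var(modulus_mpa) > 0) {
    1 - sum(residuals(fit)^2) / sum((modulus_mpa - mean(modulus_mpa))^2)
  } else NA_real_
  elastic_calibration(slope = unname(coef(fit)[["concentration_pct"]]),
                      intercept = unname(coef(fit)[["(Intercept)"]]),
                      r_squared = r2,
                      valid_range = range(concentration_pct))
}

#' Curing-agent concentration for a target Young's modulus
#'
#' Inverts the calibration line: \eqn{c = (E - b)/a}. Warns (does not fail)
#' when the result lies outside the calibrated concentration range —
#' formulation tables routinely extrapolate slightly below the softest tested
#' mix.
#'
#' @param target_modulus_mpa target Young's modulus, MPa.
#' @param cal an [elastic_calibration()].
#' @param digits decimals for the `reported` value (half-up rounding, one
#'   decimal by default, matching formulation-table precision).
#' @return list with `concentration_pct` (full precision) and `reported`
#'   (rounded).
#' @examples
#' cal <- elastic_calibration(0.18, -0.39)
#' invert_calibration(1, cal)$reported # 7.7 % for an artery-stiffness layer
#' @export
invert_calibration <- function(target_modulus_mpa, cal, digits = 1) {
  stopifnot(inherits(cal, "elastic_calibration"))
  assert_num(target_modulus_mpa, "target_modulus_mpa", len = 1)
  if (cal$slope == 0)
    stop_invalid("calibration slope is zero; line is not invertible")
  conc <- (target_modulus_mpa - cal$intercept) / cal$slope
  if (!all(is.na(cal$valid_range)) &&
      (conc < cal$valid_range[1] || conc > cal$valid_range[2]))
    warning(sprintf("concentration %.3g%% lies outside calibrated range [%.3g, %.3g]%%",
                    conc, cal$valid_range[1], cal$valid_range[2]))
  list(concentration_pct = conc, reported = round_half_up(conc, digits))
}

#' Predicted Young's modulus at a curing-agent concentration
#'
#' Forward evaluation \eqn{E = a c + b}; exact inverse of
#' [invert_calibration()].
#'
#' @param concentration_pct % curing agent.
#' @param cal an [elastic_calibration()].
#' @return modulus in MPa.
#' @export
predict_modulus <- function(concentration_pct, cal) {
  stopifnot(inherits(cal, "elastic_calibration"))
  assert_num(concentration_pct, "concentration_pct")
  cal$slope * concentration_pct + cal$intercept
}

#' Read a stress–strain curve from CSV
#'
#' Expects columns `strain` (fraction) and `stress_mpa`.
#'
#' @param path CSV file path.
#' @return a [stress_strain_curve()].
#' @export
read_stress_strain_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("strain", "stress_mpa") %in% names(d)))
    stop_invalid("CSV must have columns `strain`, `stress_mpa`: ", path)
  stress_strain_curve(d$strain, d$stress_mpa)
}

#' Read elastic calibration points from CSV
#'
#' Expects columns `curing_agent_pct` and `youngs_modulus_mpa`.
#'
#' @param path CSV file path.
#' @return data frame with the two columns.
#' @export
read_elastic_points_csv <- function(path) {
  d <- read.csv(path)
  need <- c("curing_agent_pct", "youngs_modulus_mpa")
  if (!all(need %in% names(d)))
    stop_invalid("CSV must have columns `curing_agent_pct`, `youngs_modulus_mpa`: ", path)
  d[need]
}

#' Write / read an elastic calibration as JSON
#'
#' @param cal an [elastic_calibration()].
#' @param path JSON file path.
#' @return `write_elastic_calibration_json()` returns `path` invisibly;
#'   `read_elastic_calibration_json()` returns the calibration.
#' @export
write_elastic_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "elastic_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_elastic_calibration_json
#' @export
read_elastic_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  elastic_calibration(slope = x$slope, intercept = x$intercept,
                      r_squared = x$r_squared %||% NA_real_,
                      valid_range = unlist(x$valid_range %||% c(NA_real_, NA_real_)))
}
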