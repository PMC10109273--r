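# Pump control: linear voltage -> expansion calibration of the piezo
# micropumps and synthesis of discretised drive-voltage sequences.
#
# The pumps run at a fixed 100 Hz; flow (and hence channel expansion) is
# controlled purely by the drive amplitude, 0-250 Vpp. Expansion is linear in
# voltage, so a single through-origin slope per channel diameter suffices.

#' Micropump voltage–expansion calibration
#'
#' @param slope_um_per_v radial expansion per volt (peak-to-peak), um/V;
#'   must be `>= 0`.
#' @param intercept_um expansion at 0 V, um; default 0 (the physical pump
#'   produces no flow at zero drive).
#' @param channel_diameter_um label: the channel diameter this calibration
#'   belongs to (um), or `NA`.
#' @param voltage_limits hardware drive range, Vpp; default `c(0, 250)`.
#' @param r_squared coefficient of determination of the generating fit.
#' @return Object of class `pump_calibration`.
#' @examples
#' pump_calibration(0.26, channel_diameter_um = 1000) # artery channel
#' @export
pump_calibration <- function(slope_um_per_v, intercept_um = 0,
                             channel_diameter_um = NA_real_,
                             voltage_limits = c(0, 250),
                             r_squared = NA_real_) {
  assert_num(slope_um_per_v, "slope_um_per_v", len = 1)
  assert_num(intercept_um, "intercept_um", len = 1)
  assert_num(voltage_limits, "voltage_limits", len = 2)
  if (slope_um_per_v < 0) stop_invalid("slope_um_per_v must be >= 0")
  if (voltage_limits[1] < 0 || voltage_limits[2] <= voltage_limits[1])
    stop_invalid("voltage_limits must be an increasing interval with lower bound >= 0")
  structure(list(slope_um_per_v = slope_um_per_v, intercept_um = intercept_um,
                 channel_diameter_um = channel_diameter_um,
                 voltage_limits = voltage_limits, r_squared = r_squared),
            class = "pump_calibration")
}

#' @export
print.pump_calibration <- function(x, ...) {
  cat(sprintf("Pump calibration: u = %.4g um/V * V %+.4g um\n",
              x$slope_um_per_v, x$intercept_um))
  if (!is.na(x$channel_diameter_um))
    cat(sprintf("  channel diameter: %g um\n", x$channel_diameter_um))
  cat(sprintf("  voltage limits: [%g, %g] Vpp\n",
              x$voltage_limits[1], x$voltage_limits[2]))
  invisible(x)
}

#' Fit a pump calibration from (voltage, expansion) points
#'
#' Least-squares line of expansion on drive voltage. The default is a
#' through-origin fit — the physical calibration has no offset: zero drive,
#' zero expansion. A free-intercept mode is available for diagnostics.
#'
#' @param voltage_vpp numeric, drive voltages, Vpp.
#' @param expansion_um numeric, radial expansion, um, same length.
#' @param through_origin logical, default `TRUE`.
#' @param channel_diameter_um optional label, um.
#' @param voltage_limits hardware range checked against the data and stored
#'   in the result; default `c(0, 250)`.
#' @return a [pump_calibration()].
#' @examples
#' v <- seq(0, 250, by = 10)
#' fit_pump_calibration(v, 0.26 * v)
#' @export
fit_pump_calibration <- function(voltage_vpp, expansion_um,
                                 through_origin = TRUE,
                                 channel_diameter_um = NA_real_,
                                 voltage_limits = c(0, 250)) {
  assert_num(voltage_vpp, "voltage_vpp")
  assert_num(expansion_um, "expansion_um", len = length(voltage_vpp))
  if (length(voltage_vpp) < 2L) stop_invalid("need at least 2 points")
  if (length(unique(voltage_vpp)) < 2L)
    stop_degenerate("all voltages identical; slope is undetermined")
  if (any(voltage_vpp < voltage_limits[1] - 1e-9) ||
      any(voltage_vpp > voltage_limits[2] + 1e-9))
    stop_invalid("calibration voltages outside limits [",
                 voltage_limits[1], ", ", voltage_limits[2], "] Vpp")
  if (through_origin) {
    fit <- lm(expansion_um ~ 0 + voltage_vpp)
    slope <- unname(coef(fit)[["voltage_vpp"]])
    intercept <- 0
  } else {
    fit <- lm(expansion_um ~ voltage_vpp)
    slope <- unname(coef(fit)[["voltage_vpp"]])
    intercept <- unname(coef(fit)[["(Intercept)"]])
  }
  ss_tot <- sum((expansion_um - mean(expansion_um))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  pump_calibration(slope_um_per_v = max(slope, 0), intercept_um = intercept,
                   channel_diameter_um = channel_diameter_um,
                   voltage_limits = voltage_limits, r_squared = r2)
}

#' Drive voltage for a requested channel expansion
#'
#' Inverts the calibration, \eqn{V = (u - b)/a}, then clips into the
#' hardware voltage limits (clipping, not failure, mirrors what the driver
#' electronics do; negative requested expansions clip to the lower limit).
#'
#' @param expansion_um requested radial expansion, um (vectorised).
#' @param cal a [pump_calibration()] with positive slope.
#' @return voltage(s) in Vpp, within `cal$voltage_limits`. The number of
#'   clipped entries is attached as attribute `"n_clipped"`.
#' @examples
#' voltage_for_expansion(1.35, pump_calibration(0.26)) # 5.19 Vpp
#' @export
voltage_for_expansion <- function(expansion_um, cal) {
  stopifnot(inherits(cal, "pump_calibration"))
  assert_num(expansion_um, "expansion_um")
  if (cal$slope_um_per_v == 0)
    stop_invalid("calibration slope is zero; not invertible")
  v_raw <- (expansion_um - cal$intercept_um) / cal$slope_um_per_v
  v <- pmin(pmax(v_raw, cal$voltage_limits[1]), cal$voltage_limits[2])
  structure(v, n_clipped = sum(v != v_raw))
}

#' Expansion produced by a drive voltage
#'
#' Forward evaluation \eqn{u = a V + b}; inverse of
#' [voltage_for_expansion()] inside the unclipped range.
#'
#' @param voltage_vpp drive voltage, Vpp.
#' @param cal a [pump_calibration()].
#' @return expansion in um.
#' @export
expansion_for_voltage <- function(voltage_vpp, cal) {
  stopifnot(inherits(cal, "pump_calibration"))
  assert_num(voltage_vpp, "voltage_vpp")
  cal$slope_um_per_v * voltage_vpp + cal$intercept_um
}

#' Discretised pump-voltage sequence
#'
#' @param time_s bin start times, seconds, uniform step (default step 50 ms).
#' @param voltage_vpp drive voltage per bin, Vpp, within `voltage_limits`.
#' @param drive_frequency_hz pump operating frequency carried as metadata
#'   (amplitude, not frequency, is the control variable); default 100 Hz.
#' @param voltage_limits allowed range, default `c(0, 250)` Vpp.
#' @return Object of class `voltage_sequence` (data frame `time_s`,
#'   `voltage_vpp` with attributes).
#' @export
voltage_sequence <- function(time_s, voltage_vpp, drive_frequency_hz = 100,
                             voltage_limits = c(0, 250)) {
  assert_num(time_s, "time_s")
  assert_num(voltage_vpp, "voltage_vpp", len = length(time_s))
  check_uniform_grid(time_s)
  if (any(voltage_vpp < voltage_limits[1] - 1e-9) ||
      any(voltage_vpp > voltage_limits[2] + 1e-9))
    stop_invalid("voltages outside limits [", voltage_limits[1], ", ",
                 voltage_limits[2], "] Vpp")
  structure(data.frame(time_s = time_s, voltage_vpp = voltage_vpp),
            drive_frequency_hz = drive_frequency_hz,
            voltage_limits = voltage_limits,
            class = c("voltage_sequence", "data.frame"))
}

#' Synthesize a discretised voltage sequence from a displacement waveform
#'
#' Bins the displacement waveform into windows of `step_s` (default 50 ms,
#' the pump controller's update interval), aggregates each bin, and converts
#' the binned displacement to drive voltage with
#' [voltage_for_expansion()]. Out-of-range requests are clipped to the
#' hardware limits; the clip count is reported via a message and the
#' `"n_clipped"` attribute.
#'
#' @param dw a `displacement_waveform`.
#' @param cal a [pump_calibration()].
#' @param step_s output step, seconds; default 0.05. Must be `>=` the
#'   waveform sampling interval.
#' @param aggregate `"mean"` (default, mean displacement over the bin) or
#'   `"hold"` (sample-and-hold at bin start).
#' @return a [voltage_sequence()] with one row per bin; `time_s` is the bin
#'   start.
#' @export
synthesize_voltage_sequence <- function(dw, cal, step_s = 0.05,
                                        aggregate = c("mean", "hold")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(dw, "displacement_waveform"))
    stop_invalid("`dw` must be a displacement_waveform")
  stopifnot(inherits(cal, "pump_calibration"))
  assert_num(step_s, "step_s", len = 1)
  n <- nrow(dw)
  if (n == 0L) stop_invalid("displacement waveform is empty")
  dt <- if (n > 1L) dw$time_s[2] - dw$time_s[1] else step_s
  if (dt > step_s + 1e-12)
    stop_invalid("waveform sampling interval (", dt,
                 " s) is coarser than the requested step (", step_s, " s)")
  t0 <- dw$time_s[1]
  bin <- floor((dw$time_s - t0) / step_s + 1e-9)
  # keep bins in time order (factor levels sort as character otherwise)
  binf <- factor(bin, levels = sort(unique(bin)))
  agg_fun <- if (aggregate == "mean") mean else function(x) x[1]
  u_bin <- vapply(split(dw$u_um, binf), agg_fun, numeric(1))
  v <- voltage_for_expansion(unname(u_bin), cal)
  n_clip <- attr(v, "n_clipped")
  if (n_clip > 0)
    message(sprintf("synthesize_voltage_sequence: %d of %d bins clipped to [%g, %g] Vpp",
                    n_clip, length(v), cal$voltage_limits[1], cal$voltage_limits[2]))
  out <- voltage_sequence(t0 + sort(unique(bin)) * step_s, as.numeric(v),
                          voltage_limits = cal$voltage_limits)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Pressure pulse to pump-voltage sequence
#'
#' End-to-end pipeline: [displacement_waveform()] then
#' [synthesize_voltage_sequence()]. Linear in the pressure change until
#' voltage clipping sets in.
#'
#' @param pw a [pressure_waveform()].
#' @param geom a [vessel_geometry()].
#' @param cal a [pump_calibration()].
#' @inheritParams synthesize_voltage_sequence
#' @return a [voltage_sequence()]; the intermediate displacement waveform is
#'   attached as attribute `"displacement"`.
#' @examples
#' pw <- pressure_waveform(seq(0, 0.95, by = 0.05), rep(1, 20))
#' pulse_to_voltage(pw, vessel_geometry(500, 750, 1), pump_calibration(0.26))
#' @export
pulse_to_voltage <- function(pw, geom, cal, step_s = 0.05,
                             aggregate = c("mean", "hold")) {
  dw <- displacement_waveform(geom, pw)
  vs <- synthesize_voltage_sequence(dw, cal, step_s = step_s,
                                    aggregate = aggregate)
  attr(vs, "displacement") <- dw
  vs
}

#' Read pump-calibration points from CSV
#'
#' Expects columns `voltage_vpp`, `expansion_um`.
#'
#' @param path CSV file path.
#' @return data frame with the two columns.
#' @export
read_pump_points_csv <- function(path) {
  d <- read.csv(path)
  need <- c("voltage_vpp", "expansion_um")
  if (!all(need %in% names(d)))
    stop_invalid("CSV must have columns `voltage_vpp`, `expansion_um`: ", path)
  d[need]
}

#' Write / read a pump calibration as JSON
#'
#' @param cal a [pump_calibration()].
#' @param path JSON file path.
#' @export
write_pump_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "pump_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_pump_calibration_json
#' @export
read_pump_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pump_calibration(slope_um_per_v = x$slope_um_per_v,
                   intercept_um = x$intercept_um %||% 0,
                   channel_diameter_um = x$channel_diameter_um %||% NA_real_,
                   voltage_limits = unlist(x$voltage_limits %||% c(0, 250)),
                   r_squared = x$r_squared %||% NA_real_)
}
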