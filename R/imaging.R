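# Imaging: sub-pixel channel-diameter measurement from grayscale images.
#
# A fluid channel photographed in transmission appears as a dark band on a
# bright background. The diameter is read from gray-value profiles of pixel
# lines perpendicular to the channel: robust background and trough levels
# (95th / 5th percentiles), a half-depth threshold midway between them, and
# linearly interpolated sub-pixel crossings. Several evenly spaced profile
# lines are averaged per image.

#' Grayscale channel image
#'
#' @param pixels numeric matrix (rows x cols) with intensities in \[0, 1\],
#'   or a rows x cols x 3 RGB array (converted to luma by Rec. 601:
#'   0.299 R + 0.587 G + 0.114 B).
#' @param pixel_scale_um_per_px physical size of one pixel, um; `> 0`.
#' @param channel_axis `"horizontal"` (channel runs along image rows;
#'   profiles are columns) or `"vertical"`.
#' @param invert logical; set `TRUE` for a bright channel on a dark
#'   background (intensities are flipped on construction).
#' @return Object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_scale_um_per_px,
                          channel_axis = c("horizontal", "vertical"),
                          invert = FALSE) {
  channel_axis <- match.arg(channel_axis)
  if (length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    pixels <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] +
      0.114 * pixels[, , 3]
  }
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_invalid("pixels must be a numeric matrix or RGB array")
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1)
    stop_invalid("intensities must lie within [0, 1]")
  assert_num(pixel_scale_um_per_px, "pixel_scale_um_per_px", len = 1)
  if (pixel_scale_um_per_px <= 0) stop_invalid("pixel_scale_um_per_px must be > 0")
  if (invert) pixels <- 1 - pixels
  structure(list(pixels = pixels,
                 pixel_scale_um_per_px = pixel_scale_um_per_px,
                 channel_axis = channel_axis),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("Channel image: %d x %d px, %g um/px, %s channel\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_scale_um_per_px,
              x$channel_axis))
  invisible(x)
}

#' Gray-value profile perpendicular to the channel
#'
#' @param img a [channel_image()].
#' @param line_index pixel index along the channel axis (column index for a
#'   horizontal channel, row index for a vertical one).
#' @return numeric vector of intensities along the perpendicular line.
#' @export
extract_profile <- function(img, line_index) {
  stopifnot(inherits(img, "channel_image"))
  assert_num(line_index, "line_index", len = 1)
  n_along <- if (img$channel_axis == "horizontal") ncol(img$pixels) else nrow(img$pixels)
  if (line_index < 1 || line_index > n_along || line_index != round(line_index))
    stop_invalid("line_index out of bounds [1, ", n_along, "]")
  if (img$channel_axis == "horizontal") img$pixels[, line_index]
  else img$pixels[line_index, ]
}

#' Channel diameter from a single gray-value profile
#'
#' Background level is the 95th intensity percentile of the profile; the
#' trough level is the 5th percentile within a 31-px window around the
#' global minimum (percentiles resist dust specks and shot noise, and the
#' localised trough window keeps narrow channels from being swamped by
#' background samples). The edge criterion is the half-depth threshold
#' midway between the two levels. The two
#' threshold crossings flanking the single below-threshold trough are
#' located with linear sub-pixel interpolation and their separation, times
#' the pixel scale, is the diameter. The estimate is invariant to global
#' linear intensity rescaling.
#'
#' @param profile numeric intensity vector.
#' @param pixel_scale_um_per_px um per pixel.
#' @param min_trough_px minimum run length (px) below threshold for a run to
#'   count as a trough; default 2, rejecting single-pixel noise spikes.
#' @param smooth_sigma_px light Gaussian pre-smoothing of the profile
#'   (pixels, default 0.8). Symmetric, so it does not displace the
#'   half-depth crossings of a symmetric edge, but it suppresses the
#'   outward run-extension bias that pixel noise otherwise induces at the
#'   threshold. Set 0 to disable.
#' @return diameter in um.
#' @export
diameter_from_profile <- function(profile, pixel_scale_um_per_px,
                                  min_trough_px = 2, smooth_sigma_px = 0.8) {
  assert_num(profile, "profile")
  n <- length(profile)
  if (n < 3L) stop_invalid("profile too short")
  if (smooth_sigma_px > 0) {
    rad <- max(1L, ceiling(4 * smooth_sigma_px))
    k <- exp(-(-rad:rad)^2 / (2 * smooth_sigma_px^2))
    k <- k / sum(k)
    padded <- c(rep(profile[1], rad), profile, rep(profile[n], rad))
    profile <- as.numeric(stats::filter(padded, k, sides = 2))[(rad + 1):(rad + n)]
  }
  bg <- as.numeric(quantile(profile, 0.95, names = FALSE))
  # trough level: 5th percentile inside a window around the global minimum —
  # a global 5th percentile sits in the background when the channel covers
  # less than 5% of the profile
  i_min <- which.min(profile)
  win <- max(1L, i_min - 15L):min(n, i_min + 15L)
  trough <- as.numeric(quantile(profile[win], 0.05, names = FALSE))
  if (bg - trough <= .Machine$double.eps * 100 ||
      (bg - trough) < 1e-3 * max(bg, 1e-12))
    stop(errorCondition("no channel detected: profile is flat",
                        class = c("pulsephantom_detection_failure",
                                  "pulsephantom_error")))
  thr <- (bg + trough) / 2
  below <- profile < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_trough_px
  if (!any(keep))
    stop(errorCondition("no channel detected: no below-threshold trough",
                        class = c("pulsephantom_detection_failure",
                                  "pulsephantom_error")))
  if (sum(keep) > 1L)
    stop(errorCondition(sprintf("ambiguous profile: %d troughs detected", sum(keep)),
                        class = c("pulsephantom_ambiguity_error",
                                  "pulsephantom_error")))
  i1 <- starts[keep]
  i2 <- ends[keep]
  if (i1 == 1L || i2 == n)
    stop(errorCondition("trough touches the profile edge; channel not fully imaged",
                        class = c("pulsephantom_detection_failure",
                                  "pulsephantom_error")))
  # sub-pixel crossings: linear interpolation between the bracketing samples
  x_left <- (i1 - 1) + (profile[i1 - 1] - thr) / (profile[i1 - 1] - profile[i1])
  x_right <- i2 + (thr - profile[i2]) / (profile[i2 + 1] - profile[i2])
  w_half <- x_right - x_left
  (w_half + trough_saturation_correction(profile, bg, trough, x_left, x_right)) *
    pixel_scale_um_per_px
}

# all interpolated positions where `p` crosses `level` within index range
#' @noRd
level_crossings <- function(p, level, from, to) {
  idx <- from:(to - 1L)
  straddle <- (p[idx] - level) * (p[idx + 1L] - level) < 0
  idx <- idx[straddle]
  idx + (p[idx] - level) / (p[idx] - p[idx + 1L])
}

# Half-depth width of a blurred box underestimates saturation: when the
# trough is narrow relative to the edge blur it never reaches the full
# channel depth, the mid-level threshold sits too close to the background,
# and both crossings move outward. Model each edge as an error function:
# with edge scale sigma and saturation rho = observed/true depth,
#   rho = 2 Phi(W / (2 sigma)) - 1,   W = W_half + 2 sigma Phi^-1(rho / 2).
# sigma follows from the 30%/70%-depth crossing separation; the pair
# (sigma, rho) is solved by fixed point. For deep troughs rho -> 1 and the
# correction vanishes, so saturated measurements are untouched.
#' @noRd
trough_saturation_correction <- function(profile, bg, trough, x_left, x_right) {
  n <- length(profile)
  depth <- bg - trough
  seg_l <- max(1L, floor(x_left) - 25L):min(n, ceiling(x_left) + 25L)
  seg_r <- max(1L, floor(x_right) - 25L):min(n, ceiling(x_right) + 25L)
  pick <- function(xs, target) if (length(xs)) xs[which.min(abs(xs - target))] else NA_real_
  x30l <- pick(level_crossings(profile, bg - 0.3 * depth, seg_l[1], tail(seg_l, 1)), x_left)
  x70l <- pick(level_crossings(profile, bg - 0.7 * depth, seg_l[1], tail(seg_l, 1)), x_left)
  x30r <- pick(level_crossings(profile, bg - 0.3 * depth, seg_r[1], tail(seg_r, 1)), x_right)
  x70r <- pick(level_crossings(profile, bg - 0.7 * depth, seg_r[1], tail(seg_r, 1)), x_right)
  s_edges <- c(x70l - x30l, x30r - x70r)
  s_edges <- s_edges[is.finite(s_edges) & s_edges > 0]
  if (length(s_edges) == 0L) return(0)
  s_meas <- mean(s_edges)
  w_half <- x_right - x_left
  rho <- 1
  sigma <- NA_real_
  for (i in 1:12) {
    denom <- stats::qnorm(0.7 * rho) - stats::qnorm(0.3 * rho)
    if (!is.finite(denom) || denom <= 0) return(0)
    sigma <- s_meas / denom
    w_true <- w_half + 2 * sigma * stats::qnorm(rho / 2)
    if (!is.finite(w_true) || w_true <= 0) return(0)
    rho <- min(max(2 * stats::pnorm(w_true / (2 * sigma)) - 1, 0.05), 1)
  }
  corr <- 2 * sigma * stats::qnorm(rho / 2)
  if (!is.finite(corr)) 0 else max(corr, -0.5 * w_half)
}

#' Measure a channel diameter from an image
#'
#' Applies [diameter_from_profile()] to `n_lines` evenly spaced profile
#' lines and reports their mean and standard deviation. Fails if more than
#' half the lines yield no detection.
#'
#' @param img a [channel_image()].
#' @param n_lines number of profile lines, default 11.
#' @return Object of class `diameter_estimate`: list with `diameter_um`
#'   (mean), `per_line_diameters_um`, `sd_um`, `n_lines` (successful lines).
#' @export
measure_channel_diameter <- function(img, n_lines = 11) {
  stopifnot(inherits(img, "channel_image"))
  if (n_lines < 1) stop_invalid("n_lines must be >= 1")
  n_along <- if (img$channel_axis == "horizontal") ncol(img$pixels) else nrow(img$pixels)
  idx <- unique(round(seq(1, n_along, length.out = n_lines + 2)[-c(1, n_lines + 2)]))
  if (n_lines == 1L) idx <- round((n_along + 1) / 2)
  res <- lapply(idx, function(i) {
    tryCatch(diameter_from_profile(extract_profile(img, i),
                                   img$pixel_scale_um_per_px),
             pulsephantom_error = function(e) NA_real_)
  })
  d <- unlist(res)
  ok <- !is.na(d)
  if (sum(ok) < length(idx) / 2)
    stop(errorCondition(sprintf("measurement failed on %d of %d profile lines",
                                sum(!ok), length(idx)),
                        class = c("pulsephantom_measurement_failure",
                                  "pulsephantom_error")))
  d <- d[ok]
  structure(list(diameter_um = mean(d),
                 per_line_diameters_um = d,
                 sd_um = if (length(d) > 1L) sd(d) else 0,
                 n_lines = length(d)),
            class = "diameter_estimate")
}

#' @export
print.diameter_estimate <- function(x, ...) {
  cat(sprintf("Channel diameter: %.2f um (sd %.2f um, %d lines)\n",
              x$diameter_um, x$sd_um, x$n_lines))
  invisible(x)
}

#' Pump calibration from an image series
#'
#' Measures the channel diameter at each drive voltage, converts diameter
#' change into radial expansion — half the diameter change, the motion of
#' one wall — relative to the baseline image, and delegates to
#' [fit_pump_calibration()].
#'
#' @param voltages_vpp numeric drive voltages, one per image.
#' @param images list of [channel_image()], same length.
#' @param baseline_voltage voltage of the reference (unexpanded) image;
#'   default 0. Must be present in `voltages_vpp`.
#' @param n_lines profile lines per image, default 11.
#' @param through_origin passed to [fit_pump_calibration()].
#' @return a [pump_calibration()]; the per-voltage diameters are attached
#'   as attribute `"series"` (data frame).
#' @export
expansion_series <- function(voltages_vpp, images, baseline_voltage = 0,
                             n_lines = 11, through_origin = TRUE) {
  assert_num(voltages_vpp, "voltages_vpp")
  if (length(images) != length(voltages_vpp))
    stop_invalid("need one image per voltage")
  ib <- which(voltages_vpp == baseline_voltage)
  if (length(ib) == 0L)
    stop_invalid("baseline image (voltage ", baseline_voltage, " Vpp) missing")
  d <- vapply(images, function(im)
    measure_channel_diameter(im, n_lines = n_lines)$diameter_um, numeric(1))
  d0 <- mean(d[ib])
  expansion <- (d - d0) / 2
  cal <- fit_pump_calibration(voltages_vpp, expansion,
                              through_origin = through_origin)
  attr(cal, "series") <- data.frame(voltage_vpp = voltages_vpp,
                                    diameter_um = d, expansion_um = expansion)
  cal
}

#' Diameter-estimate JSON output
#'
#' @param est a `diameter_estimate`.
#' @param path JSON file path.
#' @export
write_diameter_json <- function(est, path) {
  stopifnot(inherits(est, "diameter_estimate"))
  jsonlite::write_json(unclass(est), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
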