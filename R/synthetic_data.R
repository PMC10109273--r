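# Synthetic data: seeded generators for every input the pipeline consumes.
#
# Each generator has the statistical structure its consuming stage assumes
# (linear-elastic tensile curves, linear pump response, concentration-linear
# dopant spectra, a one-cycle arterial pulse with systolic upstroke and
# dicrotic notch, dark-channel images), so every stage round-trips its
# generating parameters in tests without any instrument data.

#' Synthetic tensile stress–strain curve
#'
#' \eqn{\sigma = E\epsilon + } Gaussian noise; linear through (and beyond)
#' the 0–5% elastic window.
#'
#' @param modulus_mpa generating Young's modulus, MPa, `> 0`.
#' @param max_strain upper strain (fraction), default 0.1.
#' @param n_points samples, default 200.
#' @param noise_sd additive stress noise, MPa, default 0.
#' @param seed RNG seed; same seed and arguments give identical output.
#' @return a [stress_strain_curve()].
#' @export
gen_stress_strain <- function(modulus_mpa, max_strain = 0.1, n_points = 200,
                              noise_sd = 0, seed = 1) {
  if (modulus_mpa <= 0) stop_invalid("modulus_mpa must be > 0")
  strain <- seq(0, max_strain, length.out = n_points)
  eps <- if (noise_sd > 0) withr::with_seed(seed, rnorm(n_points, 0, noise_sd)) else 0
  stress_strain_curve(strain, modulus_mpa * strain + eps)
}

#' Synthetic pump-calibration points
#'
#' \eqn{u = k V + } Gaussian noise, clipped at `u >= 0` (a channel cannot
#' contract below its resting diameter under forward pumping).
#'
#' @param slope_um_per_v generating slope, um/V, `>= 0`.
#' @param voltages_vpp drive voltages; default 0–250 Vpp in steps of 10.
#' @param noise_sd expansion noise, um, default 0.
#' @param seed RNG seed.
#' @return data frame `voltage_vpp`, `expansion_um`.
#' @export
gen_calibration_points <- function(slope_um_per_v,
                                   voltages_vpp = seq(0, 250, by = 10),
                                   noise_sd = 0, seed = 1) {
  if (slope_um_per_v < 0) stop_invalid("slope_um_per_v must be >= 0")
  eps <- if (noise_sd > 0)
    withr::with_seed(seed, rnorm(length(voltages_vpp), 0, noise_sd)) else 0
  data.frame(voltage_vpp = voltages_vpp,
             expansion_um = pmax(slope_um_per_v * voltages_vpp + eps, 0))
}

# log-normal lobe, zero for tau <= 0, unit peak at tau = m
#' @noRd
pulse_lobe <- function(tau, m, s) {
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- exp(-(log(tau[pos] / m))^2 / (2 * s^2))
  out
}

#' @noRd
pulse_lobe_deriv <- function(tau, m, s) {
  ifelse(tau > 0, pulse_lobe(tau, m, s) * (-log(tau / m) / (s^2 * tau)), 0)
}

# diastolic runoff: fast rise (time constant r), exponential decay (T)
#' @noRd
pulse_runoff <- function(tau, r, T) {
  ifelse(tau > 0, (1 - exp(-tau / r)) * exp(-tau / T), 0)
}

#' @noRd
pulse_runoff_deriv <- function(tau, r, T) {
  ifelse(tau > 0,
         exp(-tau / T) * (exp(-tau / r) / r - (1 - exp(-tau / r)) / T), 0)
}

#' Synthetic one-cycle arterial pressure pulse
#'
#' Constructed parametric waveform: a systolic log-normal lobe, a reflected
#' (dicrotic) log-normal lobe, and an exponential diastolic runoff, summed
#' in normalised units and scaled to `pulse_amplitude_kpa` at the systolic
#' peak. The waveform is zero before the foot (aortic-valve opening) at
#' `t_foot_s`; the lobe-peak parameter is solved numerically so the global
#' maximum falls exactly at `t_systolic_s`, and the reflected-lobe amplitude
#' is set 30% above the tangency value so a genuine local minimum — the
#' dicrotic notch — forms shortly before `t_notch_s`.
#'
#' Default landmarks: foot 0.1 s, systolic peak 0.19 s, notch 0.4 s within a
#' 1-s cycle. Default amplitude 5.33 kPa (a typical 40-mmHg adult pulse
#' pressure).
#'
#' @param cycle_s cardiac cycle length, s.
#' @param t_foot_s,t_systolic_s,t_notch_s landmark times, s; must be
#'   strictly ordered and inside the cycle.
#' @param pulse_amplitude_kpa peak transmural pressure change, kPa.
#' @param step_s sampling interval, s; default 0.001.
#' @param n_cycles periodic continuation, default 1.
#' @param noise_rel relative additive noise (fraction of amplitude),
#'   default 0.
#' @param seed RNG seed (used only when `noise_rel > 0`).
#' @return a [pressure_waveform()] covering `[0, n_cycles * cycle_s)`.
#' @export
gen_pressure_pulse <- function(cycle_s = 1, t_foot_s = 0.1,
                               t_systolic_s = 0.19, t_notch_s = 0.4,
                               pulse_amplitude_kpa = 5.33, step_s = 0.001,
                               n_cycles = 1, noise_rel = 0, seed = 1) {
  if (!(t_foot_s < t_systolic_s && t_systolic_s < t_notch_s &&
        t_notch_s < cycle_s))
    stop_invalid("landmarks must satisfy t_foot < t_systolic < t_notch < cycle")
  tau_s <- t_systolic_s - t_foot_s
  tau_n <- t_notch_s - t_foot_s
  # fixed shape widths/time constants (normalised construction)
  s1 <- 0.4            # systolic lobe width (log units)
  s2 <- 0.35           # reflected lobe width
  m2 <- tau_n + 0.06   # reflected lobe peaks just after the notch
  a3 <- 0.2            # runoff amplitude
  r3 <- 0.03           # runoff rise time constant, s
  T3 <- 0.35           # diastolic decay time constant, s
  notch_boost <- 1.3   # lift above tangency so a true minimum forms

  m1 <- tau_s
  a2 <- 0
  for (it in 1:4) {
    # reflected-lobe amplitude balancing the falling terms at the notch
    a2_tan <- -(pulse_lobe_deriv(tau_n, m1, s1) +
                  a3 * pulse_runoff_deriv(tau_n, r3, T3)) /
      pulse_lobe_deriv(tau_n, m2, s2)
    if (!is.finite(a2_tan) || a2_tan <= 0)
      stop_invalid("pulse construction failed: no positive reflected-lobe amplitude")
    a2 <- notch_boost * a2_tan
    dshape <- function(m) {
      pulse_lobe_deriv(tau_s, m, s1) + a2 * pulse_lobe_deriv(tau_s, m2, s2) +
        a3 * pulse_runoff_deriv(tau_s, r3, T3)
    }
    m1 <- uniroot(dshape, c(0.5 * tau_s, 2 * tau_s), tol = 1e-12)$root
  }
  shape <- function(tau) {
    pulse_lobe(tau, m1, s1) + a2 * pulse_lobe(tau, m2, s2) +
      a3 * pulse_runoff(tau, r3, T3)
  }
  peak <- shape(tau_s)

  time <- seq(0, n_cycles * cycle_s - step_s / 2, by = step_s)
  tau <- (time - t_foot_s) %% cycle_s
  tau[time < t_foot_s] <- -1 # zero baseline before the first foot
  dp <- pulse_amplitude_kpa * shape(tau) / peak
  if (noise_rel > 0)
    dp <- dp + withr::with_seed(seed,
      rnorm(length(dp), 0, noise_rel * pulse_amplitude_kpa))
  pw <- pressure_waveform(time, dp)
  if (pulse_amplitude_kpa > 0 && noise_rel == 0) {
    i_max <- which.max(pw$delta_p_kpa)
    if (abs(pw$time_s[i_max] - t_systolic_s) > step_s + 1e-12)
      stop("internal error: pulse maximum missed the systolic landmark")
  }
  pw
}

#' Synthetic dopant concentration series
#'
#' Spectra linear in concentration with multiplicative noise:
#' \eqn{\mu(\lambda, c) = [\mathrm{baseline} + c\,\mathrm{coeff}]
#' (1 + \varepsilon)}. With the default melanin response the absorption
#' coefficient decreases strictly with wavelength, as in pigmented tissue.
#'
#' @param response a [dopant_response()] acting as generator truth, e.g.
#'   from [synthetic_dopant_responses()].
#' @param concentrations_mg_g concentrations to simulate, mg/g.
#' @param noise_rel relative (multiplicative) noise sd, default 0.
#' @param seed RNG seed.
#' @return list with `concentrations_mg_g`, `mua_spectra`, `mus_spectra`
#'   (lists of [spectrum()]), suitable for [fit_dopant_response()].
#' @export
gen_dopant_spectra <- function(response, concentrations_mg_g,
                               noise_rel = 0, seed = 1) {
  stopifnot(inherits(response, "dopant_response"))
  wl <- response$absorption_coeff$wavelength_nm
  k <- length(concentrations_mg_g)
  noise <- if (noise_rel > 0) {
    withr::with_seed(seed,
      matrix(rnorm(2 * k * length(wl), 0, noise_rel), nrow = 2 * k))
  } else matrix(0, nrow = 2 * k, ncol = length(wl))
  mua <- vector("list", k)
  mus <- vector("list", k)
  for (i in seq_len(k)) {
    ci <- concentrations_mg_g[i]
    va <- (response$baseline_mua$value + ci * response$absorption_coeff$value) *
      (1 + noise[2 * i - 1, ])
    vs <- (response$baseline_mus$value + ci * response$scattering_coeff$value) *
      (1 + noise[2 * i, ])
    mua[[i]] <- spectrum(wl, pmax(va, 0), quantity = "mua")
    mus[[i]] <- spectrum(wl, pmax(vs, 0), quantity = "mus_prime")
  }
  list(concentrations_mg_g = concentrations_mg_g,
       mua_spectra = mua, mus_spectra = mus)
}

#' Plausible built-in dopant responses
#'
#' Smooth power-law response spectra on the canonical 500–1000 nm grid,
#' shaped like the measured single-dopant characterisations: melanin
#' absorption falling steeply with wavelength (~lambda^-3) plus weak
#' scattering; ink absorbing almost flat; TiO2 scattering ~lambda^-1;
#' small plain-PDMS baselines. Magnitudes are chosen so epidermis-like
#' recipes (~1 mg/g melanin, ~8 mg/g TiO2) land at skin-like
#' mu_a ~ 0.5 /mm and mu_s' ~ 3 /mm at 500 nm.
#'
#' @param wavelength_nm grid, default [canonical_grid()].
#' @return named list of three [dopant_response()] (`melanin`, `ink`,
#'   `tio2`).
#' @export
synthetic_dopant_responses <- function(wavelength_nm = canonical_grid()) {
  wl <- wavelength_nm
  rel <- wl / 500
  zero <- spectrum(wl, numeric(length(wl)), quantity = "mua",
                   allow_negative = TRUE)
  base_a <- spectrum(wl, rep(0.01, length(wl)), quantity = "mua")
  base_s <- spectrum(wl, 0.05 * rel^-1, quantity = "mus_prime")
  mk <- function(d, a, s) dopant_response(
    d,
    absorption_coeff = spectrum(wl, a, quantity = "mua", allow_negative = TRUE),
    scattering_coeff = spectrum(wl, s, quantity = "mus_prime",
                                allow_negative = TRUE),
    baseline_mua = base_a, baseline_mus = base_s)
  list(
    melanin = mk("melanin", 0.4 * rel^-3, 0.05 * rel^-1),
    ink = mk("ink", 0.25 * rel^-0.3, numeric(length(wl))),
    tio2 = mk("tio2", numeric(length(wl)), 0.35 * rel^-1)
  )
}

# separable Gaussian blur with replicate padding; sigma in pixels
#' @noRd
gaussian_blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(4 * sigma))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_vec <- function(v) {
    vp <- c(rep(v[1], rad), v, rep(v[length(v)], rad))
    as.numeric(stats::filter(vp, k, sides = 2))[(rad + 1):(rad + length(v))]
  }
  m <- apply(m, 2, blur_vec)
  t(apply(m, 1, blur_vec))
}

#' Synthetic channel image
#'
#' Bright background with a centred dark band of the requested physical
#' width. Band edges are anti-aliased by pixel-coverage so sub-pixel widths
#' are meaningful; optional Gaussian blur and additive noise follow, then
#' clipping to \[0, 1\].
#'
#' @param diameter_um channel width, um; must fit inside the image.
#' @param pixel_scale_um_per_px um per pixel, default 5.
#' @param image_size `c(rows, cols)` in px, default `c(240, 320)`.
#' @param background,foreground intensities, defaults 0.9 and 0.15.
#' @param blur_sigma_px Gaussian blur sigma, px, default 0.
#' @param noise_sd additive intensity noise sd, default 0.
#' @param seed RNG seed.
#' @param channel_axis `"horizontal"` (default) or `"vertical"`.
#' @return a [channel_image()].
#' @export
gen_channel_image <- function(diameter_um, pixel_scale_um_per_px = 5,
                              image_size = c(240, 320), background = 0.9,
                              foreground = 0.15, blur_sigma_px = 0,
                              noise_sd = 0, seed = 1,
                              channel_axis = c("horizontal", "vertical")) {
  channel_axis <- match.arg(channel_axis)
  width_px <- diameter_um / pixel_scale_um_per_px
  n_perp <- image_size[1]
  n_along <- image_size[2]
  if (width_px <= 0 || width_px >= n_perp - 8)
    stop_invalid("diameter (", width_px, " px) must fit inside the image")
  centre <- (n_perp + 1) / 2
  lo <- centre - width_px / 2
  hi <- centre + width_px / 2
  # coverage of pixel i (extent [i-0.5, i+0.5]) by the band [lo, hi]
  i <- seq_len(n_perp)
  cov <- pmax(0, pmin(i + 0.5, hi) - pmax(i - 0.5, lo))
  profile <- background - (background - foreground) * pmin(cov, 1)
  px <- matrix(profile, nrow = n_perp, ncol = n_along)
  px <- gaussian_blur_matrix(px, blur_sigma_px)
  if (noise_sd > 0)
    px <- px + withr::with_seed(seed,
      matrix(rnorm(length(px), 0, noise_sd), nrow = n_perp))
  px <- pmin(pmax(px, 0), 1)
  if (channel_axis == "vertical") px <- t(px)
  channel_image(px, pixel_scale_um_per_px, channel_axis = channel_axis)
}
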