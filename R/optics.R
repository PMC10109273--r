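# Optics: additive dopant spectral model, recipe solving, Sellmeier fit.
#
# Three dopants tune the optical properties of the PDMS matrix: synthetic
# melanin (absorbs, with the wavelength-decreasing mu_a of human skin, and
# scatters weakly), India ink (absorbs only), and TiO2 particles (scatters
# only). Single-dopant characterisations are combined additively and
# concentration-linearly:
#   mu(lambda) = baseline(lambda) + sum_d c_d * coeff_d(lambda)
# separately for absorption and reduced scattering. Recipe design is then a
# non-negative least-squares problem across the wavelength grid.

DOPANTS <- c("melanin", "ink", "tio2")

#' Wavelength-indexed optical spectrum
#'
#' Absorption (`mua`) or reduced scattering (`mus_prime`) coefficient on a
#' strictly increasing wavelength grid; the canonical grid is 500–1000 nm in
#' 1-nm steps. Values are stored in 1/mm; 1/cm input is converted when
#' flagged — never silently.
#'
#' @param wavelength_nm numeric, nm, strictly increasing.
#' @param value numeric, same length; `>= 0` unless
#'   `allow_negative = TRUE` (used internally for fitted per-concentration
#'   coefficient spectra, whose noise can dip below zero).
#' @param quantity `"mua"` or `"mus_prime"`. Figure axes elsewhere may label
#'   reduced scattering plainly as "mus"; this package always stores the
#'   reduced coefficient and never converts (anisotropy is not modelled).
#' @param unit `"per_mm"` (default) or `"per_cm"` (divided by 10 on input).
#' @param allow_negative logical, default `FALSE`.
#' @return Object of class `spectrum` (data frame `wavelength_nm`, `value`).
#' @export
spectrum <- function(wavelength_nm, value, quantity = c("mua", "mus_prime"),
                     unit = c("per_mm", "per_cm"), allow_negative = FALSE) {
  quantity <- match.arg(quantity)
  unit <- match.arg(unit)
  assert_num(wavelength_nm, "wavelength_nm")
  assert_num(value, "value", len = length(wavelength_nm))
  if (any(diff(wavelength_nm) <= 0))
    stop_invalid("wavelengths must be strictly increasing")
  if (unit == "per_cm") value <- value / 10
  if (!allow_negative && any(value < 0))
    stop_invalid("spectrum values must be non-negative")
  structure(data.frame(wavelength_nm = wavelength_nm, value = value),
            quantity = quantity,
            class = c("spectrum", "data.frame"))
}

#' Canonical wavelength grid, 500–1000 nm in 1-nm steps
#' @return integer-valued numeric vector of wavelengths (nm).
#' @export
canonical_grid <- function() seq(500, 1000, by = 1)

#' @noRd
same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelength_nm) == length(b$wavelength_nm) &&
    all(abs(a$wavelength_nm - b$wavelength_nm) <= tol)
}

#' @noRd
check_common_grid <- function(specs) {
  ref <- specs[[1]]
  for (s in specs[-1]) {
    if (!same_grid(ref, s))
      stop_invalid("spectra are not on a common wavelength grid; ",
                   "regrid deliberately with regrid_spectrum()")
  }
  invisible(ref$wavelength_nm)
}

#' Re-grid a spectrum by linear interpolation
#'
#' Grid mismatches are errors everywhere else in the package; interpolation
#' must be an explicit, deliberate step.
#'
#' @param spec a [spectrum()].
#' @param wavelength_nm target grid, within the source grid's range.
#' @return a [spectrum()] on the new grid.
#' @export
regrid_spectrum <- function(spec, wavelength_nm) {
  stopifnot(inherits(spec, "spectrum"))
  if (min(wavelength_nm) < min(spec$wavelength_nm) - 1e-9 ||
      max(wavelength_nm) > max(spec$wavelength_nm) + 1e-9)
    stop_invalid("target grid extends beyond the source spectrum")
  v <- approx(spec$wavelength_nm, spec$value, xout = wavelength_nm)$y
  spectrum(wavelength_nm, v, quantity = attr(spec, "quantity"),
           allow_negative = TRUE)
}

#' Per-dopant spectral response
#'
#' Concentration-linear response of one dopant: per-(mg/g) coefficient
#' spectra for absorption and reduced scattering, plus the plain-PDMS
#' baseline spectra. Role constraints are structural: ink contributes no
#' scattering, TiO2 no absorption; melanin may carry both.
#'
#' @param dopant `"melanin"`, `"ink"` or `"tio2"`.
#' @param absorption_coeff [spectrum()], 1/mm per (mg/g).
#' @param scattering_coeff [spectrum()], 1/mm per (mg/g).
#' @param baseline_mua,baseline_mus [spectrum()], plain-PDMS baselines.
#' @return Object of class `dopant_response`.
#' @export
dopant_response <- function(dopant, absorption_coeff, scattering_coeff,
                            baseline_mua, baseline_mus) {
  dopant <- match.arg(dopant, DOPANTS)
  specs <- list(absorption_coeff, scattering_coeff, baseline_mua, baseline_mus)
  lapply(specs, function(s) stopifnot(inherits(s, "spectrum")))
  check_common_grid(specs)
  if (dopant == "ink" && any(scattering_coeff$value != 0))
    stop_invalid("ink must have an identically zero scattering coefficient")
  if (dopant == "tio2" && any(absorption_coeff$value != 0))
    stop_invalid("tio2 must have an identically zero absorption coefficient")
  structure(list(dopant = dopant,
                 absorption_coeff = absorption_coeff,
                 scattering_coeff = scattering_coeff,
                 baseline_mua = baseline_mua,
                 baseline_mus = baseline_mus),
            class = "dopant_response")
}

#' Dopant recipe: concentrations per gram of plain PDMS
#'
#' @param c_melanin,c_ink,c_tio2 concentrations, mg per g of plain PDMS,
#'   all `>= 0`.
#' @return Object of class `phantom_recipe`.
#' @examples
#' phantom_recipe(1.25, 0, 8.55) # an epidermis-like mix
#' @export
phantom_recipe <- function(c_melanin, c_ink, c_tio2) {
  conc <- c(melanin = c_melanin, ink = c_ink, tio2 = c_tio2)
  assert_num(conc, "concentrations", len = 3)
  if (any(conc < 0)) stop_invalid("recipe concentrations must be >= 0")
  structure(as.list(conc), class = "phantom_recipe")
}

#' @export
print.phantom_recipe <- function(x, ...) {
  cat(sprintf("Recipe (mg per g plain PDMS): melanin %.4g, ink %.4g, TiO2 %.4g\n",
              x$melanin, x$ink, x$tio2))
  invisible(x)
}

#' Fit a dopant response from a concentration series
#'
#' Per-wavelength OLS of measured spectra against dopant concentration;
#' the intercept is the plain-PDMS baseline estimate. At least two distinct
#' concentrations are required, one of which should be 0 (or pass explicit
#' `baseline_mua`/`baseline_mus`, in which case slopes are fitted through
#' the baseline). Role constraints (ink: no scattering; TiO2: no
#' absorption) are enforced after the fit; a non-trivial zeroed component
#' triggers a warning.
#'
#' @param concentrations_mg_g numeric, mg/g, one per series entry.
#' @param mua_spectra,mus_spectra lists of [spectrum()] on a common grid,
#'   same length as `concentrations_mg_g`.
#' @param dopant `"melanin"`, `"ink"` or `"tio2"`.
#' @param baseline_mua,baseline_mus optional explicit baselines.
#' @return a [dopant_response()].
#' @export
fit_dopant_response <- function(concentrations_mg_g, mua_spectra, mus_spectra,
                                dopant, baseline_mua = NULL, baseline_mus = NULL) {
  dopant <- match.arg(dopant, DOPANTS)
  assert_num(concentrations_mg_g, "concentrations_mg_g")
  k <- length(concentrations_mg_g)
  if (length(mua_spectra) != k || length(mus_spectra) != k)
    stop_invalid("spectra lists must match the concentration vector length")
  specs <- c(mua_spectra, mus_spectra,
             Filter(Negate(is.null), list(baseline_mua, baseline_mus)))
  wl <- check_common_grid(specs)
  have_baseline <- !is.null(baseline_mua) && !is.null(baseline_mus)
  if (length(unique(concentrations_mg_g)) < 2L && !have_baseline)
    stop_degenerate("need >= 2 distinct concentrations, or explicit baselines")
  if (!have_baseline && !any(concentrations_mg_g == 0))
    stop_degenerate("series must include concentration 0 or provide baselines")

  fit_channel <- function(spectra, baseline) {
    Y <- vapply(spectra, function(s) s$value, numeric(length(wl))) # wl x k
    if (is.null(baseline)) {
      X <- cbind(1, concentrations_mg_g)
      cf <- lm.fit(X, t(Y))$coefficients # 2 x wl
      list(intercept = cf[1, ], slope = cf[2, ])
    } else {
      Yc <- t(Y) - matrix(baseline$value, k, length(wl), byrow = TRUE)
      X <- matrix(concentrations_mg_g, ncol = 1)
      cf <- lm.fit(X, Yc)$coefficients
      list(intercept = baseline$value, slope = drop(cf))
    }
  }
  fa <- fit_channel(mua_spectra, baseline_mua)
  fs <- fit_channel(mus_spectra, baseline_mus)

  zero_if_role <- function(slope, channel) {
    forced <- (dopant == "ink" && channel == "mus") ||
      (dopant == "tio2" && channel == "mua")
    if (forced) {
      # tolerate regression noise; warn only for a substantive response
      if (max(abs(slope)) > 1e-3)
        warning(sprintf("%s: fitted %s response (max |slope| %.3g) forced to zero by role constraint",
                        dopant, channel, max(abs(slope))))
      slope[] <- 0
    }
    slope
  }
  dopant_response(
    dopant,
    absorption_coeff = spectrum(wl, zero_if_role(fa$slope, "mua"),
                                quantity = "mua", allow_negative = TRUE),
    scattering_coeff = spectrum(wl, zero_if_role(fs$slope, "mus"),
                                quantity = "mus_prime", allow_negative = TRUE),
    baseline_mua = spectrum(wl, pmax(fa$intercept, 0), quantity = "mua"),
    baseline_mus = spectrum(wl, pmax(fs$intercept, 0), quantity = "mus_prime")
  )
}

#' @noRd
mixture_baselines <- function(responses) {
  wl <- responses[[1]]$baseline_mua$wavelength_nm
  ba <- rowMeans(vapply(responses, function(r) r$baseline_mua$value,
                        numeric(length(wl))))
  bs <- rowMeans(vapply(responses, function(r) r$baseline_mus$value,
                        numeric(length(wl))))
  list(mua = ba, mus = bs, wl = wl)
}

#' Predict mixture spectra from a recipe
#'
#' Additive concentration-linear model
#' \eqn{\mu(\lambda) = \mathrm{baseline}(\lambda) + \sum_d c_d\,
#' \mathrm{coeff}_d(\lambda)}, separately for absorption and reduced
#' scattering. The single mixture baseline is the elementwise mean of the
#' responses' baseline estimates (identical when fitted noiselessly).
#'
#' @param recipe a [phantom_recipe()].
#' @param responses named list with elements `melanin`, `ink`, `tio2`, each
#'   a [dopant_response()] on a common grid.
#' @return list with `mua` and `mus` [spectrum()] objects.
#' @export
predict_mixture_spectra <- function(recipe, responses) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  if (!all(DOPANTS %in% names(responses)))
    stop_invalid("responses must be a named list with melanin, ink, tio2")
  responses <- responses[DOPANTS]
  lapply(responses, function(r) stopifnot(inherits(r, "dopant_response")))
  check_common_grid(lapply(responses, function(r) r$absorption_coeff))
  check_common_grid(c(list(responses[[1]]$absorption_coeff),
                      lapply(responses, function(r) r$scattering_coeff)))
  bl <- mixture_baselines(responses)
  mua <- bl$mua
  mus <- bl$mus
  for (d in DOPANTS) {
    cd <- recipe[[d]]
    mua <- mua + cd * responses[[d]]$absorption_coeff$value
    mus <- mus + cd * responses[[d]]$scattering_coeff$value
  }
  list(mua = spectrum(bl$wl, pmax(mua, 0), quantity = "mua"),
       mus = spectrum(bl$wl, pmax(mus, 0), quantity = "mus_prime"))
}

#' Solve for a dopant recipe matching target spectra
#'
#' Non-negative least squares over the stacked residuals
#' \eqn{[\mu_a;\; w\,\mu_s']} across the whole wavelength grid: find
#' non-negative concentrations minimising the distance between the additive
#' mixture model and the target tissue spectra.
#'
#' @param target_mua,target_mus target [spectrum()] objects on the
#'   responses' grid.
#' @param responses named list of three [dopant_response()].
#' @param scattering_weight relative weight `w` of the scattering channel in
#'   the joint fit; default 1.
#' @return list with `recipe` ([phantom_recipe()]), `rms_mua`, `rms_mus`
#'   (per-channel RMS residual, 1/mm), and `fitted` (mixture spectra of the
#'   solved recipe).
#' @export
solve_recipe <- function(target_mua, target_mus, responses,
                         scattering_weight = 1) {
  stopifnot(inherits(target_mua, "spectrum"), inherits(target_mus, "spectrum"))
  if (!all(DOPANTS %in% names(responses)))
    stop_invalid("responses must be a named list with melanin, ink, tio2")
  responses <- responses[DOPANTS]
  check_common_grid(c(list(target_mua, target_mus),
                      lapply(responses, function(r) r$absorption_coeff),
                      lapply(responses, function(r) r$scattering_coeff)))
  w <- scattering_weight
  A <- do.call(cbind, lapply(responses, function(r)
    c(r$absorption_coeff$value, w * r$scattering_coeff$value)))
  if (all(A == 0)) stop_invalid("all dopant responses are zero; unsolvable")
  bl <- mixture_baselines(responses)
  b <- c(target_mua$value - bl$mua, w * (target_mus$value - bl$mus))
  sol <- nnls_solve(A, b)
  recipe <- phantom_recipe(sol$x[1], sol$x[2], sol$x[3])
  fitted <- predict_mixture_spectra(recipe, responses)
  n_wl <- length(bl$wl)
  list(recipe = recipe,
       rms_mua = sqrt(mean((fitted$mua$value - target_mua$value)^2)),
       rms_mus = sqrt(mean((fitted$mus$value - target_mus$value)^2)),
       fitted = fitted)
}

#' CSV / JSON I/O for spectra, recipes and dopant responses
#'
#' `read_spectrum_csv()` expects columns `wavelength_nm` and
#' `value_per_mm` (or `value_per_cm`, converted explicitly).
#'
#' @param path file path.
#' @param quantity `"mua"` or `"mus_prime"`.
#' @return `read_spectrum_csv()` returns a [spectrum()].
#' @export
read_spectrum_csv <- function(path, quantity = c("mua", "mus_prime")) {
  quantity <- match.arg(quantity)
  d <- read.csv(path)
  if (!"wavelength_nm" %in% names(d))
    stop_invalid("CSV needs `wavelength_nm`: ", path)
  if ("value_per_mm" %in% names(d)) {
    spectrum(d$wavelength_nm, d$value_per_mm, quantity = quantity)
  } else if ("value_per_cm" %in% names(d)) {
    spectrum(d$wavelength_nm, d$value_per_cm, quantity = quantity,
             unit = "per_cm")
  } else {
    stop_invalid("CSV needs `value_per_mm` or `value_per_cm`: ", path)
  }
}

#' @rdname read_spectrum_csv
#' @param spec a [spectrum()].
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  d <- data.frame(wavelength_nm = spec$wavelength_nm,
                  value_per_mm = spec$value)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_spectrum_csv
#' @param recipe a [phantom_recipe()].
#' @export
write_recipe_json <- function(recipe, path) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  jsonlite::write_json(unclass(recipe), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_spectrum_csv
#' @export
read_recipe_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom_recipe(x$melanin, x$ink, x$tio2)
}

#' @rdname read_spectrum_csv
#' @param responses named list of three [dopant_response()].
#' @export
write_responses_json <- function(responses, path) {
  ser <- lapply(responses, function(r) list(
    dopant = r$dopant,
    wavelength_nm = r$absorption_coeff$wavelength_nm,
    absorption_coeff = r$absorption_coeff$value,
    scattering_coeff = r$scattering_coeff$value,
    baseline_mua = r$baseline_mua$value,
    baseline_mus = r$baseline_mus$value))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_spectrum_csv
#' @export
read_responses_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(x, function(r) {
    wl <- unlist(r$wavelength_nm)
    dopant_response(
      r$dopant,
      absorption_coeff = spectrum(wl, unlist(r$absorption_coeff),
                                  quantity = "mua", allow_negative = TRUE),
      scattering_coeff = spectrum(wl, unlist(r$scattering_coeff),
                                  quantity = "mus_prime", allow_negative = TRUE),
      baseline_mua = spectrum(wl, unlist(r$baseline_mua), quantity = "mua"),
      baseline_mus = spectrum(wl, unlist(r$baseline_mus),
                              quantity = "mus_prime"))
  })
  names(out) <- vapply(out, function(r) r$dopant, character(1))
  out
}
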