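# Dopant spectral model, recipe solver, Sellmeier dispersion.

test_that("fit_dopant_response recovers linear responses exactly", {
  resp <- coarse_responses()$melanin
  ser <- gen_dopant_spectra(resp, c(0, 0.5, 1, 2))
  fit <- fit_dopant_response(ser$concentrations_mg_g, ser$mua_spectra,
                             ser$mus_spectra, "melanin")
  expect_equal(fit$absorption_coeff$value, resp$absorption_coeff$value,
               tolerance = 1e-9)
  expect_equal(fit$scattering_coeff$value, resp$scattering_coeff$value,
               tolerance = 1e-9)
  expect_equal(fit$baseline_mua$value, resp$baseline_mua$value, tolerance = 1e-9)
})

test_that("role constraints zero out forbidden channels with a warning", {
  wl <- seq(500, 1000, by = 20)
  ink <- coarse_responses()$ink
  # inject spurious scattering response into an ink series
  ser <- gen_dopant_spectra(ink, c(0, 1, 2))
  ser$mus_spectra <- lapply(seq_along(ser$mus_spectra), function(i)
    spectrum(wl, ser$mus_spectra[[i]]$value + 0.05 * (i - 1), quantity = "mus_prime"))
  expect_warning(
    fit <- fit_dopant_response(ser$concentrations_mg_g, ser$mua_spectra,
                               ser$mus_spectra, "ink"),
    "role constraint")
  expect_true(all(fit$scattering_coeff$value == 0))
})

test_that("noisy dopant series recover slope spectra within 5% RMS", {
  resp <- coarse_responses()$tio2
  ser <- gen_dopant_spectra(resp, c(0, 2, 5, 10), noise_rel = 0.02, seed = 9)
  fit <- fit_dopant_response(ser$concentrations_mg_g, ser$mua_spectra,
                             ser$mus_spectra, "tio2")
  rel_rms <- sqrt(mean((fit$scattering_coeff$value - resp$scattering_coeff$value)^2)) /
    sqrt(mean(resp$scattering_coeff$value^2))
  expect_lt(rel_rms, 0.05)
  expect_error(fit_dopant_response(2, list(ser$mua_spectra[[1]]),
                                   list(ser$mus_spectra[[1]]), "tio2"),
               class = "pulsephantom_degenerate_design")
})

test_that("predict_mixture_spectra is additive and superposes", {
  resp <- coarse_responses()
  bl <- predict_mixture_spectra(phantom_recipe(0, 0, 0), resp)
  expect_equal(bl$mua$value, resp$melanin$baseline_mua$value, tolerance = 1e-12)

  r1 <- phantom_recipe(1.25, 0, 8.55)  # epidermis-like mix
  m1 <- predict_mixture_spectra(r1, resp)
  hand <- resp$melanin$baseline_mua$value +
    1.25 * resp$melanin$absorption_coeff$value +
    8.55 * resp$tio2$absorption_coeff$value
  expect_equal(m1$mua$value, hand, tolerance = 1e-12)

  # doubling concentrations doubles the above-baseline part
  m2 <- predict_mixture_spectra(phantom_recipe(2.5, 0, 17.1), resp)
  expect_equal(m2$mua$value - bl$mua$value, 2 * (m1$mua$value - bl$mua$value),
               tolerance = 1e-9)
  expect_equal(m2$mus$value - bl$mus$value, 2 * (m1$mus$value - bl$mus$value),
               tolerance = 1e-9)
})

test_that("grid mismatches are errors, regrid is explicit", {
  resp <- coarse_responses()
  tgt <- predict_mixture_spectra(phantom_recipe(1, 0.5, 4), resp)
  off_grid <- spectrum(seq(500, 1000, by = 25), rep(1, 21), quantity = "mua")
  expect_error(solve_recipe(off_grid, tgt$mus, resp),
               class = "pulsephantom_invalid_input")
  re <- regrid_spectrum(off_grid, seq(500, 1000, by = 20))
  expect_equal(re$wavelength_nm, seq(500, 1000, by = 20))
  expect_error(regrid_spectrum(off_grid, seq(400, 900, by = 20)),
               class = "pulsephantom_invalid_input")
})

test_that("solve_recipe recovers known recipes exactly from consistent targets", {
  resp <- coarse_responses()
  for (truth in list(c(1.25, 0, 8.55), c(0.187, 1.08, 4.62), c(0.75, 0, 5.13))) {
    tgt <- predict_mixture_spectra(do.call(phantom_recipe, as.list(truth)), resp)
    sol <- solve_recipe(tgt$mua, tgt$mus, resp)
    expect_equal(unlist(sol$recipe, use.names = FALSE), truth, tolerance = 1e-6)
    expect_lt(sol$rms_mua, 1e-9)
  }
  # target at baseline needs no dopants
  bl <- predict_mixture_spectra(phantom_recipe(0, 0, 0), resp)
  sol0 <- solve_recipe(bl$mua, bl$mus, resp)
  expect_equal(unlist(sol0$recipe, use.names = FALSE), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("targets below baseline give a non-negative recipe with residual", {
  resp <- coarse_responses()
  wl <- resp$melanin$baseline_mua$wavelength_nm
  below <- spectrum(wl, pmax(resp$melanin$baseline_mua$value - 0.005, 0),
                    quantity = "mua")
  bl_mus <- spectrum(wl, resp$melanin$baseline_mus$value, quantity = "mus_prime")
  sol <- solve_recipe(below, bl_mus, resp)
  expect_true(all(unlist(sol$recipe) >= 0))
  expect_gt(sol$rms_mua, 0)
})

test_that("Lawson-Hanson agrees with the exhaustive active-set oracle", {
  withr::with_seed(31, {
    for (i in 1:25) {
      A <- matrix(rnorm(30), 10, 3)
      b <- rnorm(10)
      got <- nnls_solve(A, b)$x
      expect_equal(got, oracle_nnls(A, b), tolerance = 1e-8)
    }
  })
})

test_that("noisy targets recover recipes within 10% over 20 seeded repeats", {
  resp <- coarse_responses()
  truth <- c(1.25, 0.4, 8.55)
  tgt <- predict_mixture_spectra(do.call(phantom_recipe, as.list(truth)), resp)
  errs <- sapply(1:20, function(s) {
    noisy_mua <- spectrum(tgt$mua$wavelength_nm,
                          tgt$mua$value * (1 + withr::with_seed(100 + s,
                            rnorm(length(tgt$mua$value), 0, 0.02))),
                          quantity = "mua")
    noisy_mus <- spectrum(tgt$mus$wavelength_nm,
                          tgt$mus$value * (1 + withr::with_seed(200 + s,
                            rnorm(length(tgt$mus$value), 0, 0.02))),
                          quantity = "mus_prime")
    sol <- solve_recipe(noisy_mua, noisy_mus, resp)
    max(abs(unlist(sol$recipe, use.names = FALSE) - truth) / truth)
  })
  expect_lt(max(errs), 0.10)
})

test_that("Sellmeier evaluation matches the closed form", {
  m <- sellmeier_model(1.0, 0.01)
  expect_equal(evaluate_sellmeier(m, 1000), sqrt(1 + 1 / 0.99), tolerance = 1e-12)
  m0 <- sellmeier_model(0, 0.0)
  expect_equal(evaluate_sellmeier(m0, 700), 1)
  # pole proximity: lambda^2 - C below tolerance is a domain error
  m_pole <- sellmeier_model(1, 0.2, check_grid = 600:1000)
  expect_error(evaluate_sellmeier(m_pole, sqrt(0.2) * 1000 + 1e-4),
               class = "pulsephantom_invalid_input")
})

test_that("fit_sellmeier recovers generating coefficients from clean data", {
  wl <- seq(500, 1000, length.out = 9)
  truth <- sellmeier_model(1.0, 0.01)
  fit <- fit_sellmeier(wl, evaluate_sellmeier(truth, wl), n_terms = 1)
  expect_equal(fit$sellmeier_b, 1.0, tolerance = 0.01)
  expect_equal(fit$sellmeier_c, 0.01, tolerance = 0.01 * 0.01 + 1e-4)
  # fit -> evaluate round trip reproduces the data to the fit residual
  expect_equal(evaluate_sellmeier(fit, wl), evaluate_sellmeier(truth, wl),
               tolerance = 1e-6)
})

test_that("constant-index data produce a flat dispersion model", {
  wl <- seq(500, 1000, length.out = 9)
  fit <- fit_sellmeier(wl, rep(1.41, 9), n_terms = 2)
  n_hat <- evaluate_sellmeier(fit, seq(500, 1000, by = 50))
  expect_lt(max(abs(n_hat - 1.41)), 1e-6)
})

test_that("fit_sellmeier enforces its measurement-count precondition", {
  expect_error(fit_sellmeier(c(500, 700, 900), c(1.4, 1.41, 1.42), n_terms = 2),
               class = "pulsephantom_invalid_input")
})

test_that("spectrum and recipe I/O round-trips, including cm^-1 input", {
  tmp <- withr::local_tempdir()
  wl <- seq(500, 1000, by = 20)
  sp <- spectrum(wl, seq(0.5, 3, length.out = length(wl)), quantity = "mua")
  p <- file.path(tmp, "mua.csv")
  write_spectrum_csv(sp, p)
  expect_equal(read_spectrum_csv(p, "mua")$value, sp$value)

  # per-cm values convert by /10 only when flagged
  p2 <- file.path(tmp, "mua_cm.csv")
  write.csv(data.frame(wavelength_nm = wl, value_per_cm = 10 * sp$value), p2,
            row.names = FALSE)
  expect_equal(read_spectrum_csv(p2, "mua")$value, sp$value)

  r <- phantom_recipe(1.25, 0, 8.55)
  p3 <- file.path(tmp, "recipe.json")
  write_recipe_json(r, p3)
  expect_equal(read_recipe_json(p3), r)

  p4 <- file.path(tmp, "responses.json")
  write_responses_json(coarse_responses(), p4)
  back <- read_responses_json(p4)
  expect_equal(back$tio2$scattering_coeff$value,
               coarse_responses()$tio2$scattering_coeff$value)
})
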