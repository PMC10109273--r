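# End-to-end workflows and the CLI dispatcher.

test_that("design_phantom combines mechanics and optics per layer", {
  cal <- elastic_calibration(0.18, -0.39)
  art <- layer_spec("hypodermis") # artery layer, target E = 1 MPa
  d <- design_phantom(list(art), cal)
  expect_equal(d$layers$hypodermis$curing_agent_reported, 7.7)

  expect_error(design_phantom(list(), cal), class = "pulsephantom_invalid_input")

  resp <- coarse_responses()
  tgt <- predict_mixture_spectra(phantom_recipe(1.25, 0, 8.55), resp)
  layers <- list(
    layer_spec("epidermis", target_mua = tgt$mua, target_mus = tgt$mus),
    layer_spec("dermis"),
    layer_spec("hypodermis"))
  d3 <- design_phantom(layers, cal, responses = resp)
  expect_length(d3$layers, 3)
  expect_equal(unlist(d3$layers$epidermis$recipe, use.names = FALSE),
               c(1.25, 0, 8.55), tolerance = 1e-6)
  expect_lt(d3$layers$epidermis$rms_mua, 1e-9)
  expect_null(d3$layers$dermis$recipe)

  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "design.json")
  write_design_json(d3, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$hypodermis$curing_agent_reported, 7.7)
})

test_that("replicate_pulse writes deterministic CSV traces", {
  tmp <- withr::local_tempdir()
  pw <- gen_pressure_pulse(step_s = 0.005)
  write_waveform_csv(pw, file.path(tmp, "p.csv"))
  write_vessel_geometry_json(vessel_geometry(500, 750, 1), file.path(tmp, "g.json"))
  write_pump_calibration_json(pump_calibration(0.26), file.path(tmp, "c.json"))

  out1 <- file.path(tmp, "run1")
  out2 <- file.path(tmp, "run2")
  r1 <- replicate_pulse(file.path(tmp, "p.csv"), file.path(tmp, "g.json"),
                        file.path(tmp, "c.json"), out1)
  r2 <- replicate_pulse(file.path(tmp, "p.csv"), file.path(tmp, "g.json"),
                        file.path(tmp, "c.json"), out2)
  expect_equal(nrow(r1$voltage), 20) # 1 s cycle at 50 ms steps
  expect_true(all(r1$voltage$voltage_vpp >= 0 & r1$voltage$voltage_vpp <= 250))
  expect_identical(readLines(r1$paths[["voltage"]]),
                   readLines(r2$paths[["voltage"]]))
  # zero pulse maps to zero drive
  write_waveform_csv(pressure_waveform(pw$time_s, 0 * pw$delta_p_kpa),
                     file.path(tmp, "p0.csv"))
  r0 <- replicate_pulse(file.path(tmp, "p0.csv"), file.path(tmp, "g.json"),
                        file.path(tmp, "c.json"), file.path(tmp, "run0"))
  expect_true(all(r0$voltage$voltage_vpp == 0))
})

test_that("the CLI dispatcher drives the main subcommands end to end", {
  tmp <- withr::local_tempdir()
  withr::local_dir(tmp)

  # simulate a pulse, a calibration series and an image
  expect_silent(phantom_cli(c("simulate", "pulse", "--out", "pulse.csv",
                              "--step", "0.005")))
  expect_true(file.exists("pulse.csv"))
  phantom_cli(c("simulate", "pump-points", "--slope", "0.26",
                "--out", "points.csv"))
  phantom_cli(c("simulate", "image", "--diameter", "120", "--pixel-scale", "4",
                "--blur", "1", "--out", "chan.pgm"))

  # calibrate the pump from the simulated points
  out <- capture.output(
    cal <- phantom_cli(c("calibrate-pump", "--input", "points.csv",
                         "--out", "pump.json")))
  expect_equal(cal$slope_um_per_v, 0.26, tolerance = 1e-9)

  # measure the simulated channel
  out <- capture.output(
    est <- phantom_cli(c("measure-channel", "--image", "chan.pgm",
                         "--pixel-scale", "4", "--out", "diam.json")))
  expect_equal(est$diameter_um, 120, tolerance = 4)

  # mechanics design from a stored calibration
  write_elastic_calibration_json(elastic_calibration(0.18, -0.39), "ecal.json")
  out <- capture.output(
    inv <- phantom_cli(c("design-mechanics", "--calibration", "ecal.json",
                         "--target-modulus", "1")))
  expect_equal(inv$reported, 7.7)

  # pressure -> voltage through the file interface
  write_vessel_geometry_json(vessel_geometry(500, 750, 1), "geom.json")
  res <- phantom_cli(c("pulse-to-voltage", "--geometry", "geom.json",
                       "--calibration", "pump.json", "--pressure", "pulse.csv",
                       "--step", "0.05", "--out-dir", "out"))
  expect_true(file.exists(file.path("out", "voltage_sequence.csv")))
  expect_equal(nrow(res$voltage), 20)

  # recipe solving through the file interface
  resp <- coarse_responses()
  tgt <- predict_mixture_spectra(phantom_recipe(0.75, 0, 5.13), resp)
  write_spectrum_csv(tgt$mua, "t_mua.csv")
  write_spectrum_csv(tgt$mus, "t_mus.csv")
  write_responses_json(resp, "resp.json")
  out <- capture.output(
    sol <- phantom_cli(c("solve-recipe", "--target-mua", "t_mua.csv",
                         "--target-mus", "t_mus.csv", "--responses", "resp.json",
                         "--out", "recipe.json")))
  expect_equal(unlist(sol$recipe, use.names = FALSE), c(0.75, 0, 5.13),
               tolerance = 1e-6)
  expect_true(file.exists("recipe.json"))

  expect_error(phantom_cli("no-such-command"),
               class = "pulsephantom_invalid_input")
})

test_that("modulus fitting works through the CLI file interface", {
  tmp <- withr::local_tempdir()
  withr::local_dir(tmp)
  phantom_cli(c("simulate", "stress-strain", "--modulus", "1.42",
                "--out", "curve.csv"))
  out <- capture.output(
    e <- phantom_cli(c("fit-modulus", "--input", "curve.csv")))
  expect_equal(e, 1.42, tolerance = 1e-9)

  # calibrate-elastic from a points CSV
  conc <- c(2.5, 5, 7.5, 10)
  write.csv(data.frame(curing_agent_pct = conc,
                       youngs_modulus_mpa = 0.18 * conc - 0.39),
            "points.csv", row.names = FALSE)
  out <- capture.output(
    cal <- phantom_cli(c("calibrate-elastic", "--input", "points.csv",
                         "--out", "cal.json")))
  expect_equal(cal$slope, 0.18, tolerance = 1e-9)
})
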