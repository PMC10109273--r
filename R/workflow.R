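# End-to-end workflows: design a phantom (mechanics + optics per layer) and
# replicate a pressure pulse as a pump-voltage sequence.

#' Skin-layer specification for phantom design
#'
#' @param name `"epidermis"`, `"dermis"` or `"hypodermis"`.
#' @param thickness_um layer thickness, um; defaults by layer (epidermis
#'   500, dermis 2000, hypodermis 2000).
#' @param vessel_diameter_um embedded vessel diameter, um; defaults by
#'   layer: capillary 50 (epidermis), arteriole 200 (dermis), artery 1000
#'   (hypodermis).
#' @param target_modulus_mpa target Young's modulus of the layer's vessel
#'   wall, MPa; defaults: capillary 0.37, arteriole 0.12, artery 1.
#' @param target_mua,target_mus optional target [spectrum()] objects for
#'   recipe solving.
#' @return Object of class `layer_spec`.
#' @export
layer_spec <- function(name = c("epidermis", "dermis", "hypodermis"),
                       thickness_um = NULL, vessel_diameter_um = NULL,
                       target_modulus_mpa = NULL,
                       target_mua = NULL, target_mus = NULL) {
  name <- match.arg(name)
  defaults <- list(
    epidermis = list(thickness_um = 500, vessel_diameter_um = 50,
                     target_modulus_mpa = 0.37),
    dermis = list(thickness_um = 2000, vessel_diameter_um = 200,
                  target_modulus_mpa = 0.12),
    hypodermis = list(thickness_um = 2000, vessel_diameter_um = 1000,
                      target_modulus_mpa = 1))[[name]]
  thickness_um <- thickness_um %||% defaults$thickness_um
  vessel_diameter_um <- vessel_diameter_um %||% defaults$vessel_diameter_um
  target_modulus_mpa <- target_modulus_mpa %||% defaults$target_modulus_mpa
  if (thickness_um <= 0) stop_invalid("thickness_um must be > 0")
  if (vessel_diameter_um <= 0) stop_invalid("vessel_diameter_um must be > 0")
  structure(list(name = name, thickness_um = thickness_um,
                 vessel_diameter_um = vessel_diameter_um,
                 target_modulus_mpa = target_modulus_mpa,
                 target_mua = target_mua, target_mus = target_mus),
            class = "layer_spec")
}

#' Design a multilayer phantom
#'
#' For each layer: invert the elastic calibration to the curing-agent
#' concentration reaching the target modulus, and (when target spectra are
#' given) solve the non-negative dopant recipe matching them.
#'
#' @param layers list of [layer_spec()].
#' @param elastic_cal an [elastic_calibration()] (used for every layer) or
#'   a named list of calibrations keyed by layer name.
#' @param responses named list of three [dopant_response()], required when
#'   any layer carries target spectra.
#' @param scattering_weight passed to [solve_recipe()].
#' @return Object of class `phantom_design`: per-layer list with
#'   `curing_agent_pct`, `curing_agent_reported`, `recipe`, `rms_mua`,
#'   `rms_mus`.
#' @export
design_phantom <- function(layers, elastic_cal, responses = NULL,
                           scattering_weight = 1) {
  if (length(layers) == 0L) stop_invalid("empty layer list")
  lapply(layers, function(l) stopifnot(inherits(l, "layer_spec")))
  get_cal <- function(nm) {
    if (inherits(elastic_cal, "elastic_calibration")) return(elastic_cal)
    cal <- elastic_cal[[nm]]
    if (is.null(cal)) stop_invalid("no elastic calibration for layer ", nm)
    cal
  }
  per_layer <- lapply(layers, function(l) {
    res <- tryCatch({
      inv <- invert_calibration(l$target_modulus_mpa, get_cal(l$name))
      out <- list(name = l$name,
                  thickness_um = l$thickness_um,
                  vessel_diameter_um = l$vessel_diameter_um,
                  target_modulus_mpa = l$target_modulus_mpa,
                  curing_agent_pct = inv$concentration_pct,
                  curing_agent_reported = inv$reported,
                  recipe = NULL, rms_mua = NA_real_, rms_mus = NA_real_)
      if (!is.null(l$target_mua) && !is.null(l$target_mus)) {
        if (is.null(responses))
          stop_invalid("layer has target spectra but no dopant responses given")
        sol <- solve_recipe(l$target_mua, l$target_mus, responses,
                            scattering_weight = scattering_weight)
        out$recipe <- sol$recipe
        out$rms_mua <- sol$rms_mua
        out$rms_mus <- sol$rms_mus
      }
      out
    }, error = function(e) {
      stop_invalid("layer `", l$name, "`: ", conditionMessage(e))
    })
    res
  })
  names(per_layer) <- vapply(layers, function(l) l$name, character(1))
  structure(list(layers = per_layer), class = "phantom_design")
}

#' @export
print.phantom_design <- function(x, ...) {
  cat("Phantom design\n")
  for (l in x$layers) {
    cat(sprintf("- %s (%g um thick, vessel %g um): E target %g MPa -> curing agent %.1f %%\n",
                l$name, l$thickness_um, l$vessel_diameter_um,
                l$target_modulus_mpa, l$curing_agent_reported))
    if (!is.null(l$recipe))
      cat(sprintf("    recipe mg/g: melanin %.3g, ink %.3g, TiO2 %.3g (RMS mua %.3g, mus %.3g /mm)\n",
                  l$recipe$melanin, l$recipe$ink, l$recipe$tio2,
                  l$rms_mua, l$rms_mus))
  }
  invisible(x)
}

#' Serialise a phantom design to JSON
#'
#' @param design a `phantom_design`.
#' @param path JSON file path.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "phantom_design"))
  ser <- lapply(design$layers, function(l) {
    l$recipe <- if (!is.null(l$recipe)) unclass(l$recipe)
    l
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Replicate a pressure pulse as a pump-voltage file set
#'
#' Reads the pressure waveform, geometry and pump calibration from disk,
#' runs [pulse_to_voltage()], and writes the displacement and voltage traces
#' as CSV (columns carry units). Optionally writes a PDF overview plot.
#'
#' @param pressure_csv CSV with `time_s` and `delta_p_kpa` (or
#'   `pressure_mmhg`).
#' @param geometry_json [vessel_geometry()] JSON.
#' @param calibration_json [pump_calibration()] JSON.
#' @param out_dir output directory, created if missing.
#' @param step_s voltage discretisation step, default 0.05 s.
#' @param plot logical; write `pulse_replication.pdf`, default `FALSE`.
#' @return invisibly, a list with the waveforms and written paths.
#' @export
replicate_pulse <- function(pressure_csv, geometry_json, calibration_json,
                            out_dir, step_s = 0.05, plot = FALSE) {
  pw <- read_pressure_csv(pressure_csv)
  geom <- read_vessel_geometry_json(geometry_json)
  cal <- read_pump_calibration_json(calibration_json)
  vs <- pulse_to_voltage(pw, geom, cal, step_s = step_s)
  dw <- attr(vs, "displacement")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    displacement = file.path(out_dir, "displacement.csv"),
    voltage = file.path(out_dir, "voltage_sequence.csv"))
  write_waveform_csv(dw, paths[["displacement"]])
  write_waveform_csv(vs, paths[["voltage"]])
  if (plot) {
    pdf_path <- file.path(out_dir, "pulse_replication.pdf")
    grDevices::pdf(pdf_path, width = 7, height = 7)
    graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
    graphics::plot(pw$time_s, pw$delta_p_kpa, type = "l",
                   xlab = "time (s)", ylab = "delta p (kPa)")
    graphics::plot(dw$time_s, dw$u_um, type = "l",
                   xlab = "time (s)", ylab = "u (um)")
    graphics::plot(vs$time_s, vs$voltage_vpp, type = "s",
                   xlab = "time (s)", ylab = "drive (Vpp)")
    grDevices::dev.off()
    paths <- c(paths, plot = pdf_path)
  }
  invisible(list(pressure = pw, displacement = dw, voltage = vs,
                 paths = paths))
}
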