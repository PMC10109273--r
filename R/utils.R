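# internal helpers shared across modules

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero, matching how bench values are reported
# (base round() is banker's rounding)
#' @noRd
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pulsephantom_invalid_input", "pulsephantom_error")))
}

#' @noRd
stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pulsephantom_degenerate_design", "pulsephantom_error")))
}

#' @noRd
assert_num <- function(x, name, len = NULL, finite = TRUE) {
  if (!is.numeric(x)) stop_invalid("`", name, "` must be numeric")
  if (!is.null(len) && length(x) != len)
    stop_invalid("`", name, "` must have length ", len)
  if (finite && any(!is.finite(x)))
    stop_invalid("`", name, "` must be finite (no NA/NaN/Inf)")
  invisible(x)
}

#' Convert pressure between mmHg and kPa
#'
#' Conversion used at I/O boundaries; internally all transmural pressures are
#' kilopascal. 1 mmHg = 0.133322 kPa.
#'
#' @param x numeric vector of pressures.
#' @param from,to `"mmHg"` or `"kPa"`.
#' @return numeric vector in the `to` unit.
#' @examples
#' convert_pressure(40, from = "mmHg", to = "kPa")
#' @export
convert_pressure <- function(x, from = c("mmHg", "kPa"), to = c("kPa", "mmHg")) {
  from <- match.arg(from)
  to <- match.arg(to)
  k <- 0.133322 # kPa per mmHg
  if (from == to) return(x)
  if (from == "mmHg") x * k else x / k
}

# uniform-grid check used by the waveform types; tol in seconds
#' @noRd
check_uniform_grid <- function(time, tol = 1e-9) {
  if (length(time) < 1L) stop_invalid("time grid is empty")
  if (length(time) > 1L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop_invalid("time must be strictly increasing")
    if (max(dt) - min(dt) > tol)
      stop_invalid("time grid must be uniform within ", tol, " s")
  }
  invisible(time)
}
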