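# Sellmeier dispersion: n^2(lambda) = 1 + sum_i B_i lambda^2 / (lambda^2 - C_i),
# lambda in micrometres, C_i in um^2. Fitted to multiwavelength refractometer
# readings by variable projection: for fixed pole positions C the B
# coefficients are linear and solved by OLS; C is optimised by bounded
# quasi-Newton from several deterministic starts.

#' Sellmeier refractive-index model
#'
#' @param sellmeier_b numeric, dimensionless oscillator strengths.
#' @param sellmeier_c numeric, resonance wavelengths squared, um^2; same
#'   length, each `>= 0` and below the visible grid (poles must sit outside
#'   the evaluation range).
#' @param check_grid wavelength grid (nm) over which `n^2 >= 1` is
#'   validated at construction; default the canonical 500–1000 nm grid.
#' @return Object of class `sellmeier_model`.
#' @examples
#' sellmeier_model(1.0, 0.01)
#' @export
sellmeier_model <- function(sellmeier_b, sellmeier_c,
                            check_grid = canonical_grid()) {
  assert_num(sellmeier_b, "sellmeier_b")
  assert_num(sellmeier_c, "sellmeier_c", len = length(sellmeier_b))
  if (length(sellmeier_b) < 1L) stop_invalid("need at least one term")
  if (any(sellmeier_c < 0)) stop_invalid("sellmeier_c must be >= 0")
  lam_min_um <- min(check_grid) / 1000
  if (any(sellmeier_c >= (0.9 * lam_min_um)^2))
    stop_invalid("sellmeier_c poles must lie safely below the wavelength grid")
  m <- structure(list(sellmeier_b = sellmeier_b, sellmeier_c = sellmeier_c,
                      n_terms = length(sellmeier_b)),
                 class = "sellmeier_model")
  n2 <- evaluate_sellmeier(m, check_grid)^2
  if (any(n2 < 1 - 1e-9))
    stop_invalid("model yields n^2 < 1 over the wavelength grid")
  m
}

#' @export
print.sellmeier_model <- function(x, ...) {
  cat(sprintf("Sellmeier model, %d term(s):\n", x$n_terms))
  for (i in seq_len(x$n_terms))
    cat(sprintf("  B%d = %.6g, C%d = %.6g um^2\n",
                i, x$sellmeier_b[i], i, x$sellmeier_c[i]))
  invisible(x)
}

#' @noRd
sellmeier_n2 <- function(b, cc, lam_um) {
  l2 <- lam_um^2
  n2 <- rep(1, length(l2))
  for (i in seq_along(b)) n2 <- n2 + b[i] * l2 / (l2 - cc[i])
  n2
}

#' Evaluate a Sellmeier model
#'
#' @param model a [sellmeier_model()].
#' @param wavelength_nm wavelengths, nm (vectorised); each must satisfy
#'   \eqn{\lambda^2 > \max(C_i)} with margin (pole proximity is a domain
#'   error).
#' @return refractive index n (dimensionless).
#' @examples
#' evaluate_sellmeier(sellmeier_model(1.0, 0.01), 1000)
#' @export
evaluate_sellmeier <- function(model, wavelength_nm) {
  stopifnot(inherits(model, "sellmeier_model"))
  assert_num(wavelength_nm, "wavelength_nm")
  lam_um <- wavelength_nm / 1000
  tol <- 1e-6 # um^2
  for (cc in model$sellmeier_c)
    if (any(lam_um^2 - cc < tol))
      stop_invalid("wavelength too close to a Sellmeier pole (lambda^2 - C < ",
                   tol, " um^2)")
  sqrt(sellmeier_n2(model$sellmeier_b, model$sellmeier_c, lam_um))
}

#' Fit a Sellmeier model to refractive-index measurements
#'
#' Nonlinear least squares on \eqn{n^2(\lambda)} by variable projection:
#' B is linear given C and solved by OLS; C is optimised by L-BFGS-B within
#' \eqn{[0, (0.9\,\lambda_{\min})^2]} from a deterministic grid of starting
#' points. Two terms are the default — nine refractometer wavelengths do not
#' robustly support six parameters under noise.
#'
#' @param wavelength_nm measurement wavelengths, nm.
#' @param n_values measured refractive indices, same length.
#' @param n_terms number of Sellmeier terms, 1–3; default 2.
#' @param max_restarts starting points tried before declaring failure.
#' @return a [sellmeier_model()] with attributes `"rms_residual"` (in n
#'   units) and `"converged"`.
#' @export
fit_sellmeier <- function(wavelength_nm, n_values, n_terms = 2,
                          max_restarts = 8) {
  assert_num(wavelength_nm, "wavelength_nm")
  assert_num(n_values, "n_values", len = length(wavelength_nm))
  if (!n_terms %in% 1:3) stop_invalid("n_terms must be 1, 2 or 3")
  m <- length(wavelength_nm)
  if (m < 2 * n_terms + 1)
    stop_invalid("need >= ", 2 * n_terms + 1, " measurements for ", n_terms,
                 " term(s); got ", m)
  lam_um <- wavelength_nm / 1000
  y <- n_values^2
  c_max <- (0.9 * min(lam_um))^2

  solve_b <- function(cc) {
    X <- vapply(cc, function(ci) lam_um^2 / (lam_um^2 - ci),
                numeric(m))
    X <- matrix(X, nrow = m)
    b <- tryCatch(qr.coef(qr(X), y - 1), error = function(e) NULL)
    if (is.null(b) || any(is.na(b))) return(NULL)
    b
  }
  objective <- function(cc) {
    b <- solve_b(cc)
    if (is.null(b)) return(1e12)
    sum((sellmeier_n2(b, cc, lam_um) - y)^2)
  }

  # deterministic starts: spread pole guesses through the allowed interval
  starts <- lapply(seq_len(max_restarts), function(k) {
    frac <- (seq_len(n_terms) - 0.5) / n_terms
    c_max * frac * (k / max_restarts)^2
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, objective, method = "L-BFGS-B",
            lower = rep(0, n_terms), upper = rep(c_max * 0.999, n_terms),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop_invalid("Sellmeier fit failed to converge after ", max_restarts,
                 " restarts")
  cc <- best$par
  b <- solve_b(cc)
  rms <- sqrt(mean((sqrt(pmax(sellmeier_n2(b, cc, lam_um), 0)) - n_values)^2))
  scale_n <- max(abs(n_values))
  if (best$convergence != 0 && rms > 1e-3 * scale_n)
    stop_invalid("Sellmeier fit did not converge; RMS residual ", signif(rms, 3))
  model <- sellmeier_model(b, cc, check_grid = wavelength_nm)
  attr(model, "rms_residual") <- rms
  attr(model, "converged") <- TRUE
  model
}
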