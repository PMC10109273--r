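# Independent oracles and shared fixtures for the test suite.

# Oracle for the closed-form radial displacement: compose the Lame stress
# expressions and Hooke's law step by step, independently of the package's
# radial_displacement() implementation.
oracle_displacement_um <- function(ri_um, ro_um, e_mpa, nu, dp_kpa) {
  ri2 <- ri_um^2
  ro2 <- ro_um^2
  sr <- -dp_kpa
  sh <- dp_kpa * (ri2 + ro2) / (ro2 - ri2)
  sz <- 2 * nu * dp_kpa * ri2 / (ro2 - ri2)
  eps_hoop <- (sh - nu * (sr + sz)) / (e_mpa * 1000)
  eps_hoop * ri_um
}

# random valid vessel geometries on a fixed seed
random_geometries <- function(n, seed = 123) {
  withr::with_seed(seed, {
    ri <- runif(n, 20, 2000)
    wall <- runif(n, 0.05, 2) * ri
    data.frame(ri = ri, ro = ri + wall,
               e = runif(n, 0.05, 5),
               nu = runif(n, 0, 0.5))
  })
}

# Brute-force NNLS oracle: enumerate every support subset, solve the
# unconstrained least-squares problem on it, and keep the best feasible
# (non-negative) solution. Exact for small p; independent of the
# Lawson-Hanson path.
oracle_nnls <- function(A, b) {
  p <- ncol(A)
  best <- NULL
  best_rss <- Inf
  for (mask in 0:(2^p - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))
    x <- numeric(p)
    if (any(on)) {
      cf <- tryCatch(qr.coef(qr(A[, on, drop = FALSE]), b),
                     error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) next
      if (any(cf < 0)) next
      x[on] <- cf
    }
    rss <- sum((b - A %*% x)^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- x
    }
  }
  best
}

# small synthetic dopant world on a coarse grid (fast tests)
coarse_responses <- function() synthetic_dopant_responses(seq(500, 1000, by = 20))
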