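# Independent fixed-step RK4 integration of the full master equation,
# written against the rate definitions only (no package internals); used as
# the brute-force oracle for the eigendecomposition solver.
rk4_survival <- function(n_R, n_L, k_off, k_on, t_end, dt = 1e-4) {
  M <- min(n_R, n_L)
  if (M < 1) return(0)
  m <- 0:M
  r <- m * k_off
  g <- (n_R - m) * (n_L - m) * k_on
  g[1L] <- 0
  deriv <- function(P) {
    dP <- -(r + g) * P
    dP[1:M] <- dP[1:M] + r[2:(M + 1)] * P[2:(M + 1)]
    dP[2:(M + 1)] <- dP[2:(M + 1)] + g[1:M] * P[1:M]
    dP
  }
  P <- c(rep(0, M), 1)
  for (i in seq_len(round(t_end / dt))) {
    k1 <- deriv(P)
    k2 <- deriv(P + dt / 2 * k1)
    k3 <- deriv(P + dt / 2 * k2)
    k4 <- deriv(P + dt * k3)
    P <- P + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  1 - P[1L]
}

# 1:1 Langmuir sensorgram evaluated independently of the package
langmuir_oracle <- function(t, k_on, k_off, R_max, conc, t_assoc) {
  K_D <- k_off / k_on
  R_eq <- R_max * conc / (conc + K_D)
  k_obs <- k_on * conc + k_off
  R_end <- R_eq * (1 - exp(-k_obs * t_assoc))
  ifelse(t <= t_assoc,
         R_eq * (1 - exp(-k_obs * t)),
         R_end * exp(-k_off * (t - t_assoc)))
}

# the anchor-based calibration of the retention model is expensive; run it
# once per test session and share across files
cached_calibration <- local({
  cal <- NULL
  function() {
    if (is.null(cal))
      cal <<- calibrate_rebinding(c(250, 375), c(1.2 * 3600, 1.5 * 86400),
                                  k_off = 0.15)
    cal
  }
})
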