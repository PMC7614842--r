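#' Two-fold analyte dilution series for BLI titrations
#'
#' Eight two-fold dilutions from 2.9 uM down to ~0.023 uM, the concentration
#' range over which C3dg binding to immobilised CR2 is titrated.
#'
#' @param top highest analyte concentration, M.
#' @param n number of two-fold dilutions.
#' @return Increasing numeric vector of concentrations in M.
#' @export
bli_concentration_series <- function(top = 2.9e-6, n = 8) {
  sort(top / 2^(seq_len(n) - 1))
}

#' Simulate a 1:1 Langmuir BLI sensorgram
#'
#' Association phase `R(t) = R_eq (1 - exp(-(k_on C + k_off) t))` with
#' `R_eq = R_max C / (C + K_D)`, `K_D = k_off / k_on`, followed by a
#' dissociation phase decaying from the association end value as
#' `exp(-k_off tau)`. Optional additive Gaussian read noise.
#'
#' @param k_on association rate, M^-1 s^-1 (> 0).
#' @param k_off dissociation rate, s^-1 (> 0).
#' @param R_max saturating response, RU (> 0).
#' @param concentration analyte concentration, M (> 0).
#' @param t_assoc,t_dissoc phase durations, s (> 0).
#' @param dt sampling interval, s.
#' @param noise_sd Gaussian noise standard deviation, RU (0 = noiseless).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return A `sensorgram` object: `analyte_concentration`, `times`,
#'   `response`, `association_end_time`.
#' @export
simulate_sensorgram <- function(k_on, k_off, R_max, concentration,
                                t_assoc = 300, t_dissoc = 300, dt = 0.5,
                                noise_sd = 0, seed = 1L) {
  if (k_on <= 0 || k_off <= 0 || R_max <= 0 || concentration <= 0)
    stop("rates, R_max and concentration must be positive")
  stopifnot(t_assoc > 0, t_dissoc > 0, dt > 0, noise_sd >= 0)
  times <- seq(0, t_assoc + t_dissoc, by = dt)
  resp <- .langmuir_response(times, k_on, k_off, R_max, concentration,
                             t_assoc)
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    resp <- resp + stats::rnorm(length(resp), sd = noise_sd)
  }
  structure(list(analyte_concentration = concentration, times = times,
                 response = resp, association_end_time = t_assoc),
            class = "sensorgram")
}

# noiseless 1:1 Langmuir model over both phases
.langmuir_response <- function(times, k_on, k_off, R_max, conc, t_assoc) {
  K_D <- k_off / k_on
  R_eq <- R_max * conc / (conc + K_D)
  k_obs <- k_on * conc + k_off
  R_end <- R_eq * (1 - exp(-k_obs * t_assoc))
  ifelse(times <= t_assoc,
         R_eq * (1 - exp(-k_obs * times)),
         R_end * exp(-k_off * (times - t_assoc)))
}

#' Global 1:1 kinetic fit of a sensorgram panel
#'
#' Nonlinear least squares with `k_on`, `k_off` and `R_max` shared across
#' all analyte concentrations (global fit), parameterised on log scale.
#' Starting values come from a coarse log-spaced grid search. The reported
#' `K_D` is `k_off / k_on` by definition.
#'
#' @param sensorgrams list of `sensorgram` objects at >= 2 concentrations
#'   (a single trace is accepted with a warning: ill-conditioned).
#' @return A `kinetic_fit` object: `k_on` (M^-1 s^-1), `k_off` (s^-1),
#'   `R_max` (RU), `K_D` (M), `ssr`, `n_obs`.
#' @export
fit_kinetic <- function(sensorgrams) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  stopifnot(length(sensorgrams) >= 1L,
            all(vapply(sensorgrams, inherits, logical(1L), "sensorgram")))
  concs <- vapply(sensorgrams, `[[`, numeric(1L), "analyte_concentration")
  if (length(unique(concs)) < 2L)
    warning("kinetic fit from a single analyte concentration is ",
            "ill-conditioned; k_on and R_max are poorly separable")

  resid_fun <- function(par) {
    k_on <- exp(par[1L]); k_off <- exp(par[2L]); R_max <- exp(par[3L])
    unlist(lapply(sensorgrams, function(sg) {
      sg$response - .langmuir_response(sg$times, k_on, k_off, R_max,
                                       sg$analyte_concentration,
                                       sg$association_end_time)
    }))
  }

  # coarse grid search for starting values (log-spaced, R_max from data)
  R0 <- max(vapply(sensorgrams, function(sg) max(sg$response), numeric(1L)))
  R0 <- max(R0, .Machine$double.eps)
  grid <- expand.grid(lk_on = log(10^seq(3, 7, by = 1)),
                      lk_off = log(10^seq(-4, 1, by = 1)))
  sse <- apply(grid, 1L, function(g)
    sum(resid_fun(c(g[[1L]], g[[2L]], log(1.2 * R0)))^2))
  start <- c(grid$lk_on[which.min(sse)], grid$lk_off[which.min(sse)],
             log(1.2 * R0))

  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (fit$info %in% c(0L, 5L))
    stop("kinetic fit did not converge: ", fit$message,
         " (ssr = ", format(fit$deviance), ")")
  k_on <- exp(fit$par[1L]); k_off <- exp(fit$par[2L]); R_max <- exp(fit$par[3L])
  structure(list(k_on = k_on, k_off = k_off, R_max = R_max,
                 K_D = k_off / k_on, ssr = fit$deviance,
                 n_obs = sum(vapply(sensorgrams, function(s)
                   length(s$times), integer(1L)))),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 kinetic fit: k_on = %.6g M^-1 s^-1, k_off = %.4g s^-1,\n",
              x$k_on, x$k_off))
  cat(sprintf("  R_max = %.4g RU, K_D = %.4g nM, ssr = %.3g (%d points)\n",
              x$R_max, x$K_D * 1e9, x$ssr, x$n_obs))
  invisible(x)
}

#' Equilibrium (steady-state) binding fit
#'
#' Least-squares fit of the binding hyperbola
#' `R_eq(C) = R_max C / (C + K_D)` to plateau responses.
#'
#' @param concentrations analyte concentrations, M (>= 3 points).
#' @param plateau_responses equilibrium responses, RU.
#' @return An `equilibrium_fit`: `K_D` (M), `R_max` (RU), `ssr`.
#' @export
fit_equilibrium <- function(concentrations, plateau_responses) {
  stopifnot(is.numeric(concentrations), is.numeric(plateau_responses),
            length(concentrations) == length(plateau_responses),
            all(concentrations > 0))
  if (length(concentrations) < 3L)
    stop("equilibrium fit needs at least 3 concentration points")
  if (stats::sd(plateau_responses) == 0)
    stop("degenerate fit: all plateau responses are equal")
  df <- data.frame(C = concentrations, R = plateau_responses)
  fit <- minpack.lm::nlsLM(R ~ R_max * C / (C + K_D), data = df,
                           start = list(R_max = max(df$R) * 1.2,
                                        K_D = stats::median(df$C)),
                           lower = c(0, 0),
                           control = stats::nls.control(maxiter = 200))
  est <- stats::coef(fit)
  structure(list(K_D = unname(est["K_D"]), R_max = unname(est["R_max"]),
                 ssr = sum(stats::resid(fit)^2)),
            class = "equilibrium_fit")
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  cat(sprintf("Equilibrium fit: K_D = %.4g nM, R_max = %.4g RU, ssr = %.3g\n",
              x$K_D * 1e9, x$R_max, x$ssr))
  invisible(x)
}

#' Fluorescent-bead calibration line
#'
#' Ordinary least-squares line mapping fluorescence (MFI) to absolute
#' molecule counts, from a panel of beads conjugated with known amounts of
#' fluorophore (e.g. a 4-level PE quantitation kit). The intercept is
#' retained to absorb autofluorescence.
#'
#' @param bead_mfi measured bead fluorescence values (>= 2 distinct).
#' @param bead_molecule_counts known fluorophore counts per bead.
#' @return A `bead_calibration`: `slope`, `intercept`, `r_squared`.
#' @export
bead_calibration <- function(bead_mfi, bead_molecule_counts) {
  stopifnot(is.numeric(bead_mfi), is.numeric(bead_molecule_counts),
            length(bead_mfi) == length(bead_molecule_counts),
            length(bead_mfi) >= 2L)
  if (length(unique(bead_mfi)) < 2L)
    stop("degenerate bead panel: all MFI values identical")
  fit <- stats::lm(bead_molecule_counts ~ bead_mfi)
  co <- stats::coef(fit)
  # direct r^2 (summary.lm warns on exactly collinear panels)
  tss <- sum((bead_molecule_counts - mean(bead_molecule_counts))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 r_squared = r2),
            class = "bead_calibration")
}

#' @export
print.bead_calibration <- function(x, ...) {
  cat(sprintf("Bead calibration: molecules = %.6g * MFI + %.6g (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert a cell's MFI to a receptor surface density
#'
#' Applies the bead calibration line to obtain molecules per cell, floors
#' negative extrapolations at zero, and divides by the cell surface area.
#'
#' @param mfi fluorescence value(s).
#' @param calibration a [bead_calibration] object.
#' @param cell_surface_area cell surface area, um^2 (> 0).
#' @return Receptor density in molecules/um^2.
#' @export
mfi_to_density <- function(mfi, calibration, cell_surface_area) {
  stopifnot(inherits(calibration, "bead_calibration"), is.numeric(mfi))
  if (!is.numeric(cell_surface_area) || cell_surface_area <= 0)
    stop("cell_surface_area must be positive")
  pmax(calibration$slope * mfi + calibration$intercept, 0) /
    cell_surface_area
}

#' Exponential decay fit of in-vivo IC levels
#'
#' Least-squares fit of `A exp(-lambda * day)` to antigen MFI observations
#' over time (nonlinear regression with free intercept at day 0); the
#' derived half-life is `ln(2) / lambda`.
#'
#' @param days observation days (>= 3 points).
#' @param levels measured levels (MFI units).
#' @return A `decay_fit`: `initial_level` (A), `rate` (lambda, day^-1),
#'   `half_life_days`, `ssr`.
#' @export
fit_decay <- function(days, levels) {
  stopifnot(is.numeric(days), is.numeric(levels),
            length(days) == length(levels))
  if (length(days) < 3L) stop("decay fit needs at least 3 time points")
  pos <- levels > 0
  if (!any(pos)) stop("decay fit impossible: no positive levels")
  # log-linear start, refined by nonlinear least squares
  start_fit <- stats::lm(log(levels[pos]) ~ days[pos])
  start <- list(A = exp(unname(stats::coef(start_fit)[1L])),
                lambda = max(-unname(stats::coef(start_fit)[2L]), 1e-8))
  df <- data.frame(day = days, level = levels)
  fit <- minpack.lm::nlsLM(level ~ A * exp(-lambda * day), data = df,
                           start = start, lower = c(0, 0),
                           control = stats::nls.control(maxiter = 200))
  est <- stats::coef(fit)
  rate <- unname(est["lambda"])
  structure(list(initial_level = unname(est["A"]), rate = rate,
                 half_life_days = if (rate > 0) log(2) / rate else Inf,
                 ssr = sum(stats::resid(fit)^2)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Decay fit: A = %.4g, lambda = %.4g /day, half-life = %.4g days\n",
              x$initial_level, x$rate, x$half_life_days))
  invisible(x)
}

#' ELISA antibody titer transform
#'
#' Titers are reported as `-log2(dilution) * 40` for the limiting serum
#' dilution.
#'
#' @param dilution serum dilution fraction in (0, 1].
#' @return Dimensionless titer (vectorised).
#' @examples
#' elisa_titer(1 / 1024) # 400
#' @export
elisa_titer <- function(dilution) {
  if (!is.numeric(dilution) || any(dilution <= 0) || any(dilution > 1))
    stop("dilution must lie in (0, 1]")
  -log2(dilution) * 40
}
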