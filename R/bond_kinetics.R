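#' Bond-kinetics parameter set for the IC-FDC dissociation model
#'
#' Bundles the rate constants and valency of the multivalent-bond
#' master-equation model: an immune complex (IC) carrying `n_L` accessible
#' C3d ligands sits on a membrane patch presenting `n_R` CR2 receptors; each
#' of the `m` closed bonds opens at rate `k_off` and a new bond forms at rate
#' `C(m) * k_on` where `C(m) = (n_R - m)(n_L - m)` counts the open
#' receptor-ligand pairings (all-to-all accessibility). `k_on` is an
#' effective two-dimensional per-configuration rate in s^-1; it is *not* the
#' solution-phase association constant (M^-1 s^-1) measured by BLI -- only
#' `k_off` carries over from the solution measurement.
#'
#' @param k_off per-bond dissociation rate, s^-1 (> 0).
#' @param k_on effective per-configuration rebinding rate, s^-1 (>= 0).
#' @param n_L number of accessible C3d ligands per IC (integer >= 1).
#' @param patch_area membrane patch area in um^2 (> 0). With the default of
#'   1 um^2, CR2 densities in molecules/um^2 map one-to-one onto mean
#'   receptor counts per patch.
#' @return An object of class `bond_params`.
#' @examples
#' bond_params(k_off = 0.15, k_on = 1e-4, n_L = 8)
#' @export
bond_params <- function(k_off, k_on, n_L, patch_area = 1) {
  stopifnot(is.numeric(k_off), length(k_off) == 1L, is.finite(k_off),
            is.numeric(k_on), length(k_on) == 1L, is.finite(k_on),
            is.numeric(n_L), length(n_L) == 1L, is.finite(n_L),
            is.numeric(patch_area), length(patch_area) == 1L)
  if (k_off <= 0) stop("k_off must be > 0")
  if (k_on < 0) stop("k_on must be >= 0")
  if (n_L < 1 || n_L != round(n_L)) stop("n_L must be a positive integer")
  if (patch_area <= 0) stop("patch_area must be > 0")
  structure(list(k_off = k_off, k_on = k_on, n_L = as.integer(n_L),
                 patch_area = patch_area),
            class = "bond_params")
}

#' @export
print.bond_params <- function(x, ...) {
  cat("IC-FDC bond kinetics parameters\n")
  cat(sprintf("  k_off      %.4g s^-1   (single-bond lifetime %.3g s)\n",
              x$k_off, 1 / x$k_off))
  cat(sprintf("  k_on       %.4g s^-1   (effective per-configuration rebinding)\n",
              x$k_on))
  cat(sprintf("  n_L        %d ligands per IC\n", x$n_L))
  cat(sprintf("  patch_area %.4g um^2\n", x$patch_area))
  invisible(x)
}

#' Number of open receptor-ligand binding configurations
#'
#' All-to-all accessibility: with `m` bonds closed, `n_R - m` free receptors
#' can pair with any of `n_L - m` free ligands, so
#' `C(m) = (n_R - m)(n_L - m)`. The rebinding rate of the chain is
#' `g(m) = C(m) * k_on`; it vanishes at `m = min(n_R, n_L)`.
#'
#' @param m number of closed bonds, `0 <= m <= min(n_R, n_L)`.
#' @param n_R CR2 receptor count on the patch.
#' @param n_L ligand count on the IC.
#' @return Non-negative integer-valued count (vectorised over `m`).
#' @examples
#' configuration_count(0, n_R = 250, n_L = 40) # 10000
#' @export
configuration_count <- function(m, n_R, n_L) {
  stopifnot(is.numeric(m), is.numeric(n_R), is.numeric(n_L))
  if (any(m < 0) || any(m > min(n_R, n_L)))
    stop("m must lie in [0, min(n_R, n_L)]")
  (n_R - m) * (n_L - m)
}

#' Default logarithmic time grid for retention curves
#'
#' 400 log-spaced points from 0.1 s to 2e7 s (~231 days) prepended with
#' t = 0, wide enough to bracket IC half-lives from sub-second to months.
#'
#' @param t_min,t_max range of the logarithmic part, seconds.
#' @param n number of log-spaced points.
#' @return Increasing numeric vector starting at 0.
#' @export
retention_time_grid <- function(t_min = 0.1, t_max = 2e7, n = 400) {
  stopifnot(t_min > 0, t_max > t_min, n >= 2)
  c(0, exp(seq(log(t_min), log(t_max), length.out = n)))
}

# The eigensolve expresses S(t) with similarity-scaled weights that must sum
# to S(0) = 1 exactly; the observed drift |sum(w) - 1| ~ eps * max|w| bounds
# the absolute error of the whole curve, so curves whose drift exceeds this
# tolerance are recomputed by a stiff banded ODE solve instead.
.weight_cancel_tol <- 1e-6

# Single-patch survival S(t) (fast path). Closed form for k_on = 0
# (independent bonds), LAPACK eigensolve otherwise, ODE fallback if the
# similarity scale overflowed.
.patch_survival <- function(params, n_R, times) {
  M <- min(n_R, params$n_L)
  if (M < 1) return(rep(0, length(times)))
  if (params$k_on == 0 || M == 1) {
    # with min(nR, nL) = 1 the rebinding rate g(1) = C(1) k_on vanishes, and
    # with k_on = 0 the M bonds die independently at k_off: closed forms
    p <- exp(-params$k_off * times)
    return(1 - (1 - p)^M)
  }
  S <- .Call(C_patch_survival, as.integer(n_R), as.integer(params$n_L),
             as.numeric(params$k_off), as.numeric(params$k_on),
             as.numeric(times), .weight_cancel_tol)
  if (is.logical(S) || any(!is.finite(S)))
    S <- .ode_survival(params, n_R, times)
  pmin(pmax(S, 0), 1)
}

# Stiff ODE fallback for the transient block; rarely used, kept for
# numerical robustness when the symmetrized eigen-coefficients overflow.
.ode_survival <- function(params, n_R, times) {
  sol <- .ode_master(params, n_R, times)
  1 - sol$P[1L, ]
}

# Weighted mixture contribution sum_j w_j S_{nR_j}(t) for many patches in a
# single banded lsoda call: the per-patch transient blocks share the death
# rates r(m) = m k_off and are stacked into one tridiagonal-banded system
# (blocks are uncoupled, so bandwidth stays 1 in the flattened ordering).
# Requires min(nR_j, n_L) identical across terms; callers split otherwise.
.ode_survival_multi <- function(params, nRs, weights, times) {
  Ms <- pmin(nRs, params$n_L)
  if (length(unique(Ms)) > 1L) {
    S <- rep(0, length(times))
    for (grp in split(seq_along(nRs), Ms))
      S <- S + .ode_survival_multi(params, nRs[grp], weights[grp], times)
    return(S)
  }
  M <- Ms[1L]
  K <- length(nRs)
  m <- 1:M
  r <- m * params$k_off
  G <- vapply(nRs, function(nR) (nR - m) * (params$n_L - m) * params$k_on,
              numeric(M)) # M x K; row M is 0 since C(M) = 0
  rhs <- function(t, P, parms) {
    dim(P) <- c(M, K)
    up <- rbind(r[-1L] * P[-1L, , drop = FALSE], rep(0, K))
    down <- rbind(rep(0, K),
                  G[-M, , drop = FALSE] * P[-M, , drop = FALSE])
    dP <- up + down - (r + G) * P
    list(as.numeric(dP))
  }
  P0 <- as.numeric(rbind(matrix(0, M - 1L, K), rep(1, K)))
  tt <- times
  added0 <- FALSE
  if (tt[1L] > 0) { tt <- c(0, tt); added0 <- TRUE }
  out <- deSolve::lsoda(P0, tt, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-12,
                        jactype = "bandint", bandup = 1L, banddown = 1L)
  P <- unname(out[, -1L, drop = FALSE]) # time x (M*K)
  if (added0) P <- P[-1L, , drop = FALSE]
  # S_j(t) = sum_m P_mj(t); weight and sum across blocks
  block <- rep(seq_len(K), each = M)
  as.numeric(P %*% (weights[block]))
}

.ode_master <- function(params, n_R, times) {
  M <- min(n_R, params$n_L)
  m <- 0:M
  r <- m * params$k_off
  g <- (n_R - m) * (params$n_L - m) * params$k_on
  g[1L] <- 0 # absorbing: no re-association from m = 0
  rhs <- function(t, P, parms) {
    flow_down <- r * P                       # m -> m-1
    flow_up <- g * P                         # m -> m+1
    dP <- -flow_down - flow_up
    dP[1:M] <- dP[1:M] + flow_down[2:(M + 1)]
    dP[2:(M + 1)] <- dP[2:(M + 1)] + flow_up[1:M]
    list(dP)
  }
  P0 <- c(rep(0, M), 1)
  tt <- times
  added0 <- FALSE
  if (tt[1L] > 0) { tt <- c(0, tt); added0 <- TRUE }
  out <- deSolve::lsoda(P0, tt, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-14,
                        jactype = "bandint", bandup = 1L, banddown = 1L)
  P <- t(unname(out[, -1L, drop = FALSE]))
  if (added0) P <- P[, -1L, drop = FALSE]
  list(times = times, P = P)
}

#' Solve the IC dissociation master equation on one membrane patch
#'
#' Solves `dP_m/dt = r(m+1) P_{m+1} + g(m-1) P_{m-1} - (r(m) + g(m)) P_m` on
#' the bond-number states `m = 0..M`, `M = min(n_R, n_L)`, with
#' `r(m) = m k_off`, `g(m) = C(m) k_on` and `g(0) = 0` (once fully detached
#' the IC does not re-associate), starting from maximum bond formation
#' (all mass at `m = M`). The transient block is solved exactly by
#' eigendecomposition of its symmetrized tridiagonal form, so arbitrary
#' (e.g. log-spaced) time grids cost one decomposition.
#'
#' @param params a [bond_params] object.
#' @param n_R CR2 receptor count on the patch (integer >= 0). `n_R = 0`
#'   returns the degenerate solution with all mass at `m = 0` (survival
#'   identically zero) rather than an error.
#' @param times strictly increasing time grid in seconds starting at 0.
#' @return An object of class `me_solution`: list with `times`, the
#'   `(M+1) x length(times)` probability matrix `P` (row `m+1` is `P_m(t)`),
#'   and the patch description.
#' @seealso [survival_probability()], [poisson_mixture_survival()]
#' @export
solve_master_equation <- function(params, n_R, times) {
  stopifnot(inherits(params, "bond_params"))
  .check_times(times, require_zero = TRUE)
  if (length(n_R) != 1L || n_R < 0 || n_R != round(n_R))
    stop("n_R must be a single non-negative integer")
  n_R <- as.integer(n_R)
  M <- min(n_R, params$n_L)

  if (M == 0L) {
    P <- matrix(1, nrow = 1L, ncol = length(times))
    rownames(P) <- "0"
    return(structure(list(times = times, P = P, n_R = n_R,
                          n_L = params$n_L, M = 0L, params = params),
                     class = "me_solution"))
  }

  if (params$k_on == 0) {
    # independent bonds: binomial occupation, p(t) = exp(-k_off t)
    p <- exp(-params$k_off * times)
    P <- vapply(seq_along(times), function(i)
      stats::dbinom(0:M, size = M, prob = p[i]), numeric(M + 1L))
  } else {
    eig <- .Call(C_me_eig, n_R, as.integer(params$n_L),
                 as.numeric(params$k_off), as.numeric(params$k_on))
    scale <- exp(eig$logd[M] - eig$logd)
    P <- NULL
    if (all(is.finite(scale))) {
      B <- eig$vectors * scale # row m scaled by d_M / d_m
      Ew <- exp(outer(eig$values, times)) * eig$vectors[M, ]
      P1M <- B %*% Ew
      # similarity-scaled coefficients cancel catastrophically in strongly
      # unbalanced regimes; the t = 0 column must sum to 1 exactly
      # gate at 1e-9 so probability stays conserved to < 1e-8 even after
      # the final clamp of tiny negatives
      if (all(is.finite(P1M)) && abs(sum(P1M[, 1L]) - 1) <= 1e-9)
        P <- rbind(1 - colSums(P1M), P1M)
    }
    if (is.null(P)) P <- .ode_master(params, n_R, times)$P
  }
  P <- pmin(pmax(P, 0), 1)
  dimnames(P) <- list(0:M, NULL)
  structure(list(times = times, P = P, n_R = n_R, n_L = params$n_L,
                 M = M, params = params),
            class = "me_solution")
}

.check_times <- function(times, require_zero = FALSE) {
  if (!is.numeric(times) || length(times) < 2L || any(!is.finite(times)))
    stop("times must be a finite numeric grid with at least two points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (require_zero && times[1L] != 0) stop("time grid must start at 0")
  invisible(times)
}

#' Survival probability of an IC from a master-equation solution
#'
#' `S(t) = sum_{m >= 1} P_m(t) = 1 - P_0(t)`: the probability that at least
#' one bond still tethers the IC to the patch at time t.
#'
#' @param sol an `me_solution` from [solve_master_equation()].
#' @return A `survival_curve` object (fields `times`, `S`, `mean_n_R`,
#'   `kind = "patch"`).
#' @export
survival_probability <- function(sol) {
  stopifnot(inherits(sol, "me_solution"))
  S <- 1 - sol$P[1L, ]
  new_survival_curve(sol$times, S, mean_n_R = sol$n_R, kind = "patch",
                     params = sol$params)
}

new_survival_curve <- function(times, S, mean_n_R, kind, params = NULL) {
  structure(list(times = times, S = as.numeric(S), mean_n_R = mean_n_R,
                 kind = kind, params = params),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("IC survival curve (%s), %s = %.4g, %d time points, S(0) = %.4g\n",
              x$kind,
              if (x$kind == "poisson") "<n_R>" else "n_R",
              x$mean_n_R, length(x$times), x$S[1L]))
  invisible(x)
}

#' Poisson-averaged IC survival over receptor-count heterogeneity
#'
#' FDC membrane patches carry Poisson-distributed CR2 counts around a mean
#' density. The mixture survival is
#' `<S(t)> = sum_nR Pois(nR; mean) S_nR(t)`, with the sum truncated to a
#' central window covering at least `1 - 1e-8` of the Poisson mass. Patches
#' with `n_R = 0` never bind an IC and contribute `S = 0`, which is why
#' `<S(0)> = 1 - exp(-mean)` rather than exactly 1.
#'
#' @param params a [bond_params] object.
#' @param mean_n_R mean CR2 count per patch (>= 0); use
#'   [density_to_mean_nR()] to convert a surface density.
#' @param times strictly increasing time grid, seconds.
#' @return A `survival_curve` with `kind = "poisson"`.
#' @export
poisson_mixture_survival <- function(params, mean_n_R, times) {
  stopifnot(inherits(params, "bond_params"))
  if (!is.numeric(mean_n_R) || length(mean_n_R) != 1L ||
      !is.finite(mean_n_R) || mean_n_R < 0)
    stop("mean_n_R must be a single non-negative number")
  .check_times(times)

  if (mean_n_R == 0)
    return(new_survival_curve(times, rep(0, length(times)), 0, "poisson",
                              params))

  lo <- stats::qpois(5e-9, mean_n_R)
  hi <- stats::qpois(1 - 5e-9, mean_n_R)
  nRs <- lo:hi
  w <- stats::dpois(nRs, mean_n_R)

  if (params$k_on == 0 || min(hi, params$n_L) <= 1L) {
    # closed forms per term, no eigensolve needed
    S <- rep(0, length(times))
    for (j in seq_along(nRs)) {
      if (nRs[j] == 0L) next
      S <- S + w[j] * .patch_survival(params, nRs[j], times)
    }
  } else {
    res <- .Call(C_poisson_survival, as.integer(nRs), as.numeric(w),
                 as.integer(params$n_L), as.numeric(params$k_off),
                 as.numeric(params$k_on), as.numeric(times),
                 .weight_cancel_tol)
    S <- res[[1L]]
    bad <- which(res[[2L]])
    if (length(bad)) # ill-conditioned terms: one stacked banded ODE solve
      S <- S + .ode_survival_multi(params, nRs[bad], w[bad], times)
  }
  new_survival_curve(times, pmin(pmax(S, 0), 1), mean_n_R, "poisson", params)
}

#' Mean IC surface level on FDCs
#'
#' The observable compared against in-vivo antigen MFI: the Poisson-averaged
#' survival scaled by the mean receptor count, `<S(t)> * <n_R>` (mean ICs
#' retained per patch). Defined only for Poisson-averaged curves.
#'
#' @param curve a `survival_curve` with `kind = "poisson"`.
#' @return An `ic_level_series`: list with `times`, `level`, `mean_n_R`.
#' @export
ic_surface_level <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  if (!identical(curve$kind, "poisson"))
    stop("IC surface level is defined for Poisson-averaged curves only")
  structure(list(times = curve$times, level = curve$S * curve$mean_n_R,
                 mean_n_R = curve$mean_n_R),
            class = "ic_level_series")
}

#' Half-life of IC retention
#'
#' Time at which the (averaged) IC level first reaches half of its value at
#' the first grid point, located by interpolating the level linearly against
#' log-time between the bracketing grid points (linear in time when the
#' lower bracket is t = 0).
#'
#' @param x a `survival_curve`, an `ic_level_series`, or a numeric vector of
#'   times (then `level` must be supplied).
#' @param level numeric level series matching `x` when `x` is a time vector.
#' @param ... unused.
#' @return Half-life in seconds.
#' @export
half_life <- function(x, ...) UseMethod("half_life")

#' @rdname half_life
#' @export
half_life.survival_curve <- function(x, ...) .half_life_num(x$times, x$S)

#' @rdname half_life
#' @export
half_life.ic_level_series <- function(x, ...) .half_life_num(x$times, x$level)

#' @rdname half_life
#' @export
half_life.default <- function(x, level, ...) .half_life_num(x, level)

.half_life_num <- function(times, level) {
  stopifnot(is.numeric(times), is.numeric(level),
            length(times) == length(level), length(times) >= 2L)
  level <- cummin(pmax(level, 0)) # guard against tiny numerical wiggles
  ref <- level[1L]
  if (ref <= 0) stop("initial level must be positive")
  target <- ref / 2
  idx <- which(level <= target)
  if (length(idx) == 0L)
    stop("level never reaches half its initial value; extend the time grid")
  i <- idx[1L]
  if (i == 1L) return(times[1L])
  t0 <- times[i - 1L]; t1 <- times[i]
  l0 <- level[i - 1L]; l1 <- level[i]
  if (l0 == l1) return(t1)
  frac <- (l0 - target) / (l0 - l1)
  if (t0 <= 0) t0 + frac * (t1 - t0)
  else exp(log(t0) + frac * (log(t1) - log(t0)))
}

#' Convert a CR2 surface density to a mean per-patch receptor count
#'
#' The model works in receptor counts per membrane patch while quantitative
#' flow cytometry reports molecules/um^2; the two are linked by the patch
#' area (default 1 um^2, making the mapping the identity).
#'
#' @param density CR2 surface density, molecules/um^2 (>= 0, vectorised).
#' @param patch_area patch area in um^2 (> 0).
#' @return Mean receptor count(s) per patch.
#' @export
density_to_mean_nR <- function(density, patch_area = 1) {
  if (!is.numeric(density) || any(density < 0))
    stop("density must be non-negative")
  if (!is.numeric(patch_area) || length(patch_area) != 1L || patch_area <= 0)
    stop("patch_area must be a single positive number")
  density * patch_area
}
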