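test_that("configuration count follows the all-to-all formula", {
  expect_equal(configuration_count(0, n_R = 250, n_L = 40), 10000)
  expect_equal(configuration_count(2, n_R = 10, n_L = 2), 0)
  expect_equal(configuration_count(1, n_R = 3, n_L = 2), 2)
  expect_equal(configuration_count(0:2, n_R = 3, n_L = 2), c(6, 2, 0))
  expect_error(configuration_count(3, n_R = 3, n_L = 2), "must lie")
  expect_error(configuration_count(-1, n_R = 3, n_L = 2), "must lie")
})

test_that("master-equation solution matches closed forms", {
  tt <- c(0, exp(seq(log(0.05), log(60), length.out = 80)))
  # single ligand: pure exponential decay at k_off whatever k_on is
  p1 <- bond_params(k_off = 0.15, k_on = 3, n_L = 1)
  S1 <- survival_probability(solve_master_equation(p1, 7L, tt))
  expect_lt(max(abs(S1$S - exp(-0.15 * tt))), 1e-6)
  expect_equal(S1$S[tt == 0], 1)
  # no rebinding: independent bonds, loss requires all M open
  p0 <- bond_params(k_off = 1, k_on = 0, n_L = 2)
  S0 <- survival_probability(solve_master_equation(p0, 2L, tt))
  expect_lt(max(abs(S0$S - (1 - (1 - exp(-tt))^2))), 1e-6)
})

test_that("solver agrees with the fixed-step RK4 oracle", {
  # frozen value from the independent RK4 integrator at dt = 1e-4
  p <- bond_params(k_off = 1, k_on = 1, n_L = 2)
  sol <- solve_master_equation(p, 2L, c(0, 0.5, 1))
  expect_equal(unname(1 - sol$P[1L, 3L]), 0.6651433194, tolerance = 1e-6)
  expect_equal(unname(1 - sol$P[1L, 3L]), rk4_survival(2, 2, 1, 1, 1),
               tolerance = 1e-6)
  # a larger chain, same oracle
  expect_equal(unname(1 - solve_master_equation(bond_params(0.4, 0.05, 5),
                                                8L, c(0, 2))$P[1L, 2L]),
               rk4_survival(8, 5, 0.4, 0.05, 2), tolerance = 1e-6)
})

test_that("probability is conserved and the initial state is fully bound", {
  tt <- retention_time_grid(0.1, 1e5, 60)
  cases <- list(c(3, 2, 1, 1), c(10, 4, 0.5, 0.2), c(40, 12, 0.15, 1e-2),
                c(250, 39, 0.15, 1.6e-4), c(5, 5, 2, 0))
  for (cs in cases) {
    p <- bond_params(k_off = cs[3], k_on = cs[4], n_L = cs[2])
    sol <- solve_master_equation(p, as.integer(cs[1]), tt)
    expect_lt(max(abs(colSums(sol$P) - 1)), 1e-8)
    expect_true(all(sol$P >= 0 & sol$P <= 1))
    M <- min(cs[1], cs[2])
    expect_equal(unname(sol$P[M + 1L, 1L]), 1) # all mass at m = M at t = 0
  }
})

test_that("survival curves are monotone and vanish at long times", {
  tt <- retention_time_grid(0.1, 1e7, 120)
  p <- bond_params(k_off = 0.5, k_on = 0.05, n_L = 4)
  S <- survival_probability(solve_master_equation(p, 12L, tt))
  expect_true(all(diff(S$S) <= 1e-12))
  expect_lt(S$S[length(tt)], 1e-8) # all bonds break if one waits long enough
})

test_that("zero-receptor patches give the degenerate all-lost solution", {
  p <- bond_params(k_off = 0.15, k_on = 1, n_L = 4)
  sol <- solve_master_equation(p, 0L, c(0, 1, 10))
  expect_equal(unname(sol$P[1L, ]), c(1, 1, 1))
  expect_equal(survival_probability(sol)$S, c(0, 0, 0))
})

test_that("time grids are validated", {
  p <- bond_params(k_off = 1, k_on = 0, n_L = 2)
  expect_error(solve_master_equation(p, 2L, c(1, 2)), "start at 0")
  expect_error(solve_master_equation(p, 2L, c(0, 2, 2)), "increasing")
  expect_error(poisson_mixture_survival(p, 5, numeric(0)), "at least two")
})

test_that("Poisson mixture matches the truncated-sum oracle", {
  # frozen value from direct summation over n_R = 0..40 with the RK4
  # oracle per term: <S(2)> = 0.6624328575 for mean 5, n_L 3
  p <- bond_params(k_off = 1, k_on = 0.5, n_L = 3)
  cv <- poisson_mixture_survival(p, 5, c(0, 1, 2))
  expect_equal(cv$S[3L], 0.6624328575, tolerance = 1e-6)
  oracle <- sum(vapply(1:40, function(nR)
    dpois(nR, 5) * rk4_survival(nR, 3, 1, 0.5, 2), numeric(1L)))
  expect_equal(cv$S[3L], oracle, tolerance = 1e-6)
})

test_that("Poisson mixture limits behave", {
  tt <- c(0, 1, 10, 100)
  p <- bond_params(k_off = 0.15, k_on = 2, n_L = 1)
  expect_equal(poisson_mixture_survival(p, 0, tt)$S, rep(0, 4))
  # n_L = 1: only unloaded patches fail to bind, the rest decay at k_off
  cv <- poisson_mixture_survival(p, 3, tt)
  expect_equal(cv$S, (1 - exp(-3)) * exp(-0.15 * tt), tolerance = 1e-7)
})

test_that("IC surface level scales survival by the mean receptor count", {
  tt <- c(0, 1, 2)
  p <- bond_params(k_off = 0.15, k_on = 0, n_L = 1)
  cv <- poisson_mixture_survival(p, 250, tt)
  lev <- ic_surface_level(cv)
  expect_equal(lev$level[1L], 250 * (1 - exp(-250)), tolerance = 1e-7)
  # initial loading proportional to the mean up to the empty-patch term
  cv2 <- poisson_mixture_survival(p, 500, tt)
  expect_equal(ic_surface_level(cv2)$level[1L] / lev$level[1L], 2,
               tolerance = 1e-6)
  # the Poisson-oracle case: level = <S> * mean
  p3 <- bond_params(k_off = 1, k_on = 0.5, n_L = 3)
  cv3 <- poisson_mixture_survival(p3, 5, c(0, 2))
  expect_equal(ic_surface_level(cv3)$level[2L], 3.3121642876,
               tolerance = 1e-5)
  # single-patch curves have no defined surface level
  sp <- survival_probability(solve_master_equation(p3, 5L, c(0, 1)))
  expect_error(ic_surface_level(sp), "Poisson-averaged")
})

test_that("half-life extraction matches algebraic inversions", {
  tt <- retention_time_grid(0.01, 1e3, 300)
  p1 <- bond_params(k_off = 0.15, k_on = 0, n_L = 1)
  S1 <- survival_probability(solve_master_equation(p1, 1L, tt))
  expect_equal(half_life(S1), log(2) / 0.15, tolerance = 1e-3)
  # two independent bonds: (1 - e^-t)^2 = 1/2
  p2 <- bond_params(k_off = 1, k_on = 0, n_L = 2)
  S2 <- survival_probability(solve_master_equation(p2, 2L, tt))
  expect_equal(half_life(S2), -log(1 - 1 / sqrt(2)), tolerance = 1e-3)
  # a grid that never halves signals that it must be extended
  short <- survival_probability(
    solve_master_equation(p1, 1L, c(0, 0.1, 0.2)))
  expect_error(half_life(short), "extend the time grid")
})

test_that("density converts to mean receptor count through patch area", {
  expect_equal(density_to_mean_nR(250, 1), 250)
  expect_equal(density_to_mean_nR(250, 0.5), 125)
  expect_equal(density_to_mean_nR(0, 2), 0)
  expect_equal(density_to_mean_nR(c(10, 20), 2), c(20, 40))
  expect_error(density_to_mean_nR(-1), "non-negative")
  expect_error(density_to_mean_nR(1, 0), "positive")
})

test_that("half-life grows with density, valency and rebinding", {
  tt <- retention_time_grid(0.1, 1e6, 150)
  hl <- function(nL, kon, mean)
    half_life(poisson_mixture_survival(bond_params(0.15, kon, nL), mean, tt))
  by_density <- vapply(c(50, 150, 250, 350), function(m) hl(4, 3e-3, m),
                       numeric(1L))
  expect_true(all(diff(by_density) > 0))
  by_valency <- vapply(c(2, 4, 6, 8), function(nL) hl(nL, 1e-3, 250),
                       numeric(1L))
  expect_true(all(diff(by_valency) > 0))
  by_kon <- vapply(c(1e-4, 3e-4, 1e-3, 3e-3), function(k) hl(4, k, 250),
                   numeric(1L))
  expect_true(all(diff(by_kon) > 0))
})

test_that("parameter constructors reject invalid values", {
  expect_error(bond_params(0, 1, 2), "k_off")
  expect_error(bond_params(1, -1, 2), "k_on")
  expect_error(bond_params(1, 1, 0), "n_L")
  expect_error(bond_params(1, 1, 2.5), "n_L")
  expect_error(bond_params(1, 1, 2, patch_area = 0), "patch_area")
})
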