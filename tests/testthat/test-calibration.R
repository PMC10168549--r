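# Inverse calibration: derivative stencils, stage reconstructions, the
# residual-mortality rearrangement, and the full procedure.

test_that("finite differences use the stated stencils and are exact on linear data", {
  expect_equal(finite_difference(c(1, 3, 7, 13)), c(2, 3, 5, 6))
  expect_equal(finite_difference(rep(4.2, 9)), rep(0, 9))
  x <- 2.5 * (0:19) - 3
  expect_equal(finite_difference(x), rep(2.5, 20))
  expect_error(finite_difference(c(1, 2)), "length >= 3")
})

test_that("pupal reconstruction rearranges the adult equation and floors negatives", {
  # equilibrium: dN/dt = 0, N = 100, mu_N = 0.09, d_P = 0.3 -> P = 30
  out <- pupae_from_adults(rep(100, 3), rep(0, 3), rep(0.09, 3), rep(0.3, 3))
  expect_equal(out$P, rep(30, 3))
  expect_false(any(out$clamped))
  # direct arithmetic: (1 + 0.1 * 50) / 0.5 = 12
  out2 <- pupae_from_adults(50, 1, 0.1, 0.5)
  expect_equal(out2$P, 12)
  # a steep decline drives the raw value negative: floored and flagged
  out3 <- pupae_from_adults(100, -20, 0.1, 0.5, eps = 1e-6)
  expect_equal(out3$P, 1e-6)
  expect_true(out3$clamped)
  expect_error(pupae_from_adults(1, 0, 0.1, 0), "positive")
})

test_that("egg reconstruction decays source-free and converges to the constant-forcing fixed point", {
  r <- constant_rates(61)
  # no adults: pure exponential decay at d_E + mu_E
  E <- eggs_series(rep(0, 61), r, n_E = 63, E0 = 10)
  expect_equal(E, 10 * exp(-(r$d_E[1] + r$mu_E[1]) * (0:60)), tolerance = 1e-6)
  # constant adults: converges to n_E a N / 2 / (d_E + mu_E); ten time
  # constants of d_E + mu_E = 0.281 is ~36 days
  E2 <- eggs_series(rep(40, 61), r, n_E = 63, E0 = 1)
  fp <- 63 * r$a[1] * 40 / 2 / (r$d_E[1] + r$mu_E[1])
  expect_equal(E2[61], fp, tolerance = 1e-4)
  # default start is the quasi-equilibrium balance of the egg equation
  E3 <- eggs_series(rep(40, 61), r, n_E = 63)
  expect_equal(E3[1], fp)
  expect_equal(E3, rep(fp, 61), tolerance = 1e-6)
})

test_that("larval reconstruction recovers the larvae of a forward simulation", {
  sc <- small_scenario()
  r <- build_rate_series(sc$temps)
  n <- nrow(r)
  kappa <- 25
  mu_c <- 1.5 + 0.5 * sin(2 * pi * (0:(n - 1)) / 180)
  eq <- analytic_equilibrium(constant_rates(1, a = r$a[1], d_E = r$d_E[1],
                                            d_L = r$d_L[1], d_P = r$d_P[1],
                                            mu_E = r$mu_E[1], mu_L = r$mu_L[1],
                                            mu_P = r$mu_P[1], mu_N = r$mu_N[1]),
                             mu_c[1], kappa)
  fwd <- integrate_forward(eq, r, mu_c, kappa)
  dP <- finite_difference(fwd$P)
  rec <- larvae_series(fwd$E, fwd$P, dP, r, kappa, L0 = fwd$L[1])
  rel_rmsd <- sqrt(mean((rec$L - fwd$L)^2)) / mean(fwd$L)
  expect_lt(rel_rmsd, 0.005)
  expect_false(any(rec$clamped))
})

test_that("larval reconstruction holds a constant-rate equilibrium fixed", {
  r <- constant_rates(80)
  mu_c <- 0.8
  kappa <- 30
  eq <- analytic_equilibrium(r, mu_c, kappa)
  E <- rep(eq[["E"]], 80); P <- rep(eq[["P"]], 80)
  rec <- larvae_series(E, P, rep(0, 80), r, kappa,
                       L0 = eq[["L"]], mu_c0 = mu_c)
  expect_equal(rec$L, rep(eq[["L"]], 80), tolerance = 1e-5)
})

test_that("larval equation linearizes correctly when density terms are negligible", {
  r <- constant_rates(60)
  # huge P and kappa make d_L L^2/P and L^3/kappa negligible:
  # dL/dt = d_E E + (d_P + mu_P - d_L - mu_L) L, a linear constant-
  # coefficient equation with closed-form solution
  E <- rep(5, 60); P <- rep(1e8, 60)
  g <- r$d_P[1] + r$mu_P[1] - r$d_L[1] - r$mu_L[1]
  L0 <- 2
  rec <- larvae_series(E, P, rep(0, 60), r, kappa = Inf, L0 = L0)
  src <- r$d_E[1] * 5
  expected <- (L0 + src / g) * exp(g * (0:59)) - src / g
  expect_equal(rec$L, expected, tolerance = 1e-3)
})

test_that("residual mortality rearrangement is arithmetically exact and clamps at zero", {
  r <- constant_rates(3, d_E = 0.5, d_L = 0.2, mu_L = 0.04)
  # d_E E = 5, dL/dt = 0, L = 10, (d_L + mu_L + L^2/kappa) = 0.25
  out <- mu_c_series(rep(10, 3), rep(10, 3), rep(0, 3), r, kappa = 10000)
  expect_equal(out$mu_c, rep((5 - 2.5) / 10, 3))
  expect_false(any(out$clamped))
  # raw value below zero is stored as zero with its flag set
  r2 <- constant_rates(1, d_E = 0.1, d_L = 0.5, mu_L = 0.1)
  out2 <- mu_c_series(1, 10, 5, r2, kappa = Inf)
  expect_equal(out2$mu_c, 0)
  expect_true(out2$clamped)
})

test_that("calibration reproduces its own target under forward integration", {
  sc <- small_scenario()
  cal <- sc$calib
  expect_true(all(cal$mu_c >= 0))
  expect_lt(cal$rmsd_self, 0.02)
  n <- length(cal$mu_c)
  expect_true(all(lengths(list(cal$E, cal$L, cal$P, cal$N_reconstructed,
                               cal$N_forward)) == n))
  expect_equal(nrow(cal$clamp_flags), n)
  # kappa satisfies the dominance rule exactly at the fixed point
  expect_equal(mean(cal$L)^2 / cal$kappa_norm / mean(cal$rates$mu_L), 10,
               tolerance = 1e-8)
})

test_that("calibration is deterministic and invariant to rescaling the target", {
  sc <- small_scenario()
  a <- calibrate(sc$target$series$N_city, sc$temps)
  b <- calibrate(sc$target$series$N_city, sc$temps)
  expect_identical(a$mu_c, b$mu_c)
  # scaling the target by c rescales the normalization only; with a
  # power-of-two c the floating-point scaling is exact and mu_c is
  # bit-identical, and for arbitrary c it agrees to rounding error
  d <- calibrate(sc$target$series$N_city * 32, sc$temps)
  expect_identical(a$mu_c, d$mu_c)
  expect_identical(a$kappa_norm, d$kappa_norm)
  expect_equal(d$scale, a$scale * 32)
  e <- calibrate(sc$target$series$N_city * 37.5, sc$temps)
  expect_equal(a$mu_c, e$mu_c, tolerance = 1e-9)
})

test_that("a constant target under constant temperature yields near-constant residual mortality", {
  cfg <- thermal_config()
  df <- data.frame(day = 0:199, date = as.Date("2001-01-01") + 0:199,
                   t_mean = 26.4, t_min = 22.2, t_max = 31.7)
  temps <- temperature_series(df, cfg)
  cal <- calibrate(rep(8000, 200), temps)
  inner <- 31:199
  expect_lt(sd(cal$mu_c[inner]) / mean(cal$mu_c[inner]), 0.05)
})

test_that("calibration rejects malformed targets with the failing step named", {
  sc <- small_scenario()
  expect_error(calibrate(c(0, rep(1, 100)), sc$temps), "positive at day 0")
  expect_error(calibrate(rep(1, 10), sc$temps), "cover the target")
})
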