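test_that("recovery timescale decomposition matches the worked example", {
  p <- laf1_params()
  ts <- recovery_timescale(p)
  expect_equal(ts$tau_dil, 1190 * 1 / (3 * 94), tolerance = 1e-12)
  expect_equal(ts$tau_den, 1 / (pi^2 * 0.0017), tolerance = 1e-12)
  expect_equal(ts$tau_int, 0)
  expect_equal(ts$tau_total, 64, tolerance = 0.01)

  ## adding the inferred conductance reproduces the measured recovery time
  ts2 <- recovery_timescale(laf1_params(kappa = 7.4e-5))
  expect_equal(ts2$tau_total, 4570, tolerance = 0.005)

  ## fast-diffusion limit: only the interface term survives
  p3 <- two_phase_params(R = 2, D_den = 1e9, D_dil = 1e9, c_den = 10,
                         c_dil = 1, kappa = 0.5)
  expect_equal(recovery_timescale(p3)$tau_total, 2 / (3 * 0.5),
               tolerance = 1e-6)

  expect_error(two_phase_params(-1, 1, 1, 2, 1), "positive")
  expect_error(two_phase_params(1, 0, 1, 2, 1), "positive")
  expect_error(two_phase_params(1, 1, 1, 0.5, 1), "c_den")
  expect_error(two_phase_params(1, 1, 1, 2, 1, kappa = -2), "kappa")
})

test_that("single-exponential approximation has the right endpoints", {
  p <- laf1_params()
  tau <- recovery_timescale(p)$tau_total
  cv <- approx_recovery_curve(p, c(0, tau, 100 * tau))
  expect_equal(cv$f[1], 0)
  expect_equal(cv$f[2], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(cv$f[3], 1, tolerance = 1e-10)
  expect_error(approx_recovery_curve(p, c(-1, 2)), "non-negative")
})

test_that("equilibrium profile is a fixed point of the radial solver", {
  p <- two_phase_params(1, 0.01, 1, 100, 1, kappa = 0.1)
  fld <- solve_frap_radial(p, outer_radius = 3, t_max = 5,
                           init = "equilibrium", n_times = 25)
  drift <- max(abs(sweep(fld$values, 2, fld$values[1, ])))
  expect_lt(drift / p$c_den, 1e-10)
})

test_that("closed domains conserve mass and keep concentrations non-negative", {
  p <- two_phase_params(1, 0.01, 1, 100, 1, kappa = 0.1)
  fld <- solve_frap_radial(p, outer_radius = 3, n_times = 50)
  m <- field_mass(fld)
  expect_lt(max(abs(m / m[1] - 1)), 1e-6)
  expect_true(all(fld$values >= 0))
  expect_identical(fld$domain, "finite")

  ## unbleached fraction computed two ways: droplet content vs the
  ## dilute-phase mass balance of the closed box
  cv <- unbleached_fraction(fld)
  ins <- seq_len(fld$iface - 1L)
  m_out <- field_mass(fld) -
    as.numeric(fld$values[, ins] %*% fld$volumes[ins])
  f_balance <- m_out / (p$c_den * sum(fld$volumes[ins]))
  expect_lt(max(abs(cv$f - f_balance)), 1e-6)
  expect_equal(cv$f[1], 0, tolerance = 1e-12)
  ## recovery is monotone up to solver tolerance
  expect_gt(min(diff(cv$f)), -1e-8)
})

test_that("a coarse grid trips the interface flux self-consistency check", {
  p <- two_phase_params(1, 0.01, 1, 100, 1, kappa = 0.1)
  expect_error(solve_frap_radial(p, outer_radius = 3, n_inner = 30),
               "too coarse")
})

test_that("uniform fields give the expected unbleached fractions", {
  p <- two_phase_params(1, 0.01, 1, 100, 1, kappa = 0.1)
  fld <- solve_frap_radial(p, outer_radius = 3, t_max = 1, n_times = 12,
                           init = "equilibrium")
  full <- fld
  full$values[] <- p$c_den            # c = c_den everywhere inside
  expect_equal(max(abs(unbleached_fraction(full)$f)), 0, tolerance = 1e-12)
  half <- fld
  half$values[] <- p$c_den / 2
  expect_equal(unbleached_fraction(half)$f, rep(0.5, 12), tolerance = 1e-12)
  expect_error(unbleached_fraction(fld, R = 0.456), "grid face")
})

test_that("finite-reservoir fit recovers known parameters", {
  tt <- seq(0, 0.6, length.out = 80)
  cv <- recovery_curve(tt, 0.5 * (1 - exp(-tt / (0.5 * 0.071))))
  fit <- fit_finite_recovery(cv)
  expect_equal(fit$fit_A, 0.5, tolerance = 1e-6)
  expect_equal(fit$fit_tau, 0.071, tolerance = 1e-6)

  ## with A = 1 the fit reduces to the single-exponential form
  cv1 <- recovery_curve(tt, 1 - exp(-tt / 0.071))
  f1 <- fit_finite_recovery(cv1)
  f2 <- fit_finite_recovery(cv1, fix_A = TRUE)
  expect_equal(f1$fit_A, 1, tolerance = 1e-5)
  expect_equal(f1$fit_tau, f2$fit_tau, tolerance = 1e-5)
  expect_error(fit_finite_recovery(recovery_curve(tt[1:5], tt[1:5])),
               "10 time points")
})

test_that("recovery time grows in R, 1/kappa, 1/D_den, 1/D_dil", {
  base <- list(R = 1, D_den = 0.01, D_dil = 1, c_den = 100, c_dil = 1,
               kappa = 0.05)
  tau_of <- function(l) recovery_timescale(do.call(two_phase_params, l))$tau_total
  t0 <- tau_of(base)
  for (f in c("D_den", "D_dil", "kappa")) {
    l <- base; l[[f]] <- l[[f]] / 2
    expect_gt(tau_of(l), t0)
  }
  l <- base; l$R <- 2
  expect_gt(tau_of(l), 2 * t0)   # superlinear in R
})

test_that("with fast dilute transport the tail decay is the dense eigenmode", {
  p <- two_phase_params(1, 0.01, 1e4, 100, 1, kappa = Inf)
  fld <- solve_frap_radial(p, outer_radius = Inf, t_max = 60, n_times = 100)
  tau_tail <- tail_decay_time(unbleached_fraction(fld))
  expect_equal(tau_tail, 1 / (pi^2 * 0.01), tolerance = 0.02)
})

test_that("kappa imposed in the solver is recovered from the fitted time", {
  ## interface-resistance-dominated regimes, where the inversion is used
  for (Dr in c(20, 1000)) for (tr in c(10, 30, 70)) {
    D_den <- 0.01; D_dil <- Dr * D_den; P <- 154
    base <- recovery_timescale(two_phase_params(1, D_den, D_dil, P, 1))
    kap <- 1 / (3 * tr * (base$tau_den + base$tau_dil))
    p <- two_phase_params(1, D_den, D_dil, P, 1, kappa = kap)
    fld <- solve_frap_radial(p, outer_radius = Inf, n_times = 100)
    fit <- fit_recovery_tau(unbleached_fraction(fld))
    kap_rec <- (p$R / 3) / (fit$tau - base$tau_den - base$tau_dil)
    expect_equal(kap_rec, kap, tolerance = 0.05)
  }
})
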