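test_that("flat dilute-level profile reproduces the sharp-interface formula", {
  x <- seq(0, 5, length.out = 2001)
  pr <- interface_profile(x, rep(0.05, 2001), rep(17, 2001))
  k_int <- mean_field_kappa(pr, c_den = 7.7)
  k0 <- kappa0(c_dil = 0.05, D_dil = 17, delta = 5, c_den = 7.7)
  expect_equal(k_int, k0, tolerance = 1e-10)
  bad <- interface_profile(x, rep(0.05, 2001), rep(17, 2001))
  bad$D_local[5] <- 0
  expect_error(mean_field_kappa(bad, 7.7), "positive")
})

test_that("kappa0 scaling identities hold", {
  expect_equal(kappa0(3, 5, 10, 3), 5 / (10 * 1e-3), tolerance = 1e-12)
  expect_equal(kappa0(0.1, 2, 8, 10), 2 * kappa0(0.1, 2, 16, 10),
               tolerance = 1e-12)
})

test_that("any monotone profile beats the series-resistance bound", {
  set.seed(42)
  for (rep in 1:20) {
    c_den <- runif(1, 1, 20); c_dil <- runif(1, 0.001, 0.5) * c_den
    D_den <- runif(1, 0.001, 0.1); D_dil <- runif(1, 1, 50)
    delta <- runif(1, 1, 30)
    x <- seq(0, delta, length.out = 600)
    s <- (1 - tanh(runif(1, 1, 4) * (x / delta - runif(1, 0.3, 0.7)))) / 2
    c_eq <- c_dil + (c_den - c_dil) * s
    D <- D_dil + (D_den - D_dil) * s
    k <- mean_field_kappa(interface_profile(x, rev(c_eq), rev(D)), c_den)
    bound_inv <- (delta / D_den + delta * c_den / (c_dil * D_dil)) * 1e-3
    expect_lt(1 / k, bound_inv)
  }
  ## a narrower window gives a larger conductance (delta -> 0: kappa -> Inf)
  mk <- function(delta) {
    x <- seq(0, delta, length.out = 400)
    c_eq <- 0.05 + (7.7 - 0.05) * (1 - x / delta)
    D <- 17 + (0.013 - 17) * (1 - x / delta)
    mean_field_kappa(interface_profile(x, c_eq, D), 7.7)
  }
  ks <- vapply(c(16, 8, 4, 2), mk, numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("sticker-availability kappa obeys its exact identities", {
  set.seed(7)
  for (rep in 1:25) {
    sa <- sticker_availability(r0 = runif(1, 0.5, 2), delta = runif(1, 2, 30),
                               n = sample(4:20, 1), s = exp(runif(1, -1.5, 1.5)),
                               f_dil_A = runif(1), f_dil_B = runif(1),
                               f_den_A = runif(1), f_den_B = runif(1),
                               c_dil = 10^runif(1, -6, -4),
                               c_den = 10^runif(1, -3, -2),
                               D_dil = runif(1, 0.01, 20))
    k <- kappa_sticker_theory(sa)
    u <- u_parameter(sa)
    k0 <- kappa0(sa$c_dil, sa$D_dil, sa$delta, sa$c_den)
    expect_equal(k / k0, u, tolerance = 1e-12)
    ## symmetric under swapping sticker identities and s <-> 1/s
    swap <- sticker_availability(sa$r0, sa$delta, sa$n, 1 / sa$s,
                                 sa$f_dil_B, sa$f_dil_A, sa$f_den_B,
                                 sa$f_den_A, sa$c_dil, sa$c_den, sa$D_dil)
    expect_equal(kappa_sticker_theory(swap), k, tolerance = 1e-12)
  }
  ## saturated stickers transmit nothing
  sat <- sticker_availability(1, 10, 12, 1, 0, 0, 0, 0, 1e-5, 5e-3, 0.1)
  expect_identical(kappa_sticker_theory(sat), 0)
  expect_identical(u_parameter(sat), 0)
  ## equal stoichiometry: the combinatorial factor is 1/4
  s1 <- sticker_availability(1, 10, 12, 1, 0.5, 0.5, 0.5, 0.5, 1e-5, 5e-3, 0.1)
  expect_equal(kappa_sticker_theory(s1),
               4 * pi * 1 * 10 * 0.1 * 144 * 1e-5 / 4 * 0.5 * 1e3,
               tolerance = 1e-12)
  expect_error(sticker_availability(1, 10, 12, -1, .5, .5, .5, .5,
                                    1e-5, 5e-3, 0.1), "positive")
})

test_that("slab decay inversion has the right limits and precondition", {
  ## faster than pure diffusion allows -> no finite kappa
  d <- 20; D <- 10
  expect_error(slab_kappa_from_decay((2 * d / pi)^2 / D * 0.99, d, D, 1, 100),
               "diffusion-limited")
  ## slow decay: small-argument expansion kappa ~ c_dil d/(c_den tau)
  tau <- 1e4 * d^2 / D
  expect_equal(slab_kappa_from_decay(tau, d, D, 1, 100), d / (100 * tau),
               tolerance = 1e-4)
})

test_that("slab decay inversion round-trips a numerical slab solution", {
  for (kap in c(0.002, 0.02, 0.2)) for (d in c(20, 60)) {
    sol <- solve_slab_decay(kappa = kap, d = d, D_dil = 10, c_dil = 1,
                            c_den = 100)
    expect_equal(slab_kappa_from_decay(sol$tau, d, 10, 1, 100), kap,
                 tolerance = 0.03)
  }
})

test_that("crossover radius balances interface against diffusion", {
  p <- laf1_params(kappa = 7.4e-5)
  Rx <- crossover_radius(p)
  expect_equal(Rx, 71, tolerance = 0.02)
  ## at R = Rx the interface term equals the sum of the diffusive terms
  px <- two_phase_params(Rx, p$D_den, p$D_dil, p$c_den, p$c_dil, p$kappa)
  ts <- recovery_timescale(px)
  expect_equal(ts$tau_int, ts$tau_den + ts$tau_dil, tolerance = 1e-12)
  expect_identical(crossover_radius(laf1_params()), 0)
})
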