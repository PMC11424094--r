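test_that("survival stays at one when no labeled polymer ever touches", {
  sch <- data.frame(touch_start = rep(NA_real_, 12),
                    touch_end = rep(NA_real_, 12), enters = FALSE)
  tr <- fixture_scripted_exchange(n_dense = 6, schedule = sch, n_frames = 30,
                                  dt = 1, box = c(150, 40, 40))
  sr <- survival_protocol(tr, pair_lifetime = 10)
  expect_true(all(sr$S == 1))
  expect_true(all(is.na(sr$entry_times)))
  expect_true(is.na(sr$decay_tau))
})

test_that("scripted entry events produce the hand-computed survival curve", {
  ## threshold = 2 lifetimes * 5 = 10 time units; contacts are continuous,
  ## so a polymer unlabels 11 frames after its touch begins
  sch <- data.frame(touch_start = c(5, 10, NA, 20),
                    touch_end = c(8, 60, NA, 60),
                    enters = c(FALSE, TRUE, FALSE, TRUE))
  tr <- fixture_scripted_exchange(n_dense = 8, schedule = sch, n_frames = 60,
                                  dt = 1, box = c(150, 40, 40))
  sr <- survival_protocol(tr, pair_lifetime = 5, entry_multiple = 2,
                          min_labeled = 3)
  expect_equal(sum(!is.na(sr$entry_times)), 2)
  expect_equal(unname(sr$entry_times[sr$labeled[2]]), 21)  # 10 + 10 + 1
  expect_equal(unname(sr$entry_times[sr$labeled[4]]), 31)
  S_exp <- rep(1, 60)
  S_exp[21:60] <- 0.75
  S_exp[31:60] <- 0.5
  expect_equal(sr$S, S_exp)
  ## label bookkeeping: unlabeling is permanent and counts conserved
  expect_true(all(diff(sr$S) <= 0))
  expect_length(sr$labeled, 4)
})

test_that("too-coarse recording is rejected for bond-continuity tracking", {
  sch <- data.frame(touch_start = NA_real_, touch_end = NA_real_,
                    enters = FALSE)[rep(1, 12), ]
  tr <- fixture_scripted_exchange(n_dense = 5, schedule = sch, n_frames = 10,
                                  dt = 1, box = c(150, 40, 40))
  expect_error(survival_protocol(tr, pair_lifetime = 2, entry_multiple = 10,
                                 min_labeled = 3),
               "recording interval")
})

test_that("flux kappa is the entry rate per area per dense concentration", {
  expect_equal(flux_kappa(12, area = 100, c_den = 0.005, total_time = 60),
               12 / (60 * 100 * 0.005), tolerance = 1e-12)
  expect_error(flux_kappa(0, area = 1, c_den = 1, total_time = 1), "entry")
})

test_that("survival-fit and flux-count kappa estimates agree statistically", {
  ## stochastic scripted exchange: Poisson entries at rate 1/800 per
  ## labeled polymer; both estimators must see the same conductance
  set.seed(19)
  n_lab <- 150
  T_end <- 400
  entry <- stats::rexp(n_lab, rate = 1 / 600)
  sch <- data.frame(touch_start = ifelse(entry < T_end - 15, ceiling(entry) + 1,
                                         NA_real_),
                    touch_end = T_end, enters = entry < T_end - 15)
  tr <- fixture_scripted_exchange(n_dense = 10, schedule = sch,
                                  n_frames = T_end, dt = 1,
                                  box = c(500, 40, 40))
  sr <- survival_protocol(tr, pair_lifetime = 5, entry_multiple = 2)
  n_e <- sum(!is.na(sr$entry_times))
  expect_gt(n_e, 40)
  ## shared geometry: interface area A, dilute half-width d, so that
  ## c_dil = n_lab / (A d)
  A <- 2 * 40 * 40
  d <- 150
  c_dil <- n_lab / (A * d)
  c_den <- 0.005
  ## flux route: entries per unit labeled exposure time
  et <- sr$entry_times[sr$labeled]
  exposure <- sum(ifelse(is.na(et), T_end, et))
  k_flux <- flux_kappa(sr, area = A, c_den = c_den,
                       total_time = exposure / n_lab)
  ## survival route: exponential decay time inverted in the slow
  ## (reaction-limited) slab regime
  k_surv <- slab_kappa_from_decay(sr$decay_tau, d = d, D_dil = 1e6,
                                  c_dil = c_dil, c_den = c_den)
  expect_equal(k_flux / k_surv, 1, tolerance = 0.3)
})

test_that("droplet radius solves the closed-box mass balance", {
  R <- droplet_radius(mM_to_nm3(8.1), mM_to_nm3(0.073), 286^3, 2000)
  expect_equal(R, 36.34, tolerance = 0.001)
  ## empty dilute phase: all polymers in the droplet
  expect_equal(droplet_radius(1e-3, 0, 1e6, 500),
               (3 * 500 / (4 * pi * 1e-3))^(1 / 3), tolerance = 1e-12)
  ## exactly the dilute capacity: no droplet volume left
  expect_equal(droplet_radius(1e-3, 1e-5, 1e6, 10), 0, tolerance = 1e-12)
  expect_error(droplet_radius(1e-3, 1e-5, 1e6, 5), "no droplet")
  expect_error(droplet_radius(1e-5, 1e-6, 1e3, 999999), "larger than the box")
})

test_that("in-silico FRAP reproduces a hand-computed bookkeeping curve", {
  ## one dilute polymer joins the 5-polymer droplet at frame 13 and stays
  sch <- data.frame(touch_start = 13, touch_end = 24, enters = TRUE)
  tr <- fixture_scripted_exchange(n_dense = 5, schedule = sch, n_frames = 24,
                                  dt = 1, box = c(150, 40, 40))
  br <- insilico_frap(tr, equil_frac = 0.25, max_lag_frac = 0.5)
  expect_equal(br$f[1], 0)       # immediately after bleach
  ## expected curve from the definition: members(t) = dense 5 (+ joiner
  ## from frame 13); bleached set = members at t0; average over t0 = 6..15
  t0s <- 6:15
  nlag <- 9
  f_exp <- vapply(0:nlag, function(l) {
    mean(vapply(t0s, function(t0) {
      m0 <- c(rep(TRUE, 5), t0 >= 13)
      mt <- c(rep(TRUE, 5), t0 + l >= 13)
      sum(mt & !m0) / sum(mt)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(br$f, f_exp)
  ## the initially-outside fraction sets the closed-box plateau scale
  expect_equal(br$unbleached_fraction0,
               mean(vapply(t0s, function(t0) 1 - (5 + (t0 >= 13)) / 6,
                           numeric(1))))
})

test_that("bounce events classify touch intervals of a single polymer", {
  ## hand-built trace: dense line of 4 B-A dimers plus one roaming dimer
  ## touching at frames 3-4, 8-9, then 14-20 with a lasting bond
  n_dense <- 4
  box <- c(80, 30, 30)
  dense <- matrix(0, n_dense * 2, 3)
  for (p in seq_len(n_dense)) {
    base <- box / 2 + c((p - 1) * 1.6 - (n_dense - 1) * 0.8, 0, 0)
    dense[(p - 1) * 2 + 1, ] <- base
    dense[(p - 1) * 2 + 2, ] <- base + c(0.8, 0, 0)
  }
  site <- dense[2, ] + c(0, 0, 0.5)
  far <- c(5, 5, 5)
  nf <- 20
  coords <- array(0, c(n_dense * 2 + 2, 3, nf))
  for (k in seq_len(nf)) {
    roam1 <- if (k %in% c(3, 4, 8, 9) || k >= 14) site else far
    coords[, , k] <- rbind(dense, roam1, roam1 + c(0, 3, 0))
  }
  tr <- cg_trajectory(seq_len(nf), coords,
                      type = rep(c(2L, 1L), n_dense + 1),
                      mol = rep(seq_len(n_dense + 1), each = 2), box = box)
  be <- bounce_events(tr, polymer = n_dense + 1, pair_lifetime = 1,
                      entry_multiple = 3)
  expect_equal(nrow(be), 3)
  expect_equal(be$start, c(3, 8, 14))
  expect_equal(be$entered, c(FALSE, FALSE, TRUE))
  ## a polymer that never approaches produces no events
  tr2 <- tr
  tr2$coords[n_dense * 2 + 1:2, , ] <- far
  be2 <- bounce_events(tr2, polymer = n_dense + 1, pair_lifetime = 1)
  expect_equal(nrow(be2), 0)
})
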