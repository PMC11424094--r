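test_that("concentration unit conversion follows Avogadro arithmetic", {
  expect_equal(nm3_to_mM(8e-4), 1.33, tolerance = 0.002)
  expect_equal(mM_to_nm3(nm3_to_mM(0.0123)), 0.0123, tolerance = 1e-12)
})

test_that("slab fixture concentrations are recovered within 3 percent", {
  st <- fixture_slab_config(c_den = 4.878e-3, c_dil = 3.0e-5,
                            box = c(120, 40, 40), seed = 4)
  dp <- density_profile(state_trajectory(st), axis = "x", bins = 48,
                        recenter = FALSE)
  expect_equal(dp$c_den, 4.878e-3, tolerance = 0.03)
  expect_equal(dp$c_dil, 3.0e-5, tolerance = 0.03)
  expect_gt(dp$delta, 0)
  ## slab occupies 30% of x: dilute half-width (120 - 36)/2 = 42
  expect_equal(dp$d, 42, tolerance = 0.1)
  ## concentration bookkeeping: phases account for all polymers
  V <- prod(st$box)
  Vden <- 2 * dp$u0 * st$box[2] * st$box[3]
  expect_equal(dp$c_den * Vden + dp$c_dil * (V - Vden), max(st$mol),
               tolerance = 0.02)
})

test_that("droplet fixture concentrations are recovered radially", {
  st <- fixture_droplet_config(c_den = 4.878e-3, c_dil = 5e-5,
                               box = c(90, 90, 90), seed = 5)
  dp <- density_profile(state_trajectory(st), axis = "radial", bins = 40,
                        recenter = FALSE)
  expect_equal(dp$c_den, 4.878e-3, tolerance = 0.03)
  expect_equal(dp$c_dil, 5e-5, tolerance = 0.2)   # few dilute chains
})

test_that("a uniform ideal-gas box shows no dense phase", {
  tr <- fixture_brownian_traj(n = 150, D = 0.5, dt = 1, n_frames = 4,
                              box = c(40, 40, 40), seed = 2)
  expect_warning(dp <- density_profile(tr, axis = "x", bins = 20),
                 "no dense phase")
  expect_true(is.na(dp$c_den))
  expect_equal(dp$c_dil, 150 / 40^3, tolerance = 0.1)
})

test_that("recentering on the largest cluster is idempotent", {
  st <- fixture_slab_config(c_den = 4.878e-3, c_dil = 1e-4,
                            box = c(120, 30, 30), seed = 8)
  ## shift the whole box so the slab straddles the periodic boundary
  pos <- sweep(st$pos, 2, c(55, 0, 0), "+")
  pos <- sweep(pos, 2, st$box, function(a, L) a - L * floor(a / L))
  ctr1 <- vapply(1:3, function(a) condex:::circular_com(pos[, a], st$box[a]),
                 numeric(1))
  rec1 <- condex:::recenter_coords(pos, st$box, ctr1)
  ctr2 <- vapply(1:3, function(a) condex:::circular_com(rec1[, a], st$box[a]),
                 numeric(1))
  rec2 <- condex:::recenter_coords(rec1, st$box, ctr2)
  expect_equal(rec2, rec1, tolerance = 1e-6)
})

test_that("MSD analysis recovers known diffusion coefficients", {
  ## static trajectory: D = 0
  n <- 20
  coords <- array(rep(matrix(runif(n * 3, 0, 10), n, 3), 12), c(n, 3, 12))
  tr0 <- cg_trajectory(1:12, coords, rep(1L, n), 1:n, c(10, 10, 10))
  expect_equal(msd_diffusion(tr0)$D, 0, tolerance = 1e-12)
  ## Brownian fixture with exact D
  tr <- fixture_brownian_traj(n = 200, D = 0.5, dt = 0.5, n_frames = 300,
                              box = c(60, 60, 60), seed = 3)
  m <- msd_diffusion(tr)
  expect_equal(m$D, 0.5, tolerance = 0.05)
  expect_gt(m$r_squared, 0.98)
  expect_error(msd_diffusion(tr0, max_lag_frac = 0.01), "lags")
})

test_that("unbound fractions follow the contact rule and a brute-force scan", {
  ## all A-B pairs in contact: nothing unbound
  pos <- rbind(c(5, 5, 5), c(5.5, 5, 5), c(8, 8, 8), c(8.5, 8, 8))
  st <- sim_state(pos, c(1L, 2L, 1L, 2L), c(1L, 1L, 2L, 2L), c(20, 20, 20))
  uf <- unbound_fractions(st, labels = c(1L, 2L))
  expect_equal(uf$f_den_A + uf$f_den_B, 0)
  ## no contacts: everything unbound
  pos2 <- rbind(c(1, 5, 5), c(6, 5, 5), c(11, 5, 5), c(16, 5, 5))
  st2 <- sim_state(pos2, c(1L, 2L, 1L, 2L), c(1L, 1L, 2L, 2L), c(20, 20, 20))
  uf2 <- unbound_fractions(st2, labels = c(1L, 2L))
  expect_equal(uf2$f_dil_A, 1)
  expect_equal(uf2$f_dil_B, 1)
  ## random configuration matches the O(N^2) oracle
  set.seed(11)
  n <- 60
  pos3 <- matrix(runif(n * 3, 0, 15), n, 3)
  st3 <- sim_state(pos3, rep(c(1L, 2L), n / 2), rep(1:(n / 2), each = 2),
                   c(15, 15, 15))
  lab <- cluster_polymers(st3)
  uf3 <- unbound_fractions(st3, labels = lab)
  bound <- brute_unbound(st3)
  dense <- lab[st3$mol] == 1L
  expect_equal(uf3$f_den_A, mean(!bound[dense & st3$type == 1L]))
  expect_equal(uf3$f_dil_B, mean(!bound[!dense & st3$type == 2L]))
})

test_that("first-half/second-half diagnostic sees an equilibrated fixture", {
  tr <- fixture_brownian_traj(n = 100, D = 0.3, dt = 1, n_frames = 60,
                              box = c(30, 30, 30), seed = 6)
  chk <- equilibration_check(tr, function(t, frames) {
    mean(vapply(frames, function(k) mean(t$coords[, 1, k]), numeric(1)))
  })
  expect_lt(chk$rel_diff, 0.1)
})
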