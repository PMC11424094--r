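test_that("the fixture dispatcher builds every kind deterministically", {
  b1 <- generate_fixture(list(kind = "brownian-traj", n = 10, D = 0.2,
                              dt = 1, n_frames = 20, box = c(20, 20, 20),
                              seed = 3))
  b2 <- generate_fixture(list(kind = "brownian-traj", n = 10, D = 0.2,
                              dt = 1, n_frames = 20, box = c(20, 20, 20),
                              seed = 3))
  expect_identical(b1$coords, b2$coords)
  rc <- generate_fixture(list(kind = "recovery-curve", A = 0.5, tau = 0.071,
                              times = seq(0, 0.5, 0.005)))
  fit <- fit_finite_recovery(rc)
  expect_equal(fit$fit_A, 0.5, tolerance = 1e-8)
  expect_equal(fit$fit_tau, 0.071, tolerance = 1e-8)
  sc <- generate_fixture(list(kind = "slab-config", c_den = 4e-3,
                              c_dil = 5e-5, box = c(100, 30, 30), seed = 2))
  expect_s3_class(sc, "sim_state")
  expect_error(generate_fixture(list(kind = "nope")), "unknown fixture")
  ## infeasible target: dense slab without a single chain
  expect_error(fixture_slab_config(c_den = 1e-9, c_dil = 1e-10,
                                   box = c(10, 5, 5)), "infeasible")
})

test_that("noisy recovery-curve fixtures still fit to the target values", {
  rc <- fixture_recovery_curve(A = 0.6, tau = 0.1,
                               times = seq(0, 1, 0.005), noise_sd = 0.005,
                               seed = 10)
  fit <- fit_finite_recovery(rc)
  expect_equal(fit$fit_A, 0.6, tolerance = 0.02)
  expect_equal(fit$fit_tau, 0.1, tolerance = 0.05)
})

test_that("XYZ files round-trip coordinates, types and topology", {
  tr <- fixture_brownian_traj(n = 8, D = 0.3, dt = 1, n_frames = 5,
                              box = c(15, 15, 15), seed = 1)
  tr$type <- rep(c(1L, 2L), 4)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  tr2 <- read_xyz(f)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-7)
  expect_identical(tr2$type, tr$type)
  expect_identical(tr2$mol, tr$mol)
  expect_equal(tr2$times, tr$times)
  expect_equal(tr2$box, tr$box)
  expect_error(read_xyz(withr::local_tempfile(lines = "junk")), "malformed|parse")
})

test_that("LAMMPS dump files round-trip and are sorted by atom id", {
  tr <- fixture_brownian_traj(n = 6, D = 0.3, dt = 2, n_frames = 4,
                              box = c(12, 12, 12), seed = 2)
  tr$mol <- rep(1:3, each = 2)
  f <- withr::local_tempfile(fileext = ".dump")
  write_lammps_dump(tr, f, dt = 2)
  lines <- readLines(f)
  first_atoms <- lines[(which(lines == "ITEM: ATOMS id type mol x y z")[1] + 1):
                       (which(lines == "ITEM: ATOMS id type mol x y z")[1] + 6)]
  ids <- as.integer(vapply(strsplit(first_atoms, " "), `[`, character(1), 1))
  expect_identical(ids, 1:6)
  tr2 <- read_lammps_dump(f, dt = 2)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-7)
  expect_identical(tr2$mol, tr$mol)
  expect_equal(tr2$times, tr$times)
})

test_that("curve CSV keeps metadata and values", {
  cv <- recovery_curve(seq(0, 5, 0.5), 1 - exp(-seq(0, 5, 0.5)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, f, meta = list(units = "s", seed = 7))
  cv2 <- read_curve_csv(f)
  expect_equal(cv2$times, cv$times)
  expect_equal(cv2$f, cv$f, tolerance = 1e-10)
  expect_identical(attr(cv2, "meta")$units, "s")
})

test_that("configs round-trip and unknown keys are rejected", {
  cfg <- list(params = list(R = 1, D_den = 0.0017, D_dil = 94,
                            c_den = 1190, c_dil = 1, kappa = 7.4e-5),
              run = list(n_steps = 1000, dt = 0.005, seed = 3))
  fy <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, fy)
  expect_equal(read_config(fy), cfg, tolerance = 1e-12)
  fj <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, fj)
  expect_equal(read_config(fj), cfg, tolerance = 1e-12)
  expect_error(validate_config(list(params = list(R = 1, bogus = 2))),
               "unknown key")
  expect_error(validate_config(list(nonsense = list(a = 1))),
               "unknown config section")
})

test_that("config hash changes exactly when a parameter changes", {
  cfg <- list(params = list(R = 1, D_den = 0.0017), run = list(seed = 1))
  h <- config_hash(cfg)
  expect_identical(h, config_hash(cfg))
  ## key order is canonicalised
  expect_identical(h, config_hash(list(run = list(seed = 1),
                                       params = list(D_den = 0.0017, R = 1))))
  for (mod in list(c("params", "R", 2), c("params", "D_den", 0.002),
                   c("run", "seed", 2))) {
    cfg2 <- cfg
    cfg2[[mod[[1]]]][[mod[[2]]]] <- as.numeric(mod[[3]])
    expect_false(identical(h, config_hash(cfg2)))
  }
})

test_that("measurement JSON includes a provenance block", {
  pm <- phase_measurement(c_den = 5e-3, c_dil = 1e-5, delta = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_measurement_json(pm, f, provenance = list(seed = 4))
  back <- jsonlite::fromJSON(f)
  expect_equal(back$c_den, 5e-3)
  expect_equal(back$provenance$seed, 4)
  expect_true(nzchar(back$provenance$package))
})
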