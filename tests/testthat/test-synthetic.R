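test_that("toy dimer satisfies its interface-contact invariants", {
  d <- fix_dimer(10, 5, seed = 1)
  expect_s3_class(d, "toy_dimer")
  nat <- define_native_contacts(d$traj, 1, 4.5)
  # exactly the designed pairs are in contact at the conventional cutoff
  expect_equal(nat$resno_a, d$interface_pairs$resno_a)
  expect_equal(nat$resno_b, d$interface_pairs$resno_b)
  pd <- dissockit:::residue_pair_min_dist(d$traj, 1)
  designed <- paste(d$interface_pairs$resno_a, d$interface_pairs$resno_b)
  dmin <- pd$dmin[match(designed, paste(pd$resno_a, pd$resno_b))]
  expect_true(all(dmin < 4.5))
})

test_that("toy dimer is a pure function of its seed", {
  a <- fix_dimer(10, 5, seed = 7)
  b <- fix_dimer(10, 5, seed = 7)
  c <- fix_dimer(10, 5, seed = 8)
  expect_identical(a$traj$xyz, b$traj$xyz)
  expect_false(identical(a$traj$xyz, c$traj$xyz))
})

test_that("toy dimer rejects undersized inputs", {
  expect_error(build_toy_dimer(3, 2), "invalid parameter")
  expect_error(build_toy_dimer(10, 0), "invalid parameter")
  expect_error(build_toy_dimer(5, 9), "invalid parameter")
})

test_that("programmed dissociation stages Q as designed", {
  d <- fix_dimer(10, 4, seed = 2)
  sch <- dissociation_schedule(n_frames = 100, t_encounter = 50,
                               t_unbound = 80, noise_sigma = 0.05, seed = 3)
  tr <- generate_dissociation_trajectory(d, sch)
  expect_equal(n_frames(tr), 100)
  nat <- define_native_contacts(d$traj, 1, 4.5)
  q <- vapply(c(1, 25, 49, 60, 79, 80, 100),
              function(f) fraction_native_contacts(tr, f, nat), numeric(1))
  expect_true(all(q[1:3] == 1))                    # bound: all contacts
  persist <- mean(!d$interface_pairs$break_first)
  expect_equal(q[4], persist, tolerance = 1e-9)    # staged subset loss
  expect_equal(q[5], persist, tolerance = 1e-9)
  expect_true(all(q[6:7] == 0))                    # unbound: none
})

test_that("unbound frames exceed twice the contact cutoff everywhere", {
  d <- fix_dimer(8, 3, seed = 4)
  sch <- dissociation_schedule(20, 8, 15, noise_sigma = 0, seed = 1)
  tr <- generate_dissociation_trajectory(d, sch)
  pd <- dissockit:::residue_pair_min_dist(tr, 16)
  expect_true(min(pd$dmin) > 2 * d$contact_cutoff)
})

test_that("zero-noise bound frames equal the reference pose", {
  d <- fix_dimer(8, 3, seed = 5)
  sch <- dissociation_schedule(12, 6, 10, noise_sigma = 0, seed = 1)
  tr <- generate_dissociation_trajectory(d, sch)
  for (f in 1:5)
    expect_equal(frame_coords(tr, f), frame_coords(d$traj, 1))
})

test_that("COM distance is non-decreasing across stage windows", {
  d <- fix_dimer(10, 4, seed = 6)
  sch <- dissociation_schedule(60, 25, 45, noise_sigma = 0.05, seed = 2)
  tr <- generate_dissociation_trajectory(d, sch)
  dc <- vapply(seq_len(60), function(f) com_distance(tr, f), numeric(1))
  expect_lt(mean(dc[1:24]), mean(dc[25:44]))
  expect_lt(mean(dc[25:44]), mean(dc[45:60]))
})

test_that("schedule preconditions are enforced", {
  expect_error(dissociation_schedule(100, 80, 50), "invalid parameter")
  expect_error(dissociation_schedule(100, 1, 50), "invalid parameter")
  expect_error(dissociation_schedule(100, 20, 120), "invalid parameter")
  expect_error(dissociation_schedule(100, 20, 80, noise_sigma = -1),
               "invalid parameter")
})

test_that("unbiased harmonic Langevin reproduces the Boltzmann variance", {
  pot <- harmonic_potential(k = 10, domain = c(-3, 3))
  lv <- langevin_params(n_steps = 1e6, seed = 42)
  r <- simulate_langevin_metadynamics(pot, lv, hill_height = 0,
                                      cv_stride = 10)
  expect_equal(var(r$cv$cv), kT300 / 10, tolerance = 0.05)
  expect_equal(nrow(r$hills), 0L)
})

test_that("hill bookkeeping: one Gaussian per deposit stride", {
  pot <- harmonic_potential(k = 10, domain = c(-3, 3))
  lv <- langevin_params(n_steps = 1e6, seed = 1)
  r <- simulate_langevin_metadynamics(pot, lv, hill_height = 0.1,
                                      hill_width = 0.05,
                                      deposit_stride = 5000)
  expect_equal(nrow(r$hills), 200L)
  expect_true(all(diff(r$hills$time) > 0))
  expect_true(all(r$hills$height == 0.1))
})

test_that("seeded Langevin runs are reproducible, different seeds differ", {
  pot <- harmonic_potential()
  lv <- langevin_params(n_steps = 1e4, seed = 9)
  r1 <- simulate_langevin_metadynamics(pot, lv, 0.1)
  r2 <- simulate_langevin_metadynamics(pot, lv, 0.1)
  expect_identical(r1$cv$cv, r2$cv$cv)
  lv2 <- langevin_params(n_steps = 1e4, seed = 10)
  r3 <- simulate_langevin_metadynamics(pot, lv2, 0.1)
  expect_false(identical(r1$cv$cv, r3$cv$cv))
})

test_that("filled double well is visited on both sides", {
  pot <- double_well_potential()
  lv <- langevin_params(n_steps = 1e6, seed = 3)
  r <- simulate_langevin_metadynamics(pot, lv, 0.5, 0.05, 500)
  expect_gt(mean(r$cv$cv < 0), 0.1)
  expect_gt(mean(r$cv$cv > 0), 0.1)
})

test_that("unbiased CV histogram approaches exp(-U/kT) with more steps", {
  pot <- double_well_potential(barrier = 6, depth_difference = 2)
  ks_stat <- function(n_steps) {
    lv <- langevin_params(n_steps = n_steps, seed = 11)
    r <- simulate_langevin_metadynamics(pot, lv, 0, cv_stride = 20)
    sg <- seq(-1.1, 1.1, length.out = 400)
    p <- exp(-pot$U(sg) / kT300)
    cdf <- cumsum(p) / sum(p)
    emp <- ecdf(r$cv$cv)(sg)
    max(abs(emp - cdf))
  }
  expect_lt(ks_stat(4e5), ks_stat(2e4))
})

test_that("double-well calibration realizes the requested energies", {
  pot <- double_well_potential(wells = c(-0.5, 0.5), barrier = 12,
                               depth_difference = 4)
  expect_equal(pot$truth$barrier_height, 12, tolerance = 1e-6)
  expect_equal(pot$truth$depth_difference, 4, tolerance = 1e-6)
  expect_lt(abs(pot$truth$deep_min - (-0.5)), 0.1)
})

test_that("Langevin parameter and potential validation", {
  expect_error(langevin_params(temperature = -1), "invalid parameter")
  expect_error(langevin_params(timestep = 0), "invalid parameter")
  expect_error(tabulated_potential(seq(0, 1, 0.1), rep(Inf, 11)),
               "finite")
  expect_error(tabulated_potential(seq(0.2, 0.8, 0.1), rep(1, 7),
                                   domain = c(0, 1)), "cover")
})

test_that("trajectory PDB round trip preserves coordinates and chains", {
  d <- fix_dimer(8, 3, seed = 3)
  sch <- dissociation_schedule(10, 4, 8, noise_sigma = 0.1, seed = 1)
  tr <- generate_dissociation_trajectory(d, sch)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- load_trajectory(f, chain_a = "A", chain_b = "B")
  expect_equal(n_frames(tr2), 10)
  expect_equal(tr2$xyz, tr$xyz, tolerance = 2e-3)
  expect_equal(tr2$atoms$resno, tr$atoms$resno)
})

test_that("HILLS and COLVAR files round trip", {
  h <- hills_record(time = 1:5, center = seq(0.1, 0.5, 0.1),
                    sigma = rep(0.05, 5), height = rep(0.1, 5))
  f <- withr::local_tempfile()
  write_hills(h, f)
  h2 <- read_hills(f)
  expect_equal(h2$center, h$center, tolerance = 1e-6)
  expect_equal(nrow(h2), 5)

  cv <- structure(data.frame(time = 1:4, cv = c(1, 1.1, 1.2, 1.3)),
                  class = c("cv_series", "data.frame"))
  f2 <- withr::local_tempfile()
  write_colvar(cv, f2)
  cv2 <- read_colvar(f2)
  expect_equal(cv2$cv, cv$cv, tolerance = 1e-6)
})

test_that("malformed HILLS files are rejected with line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("# header", "1 0.1 0.05 0.1", "2 0.2 0.05 0.1",
               "1.5 0.3 0.05 0.1"), f)
  expect_error(read_hills(f), "line 4")
  writeLines(c("1 0.1 0.05 0.1", "2 0.2 -0.05 0.1"), f)
  expect_error(read_hills(f), "sigma")
})
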