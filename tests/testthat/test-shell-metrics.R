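# Published whole-shell statistics for the eight AFPs: the estimator
# arithmetic must reproduce every printed increment and partial molar volume
# from the printed inputs.
test_that("eta and v reproduce all eight reference rows from their inputs", {
  ref <- afp_reference("shell")
  expect_equal(nrow(ref), 8)
  eta <- shell_density_increment(ref$N_shell, ref$V_shell, ref$V_ex, 33.33)$eta
  expect_true(all(abs(eta - ref$eta) <= 0.002))
  v <- partial_molar_volume(ref$N_shell, ref$V_shell, ref$V_ex, 33.33)
  expect_true(all(abs(v - ref$pmv) <= 0.03))
})

test_that("a bulk-filled shell gives eta = 0 and pmv = N_A * V_ex exactly", {
  rho <- 33.33; vs <- 60; vex <- 12
  n <- rho * (vs - vex)
  expect_equal(shell_density_increment(n, vs, vex, rho)$eta, 0)
  expect_equal(partial_molar_volume(n, vs, vex, rho), 0.6022 * vex)
  # doubling rho_bulk halves (1 + eta)
  e1 <- shell_density_increment(n, vs, vex, rho)$eta
  e2 <- shell_density_increment(n, vs, vex, 2 * rho)$eta
  expect_equal(1 + e2, (1 + e1) / 2)
  expect_error(shell_density_increment(100, 10, 11), "exceed")
})

test_that("shell water counting matches construction and brute force", {
  E <- ellipsoid(c(3, 3, 3), c(1, 1, 1))
  u <- matrix(rnorm(45), ncol = 3); u <- u / sqrt(rowSums(u^2))
  d <- c(rep(0.5, 10), rep(1.5, 5))
  opos <- sweep(u * (1 + d), 2, c(3, 3, 3), "+")
  tr <- toy_water_traj(opos, box = c(7, 7, 7))
  expect_equal(as.numeric(count_shell_waters(tr, E, 1.0)), 10)

  set.seed(301)
  opos <- cbind(runif(400, 0, 7), runif(400, 0, 7), runif(400, 0, 7))
  tr <- toy_water_traj(opos, box = c(7, 7, 7))
  n <- suppressMessages(count_shell_waters(tr, E, 1.0))
  bf <- sum(sqrt(rowSums(sweep(opos, 2, c(3, 3, 3))^2)) <= 2)  # sphere: d <= 1
  expect_equal(as.numeric(n), bf)
})

test_that("excluded volume matches closed forms for one, two and overlapping spheres", {
  # isolated atom
  v1 <- excluded_volume(matrix(c(0, 0, 0), 1), 0.15, probe = 0.14)
  expect_equal(v1, 4 * pi / 3 * 0.29^3, tolerance = 0.005)
  # far-apart atoms add
  v2 <- excluded_volume(rbind(c(0, 0, 0), c(2, 0, 0)), c(0.15, 0.17), probe = 0.14)
  expect_equal(v2, 4 * pi / 3 * (0.29^3 + 0.31^3), tolerance = 0.005)
  # overlapping pair vs the analytic sphere-sphere union (lens subtraction)
  R1 <- 0.29; R2 <- 0.31; dd <- 0.35
  lens <- pi * (R1 + R2 - dd)^2 *
    (dd^2 + 2 * dd * (R1 + R2) - 3 * (R1 - R2)^2) / (12 * dd)
  vu <- 4 * pi / 3 * (R1^3 + R2^3) - lens
  v3 <- excluded_volume(rbind(c(0, 0, 0), c(dd, 0, 0)), c(0.15, 0.17), probe = 0.14)
  expect_equal(v3, vu, tolerance = 0.005)
  expect_error(excluded_volume(matrix(0, 1, 3), NA_real_), "radius")
})

test_that("block standard errors match hand computation and white-noise theory", {
  expect_equal(block_standard_error(rep(5, 12))$se, 0)
  b <- block_standard_error(c(1, 1, 1, 2, 2, 2, 3, 3, 3), 3)
  expect_equal(b$block_means, c(1, 2, 3))
  expect_equal(b$se, sd(c(1, 2, 3)) / sqrt(3))
  expect_error(block_standard_error(c(1, 2), 3), "shorter")

  # white noise: SE estimate should be unbiased for sigma/sqrt(n) on average
  set.seed(302)
  sigma <- 2; n <- 300
  ses <- replicate(400, block_standard_error(rnorm(n, sd = sigma), 3)$se)
  # E[se^2] = sigma^2/n for independent samples split into equal blocks
  expect_equal(mean(ses^2), sigma^2 / n, tolerance = 0.15)
})

test_that("whole-shell summary recovers the designed null and enhancement", {
  spec0 <- synthetic_spec(amplitude = 0, seed = 310,
                          semi_axes = c(1.2, 1.0, 0.8), box = c(4.6, 4.4, 4.4),
                          n_protein_atoms = 80)
  traj0 <- generate_hydrated_frames(spec0, 36)
  prot0 <- attr(traj0, "protein")
  s0 <- suppressMessages(shell_summary(traj0, prot0$E_true, rho_bulk = spec0$rho_bulk))
  ex0 <- expected_shell_stats(spec0, prot0, n_qmc = 6e5)
  expect_lt(abs(s0$eta - ex0$eta_expected), 3 * pmax(s0$eta_se, 1e-4))
  expect_equal(s0$rho_shell, s0$N_shell / (s0$V_shell - s0$V_ex))
  expect_equal(s0$V_ex, ex0$V_ex, tolerance = 0.01)

  spec1 <- synthetic_spec(amplitude = 0.10, seed = 311,
                          semi_axes = c(1.2, 1.0, 0.8), box = c(4.6, 4.4, 4.4),
                          n_protein_atoms = 80)
  traj1 <- generate_hydrated_frames(spec1, 36)
  prot1 <- attr(traj1, "protein")
  s1 <- suppressMessages(shell_summary(traj1, prot1$E_true, rho_bulk = spec1$rho_bulk))
  ex1 <- expected_shell_stats(spec1, prot1, n_qmc = 6e5)
  expect_lt(abs(s1$eta - ex1$eta_expected), 3 * pmax(s1$eta_se, 1e-4))
  expect_gt(s1$eta, s0$eta)
})

test_that("shell eta agrees with the shell-averaged ratio profile", {
  # two routes to the same physics: eta from counts over the geometric
  # water-accessible volume, versus the shell-integrated real/fictitious
  # count ratio. They differ only through the slightly different inner
  # boundaries (SAS probe contact vs vdW contact in the overlay), so
  # agreement is asserted to ~0.02 rather than to sampling error.
  spec <- synthetic_spec(amplitude = 0.08, seed = 330,
                         semi_axes = c(1.0, 0.9, 0.8), box = c(4.2, 4.0, 4.0),
                         n_protein_atoms = 60)
  prot <- generate_protein_mimic(spec)
  traj <- generate_hydrated_frames(spec, 24, prot)
  bulk <- generate_bulk_box(spec, 24)
  fict <- fictitious_configs(traj, bulk)
  s <- suppressMessages(shell_summary(traj, prot$E_true, rho_bulk = spec$rho_bulk))
  dp_r <- density_profile(traj, prot$E_true, 0.05, 1.0)
  dp_f <- density_profile(fict, prot$E_true, 0.05, 1.0)
  eta_profile <- sum(dp_r$counts) / sum(dp_f$counts) - 1
  expect_lt(abs(s$eta - eta_profile), 0.025)
})

test_that("measured bulk density agrees with the generator target", {
  spec <- synthetic_spec(semi_axes = NULL, box = c(4, 4, 4), seed = 320)
  bulk <- generate_bulk_box(spec, 25)
  # 3 standard errors of the 25-frame mean (per-frame counts are Poisson)
  expect_equal(measure_bulk_density(bulk), spec$rho_bulk, tolerance = 0.013)
})
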