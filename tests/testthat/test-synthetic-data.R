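test_that("identical spec and seed give bit-identical configurations", {
  spec <- synthetic_spec(amplitude = 0.05, seed = 501,
                         semi_axes = c(1.0, 0.9, 0.8), box = c(4.2, 4.0, 4.0),
                         n_protein_atoms = 50)
  t1 <- generate_hydrated_frames(spec, 3)
  t2 <- generate_hydrated_frames(spec, 3)
  expect_identical(t1$frames[[2]]$xyz, t2$frames[[2]]$xyz)
  b1 <- generate_bulk_box(spec, 2)
  b2 <- generate_bulk_box(spec, 2)
  expect_identical(b1$frames[[1]]$xyz, b2$frames[[1]]$xyz)
  # different seeds differ
  spec2 <- synthetic_spec(amplitude = 0.05, seed = 502,
                          semi_axes = c(1.0, 0.9, 0.8), box = c(4.2, 4.0, 4.0),
                          n_protein_atoms = 50)
  t3 <- generate_hydrated_frames(spec2, 3)
  expect_false(nrow(t1$frames[[1]]$xyz) == nrow(t3$frames[[1]]$xyz) &&
               isTRUE(all.equal(t1$frames[[1]]$xyz, t3$frames[[1]]$xyz)))
})

test_that("bulk frames hit the target count and respect the hard core", {
  spec <- synthetic_spec(semi_axes = NULL, box = c(3.6, 3.6, 3.6), seed = 503)
  bulk <- generate_bulk_box(spec, 12)
  V <- prod(spec$box)
  counts <- vapply(seq_len(n_frames(bulk)), function(i) {
    length(intersect(water_oxygen_idx(bulk$atoms), bulk$frames[[i]]$atom_idx))
  }, integer(1))
  expect_lt(abs(mean(counts) - spec$rho_bulk * V),
            3.5 * sqrt(spec$rho_bulk * V / 12))
  # minimum image O-O distances never undercut the hard core
  for (i in c(1, 7)) {
    idx <- bulk$frames[[i]]$atom_idx
    orows <- match(intersect(water_oxygen_idx(bulk$atoms), idx), idx)
    op <- bulk$frames[[i]]$xyz[orows, ]
    dmin <- Inf
    for (j in seq_len(nrow(op) - 1)) {
      dd <- sweep(op[(j + 1):nrow(op), , drop = FALSE], 2, op[j, ])
      dd <- dd - spec$box[1] * round(dd / spec$box[1])
      dmin <- min(dmin, sqrt(rowSums(dd^2)))
    }
    expect_gte(dmin, spec$hard_core - 1e-12)
  }
  # zero-density request yields no waters
  spec0 <- synthetic_spec(semi_axes = NULL, box = c(3, 3, 3), rho_bulk = 0, seed = 1)
  b0 <- generate_bulk_box(spec0, 1)
  expect_equal(length(intersect(water_oxygen_idx(b0$atoms), b0$frames[[1]]$atom_idx)), 0)
})

test_that("infeasible hard-core densities error out", {
  expect_error(synthetic_spec(semi_axes = NULL, rho_bulk = 60, seed = 1), "infeasible")
})

test_that("the protein mimic matches its spec geometrically and chemically", {
  spec <- synthetic_spec(seed = 504, semi_axes = c(1.4, 1.1, 0.9),
                         box = c(5.2, 5.0, 4.8), n_protein_atoms = 400)
  prot <- generate_protein_mimic(spec)
  f <- fit_ellipsoid(prot$xyz)
  expect_equal(f$semi_axes, spec$semi_axes, tolerance = 0.06)
  expect_equal(f$center, spec$box / 2, tolerance = 0.05)
  expect_true(all(prot$atoms$vdw_radius >= 0.15 & prot$atoms$vdw_radius <= 0.19))
  # patch polar fractions within binomial error of the spec
  for (p in c("IBS", "NIBS")) {
    sel <- prot$atoms$patch == p
    frac <- mean(abs(prot$atoms$partial_charge[sel]) > 0.2)
    n <- sum(sel)
    expect_lt(abs(frac - spec$polar_fraction[[p]]),
              3.5 * sqrt(spec$polar_fraction[[p]] * (1 - spec$polar_fraction[[p]]) / n))
  }
  # minimal 4-atom case still yields a usable, non-coplanar cloud
  spec4 <- synthetic_spec(seed = 505, semi_axes = c(1.0, 0.9, 0.8),
                          box = c(4.2, 4.0, 4.0), n_protein_atoms = 4)
  prot4 <- generate_protein_mimic(spec4)
  expect_s3_class(fit_ellipsoid(prot4$xyz), "ellipsoid")
})

test_that("hydrated frames carry the designed intensity: null and step recovery", {
  spec <- synthetic_spec(amplitude = 0, seed = 506,
                         semi_axes = c(1.0, 0.9, 0.8), box = c(4.2, 4.0, 4.0),
                         n_protein_atoms = 60)
  traj <- generate_hydrated_frames(spec, 40)
  prot <- attr(traj, "protein")
  s <- suppressMessages(shell_summary(traj, prot$E_true, rho_bulk = spec$rho_bulk))
  ex <- expected_shell_stats(spec, prot, n_qmc = 6e5)
  expect_lt(abs(ex$eta_expected), 0.005)  # null spec has no enhancement
  expect_lt(abs(s$eta - ex$eta_expected), 3 * pmax(s$eta_se, 1e-4))
})

test_that("waters never intrude into the solvent-accessible surface region", {
  spec <- synthetic_spec(amplitude = 0.05, seed = 507,
                         semi_axes = c(1.0, 0.9, 0.8), box = c(4.2, 4.0, 4.0),
                         n_protein_atoms = 60)
  traj <- generate_hydrated_frames(spec, 4)
  prot <- attr(traj, "protein")
  for (i in 1:4) {
    idx <- traj$frames[[i]]$atom_idx
    orows <- match(intersect(water_oxygen_idx(traj$atoms), idx), idx)
    op <- traj$frames[[i]]$xyz[orows, ]
    marg <- Inf
    for (j in seq_len(nrow(prot$xyz))) {
      marg <- pmin(marg, sqrt(rowSums(sweep(op, 2, prot$xyz[j, ])^2)) -
                          prot$atoms$vdw_radius[j])
    }
    expect_gte(min(marg), spec$probe)
  }
})

test_that("patchwise enhancement orders the surface densities as designed", {
  spec <- synthetic_spec(amplitude = c(IBS = 0.04, NIBS = 0.08), seed = 508,
                         semi_axes = c(1.2, 1.0, 0.9), box = c(4.6, 4.4, 4.4),
                         n_protein_atoms = 90)
  prot <- generate_protein_mimic(spec)
  exI <- expected_surface_stats(spec, prot, "IBS", n_qmc = 4e5)
  exN <- expected_surface_stats(spec, prot, "NIBS", n_qmc = 4e5)
  expect_lt(exI$eta_surf_expected, exN$eta_surf_expected)
})

test_that("a synthetic system written to disk reads back equivalent", {
  spec <- synthetic_spec(amplitude = 0.05, seed = 509,
                         semi_axes = c(1.0, 0.9, 0.8), box = c(4.2, 4.0, 4.0),
                         n_protein_atoms = 40)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_system(spec, dir, n_frames = 3)
  expect_true(all(file.exists(unlist(paths))))
  suppressMessages(back <- read_trajectory(paths$trajectory))
  traj <- generate_hydrated_frames(spec, 3)
  expect_equal(n_frames(back), 3)
  i1 <- traj$frames[[1]]$atom_idx
  expect_equal(back$frames[[1]]$xyz, traj$frames[[1]]$xyz, tolerance = 2e-3,
               ignore_attr = TRUE)
})
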