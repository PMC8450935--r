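test_that("profile of an empty box is identically zero", {
  tr <- toy_water_traj(matrix(numeric(0), 0, 3), box = c(6, 6, 6))
  E <- ellipsoid(c(3, 3, 3), c(0.8, 0.7, 0.6))
  dp <- density_profile(tr, E, 0.1, 1.5)
  expect_true(all(dp$density == 0))
  expect_true(all(dp$bin_volumes > 0))
})

test_that("uniform Poisson waters give a flat profile at the known density", {
  set.seed(201)
  box <- c(6, 6, 6)
  rho <- 20
  frames <- lapply(1:40, function(i) {
    n <- rpois(1, rho * prod(box))
    cbind(runif(n, 0, 6), runif(n, 0, 6), runif(n, 0, 6))
  })
  tr <- solvated_traj(toy_protein_traj(runif_ellipsoid(10, c(0.5, 0.5, 0.5), c(3, 3, 3)),
                                       box = box),
                      frames, box = box)
  E <- ellipsoid(c(3, 3, 3), c(1, 1, 1))
  dp <- density_profile(tr, E, 0.1, 1.5)
  # every bin within 3 Poisson standard errors of rho
  se <- sqrt(rho * dp$bin_volumes * dp$n_frames) / (dp$bin_volumes * dp$n_frames)
  expect_true(all(abs(dp$density - rho) < 3.5 * se))
  # totals are conserved: density * volume * frames = counts
  expect_equal(sum(dp$density * dp$bin_volumes * dp$n_frames), sum(dp$counts))
})

test_that("waters confined to a slab appear only in that slab's bins", {
  set.seed(202)
  E <- ellipsoid(c(3, 3, 3), c(1, 1, 1))
  # place oxygens at distances in [0.2, 0.4) along random directions
  u <- matrix(rnorm(300), ncol = 3); u <- u / sqrt(rowSums(u^2))
  d <- runif(100, 0.2, 0.3999)
  opos <- sweep(u * (1 + d), 2, c(3, 3, 3), "+")
  tr <- toy_water_traj(opos, box = c(6, 6, 6))
  dp <- density_profile(tr, E, 0.1, 1.0)
  hot <- dp$mid > 0.2 & dp$mid < 0.4
  expect_true(all(dp$density[!hot] == 0))
  expect_true(all(dp$density[hot] > 0))
  expect_equal(sum(dp$counts), 100)
})

test_that("a shell wider than the box is refused", {
  tr <- toy_water_traj(matrix(c(1, 1, 1), 1), box = c(4, 4, 4))
  E <- ellipsoid(c(2, 2, 2), c(1.5, 1, 1))
  expect_error(density_profile(tr, E, 0.1, 1.0), "periodic|box")
})

test_that("overlay removal respects the sum-of-radii threshold exactly", {
  prot <- toy_protein_traj(matrix(c(2, 2, 2), 1), box = c(5, 5, 5), radius = 0.17)
  mk_bulk <- function(d) toy_water_traj(matrix(c(2 + d, 2, 2), 1), box = c(5, 5, 5))
  # water O radius 0.152 here: threshold at 0.17 + 0.152 = 0.322
  near <- mk_bulk(0.32); far <- mk_bulk(0.33)
  near$atoms$vdw_radius[near$atoms$element == "O"] <- 0.152
  far$atoms$vdw_radius[far$atoms$element == "O"] <- 0.152
  f_near <- fictitious_configs(prot, near)
  f_far <- fictitious_configs(prot, far)
  expect_equal(sum(f_near$atoms$is_water[f_near$frames[[1]]$atom_idx]), 0)
  expect_equal(sum(f_far$atoms$is_water[f_far$frames[[1]]$atom_idx]), 3)
})

test_that("with no protein the overlay returns the bulk waters unchanged", {
  set.seed(203)
  bulk <- toy_water_traj(cbind(runif(50, 0, 5), runif(50, 0, 5), runif(50, 0, 5)))
  prot <- toy_protein_traj(matrix(numeric(0), 0, 3))
  fict <- fictitious_configs(prot, bulk)
  expect_equal(nrow(fict$frames[[1]]$xyz), 150)
  expect_equal(fict$frames[[1]]$xyz, bulk$frames[[1]]$xyz, ignore_attr = TRUE)
})

test_that("overlay removal matches a brute-force all-pairs check on random configs", {
  set.seed(204)
  box <- c(4, 4, 4)
  pxyz <- runif_ellipsoid(30, c(0.8, 0.7, 0.6), c(2, 2, 2))
  prot <- toy_protein_traj(pxyz, box = box, radius = runif(30, 0.15, 0.19))
  prot$atoms$vdw_radius <- runif(30, 0.15, 0.19)
  opos <- cbind(runif(200, 0, 4), runif(200, 0, 4), runif(200, 0, 4))
  bulk <- toy_water_traj(opos, box = box)
  fict <- fictitious_configs(prot, bulk)
  kept_mol <- unique(bulk$atoms$residue_id[fict$frames[[1]]$atom_idx[-(1:30)] - 30])

  # independent brute force in plain R over every water atom / protein atom pair
  wat <- bulk$atoms
  removed <- logical(200)
  for (m in 1:200) {
    rows <- which(wat$residue_id == m)
    for (r in rows) {
      dd <- sweep(pxyz, 2, bulk$frames[[1]]$xyz[r, ])
      dd <- dd - box[1] * round(dd / box[1])
      if (any(sqrt(rowSums(dd^2)) < prot$atoms$vdw_radius + wat$vdw_radius[r])) {
        removed[m] <- TRUE; break
      }
    }
  }
  expect_setequal(kept_mol, which(!removed))
  # conservation: waters out = waters in - removed
  expect_equal(length(kept_mol), 200 - sum(removed))
})

test_that("ratio profile handles identity, scaling and undefined bins", {
  set.seed(205)
  E <- ellipsoid(c(3, 3, 3), c(1, 1, 1))
  frames <- lapply(1:10, function(i) {
    n <- rpois(1, 15 * 216)
    cbind(runif(n, 0, 6), runif(n, 0, 6), runif(n, 0, 6))
  })
  tr <- toy_water_traj(frames, box = c(6, 6, 6))
  dp <- density_profile(tr, E, 0.1, 1.2)
  rp <- ratio_profile(dp, dp)
  expect_equal(rp$ratio, rep(1, length(rp$ratio)))

  dp2 <- dp
  dp2$counts <- dp$counts * 1.1
  rp2 <- ratio_profile(dp2, dp)
  expect_equal(rp2$ratio, rep(1.1, length(rp2$ratio)))

  dp0 <- dp; dp0$counts[, 1] <- 0
  rp0 <- ratio_profile(dp, dp0)
  expect_true(is.na(rp0$ratio[1]) && !rp0$defined[1])
  expect_false(any(is.infinite(rp0$ratio), na.rm = TRUE))

  dp3 <- density_profile(tr, E, 0.1, 1.0)
  expect_error(ratio_profile(dp, dp3), "binning")
})

test_that("plateau detection finds the step and the trivial cases", {
  mk_rp <- function(ratio, width = 0.1) {
    edges <- seq(0, by = width, length.out = length(ratio) + 1)
    structure(list(edges = edges, mid = edges[-1] - width / 2, ratio = ratio,
                   stderr = rep(0, length(ratio)), defined = rep(TRUE, length(ratio))),
              class = "ratio_profile")
  }
  expect_equal(as.numeric(detect_plateau(mk_rp(rep(1, 15)), 0.02, 3)), 0)
  step <- c(rep(1.1, 10), rep(1.0, 5))
  expect_equal(as.numeric(detect_plateau(mk_rp(step), 0.02, 3)), 1.0)
  none <- mk_rp(rep(1.2, 15))
  res <- detect_plateau(none, 0.02, 3)
  expect_true(is.na(res) && !attr(res, "found"))
})

test_that("plateau is recovered within one bin on noisy synthetic decays", {
  set.seed(206)
  hits <- 0
  for (rep in 1:50) {
    width <- 0.05
    mid <- seq(width / 2, 1.5, by = width)
    ratio <- 1 + 0.12 * (mid < 0.6) + rnorm(length(mid), sd = 0.004)
    edges <- seq(0, by = width, length.out = length(mid) + 1)
    rp <- structure(list(edges = edges, mid = mid, ratio = ratio,
                         stderr = rep(0.004, length(mid)),
                         defined = rep(TRUE, length(mid))),
                    class = "ratio_profile")
    p <- detect_plateau(rp, tol = 0.03, run_length = 4)
    if (abs(p - 0.6) <= width + 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 48)
})
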