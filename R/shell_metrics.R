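#' Conversion factor nm^3 -> l/mol (Avogadro constant x 1e-24)
#' @keywords internal
NM3_TO_L_PER_MOL <- 0.6022

#' Default bulk water number density (molecules nm^-3, SPC water at 300 K)
#' @export
RHO_BULK_DEFAULT <- 33.33

#' Count water molecules inside the hydration shell
#'
#' Number of water oxygens whose signed distance from the ellipsoid surface
#' is at most `thickness`. There is no inner cutoff: waters cannot physically
#' penetrate the protein, and any interior waters present in synthetic
#' configurations are counted and reported via the `n_interior` attribute.
#'
#' @param traj a `hydration_traj`.
#' @param E the reference `"ellipsoid"`.
#' @param thickness shell thickness (nm), default 1.0.
#' @return integer vector of per-frame counts, with attribute `n_interior`
#'   (per-frame counts of waters with negative distance).
#' @export
count_shell_waters <- function(traj, E, thickness = 1.0) {
  if (thickness <= 0) stopf("shell thickness must be positive")
  oidx <- water_oxygen_idx(traj$atoms)
  nf <- n_frames(traj)
  counts <- integer(nf)
  interior <- integer(nf)
  for (i in seq_len(nf)) {
    fr <- traj$frames[[i]]
    present <- frame_atoms(traj, i)
    rows <- match(intersect(oidx, present), present)
    if (length(rows) == 0) next
    xyz <- fr$xyz[rows, , drop = FALSE]
    if (!is.null(fr$box) && all(!is.na(fr$box))) {
      xyz <- wrap_about(xyz, fr$box, E$center)
      Ec <- E; Ec$center <- fr$box / 2
      d <- ellipsoid_distance(xyz, Ec)
    } else {
      d <- ellipsoid_distance(xyz, E)
    }
    counts[i] <- sum(d <= thickness)
    interior[i] <- sum(d < 0)
  }
  if (any(interior > 0)) {
    message(sprintf("count_shell_waters: %d water(s) found inside the ellipsoid across %d frame(s); counted",
                    sum(interior), sum(interior > 0)))
  }
  structure(counts, n_interior = interior)
}

#' Protein excluded volume (volume enclosed by the solvent-accessible surface)
#'
#' Volume of the union of spheres of radius `vdw_radius + probe` centred on
#' the atoms, evaluated by counting grid cells whose centre falls inside any
#' sphere. With the default 0.02 nm spacing the relative error is well below
#' 0.5% for protein-sized solutes.
#'
#' @param xyz n x 3 atom coordinates (nm).
#' @param radii per-atom vdW radii (nm).
#' @param probe probe radius (nm), default 0.14.
#' @param spacing grid spacing (nm), default 0.01 (relative error well below
#'   0.5% even for single-atom solutes).
#' @return volume in nm^3.
#' @export
excluded_volume <- function(xyz, radii, probe = 0.14, spacing = 0.01) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  if (length(radii) != nrow(xyz)) stopf("radii length does not match atom count")
  if (anyNA(radii)) stopf("missing vdW radius; run assign_parameters() first")
  R <- radii + probe
  lo <- apply(xyz - R, 2, min) - spacing
  hi <- apply(xyz + R, 2, max) + spacing
  gx <- seq(lo[1] + spacing / 2, hi[1], by = spacing)
  gy <- seq(lo[2] + spacing / 2, hi[2], by = spacing)
  gz <- seq(lo[3] + spacing / 2, hi[3], by = spacing)
  # process the z axis in blocks so the occupancy array stays modest
  zblock <- max(1L, min(length(gz), ceiling(2e7 / (length(gx) * length(gy)))))
  n_in <- 0
  z0 <- 1L
  while (z0 <= length(gz)) {
    z1 <- min(z0 + zblock - 1L, length(gz))
    gzb <- gz[z0:z1]
    occ <- array(FALSE, c(length(gx), length(gy), length(gzb)))
    for (i in seq_len(nrow(xyz))) {
      iz <- which(abs(gzb - xyz[i, 3]) <= R[i])
      if (!length(iz)) next
      ix <- which(abs(gx - xyz[i, 1]) <= R[i])
      iy <- which(abs(gy - xyz[i, 2]) <= R[i])
      if (!length(ix) || !length(iy)) next
      d2 <- outer(outer((gx[ix] - xyz[i, 1])^2, (gy[iy] - xyz[i, 2])^2, "+"),
                  (gzb[iz] - xyz[i, 3])^2, "+")
      occ[ix, iy, iz] <- occ[ix, iy, iz] | as.vector(d2 <= R[i]^2)
    }
    n_in <- n_in + sum(occ)
    z0 <- z1 + 1L
  }
  n_in * spacing^3
}

#' Hydration-shell density and relative density increment
#'
#' The shell density is the mean shell water count over the water-accessible
#' shell volume, \eqn{\rho_{shell} = \langle N_{shell}\rangle /
#' (\langle V_{shell}\rangle - \langle V_{ex}\rangle)}, and the relative
#' increment over bulk is \eqn{\eta = \rho_{shell}/\rho_{bulk} - 1}.
#'
#' @param n_shell mean shell water count.
#' @param v_shell mean shell (outer-parallel-body) volume, nm^3.
#' @param v_ex mean excluded volume, nm^3; must be below `v_shell`.
#' @param rho_bulk bulk number density, molecules nm^-3.
#' @return list with `rho_shell` (nm^-3) and `eta` (dimensionless).
#' @export
shell_density_increment <- function(n_shell, v_shell, v_ex, rho_bulk = RHO_BULK_DEFAULT) {
  if (any(v_shell <= v_ex)) stopf("v_shell must exceed v_ex")
  if (rho_bulk <= 0) stopf("rho_bulk must be positive")
  rho_shell <- n_shell / (v_shell - v_ex)
  list(rho_shell = rho_shell, eta = rho_shell / rho_bulk - 1)
}

#' Partial molar volume from shell statistics
#'
#' The excess number of shell waters over a bulk-filled shell is
#' \eqn{\Delta N = \langle N_{shell}\rangle - \rho_{bulk}(\langle
#' V_{shell}\rangle - \langle V_{ex}\rangle)}; the partial molar volume is
#' \eqn{v = N_A (V_{ex} - \Delta N/\rho_{bulk})} converted with
#' 1 nm^3 = 0.6022 l/mol.
#'
#' @inheritParams shell_density_increment
#' @return partial molar volume in l/mol.
#' @export
partial_molar_volume <- function(n_shell, v_shell, v_ex, rho_bulk = RHO_BULK_DEFAULT) {
  if (any(v_shell <= v_ex)) stopf("v_shell must exceed v_ex")
  if (rho_bulk <= 0) stopf("rho_bulk must be positive")
  dN <- n_shell - rho_bulk * (v_shell - v_ex)
  NM3_TO_L_PER_MOL * (v_ex - dN / rho_bulk)
}

#' Block (subtrajectory) standard error
#'
#' Splits a per-frame series into `n_blocks` contiguous blocks (remainder
#' frames go to the last block) and returns the mean and the standard error
#' of the block means, `sd(block means)/sqrt(n_blocks)`.
#'
#' @param x numeric per-frame series.
#' @param n_blocks number of subtrajectories, default 3.
#' @return list with `mean`, `se`, and `block_means`.
#' @export
block_standard_error <- function(x, n_blocks = 3) {
  n <- length(x)
  if (n < n_blocks) stopf("series of length %d is shorter than %d blocks", n, n_blocks)
  size <- n %/% n_blocks
  starts <- (seq_len(n_blocks) - 1) * size + 1
  ends <- c(starts[-1] - 1, n)
  bm <- vapply(seq_len(n_blocks), function(b) mean(x[starts[b]:ends[b]]), numeric(1))
  list(mean = mean(x), se = sd(bm) / sqrt(n_blocks), block_means = bm)
}

# TRUE when the protein coordinates are identical in every frame.
protein_is_static <- function(traj, prot_idx) {
  if (n_frames(traj) < 2) return(TRUE)
  ref <- frame_xyz(traj, 1, prot_idx)
  for (i in 2:n_frames(traj)) {
    if (max(abs(frame_xyz(traj, i, prot_idx) - ref)) > 1e-12) return(FALSE)
  }
  TRUE
}

#' Whole-shell summary: excluded volume, shell volume, counts, eta, and v
#'
#' Computes the full row of whole-shell statistics for one protein: the
#' shell volume as the outer-parallel-body volume of the ellipsoid at the
#' shell thickness, the excluded volume averaged over frames, the shell
#' water count averaged over frames, the relative density increment and the
#' partial molar volume, with standard errors over contiguous
#' subtrajectories.
#'
#' @param traj solvated trajectory with radii assigned.
#' @param E the reference `"ellipsoid"`.
#' @param thickness shell thickness (nm).
#' @param probe probe radius for the excluded volume (nm).
#' @param rho_bulk bulk density (molecules nm^-3); if `bulk_traj` is given
#'   the measured bulk density is used and both values are reported.
#' @param n_blocks subtrajectories for error estimation.
#' @param bulk_traj optional bulk-water trajectory used to measure
#'   `rho_bulk`.
#' @return an object of class `"shell_summary"` (a one-row data frame with
#'   `V_ex`, `V_shell`, `N_shell`, `rho_shell`, `rho_bulk`, `eta`, `pmv` and
#'   `*_se` columns).
#' @export
shell_summary <- function(traj, E, thickness = 1.0, probe = 0.14,
                          rho_bulk = RHO_BULK_DEFAULT, n_blocks = 3,
                          bulk_traj = NULL) {
  rho_bulk_input <- rho_bulk
  if (!is.null(bulk_traj)) rho_bulk <- measure_bulk_density(bulk_traj)
  nshell <- as.numeric(count_shell_waters(traj, E, thickness))
  v_shell <- parallel_body_volume(E, thickness)
  prot_idx <- which(!traj$atoms$is_water)
  if (length(prot_idx) == 0) stopf("trajectory contains no protein atoms")
  radii <- traj$atoms$vdw_radius[prot_idx]
  if (protein_is_static(traj, prot_idx)) {
    vex <- rep(excluded_volume(frame_xyz(traj, 1, prot_idx), radii, probe), n_frames(traj))
  } else {
    vex <- vapply(seq_len(n_frames(traj)), function(i) {
      excluded_volume(frame_xyz(traj, i, prot_idx), radii, probe)
    }, numeric(1))
  }
  bn <- block_standard_error(nshell, n_blocks)
  bv <- block_standard_error(vex, n_blocks)
  inc <- shell_density_increment(bn$mean, v_shell, bv$mean, rho_bulk)
  pmv <- partial_molar_volume(bn$mean, v_shell, bv$mean, rho_bulk)
  eta_blocks <- shell_density_increment(bn$block_means, v_shell, bv$block_means, rho_bulk)$eta
  pmv_blocks <- partial_molar_volume(bn$block_means, v_shell, bv$block_means, rho_bulk)
  out <- data.frame(
    V_ex = bv$mean, V_ex_se = bv$se,
    V_shell = v_shell,
    N_shell = bn$mean, N_shell_se = bn$se,
    rho_shell = inc$rho_shell, rho_bulk = rho_bulk,
    eta = inc$eta, eta_se = sd(eta_blocks) / sqrt(n_blocks),
    pmv = pmv, pmv_se = sd(pmv_blocks) / sqrt(n_blocks)
  )
  attr(out, "rho_bulk_input") <- rho_bulk_input
  class(out) <- c("shell_summary", "data.frame")
  out
}

#' Measure bulk water density from a bulk trajectory
#'
#' @param bulk_traj pure-water trajectory with boxes.
#' @return mean number density (molecules nm^-3).
#' @export
measure_bulk_density <- function(bulk_traj) {
  oidx <- water_oxygen_idx(bulk_traj$atoms)
  dens <- vapply(seq_len(n_frames(bulk_traj)), function(i) {
    fr <- bulk_traj$frames[[i]]
    n <- length(intersect(oidx, frame_atoms(bulk_traj, i)))
    n / prod(fr$box)
  }, numeric(1))
  mean(dens)
}
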