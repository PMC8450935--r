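#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Classic point-sampling SASA: each atom is expanded by the probe radius and
#' covered with a deterministic near-uniform (Fibonacci spiral) point set; a
#' point is accessible when outside every neighbouring expanded sphere. The
#' per-atom areas sum exactly to the total.
#'
#' @param xyz n x 3 atom coordinates (nm).
#' @param radii per-atom vdW radii (nm).
#' @param probe probe radius (nm), default 0.14.
#' @param n_points sample points per atom, default 960.
#' @return object of class `"sasa"`: `per_atom_area` (nm^2), `total` (nm^2),
#'   plus the call parameters.
#' @export
compute_sasa <- function(xyz, radii, probe = 0.14, n_points = 960) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (length(radii) != n) stopf("radii length does not match atom count")
  if (anyNA(radii)) stopf("missing vdW radius; run assign_parameters() first")
  R <- radii + probe
  U <- fibonacci_sphere(n_points)
  area <- numeric(n)
  dmat <- as.matrix(dist(xyz))
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] < R[i] + R & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    P <- sweep(U * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      acc <- acc & (rowSums(sweep(P, 2, xyz[j, ])^2) > R[j]^2)
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  structure(list(per_atom_area = area, total = sum(area),
                 probe = probe, n_points = n_points),
            class = "sasa")
}

#' @export
print.sasa <- function(x, ...) {
  cat(sprintf("sasa: %d atoms, total %.3f nm^2 (probe %.2f nm, %d points/atom)\n",
              length(x$per_atom_area), x$total, x$probe, x$n_points))
  invisible(x)
}

#' Hydrophobic fraction of the solvent-accessible surface
#'
#' Atoms with partial charge in `[-threshold, threshold]` (inclusive at the
#' boundary) are classified nonpolar; the hydrophobic area is the sum of
#' their accessible areas.
#'
#' @param sasa a `"sasa"` result.
#' @param charges per-atom partial charges (e), same order as the SASA atoms.
#' @param threshold charge magnitude below which an atom is nonpolar (e).
#' @return list with `S_pho` (nm^2) and `fraction` (`S_pho / total`).
#' @export
hydrophobic_fraction <- function(sasa, charges, threshold = 0.2) {
  if (length(charges) != length(sasa$per_atom_area)) {
    stopf("charges length does not match the SASA atom count")
  }
  if (anyNA(charges)) stopf("missing partial charge; run assign_parameters() first")
  S_pho <- sum(sasa$per_atom_area[abs(charges) <= threshold])
  list(S_pho = S_pho, fraction = if (sasa$total > 0) S_pho / sasa$total else NA_real_)
}

#' SASA of a residue selection within the whole protein
#'
#' Sums per-atom accessible areas over the selection's atoms. The areas come
#' from the whole-protein SASA computation, so buried parts of the selection
#' contribute their true (occluded) exposure, not that of an isolated
#' fragment.
#'
#' @param sasa whole-protein `"sasa"` result.
#' @param atoms the atom table the SASA was computed over (same order).
#' @param sel a `"surface_selection"`.
#' @return area in nm^2.
#' @export
selection_sasa <- function(sasa, atoms, sel) {
  key <- paste(atoms$chain_id, atoms$residue_id)
  skey <- paste(sel$residues$chain_id, sel$residues$residue_id)
  idx <- key %in% skey
  if (!any(idx)) stopf("selection %s matches no atoms of the SASA computation", sel$label)
  sum(sasa$per_atom_area[idx])
}

#' Count waters within a cutoff of a surface's heavy atoms
#'
#' Number of distinct water molecules whose oxygen lies within `cutoff`
#' (minimum image) of any heavy atom of the selection, per frame. Each water
#' is counted at most once per selection; waters near the IBS/NIBS boundary
#' may be counted by both surfaces, which are tallied independently.
#'
#' @param traj a `hydration_traj` (real or fictitious).
#' @param sel_idx topology indices of the selection's heavy atoms.
#' @param cutoff distance cutoff (nm), default 0.55.
#' @return integer vector of per-frame counts.
#' @export
surface_water_count <- function(traj, sel_idx, cutoff = 0.55) {
  if (cutoff <= 0) stopf("cutoff must be positive")
  oidx <- water_oxygen_idx(traj$atoms)
  nf <- n_frames(traj)
  counts <- integer(nf)
  for (i in seq_len(nf)) {
    fr <- traj$frames[[i]]
    present <- frame_atoms(traj, i)
    orow <- match(intersect(oidx, present), present)
    srow <- match(sel_idx, present)
    if (anyNA(srow)) stopf("frame %d lacks %d selection atom(s)", i, sum(is.na(srow)))
    if (length(orow) == 0) next
    box <- fr$box
    if (is.null(box) || anyNA(box)) box <- c(-1, -1, -1)
    margin <- min_margin_cpp(fr$xyz[orow, , drop = FALSE],
                             fr$xyz[srow, , drop = FALSE],
                             rep(0, length(srow)), box)
    counts[i] <- sum(margin <= cutoff)
  }
  counts
}

#' Per-surface local density and relative increment
#'
#' The local surface density is the ratio of means \eqn{\rho_{surf} =
#' \langle N_w\rangle / \langle S\rangle} with the water count and the SASA
#' averaged separately along the trajectory. The same count on the
#' fictitious (bulk-filled) configurations, using the real protein's SASA
#' series, gives \eqn{\rho_{surf}^{fict}}, and the relative increment is
#' \eqn{\eta_{surf} = \rho_{surf}/\rho_{surf}^{fict} - 1}.
#'
#' @param traj real solvated trajectory.
#' @param fict fictitious trajectory from [fictitious_configs()].
#' @param sel_idx topology indices of the selection's heavy atoms (the same
#'   protein atoms must head the fictitious topology, as built by
#'   [fictitious_configs()]).
#' @param sasa_series per-frame SASA (nm^2) of the selection.
#' @param label selection label for reporting.
#' @param cutoff counting cutoff (nm), default 0.55.
#' @param n_blocks subtrajectories for the error estimate.
#' @param fict_sel_idx selection indices in the fictitious topology when they
#'   differ from `sel_idx`.
#' @return object of class `"surface_density"` (one-row data frame with
#'   `N_w`, `S`, `rho_surf`, `rho_surf_fict`, `eta_surf`, `eta_surf_se`).
#' @export
surface_density <- function(traj, fict, sel_idx, sasa_series, label = "WHOLE",
                            cutoff = 0.55, n_blocks = 3, fict_sel_idx = sel_idx) {
  nw <- surface_water_count(traj, sel_idx, cutoff)
  nf <- surface_water_count(fict, fict_sel_idx, cutoff)
  if (length(sasa_series) == 1) sasa_series <- rep(sasa_series, length(nw))
  if (mean(nf) == 0) stopf("fictitious surface density is zero for selection %s", label)
  S_mean <- mean(sasa_series)
  rho <- mean(nw) / S_mean
  rho_f <- mean(nf) / S_mean
  eta <- rho / rho_f - 1
  br <- block_standard_error(nw, n_blocks)$block_means
  bf <- block_standard_error(nf, n_blocks)$block_means
  eta_blocks <- br / bf - 1
  out <- data.frame(selection = label, N_w = mean(nw), S = S_mean,
                    rho_surf = rho, rho_surf_fict = rho_f,
                    eta_surf = eta, eta_surf_se = sd(eta_blocks) / sqrt(n_blocks),
                    stringsAsFactors = FALSE)
  class(out) <- c("surface_density", "data.frame")
  out
}
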